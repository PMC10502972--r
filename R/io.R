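#' Read a grayscale OCT B-scan from PNG or TIFF
#'
#' Intensities are rescaled to \[0, 1\]. Only single-channel images are
#' accepted. If a sidecar metadata file `<path>.meta` exists (plain-text
#' `key: value` lines), `axial_scale` and `orientation` are taken from it;
#' explicit arguments override the sidecar.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @param axial_scale Axial pixel pitch, µm/pixel.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return A [bscan()].
#' @export
read_bscan <- function(path, axial_scale = NULL, orientation = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- read_gray(path)
  meta <- read_sidecar(paste0(path, ".meta"))
  bscan(px,
        axial_scale = axial_scale %||% meta$axial_scale %||% 3.87,
        orientation = orientation %||% meta$orientation %||% "horizontal")
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1) {
      stop("multi-channel image rejected: B-scans must be single-channel grayscale")
    }
    arr <- arr[, , 1]
  }
  pmin(pmax(arr, 0), 1)
}

#' Write a B-scan (and optionally its mask) to disk
#'
#' The image is written as 8-bit grayscale PNG or 16-bit grayscale TIFF
#' (by file extension); intensities are quantized to the bit depth. The
#' mask, when given, is written as an 8-bit PNG (0/255) next to the image.
#' A plain-text sidecar `<path>.meta` records axial scale, orientation and
#' any extra metadata.
#'
#' @param b A [bscan()].
#' @param path Destination (`.png` or `.tif`/`.tiff`).
#' @param mask Optional [seg_mask()]; written to `<path stem>_mask.png`.
#' @param extra Named list of extra sidecar entries (e.g. `fovea_column`,
#'   `seed`).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(b, path, mask = NULL, extra = list()) {
  stopifnot(inherits(b, "bscan"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(round(b$pixels * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(round(b$pixels * 65535) / 65535, path,
                    bits.per.sample = 16L)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  meta <- c(list(axial_scale = b$axial_scale, orientation = b$orientation),
            extra)
  writeLines(paste0(names(meta), ": ", unlist(meta)), paste0(path, ".meta"))
  if (!is.null(mask)) {
    mp <- paste0(tools::file_path_sans_ext(path), "_mask.png")
    png::writePNG(as_mask_matrix(mask) + 0, mp)
  }
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, ":\\s*")
  out <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = ":")),
                         vapply(kv, `[[`, character(1), 1))
  for (num in c("axial_scale", "fovea_column", "seed")) {
    if (!is.null(out[[num]])) out[[num]] <- as.numeric(out[[num]])
  }
  out
}

#' Write / read SfChT measurements as CSV
#'
#' One row per scan plus one `scan_id = "mean"` row per subject-visit with
#' the averaged SfChT. Thickness values are reported in µm to 2 decimals;
#' a round-trip read reproduces them to that precision.
#'
#' @param measurements An `sfcht_measurement` (or list of them).
#' @param path Destination CSV.
#' @return `write_measurements` returns `path` invisibly;
#'   `read_measurements` returns the measurement tibble.
#' @export
write_measurements <- function(measurements, path) {
  if (inherits(measurements, "sfcht_measurement")) {
    measurements <- list(measurements)
  }
  if (!length(measurements)) stop("no measurements to write")
  rows <- purrr::map(measurements, function(m) {
    stopifnot(inherits(m, "sfcht_measurement"))
    per_scan <- tibble::tibble(
      subject = m$subject, visit = m$visit,
      scan_id = as.character(m$scan_id), orientation = m$orientation,
      fovea_col = m$fovea_col,
      sfcht_um = round(m$sfcht_um, 2),
      mean_sfcht_um = NA_real_
    )
    mean_row <- tibble::tibble(
      subject = m$subject[1], visit = m$visit[1],
      scan_id = "mean", orientation = NA_character_, fovea_col = NA_integer_,
      sfcht_um = NA_real_,
      mean_sfcht_um = round(attr(m, "mean_sfcht_um"), 2)
    )
    dplyr::bind_rows(per_scan, mean_row)
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a dataset manifest CSV
#'
#' The manifest has columns `image_path`, `mask_path` (optional entries may
#' be empty), `orientation`, `axial_scale`; paths are resolved relative to
#' the manifest location. Images and masks are loaded into a dataset tibble
#' usable by [train_network()], [evaluate_models()] and [measure_sfcht()].
#'
#' @param path Manifest CSV.
#' @return Tibble with `id`, `image`, `mask`, `orientation`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("image_path" %in% names(man))
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(root, p))
  imgs <- purrr::map(seq_len(nrow(man)), function(i) {
    read_bscan(resolve(man$image_path[i]),
               axial_scale = if ("axial_scale" %in% names(man)) man$axial_scale[i],
               orientation = if ("orientation" %in% names(man)) man$orientation[i])
  })
  masks <- if ("mask_path" %in% names(man)) {
    purrr::map(seq_len(nrow(man)), function(i) {
      mp <- man$mask_path[i]
      if (is.na(mp) || !nzchar(mp)) return(NULL)
      seg_mask(matrix(as.integer(read_gray(resolve(mp)) > 0.5),
                      nrow = nrow(imgs[[i]]$pixels)))
    })
  } else {
    vector("list", nrow(man))
  }
  tibble::tibble(
    id = seq_len(nrow(man)),
    image = imgs,
    mask = masks,
    orientation = purrr::map_chr(imgs, "orientation")
  )
}
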