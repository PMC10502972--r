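#' Binarize a probability map
#'
#' Pixels with probability greater than or equal to `threshold` (inclusive,
#' by documented convention) become foreground.
#'
#' @param p Probability matrix or `prob_map`.
#' @param threshold Decision threshold, default 0.5.
#' @return A [seg_mask()].
#' @export
binarize <- function(p, threshold = 0.5) {
  p <- as_prob_matrix(p)
  seg_mask(matrix(as.integer(p >= threshold), nrow(p), ncol(p)))
}

#' Keep only the largest connected foreground component
#'
#' Eliminates false-positive islands outside the choroid by retaining the
#' maximally connected foreground domain. Component size ties are broken by
#' keeping the component containing the pixel with the smallest (row, col)
#' in lexicographic order. An empty mask is returned unchanged.
#'
#' @param m A binary matrix or [seg_mask()].
#' @param connectivity 8 (default) or 4 neighbourhood.
#' @param fill_holes Fill enclosed background holes (e.g. choroidal lacunae)
#'   inside the retained component before returning.
#' @return A [seg_mask()].
#' @export
largest_component <- function(m, connectivity = 8, fill_holes = TRUE) {
  mm <- as_mask_matrix(m)
  if (sum(mm) == 0) return(seg_mask(mm))
  lab <- label_components(mm, connectivity)
  sizes <- tabulate(lab[lab > 0])
  best <- max(sizes)
  cand <- which(sizes == best)
  if (length(cand) > 1) {
    # lexicographic (row, col) minimum among tied components
    first_pix <- vapply(cand, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      ord <- order(idx[, 1], idx[, 2])
      idx[ord[1], 1] * (ncol(mm) + 1) + idx[ord[1], 2]
    }, numeric(1))
    keep <- cand[which.min(first_pix)]
  } else {
    keep <- cand
  }
  out <- matrix(as.integer(lab == keep), nrow(mm), ncol(mm))
  if (fill_holes) {
    out <- matrix(as.integer(EBImage::imageData(
      EBImage::fillHull(EBImage::as.Image(out))) > 0), nrow(mm), ncol(mm))
  }
  seg_mask(out)
}

label_components <- function(m, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  # EBImage::bwlabel uses 4-connectivity; 8-connectivity merges its labels
  # across diagonal adjacencies with a union-find pass
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(m)))
  storage.mode(lab) <- "integer"
  if (connectivity == 4 || max(lab) < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- c(0L, root)
  matrix(remap[lab + 1L], h, w)
}

#' Locate the fovea as the thinnest-retina column
#'
#' Within the central `band_width` columns of the B-scan, Otsu thresholding
#' separates the bright retinal band from the background; the retina pixel
#' count per column is the retinal thickness proxy, and the column with the
#' minimum count is the fovea. Ties are broken toward the image centre. For
#' an even-width image the band is centred one column to the left.
#'
#' When a choroid mask is supplied, counting is restricted to rows above the
#' choroid's top boundary in each column, which isolates the retinal layer
#' from choroidal intensity structure.
#'
#' @param b A [bscan()] or intensity matrix.
#' @param mask Optional choroid [seg_mask()] used to bound the retina rows.
#' @param band_width Number of central columns (A-scans) searched, default 25.
#' @return Integer column index of the fovea (1-based, full-image coordinates).
#' @export
locate_fovea <- function(b, mask = NULL, band_width = 25) {
  px <- if (inherits(b, "bscan")) b$pixels else b
  w <- ncol(px)
  if (w <= band_width) stop("image must be wider than band_width")
  centre <- (w + 1) %/% 2
  half <- (band_width - 1) %/% 2
  band_cols <- (centre - half):(centre - half + band_width - 1)
  band <- px[, band_cols, drop = FALSE]
  if (max(band) - min(band) < 1e-12) {
    stop("Otsu thresholding is degenerate: constant intensity in the central band")
  }
  thr <- EBImage::otsu(EBImage::as.Image(band), range = c(0, 1))
  retina <- band >= thr
  if (!is.null(mask)) {
    mm <- as_mask_matrix(mask)[, band_cols, drop = FALSE]
    for (j in seq_along(band_cols)) {
      top <- which(mm[, j] == 1)
      if (length(top)) retina[min(top):nrow(retina), j] <- FALSE
    }
  }
  counts <- colSums(retina)
  best <- which(counts == min(counts))
  if (length(best) > 1) {
    # tie-break toward the image centre
    best <- best[which.min(abs(band_cols[best] - centre))]
  }
  as.integer(band_cols[best])
}

#' Per-column choroid thickness profile
#'
#' Thickness in each column is the foreground pixel count times the axial
#' pixel pitch. Columns without any foreground are flagged invalid.
#'
#' @param m A [seg_mask()] or binary matrix.
#' @param axial_scale Axial pixel pitch, micrometres per pixel (> 0).
#' @return A tibble with columns `column`, `thickness_px`, `thickness_um`,
#'   `valid`; the axial scale is attached as attribute `axial_scale`.
#' @export
thickness_profile <- function(m, axial_scale) {
  mm <- as_mask_matrix(m)
  if (!is.numeric(axial_scale) || length(axial_scale) != 1 || axial_scale <= 0) {
    stop("axial_scale must be a single positive number (µm/pixel)")
  }
  counts <- colSums(mm)
  out <- tibble::tibble(
    column = seq_len(ncol(mm)),
    thickness_px = as.integer(counts),
    thickness_um = counts * axial_scale,
    valid = counts > 0
  )
  attr(out, "axial_scale") <- axial_scale
  out
}

#' Measure subfoveal choroidal thickness from a set of line scans
#'
#' For each scan, the fovea column is located on the B-scan ([locate_fovea()])
#' and the subfoveal choroidal thickness (SfChT) is the choroid thickness at
#' that column ([thickness_profile()]). The reported SfChT is the arithmetic
#' mean over the available scans (clinically: three horizontal and three
#' vertical line scans). A scan whose subfoveal column carries no choroid
#' foreground is excluded with a warning; if all scans are excluded the
#' measurement is rejected.
#'
#' @param scans A tibble as returned by [generate_scan_set()] (columns
#'   `scan_id`, `orientation`, `image`, `mask`), or a plain list of
#'   `list(image =, mask =)` pairs (1 to 6 scans).
#' @param band_width Central search band for [locate_fovea()].
#' @param subject,visit Optional identifiers carried into the result.
#' @return An `sfcht_measurement`: a tibble with one row per scan (`scan_id`,
#'   `orientation`, `fovea_col`, `sfcht_um`, `used`) plus attributes
#'   `mean_sfcht_um`, `subject`, `visit`. [glance()][generics::glance]-style
#'   summary via `summary()`.
#' @export
measure_sfcht <- function(scans, band_width = 25, subject = NA_character_,
                          visit = NA_character_) {
  scans <- normalize_scan_table(scans)
  if (nrow(scans) < 1 || nrow(scans) > 6) {
    stop("measure_sfcht expects between 1 and 6 scans")
  }
  res <- purrr::map(seq_len(nrow(scans)), function(i) {
    img <- scans$image[[i]]
    msk <- scans$mask[[i]]
    fc <- locate_fovea(img, mask = msk, band_width = band_width)
    prof <- thickness_profile(msk, axial_scale = img$axial_scale)
    list(fovea_col = fc,
         sfcht_um = prof$thickness_um[fc],
         valid = prof$valid[fc])
  })
  out <- tibble::tibble(
    subject = subject,
    visit = visit,
    scan_id = scans$scan_id,
    orientation = scans$orientation,
    fovea_col = purrr::map_int(res, "fovea_col"),
    sfcht_um = purrr::map_dbl(res, "sfcht_um"),
    used = purrr::map_lgl(res, "valid")
  )
  if (any(!out$used)) {
    warning(sum(!out$used), " scan(s) excluded: no choroid foreground at the ",
            "subfoveal column")
  }
  if (!any(out$used)) stop("all scans excluded; SfChT cannot be measured")
  attr(out, "mean_sfcht_um") <- mean(out$sfcht_um[out$used])
  class(out) <- c("sfcht_measurement", class(out))
  out
}

normalize_scan_table <- function(scans) {
  if (is.data.frame(scans)) {
    stopifnot(all(c("image", "mask") %in% names(scans)))
    if (!"scan_id" %in% names(scans)) scans$scan_id <- seq_len(nrow(scans))
    if (!"orientation" %in% names(scans)) {
      scans$orientation <- purrr::map_chr(scans$image, "orientation")
    }
    return(scans)
  }
  tibble::tibble(
    scan_id = seq_along(scans),
    orientation = purrr::map_chr(scans, ~ .x$image$orientation),
    image = purrr::map(scans, "image"),
    mask = purrr::map(scans, "mask")
  )
}

#' @export
summary.sfcht_measurement <- function(object, ...) {
  cat(sprintf("SfChT: %.2f µm (mean of %d scan(s))\n",
              attr(object, "mean_sfcht_um"), sum(object$used)))
  invisible(attr(object, "mean_sfcht_um"))
}

#' Mean SfChT of a measurement
#' @param m An `sfcht_measurement`.
#' @return Mean subfoveal choroidal thickness in micrometres.
#' @export
mean_sfcht <- function(m) {
  stopifnot(inherits(m, "sfcht_measurement"))
  attr(m, "mean_sfcht_um")
}
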