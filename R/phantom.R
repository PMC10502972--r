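#' B-scan and segmentation-mask containers
#'
#' A `bscan` holds one grayscale OCT B-scan as a numeric matrix with
#' intensities in \[0, 1\] (row 1 = anterior/vitreous at the top, columns =
#' lateral A-scan positions) plus acquisition metadata: the axial pixel pitch
#' in micrometres per pixel and the scan orientation. A `seg_mask` holds a
#' binary matrix on the same grid where 1 marks the choroid (the area between
#' the retinal pigment epithelium and the chorio-scleral boundary).
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\] (`bscan`) or
#'   0/1 values (`seg_mask`).
#' @param axial_scale Axial pixel pitch, micrometres per pixel (> 0).
#' @param orientation `"horizontal"` or `"vertical"` line-scan orientation.
#' @return An object of class `bscan` or `seg_mask`.
#' @export
bscan <- function(pixels, axial_scale = 3.87, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("bscan intensities must lie in [0, 1]")
  }
  if (!is.numeric(axial_scale) || length(axial_scale) != 1 || axial_scale <= 0) {
    stop("axial_scale must be a single positive number (µm/pixel)")
  }
  structure(list(pixels = pixels, axial_scale = axial_scale,
                 orientation = orientation), class = "bscan")
}

#' @rdname bscan
#' @export
seg_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!all(pixels %in% c(0, 1))) stop("seg_mask values must be exactly 0 or 1")
  structure(list(pixels = pixels), class = "seg_mask")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %dx%d, %s, %.2f µm/px>\n",
              nrow(x$pixels), ncol(x$pixels), x$orientation, x$axial_scale))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask %dx%d, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Specification of a synthetic layered OCT phantom
#'
#' Describes a layered B-scan phantom: dark vitreous on top, a bright retinal
#' band whose thickness profile carves a foveal pit, the brightest thin RPE
#' line, a medium-intensity choroid band (optionally with darker lacunae),
#' and a dim sclera below. Layer boundaries are integer rows, so the ground
#' truth choroid mask is pixel-exact: its per-column thickness equals
#' `choroid_thickness_profile` everywhere.
#'
#' The default geometry emulates a Spectralis-like 496x768 B-scan; the
#' `"tiny"` preset (64x96) keeps CPU training and testing fast. The default
#' axial pitch of 3.87 um/pixel is a typical spectral-domain OCT value.
#'
#' @param preset `"full"` (496x768) or `"tiny"` (64x96); sets all geometry
#'   defaults, each overridable.
#' @param height,width Image size in pixels.
#' @param ilm_depth Row of the inner limiting membrane at the foveal pit
#'   bottom reference (top retinal surface anchor).
#' @param retina_thickness_profile,choroid_thickness_profile Optional integer
#'   vectors (length `width`) of per-column band thicknesses; built from the
#'   preset geometry when omitted.
#' @param fovea_column Column index of the foveal pit (unique thinnest-retina
#'   column).
#' @param pit_depth,pit_sigma Depth (px) and lateral Gaussian width (px) of
#'   the foveal pit carved into the retinal band.
#' @param axial_scale Axial pixel pitch, um/pixel.
#' @param speckle_sigma Standard deviation of multiplicative speckle noise.
#' @param lacunae_density Fraction in \[0, 1\] controlling how many dark
#'   choroidal lacunae are drawn.
#' @param rpe_thickness RPE band thickness in pixels.
#' @param seed Integer seed making the phantom fully reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(preset = c("full", "tiny"),
                         height = NULL, width = NULL,
                         ilm_depth = NULL,
                         retina_thickness_profile = NULL,
                         choroid_thickness_profile = NULL,
                         fovea_column = NULL,
                         pit_depth = NULL, pit_sigma = NULL,
                         axial_scale = 3.87,
                         speckle_sigma = 0.04,
                         lacunae_density = 0.1,
                         rpe_thickness = NULL,
                         seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(height = 496L, width = 768L, ilm_depth = 60L, retina_base = 110L,
         pit_depth = 45L, pit_sigma = 40, choroid_base = 72L, dome = 12L,
         rpe_thickness = 3L)
  } else {
    list(height = 64L, width = 96L, ilm_depth = 8L, retina_base = 16L,
         pit_depth = 7L, pit_sigma = 6, choroid_base = 18L, dome = 3L,
         rpe_thickness = 2L)
  }
  height <- as.integer(height %||% def$height)
  width <- as.integer(width %||% def$width)
  ilm_depth <- as.integer(ilm_depth %||% def$ilm_depth)
  fovea_column <- as.integer(fovea_column %||% ((width %/% 2) + 1L))
  pit_depth <- pit_depth %||% def$pit_depth
  pit_sigma <- pit_sigma %||% def$pit_sigma
  rpe_thickness <- as.integer(rpe_thickness %||% def$rpe_thickness)

  cols <- seq_len(width)
  if (is.null(retina_thickness_profile)) {
    ret <- def$retina_base -
      round(pit_depth * exp(-((cols - fovea_column)^2) / (2 * pit_sigma^2)))
    # integer rounding can tie neighbouring columns with the pit centre;
    # deepen the centre by one pixel so the argmin is unique
    if (sum(ret == min(ret)) > 1 || which.min(ret) != fovea_column) {
      ret[fovea_column] <- min(ret) - 1L
    }
    retina_thickness_profile <- as.integer(ret)
  }
  if (is.null(choroid_thickness_profile)) {
    choroid_thickness_profile <- as.integer(
      round(def$choroid_base + def$dome * cos((cols - fovea_column) * pi / width))
    )
  }
  spec <- structure(list(
    height = height, width = width, ilm_depth = ilm_depth,
    retina_thickness_profile = as.integer(retina_thickness_profile),
    choroid_thickness_profile = as.integer(choroid_thickness_profile),
    fovea_column = fovea_column,
    rpe_thickness = rpe_thickness,
    axial_scale = axial_scale,
    speckle_sigma = speckle_sigma,
    lacunae_density = lacunae_density,
    seed = as.integer(seed),
    preset = preset
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(retina_thickness_profile) != width ||
        length(choroid_thickness_profile) != width) {
      stop("thickness profiles must have one entry per column (width = ", width, ")")
    }
    if (any(retina_thickness_profile < 1) || any(choroid_thickness_profile < 1)) {
      stop("all layer thicknesses must be positive")
    }
    max_extent <- ilm_depth + max(retina_thickness_profile) + rpe_thickness +
      max(choroid_thickness_profile)
    if (max_extent > height) {
      stop("invalid geometry: layers exceed image height (need ", max_extent,
           " rows, have ", height, ")")
    }
    if (ilm_depth < 1) stop("ilm_depth must be >= 1")
    mins <- which(retina_thickness_profile == min(retina_thickness_profile))
    if (length(mins) != 1 || mins != fovea_column) {
      stop("fovea_column must be the unique argmin of retina_thickness_profile")
    }
    if (axial_scale <= 0) stop("axial_scale must be > 0")
    if (speckle_sigma < 0) stop("speckle_sigma must be >= 0")
    if (lacunae_density < 0 || lacunae_density > 1) {
      stop("lacunae_density must lie in [0, 1]")
    }
  })
  spec
}

# band intensities of the noise-free phantom (design constants)
phantom_intensities <- function() {
  c(vitreous = 0.05, retina = 0.60, rpe = 0.95, choroid = 0.35,
    sclera = 0.15, lacuna = 0.12)
}

#' Generate a synthetic layered OCT B-scan with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: piecewise-constant
#' intensity bands (vitreous dark, retina bright, RPE brightest, choroid
#' medium with optional darker elliptical lacunae, sclera dim), multiplicative
#' speckle noise clipped to \[0, 1\], and a pixel-exact binary choroid mask.
#' Only the intensity image receives noise; the mask is drawn from integer
#' boundary rows so its per-column thickness equals the generating profile
#' exactly. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param orientation Orientation tag stored on the returned `bscan`.
#' @return A list with elements `image` (a [bscan()]) and `mask` (a
#'   [seg_mask()]).
#' @examples
#' ph <- generate_phantom(phantom_spec("tiny", seed = 7))
#' range(ph$image$pixels)
#' @export
generate_phantom <- function(spec, orientation = "horizontal") {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  ints <- phantom_intensities()
  h <- spec$height; w <- spec$width
  ret <- spec$retina_thickness_profile
  cho <- spec$choroid_thickness_profile
  rpe_top <- spec$ilm_depth + max(ret)          # first RPE row (flat)
  cho_top <- rpe_top + spec$rpe_thickness       # first choroid row (flat)

  img <- matrix(ints["sclera"], h, w)
  mask <- matrix(0L, h, w)
  rows <- seq_len(h)
  for (c in seq_len(w)) {
    ilm <- rpe_top - ret[c]                     # first retina row in this column
    img[rows < ilm, c] <- ints["vitreous"]
    img[rows >= ilm & rows < rpe_top, c] <- ints["retina"]
    img[rows >= rpe_top & rows < cho_top, c] <- ints["rpe"]
    cho_bot <- cho_top + cho[c]                 # first sclera row
    img[rows >= cho_top & rows < cho_bot, c] <- ints["choroid"]
    mask[rows >= cho_top & rows < cho_bot, c] <- 1L
  }

  img <- with_seed(spec$seed, {
    if (spec$lacunae_density > 0) {
      img <- draw_lacunae(img, cho_top, cho, spec$lacunae_density, ints["lacuna"])
    }
    if (spec$speckle_sigma > 0) {
      img <- img * (1 + spec$speckle_sigma * matrix(stats::rnorm(h * w), h, w))
    }
    img
  })
  img <- pmin(pmax(img, 0), 1)

  list(image = bscan(img, axial_scale = spec$axial_scale, orientation = orientation),
       mask = seg_mask(mask))
}

# seeded dark ellipses fully inside the choroid band
draw_lacunae <- function(img, cho_top, cho, density, intensity) {
  w <- ncol(img)
  n <- round(density * w / 8)
  if (n == 0) return(img)
  for (i in seq_len(n)) {
    a <- stats::runif(1, 2, max(3, w / 40))          # lateral semi-axis
    cc <- stats::runif(1, 1 + a, w - a)              # centre column
    span <- max(1L, floor(cc - a)):min(w, ceiling(cc + a))
    min_cho <- min(cho[span])
    b_max <- floor(min_cho / 2) - 1
    if (b_max < 1) next
    b <- stats::runif(1, 1, max(1, min(b_max, nrow(img) / 20)))
    cr <- stats::runif(1, cho_top + b, cho_top + min_cho - 1 - b)
    for (c in span) {
      dy <- b * sqrt(pmax(0, 1 - ((c - cc) / a)^2))
      if (dy < 0.5) next
      rws <- max(1L, ceiling(cr - dy)):min(nrow(img), floor(cr + dy))
      img[rws, c] <- intensity
    }
  }
  img
}

#' Generate a set of six line scans (3 horizontal + 3 vertical)
#'
#' Emulates the clinical acquisition of three horizontal and three vertical
#' line scans through the fovea. Each scan is a phantom rendered from `spec`
#' with a small seeded integer jitter (a per-scan constant shift of the
#' choroid thickness profile, up to `jitter_px` pixels) and its own noise
#' seed, so per-scan subfoveal thickness is recoverable exactly from its
#' ground-truth mask.
#'
#' @param spec A [phantom_spec()].
#' @param jitter_seed Integer seed for the jitter and per-scan noise seeds.
#' @param jitter_px Maximum absolute choroid-thickness jitter in pixels.
#' @return A tibble with columns `scan_id`, `orientation`, `image`
#'   (list of [bscan()]), `mask` (list of [seg_mask()]) and
#'   `thickness_jitter_px`.
#' @export
generate_scan_set <- function(spec, jitter_seed = 1L, jitter_px = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  draws <- with_seed(as.integer(jitter_seed), list(
    deltas = sample(seq(-jitter_px, jitter_px), 6, replace = TRUE),
    seeds = sample.int(.Machine$integer.max %/% 2, 6)
  ))
  orientation <- rep(c("horizontal", "vertical"), each = 3)
  scans <- purrr::map(1:6, function(i) {
    sp <- spec
    sp$choroid_thickness_profile <- pmax(
      1L, spec$choroid_thickness_profile + as.integer(draws$deltas[i]))
    sp$seed <- draws$seeds[i]
    sp <- validate_phantom_spec(sp)
    generate_phantom(sp, orientation = orientation[i])
  })
  tibble::tibble(
    scan_id = 1:6,
    orientation = orientation,
    image = purrr::map(scans, "image"),
    mask = purrr::map(scans, "mask"),
    thickness_jitter_px = as.integer(draws$deltas)
  )
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
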