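#' Seeded online augmentation of a B-scan / mask pair
#'
#' Applies one random draw of the training augmentation policy: a random
#' rotation within `±rotation_deg` degrees, random horizontal (lateral)
#' flipping, and random photometric jitter (brightness and contrast). The
#' geometric transform is identical for image and mask; the photometric
#' jitter touches the image only. The mask is resampled nearest-neighbour
#' and re-thresholded, so it stays strictly binary. Rotation fills exposed
#' borders with the image's background intensity (median of the top row,
#' i.e. vitreous) and with 0 in the mask. Saturation jitter is a no-op on
#' single-channel data and is therefore not applied.
#'
#' @param b A [bscan()] or intensity matrix.
#' @param m The paired [seg_mask()] or binary matrix.
#' @param seed Integer seed; the same seed reproduces the same transform.
#' @param rotation_deg Maximum absolute rotation (degrees).
#' @param flip_prob Probability of a horizontal flip.
#' @param jitter_strength Half-width of the brightness shift and of the
#'   contrast factor deviation from 1.
#' @return `list(image =, mask =)` with the same classes as the inputs.
#' @export
augment_pair <- function(b, m, seed, rotation_deg = 10, flip_prob = 0.5,
                         jitter_strength = 0.1) {
  px <- if (inherits(b, "bscan")) b$pixels else b
  mk <- as_mask_matrix(m)
  check_same_shape(px, mk)
  stopifnot(rotation_deg >= 0, flip_prob >= 0, flip_prob <= 1,
            jitter_strength >= 0)
  draws <- with_seed(as.integer(seed), list(
    angle = stats::runif(1, -rotation_deg, rotation_deg),
    flip = stats::runif(1) < flip_prob,
    brightness = stats::runif(1, -jitter_strength, jitter_strength),
    contrast = stats::runif(1, 1 - jitter_strength, 1 + jitter_strength)
  ))
  if (rotation_deg > 0 && abs(draws$angle) > 1e-12) {
    bg <- stats::median(px[1, ])
    px <- EBImage::imageData(EBImage::rotate(
      EBImage::as.Image(px), draws$angle, filter = "bilinear",
      output.dim = dim(px), bg.col = bg))
    mk <- EBImage::imageData(EBImage::rotate(
      EBImage::as.Image(mk), draws$angle, filter = "none",
      output.dim = dim(mk), bg.col = 0))
    mk <- matrix(as.integer(mk > 0.5), nrow(mk), ncol(mk))
  }
  if (draws$flip) {
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    mk <- mk[, rev(seq_len(ncol(mk))), drop = FALSE]
  }
  if (jitter_strength > 0) {
    mu <- mean(px)
    px <- (px - mu) * draws$contrast + mu + draws$brightness
  }
  px <- pmin(pmax(px, 0), 1)
  img_out <- if (inherits(b, "bscan")) {
    bscan(px, axial_scale = b$axial_scale, orientation = b$orientation)
  } else px
  mask_out <- if (inherits(m, "seg_mask")) seg_mask(mk) else mk
  list(image = img_out, mask = mask_out)
}
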