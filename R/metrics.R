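#' Dice similarity coefficient between two binary masks
#'
#' Computes DSC(X, Y) = 2|X ∩ Y| / (|X| + |Y|), the standard overlap metric
#' for binary segmentations, where |X| is the number of foreground pixels.
#'
#' @param x,y Binary matrices (values 0/1) of identical dimensions, or
#'   `seg_mask` objects.
#' @return A single number in \[0, 1\]. Two empty masks are defined to have
#'   DSC 1 (perfect agreement on "nothing present").
#' @examples
#' a <- matrix(0, 4, 4); a[2:3, 2:3] <- 1
#' dice_score(a, a) # 1
#' @export
dice_score <- function(x, y) {
  x <- as_mask_matrix(x)
  y <- as_mask_matrix(y)
  check_same_shape(x, y)
  nx <- sum(x)
  ny <- sum(y)
  if (nx == 0 && ny == 0) {
    return(1)
  }
  2 * sum(x * y) / (nx + ny)
}

#' Average symmetric surface distance between two binary masks
#'
#' Surface points are foreground pixels with at least one background
#' 4-neighbour (image borders count as background). Distances are Euclidean
#' between pixel centres. The default convention averages all nearest-surface
#' distances from both directions,
#' (sum_i d_i + sum_j d_j*) / (N_seg + N_gt),
#' which is well defined for surfaces of unequal size. With `paired = TRUE`
#' the per-index paired sum (1/N) sum_i (d_i + d_i*) is computed instead;
#' this requires both surfaces to have the same number of points.
#'
#' @param x,y Non-empty binary matrices of identical dimensions.
#' @param paired Use the paired-sum convention (equal-size surfaces only).
#' @return Distance in pixels (non-negative).
#' @export
assd <- function(x, y, paired = FALSE) {
  x <- as_mask_matrix(x)
  y <- as_mask_matrix(y)
  check_same_shape(x, y)
  if (sum(x) == 0 || sum(y) == 0) {
    stop("assd() is undefined for an empty mask; both inputs need foreground pixels")
  }
  bx <- boundary_points(x)
  by <- boundary_points(y)
  d <- cross_dist(bx, by) # |bx| x |by|
  dx <- apply(d, 1, min)  # each x-surface point -> nearest y-surface point
  dy <- apply(d, 2, min)
  if (paired) {
    if (length(dx) != length(dy)) {
      stop("paired ASSD requires surfaces with equal point counts (",
           length(dx), " vs ", length(dy), ")")
    }
    mean(dx + dy)
  } else {
    (sum(dx) + sum(dy)) / (length(dx) + length(dy))
  }
}

#' Soft dice loss between a probability map and a binary mask
#'
#' `1 - (2 sum(p*y) + s) / (sum(p) + sum(y) + s)` with smoothing constant
#' `s` (default 1) added to numerator and denominator for stability on
#' near-empty masks. For hard 0/1 probabilities this approaches
#' `1 - dice_score()` as the mask grows relative to `s`.
#'
#' @param p Matrix of probabilities in \[0, 1\].
#' @param y Binary mask of identical dimensions.
#' @param smooth Smoothing constant.
#' @return Loss value, >= 0.
#' @export
dice_loss <- function(p, y, smooth = 1) {
  p <- as_prob_matrix(p)
  y <- as_mask_matrix(y)
  check_same_shape(p, y)
  1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' Surface (boundary) pixels of a binary mask
#'
#' A foreground pixel is a surface point if any of its 4-neighbours is
#' background; pixels on the image border are surface points by definition.
#'
#' @param m Binary matrix.
#' @return Two-column matrix of (row, col) coordinates, one row per surface
#'   point, in column-major pixel order.
#' @keywords internal
boundary_points <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(
    pad[1:h, 2:(w + 1)],     # up
    pad[3:(h + 2), 2:(w + 1)], # down
    pad[2:(h + 1), 1:w],     # left
    pad[2:(h + 1), 3:(w + 2)]  # right
  )
  which(core == 1 & nb_min == 0, arr.ind = TRUE)
}

# All-pairs Euclidean distances between two point sets (n x 2, m x 2).
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

as_mask_matrix <- function(m, arg = deparse(substitute(m))) {
  if (inherits(m, "seg_mask")) m <- m$pixels
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  if (!is.matrix(m)) stop(arg, " must be a matrix or seg_mask")
  if (!all(m %in% c(0, 1))) stop(arg, " must be strictly binary (0/1)")
  m
}

as_prob_matrix <- function(p, arg = deparse(substitute(p))) {
  if (inherits(p, "prob_map")) p <- p$pixels
  if (!is.matrix(p)) stop(arg, " must be a matrix or prob_map")
  if (anyNA(p) || min(p) < 0 || max(p) > 1) {
    stop(arg, " must contain probabilities in [0, 1]")
  }
  p
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
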