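#' Training configuration
#'
#' Hyperparameters for dice-loss training with the Adam optimizer. Defaults
#' were fixed once by pilot convergence runs on tiny phantoms: learning rate
#' 0.01, batch size 5. The augmentation policy follows the standard online
#' recipe for OCT segmentation: random rotations within ±10°, random
#' horizontal flips, random brightness/contrast jitter.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed controlling shuffling, augmentation and reproducibility.
#' @param augment Apply online augmentation.
#' @param rotation_deg,flip_prob,jitter_strength Augmentation policy, see
#'   [augment_pair()].
#' @param train_fraction Fraction of a dataset assigned to training by
#'   [split_dataset()].
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 20L, batch_size = 5L, learning_rate = 0.01,
                         seed = 1L, augment = TRUE, rotation_deg = 10,
                         flip_prob = 0.5, jitter_strength = 0.1,
                         train_fraction = 0.75) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            rotation_deg >= 0, flip_prob >= 0, flip_prob <= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = isTRUE(augment), rotation_deg = rotation_deg,
                 flip_prob = flip_prob, jitter_strength = jitter_strength,
                 train_fraction = train_fraction),
            class = "train_config")
}

#' Generate a phantom dataset
#'
#' Convenience wrapper producing `n` phantoms from a base [phantom_spec()]
#' with per-phantom seeded variation of pit position, layer thicknesses and
#' noise, as a tibble dataset for [train_network()] / [evaluate_models()].
#'
#' @param n Number of phantoms.
#' @param spec Base [phantom_spec()].
#' @param seed Master seed.
#' @param vary_pit Maximum pit displacement (columns) from the image centre.
#' @return Tibble with columns `id`, `image`, `mask`, `fovea_column`,
#'   `sfcht_px`.
#' @export
phantom_dataset <- function(n, spec = phantom_spec("tiny"), seed = 1L,
                            vary_pit = 5L) {
  draws <- with_seed(as.integer(seed), list(
    seeds = sample.int(.Machine$integer.max %/% 2, n),
    pit = sample(seq(-vary_pit, vary_pit), n, replace = TRUE),
    cho = sample(-2:2, n, replace = TRUE),
    ret = sample(-2:2, n, replace = TRUE)
  ))
  rows <- purrr::map(seq_len(n), function(i) {
    sp <- phantom_spec(
      preset = spec$preset,
      height = spec$height, width = spec$width,
      ilm_depth = spec$ilm_depth,
      fovea_column = spec$fovea_column + draws$pit[i],
      axial_scale = spec$axial_scale,
      speckle_sigma = spec$speckle_sigma,
      lacunae_density = spec$lacunae_density,
      rpe_thickness = spec$rpe_thickness,
      seed = draws$seeds[i]
    )
    sp$choroid_thickness_profile <- pmax(
      1L, sp$choroid_thickness_profile + as.integer(draws$cho[i]))
    sp$retina_thickness_profile <- pmax(
      2L, sp$retina_thickness_profile + as.integer(draws$ret[i]))
    sp <- validate_phantom_spec(sp)
    ph <- generate_phantom(sp)
    tibble::tibble(
      id = i,
      image = list(ph$image),
      mask = list(ph$mask),
      fovea_column = sp$fovea_column,
      sfcht_px = sp$choroid_thickness_profile[sp$fovea_column]
    )
  })
  dplyr::bind_rows(rows)
}

#' Split a dataset into training and evaluation subsets
#'
#' @param dataset A tibble with one row per image.
#' @param cfg A [train_config()] (uses `train_fraction` and `seed`), or a
#'   fraction.
#' @return `list(train =, eval =)` tibbles.
#' @export
split_dataset <- function(dataset, cfg = train_config()) {
  frac <- if (inherits(cfg, "train_config")) cfg$train_fraction else cfg
  seed <- if (inherits(cfg, "train_config")) cfg$seed else 1L
  n <- nrow(dataset)
  n_train <- max(1L, round(frac * n))
  idx <- with_seed(seed, sample.int(n))
  list(train = dataset[sort(idx[seq_len(n_train)]), ],
       eval = dataset[sort(idx[-seq_len(n_train)]), ])
}

#' Train a segmentation network with dice loss and Adam
#'
#' Minimizes the soft dice loss over the dataset with the Adam optimizer,
#' with optional seeded online augmentation. Fully reproducible for a fixed
#' `cfg$seed`: the same seed yields identical loss histories and weights.
#'
#' @param model A `seg_model` from [build_network()].
#' @param dataset Tibble with list-columns `image` and `mask` (e.g. from
#'   [phantom_dataset()]).
#' @param cfg A [train_config()].
#' @return `list(model =, history =)` of class `train_result`; `history` is
#'   a tibble with per-epoch mean dice loss.
#' @export
train_network <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop("training requires a non-empty dataset")
  }
  shp <- model$cfg$input_shape
  HW <- prod(shp)
  imgs <- purrr::map(dataset$image, ~ if (inherits(.x, "bscan")) .x$pixels else .x)
  msks <- purrr::map(dataset$mask, ~ as_mask_matrix(.x))
  n <- length(imgs)
  adam <- new.env(parent = emptyenv())
  adam$t <- 0
  history <- numeric(cfg$epochs)

  res <- with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
        pairs <- lapply(ids, function(i) {
          if (cfg$augment) {
            augment_pair(imgs[[i]], msks[[i]],
                         seed = sample.int(.Machine$integer.max %/% 2, 1),
                         rotation_deg = cfg$rotation_deg,
                         flip_prob = cfg$flip_prob,
                         jitter_strength = cfg$jitter_strength)
          } else {
            list(image = imgs[[i]], mask = msks[[i]])
          }
        })
        B <- length(ids)
        x <- matrix(unlist(lapply(pairs, `[[`, "image"), use.names = FALSE), ncol = 1)
        y <- matrix(unlist(lapply(pairs, `[[`, "mask"), use.names = FALSE), ncol = 1)
        fwd <- model_forward(model, x, B, training = TRUE)
        model <- fwd$model
        p <- fwd$out
        grp <- rep(seq_len(B), each = HW)
        inter <- rowsum(p * y, grp, reorder = FALSE)
        sp <- rowsum(p, grp, reorder = FALSE)
        sy <- rowsum(y, grp, reorder = FALSE)
        smooth <- 1
        denom <- sp + sy + smooth
        loss_i <- 1 - (2 * inter + smooth) / denom
        batch_losses <- c(batch_losses, mean(loss_i))
        # d(mean loss)/dp per pixel
        dldp <- ((2 * inter + smooth)[grp] / denom[grp]^2 - 2 * y / denom[grp]) / B
        grads <- model_backward(model, fwd$acts, fwd$caches, dldp, B)
        model <- adam_step(model, grads, adam, cfg$learning_rate)
      }
      history[epoch] <- mean(batch_losses)
    }
    # inference-mode calibration of batch-norm statistics on clean images
    model <- bn_recalibrate(model, imgs)
    list(model = model, history = history)
  })
  structure(list(
    model = res$model,
    history = tibble::tibble(epoch = seq_len(cfg$epochs), dice_loss = res$history),
    config = cfg
  ), class = "train_result")
}

adam_step <- function(model, grads, adam, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  adam$t <- adam$t + 1
  bc1 <- 1 - beta1^adam$t
  bc2 <- 1 - beta2^adam$t
  for (i in seq_along(model$nodes)) {
    nm <- model$nodes[[i]]$name
    g <- grads[[nm]]
    if (is.null(g)) next
    for (pn in names(g)) {
      key <- paste0(nm, ".", pn)
      if (is.null(adam[[key]])) {
        adam[[key]] <- list(m = 0 * g[[pn]], v = 0 * g[[pn]])
      }
      st <- adam[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
      adam[[key]] <- st
      model$nodes[[i]]$params[[pn]] <- model$nodes[[i]]$params[[pn]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  model
}

#' Evaluate segmentation models on a dataset
#'
#' Predicts each image with one model (or fuses two models' probability maps,
#' the late-fusion ensemble), applies the post-processing chain (0.5
#' binarization, largest connected component, hole filling), and computes
#' per-image DSC and ASSD against the ground-truth masks. Images on which a
#' metric fails (e.g. an empty prediction) are excluded with a warning.
#'
#' @param models A `seg_model`, a list of one or two `seg_model`s, or (for
#'   testing the harness) plain functions mapping a [bscan()] to a
#'   `prob_map`.
#' @param dataset Tibble with list-columns `image` and `mask`.
#' @param fuse Average the two models' probability maps before
#'   post-processing (requires two models).
#' @param postprocess Apply the post-processing chain before metrics.
#' @param batch_size Inference batch size.
#' @return An `eval_report`: per-image tibble (`id`, `dsc`, `assd`) with
#'   aggregate statistics as attributes; see [glance.eval_report()].
#' @export
evaluate_models <- function(models, dataset, fuse = NULL, postprocess = TRUE,
                            batch_size = 8L) {
  if (inherits(models, "seg_model") || is.function(models)) models <- list(models)
  stopifnot(length(models) %in% 1:2,
            all(vapply(models, function(m) {
              inherits(m, "seg_model") || is.function(m)
            }, logical(1))))
  do_fuse <- fuse %||% (length(models) == 2)
  if (do_fuse && length(models) != 2) stop("fusion requires two models")
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop("evaluation requires a non-empty dataset")
  }
  n <- nrow(dataset)
  ids <- if ("id" %in% names(dataset)) dataset$id else seq_len(n)
  preds <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    batch <- dataset$image[take]
    per_model <- lapply(models, function(m) {
      if (is.function(m)) lapply(batch, m) else predict(m, batch)
    })
    for (j in seq_along(take)) {
      pm <- per_model[[1]][[j]]
      if (do_fuse) pm <- fuse(per_model[[1]][[j]], per_model[[2]][[j]])
      preds[[take[j]]] <- pm
    }
  }
  rows <- purrr::map(seq_len(n), function(i) {
    gt <- as_mask_matrix(dataset$mask[[i]])
    pred <- binarize(preds[[i]], 0.5)
    if (postprocess) pred <- largest_component(pred)
    tryCatch(
      tibble::tibble(id = ids[i],
                     dsc = dice_score(pred, gt),
                     assd = assd(pred, gt)),
      error = function(e) {
        warning("image ", ids[i], " excluded from evaluation: ",
                conditionMessage(e))
        NULL
      })
  })
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0) stop("no image could be evaluated")
  out <- per_image
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  attr(out, "dsc_mean") <- mean(per_image$dsc)
  attr(out, "dsc_sd") <- sd0(per_image$dsc)
  attr(out, "dsc_max") <- max(per_image$dsc)
  attr(out, "assd_mean") <- mean(per_image$assd)
  attr(out, "assd_sd") <- sd0(per_image$assd)
  attr(out, "n_models") <- length(models)
  attr(out, "fused") <- do_fuse
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation evaluation on %d image(s)%s\n  DSC  %.2f ± %.2f (max %.2f)\n  ASSD %.2f ± %.2f px\n",
    nrow(x), if (attr(x, "fused")) " (fusion of 2 models)" else "",
    100 * attr(x, "dsc_mean"), 100 * (attr(x, "dsc_sd") %||% 0),
    100 * attr(x, "dsc_max"),
    attr(x, "assd_mean"), attr(x, "assd_sd") %||% 0))
  invisible(x)
}

#' Compare manual and automated thickness measurements
#'
#' Ordinary least-squares regression of automated on manual subfoveal
#' choroidal thickness plus the Pearson correlation R — the standard
#' validation of an automated pipeline against an independent grader.
#'
#' @param manual,auto Numeric vectors of paired measurements (µm), or a
#'   data frame with columns `manual` and `auto` as first argument.
#' @return A `manual_auto_fit` with elements `slope`, `intercept`, `r`, `n`
#'   and the underlying `lm` fit; [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods are available.
#' @export
compare_manual_auto <- function(manual, auto = NULL) {
  if (is.data.frame(manual)) {
    stopifnot(all(c("manual", "auto") %in% names(manual)))
    auto <- manual$auto
    manual <- manual$manual
  }
  if (length(manual) != length(auto)) stop("manual and auto must be paired")
  if (length(manual) < 3) stop("at least 3 pairs are required")
  if (stats::var(manual) == 0 || stats::var(auto) == 0) {
    stop("degenerate variance: both measurement series must vary")
  }
  fit <- stats::lm(auto ~ manual, data = data.frame(manual = manual, auto = auto))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(manual, auto),
    n = length(manual),
    fit = fit
  ), class = "manual_auto_fit")
}

#' @export
print.manual_auto_fit <- function(x, ...) {
  cat(sprintf("Manual vs automated SfChT (n = %d): auto = %.3f x manual %+.2f, R = %.3f\n",
              x$n, x$slope, x$intercept, x$r))
  invisible(x)
}
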