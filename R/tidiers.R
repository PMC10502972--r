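#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-image evaluation metrics
#' @param x An `eval_report` from [evaluate_models()].
#' @param ... Unused.
#' @return Tibble with one row per evaluated image (`id`, `dsc`, `assd`).
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("id", "dsc", "assd")])
}

#' One-row evaluation summary (DSC mean/SD/max, ASSD mean/SD)
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble mirroring the standard performance-table shape.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x),
    dsc_mean = attr(x, "dsc_mean"),
    dsc_sd = attr(x, "dsc_sd"),
    dsc_max = attr(x, "dsc_max"),
    assd_mean = attr(x, "assd_mean"),
    assd_sd = attr(x, "assd_sd"),
    fused = attr(x, "fused")
  )
}

#' Tidy the per-epoch loss history
#' @param x A `train_result` from [train_network()].
#' @param ... Unused.
#' @return Tibble with `epoch` and `dice_loss`.
#' @export
tidy.train_result <- function(x, ...) x$history

#' One-row training summary
#' @param x A `train_result`.
#' @param ... Unused.
#' @return One-row tibble with epoch count, first/final loss and parameters.
#' @export
glance.train_result <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    first_loss = x$history$dice_loss[1],
    final_loss = utils::tail(x$history$dice_loss, 1),
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy the manual-vs-automated regression
#' @param x A `manual_auto_fit` from [compare_manual_auto()].
#' @param ... Unused.
#' @return Tibble of regression terms with estimates and standard errors.
#' @export
tidy.manual_auto_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = cf[, 1],
    std_error = cf[, 2],
    p_value = cf[, 4]
  )
}

#' One-row manual-vs-automated summary
#' @param x A `manual_auto_fit`.
#' @param ... Unused.
#' @return One-row tibble with `r`, `slope`, `intercept`, `n`.
#' @export
glance.manual_auto_fit <- function(x, ...) {
  tibble::tibble(r = x$r, slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Tidy standardized coefficients of a hierarchical regression
#' @param x A `hier_regression` from [hierarchical_regression()].
#' @param ... Unused.
#' @return Tibble of standardized betas per model.
#' @export
tidy.hier_regression <- function(x, ...) x$coefficients

#' One-row hierarchical-regression summary
#' @param x A `hier_regression`.
#' @param ... Unused.
#' @return One-row tibble with both models' R² and the candidate block ΔR².
#' @export
glance.hier_regression <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    candidate = x$candidate,
    r2_model1 = x$r2_model1,
    r2_model2 = x$r2_model2,
    delta_r2 = x$delta_r2
  )
}

#' One-row SfChT measurement summary
#' @param x An `sfcht_measurement` from [measure_sfcht()].
#' @param ... Unused.
#' @return One-row tibble with the mean SfChT and scan counts.
#' @export
glance.sfcht_measurement <- function(x, ...) {
  tibble::tibble(
    subject = x$subject[1],
    visit = x$visit[1],
    mean_sfcht_um = attr(x, "mean_sfcht_um"),
    n_scans = nrow(x),
    n_used = sum(x$used)
  )
}

#' One-row adjusted-group-change summary
#' @param x An `adjusted_change` from [adjusted_group_change()].
#' @param ... Unused.
#' @return One-row tibble with the between-group adjusted difference, its
#'   standard error and p-value.
#' @export
glance.adjusted_change <- function(x, ...) {
  tibble::tibble(
    difference = attr(x, "difference"),
    difference_se = attr(x, "difference_se"),
    p_value = attr(x, "p_value")
  )
}
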