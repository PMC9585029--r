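# broom-style tidiers for the fitted objects.

#' @describeIn fit_hgnnlda Tidy the training loss trajectory.
#' @param x An `hgnnlda_fit`.
#' @export
tidy.hgnnlda_fit <- function(x, ...) {
  x$trajectory
}

#' @describeIn fit_hgnnlda One-row fit summary.
#' @export
glance.hgnnlda_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    d = x$config$d,
    n_pairs = nrow(x$samples),
    n_positive = sum(x$samples$label == 1),
    epochs = x$config$epochs,
    initial_loss = x$trajectory$loss[1],
    final_loss = tail(x$trajectory$loss, 1),
    n_parameters = n_parameters(x$state)
  )
}

#' @describeIn five_fold_cv Per-fold metrics.
#' @param x An `hgnnlda_cv`.
#' @param ... Unused.
#' @export
tidy.hgnnlda_cv <- function(x, ...) {
  x$folds
}

#' @describeIn five_fold_cv One-row cross-validation summary.
#' @export
glance.hgnnlda_cv <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    leakage_mode = x$leakage_mode,
    n_folds = nrow(x$folds),
    mean_auc = x$mean_auc,
    mean_aupr = x$mean_aupr,
    leakage_ok = x$leakage_ok,
    seed = x$seed
  )
}

#' Export cross-validated scores as a tidy table
#'
#' @param x An `hgnnlda_cv`.
#' @return A tibble `lncrna`, `disease`, `label`, `fold`, `score`.
#' @export
cv_scores <- function(x) {
  stopifnot(inherits(x, "hgnnlda_cv"))
  x$scores
}
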