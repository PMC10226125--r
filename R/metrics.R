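## metrics: the evaluation statistics used for predicted-vs-experimental
## binding free energies -- predictive index, Pearson/Spearman correlation,
## and the mean-unsigned-error family.

check_pred_exp <- function(pred, exp, n_min = 2) {
  if (length(pred) != length(exp)) {
    mmp_stop("mmpbsar_domain_error", "pred and exp must have equal length")
  }
  if (length(pred) < n_min) {
    mmp_stop("mmpbsar_domain_error", "need at least %d observations", n_min)
  }
  if (any(!is.finite(pred)) || any(!is.finite(exp))) {
    mmp_stop("mmpbsar_domain_error", "pred and exp must be finite")
  }
  invisible(TRUE)
}

#' Predictive index
#'
#' Pairwise rank-agreement statistic weighted by experimental affinity
#' differences: `PI = sum_{j>i} w_ij c_ij / sum_{j>i} w_ij` with
#' `w_ij = |exp_j - exp_i|` and `c_ij = +1` when the predicted difference has
#' the same sign as the experimental one, `-1` when opposite, and `0` when
#' the predicted difference is zero. Pairs with equal experimental values
#' carry zero weight. Sign convention: binding free energies, so a more
#' negative value is stronger binding, and agreement means larger predicted
#' paired with larger experimental.
#'
#' @param pred,exp Predicted and experimental binding free energies
#'   (kcal/mol), equal length, n >= 2.
#' @return PI in `[-1, 1]`.
#' @export
predictive_index <- function(pred, exp) {
  check_pred_exp(pred, exp, 2)
  n <- length(pred)
  ij <- utils::combn(n, 2)
  de <- exp[ij[2, ]] - exp[ij[1, ]]
  dp <- pred[ij[2, ]] - pred[ij[1, ]]
  w <- abs(de)
  if (sum(w) == 0) {
    mmp_stop("mmpbsar_undefined_weight_error",
             "all experimental values are equal; PI weights vanish")
  }
  cij <- sign(de) * sign(dp)
  sum(w * cij) / sum(w)
}

#' Mean-unsigned-error family
#'
#' `MUE` is the plain mean unsigned error. `MUEtr` subtracts the mean signed
#' error from the predictions first (shift-invariant; isolates ranking error
#' from a constant offset). `MUEsc` first maps the predictions onto
#' experiment by least-squares affine regression (invariant to any
#' positive-affine transform of the predictions; the error left after the
#' scale of the estimator's raw output is fitted away).
#'
#' @inheritParams predictive_index
#' @return Named numeric vector `c(MUE, MUEtr, MUEsc)` (kcal/mol).
#' @export
mue_family <- function(pred, exp) {
  check_pred_exp(pred, exp, 2)
  mue <- mean(abs(pred - exp))
  muetr <- mean(abs((pred - mean(pred - exp)) - exp))
  if (stats::var(pred) == 0) {
    mmp_stop("mmpbsar_degenerate_slope_error",
             "zero variance in predictions; MUEsc slope is undefined")
  }
  fit <- stats::lm.fit(cbind(1, pred), exp)
  muesc <- mean(abs((fit$coefficients[1] + fit$coefficients[2] * pred) - exp))
  c(MUE = mue, MUEtr = muetr, MUEsc = muesc)
}

#' Pearson and Spearman correlations
#'
#' Standard product-moment and rank correlations (Spearman ties by average
#' ranks, as in [stats::cor()]).
#'
#' @inheritParams predictive_index
#' @return Named vector `c(pearson_r, spearman_r)`.
#' @export
correlations <- function(pred, exp) {
  check_pred_exp(pred, exp, 3)
  if (stats::var(pred) == 0 || stats::var(exp) == 0) {
    mmp_stop("mmpbsar_undefined_correlation_error",
             "zero variance; correlation undefined")
  }
  c(pearson_r = stats::cor(pred, exp, method = "pearson"),
    spearman_r = stats::cor(pred, exp, method = "spearman"))
}

#' Full metrics report
#'
#' @inheritParams predictive_index
#' @return Object of class `metrics_report`: list with `PI`, `pearson_r`,
#'   `spearman_r`, `MUE`, `MUEtr`, `MUEsc`, `n`.
#' @export
metrics_report <- function(pred, exp) {
  mu <- mue_family(pred, exp)
  co <- correlations(pred, exp)
  structure(list(PI = predictive_index(pred, exp),
                 pearson_r = unname(co["pearson_r"]),
                 spearman_r = unname(co["spearman_r"]),
                 MUE = unname(mu["MUE"]), MUEtr = unname(mu["MUEtr"]),
                 MUEsc = unname(mu["MUEsc"]), n = length(pred)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics (n = %d): PI %.3f | Pearson %.3f | Spearman %.3f | MUE %.3f | MUEtr %.3f | MUEsc %.3f\n",
    x$n, x$PI, x$pearson_r, x$spearman_r, x$MUE, x$MUEtr, x$MUEsc))
  invisible(x)
}
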