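## fitting: coefficient fitting against experimental binding free energies
## and dielectric grid scans. The estimators are affine in every coefficient,
## so the design matrix is built by scoring at unit coefficient vectors and
## ordinary least squares does the rest.

#' Assemble a fitting dataset
#'
#' Joins a delta-terms table with experimental binding free energies (and an
#' optional train/test split) by `complex_id`.
#'
#' @param delta A `delta_terms` table.
#' @param exp data.frame with columns `complex_id` and `dG_exp` (kcal/mol).
#' @param split Optional data.frame `complex_id, split` with labels `"train"`
#'   and `"test"`; fitting uses the train rows, the test rows give a held-out
#'   metrics report.
#' @return Object of class `bfe_dataset`.
#' @export
bfe_dataset <- function(delta, exp, split = NULL) {
  if (!all(c("complex_id", "dG_exp") %in% names(exp))) {
    mmp_stop("mmpbsar_schema_error",
             "exp must have columns complex_id and dG_exp")
  }
  idx <- match(delta$complex_id, exp$complex_id)
  if (anyNA(idx)) {
    mmp_stop("mmpbsar_integrity_error",
             "no experimental value for complex(es): %s",
             paste(delta$complex_id[is.na(idx)], collapse = ", "))
  }
  dg <- exp$dG_exp[idx]
  if (any(!is.finite(dg))) {
    mmp_stop("mmpbsar_domain_error", "experimental values must be finite")
  }
  lab <- rep("train", nrow(delta))
  if (!is.null(split)) {
    sidx <- match(delta$complex_id, split$complex_id)
    lab[!is.na(sidx)] <- split$split[sidx[!is.na(sidx)]]
  }
  structure(list(delta = delta, dG_exp = dg, split = lab),
            class = "bfe_dataset")
}

## design matrix for the free coefficients of a regime at a dielectric pair:
## column k = d(prediction)/d(coef k), obtained by scoring at unit vectors
build_design <- function(delta, regime, free, fixed, pair, term_map) {
  base <- stats::setNames(rep(0, length(REGIME_COEFS[[regime]])),
                          REGIME_COEFS[[regime]])
  base[names(fixed)] <- fixed
  m0 <- model_spec(regime, base, term_map = term_map)
  c0 <- score(delta, m0, pair)$dG_pred
  X <- vapply(free, function(k) {
    cf <- base; cf[k] <- 1
    score(delta, model_spec(regime, cf, term_map = term_map), pair)$dG_pred - c0
  }, numeric(nrow(delta)))
  X <- matrix(X, nrow = nrow(delta), dimnames = list(NULL, free))
  list(c0 = c0, X = X)
}

#' Fit estimator coefficients to experimental affinities
#'
#' Ordinary least squares on `dG_pred - dG_exp` over the regime's free
#' coefficients, exploiting the estimators' affinity in their coefficients;
#' pinned coefficients are held fixed. For the `pbsa_e` regime the internal
#' surface-tension factor `gamma` is not identifiable jointly with its
#' empirical weight, so it is pinned (default 0.0072) unless supplied in
#' `fixed`. With `objective = "pearson"` the correlation is maximised
#' directly (Nelder-Mead seeded at the least-squares solution); for a fully
#' free affine family both objectives give the same correlation.
#'
#' @param dataset A [bfe_dataset()] (needs >= 3 training complexes).
#' @param regime Estimator regime (see [model_spec()]) or a `model_spec`
#'   whose regime/term_map to use.
#' @param fixed Named numeric vector of pinned coefficients.
#' @param pair [dielectric_pair()] applied before fitting.
#' @param objective `"sse"` (default) or `"pearson"`.
#' @return Object of class `bfe_fit`: fitted `model` ([model_spec()]),
#'   `coefficients`, `se` (OLS standard errors), `metrics_train`, and
#'   `metrics_test` when the dataset has held-out rows.
#' @export
fit <- function(dataset, regime, fixed = NULL,
                pair = dielectric_pair(1, 1),
                objective = c("sse", "pearson")) {
  objective <- match.arg(objective)
  stopifnot(inherits(dataset, "bfe_dataset"))
  term_map <- NULL
  if (inherits(regime, "model_spec")) {
    term_map <- regime$term_map
    regime <- regime$regime
  }
  regime <- match.arg(regime, REGIMES)
  fixed <- fixed %||% numeric(0)
  if (regime == "pbsa_e" && !"gamma" %in% names(fixed)) {
    fixed <- c(fixed, gamma = 0.0072)
  }
  bad <- setdiff(names(fixed), REGIME_COEFS[[regime]])
  if (length(bad) > 0) {
    mmp_stop("mmpbsar_config_error",
             "pinned coefficient(s) not in regime '%s': %s", regime,
             paste(bad, collapse = ", "))
  }
  free <- setdiff(REGIME_COEFS[[regime]], names(fixed))
  tr <- dataset$split == "train"
  if (sum(tr) < 3) {
    mmp_stop("mmpbsar_domain_error", "need >= 3 training complexes")
  }
  delta_tr <- dataset$delta[tr, , drop = FALSE]
  y_tr <- dataset$dG_exp[tr]

  des <- build_design(delta_tr, regime, free, fixed, pair, term_map)
  qrX <- qr(des$X)
  if (qrX$rank < ncol(des$X)) {
    collinear <- colnames(des$X)[qrX$pivot[(qrX$rank + 1):ncol(des$X)]]
    mmp_stop("mmpbsar_singular_design_error",
             "design matrix is rank deficient; collinear coefficient(s): %s",
             paste(collinear, collapse = ", "))
  }
  theta <- qr.coef(qrX, y_tr - des$c0)
  if (objective == "pearson") {
    negcor <- function(th) -stats::cor(des$c0 + des$X %*% th, y_tr)
    opt <- stats::optim(theta, negcor, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    theta <- stats::setNames(opt$par, names(theta))
  }
  resid <- y_tr - (des$c0 + des$X %*% theta)
  dof <- max(1L, sum(tr) - length(free))
  sigma2 <- sum(resid^2) / dof
  se <- sqrt(diag(chol2inv(qr.R(qrX))) * sigma2)
  names(se) <- colnames(des$X)

  cf <- stats::setNames(rep(0, length(REGIME_COEFS[[regime]])),
                        REGIME_COEFS[[regime]])
  cf[names(fixed)] <- fixed
  cf[names(theta)] <- theta
  model <- model_spec(regime, cf, term_map = term_map)

  pred <- score(dataset$delta, model, pair)$dG_pred
  metrics_train <- metrics_report(pred[tr], dataset$dG_exp[tr])
  metrics_test <- NULL
  if (any(dataset$split == "test")) {
    te <- dataset$split == "test"
    metrics_test <- metrics_report(pred[te], dataset$dG_exp[te])
  }
  structure(list(model = model, coefficients = cf, se = se, fixed = fixed,
                 pair = pair, objective = objective,
                 sse = sum(resid^2), n_train = sum(tr),
                 metrics_train = metrics_train, metrics_test = metrics_test),
            class = "bfe_fit")
}

#' @export
print.bfe_fit <- function(x, ...) {
  cat(sprintf("bfe_fit: regime '%s' (%s objective, n_train = %d)\n",
              x$model$regime, x$objective, x$n_train))
  cat("  coefficients:",
      paste(sprintf("%s = %.5g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat("  train "); print(x$metrics_train)
  if (!is.null(x$metrics_test)) { cat("  test  "); print(x$metrics_test) }
  invisible(x)
}

#' Scan interior-dielectric values
#'
#' Evaluates the estimator over a grid of interior-dielectric pairs --
#' either the full two-valued grid (`eps_ele` x `eps_pb`) or the
#' single-valued diagonal (`eps_ele == eps_pb`) -- and reports the metrics
#' at every grid point plus the pair maximising Pearson correlation (ties
#' broken toward the lexicographically smaller pair). By default the model's
#' coefficients are held fixed and only the algebraic dielectric rescaling
#' varies; `refit = TRUE` refits the free coefficients at every grid point.
#'
#' @param dataset A [bfe_dataset()].
#' @param model A [model_spec()] (used as-is unless `refit`).
#' @param grid Numeric vector of dielectric values, all >= 1.
#' @param two_valued If `FALSE`, constrain `eps_ele == eps_pb`.
#' @param refit Refit free coefficients at each grid point.
#' @param fixed Pinned coefficients forwarded to [fit()] when refitting.
#' @return Object of class `dielectric_scan`: `table` (one row of metrics
#'   per pair), `best` (row index), `best_pair`.
#' @export
scan_dielectrics <- function(dataset, model, grid, two_valued = TRUE,
                             refit = FALSE, fixed = NULL) {
  stopifnot(inherits(dataset, "bfe_dataset"))
  if (length(grid) == 0) {
    mmp_stop("mmpbsar_config_error", "dielectric grid is empty")
  }
  if (any(!is.finite(grid)) || any(grid < 1)) {
    mmp_stop("mmpbsar_domain_error", "grid values must be finite and >= 1")
  }
  grid <- sort(unique(grid))
  pairs <- if (two_valued) {
    expand.grid(eps_ele = grid, eps_pb = grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(eps_ele = grid, eps_pb = grid)
  }
  tr <- dataset$split == "train"
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- dielectric_pair(pairs$eps_ele[i], pairs$eps_pb[i])
    mdl <- if (refit) fit(dataset, model, fixed = fixed, pair = pr)$model
           else model
    pred <- score(dataset$delta, mdl, pr)$dG_pred
    m <- metrics_report(pred[tr], dataset$dG_exp[tr])
    data.frame(eps_ele = pr$eps_ele, eps_pb = pr$eps_pb, PI = m$PI,
               pearson_r = m$pearson_r, spearman_r = m$spearman_r,
               MUE = m$MUE, MUEtr = m$MUEtr, MUEsc = m$MUEsc)
  })
  tab <- do.call(rbind, rows)
  ## argmax Pearson, ties toward the lexicographically smaller pair
  ord <- order(-tab$pearson_r, tab$eps_ele, tab$eps_pb)
  best <- ord[1]
  structure(list(table = tab, best = best,
                 best_pair = dielectric_pair(tab$eps_ele[best],
                                             tab$eps_pb[best]),
                 two_valued = two_valued, refit = refit),
            class = "dielectric_scan")
}

#' @export
print.dielectric_scan <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf(
    "dielectric scan (%s, %d points%s): best (eps_ele, eps_pb) = (%g, %g), Pearson R = %.4f\n",
    if (x$two_valued) "two-valued" else "single-valued", nrow(x$table),
    if (x$refit) ", refit" else "", b$eps_ele, b$eps_pb, b$pearson_r))
  invisible(x)
}
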