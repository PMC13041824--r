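# Per-unit Poisson encoding models: per-wingbeat feature matrix,
# elastic-net feature selection, cross-validated pseudo-R2, and the
# participation ratio of model weights.

#' Per-cycle means of kinematic series
#'
#' @param kin data.frame from [derive_kinematics()] (any subset of the
#'   session covering the cycles).
#' @param wingbeats wingbeat table.
#' @param cols kinematic columns to average.
#' @return matrix wingbeats x features of per-cycle means.
#' @export
cycle_kinematic_means <- function(kin, wingbeats,
                                  cols = c("speed", "g_force", "ang_vel",
                                           "fpa", "vx", "vy", "vz", "ax",
                                           "ay", "az")) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  M <- matrix(NA_real_, nrow(wingbeats), length(cols),
              dimnames = list(wingbeats$wingbeat_id, cols))
  for (i in seq_len(nrow(wingbeats))) {
    sel <- kin$t >= wingbeats$onset[i] & kin$t < wingbeats$offset[i]
    M[i, ] <- vapply(cols, function(cc) mean(kin[[cc]][sel], na.rm = TRUE),
                     numeric(1))
  }
  M
}

#' Assemble the per-wingbeat kinematic feature matrix
#'
#' Builds the default 17-feature registry (see [cycle_feature_names()]):
#' per-cycle means of the position-derived kinematics plus turn curvature
#' (`ang_vel / speed`), the upper stroke envelopes of the left/right wrist
#' and wingtip, the wrist envelope asymmetry, and the cycle period.
#' Columns are z-scored (mean 0, sd 1); envelope features are dropped
#' (with a message) when the corresponding keypoints are unavailable.
#'
#' @param kin kinematic series covering the cycles.
#' @param envelopes named list of envelope data.frames with entries
#'   `wrist_l`, `wrist_r`, `wingtip_l`, `wingtip_r` (or `NULL`).
#' @param wingbeats wingbeat table.
#' @return z-scored matrix wingbeats x features; raw (pre-scaling) means
#'   in attribute `"raw"`.
#' @export
build_feature_matrix <- function(kin, envelopes, wingbeats) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  K <- cycle_kinematic_means(kin, wingbeats)
  curvature <- K[, "ang_vel"] / pmax(K[, "speed"], 1e-6)
  X <- cbind(K, curvature = curvature)
  need <- c("wrist_l", "wrist_r", "wingtip_l", "wingtip_r")
  if (!is.null(envelopes) && all(need %in% names(envelopes))) {
    X <- cbind(X,
               env_wrist_l = envelopes$wrist_l$upper,
               env_wrist_r = envelopes$wrist_r$upper,
               env_wingtip_l = envelopes$wingtip_l$upper,
               env_wingtip_r = envelopes$wingtip_r$upper,
               asym_wrist = envelopes$wrist_r$upper -
                 envelopes$wrist_l$upper)
  } else {
    message("keypoint envelopes unavailable; 5 envelope features dropped")
  }
  X <- cbind(X, period = wingbeats$period_ms)
  bad <- !stats::complete.cases(X)
  if (any(bad)) X[bad, ] <- NA
  Z <- zscore_cols(X)
  Z[bad, ] <- NA
  attr(Z, "raw") <- X
  Z
}

#' Poisson deviance
#'
#' `2 * sum(y * log(y / mu) - (y - mu))` with the `0 * log(0)` terms
#' taken as zero; the goodness-of-fit currency of the cross-validated
#' pseudo-R2.
#'
#' @param y observed counts.
#' @param mu predicted means (floored at a tiny positive value).
#' @return scalar deviance.
#' @export
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Elastic-net feature selection for a Poisson encoding model
#'
#' Fits a Poisson elastic-net path (`glmnet`, mixing parameter
#' `alpha = 0.5` by default) over the z-scored feature matrix, picks the
#' penalty by k-fold cross-validated deviance with the one-standard-error
#' rule, and returns the features with nonzero coefficients.
#'
#' @param counts per-wingbeat spike counts.
#' @param X z-scored feature matrix (cycles x features).
#' @param k_folds CV folds.
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param rule `"1se"` or `"min"` penalty choice.
#' @return character vector of selected feature names (empty for an
#'   all-zero unit), with the `cv.glmnet` fit in attribute `"fit"`.
#' @export
select_features_elastic_net <- function(counts, X, k_folds = 5,
                                        alpha = 0.5,
                                        rule = c("1se", "min")) {
  rule <- match.arg(rule)
  keep <- stats::complete.cases(X)
  counts <- counts[keep]; X <- X[keep, , drop = FALSE]
  if (sum(counts) == 0) return(character())
  foldid <- stratified_folds(counts > 0, k_folds)
  cv <- glmnet::cv.glmnet(X, counts, family = "poisson", alpha = alpha,
                          foldid = foldid, standardize = FALSE)
  s <- if (rule == "1se") "lambda.1se" else "lambda.min"
  co <- as.matrix(stats::coef(cv, s = s))[-1, 1]
  sel <- names(co)[co != 0]
  attr(sel, "fit") <- cv
  sel
}

#' Cross-validated Poisson GLM on selected features
#'
#' Unpenalized Poisson regression of per-wingbeat spike counts on the
#' selected (z-scored) features. The cross-validated pseudo-R2 is
#' `1 - CV deviance(model) / CV deviance(intercept-only)`, pooled over
#' folds; non-convergent fits fall back to a lightly ridged `glmnet` fit
#' with a warning.
#'
#' @param counts per-wingbeat spike counts.
#' @param X z-scored feature matrix.
#' @param selected names of selected features (nonempty).
#' @param k_folds CV folds.
#' @return a `wb_glm_fit` list: `selected`, `coef` (zero outside the
#'   selected set), `intercept`, `cv_pseudo_r2`, `weight_pr`,
#'   `weight_pr_norm`.
#' @export
fit_poisson_glm_cv <- function(counts, X, selected, k_folds = 5) {
  stopifnot(length(selected) >= 1)
  keep <- stats::complete.cases(X)
  counts <- counts[keep]
  Xs <- X[keep, selected, drop = FALSE]
  # lightly ridge-penalized IRLS (intercept unpenalized); used directly as
  # the fallback when the unpenalized fit separates or fails to converge
  ridge_poisson <- function(y, M, lambda = 1e-2, iters = 50) {
    p <- ncol(M)
    b <- c(log(mean(y) + 1e-6), numeric(p))
    Xd <- cbind(1, M)
    pen <- diag(c(0, rep(lambda, p)))
    for (i in seq_len(iters)) {
      eta <- pmin(pmax(Xd %*% b, -20), 20)
      mu <- exp(eta)
      z <- eta + (y - mu) / mu
      W <- as.numeric(mu)
      b_new <- solve(crossprod(Xd, W * Xd) + length(y) * pen,
                     crossprod(Xd, W * z))
      if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
      b <- b_new
    }
    as.numeric(b)
  }
  fit_one <- function(y, M) {
    df <- data.frame(y = y, M)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = df,
                                  family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(stats::coef(fit)) ||
          any(abs(stats::coef(fit)) > 20)) {
      warning("Poisson GLM did not converge cleanly; ridge fallback")
      return(ridge_poisson(y, M))
    }
    stats::coef(fit)
  }
  foldid <- stratified_folds(counts > 0, k_folds)
  dev_m <- 0; dev_0 <- 0
  for (k in seq_len(k_folds)) {
    tr <- foldid != k; te <- foldid == k
    b <- fit_one(counts[tr], Xs[tr, , drop = FALSE])
    eta <- b[1] + Xs[te, , drop = FALSE] %*% b[-1]
    dev_m <- dev_m + poisson_deviance(counts[te], exp(eta))
    dev_0 <- dev_0 + poisson_deviance(counts[te],
                                      rep(mean(counts[tr]), sum(te)))
  }
  b_full <- fit_one(counts, Xs)
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  coefs[selected] <- b_full[-1]
  pr <- weight_participation_ratio(b_full[-1])
  structure(list(selected = selected, coef = coefs,
                 intercept = unname(b_full[1]),
                 cv_pseudo_r2 = 1 - dev_m / dev_0,
                 weight_pr = pr$pr, weight_pr_norm = pr$pr_norm),
            class = "wb_glm_fit")
}

#' Participation ratio of GLM weights
#'
#' `PR = (sum(w^2))^2 / sum(w^4)` over the selected weights (weights enter
#' squared, as variance-like quantities), normalized by the number of
#' selected features so that 1 indicates maximally distributed weights.
#'
#' @param w coefficient vector over the selected features.
#' @return list with `pr` and `pr_norm` in `(0, 1]`.
#' @export
weight_participation_ratio <- function(w) {
  w <- w[w != 0 & is.finite(w)]
  if (!length(w)) return(list(pr = NA_real_, pr_norm = NA_real_))
  pr <- participation_ratio(w^2)
  list(pr = pr, pr_norm = pr / length(w))
}

#' Fit encoding models for every unit
#'
#' Convenience loop: elastic-net selection then cross-validated Poisson
#' fit per unit. Units with an empty selected set get `NA` fits.
#'
#' @param count_matrix wingbeats x units spike-count matrix.
#' @param X z-scored feature matrix.
#' @param ... passed to the selection / fitting functions.
#' @return data.frame: `unit_id`, `n_selected`, `selected`
#'   (comma-separated), `cv_pseudo_r2`, `weight_pr_norm`.
#' @export
fit_unit_glms <- function(count_matrix, X, ...) {
  units <- colnames(count_matrix)
  if (is.null(units)) units <- as.character(seq_len(ncol(count_matrix)))
  rows <- lapply(seq_along(units), function(j) {
    y <- count_matrix[, j]
    sel <- select_features_elastic_net(y, X, ...)
    if (!length(sel))
      return(data.frame(unit_id = units[j], n_selected = 0L,
                        selected = "", cv_pseudo_r2 = NA_real_,
                        weight_pr_norm = NA_real_))
    fit <- fit_poisson_glm_cv(y, X, sel)
    data.frame(unit_id = units[j], n_selected = length(sel),
               selected = paste(sel, collapse = ","),
               cv_pseudo_r2 = fit$cv_pseudo_r2,
               weight_pr_norm = fit$weight_pr_norm)
  })
  do.call(rbind, rows)
}
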