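# Demixed PCA: splits trial-averaged population variance into
# condition-invariant (time-only) and condition-specific (wingbeat group
# and group x time) marginalizations, each compressed by regularized
# reduced-rank regression.

#' Marginalize a trial-averaged tensor
#'
#' Decomposes the per-unit centered tensor into a time-only part (the mean
#' across groups, identical for every group) and the group-specific
#' remainder (group main effect plus group x time interaction). The two
#' parts are orthogonal and sum to the centered tensor exactly.
#'
#' @param Xbar array units x time x groups (trial-averaged).
#' @return list of arrays `Xt`, `Xg` with `dim(Xbar)`, plus `Xc` (the
#'   centered tensor).
#' @export
dpca_marginalize <- function(Xbar) {
  d <- dim(Xbar)
  mu <- apply(Xbar, 1, mean)
  Xc <- sweep(Xbar, 1, mu)
  t_marg <- apply(Xc, c(1, 2), mean)          # N x T
  Xt <- array(rep(t_marg, d[3]), d)
  Xg <- Xc - Xt
  list(Xt = Xt, Xg = Xg, Xc = Xc)
}

# rank-q ridge reduced-rank regression of Xphi on X (both N x S)
dpca_rrr <- function(Xphi, X, lambda, q) {
  N <- nrow(X)
  G <- X %*% t(X) + diag(lambda, N)
  A_full <- Xphi %*% t(X) %*% solve(G)
  M <- A_full %*% X
  q <- min(q, N, ncol(X))
  sv <- svd(M, nu = q, nv = 0)
  U <- sv$u
  D <- t(U) %*% A_full        # encoder (q x N)
  list(F = U, D = D)          # A_q = U %*% D
}

#' Demixed PCA decomposition into group-specific and group-invariant EV
#'
#' For each marginalization (time-only; group + group x time combined) a
#' reduced-rank ridge regression maps the full trial-averaged data onto
#' that marginalization; explained variance is the fraction of total
#' centered variance captured by the marginalization's components. The
#' ridge penalty is chosen by cross-validation on split-half trial
#' averages (odd vs even trials); with fewer than 2 trials an analytic
#' heuristic is used with a warning.
#'
#' @param trials array units x time x groups x trials.
#' @param n_comp components retained per marginalization.
#' @param lambda_grid ridge penalties relative to the total variance;
#'   default `10^seq(-10, -3)`.
#' @return list: `ev_group`, `ev_time`, `ev_unexplained`, `ratio`
#'   (group-specific / group-invariant EV), `lambda`, and `components`
#'   (per marginalization: decoder `D`, encoder `F`, component scores).
#' @export
dpca_decompose <- function(trials, n_comp = 10, lambda_grid = NULL) {
  stopifnot(length(dim(trials)) == 4)
  d <- dim(trials)
  if (d[3] < 2) stop("need >= 2 groups")
  Xbar <- apply(trials, 1:3, mean)
  m <- dpca_marginalize(Xbar)
  flat <- function(A) matrix(A, d[1], d[2] * d[3])
  Xf <- flat(m$Xc); Xtf <- flat(m$Xt); Xgf <- flat(m$Xg)
  tot <- sum(Xf^2)
  if (is.null(lambda_grid)) lambda_grid <- 10^seq(-10, -3)
  lam_abs <- lambda_grid * tot
  if (d[4] >= 2) {
    odd <- seq(1, d[4], by = 2); even <- seq(2, d[4], by = 2)
    Xa <- apply(trials[, , , odd, drop = FALSE], 1:3, mean)
    Xb <- apply(trials[, , , even, drop = FALSE], 1:3, mean)
    ma <- dpca_marginalize(Xa)
    mb_c <- flat(dpca_marginalize(Xb)$Xc)
    Xaf <- flat(ma$Xc)
    err <- vapply(lam_abs, function(l) {
      rec <- matrix(0, d[1], d[2] * d[3])
      for (Xphi in list(flat(ma$Xt), flat(ma$Xg))) {
        rr <- dpca_rrr(Xphi, Xaf, l, n_comp)
        rec <- rec + rr$F %*% (rr$D %*% Xaf)
      }
      sum((mb_c - rec)^2)
    }, numeric(1))
    lambda <- lam_abs[which.min(err)]
  } else {
    warning("single trial per condition: using heuristic ridge penalty")
    lambda <- 1e-6 * tot
  }
  comp <- list()
  ev <- c(time = 0, group = 0)
  for (phi in c("time", "group")) {
    Xphi <- if (phi == "time") Xtf else Xgf
    rr <- dpca_rrr(Xphi, Xf, lambda, n_comp)
    rec <- rr$F %*% (rr$D %*% Xf)
    ev[phi] <- (tot - sum((Xf - rec)^2)) / tot
    scores <- rr$D %*% Xf
    comp[[phi]] <- list(F = rr$F, D = rr$D,
                        scores = array(scores,
                                       c(nrow(scores), d[2], d[3])))
  }
  list(ev_group = unname(ev["group"]), ev_time = unname(ev["time"]),
       ev_unexplained = max(0, 1 - sum(ev)),
       ratio = unname(ev["group"] / ev["time"]),
       lambda = lambda, components = comp)
}
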