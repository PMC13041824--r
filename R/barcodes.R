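# Wingbeat barcodes, wingbeat-group decoding, shuffle nulls, similarity
# lag curves and cross-path divergence.

#' Build binary wingbeat barcodes
#'
#' Entry `[w, u] = 1` iff unit `u` emitted at least one spike during
#' wingbeat `w`. The integer count matrix is attached as attribute
#' `"counts"` for analyses that use firing-rate vectors.
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param wingbeats wingbeat table (or `wb_wingbeats`).
#' @param units unit ids (column order); default all in `spikes`.
#' @return binary matrix wingbeats x units with `counts` attribute.
#' @export
build_barcodes <- function(spikes, wingbeats,
                           units = sort(unique(spikes$unit_id))) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  counts <- vapply(units, function(u) {
    cycle_spike_counts(spikes$t[spikes$unit_id == u], wingbeats)
  }, integer(nrow(wingbeats)))
  counts <- matrix(counts, nrow = nrow(wingbeats),
                   dimnames = list(wingbeats$wingbeat_id, units))
  B <- (counts > 0) * 1L
  attr(B, "counts") <- counts
  B
}

# one-vs-rest linear SVM with balanced class weights
ovr_svm_fit <- function(X, y, cost = 1) {
  classes <- sort(unique(y))
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    w <- c(pos = sum(yy == "neg") / length(yy),
           neg = sum(yy == "pos") / length(yy))
    e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE,
               class.weights = w)
  })
  list(classes = classes, models = models)
}

ovr_svm_predict <- function(fit, X) {
  D <- vapply(fit$models, function(m) {
    d <- attr(stats::predict(m, X, decision.values = TRUE),
              "decision.values")
    # orient so positive score means the "pos" class
    if (colnames(d)[1] == "neg/pos") -d[, 1] else d[, 1]
  }, numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X))
  fit$classes[max.col(D, ties.method = "first")]
}

#' Decode wingbeat group from barcodes
#'
#' One-vs-rest linear support-vector classification (cost 1, balanced
#' class weights) of the wingbeat-group label from binary barcode rows,
#' evaluated by stratified k-fold cross-validation. Groups with fewer than
#' `k_folds` members are merged into their ordinal neighbor (with a
#' message).
#'
#' @param barcodes matrix wingbeats x units (binary or counts).
#' @param groups integer group label per wingbeat.
#' @param k_folds stratified CV folds.
#' @param cost SVM cost parameter.
#' @return list: `confusion` (true x predicted counts over ordered group
#'   labels), `accuracy`, `predicted`, `groups` (after merging).
#' @export
decode_wingbeat_group <- function(barcodes, groups, k_folds = 5,
                                  cost = 1) {
  groups <- as.integer(groups)
  X <- as.matrix(barcodes)
  # merge undersized groups into the nearest (ordinal) neighbor label
  repeat {
    tab <- table(groups)
    small <- as.integer(names(tab)[tab < k_folds])
    if (!length(small)) break
    g <- small[1]
    others <- setdiff(unique(groups), g)
    nn <- others[which.min(abs(others - g))]
    message("merging group ", g, " (n=", tab[as.character(g)],
            ") into neighbor ", nn)
    groups[groups == g] <- nn
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >= 2 groups after merging")
  folds <- stratified_folds(groups, k_folds)
  pred <- integer(length(groups))
  for (k in seq_len(k_folds)) {
    tr <- folds != k; te <- folds == k
    fit <- ovr_svm_fit(X[tr, , drop = FALSE], groups[tr], cost)
    pred[te] <- ovr_svm_predict(fit, X[te, , drop = FALSE])
  }
  conf <- table(factor(groups, levels = lev),
                factor(pred, levels = lev))
  list(confusion = unclass(conf), accuracy = mean(pred == groups),
       predicted = pred, groups = groups)
}

#' Accuracy within a band around the true group
#'
#' Fraction of predictions within `band` groups of the truth: the sum of
#' the confusion-matrix diagonal band divided by the total. Monotone
#' non-decreasing in `band`.
#'
#' @param confusion square confusion matrix (true x predicted).
#' @param band half-width of the accepted diagonal band (0 = exact).
#' @return accuracy in `[0, 1]`.
#' @export
band_accuracy <- function(confusion, band = 0) {
  G <- nrow(confusion)
  stopifnot(ncol(confusion) == G)
  if (band >= G) warning("band >= number of groups; accuracy trivially 1")
  idx <- abs(row(confusion) - col(confusion)) <= band
  sum(confusion[idx]) / sum(confusion)
}

#' Label-shuffle null distribution of decoding accuracy
#'
#' Re-runs the full decoding pipeline with permuted group labels.
#'
#' @inheritParams decode_wingbeat_group
#' @param n_iter number of label permutations.
#' @param bands bands at which to record accuracy.
#' @return matrix `n_iter` x `length(bands)` of null accuracies.
#' @export
decoder_shuffle_null <- function(barcodes, groups, n_iter = 100,
                                 k_folds = 5, cost = 1, bands = 0) {
  out <- matrix(NA_real_, n_iter, length(bands),
                dimnames = list(NULL, paste0("band", bands)))
  for (i in seq_len(n_iter)) {
    gs <- sample(groups)
    d <- suppressMessages(decode_wingbeat_group(barcodes, gs, k_folds,
                                                cost))
    out[i, ] <- vapply(bands, function(b) band_accuracy(d$confusion, b),
                       numeric(1))
  }
  out
}

#' Cosine similarity of population vectors vs wingbeat lag
#'
#' As [adaptation_similarity_curve()] but on neural per-cycle population
#' vectors (spike counts by default, or binary barcodes); the decay of the
#' two curves can be compared with [fit_decay_constant()].
#'
#' @param barcodes matrix from [build_barcodes()].
#' @param flight_ids flight id per wingbeat row.
#' @param max_lag maximal wingbeat lag.
#' @param use `"counts"` (firing-rate vectors) or `"binary"`.
#' @return data.frame from [cosine_lag_curve()].
#' @export
barcode_similarity_curve <- function(barcodes, flight_ids, max_lag = 10,
                                     use = c("counts", "binary")) {
  use <- match.arg(use)
  M <- if (use == "counts" && !is.null(attr(barcodes, "counts")))
    attr(barcodes, "counts") else as.matrix(barcodes)
  cosine_lag_curve(M, flight_ids, max_lag)
}

# per-unit mean rate traces for a set of flights, aligned at takeoff
mean_rate_traces <- function(spikes, flights, units, bin_s, dur) {
  nb <- floor(dur / bin_s)
  M <- matrix(0, nb, length(units))
  for (i in seq_len(nrow(flights))) {
    t0 <- flights$start[i]
    for (j in seq_along(units)) {
      cnt <- bin_events(spikes$t[spikes$unit_id == units[j]], t0,
                        t0 + dur, bin_s)
      M[, j] <- M[, j] + cnt[seq_len(nb)] / bin_s
    }
  }
  M / nrow(flights)
}

#' Cross-path divergence of population activity
#'
#' Per-unit mean firing-rate traces (aligned at takeoff, truncated to the
#' shorter path) are z-scored with pooled mean/sd across both paths; the
#' divergence trace is the mean absolute z difference across units,
#' averaged in sliding windows (default 250 ms, 5 ms steps). The
#' within-path control applies the same computation between odd and even
#' flights of path A.
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param flights_a,flights_b flight tables of the two paths.
#' @param units population unit ids.
#' @param bin_s step size (s).
#' @param window_s sliding window size (s).
#' @return data.frame: `t` (s from takeoff), `between`, `within`.
#' @export
cross_path_divergence <- function(spikes, flights_a, flights_b, units,
                                  bin_s = 0.005, window_s = 0.25) {
  dur <- min(min(flights_a$end - flights_a$start),
             min(flights_b$end - flights_b$start))
  Ra <- mean_rate_traces(spikes, flights_a, units, bin_s, dur)
  Rb <- mean_rate_traces(spikes, flights_b, units, bin_s, dur)
  odd <- flights_a[seq(1, nrow(flights_a), by = 2), ]
  even <- flights_a[seq(2, nrow(flights_a), by = 2), ]
  Ro <- mean_rate_traces(spikes, odd, units, bin_s, dur)
  Re <- mean_rate_traces(spikes, even, units, bin_s, dur)
  zpair <- function(A, B) {
    mu <- colMeans(rbind(A, B))
    sd <- apply(rbind(A, B), 2, stats::sd)
    sd[sd == 0] <- 1
    za <- sweep(sweep(A, 2, mu), 2, sd, "/")
    zb <- sweep(sweep(B, 2, mu), 2, sd, "/")
    rowMeans(abs(za - zb))
  }
  w <- max(1L, round(window_s / bin_s))
  box <- function(x) as.numeric(stats::filter(x, rep(1 / w, w),
                                              sides = 2))
  data.frame(t = (seq_len(nrow(Ra)) - 0.5) * bin_s,
             between = box(zpair(Ra, Rb)),
             within = box(zpair(Ro, Re)))
}
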