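#' Assign mutations to their most likely signature and bin along the genome
#'
#' Each mutation is attributed to the signature with the highest posterior
#' attribution (ties broken by the lexicographically first signature name
#' and flagged), and counts are aggregated into fixed genomic windows.
#' Signatures averaging fewer than one mutation per window are flagged
#' ineligible for downstream epigenome matching.
#'
#' @param attributions Matrix of per-variant posteriors, mutations x
#'   signatures (named columns).
#' @param window Integer window index per mutation (1..n_windows).
#' @param n_windows Total number of windows.
#' @return List: `counts` (n_windows x signatures matrix), `eligible`
#'   (named logical), `ties` (number of tied argmax attributions).
#' @export
attribute_and_bin <- function(attributions, window, n_windows) {
  attributions <- as.matrix(attributions)
  stopifnot(nrow(attributions) == length(window))
  if (any(window < 1L | window > n_windows)) {
    stop("mutation outside the window set")
  }
  sig_names <- colnames(attributions)
  ord <- order(sig_names)  # lexicographic tie-break
  amax <- apply(attributions[, ord, drop = FALSE], 1, which.max)
  assigned <- sig_names[ord][amax]
  ties <- sum(apply(attributions, 1, function(a) sum(a == max(a)) > 1L))
  counts <- matrix(0L, n_windows, length(sig_names),
                   dimnames = list(NULL, sig_names))
  for (s in sig_names) {
    t <- tabulate(window[assigned == s], nbins = n_windows)
    counts[, s] <- t
  }
  eligible <- colMeans(counts) >= 1
  list(counts = counts, eligible = eligible, ties = ties)
}

#' LogCosh distance between observed and predicted profiles
#'
#' Mean over windows of log(cosh(observed - predicted)): approximately
#' quadratic for small residuals and linear for large ones, making it
#' robust to extreme windows.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
logcosh_distance <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  r <- abs(observed - predicted)
  # log(cosh(r)) computed stably: r + log1p(exp(-2r)) - log 2
  mean(r + log1p(exp(-2 * r)) - log(2))
}

#' Match a mutation profile to candidate epigenomes
#'
#' For each candidate epigenome, regresses per-window mutation counts on
#' that epigenome's histone-mark features with a random-forest regressor
#' (500 trees, seeded) in k-fold cross-validation, scoring each held-out
#' fold by the LogCosh distance between observed and predicted counts.
#' The best-matching epigenome has the lowest mean distance; candidates
#' are compared pairwise by a paired two-sided Wilcoxon test on the
#' per-fold distances.
#'
#' @param profile Per-window mutation counts (length n_windows).
#' @param tracks Feature matrix, n_windows x features; `groups` assigns
#'   each column to an epigenome (defaults to one epigenome per column).
#' @param groups Character vector, one entry per track column.
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment and forests).
#' @param num_trees Trees per forest (default 500).
#' @return Object of class `epigenome_match`: `scores` data.frame
#'   (epigenome, mean_distance), `fold_distances` (folds x epigenomes),
#'   `pairwise_p` (matrix), `best`.
#' @export
epigenome_match <- function(profile, tracks, groups = colnames(tracks),
                            folds = 10L, seed = 1L, num_trees = 500L) {
  tracks <- as.matrix(tracks)
  if (is.null(groups)) groups <- paste0("epi", seq_len(ncol(tracks)))
  n <- length(profile)
  stopifnot(nrow(tracks) == n)
  if (n < folds * 5L) stop("need at least folds x 5 windows")
  epis <- unique(groups)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  fold_d <- matrix(NA_real_, folds, length(epis),
                   dimnames = list(NULL, epis))
  for (e in epis) {
    X <- tracks[, groups == e, drop = FALSE]
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    df <- data.frame(y = profile, X)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      rf <- ranger::ranger(y ~ ., data = df[!test, , drop = FALSE],
                           num.trees = num_trees, seed = seed + k,
                           num.threads = 1)
      pred <- stats::predict(rf, df[test, , drop = FALSE])$predictions
      fold_d[k, e] <- logcosh_distance(profile[test], pred)
    }
  }
  mean_d <- colMeans(fold_d)
  pw <- matrix(NA_real_, length(epis), length(epis),
               dimnames = list(epis, epis))
  for (i in seq_along(epis)) {
    for (j in seq_along(epis)) {
      if (i == j) next
      pw[i, j] <- if (isTRUE(all.equal(fold_d[, i], fold_d[, j]))) 1 else
        suppressWarnings(stats::wilcox.test(fold_d[, i], fold_d[, j],
                                            paired = TRUE)$p.value)
    }
  }
  structure(list(
    scores = data.frame(epigenome = epis, mean_distance = unname(mean_d)),
    fold_distances = fold_d, pairwise_p = pw,
    best = epis[which.min(mean_d)]
  ), class = "epigenome_match")
}

#' @export
print.epigenome_match <- function(x, ...) {
  cat("Epigenome match (LogCosh, cross-validated)\n")
  s <- x$scores[order(x$scores$mean_distance), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f%s\n", s$epigenome[i], s$mean_distance[i],
                if (s$epigenome[i] == x$best) "  <- best" else ""))
  }
  invisible(x)
}

#' Subsample a window profile to a target total
#'
#' Draws without replacement from the mutations of the larger profile
#' (multivariate hypergeometric across windows, seeded), so the expected
#' subsampled count per window is proportional to the original.
#'
#' @param profile Integer per-window counts.
#' @param target Total mutations after subsampling.
#' @param seed Integer seed.
#' @return Integer profile with sum equal to `target`.
#' @export
subsample_profile <- function(profile, target, seed = 1L) {
  total <- sum(profile)
  if (target > total) stop("target exceeds profile total")
  if (target == total) return(profile)
  set.seed(seed)
  out <- integer(length(profile))
  remaining <- total
  need <- target
  for (i in seq_along(profile)) {
    if (need == 0L) break
    k <- stats::rhyper(1, profile[i], remaining - profile[i], need)
    out[i] <- k
    need <- need - k
    remaining <- remaining - profile[i]
  }
  out
}

#' Compare two signatures' epigenome matches at equal mutation numbers
#'
#' Subsamples the larger profile to the smaller's total, runs
#' [epigenome_match()] on both, and compares fold distances of the best
#' matches with an unpaired two-sided Wilcoxon test.
#'
#' @param profileA,profileB Per-window counts (A's total >= B's).
#' @param tracks,groups,folds,seed As in [epigenome_match()].
#' @return List: matchA, matchB (on the equalised profiles), p (unpaired
#'   Wilcoxon between the best matches' fold distances).
#' @export
matched_count_control <- function(profileA, profileB, tracks,
                                  groups = colnames(tracks), folds = 10L,
                                  seed = 1L) {
  if (sum(profileA) == 0 || sum(profileB) == 0) stop("zero-total profile")
  if (sum(profileA) < sum(profileB)) stop("profileA must have the larger total")
  a <- subsample_profile(profileA, sum(profileB), seed = seed)
  mA <- epigenome_match(a, tracks, groups, folds, seed)
  mB <- epigenome_match(profileB, tracks, groups, folds, seed)
  dA <- mA$fold_distances[, mA$best]
  dB <- mB$fold_distances[, mB$best]
  p <- suppressWarnings(stats::wilcox.test(dA, dB)$p.value)
  list(matchA = mA, matchB = mB, p = p)
}
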