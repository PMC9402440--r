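#' Genotype a colony at a candidate variant
#'
#' A variant is called present in a colony if it has at least two
#' alternate reads and a variant allele fraction (VAF) of at least 20%.
#'
#' @param alt,depth Integer vectors of alternate and total read counts.
#' @return Logical vector: TRUE = present.
#' @export
call_genotype <- function(alt, depth) {
  if (any(alt > depth)) stop("alt cannot exceed depth")
  if (any(alt < 0 | depth < 0)) stop("counts must be non-negative")
  depth > 0 & alt >= 2L & alt / pmax(depth, 1L) >= 0.20
}

#' Mean-VAF germline screen across a donor's colonies
#'
#' Variants whose mean VAF over colonies with non-zero depth exceeds 40%
#' are flagged as probable germline and dropped.
#'
#' @param alt,depth Count vectors over the donor's colonies (one variant).
#' @return "keep", "drop", or "indeterminate" when no colony has depth.
#' @export
mean_vaf_screen <- function(alt, depth) {
  ok <- depth > 0
  if (!any(ok)) return("indeterminate")
  if (mean(alt[ok] / depth[ok]) > 0.40) "drop" else "keep"
}

#' One-sided exact binomial test for germline allele balance
#'
#' Tests whether the pooled alternate-read fraction across a donor's
#' colonies is consistent with the heterozygous expectation `p0` (0.5 for
#' autosomes and female X; 0.95 for male sex chromosomes), against the
#' alternative that the success proportion is less than `p0`.
#'
#' @param sum_alt,sum_depth Pooled alternate and total read counts.
#' @param p0 Null success probability.
#' @return Exact lower-tail p-value P(X <= sum_alt | Binomial(sum_depth, p0)).
#' @export
aggregate_binomial_test <- function(sum_alt, sum_depth, p0 = 0.5) {
  if (any(sum_depth <= 0)) stop("sum_depth must be positive")
  if (any(sum_alt > sum_depth)) stop("sum_alt cannot exceed sum_depth")
  stats::pbinom(sum_alt, sum_depth, p0)
}

#' Classify variants as germline by failure to reject allele balance
#'
#' Benjamini-Hochberg q-values are computed within the donor; a variant is
#' called germline when the null is not rejected at q >= 1e-6.
#'
#' @param p Vector of [aggregate_binomial_test()] p-values.
#' @param q_threshold FDR threshold below which the null is rejected.
#' @return data.frame with p, q and label ("germline"/"somatic").
#' @export
classify_germline <- function(p, q_threshold = 1e-6) {
  if (length(p) == 0L) {
    return(data.frame(p = numeric(0), q = numeric(0), label = character(0)))
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q,
             label = ifelse(q >= q_threshold, "germline", "somatic"),
             stringsAsFactors = FALSE)
}

# beta-binomial log-likelihood at shared mean mu and overdispersion rho,
# vectorised over a sites x colonies count matrix
.bb_loglik <- function(alt, depth, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  ll <- lbeta(alt + a, depth - alt + b) - lbeta(a, b) +
    lchoose(depth, alt)
  rowSums(ll)
}

.rho_grid <- function() c(1e-4, exp(seq(log(2e-4), log(0.999), length.out = 60)))

#' Beta-binomial overdispersion test across a donor's colonies
#'
#' Fits a beta-binomial with shared mean across colonies by maximum
#' likelihood over a fixed grid of overdispersion values rho in (0, 1),
#' and compares it to the binomial fit (rho -> 0) with a likelihood-ratio
#' statistic. Germline variants and binomial artefacts are not
#' overdispersed; truly clonal somatic variants, present at VAF ~0.5 in a
#' subset of colonies and absent elsewhere, are strongly overdispersed.
#'
#' Accepts a single variant (vectors) or a sites x colonies matrix.
#'
#' @param alt,depth Count vectors, or matrices with one row per variant.
#' @return data.frame: rho_hat (grid-ML estimate), stat (LRT statistic),
#'   p (chi-square 1 df tail, halved for the boundary) and score
#'   (-log10 p), one row per variant.
#' @export
betabinom_overdispersion <- function(alt, depth) {
  if (is.null(dim(alt))) alt <- matrix(alt, nrow = 1L)
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = 1L)
  stopifnot(all(dim(alt) == dim(depth)))
  if (any(rowSums(depth > 0) < 3L)) {
    stop("need at least 3 colonies with positive depth per variant")
  }
  mu <- rowSums(alt) / rowSums(depth)
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  ll0 <- rowSums(stats::dbinom(alt, depth, mu, log = TRUE))
  grid <- .rho_grid()
  ll <- sapply(grid, function(r) .bb_loglik(alt, depth, mu, r))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  best <- max.col(ll, ties.method = "first")
  ll1 <- ll[cbind(seq_len(nrow(ll)), best)]
  rho_hat <- grid[best]
  stat <- pmax(2 * (ll1 - ll0), 0)
  # variants with no alternate reads carry no overdispersion signal
  none <- rowSums(alt) == 0
  rho_hat[none] <- 0
  stat[none] <- 0
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p <- pmin(p, 1)
  data.frame(rho_hat = rho_hat, stat = stat, p = p,
             score = -log10(pmax(p, 1e-300)))
}

#' Valley-finding threshold between two modes of a score distribution
#'
#' Estimates a kernel density (Silverman bandwidth) over the scores,
#' identifies the two largest modes, and returns the score at the deepest
#' local minimum between them. If the density is unimodal the configured
#' fallback is returned with a flag.
#'
#' @param scores Numeric vector (>= 50 values).
#' @param fallback Cutoff to use when no valley exists.
#' @param min_peak_frac Modes below this fraction of the tallest mode are
#'   treated as density-estimation wiggles, not real modes.
#' @return List: cutoff, fallback_used (logical).
#' @export
valley_threshold <- function(scores, fallback = stats::median(scores),
                             min_peak_frac = 0.1) {
  if (length(scores) < 50L) stop("need at least 50 scores for a reliable density")
  d <- stats::density(scores, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n], FALSE)
  peaks <- which(is_max)
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y)]
  if (length(peaks) < 2L) {
    return(list(cutoff = fallback, fallback_used = TRUE))
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valleys <- which(is_min)
  valleys <- valleys[valleys > lo & valleys < hi]
  if (!length(valleys)) {
    return(list(cutoff = fallback, fallback_used = TRUE))
  }
  best <- valleys[order(y[valleys], d$x[valleys])][1]  # deepest, then smallest
  list(cutoff = d$x[best], fallback_used = FALSE)
}

#' Per-colony sensitivity from germline-variant recall
#'
#' Sensitivity is the proportion of (true) germline variants genotyped
#' present in a colony.
#'
#' @param present Logical matrix, germline variants x colonies (or vector
#'   for a single colony), as returned by [call_genotype()].
#' @return Numeric vector of per-colony sensitivities in [0, 1].
#' @export
germline_recall_sensitivity <- function(present) {
  if (is.null(dim(present))) present <- matrix(present, ncol = 1L)
  if (nrow(present) == 0L) stop("germline set must be non-empty")
  colMeans(present)
}

#' Filter a donor's candidate variants into germline, somatic and artefact
#'
#' Runs the full unmatched-normal filtering cascade on a read-count
#' matrix: (1) mean-VAF screen (> 40% -> GERMLINE); (2) pooled one-sided
#' exact binomial test against allele balance with Benjamini-Hochberg
#' control, failure to reject at q >= 1e-6 -> GERMLINE; (3) beta-binomial
#' overdispersion score with a per-donor valley-finding cutoff on the
#' -log10 tail probability — variants below the cutoff are rejected as
#' ARTEFACT_BB, variants above it PASS as somatic. An optional external
#' `subclonal` logical vector (e.g. from a subclonality caller) is AND-ed
#' with the overdispersion pass, and an optional `blacklist` is applied
#' up-front.
#'
#' @param alt,depth Integer matrices, sites x colonies.
#' @param p0 Null allele fraction for the pooled binomial test.
#' @param q_threshold FDR threshold for the germline call.
#' @param subclonal Optional logical vector, one per site.
#' @param blacklist Optional logical vector; TRUE sites are dropped as
#'   ARTEFACT_EXTERNAL.
#' @return List of class `filter_result`: `table` (per-site label, scores,
#'   p, q), `cutoff`, `fallback_used`, `sensitivity` (per colony, from the
#'   germline-labelled set), and `genotypes` (sites x colonies logical).
#' @export
filter_variants <- function(alt, depth, p0 = 0.5, q_threshold = 1e-6,
                            subclonal = NULL, blacklist = NULL) {
  stopifnot(is.matrix(alt), all(dim(alt) == dim(depth)))
  n <- nrow(alt)
  label <- rep(NA_character_, n)
  if (!is.null(blacklist)) label[blacklist] <- "ARTEFACT_EXTERNAL"

  vaf_call <- vapply(seq_len(n), function(i) mean_vaf_screen(alt[i, ], depth[i, ]), "")
  label[is.na(label) & vaf_call == "drop"] <- "GERMLINE"

  p <- aggregate_binomial_test(rowSums(alt), rowSums(depth), p0)
  q <- stats::p.adjust(p, method = "BH")
  label[is.na(label) & q >= q_threshold] <- "GERMLINE"

  od <- betabinom_overdispersion(alt, depth)
  open <- which(is.na(label))
  vt <- valley_threshold(od$score[open])
  pass <- od$score[open] > vt$cutoff
  if (!is.null(subclonal)) pass <- pass & subclonal[open]
  label[open] <- ifelse(pass, "PASS", "ARTEFACT_BB")

  geno <- matrix(call_genotype(as.vector(alt), as.vector(depth)),
                 nrow = n, dimnames = dimnames(alt))
  germ <- label == "GERMLINE"
  sens <- if (any(germ)) germline_recall_sensitivity(geno[germ, , drop = FALSE])
          else rep(NA_real_, ncol(alt))
  structure(list(
    table = data.frame(site = seq_len(n), label = label, p = p, q = q,
                       rho_hat = od$rho_hat, score = od$score),
    cutoff = vt$cutoff, fallback_used = vt$fallback_used,
    sensitivity = sens, genotypes = geno
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  tab <- table(x$table$label)
  cat("Variant filtering result\n")
  cat("  sites:", nrow(x$table), "\n")
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  cat(sprintf("  overdispersion score cutoff: %.2f%s\n", x$cutoff,
              if (x$fallback_used) " (fallback)" else ""))
  cat(sprintf("  median colony sensitivity: %.4f\n",
              stats::median(x$sensitivity, na.rm = TRUE)))
  invisible(x)
}
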