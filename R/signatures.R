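#' Cosine similarity between two mutation spectra
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Cosine similarity in [0, 1] for non-negative spectra.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# EM maximum likelihood for multinomial mixture exposures
.fit_exposures_ml <- function(counts, sigs, tol = 1e-10, max_iter = 5000L) {
  S <- ncol(sigs)
  w <- rep(1 / S, S)
  n <- sum(counts)
  nz <- counts > 0
  cts <- counts[nz]
  P <- sigs[nz, , drop = FALSE]
  for (it in seq_len(max_iter)) {
    num <- P * rep(w, each = nrow(P))         # channel x sig
    denom <- rowSums(num)
    r <- num / pmax(denom, 1e-300)
    w_new <- colSums(r * cts) / n
    if (sum(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Estimate signature exposures for a mutation catalogue
#'
#' Maximum-likelihood mixing proportions under counts ~ Multinomial(n,
#' sum_s w_s S_s), found by expectation-maximisation on the simplex, with
#' a 90% interval per signature from a seeded multinomial bootstrap
#' (resample the catalogue, refit, take the 5th and 95th percentiles).
#'
#' @param catalog Integer 96-vector of channel counts (canonical order).
#' @param sigs 96 x S signature matrix.
#' @param n_boot Bootstrap refits (0 disables the interval).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `exposure_fit`: `exposures` (named
#'   proportions), `lower`, `upper` (90% interval), `counts`
#'   (proportion x total burden), `total`.
#' @export
fit_exposures <- function(catalog, sigs, n_boot = 200L, seed = 1L) {
  if (length(catalog) != nrow(sigs)) {
    stop("catalogue must have one count per signature channel")
  }
  if (sum(catalog) <= 0) stop("catalogue is empty")
  if (any(catalog < 0)) stop("negative catalogue counts")
  w <- .fit_exposures_ml(catalog, sigs)
  names(w) <- colnames(sigs)
  lower <- upper <- rep(NA_real_, length(w))
  if (n_boot > 0) {
    set.seed(seed)
    n <- sum(catalog)
    boot <- replicate(n_boot, {
      res <- stats::rmultinom(1, n, catalog / n)[, 1]
      .fit_exposures_ml(res, sigs)
    })
    lower <- apply(boot, 1, stats::quantile, probs = 0.05)
    upper <- apply(boot, 1, stats::quantile, probs = 0.95)
  }
  structure(list(exposures = w, lower = lower, upper = upper,
                 counts = w * sum(catalog), total = sum(catalog)),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposures (", x$total, " mutations)\n", sep = "")
  for (i in seq_along(x$exposures)) {
    cat(sprintf("  %-9s %6.3f", names(x$exposures)[i], x$exposures[i]))
    if (!is.na(x$lower[i])) {
      cat(sprintf("  [90%%: %.3f-%.3f]", x$lower[i], x$upper[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Drop globally rare signatures and refit exposures
#'
#' Signatures whose first-pass exposure is below `drop_threshold` in every
#' sample are removed from the catalogue and all samples are refitted on
#' the reduced set. A per-sample display mask is also computed: a
#' signature is displayed for a sample only when the lower bound of its
#' 90% interval is at least `display_lower`.
#'
#' @param catalogs Matrix of channel counts, 96 x n_samples.
#' @param sigs 96 x S signature matrix.
#' @param drop_threshold Global exclusion rule (default 0.10).
#' @param display_lower Per-sample display rule (default 0.01).
#' @param n_boot,seed Bootstrap settings passed to [fit_exposures()].
#' @return List: `sigs` (reduced matrix), `dropped` (names), `exposures`
#'   (S' x n_samples matrix of refitted proportions), `display` (logical
#'   S' x n_samples), `fits` (list of `exposure_fit`).
#' @export
exclude_and_refit <- function(catalogs, sigs, drop_threshold = 0.10,
                              display_lower = 0.01, n_boot = 100L, seed = 1L) {
  catalogs <- as.matrix(catalogs)
  first <- sapply(seq_len(ncol(catalogs)), function(j) {
    .fit_exposures_ml(catalogs[, j], sigs)
  })
  rownames(first) <- colnames(sigs)
  keep <- apply(first, 1, max) >= drop_threshold
  if (!any(keep)) stop("exclusion rule would drop every signature")
  reduced <- sigs[, keep, drop = FALSE]
  fits <- lapply(seq_len(ncol(catalogs)), function(j) {
    fit_exposures(catalogs[, j], reduced, n_boot = n_boot, seed = seed + j)
  })
  expo <- sapply(fits, function(f) f$exposures)
  low <- sapply(fits, function(f) f$lower)
  rownames(expo) <- rownames(low) <- colnames(reduced)
  list(sigs = reduced, dropped = colnames(sigs)[!keep], exposures = expo,
       display = low >= display_lower, fits = fits)
}

#' Posterior signature attribution for a single variant
#'
#' Given the sample's exposures w and the catalogue S, a mutation in
#' channel c is attributed P(s | c) = w_s S_s[c] / sum_t w_t S_t[c].
#'
#' @param channel Channel index (1..96) or label.
#' @param exposures Exposure vector (named by signature).
#' @param sigs 96 x S signature matrix.
#' @return Named posterior probabilities summing to 1.
#' @export
per_variant_attribution <- function(channel, exposures, sigs) {
  if (is.character(channel)) channel <- match(channel, rownames(sigs))
  if (is.na(channel) || channel < 1 || channel > nrow(sigs)) {
    stop("channel outside the 96-channel scheme")
  }
  num <- exposures * sigs[channel, ]
  tot <- sum(num)
  if (tot <= 0) stop("channel has zero probability under every active signature")
  num / tot
}

#' Attribute mutations to signatures within fine-scale genomic bins
#'
#' Mutation placement within each coarse (e.g. 1-Mb) window is refined to
#' sub-bins (e.g. 10 kb): each mutation contributes its posterior
#' attribution P(s | channel), computed under its parent window's
#' exposures, to the sub-bin it falls in. A sub-bin is included for a
#' signature only when the mean attribution of its mutations to that
#' signature exceeds 0.5, which protects against high-burden bins
#' acquiring spurious counts from trivially small attributions.
#'
#' @param mutations data.frame with columns `pos`, `channel` (1..96 or
#'   label), and `window` (parent window id).
#' @param window_exposures Matrix of exposures, signatures x windows
#'   (columns named by window id).
#' @param sigs 96 x S signature matrix.
#' @param bin_size Sub-bin width in bp (default 10000).
#' @return data.frame: bin start, one expected-count column per signature,
#'   `raw_count`, and one `included_<sig>` flag per signature.
#' @export
window_attribution <- function(mutations, window_exposures, sigs,
                               bin_size = 10000) {
  stopifnot(all(c("pos", "channel", "window") %in% names(mutations)))
  if (!all(as.character(mutations$window) %in% colnames(window_exposures))) {
    stop("mutation outside any fitted window")
  }
  S <- colnames(sigs)
  att <- t(vapply(seq_len(nrow(mutations)), function(i) {
    per_variant_attribution(mutations$channel[i],
                            window_exposures[, as.character(mutations$window[i])],
                            sigs)
  }, numeric(length(S))))
  bin <- floor(mutations$pos / bin_size)
  agg <- rowsum(att, bin)
  nmut <- as.vector(rowsum(rep(1, nrow(att)), bin))
  means <- agg / nmut
  out <- data.frame(bin_start = as.numeric(rownames(agg)) * bin_size,
                    agg, raw_count = nmut, check.names = FALSE)
  for (s in S) out[[paste0("included_", s)]] <- means[, s] > 0.5
  rownames(out) <- NULL
  out
}

#' Per-gene signature enrichment against genomic background
#'
#' For each gene, the mean per-variant attribution to the signature is
#' compared with the genome-wide mean by a two-sided one-sample t-test.
#' Genes with fewer than two variants return NA with a flag.
#'
#' @param attribution Per-variant attribution values (one signature).
#' @param gene Gene label per variant (NA = intergenic; still contributes
#'   to the background mean).
#' @param background Genome-wide mean attribution; default the mean over
#'   all variants.
#' @return data.frame: gene, n, mean_attribution, p, testable.
#' @export
gene_signature_enrichment <- function(attribution, gene,
                                      background = mean(attribution)) {
  stopifnot(length(attribution) == length(gene))
  genes <- sort(unique(gene[!is.na(gene)]))
  res <- lapply(genes, function(g) {
    a <- attribution[!is.na(gene) & gene == g]
    if (length(a) < 2L || stats::sd(a) == 0) {
      # degenerate variance: identical to background is uninformative (p=1),
      # identical but shifted is unambiguous (p=0), single variant untestable
      p <- if (length(a) < 2L) NA_real_
        else if (all(a == background)) 1 else 0
      return(data.frame(gene = g, n = length(a), mean_attribution = mean(a),
                        p = p, testable = !is.na(p)))
    }
    tt <- stats::t.test(a, mu = background)
    data.frame(gene = g, n = length(a), mean_attribution = mean(a),
               p = tt$p.value, testable = TRUE)
  })
  do.call(rbind, res)
}
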