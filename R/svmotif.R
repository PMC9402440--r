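#' Position weight matrices for RSS motifs
#'
#' Consensus-derived PWMs for the recombination signal sequence: heptamer
#' CACAGTG and nonamer ACAAAAACC, with probability 0.85 on the consensus
#' base and 0.05 on each alternative.
#'
#' @param kind "heptamer" or "nonamer".
#' @return 4 x L probability matrix with rownames A, C, G, T.
#' @export
rss_pwm <- function(kind = c("heptamer", "nonamer")) {
  kind <- match.arg(kind)
  cons <- strsplit(switch(kind, heptamer = "CACAGTG", nonamer = "ACAAAAACC"),
                   "")[[1]]
  m <- matrix(0.05, 4, length(cons), dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(cons)) m[cons[j], j] <- 0.85
  m
}

#' Exact tail probability of a PWM log-odds score under uniform background
#'
#' Enumerates the full distribution of the log-odds score (log p/0.25 per
#' position) of a random uniform sequence by convolving the per-position
#' score distributions, and returns P(S >= score).
#'
#' @param pwm 4 x L probability matrix.
#' @param score Observed log-odds score.
#' @return Exact tail probability.
#' @export
pwm_tail_prob <- function(pwm, score) {
  dist <- data.frame(s = 0, p = 1)
  for (j in seq_len(ncol(pwm))) {
    col <- log(pwm[, j] / 0.25)
    new_s <- as.vector(outer(dist$s, col, "+"))
    new_p <- as.vector(outer(dist$p, rep(0.25, 4), "*"))
    key <- round(new_s, 9)
    agg <- rowsum(new_p, key)
    dist <- data.frame(s = as.numeric(rownames(agg)), p = as.vector(agg))
  }
  sum(dist$p[dist$s >= score - 1e-6])
}

#' Log-odds score cutoff at a scan p-value threshold
#'
#' The smallest achievable score whose exact tail probability is below
#' `p_threshold`; a scanned position is a hit when its score reaches the
#' cutoff.
#'
#' @param pwm 4 x L probability matrix.
#' @param p_threshold Scan p-value threshold (default 1e-4).
#' @return Numeric score cutoff.
#' @export
pwm_score_cutoff <- function(pwm, p_threshold = 1e-4) {
  dist <- data.frame(s = 0, p = 1)
  for (j in seq_len(ncol(pwm))) {
    col <- log(pwm[, j] / 0.25)
    new_s <- as.vector(outer(dist$s, col, "+"))
    new_p <- as.vector(outer(dist$p, rep(0.25, 4), "*"))
    key <- round(new_s, 9)
    agg <- rowsum(new_p, key)
    dist <- data.frame(s = as.numeric(rownames(agg)), p = as.vector(agg))
  }
  dist <- dist[order(-dist$s), ]
  tail_p <- cumsum(dist$p)
  ok <- which(tail_p < p_threshold)
  if (!length(ok)) stop("no achievable score reaches the p-value threshold")
  dist$s[max(ok)]
}

.pwm_cache <- new.env(parent = emptyenv())

.cached_cutoff <- function(kind) {
  if (is.null(.pwm_cache[[kind]])) {
    .pwm_cache[[kind]] <- pwm_score_cutoff(rss_pwm(kind))
  }
  .pwm_cache[[kind]]
}

.seq_to_chars <- function(s) strsplit(toupper(s), "")[[1]]

.revcomp <- function(s) {
  paste(rev(unname(.complement[.seq_to_chars(s)])), collapse = "")
}

# scan one strand of a character sequence; returns start positions and scores
.scan_one <- function(chars, pwm, cutoff) {
  L <- ncol(pwm)
  n <- length(chars) - L + 1L
  if (n < 1L) return(data.frame(start = integer(0), score = numeric(0)))
  idx <- match(chars, c("A", "C", "G", "T"))
  logodds <- log(pwm / 0.25)
  score <- numeric(n)
  for (j in seq_len(L)) {
    v <- logodds[cbind(idx[j:(j + n - 1L)], j)]
    v[is.na(v)] <- -Inf
    score <- score + v
  }
  hit <- which(score >= cutoff - 1e-6)
  data.frame(start = hit, score = score[hit])
}

#' Scan a breakpoint's flanks for RSS motifs
#'
#' Scans both strands of the `window` bp on each side of a breakpoint for
#' the RSS heptamer and for the full RSS (heptamer + 12 or 23 bp spacer,
#' with 1 bp tolerance, + nonamer), using consensus PWMs and an exact
#' enumeration p-value threshold of 1e-4 per motif component.
#'
#' @param reference Reference sequence (character scalar).
#' @param breakpoint 1-based breakpoint position.
#' @param window Flank width in bp (default 50).
#' @param interior +1 if interior of the SV lies at higher coordinates
#'   than the breakpoint, -1 if lower, 0 if undefined (non-deletions);
#'   controls the sign of the reported positions.
#' @return data.frame of hits: kind ("RSS-heptamer" or "RSS-full"),
#'   position (signed bp of the motif start relative to the breakpoint;
#'   positive = interior), strand, score, spacer (NA for heptamer-only).
#' @export
scan_rss <- function(reference, breakpoint, window = 50, interior = 1L) {
  hep <- rss_pwm("heptamer"); non <- rss_pwm("nonamer")
  cut_h <- .cached_cutoff("heptamer"); cut_n <- .cached_cutoff("nonamer")
  glen <- nchar(reference)
  lo <- max(1L, breakpoint - window)
  hi <- min(glen, breakpoint + window + ncol(hep) - 1L)
  truncated <- lo > breakpoint - window || hi < breakpoint + window + ncol(hep) - 1L
  win <- substr(reference, lo, hi)
  chars_p <- .seq_to_chars(win)
  chars_m <- .seq_to_chars(.revcomp(win))
  wlen <- nchar(win)

  hits <- list()
  for (strand in c("+", "-")) {
    chars <- if (strand == "+") chars_p else chars_m
    h <- .scan_one(chars, hep, cut_h)
    if (nrow(h)) {
      # genome start of each heptamer hit
      gstart <- if (strand == "+") lo + h$start - 1L else
        lo + (wlen - (h$start + ncol(hep) - 1L))
      full <- rep(NA_integer_, nrow(h))
      nh <- .scan_one(chars, non, cut_n)
      for (i in seq_len(nrow(h))) {
        for (sp in c(11:13, 22:24)) {
          want <- h$start[i] + ncol(hep) + sp
          if (any(nh$start == want)) { full[i] <- sp; break }
        }
      }
      rel <- gstart - breakpoint
      if (interior < 0) rel <- -rel
      hits[[strand]] <- data.frame(
        kind = ifelse(is.na(full), "RSS-heptamer", "RSS-full"),
        position = rel, strand = strand, score = h$score, spacer = full,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(0), position = integer(0),
               strand = character(0), score = numeric(0), spacer = integer(0))
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Scan a breakpoint's flanks for a CSR switch-motif cluster
#'
#' A cluster is at least two exact AGCT or TGCA occurrences with
#' consecutive gaps of at most `max_gap` bp, anywhere within `window` bp
#' of the breakpoint.
#'
#' @param reference Reference sequence (character scalar).
#' @param breakpoint 1-based position.
#' @param window Flank width (default 1000).
#' @param max_gap Maximum gap between consecutive motif starts' ends
#'   (default 100).
#' @return TRUE if a cluster is present.
#' @export
scan_csr <- function(reference, breakpoint, window = 1000, max_gap = 100) {
  glen <- nchar(reference)
  lo <- max(1L, breakpoint - window)
  hi <- min(glen, breakpoint + window + 3L)
  win <- substr(reference, lo, hi)
  starts <- sort(unique(c(
    as.vector(gregexpr("AGCT", win, fixed = TRUE)[[1]]),
    as.vector(gregexpr("TGCA", win, fixed = TRUE)[[1]])
  )))
  starts <- starts[starts > 0]
  if (length(starts) < 2L) return(FALSE)
  gaps <- diff(starts) - 4L  # gap between end of one match and start of next
  any(gaps <= max_gap)
}

#' Genomic background rate of breakpoint motif hits
#'
#' Draws `n_sets` control sets of `set_size` positions from the callable
#' mask, applies the supplied per-position scan to each, and returns the
#' median per-set hit proportion — the motif rate expected at random
#' breakpoints.
#'
#' @param reference Reference sequence.
#' @param mask Integer vector of callable 1-based positions.
#' @param n_sets Number of control sets (default 100).
#' @param set_size Positions per set.
#' @param seed Integer seed.
#' @param scan_fn Function(reference, position) -> logical hit; default
#'   any RSS heptamer/full hit within 50 bp.
#' @return List: background (median proportion), per_set (n_sets values).
#' @export
genomic_background <- function(reference, mask, n_sets = 100, set_size,
                               seed = 1L,
                               scan_fn = function(ref, pos)
                                 nrow(scan_rss(ref, pos)) > 0) {
  if (length(mask) < set_size) stop("callable mask too small for set_size")
  set.seed(seed)
  per_set <- vapply(seq_len(n_sets), function(s) {
    pos <- sample(mask, set_size)
    mean(vapply(pos, function(p) scan_fn(reference, p), TRUE))
  }, numeric(1))
  list(background = stats::median(per_set), per_set = per_set)
}

#' Background-corrected mechanism-attributable fraction
#'
#' The fraction of structural variants attributable to the mechanism is
#' the observed motif proportion minus the genomic background proportion,
#' clamped at zero.
#'
#' @param p_obs Observed proportion of SVs with the motif.
#' @param p_bg Genomic background proportion.
#' @return max(p_obs - p_bg, 0).
#' @export
rag_attributable_fraction <- function(p_obs, p_bg) {
  stopifnot(p_obs >= 0, p_obs <= 1, p_bg >= 0, p_bg <= 1)
  pmax(p_obs - p_bg, 0)
}

#' Classify a breakpoint as Ig-TCR or other
#'
#' @param chrom,pos Breakpoint coordinates (1-based).
#' @param intervals data.frame(chrom, start, end), 1-based inclusive;
#'   defaults to [ig_tcr_intervals()].
#' @return "IgTCR" or "other".
#' @export
classify_region <- function(chrom, pos, intervals = ig_tcr_intervals()) {
  if (!chrom %in% c(intervals$chrom, paste0("chr", 1:22), "chrX", "chrY", "chrS")) {
    stop("unknown chromosome: ", chrom)
  }
  hit <- intervals$chrom == chrom & pos >= intervals$start & pos <= intervals$end
  if (any(hit)) "IgTCR" else "other"
}

#' Immunoglobulin and T cell receptor intervals (GRCh37)
#'
#' The three Ig loci (IGH on chr14, IGK on chr2, IGL on chr22) use the
#' exclusion intervals applied in selection analysis; the four TCR loci
#' (TRA/TRD on chr14, TRB on chr7, TRG on chr7) are standard GRCh37 gene
#' spans and can be replaced with a custom table.
#'
#' @return data.frame: chrom, start, end, locus (1-based inclusive).
#' @export
ig_tcr_intervals <- function() {
  data.frame(
    chrom = c("chr14", "chr2", "chr22", "chr14", "chr7", "chr7"),
    start = c(106304735, 89160078, 22385390, 22090057, 141998851, 38279625),
    end = c(107283226, 90274237, 23263607, 23021097, 142510972, 38407656),
    locus = c("IGH", "IGK", "IGL", "TRA_TRD", "TRB", "TRG"),
    stringsAsFactors = FALSE
  )
}

#' Annotate structural variants for RSS and CSR motifs
#'
#' Runs [scan_rss()] (both breakpoints, interior-signed for deletions) and
#' [scan_csr()] on each SV.
#'
#' @param reference Reference sequence.
#' @param svs data.frame with columns posA, posB, class (and optionally
#'   insseq).
#' @param window,csr_window Scan windows in bp.
#' @return `svs` with added columns rss_hit, rss_full, rss_position
#'   (closest hit, interior-positive), csr_cluster, has_insertion.
#' @export
annotate_svs <- function(reference, svs, window = 50, csr_window = 1000) {
  n <- nrow(svs)
  rss_hit <- logical(n); rss_full <- logical(n)
  rss_position <- rep(NA_integer_, n); csr_cluster <- logical(n)
  for (i in seq_len(n)) {
    is_del <- svs$class[i] == "deletion"
    hA <- scan_rss(reference, svs$posA[i], window,
                   interior = if (is_del) 1L else 0L)
    hB <- scan_rss(reference, svs$posB[i], window,
                   interior = if (is_del) -1L else 0L)
    h <- rbind(hA, hB)
    if (nrow(h)) {
      rss_hit[i] <- TRUE
      rss_full[i] <- any(h$kind == "RSS-full")
      rss_position[i] <- h$position[which.min(abs(h$position))]
    }
    csr_cluster[i] <- scan_csr(reference, svs$posA[i], csr_window) ||
      scan_csr(reference, svs$posB[i], csr_window)
  }
  svs$rss_hit <- rss_hit
  svs$rss_full <- rss_full
  svs$rss_position <- rss_position
  svs$csr_cluster <- csr_cluster
  svs$has_insertion <- if ("insseq" %in% names(svs)) nzchar(svs$insseq) else NA
  svs
}

#' Proportion of deletions with an RSS motif by distance from breakpoint
#'
#' Bins the signed motif-to-breakpoint distances (positive = interior to
#' the deletion) and reports the proportion of deletions with a hit in
#' each bin, with the genomic background overlaid.
#'
#' @param reference Reference sequence.
#' @param svs Deletion records (posA, posB, class == "deletion").
#' @param bin_width Distance bin width in bp.
#' @param max_distance Profile half-width in bp.
#' @param background Background proportion line (scalar, optional).
#' @return data.frame: bin midpoint, proportion, background; class
#'   `motif_profile`.
#' @export
motif_distance_profile <- function(reference, svs, bin_width = 10,
                                   max_distance = 200, background = NA_real_) {
  svs <- svs[svs$class == "deletion", , drop = FALSE]
  breaks <- seq(-max_distance, max_distance, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  if (nrow(svs) == 0L) {
    return(structure(data.frame(distance = numeric(0), proportion = numeric(0),
                                background = numeric(0)),
                     class = c("motif_profile", "data.frame")))
  }
  hitmat <- matrix(FALSE, nrow(svs), length(mids))
  for (i in seq_len(nrow(svs))) {
    hA <- scan_rss(reference, svs$posA[i], max_distance, interior = 1L)
    hB <- scan_rss(reference, svs$posB[i], max_distance, interior = -1L)
    pos <- c(hA$position, hB$position)
    if (length(pos)) {
      b <- findInterval(pos, breaks, rightmost.closed = TRUE)
      b <- b[b >= 1 & b <= length(mids)]
      hitmat[i, unique(b)] <- TRUE
    }
  }
  structure(data.frame(distance = mids, proportion = colMeans(hitmat),
                       background = background),
            class = c("motif_profile", "data.frame"))
}

#' @export
plot.motif_profile <- function(x, ...) {
  graphics::plot(x$distance, x$proportion, type = "h", lwd = 3,
                 xlab = "distance from breakpoint (bp; + = interior)",
                 ylab = "proportion of deletions with RSS motif", ...)
  if (!all(is.na(x$background))) {
    graphics::abline(h = x$background[1], lty = 2)
  }
  invisible(x)
}

#' Enrichment of non-templated insertions in RSS-positive SVs
#'
#' Two-sided Fisher exact test on the 2x2 contingency of
#' insertion-presence by RSS-hit status.
#'
#' @param svs data.frame with logical columns rss_hit and has_insertion
#'   (see [annotate_svs()]), or a 2x2 matrix (rows: RSS+/RSS-, columns:
#'   insertion+/insertion-).
#' @return List: table, odds_ratio (cross-product), p (NA on an empty
#'   margin).
#' @export
insertion_enrichment <- function(svs) {
  tab <- if (is.matrix(svs)) svs else {
    with(svs, table(factor(rss_hit, c(TRUE, FALSE)),
                    factor(has_insertion, c(TRUE, FALSE))))
  }
  tab <- matrix(as.numeric(tab), 2, 2,
                dimnames = list(c("RSS+", "RSS-"), c("ins+", "ins-")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab,
       odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p = ft$p.value)
}
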