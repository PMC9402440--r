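#' Somatic hypermutation rate of the productive IGHV gene
#'
#' The fraction of bases of the productive IGHV rearrangement that are
#' mutated: variant count divided by gene length, capped at 1 with a flag.
#'
#' @param n_ighv_variants Variants in the productive IGHV gene.
#' @param gene_length Gene length in bp.
#' @return List: rate (in [0, 1]), capped.
#' @export
shm_rate <- function(n_ighv_variants, gene_length) {
  if (gene_length <= 0) stop("gene_length must be positive")
  r <- n_ighv_variants / gene_length
  list(rate = min(r, 1), capped = r > 1)
}

#' Genome-wide SBS9 burden and per-bp rate
#'
#' SBS9 burden is the SBS9 exposure proportion times the SNV burden; the
#' rate divides by the callable genome (3.1 Gb minus the average 383 kb
#' excluded from variant calling).
#'
#' @param sbs9_proportion SBS9 exposure proportion in [0, 1].
#' @param snv_burden Total SNV burden of the genome.
#' @param callable_bp Callable genome size in bp.
#' @return List: count, rate (per bp).
#' @export
sbs9_genome_rate <- function(sbs9_proportion, snv_burden,
                             callable_bp = 3.1e9 - 383e3) {
  if (callable_bp <= 0) stop("callable genome must be positive")
  if (sbs9_proportion < 0 || sbs9_proportion > 1) {
    stop("proportion must lie in [0, 1]")
  }
  count <- sbs9_proportion * snv_burden
  list(count = count, rate = count / callable_bp)
}

#' Fold difference between on-target and off-target mutation density
#' @param shm_rate On-target per-bp mutation rate (IGHV).
#' @param sbs9_rate Genome-wide per-bp SBS9 rate.
#' @return Ratio (NA with a warning attribute when the denominator is 0).
#' @export
density_fold <- function(shm_rate, sbs9_rate) {
  if (sbs9_rate <= 0) return(structure(NA_real_, zero_denominator = TRUE))
  shm_rate / sbs9_rate
}

#' Off-target SBS9 mutations per on-target IGHV mutation
#' @param sbs9_count Genome-wide SBS9 mutation count.
#' @param ighv_count On-target IGHV mutation count.
#' @return Ratio (NA when ighv_count is 0).
#' @export
offtarget_ratio <- function(sbs9_count, ighv_count) {
  if (ighv_count <= 0) return(structure(NA_real_, zero_denominator = TRUE))
  sbs9_count / ighv_count
}

#' Ordinary least-squares association between two per-cell quantities
#'
#' @param x,y Numeric vectors (n >= 3; x not constant).
#' @return List: slope, intercept, r_squared, p (two-sided slope test),
#'   and the lm fit.
#' @export
linear_association <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = s$coefficients[2, 4],
       fit = fit)
}

#' Fraction of non-synonymous mutations under positive selection
#'
#' Converts a dN/dS ratio omega into the excess fraction of
#' non-synonymous mutations attributable to selection, (omega - 1)/omega,
#' clamped at zero under neutrality or purifying selection.
#'
#' @param omega dN/dS ratio (> 0).
#' @return Fraction in [0, 1).
#' @export
driver_fraction <- function(omega) {
  stopifnot(all(omega > 0))
  pmax((omega - 1) / omega, 0)
}

#' Remove variants inside the immunoglobulin loci
#'
#' Drops variants falling in the GRCh37 Ig exclusion intervals
#' (chr14:106304735-107283226, chr2:89160078-90274237,
#' chr22:22385390-23263607; 1-based inclusive), where somatic
#' hypermutation violates the mutation-rate assumptions of selection
#' analysis.
#'
#' @param variants data.frame with columns chrom and pos.
#' @param intervals Interval table; defaults to the three Ig loci.
#' @return The retained variants; attribute `n_removed` reports the count.
#' @export
apply_ig_mask <- function(variants, intervals = NULL) {
  if (is.null(intervals)) {
    it <- ig_tcr_intervals()
    intervals <- it[it$locus %in% c("IGH", "IGK", "IGL"), ]
  }
  if (nrow(variants) == 0L) {
    attr(variants, "n_removed") <- 0L
    return(variants)
  }
  inside <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (variants$chrom == intervals$chrom[i] &
                          variants$pos >= intervals$start[i] &
                          variants$pos <= intervals$end[i])
  }
  out <- variants[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Per-cell germinal-centre mutagenesis summary
#'
#' Combines the on-target SHM rate, the genome-wide SBS9 count and rate,
#' the on/off-target density fold and the off-target ratio for one memory
#' B cell.
#'
#' @param n_ighv_variants,gene_length On-target inputs.
#' @param sbs9_proportion,snv_burden Off-target inputs.
#' @param callable_bp Callable genome size.
#' @return data.frame with one row: shm_rate, sbs9_count, sbs9_rate,
#'   density_fold, offtarget_ratio.
#' @export
gc_summary <- function(n_ighv_variants, gene_length, sbs9_proportion,
                       snv_burden, callable_bp = 3.1e9 - 383e3) {
  sr <- shm_rate(n_ighv_variants, gene_length)
  s9 <- sbs9_genome_rate(sbs9_proportion, snv_burden, callable_bp)
  data.frame(
    shm_rate = sr$rate,
    sbs9_count = s9$count,
    sbs9_rate = s9$rate,
    density_fold = as.numeric(density_fold(sr$rate, s9$rate)),
    offtarget_ratio = as.numeric(offtarget_ratio(s9$count, n_ighv_variants))
  )
}
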