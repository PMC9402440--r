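#' Simulation configuration for synthetic lymphocyte-colony data
#'
#' Bundles the generative quantities that the downstream estimators are
#' meant to recover: per-cell-type mutation-accumulation slopes (SNVs per
#' cell per year), differentiation-associated burden offsets relative to
#' HSPCs, per-cell-type residual standard deviations, the between-donor
#' standard deviation, sequencing depth, and the numbers of germline,
#' somatic and artifact sites per donor.
#'
#' Defaults mirror the study conditions for normal blood: seven donors
#' (a neonate, two 4-year-olds and four adults aged 27-81), five cell
#' compartments (HSPC, naive/memory B, naive/memory T) with slopes
#' 16/15/17/22/25 SNVs per cell per year, offsets 0/110/1034/59/277 SNVs,
#' residual standard deviations 70/150/820/150/592 SNVs, donor standard
#' deviation 60 SNVs, and a mean sequencing depth of 20 reads.
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param n_donors Number of donors.
#' @param ages Donor ages in years (recycled/truncated to `n_donors`).
#' @param cell_types Character vector of cell-type labels.
#' @param slope_per_type Named SNVs/cell/year per cell type.
#' @param offset_per_type Named extra SNVs per cell vs the first type.
#' @param resid_sd_per_type Named residual s.d. (SNVs) per cell type.
#' @param donor_sd Donor random-effect s.d. (SNVs).
#' @param depth_mean Mean sequencing depth (reads).
#' @param n_colonies Colonies per donor (read-count simulation) or per
#'   donor and cell type (burden simulation).
#' @param genome_length Synthetic genome length in bp.
#' @param n_germline_sites,n_somatic_sites,n_artifact_sites Site counts
#'   per simulated donor.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 7L,
                       ages = c(0, 4, 4, 27, 45, 63, 81),
                       cell_types = c("HSPC", "naiveB", "memB", "naiveT", "memT"),
                       slope_per_type = c(HSPC = 16, naiveB = 15, memB = 17,
                                          naiveT = 22, memT = 25),
                       offset_per_type = c(HSPC = 0, naiveB = 110, memB = 1034,
                                           naiveT = 59, memT = 277),
                       resid_sd_per_type = c(HSPC = 70, naiveB = 150, memB = 820,
                                             naiveT = 150, memT = 592),
                       donor_sd = 60,
                       depth_mean = 20,
                       n_colonies = 30L,
                       genome_length = 1e5,
                       n_germline_sites = 4000L,
                       n_somatic_sites = 4000L,
                       n_artifact_sites = 2000L) {
  if (length(cell_types) < 1L) stop("cell_types must be non-empty")
  ages <- rep_len(ages, n_donors)
  for (nm in c("slope_per_type", "offset_per_type", "resid_sd_per_type")) {
    v <- get(nm)
    if (is.null(names(v))) names(v) <- cell_types[seq_along(v)]
    if (!all(cell_types %in% names(v))) {
      stop(nm, " must name every cell type")
    }
    assign(nm, v[cell_types])
  }
  cfg <- list(
    seed = as.integer(seed), n_donors = as.integer(n_donors), ages = ages,
    cell_types = cell_types, slope_per_type = slope_per_type,
    offset_per_type = offset_per_type, resid_sd_per_type = resid_sd_per_type,
    donor_sd = donor_sd, depth_mean = depth_mean,
    n_colonies = as.integer(n_colonies), genome_length = genome_length,
    n_germline_sites = as.integer(n_germline_sites),
    n_somatic_sites = as.integer(n_somatic_sites),
    n_artifact_sites = as.integer(n_artifact_sites)
  )
  num <- unlist(cfg[c("slope_per_type", "resid_sd_per_type", "donor_sd",
                      "depth_mean", "genome_length", "n_germline_sites",
                      "n_somatic_sites", "n_artifact_sites", "n_colonies")])
  if (any(num < 0)) stop("rates and counts must be non-negative")
  structure(cfg, class = "sim_config")
}

# per-site, per-colony depth: Poisson around the colony mean, >= 1
.sim_depth <- function(n, mean_depth) {
  d <- stats::rpois(n, mean_depth)
  pmax(d, 1L)
}

#' Simulate per-colony read counts for one donor with known truth
#'
#' Emulates the substrate of the unmatched-normal filtering problem:
#' germline heterozygous sites at expected VAF 0.5 in every colony; clonal
#' somatic variants at expected VAF 0.5 in their carrier colonies (private
#' to one colony with probability 0.8, otherwise shared by a random clade)
#' and absent elsewhere; artifact sites whose alternate reads are binomial
#' with a small site-specific error probability shared across colonies
#' (hence not overdispersed). Depth is Poisson around the colony mean,
#' truncated at 1.
#'
#' @param config A [sim_config()].
#' @return List with integer matrices `alt` and `depth` (sites x colonies),
#'   a `meta` data.frame (colony, donor, age, cell_type, mean_depth) and a
#'   `truth` data.frame (site, label, n_carriers).
#' @export
simulate_colony_readcounts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_col <- config$n_colonies
  n_site <- config$n_germline_sites + config$n_somatic_sites +
    config$n_artifact_sites
  if (n_col < 1L || n_site < 1L) stop("need at least one colony and one site")
  set.seed(config$seed)

  label <- rep(c("germline", "somatic", "artifact"),
               c(config$n_germline_sites, config$n_somatic_sites,
                 config$n_artifact_sites))
  depth <- matrix(.sim_depth(n_site * n_col, config$depth_mean),
                  nrow = n_site, ncol = n_col)

  # per-site VAF matrix
  p <- matrix(0, n_site, n_col)
  p[label == "germline", ] <- 0.5
  n_carriers <- integer(n_site)
  n_carriers[label == "germline"] <- n_col
  som <- which(label == "somatic")
  for (i in som) {
    if (stats::runif(1) < 0.8 || n_col < 3L) {
      carriers <- sample.int(n_col, 1L)
    } else {
      k <- sample(2:max(2L, floor(n_col / 3)), 1L)
      carriers <- sample.int(n_col, k)
    }
    p[i, carriers] <- 0.5
    n_carriers[i] <- length(carriers)
  }
  art <- which(label == "artifact")
  if (length(art)) {
    err <- stats::runif(length(art), 0.01, 0.05)
    p[art, ] <- err  # same error probability in every colony
  }
  alt <- matrix(stats::rbinom(n_site * n_col, as.vector(depth), as.vector(p)),
                n_site, n_col)

  meta <- data.frame(
    colony = sprintf("colony%02d", seq_len(n_col)),
    donor = "donor1",
    age = config$ages[1],
    cell_type = rep_len(config$cell_types, n_col),
    mean_depth = config$depth_mean,
    stringsAsFactors = FALSE
  )
  colnames(alt) <- colnames(depth) <- meta$colony
  list(alt = alt, depth = depth, meta = meta,
       truth = data.frame(site = seq_len(n_site), label = label,
                          n_carriers = n_carriers))
}

#' Simulate a per-colony mutation burden table
#'
#' Generative twin of the mixed-effects burden model: burden =
#' slope(type) x age + offset(type) + donor effect + residual, with the
#' donor effect drawn per donor and cell type from Normal(0, donor_sd^2)
#' and residuals from Normal(0, resid_sd(type)^2). Negative draws are
#' clamped to zero and flagged.
#'
#' @param config A [sim_config()]; `n_colonies` colonies are generated per
#'   donor and cell type.
#' @return data.frame: colony, donor, age, cell_type, burden, clamped.
#' @export
simulate_burden_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_donors < 2L) stop("need at least 2 donors")
  if (length(unique(config$ages)) < 2L) {
    warning("single age value: age slope is unidentifiable")
  }
  set.seed(config$seed + 1L)
  grid <- expand.grid(
    rep = seq_len(config$n_colonies),
    cell_type = config$cell_types,
    donor = seq_len(config$n_donors),
    stringsAsFactors = FALSE
  )
  grid$age <- config$ages[grid$donor]
  # one random intercept per donor x cell type, as fitted downstream
  de_key <- interaction(grid$donor, grid$cell_type, drop = TRUE)
  de <- stats::rnorm(nlevels(de_key), 0, config$donor_sd)
  mu <- config$slope_per_type[grid$cell_type] * grid$age +
    config$offset_per_type[grid$cell_type] + de[as.integer(de_key)]
  burden <- mu + stats::rnorm(nrow(grid),
                              0, config$resid_sd_per_type[grid$cell_type])
  clamped <- burden < 0
  if (any(clamped)) {
    warning(sum(clamped), " negative burdens clamped to 0")
    burden[clamped] <- 0
  }
  data.frame(
    colony = sprintf("d%d_%s_%02d", grid$donor, grid$cell_type, grid$rep),
    donor = paste0("donor", grid$donor),
    age = grid$age,
    cell_type = grid$cell_type,
    burden = unname(burden),
    clamped = clamped,
    stringsAsFactors = FALSE
  )
}

#' Simulate a 96-channel mutation catalogue from a signature mixture
#'
#' Draws `n` mutations from Multinomial(n, sum_s w_s S_s).
#'
#' @param exposures Non-negative mixing proportions summing to 1 (named by
#'   signature, or in catalogue column order).
#' @param signatures 96 x S signature matrix (columns sum to 1).
#' @param n Number of mutations.
#' @param seed Integer seed.
#' @return Named integer vector of 96 channel counts summing to `n`.
#' @export
simulate_catalog <- function(exposures, signatures, n, seed = 1L) {
  if (any(exposures < 0)) stop("exposures must be non-negative")
  if (abs(sum(exposures) - 1) > 1e-8) stop("exposures must sum to 1")
  stopifnot(nrow(signatures) == 96L, length(exposures) == ncol(signatures))
  p <- as.vector(signatures %*% exposures)
  set.seed(seed)
  counts <- if (n > 0) as.integer(stats::rmultinom(1, n, p)) else integer(96)
  names(counts) <- rownames(signatures)
  counts
}

#' Simulate genomic bins whose mutation counts depend on feature tracks
#'
#' Per-bin counts are Poisson with log-rate beta0 + sum_f g_f(x_f), where
#' the feature values x_f are i.i.d. Uniform(0, 1) and the g_f are the
#' supplied smooth link functions. Additional pure-noise features (no
#' effect on the rate) can be appended.
#'
#' @param n_bins Number of 10-kb bins.
#' @param link Named list of vectorised functions, one per causal feature.
#' @param seed Integer seed.
#' @param beta0 Baseline log-rate.
#' @param n_noise Number of extra noise features (named noise1, noise2, ...).
#' @return data.frame with columns chrom/start/end, one column per feature
#'   and `count`; attribute `truth` records `link` and `beta0`.
#' @export
simulate_feature_bins <- function(n_bins, link, seed = 1L, beta0 = log(5),
                                  n_noise = 0L) {
  if (length(link) < 1L) stop("need at least one feature")
  if (is.null(names(link))) names(link) <- paste0("feature", seq_along(link))
  set.seed(seed)
  x <- matrix(stats::runif(n_bins * length(link)), n_bins)
  colnames(x) <- names(link)
  eta <- beta0
  for (f in names(link)) eta <- eta + link[[f]](x[, f])
  counts <- stats::rpois(n_bins, exp(eta))
  out <- data.frame(
    chrom = "chrS", start = (seq_len(n_bins) - 1L) * 10000L,
    end = seq_len(n_bins) * 10000L, x, count = counts,
    check.names = FALSE
  )
  if (n_noise > 0L) {
    z <- matrix(stats::runif(n_bins * n_noise), n_bins)
    colnames(z) <- paste0("noise", seq_len(n_noise))
    out <- cbind(out[setdiff(names(out), "count")], z, count = counts)
  }
  attr(out, "truth") <- list(link = link, beta0 = beta0)
  out
}

.plant <- function(seq_chars, pos, motif) {
  m <- strsplit(motif, "")[[1]]
  seq_chars[pos:(pos + length(m) - 1L)] <- m
  seq_chars
}

#' Simulate a reference sequence and structural variants with planted motifs
#'
#' Builds an i.i.d. uniform A/C/G/T reference of the requested length with
#' a designated synthetic Ig-TCR interval, then places `n_svs` deletion
#' breakpoint pairs. A fraction `rag_fraction` are RAG-true: an exact RSS
#' heptamer (CACAGTG) is planted within 50 bp interior to a breakpoint,
#' and a short non-templated insertion is attached with probability 0.7.
#' A fraction `csr_fraction` are CSR-true: >= 2 AGCT/TGCA occurrences with
#' gaps <= 100 bp planted within 1,000 bp of a breakpoint. The remainder
#' are mechanism "other" (insertion probability 0.2).
#'
#' @param genome_length Reference length in bp (single synthetic contig).
#' @param n_svs Number of structural variants.
#' @param rag_fraction,csr_fraction Fractions in [0, 1] with sum <= 1.
#' @param seed Integer seed.
#' @param igtcr_fraction Fraction of SVs placed inside the Ig-TCR interval.
#' @return List: `reference` (character scalar), `svs` data.frame (chrom,
#'   posA, posB, class, region, insseq, mechanism), `igtcr` the labelled
#'   interval c(start, end), 1-based inclusive.
#' @export
simulate_reference_and_svs <- function(genome_length, n_svs, rag_fraction,
                                       csr_fraction, seed = 1L,
                                       igtcr_fraction = 0.5) {
  if (rag_fraction < 0 || csr_fraction < 0 || rag_fraction + csr_fraction > 1) {
    stop("mechanism fractions must be in [0,1] and sum to at most 1")
  }
  if (genome_length < 4000 * max(n_svs, 1L)) {
    stop("genome too short for the requested number of SVs")
  }
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  ig_len <- max(5000, round(genome_length * 0.1))
  ig_start <- round(genome_length * 0.45)
  igtcr <- c(ig_start, min(ig_start + ig_len - 1L, genome_length))

  n_rag <- round(n_svs * rag_fraction)
  n_csr <- round(n_svs * csr_fraction)
  mech <- sample(rep(c("RAG", "CSR", "other"),
                     c(n_rag, n_csr, n_svs - n_rag - n_csr)))
  in_ig <- stats::runif(n_svs) < igtcr_fraction
  lane <- floor(genome_length / max(n_svs, 1L))
  posA <- posB <- integer(n_svs)
  insseq <- character(n_svs)
  for (i in seq_len(n_svs)) {
    # keep each SV in its own lane so planted motifs cannot collide
    lo <- (i - 1L) * lane + 1200L
    hi <- i * lane - 1200L
    if (in_ig[i]) { lo <- igtcr[1] + 10L; hi <- igtcr[2] - 2200L }
    a <- sample(lo:(hi - 2000L), 1L)
    b <- a + sample(500:2000, 1L)
    posA[i] <- a; posB[i] <- b
    if (mech[i] == "RAG") {
      off <- sample(5:43, 1L)  # interior to the deletion, within 50 bp
      ref <- .plant(ref, a + off, "CACAGTG")
      if (stats::runif(1) < 0.7) {
        insseq[i] <- paste(sample(c("A", "C", "G", "T"),
                                  sample(2:8, 1L), TRUE), collapse = "")
      }
    } else if (mech[i] == "CSR") {
      n_rep <- sample(3:5, 1L)
      start <- a + sample(20:100, 1L)
      for (k in seq_len(n_rep)) {
        ref <- .plant(ref, start, sample(c("AGCT", "TGCA"), 1L))
        start <- start + 4L + sample(10:80, 1L)
      }
    } else if (stats::runif(1) < 0.2) {
      insseq[i] <- paste(sample(c("A", "C", "G", "T"),
                                sample(2:8, 1L), TRUE), collapse = "")
    }
  }
  svs <- data.frame(
    chrom = "chrS", posA = posA, posB = posB, class = "deletion",
    region = ifelse(in_ig, "IgTCR", "other"), insseq = insseq,
    mechanism = mech, stringsAsFactors = FALSE
  )
  list(reference = paste(ref, collapse = ""), svs = svs, igtcr = igtcr)
}

#' Simulate epigenome tracks and mutation placement along the genome
#'
#' Tracks are smooth positive autocorrelated series (exponentiated,
#' kernel-smoothed Gaussian noise). Mutations are placed multinomially
#' across windows with probability proportional to the designated
#' placement track.
#'
#' @param n_tracks Number of independent tracks.
#' @param n_windows Number of genomic windows (>= 10).
#' @param placement_track Index of the track that shapes placement.
#' @param n_mutations Total mutations to place.
#' @param seed Integer seed.
#' @param smooth_span Width of the moving-average smoother, in windows.
#' @return List: `tracks` (n_windows x n_tracks matrix), `mutations`
#'   (integer counts per window).
#' @export
simulate_epigenome_tracks <- function(n_tracks, n_windows, placement_track,
                                      n_mutations, seed = 1L,
                                      smooth_span = 21L) {
  if (n_windows < 10L) stop("need at least 10 windows")
  if (placement_track > n_tracks) stop("placement_track must index a track")
  set.seed(seed)
  k <- stats::dnorm(seq(-2, 2, length.out = smooth_span))
  k <- k / sum(k)
  tracks <- sapply(seq_len(n_tracks), function(i) {
    z <- stats::rnorm(n_windows + smooth_span)
    s <- stats::filter(z, k, sides = 2)
    s <- s[!is.na(s)][seq_len(n_windows)]
    exp(2 * as.numeric(s))
  })
  colnames(tracks) <- paste0("track", seq_len(n_tracks))
  p <- tracks[, placement_track]
  mutations <- if (n_mutations > 0) {
    as.integer(stats::rmultinom(1, n_mutations, p / sum(p)))
  } else integer(n_windows)
  list(tracks = tracks, mutations = mutations)
}
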