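test_that("breakpoints are classified against Ig-TCR intervals", {
  expect_equal(classify_region("chr14", 106500000), "IgTCR")
  expect_equal(classify_region("chr1", 1000), "other")
  # left edge of the IGL interval, 1-based inclusive
  expect_equal(classify_region("chr22", 22385390), "IgTCR")
  expect_equal(classify_region("chr22", 22385389), "other")
  expect_error(classify_region("chrZZ", 100), "unknown chromosome")
})

test_that("PWM tail probabilities match exhaustive enumeration", {
  hep <- rss_pwm("heptamer")
  max_score <- 7 * log(0.85 / 0.25)
  # full-score tail equals the probability of the exact consensus
  expect_equal(pwm_tail_prob(hep, max_score), 0.25^7, tolerance = 1e-12)
  expect_equal(pwm_tail_prob(hep, max_score), pwm_tail_oracle(hep, max_score),
               tolerance = 1e-12)
  # one mismatch allowed
  s6 <- 6 * log(0.85 / 0.25) + log(0.05 / 0.25)
  expect_equal(pwm_tail_prob(hep, s6), pwm_tail_oracle(hep, s6),
               tolerance = 1e-12)
  # the 1e-4 cutoff for the heptamer requires the exact consensus
  expect_equal(pwm_score_cutoff(hep), max_score, tolerance = 1e-6)
  expect_lt(pwm_tail_prob(hep, pwm_score_cutoff(hep)), 1e-4)
})

test_that("planted heptamers are found at the right offset and strand", {
  set.seed(5)
  bg <- paste(sample(c("A", "C"), 400, TRUE), collapse = "")  # no G/T: motif-free
  ref <- paste0(substr(bg, 1, 209), "CACAGTG", substr(bg, 217, 400))
  # breakpoint at 200: motif starts 10 bp interior
  h <- scan_rss(ref, 200, window = 50)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 10L)
  expect_equal(h$strand, "+")
  expect_equal(h$kind, "RSS-heptamer")
  # reverse complement on the minus strand
  ref2 <- paste0(substr(bg, 1, 209), "CACTGTG", substr(bg, 217, 400))
  h2 <- scan_rss(ref2, 200, window = 50)
  expect_equal(h2$strand, "-")
})

test_that("full RSS needs heptamer plus nonamer at a 12/23 spacer", {
  pad <- function(n) paste(rep("A", n), collapse = "")
  full12 <- paste0(pad(100), "CACAGTG", pad(12), "ACAAAAACC", pad(100))
  h <- scan_rss(full12, 95, window = 50)
  expect_true(any(h$kind == "RSS-full" & h$spacer == 12))
  # spacer tolerance of one base
  full24 <- paste0(pad(100), "CACAGTG", pad(24), "ACAAAAACC", pad(100))
  h24 <- scan_rss(full24, 95, window = 50)
  expect_true(any(h24$kind == "RSS-full" & h24$spacer == 24))
  # spacer far from 12/23: heptamer-only
  bad <- paste0(pad(100), "CACAGTG", pad(17), "ACAAAAACC", pad(100))
  hb <- scan_rss(bad, 95, window = 50)
  expect_false(any(hb$kind == "RSS-full"))
})

test_that("strand symmetry: the reverse-complemented reference mirrors hits", {
  set.seed(8)
  ref <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  rc <- lymphmut:::.revcomp(ref)
  bp <- 1500
  h_fwd <- scan_rss(ref, bp, window = 200)
  h_rev <- scan_rss(rc, nchar(ref) - bp + 1, window = 200)
  expect_equal(nrow(h_fwd), nrow(h_rev))
  if (nrow(h_fwd)) {
    expect_setequal(h_fwd$score, h_rev$score)
    expect_setequal(h_fwd$strand,
                    chartr("+-", "-+", h_rev$strand))
  }
})

test_that("CSR clusters require two close AGCT/TGCA occurrences", {
  pad <- function(n) paste(rep("C", n), collapse = "")
  five <- paste0(pad(500), paste(rep(paste0("AGCT", pad(10)), 5),
                                 collapse = ""), pad(500))
  expect_true(scan_csr(five, 510))
  single <- paste0(pad(500), "AGCT", pad(500))
  expect_false(scan_csr(single, 500))
  far <- paste0(pad(500), "AGCT", pad(150), "AGCT", pad(500))
  expect_false(scan_csr(far, 500))      # gap 150 > 100
  near <- paste0(pad(500), "TGCA", pad(90), "AGCT", pad(500))
  expect_true(scan_csr(near, 500))      # gap 90 <= 100
})

test_that("genomic background spans the degenerate extremes", {
  flat <- paste(rep("C", 20000), collapse = "")  # cannot contain any motif
  bg0 <- genomic_background(flat, 500:19500, n_sets = 10, set_size = 20,
                            seed = 1)
  expect_equal(bg0$background, 0)
  tandem <- paste(rep("CACAGTG", 3000), collapse = "")
  bg1 <- genomic_background(tandem, 500:20000, n_sets = 10, set_size = 20,
                            seed = 1)
  expect_equal(bg1$background, 1)
  expect_error(genomic_background(flat, 1:10, n_sets = 5, set_size = 100,
                                  seed = 1), "too small")
})

test_that("random-sequence hit rates match the enumerated tail expectation", {
  set.seed(33)
  ref <- paste(sample(c("A", "C", "G", "T"), 6e5, TRUE), collapse = "")
  bg <- genomic_background(ref, 1000:(6e5 - 1000), n_sets = 50,
                           set_size = 60, seed = 33)
  # per-position heptamer probability from the exact enumeration
  hep <- rss_pwm("heptamer")
  p_pos <- pwm_tail_prob(hep, pwm_score_cutoff(hep))
  n_pos <- 2 * (2 * 50 + 1)   # both strands, both flanks around the breakpoint
  p_window <- 1 - (1 - p_pos)^n_pos
  n_scans <- 50 * 60
  se <- sqrt(p_window * (1 - p_window) / n_scans)
  expect_lt(abs(mean(bg$per_set) - p_window), 3 * se)
})

test_that("background correction reproduces the published arithmetic", {
  expect_equal(rag_attributable_fraction(0.96, 0.12), 0.84)
  expect_equal(rag_attributable_fraction(0.24, 0.12), 0.12)
  expect_equal(rag_attributable_fraction(0.05, 0.12), 0)
})

test_that("the distance profile localises planted motifs", {
  pad <- function(n, b = "A") paste(rep(b, n), collapse = "")
  # deletions at positions 1000/2000 with motifs planted 10 bp interior
  ref <- paste0(pad(1009), "CACAGTG", pad(984), "CACAGTG", pad(1000))
  svs <- data.frame(chrom = "chrS", posA = c(1000, 1991),
                    posB = c(1500, 2491), class = "deletion")
  prof <- motif_distance_profile(ref, svs, bin_width = 10, max_distance = 100)
  enriched <- prof$distance[prof$proportion > 0]
  expect_true(all(enriched > 0 & enriched <= 20))
  # empty input
  empty <- motif_distance_profile(ref, svs[svs$class == "x", ])
  expect_equal(nrow(empty), 0L)
  # motif-free deletions give a flat zero profile
  ref0 <- pad(4000, "C")
  prof0 <- motif_distance_profile(ref0, svs, bin_width = 10,
                                  max_distance = 100)
  expect_true(all(prof0$proportion == 0))
})

test_that("insertion enrichment reproduces the Fisher arithmetic", {
  tab <- matrix(c(44, 21, 56, 79), 2, 2)
  res <- insertion_enrichment(tab)
  expect_equal(res$odds_ratio, (44 * 79) / (56 * 21), tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  same <- insertion_enrichment(matrix(c(10, 10, 30, 30), 2, 2))
  expect_equal(same$p, 1)
  expect_true(is.na(insertion_enrichment(matrix(0, 2, 2))$p))
})

test_that("corrected RAG fraction recovers the planted fraction", {
  sv <- simulate_reference_and_svs(8e5, 200, rag_fraction = 0.5,
                                   csr_fraction = 0.1, seed = 1)
  ann <- annotate_svs(sv$reference, sv$svs)
  # RAG-true deletions all carry their planted motif
  expect_true(all(ann$rss_hit[ann$mechanism == "RAG"]))
  bg <- genomic_background(sv$reference, 1100:(8e5 - 1100), n_sets = 25,
                           set_size = 100, seed = 1)
  corrected <- rag_attributable_fraction(mean(ann$rss_hit), bg$background)
  expect_lt(abs(corrected - 0.5), 0.05)
})
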