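test_that("genotype rule requires two alt reads and 20% VAF", {
  expect_true(call_genotype(2L, 10L))    # exact boundary
  expect_false(call_genotype(1L, 2L))    # VAF 0.5 but one read
  expect_false(call_genotype(3L, 20L))   # VAF 0.15
  expect_false(call_genotype(0L, 0L))    # zero depth
  expect_error(call_genotype(5L, 3L), "exceed")
})

test_that("mean-VAF screen drops only variants strictly above 40%", {
  expect_equal(mean_vaf_screen(c(5, 5, 5), c(10, 10, 10)), "drop")
  expect_equal(mean_vaf_screen(c(5, 0, 0, 0, 0), rep(10, 5)), "keep")
  expect_equal(mean_vaf_screen(c(4, 4), c(10, 10)), "keep")  # exactly 0.40
  expect_equal(mean_vaf_screen(c(0, 0), c(0, 0)), "indeterminate")
})

test_that("aggregate binomial test equals the exact lower tail", {
  expect_equal(aggregate_binomial_test(0, 100, 0.5), 2^-100)
  expect_equal(aggregate_binomial_test(50, 100, 0.5),
               binom_lower_tail(50, 100, 0.5), tolerance = 1e-12)
  expect_equal(aggregate_binomial_test(50, 100, 0.5), 0.5398, tolerance = 1e-4)
  expect_equal(aggregate_binomial_test(100, 100, 0.5), 1)
  expect_error(aggregate_binomial_test(0, 0, 0.5), "positive")
})

test_that("germline classification applies BH within donor", {
  expect_equal(classify_germline(0.5)$label, "germline")
  expect_equal(classify_germline(1e-300)$label, "somatic")
  p <- c(rep(1e-300, 10), rep(0.5, 10))
  res <- classify_germline(p)
  expect_equal(sum(res$label == "somatic"), 10L)
  expect_equal(sum(res$label == "germline"), 10L)
  expect_equal(res$q, bh_by_hand(p), tolerance = 1e-12)
  expect_equal(nrow(classify_germline(numeric(0))), 0L)
})

test_that("q-values are a monotone transform of p-values", {
  set.seed(42)
  p <- runif(200)^2
  res <- classify_germline(p)
  o <- order(p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("overdispersion estimates match the grid-ML oracle", {
  # binomial-consistent data
  od <- betabinom_overdispersion(c(5, 5, 5, 5), c(10, 10, 10, 10))
  expect_lte(od$rho_hat, 0.01)
  # strongly bimodal data
  od2 <- betabinom_overdispersion(c(10, 0, 10, 0), c(10, 10, 10, 10))
  expect_gte(od2$rho_hat, 0.5)
  expect_equal(od2$rho_hat, bb_grid_ml_oracle(c(10, 0, 10, 0), rep(10, 4)))
  # sparse singleton
  od3 <- betabinom_overdispersion(c(1, 0, 0, 0, 0, 0), rep(20, 6))
  expect_equal(od3$rho_hat, bb_grid_ml_oracle(c(1, 0, 0, 0, 0, 0), rep(20, 6)))
  # no alternate reads: rho = 0 by convention
  expect_equal(betabinom_overdispersion(rep(0, 5), rep(10, 5))$rho_hat, 0)
  expect_error(betabinom_overdispersion(c(1, 1), c(5, 5)), "3 colonies")
})

test_that("overdispersion agrees with the oracle on random instances", {
  set.seed(99)
  grid <- c(1e-4, exp(seq(log(2e-4), log(0.999), length.out = 60)))
  for (i in 1:50) {
    n_col <- sample(4:12, 1)
    depth <- rpois(n_col, 20) + 1L
    alt <- rbinom(n_col, depth, runif(1, 0.05, 0.5))
    if (sum(alt) == 0) next
    got <- betabinom_overdispersion(alt, depth)$rho_hat
    want <- bb_grid_ml_oracle(alt, depth)
    gi <- which.min(abs(grid - got)); wi <- which.min(abs(grid - want))
    expect_lte(abs(gi - wi), 1L)
  }
})

test_that("valley finding locates the density minimum between two modes", {
  set.seed(21)
  scores <- c(rnorm(250, 1, 0.1), rnorm(250, 5, 0.3))
  vt <- valley_threshold(scores)
  expect_false(vt$fallback_used)
  expect_gt(vt$cutoff, 2); expect_lt(vt$cutoff, 4)
  expect_equal(vt$cutoff, kde_valley_oracle(scores), tolerance = 1e-8)

  vt2 <- valley_threshold(c(rep(1, 100), rep(9, 100)))
  expect_gt(vt2$cutoff, 1); expect_lt(vt2$cutoff, 9)

  set.seed(22)
  vt3 <- valley_threshold(rnorm(500, 3, 1))
  expect_true(vt3$fallback_used)
  expect_error(valley_threshold(rnorm(10)), "at least 50")
})

test_that("sensitivity is the germline recall per colony", {
  expect_equal(unname(germline_recall_sensitivity(matrix(TRUE, 80, 2))),
               c(1, 1))
  expect_equal(unname(germline_recall_sensitivity(
    matrix(rep(c(TRUE, FALSE), 40), ncol = 1))), 0.5)
  # analytic model at depth 20: detection needs >= 4 alt reads
  p_detect <- sum(sapply(0:20, function(k) {
    if (call_genotype(k, 20L)) choose(20, k) * 0.5^20 else 0
  }))
  expect_equal(p_detect, 1 - pbinom(3, 20, 0.5), tolerance = 1e-12)
  expect_equal(p_detect, 0.9987, tolerance = 1e-4)
})

test_that("sensitivity rises with depth under binomial detection", {
  # the genotype rule's alt-read threshold steps up with depth, so
  # sensitivity oscillates slightly at threshold boundaries; across
  # doublings of depth it increases strictly
  p_at <- vapply(c(5, 10, 20, 40, 80), function(d) {
    sum(vapply(0:d, function(k) {
      if (call_genotype(k, d)) choose(d, k) * 0.5^d else 0
    }, 0))
  }, 0)
  expect_true(all(diff(p_at) > 0))
  expect_gt(p_at[5], 0.999)
})

test_that("the filtering cascade separates germline, somatic and artifacts", {
  cfg <- sim_config(seed = 2, n_colonies = 25L, n_germline_sites = 1200L,
                    n_somatic_sites = 1200L, n_artifact_sites = 600L)
  rc <- simulate_colony_readcounts(cfg)
  fr <- filter_variants(rc$alt, rc$depth)
  lab <- fr$table$label
  truth <- rc$truth$label
  expect_gte(mean(lab[truth == "germline"] == "GERMLINE"), 0.99)
  expect_gte(mean(lab[truth == "artifact"] == "ARTEFACT_BB"), 0.95)
  expect_gte(mean(lab[truth == "somatic"] == "PASS"), 0.90)
  expect_true(all(fr$sensitivity > 0.9))
  expect_output(print(fr), "Variant filtering result")
})

test_that("external subclonal and blacklist hooks are honoured", {
  cfg <- small_config(seed = 8)
  rc <- simulate_colony_readcounts(cfg)
  n <- nrow(rc$alt)
  # vetoing every variant via the subclonal flag leaves no PASS
  fr <- filter_variants(rc$alt, rc$depth, subclonal = rep(FALSE, n))
  expect_equal(sum(fr$table$label == "PASS"), 0L)
  bl <- rep(FALSE, n); bl[1:5] <- TRUE
  fr2 <- filter_variants(rc$alt, rc$depth, blacklist = bl)
  expect_equal(fr2$table$label[1:5], rep("ARTEFACT_EXTERNAL", 5))
})
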