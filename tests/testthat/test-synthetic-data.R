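test_that("generators are pure functions of their seed", {
  cfg <- small_config(seed = 11L)
  a <- simulate_colony_readcounts(cfg)
  b <- simulate_colony_readcounts(cfg)
  expect_identical(a, b)
  expect_identical(suppressWarnings(simulate_burden_table(cfg)),
                   suppressWarnings(simulate_burden_table(cfg)))
  sv1 <- simulate_reference_and_svs(2e5, 20, 0.5, 0.2, seed = 4)
  sv2 <- simulate_reference_and_svs(2e5, 20, 0.5, 0.2, seed = 4)
  expect_identical(sv1, sv2)
  tr1 <- simulate_epigenome_tracks(3, 100, 1, 1000, seed = 9)
  tr2 <- simulate_epigenome_tracks(3, 100, 1, 1000, seed = 9)
  expect_identical(tr1, tr2)
  expect_false(identical(
    simulate_epigenome_tracks(3, 100, 1, 1000, seed = 10), tr1))
})

test_that("site labels partition all simulated sites", {
  cfg <- small_config()
  rc <- simulate_colony_readcounts(cfg)
  expect_equal(nrow(rc$truth),
               cfg$n_germline_sites + cfg$n_somatic_sites +
                 cfg$n_artifact_sites)
  expect_equal(as.vector(table(rc$truth$label)[c("germline", "somatic",
                                                 "artifact")]),
               c(cfg$n_germline_sites, cfg$n_somatic_sites,
                 cfg$n_artifact_sites))
})

test_that("germline sites have mean VAF near 0.5 across colonies", {
  cfg <- sim_config(seed = 3, n_colonies = 25L, n_germline_sites = 100L,
                    n_somatic_sites = 0L, n_artifact_sites = 0L)
  rc <- simulate_colony_readcounts(cfg)
  expect_equal(nrow(rc$alt), 100L)
  vaf <- rc$alt / rc$depth
  se <- sqrt(0.25 / sum(rc$depth))  # pooled binomial s.e. of the grand mean
  grand <- sum(rc$alt) / sum(rc$depth)
  expect_lt(abs(grand - 0.5), 3 * se)
})

test_that("carrier alt counts at depth 20 match Binomial(20, 0.5)", {
  cfg <- sim_config(seed = 5, n_colonies = 30L, n_germline_sites = 10000L,
                    n_somatic_sites = 0L, n_artifact_sites = 0L)
  rc <- simulate_colony_readcounts(cfg)
  at20 <- rc$alt[rc$depth == 20L]
  expect_gt(length(at20), 10000L)
  obs <- tabulate(at20 + 1L, nbins = 21L)
  expected_p <- vapply(0:20, function(k) choose(20, k) * 0.5^20, 0)
  # pool sparse tail cells for a valid chi-square
  grp <- pmin(pmax(0:20, 4L), 16L)
  obs_g <- tapply(obs, grp, sum)
  exp_g <- tapply(expected_p, grp, sum) * length(at20)
  stat <- sum((obs_g - exp_g)^2 / exp_g)
  p <- pchisq(stat, df = length(obs_g) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("artifact sites are binomial across colonies (not overdispersed)", {
  cfg <- sim_config(seed = 7, n_colonies = 30L, n_germline_sites = 0L,
                    n_somatic_sites = 0L, n_artifact_sites = 300L)
  rc <- simulate_colony_readcounts(cfg)
  od <- betabinom_overdispersion(rc$alt, rc$depth)
  expect_lt(median(od$rho_hat), 0.01)
  expect_lt(mean(od$p < 0.01), 0.05)
})

test_that("noiseless burden tables reproduce the linear model exactly", {
  cfg <- sim_config(seed = 1, n_donors = 2L, ages = c(5, 5),
                    cell_types = "A", slope_per_type = c(A = 10),
                    offset_per_type = c(A = 0), resid_sd_per_type = c(A = 0),
                    donor_sd = 0, n_colonies = 4L)
  bt <- suppressWarnings(simulate_burden_table(cfg))
  expect_true(all(bt$burden == 50))
})

test_that("single age value warns about unidentifiable slope", {
  cfg <- sim_config(seed = 1, n_donors = 2L, ages = c(40, 40),
                    cell_types = "HSPC", slope_per_type = c(HSPC = 16),
                    offset_per_type = c(HSPC = 1000),
                    resid_sd_per_type = c(HSPC = 70), n_colonies = 2L)
  expect_warning(simulate_burden_table(cfg), "unidentifiable")
})

test_that("empirical residual s.d. matches the configured value", {
  cfg <- sim_config(seed = 2, n_donors = 2L, ages = c(30, 60),
                    cell_types = c("A", "B"),
                    slope_per_type = c(A = 10, B = 20),
                    offset_per_type = c(A = 3000, B = 3000),
                    resid_sd_per_type = c(A = 100, B = 500),
                    donor_sd = 0, n_colonies = 2500L)
  bt <- simulate_burden_table(cfg)
  for (ty in c("A", "B")) {
    sub <- bt[bt$cell_type == ty, ]
    resid <- sub$burden - (cfg$slope_per_type[[ty]] * sub$age +
                             cfg$offset_per_type[[ty]])
    expect_lt(abs(sd(resid) / cfg$resid_sd_per_type[[ty]] - 1), 0.03)
  }
})

test_that("catalogue draws follow the mixture multinomial", {
  sigs <- cbind(s1 = rep(1 / 96, 96), s2 = c(rep(1 / 48, 48), rep(0, 48)))
  rownames(sigs) <- sbs_channels()
  n <- 100000L
  counts <- simulate_catalog(c(0.7, 0.3), sigs, n, seed = 8)
  expect_equal(sum(counts), n)
  p <- as.vector(sigs %*% c(0.7, 0.3))
  se <- sqrt(p * (1 - p) * n)
  expect_true(all(abs(counts - n * p) <= 3.5 * se + 1))
  expect_equal(sum(simulate_catalog(c(0.7, 0.3), sigs, 0L, seed = 1)), 0L)
  expect_error(simulate_catalog(c(-0.1, 1.1), sigs, 10, seed = 1),
               "non-negative")
})

test_that("feature-bin counts follow the configured Poisson link", {
  bins <- simulate_feature_bins(10000, list(f = function(x) 0 * x),
                                seed = 3, beta0 = log(5))
  se <- sqrt(5 / 10000)
  expect_lt(abs(mean(bins$count) - 5), 3 * se)
  strong <- simulate_feature_bins(2000, list(f = function(x) 2 * x), seed = 4)
  expect_gt(cor(strong$f, strong$count, method = "spearman"), 0.5)
  expect_identical(simulate_feature_bins(100, list(f = identity), seed = 5),
                   simulate_feature_bins(100, list(f = identity), seed = 5))
})

test_that("RAG-true deletions carry a planted heptamer interior to a breakpoint", {
  sv <- simulate_reference_and_svs(2e5, 30, rag_fraction = 1,
                                   csr_fraction = 0, seed = 6)
  for (i in seq_len(nrow(sv$svs))) {
    interior <- substr(sv$reference, sv$svs$posA[i], sv$svs$posA[i] + 50L)
    expect_true(grepl("CACAGTG", interior, fixed = TRUE))
  }
  expect_error(simulate_reference_and_svs(1000, 30, 1, 0, seed = 1),
               "too short")
})

test_that("motif-free SV sets sit at the genomic background rate", {
  sv <- simulate_reference_and_svs(4e5, 60, rag_fraction = 0,
                                   csr_fraction = 0, seed = 12)
  ann <- annotate_svs(sv$reference, sv$svs)
  bg <- genomic_background(sv$reference, 1100:(4e5 - 1100), n_sets = 25,
                           set_size = 60, seed = 12)
  # binomial test of observed hit count against the background proportion
  p <- binom.test(sum(ann$rss_hit), nrow(ann),
                  p = max(bg$background, 1e-6))$p.value
  expect_gt(p, 0.01)
})

test_that("mutations preferentially follow the placement track", {
  wins <- 0L
  for (s in 1:10) {
    tr <- simulate_epigenome_tracks(4, 400, placement_track = 2,
                                    n_mutations = 4000, seed = s)
    cors <- cor(tr$tracks, tr$mutations)
    if (which.max(cors) == 2L) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
  expect_equal(sum(simulate_epigenome_tracks(2, 50, 1, 0, seed = 1)$mutations),
               0L)
  expect_error(simulate_epigenome_tracks(2, 5, 1, 10, seed = 1),
               "at least 10")
})
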