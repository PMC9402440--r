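.stage_seed <- function(seed, stage) {
  # fixed per-stage offsets keep stages independently reproducible
  offsets <- c(readcounts = 0L, burden = 1000L, signatures = 2000L,
               features = 3000L, svmotif = 4000L, timing = 5000L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a synthetic dataset from `config`, then runs the stages in
#' dependency order — variant filtering, depth-corrected burden modelling,
#' signature exposure fitting, feature regression, SV motif annotation and
#' epigenome matching — writing one TSV report per stage plus a
#' provenance manifest, all under `out_dir`. Deterministic given
#' (config, seed).
#'
#' @param config A [sim_config()]; its `seed` seeds every stage through
#'   fixed offsets.
#' @param out_dir Output directory (created if needed).
#' @param n_svs Structural variants to simulate.
#' @param n_windows Epigenome windows.
#' @return Invisibly, a named list of the stage result objects.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("lymphmut_"),
                         n_svs = 100L, n_windows = 500L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  results <- list()

  # filtering
  rc <- simulate_colony_readcounts(config)
  fr <- filter_variants(rc$alt, rc$depth)
  utils::write.table(fr$table, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(colony = colnames(rc$alt), sensitivity = fr$sensitivity),
    file.path(out_dir, "sensitivity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  results$filter <- fr

  # burden
  bt <- simulate_burden_table(config)
  bf <- fit_burden_age_model(bt)
  utils::write.table(bf$slopes, file.path(out_dir, "burden_slopes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$burden <- bf

  # signatures
  sigs <- synthetic_signature_catalog()
  expo_true <- c(SBSblood = 0.45, SBS1 = 0.1, SBS9 = 0.35, SHM = 0.1)
  w <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  w[names(expo_true)] <- expo_true
  catalog <- simulate_catalog(w, sigs, 20000,
                              seed = .stage_seed(seed, "signatures"))
  ef <- fit_exposures(catalog, sigs, n_boot = 100,
                      seed = .stage_seed(seed, "signatures"))
  utils::write.table(
    data.frame(signature = names(ef$exposures), exposure = ef$exposures,
               lower90 = ef$lower, upper90 = ef$upper),
    file.path(out_dir, "exposures.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  results$exposures <- ef

  # feature regression
  bins <- simulate_feature_bins(
    2000, list(timing = function(x) 1.2 * x),
    seed = .stage_seed(seed, "features"), n_noise = 3
  )
  bins$included <- TRUE
  tab <- assemble_regression_table(bins, seed = .stage_seed(seed, "features"))
  fa <- fit_penalized_additive(tab, seed = .stage_seed(seed, "features"))
  sel <- data.frame(feature = names(fa$selected), selected = fa$selected,
                    individual_r2 = vapply(names(fa$selected), function(f)
                      individual_feature_r2(tab, f)$r_squared, 0))
  utils::write.table(sel, file.path(out_dir, "feature_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$features <- fa

  # SV motifs
  sv <- simulate_reference_and_svs(4000 * n_svs + 20000, n_svs,
                                   rag_fraction = 0.5, csr_fraction = 0.1,
                                   seed = .stage_seed(seed, "svmotif"))
  ann <- annotate_svs(sv$reference, sv$svs)
  bg <- genomic_background(sv$reference, seq(100, nchar(sv$reference) - 100),
                           n_sets = 20, set_size = 50,
                           seed = .stage_seed(seed, "svmotif"))
  ann$corrected_fraction <- rag_attributable_fraction(mean(ann$rss_hit),
                                                      bg$background)
  write_svs_bedpe(ann, file.path(out_dir, "svs_annotated.bedpe"))
  results$svmotif <- list(svs = ann, background = bg)

  # timing
  tr <- simulate_epigenome_tracks(4, n_windows, placement_track = 1,
                                  n_mutations = 10 * n_windows,
                                  seed = .stage_seed(seed, "timing"))
  em <- epigenome_match(tr$mutations, tr$tracks, folds = 5,
                        seed = .stage_seed(seed, "timing"), num_trees = 100)
  utils::write.table(em$scores, file.path(out_dir, "epigenome_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$timing <- em

  write_config_txt(config, file.path(out_dir, "config.txt"))
  manifest <- c(
    paste0("package = lymphmut ",
           as.character(utils::packageVersion("lymphmut"))),
    paste0("seed = ", seed),
    paste0("generated = ", paste(sort(list.files(out_dir)), collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(results)
}

#' Generate a small bundled synthetic fixture set
#'
#' Writes a compact synthetic dataset (read counts, burden table,
#' reference FASTA, SV BEDPE, epigenome tracks, config) that exercises
#' every pipeline stage.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, the output directory.
#' @export
make_fixtures <- function(seed = 1L, out_dir = tempfile("fixtures_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, n_colonies = 10L,
                    n_germline_sites = 400L, n_somatic_sites = 400L,
                    n_artifact_sites = 200L)
  rc <- simulate_colony_readcounts(cfg)
  write_readcounts_tsv(rc$alt, rc$depth, file.path(out_dir, "readcounts.tsv"))
  utils::write.table(rc$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bt <- simulate_burden_table(cfg)
  utils::write.table(bt, file.path(out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sv <- simulate_reference_and_svs(2e5, 40, 0.5, 0.1, seed = seed)
  write_reference_fasta(sv$reference, file.path(out_dir, "reference.fa"))
  write_svs_bedpe(sv$svs, file.path(out_dir, "svs.bedpe"))
  tr <- simulate_epigenome_tracks(4, 200, 1, 2000, seed = seed)
  for (j in seq_len(ncol(tr$tracks))) {
    write_track_bedgraph(tr$tracks[, j],
                         file.path(out_dir, paste0("track", j, ".bedGraph")))
  }
  write_signature_catalog(synthetic_signature_catalog(),
                          file.path(out_dir, "signatures_96_synthetic.tsv"))
  write_config_txt(cfg, file.path(out_dir, "config.txt"))
  invisible(out_dir)
}
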