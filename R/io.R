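#' Write/read a read-count matrix as TSV
#'
#' Site rows with paired `<colony>.alt` / `<colony>.dp` columns.
#'
#' @param alt,depth Integer matrices, sites x colonies (same dimnames).
#' @param path Output path.
#' @export
write_readcounts_tsv <- function(alt, depth, path) {
  cols <- colnames(alt)
  df <- data.frame(site = seq_len(nrow(alt)))
  for (cl in cols) {
    df[[paste0(cl, ".alt")]] <- alt[, cl]
    df[[paste0(cl, ".dp")]] <- depth[, cl]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_readcounts_tsv
#' @return `read_readcounts_tsv`: list with `alt` and `depth` matrices.
#' @export
read_readcounts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  alt_cols <- grep("\\.alt$", names(df), value = TRUE)
  cols <- sub("\\.alt$", "", alt_cols)
  alt <- as.matrix(df[, paste0(cols, ".alt")])
  depth <- as.matrix(df[, paste0(cols, ".dp")])
  colnames(alt) <- colnames(depth) <- cols
  list(alt = alt, depth = depth)
}

#' Write a reference sequence as FASTA
#' @param reference Character scalar sequence.
#' @param path Output path.
#' @param name Sequence name.
#' @export
write_reference_fasta <- function(reference, path, name = "chrS") {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a single-contig reference FASTA as a character scalar
#' @param path FASTA path.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' Write structural variants as BEDPE
#'
#' 0-based half-open breakpoint intervals; extra columns (class, region,
#' insseq, mechanism) are appended after the standard six.
#'
#' @param svs data.frame with chrom, posA, posB (1-based positions).
#' @param path Output path.
#' @export
write_svs_bedpe <- function(svs, path) {
  bed <- data.frame(
    chrom1 = svs$chrom, start1 = svs$posA - 1L, end1 = svs$posA,
    chrom2 = svs$chrom, start2 = svs$posB - 1L, end2 = svs$posB,
    svs[setdiff(names(svs), c("chrom", "posA", "posB"))]
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-window track as bedGraph
#' @param values Numeric vector, one value per window.
#' @param path Output path.
#' @param chrom Contig name.
#' @param window_size Window width in bp.
#' @export
write_track_bedgraph <- function(values, path, chrom = "chrS",
                                 window_size = 1e6) {
  df <- data.frame(chrom = chrom,
                   start = (seq_along(values) - 1L) * window_size,
                   end = seq_along(values) * window_size,
                   value = values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a flat key-value configuration file
#' @param config A `sim_config` or named list of scalars/vectors.
#' @param path Output path.
#' @export
write_config_txt <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
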