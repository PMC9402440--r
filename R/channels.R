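#' The 96 single-base-substitution channels
#'
#' Channel labels follow the standard trinucleotide convention: six
#' pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G),
#' each expanded over the 16 flanking-base combinations, grouped by the
#' base 5' of the mutated base and within each group by the 3' base, both
#' in the order A, C, G, T. Labels look like \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96, in canonical order.
#' @export
sbs_channels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cl in classes) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", cl, "]", p3))
      }
    }
  }
  out
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp_chr <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(.complement[b])), collapse = ""), "")
}

#' Map a mutation in trinucleotide context to its 96-channel label
#'
#' Uses the pyrimidine-strand convention: when the mutated (central) base is
#' a purine, the trinucleotide and the alternate allele are
#' reverse-complemented so the reported reference base is C or T.
#'
#' @param trinuc Reference trinucleotide centred on the mutated base
#'   (character vector).
#' @param ref,alt Reference and alternate alleles (single bases).
#' @return Channel labels as in [sbs_channels()].
#' @export
mutation_channel <- function(trinuc, ref, alt) {
  stopifnot(length(trinuc) == length(ref), length(ref) == length(alt))
  if (any(nchar(trinuc) != 3L)) stop("trinucleotides must have length 3")
  if (any(substr(trinuc, 2, 2) != ref)) stop("central base of trinuc must equal ref")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  trinuc[flip] <- .revcomp_chr(trinuc[flip])
  alt[flip] <- unname(.complement[alt[flip]])
  ref[flip] <- unname(.complement[ref[flip]])
  lab <- paste0(
    substr(trinuc, 1, 1), "[", ref, ">", alt, "]", substr(trinuc, 3, 3)
  )
  bad <- !(lab %in% sbs_channels())
  if (any(bad)) stop("invalid channel: ", lab[which(bad)[1]])
  lab
}

#' Synthetic 96-channel signature catalogue
#'
#' Deterministically constructs a stand-in catalogue with the
#' characteristic channel concentrations of the signatures relevant to
#' lymphocyte genomes: the clock-like blood signature (SBSblood), CpG
#' deamination (SBS1), ultraviolet light (SBS7a), SBS8, the germinal-centre
#' polymerase-eta signature (SBS9, T>N in a TpW context), SBS17b, SBS18 and
#' the on-target somatic-hypermutation spectrum (SHM). These are synthetic
#' vectors shaped like the published signatures, not the published matrices
#' themselves; substitute a real catalogue via [read_signature_catalog()]
#' for real-data work.
#'
#' @return Numeric matrix, 96 rows (channels) by 8 signatures; columns sum
#'   to 1.
#' @export
synthetic_signature_catalog <- function() {
  ch <- sbs_channels()
  cls <- sub(".*\\[(.*)\\].*", "\\1", ch)
  p5 <- substr(ch, 1, 1)
  p3 <- substr(ch, nchar(ch), nchar(ch))

  weight <- function(w) w / sum(w)
  base <- rep(1, 96)

  # flat-ish clock-like signature, mild excess of T>C and C>T outside CpG
  sbsblood <- base + 3 * (cls == "T>C") + 2 * (cls == "C>T" & p3 != "G") +
    1.5 * (cls == "C>A")
  # CpG C>T deamination
  sbs1 <- 0.02 * base + 25 * (cls == "C>T" & p3 == "G")
  # UV: C>T at dipyrimidines (5' C or T)
  sbs7a <- 0.02 * base + 20 * (cls == "C>T" & p5 %in% c("C", "T"))
  # broad, C>A / C>T leaning
  sbs8 <- base + 4 * (cls == "C>A") + 2 * (cls == "C>T" & p3 != "G")
  # polymerase-eta: T mutations in TpW context (5' T, 3' A/T), sparse at C:G
  sbs9 <- 0.05 * base +
    12 * (cls %in% c("T>A", "T>C", "T>G") & p5 == "T" & p3 %in% c("A", "T")) +
    3 * (cls %in% c("T>C", "T>G") & p5 == "T")
  # T>G in TpT context
  sbs17b <- 0.02 * base + 30 * (cls == "T>G" & p5 == "T" & p3 == "T") +
    6 * (cls == "T>G" & p5 == "T")
  # oxidative C>A
  sbs18 <- 0.05 * base + 15 * (cls == "C>A" & p5 %in% c("G", "T"))
  # SHM: AID hotspot-like C>N at WRC plus polymerase-eta A:T component
  shm <- 0.2 * base +
    8 * (cls %in% c("C>T", "C>G") & p5 %in% c("A", "G")) +
    4 * (cls %in% c("T>A", "T>C") & p5 == "T")

  sigs <- cbind(
    SBSblood = weight(sbsblood), SBS1 = weight(sbs1), SBS7a = weight(sbs7a),
    SBS8 = weight(sbs8), SBS9 = weight(sbs9), SBS17b = weight(sbs17b),
    SBS18 = weight(sbs18), SHM = weight(shm)
  )
  rownames(sigs) <- ch
  sigs
}

#' Read a signature catalogue from TSV
#'
#' Expects 96 data rows, a first column of channel labels and one named
#' column per signature. Rows may be in any order; they are reordered to
#' the canonical channel order and columns renormalised to sum to 1.
#'
#' @param path Path to a tab-separated catalogue file.
#' @return Numeric matrix, 96 x n_signatures.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ch <- df[[1]]
  if (!setequal(ch, sbs_channels()) || length(ch) != 96L) {
    stop("catalogue must contain exactly the 96 canonical channels")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ch
  m <- m[sbs_channels(), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Write a signature catalogue to TSV
#' @param sigs 96 x S signature matrix with channel rownames.
#' @param path Output path.
#' @export
write_signature_catalog <- function(sigs, path) {
  df <- data.frame(channel = rownames(sigs), sigs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
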