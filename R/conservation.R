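## Per-column conservation scoring of multiple sequence alignments,
## mapping scores onto atomic models, and sequence-logo matrices.

.as_alignment_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (inherits(msa, "XStringSet")) {
    msa <- as.character(msa)
  }
  if (is.character(msa)) {
    if (length(msa) < 2) stop("alignment needs at least 2 sequences")
    if (length(unique(nchar(msa))) != 1)
      stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(toupper(msa), ""))
    rownames(m) <- names(msa)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' Per-column conservation profile of an alignment
#'
#' Scores each column by sum-of-pairs identity over non-gap pairs, then
#' z-normalises across columns (mean 0, sd 1), matching the signed score
#' ranges conventionally painted on structures. When every column has the
#' same raw score (no variance) all z-scores are 0 by convention. Columns
#' gapped in the reference row are dropped from the column-to-residue map.
#'
#' @param msa Alignment: character matrix, equal-length character vector,
#'   or a Biostrings `XStringSet`.
#' @param reference_row Name or index of the reference sequence.
#' @return Object of class `conservation_profile`: list with `scores`
#'   (z-scores per column), `raw` (sum-of-pairs identities), `column_map`
#'   (named integer vector: alignment column for each reference residue).
#' @export
conservation_profile <- function(msa, reference_row = 1) {
  m <- .as_alignment_matrix(msa)
  if (nrow(m) < 2) stop("alignment needs at least 2 sequences")
  if (is.character(reference_row)) {
    reference_row <- match(reference_row, rownames(m))
    if (is.na(reference_row)) stop("reference row not found in the alignment")
  }
  gap <- m == "-" | m == "."
  raw <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j][!gap[, j]]
    n <- length(col)
    if (n < 2) return(NA_real_)
    tab <- table(col)
    same <- sum(tab * (tab - 1) / 2)
    same / (n * (n - 1) / 2)
  }, numeric(1))
  ok <- !is.na(raw)
  mu <- mean(raw[ok])
  sdv <- stats::sd(raw[ok])
  z <- raw
  z[ok] <- if (is.na(sdv) || sdv < 1e-12) 0 else (raw[ok] - mu) / sdv
  refgap <- gap[reference_row, ]
  cols <- which(!refgap)
  column_map <- stats::setNames(cols, seq_along(cols))
  structure(list(scores = z, raw = raw, column_map = column_map,
                 reference_row = rownames(m)[reference_row]),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  ok <- !is.na(x$scores)
  cat(sprintf("Conservation profile: %d columns (%d mapped to reference), score range %.2f..%.2f\n",
              length(x$scores), length(x$column_map),
              min(x$scores[ok]), max(x$scores[ok])))
  invisible(x)
}

#' Map a conservation profile onto an atomic model
#'
#' Writes the per-residue z-score into the temperature-factor (B-factor)
#' column of a PDB file for the requested chain, residue i receiving the
#' score of the profile's i-th mapped column. Residues without a mapped
#' score receive the sentinel value (documented in the output header).
#'
#' @param profile A `conservation_profile`.
#' @param pdb_path Input PDB file.
#' @param chain Chain identifier; absence is an error.
#' @param out_path Output PDB path.
#' @param sentinel B-factor written for unmapped residues.
#' @return `out_path`, invisibly; attributes `n_mapped` and `n_sentinel`
#'   report coverage.
#' @export
map_conservation_to_model <- function(profile, pdb_path, chain, out_path,
                                      sentinel = -99.9) {
  pdb <- bio3d::read.pdb(pdb_path)
  sel <- pdb$atom$chain == chain
  if (!any(sel)) stop("chain '", chain, "' absent from ", pdb_path)
  resno <- pdb$atom$resno
  scores <- profile$scores[profile$column_map]
  b <- pdb$atom$b
  n_map <- 0L; n_sent <- 0L
  for (rn in unique(resno[sel])) {
    idx <- sel & resno == rn
    if (rn >= 1 && rn <= length(scores) && !is.na(scores[rn])) {
      b[idx] <- scores[rn]
      n_map <- n_map + 1L
    } else {
      b[idx] <- sentinel
      n_sent <- n_sent + 1L
    }
  }
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_path, b = b)
  ## prepend a REMARK documenting the sentinel
  lines <- readLines(out_path)
  header <- c(sprintf("REMARK   3 B-FACTOR COLUMN = CONSERVATION Z-SCORE; SENTINEL %.2f = UNMAPPED", sentinel))
  writeLines(c(header, lines), out_path)
  out <- out_path
  attr(out, "n_mapped") <- n_map
  attr(out, "n_sentinel") <- n_sent
  invisible(out)
}

#' Sequence-logo matrix
#'
#' Per-column base frequencies and information content `2 - H` (Shannon
#' entropy in bits over A, C, G, T), as used for WebLogo-style displays of
#' conserved motifs. No small-sample correction is applied by default.
#'
#' @param motifs Character vector of equal-length DNA strings (>= 2).
#' @return List with `frequencies` (4 x L matrix, rows A, C, G, T) and
#'   `information` (numeric length L, bits).
#' @export
logo_matrix <- function(motifs) {
  if (length(motifs) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(motifs))) != 1) stop("motif lengths differ")
  m <- do.call(rbind, strsplit(toupper(motifs), ""))
  L <- ncol(m)
  freqs <- vapply(seq_len(L), function(j) {
    counts <- table(factor(m[, j], levels = .dna_alphabet))
    n <- sum(counts)
    if (n == 0) rep(0, 4) else as.numeric(counts) / n
  }, numeric(4))
  rownames(freqs) <- .dna_alphabet
  info <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(frequencies = freqs, information = info)
}

#' Write a logo matrix as TSV
#'
#' @param logo Result of [logo_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = seq_along(logo$information),
                   t(logo$frequencies),
                   information = logo$information)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
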