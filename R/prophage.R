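## Prophage locus calling from homology hit tables and dif-site palindrome
## detection. Hits are inputs (e.g. parsed BLASTp tables), never computed
## here; coordinates are 1-based inclusive throughout.

#' Call prophage loci from homology hits
#'
#' A locus is a replication-initiator hit followed in proximity by a major
#' capsid protein hit on the same genome and strand ("followed" in locus
#' orientation: downstream on +, upstream on -). Overlapping candidate
#' pairings are resolved greedily by smallest gap, then leftmost, each hit
#' used once. Locus boundaries are the extent of the two hits (provisional;
#' [find_dif_sites()] refines them); loci with lengths outside
#' `length_range` are flagged, not dropped.
#'
#' @param hits Data frame with columns `query_id`, `genome_id`, `start`,
#'   `end`, `strand`, `score`.
#' @param max_gap Largest allowed gap (nt) between the rep hit and the MCP
#'   hit.
#' @param length_range Expected prophage length range (nt), defaults to the
#'   observed 5-10 kb scale of these elements.
#' @param rep_query,mcp_query `query_id` values identifying the two genes.
#' @return Data frame of loci: `genome_id`, `start`, `end`, `length`,
#'   `strand`, `gap`, `rep_start`, `rep_end`, `mcp_start`, `mcp_end`,
#'   `length_in_range`.
#' @export
call_prophage_loci <- function(hits, max_gap = 10000,
                               length_range = c(5000, 10000),
                               rep_query = "rep_initiator", mcp_query = "mcp") {
  req <- c("query_id", "genome_id", "start", "end", "strand", "score")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0)
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(hits$start > hits$end)) stop("hit with start > end")
  loci <- list()
  for (g in unique(hits$genome_id)) {
    for (s in c("+", "-")) {
      hs <- hits[hits$genome_id == g & hits$strand == s, , drop = FALSE]
      reps <- hs[hs$query_id == rep_query, , drop = FALSE]
      mcps <- hs[hs$query_id == mcp_query, , drop = FALSE]
      if (nrow(reps) == 0 || nrow(mcps) == 0) next
      ## candidate pairs with mcp following rep in locus orientation
      cand <- list()
      for (i in seq_len(nrow(reps))) for (j in seq_len(nrow(mcps))) {
        gap <- if (s == "+") mcps$start[j] - reps$end[i]
               else reps$start[i] - mcps$end[j]
        if (gap >= 0 && gap <= max_gap)
          cand[[length(cand) + 1]] <- c(i, j, gap,
                                        min(reps$start[i], mcps$start[j]))
      }
      if (length(cand) == 0) next
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3], cm[, 4]), , drop = FALSE]
      used_r <- logical(nrow(reps)); used_m <- logical(nrow(mcps))
      for (r in seq_len(nrow(cm))) {
        i <- cm[r, 1]; j <- cm[r, 2]
        if (used_r[i] || used_m[j]) next
        used_r[i] <- TRUE; used_m[j] <- TRUE
        st <- min(reps$start[i], mcps$start[j])
        en <- max(reps$end[i], mcps$end[j])
        loci[[length(loci) + 1]] <- data.frame(
          genome_id = g, start = st, end = en, length = en - st + 1L,
          strand = s, gap = cm[r, 3],
          rep_start = reps$start[i], rep_end = reps$end[i],
          mcp_start = mcps$start[j], mcp_end = mcps$end[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(loci) == 0) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), gap = numeric(0),
                      rep_start = integer(0), rep_end = integer(0),
                      mcp_start = integer(0), mcp_end = integer(0),
                      length_in_range = logical(0)))
  }
  out <- do.call(rbind, loci)
  out$length_in_range <- out$length >= length_range[1] &
    out$length <= length_range[2]
  out <- out[order(out$genome_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.dna_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], .dna_alphabet)  # NA for ambiguity
}

#' Palindromicity of a DNA sequence
#'
#' Fraction of positions i (outside the spacer) whose base complements the
#' base at the mirrored position `L + 1 - i`. Ambiguity codes score as
#' mismatches. The score is symmetric under reverse complement.
#'
#' @param seq DNA string.
#' @param spacer Optional `c(start, len)`: positions
#'   `start ... start + len - 1` (and their mirror partners) are excluded,
#'   e.g. the central hexanucleotide of a dif locus.
#' @return Fraction in `[0, 1]`.
#' @export
palindrome_score <- function(seq, spacer = NULL) {
  code <- .dna_codes(seq)
  L <- length(code)
  if (L < 2) stop("sequence too short")
  excl <- rep(FALSE, L)
  if (!is.null(spacer)) {
    if (length(spacer) != 2 || spacer[1] < 1 || spacer[2] < 0)
      stop("spacer must be c(start, len)")
    if (spacer[1] + spacer[2] - 1 > L)
      stop("sequence shorter than the spacer extent")
    if (spacer[2] > 0) excl[spacer[1]:(spacer[1] + spacer[2] - 1)] <- TRUE
  }
  i <- seq_len(L)
  j <- L + 1L - i
  consider <- !excl[i] & !excl[j]
  if (!any(consider)) stop("spacer excludes every position")
  ## complement in code space: A(1)<->T(4), C(2)<->G(3)
  comp <- 5L - code[j]
  matches <- code[i] == comp
  matches[is.na(matches)] <- FALSE  # ambiguity codes count as mismatch
  mean(matches[consider])
}

## palindrome scores of every window of width L in seq (vectorised);
## returns numeric vector of length nchar(seq) - L + 1
.scan_palindromes <- function(seq, L = 28, spacer = NULL) {
  code <- .dna_codes(seq)
  n <- length(code) - L + 1L
  if (n < 1) return(numeric(0))
  excl <- rep(FALSE, L)
  if (!is.null(spacer) && spacer[2] > 0)
    excl[spacer[1]:(spacer[1] + spacer[2] - 1)] <- TRUE
  i_all <- seq_len(L)
  j_all <- L + 1L - i_all
  consider <- which(!excl[i_all] & !excl[j_all])
  acc <- numeric(n)
  for (i in consider) {
    j <- L + 1L - i
    a <- code[i + seq_len(n) - 1L]
    b <- code[j + seq_len(n) - 1L]
    m <- a == (5L - b)
    m[is.na(m)] <- FALSE
    acc <- acc + m
  }
  acc / length(consider)
}

#' Locate dif sites flanking a prophage locus
#'
#' Scans both flanks of a locus for 28-nt windows whose palindrome score
#' (spacer excluded) reaches `min_score`, then looks for an
#' upstream/downstream pair with sequence identity at least
#' `min_pair_identity`. The best pair -- highest identity, then highest
#' summed palindrome score, then closest to the locus -- is decomposed into
#' XerC arm, central hexanucleotide and XerD arm. Absence is a valid
#' result.
#'
#' @param genome DNA string (or `synthetic_genome`).
#' @param locus One row of [call_prophage_loci()] output, or a list with
#'   `start`, `end`.
#' @param flank Flank width to scan (nt).
#' @param min_score Minimum palindrome score per site.
#' @param min_pair_identity Minimum identity between the paired sites.
#' @param motif_length Motif width (28 for the canonical dif locus).
#' @param arms `c(xerC, xerD)` arm lengths; with the central spacer they
#'   must partition the motif (default 11 + 6 + 11).
#' @return List with `dif_upstream` and `dif_downstream` (each `NULL` or a
#'   list with `position`, `sequence`, `xerC_arm`, `central_hexamer`,
#'   `xerD_arm`, `palindrome_score`) plus `pair_identity`.
#' @export
find_dif_sites <- function(genome, locus, flank = 5000, min_score = 0.9,
                           min_pair_identity = 0.9, motif_length = 28,
                           arms = c(11, 11)) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$sequence
  spacer_len <- motif_length - sum(arms)
  if (spacer_len < 0) stop("arms longer than the motif")
  spacer <- c(arms[1] + 1, spacer_len)
  st <- locus$start; en <- locus$end
  L <- nchar(genome)
  if (st < 1 || en > L || st > en) stop("locus not within the genome")
  empty <- list(dif_upstream = NULL, dif_downstream = NULL,
                pair_identity = NA_real_)

  scan_region <- function(a, b) {
    if (b - a + 1 < motif_length) return(NULL)
    sub <- substr(genome, a, b)
    sc <- .scan_palindromes(sub, motif_length, spacer)
    hit <- which(sc >= min_score)
    if (length(hit) == 0) return(NULL)
    data.frame(position = as.integer(a + hit - 1L), score = sc[hit])
  }
  up <- scan_region(max(1L, st - flank), st - 1L)
  dn <- scan_region(en + 1L, min(L, en + flank))
  if (is.null(up) || is.null(dn)) return(empty)

  best <- NULL
  for (i in seq_len(nrow(up))) {
    su <- substr(genome, up$position[i], up$position[i] + motif_length - 1L)
    for (j in seq_len(nrow(dn))) {
      sd <- substr(genome, dn$position[j], dn$position[j] + motif_length - 1L)
      idm <- mean(strsplit(su, "")[[1]] == strsplit(sd, "")[[1]])
      if (idm < min_pair_identity) next
      key <- c(idm, up$score[i] + dn$score[j],
               -(st - up$position[i]) - (dn$position[j] - en))
      if (is.null(best) ||
          key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2]) ||
          (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])) {
        best <- list(i = i, j = j, key = key, identity = idm)
      }
    }
  }
  if (is.null(best)) return(empty)

  mk <- function(pos) {
    sq <- substr(genome, pos, pos + motif_length - 1L)
    list(position = pos, sequence = sq,
         xerC_arm = substr(sq, 1, arms[1]),
         central_hexamer = substr(sq, arms[1] + 1, arms[1] + spacer_len),
         xerD_arm = substr(sq, arms[1] + spacer_len + 1, motif_length),
         palindrome_score = palindrome_score(sq, spacer))
  }
  list(dif_upstream = mk(up$position[best$i]),
       dif_downstream = mk(dn$position[best$j]),
       pair_identity = best$identity)
}

#' Refine locus boundaries with dif sites
#'
#' When both flanking dif sites are found, the locus is extended to the
#' interval between them (exclusive of the motifs themselves).
#'
#' @param locus One row of [call_prophage_loci()] output.
#' @param dif Result of [find_dif_sites()].
#' @param motif_length Motif width.
#' @return The locus row with refined `start`, `end`, `length`.
#' @export
refine_locus_with_dif <- function(locus, dif, motif_length = 28) {
  if (is.null(dif$dif_upstream) || is.null(dif$dif_downstream)) return(locus)
  locus$start <- as.integer(dif$dif_upstream$position + motif_length)
  locus$end <- as.integer(dif$dif_downstream$position - 1L)
  locus$length <- locus$end - locus$start + 1L
  locus
}
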