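## Seeded synthetic-data generators: particle metadata tables, host genomes
## with implanted prophage cassettes, and mutated sequence families, each
## carrying ground-truth records. Every generator runs on a single seeded
## RNG stream and is bit-reproducible for a fixed seed; the caller's RNG
## state is left untouched.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Synthetic particle metadata table
#'
#' Generates n particle records with orientations uniform over rotations
#' (normalised-quaternion sampling), defocus values uniform over the given
#' range, and small uniform origin offsets -- the metadata a refined capsid
#' data set provides, with no image content. Defaults mirror a 200 kV
#' counting-mode data set: defocus 0.1-2.2 micrometre, pixel size 1.24
#' Angstrom.
#'
#' @param n Number of particles (>= 1).
#' @param seed RNG seed; the same seed reproduces the table bit-for-bit.
#' @param defocus_range Length-2 range in micrometres (min < max).
#' @param pixel_size Calibrated pixel size in Angstrom.
#' @return Object of class `synthetic_particles`: list with `particles`
#'   (data frame: `id`, `euler_rot`, `euler_tilt`, `euler_psi`, `origin_x`,
#'   `origin_y`, `defocus_u`, `defocus_v` (Angstrom), `image_ref`,
#'   `pixel_size`), `n`, `seed`, `defocus_range`.
#' @export
gen_particle_table <- function(n, seed, defocus_range = c(0.1, 2.2),
                               pixel_size = 1.24) {
  stopifnot(n >= 1, n == round(n))
  if (length(defocus_range) != 2 || diff(defocus_range) <= 0)
    stop("defocus_range must be an increasing (min, max) pair in micrometres")
  particles <- .with_seed(seed, {
    A <- random_rotations(n)
    eul <- matrix_to_euler(A)
    def_u <- stats::runif(n, defocus_range[1], defocus_range[2]) * 1e4
    def_v <- stats::runif(n, defocus_range[1], defocus_range[2]) * 1e4
    data.frame(
      id = sprintf("p%06d", seq_len(n)),
      euler_rot = eul$rot, euler_tilt = eul$tilt, euler_psi = eul$psi,
      origin_x = stats::runif(n, -5, 5),
      origin_y = stats::runif(n, -5, 5),
      defocus_u = def_u, defocus_v = def_v,
      image_ref = sprintf("%06d@mic%04d.mrcs",
                          (seq_len(n) - 1L) %% 100L + 1L,
                          (seq_len(n) - 1L) %/% 100L + 1L),
      pixel_size = pixel_size,
      stringsAsFactors = FALSE)
  })
  structure(list(particles = particles, n = as.integer(n),
                 seed = seed, defocus_range = defocus_range,
                 orientation_model = "uniform-SO3"),
            class = "synthetic_particles")
}

#' @export
print.synthetic_particles <- function(x, ...) {
  cat(sprintf("Synthetic particle set: n = %d, seed = %s, defocus %.1f-%.1f um\n",
              x$n, format(x$seed), x$defocus_range[1], x$defocus_range[2]))
  invisible(x)
}

.dna_alphabet <- c("A", "C", "G", "T")

.comp_map <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "")[[1]])
  out <- .comp_map[ch]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

#' Synthetic host genome
#'
#' I.i.d. bases with the requested GC content (G and C equiprobable, A and
#' T equiprobable). The truth record starts empty; implanting features
#' fills it.
#'
#' @param length Genome length in nt (>= 1000).
#' @param gc GC fraction in (0, 1); the phage-relevant hosts sit near 0.31.
#' @param circular Logical flag recorded on the object; coordinates are
#'   reported on the linearised sequence starting at position 1.
#' @param seed RNG seed.
#' @return Object of class `synthetic_genome`: list with `sequence`, `gc`,
#'   `circular`, `truth` (features data frame), `hits` (synthetic homology
#'   hit table), `seed`.
#' @export
gen_genome <- function(length, gc = 0.305, circular = TRUE, seed = 1) {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  seqc <- .with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.dna_alphabet, length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(sequence = seqc, gc = gc, circular = circular,
                 truth = data.frame(), hits = data.frame(), seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d nt, target GC %.3f, %s, %d truth feature(s)\n",
              nchar(x$sequence), x$gc, ifelse(x$circular, "circular", "linear"),
              nrow(x$truth)))
  invisible(x)
}

#' Default dif-site sequence
#'
#' A 28-nt dif locus in the canonical bacterial arrangement used by the
#' generator: an 11-nt XerC arm, a 6-nt central hexanucleotide, and an
#' 11-nt XerD arm that is the reverse complement of the XerC arm, so the
#' arm positions are perfectly palindromic.
#'
#' @return Character scalar of length 28.
#' @export
default_dif_seq <- function() {
  xerC <- "GGTGCGTACAA"
  central <- "TGTATA"
  paste0(xerC, central, revcomp(xerC))
}

#' Implant a prophage cassette into a host genome
#'
#' Inserts a cassette emulating an integrated ssDNA phage: a replication
#' initiator ORF near the cassette start, followed by a major capsid
#' protein ORF and a spike ORF (synthetic sequences marked by coordinates,
#' not realistic codon structure), the whole cassette flanked by two copies
#' of the 28-nt dif sequence, as expected from XerC/XerD-mediated
#' integration at the host dif locus. The truth record receives all
#' coordinates and a matching synthetic homology hit table for the rep and
#' MCP (and spike) genes.
#'
#' @param host A `synthetic_genome`.
#' @param cassette_length Prophage length in nt (default 7642, the model
#'   phage genome length); must fit in the host with margins.
#' @param dif_seq 28-nt dif sequence flanking the cassette.
#' @param position Insertion point (cassette starts at `position + 1`), or
#'   `NULL` for a seeded random position away from the host ends.
#' @param seed RNG seed for the cassette sequence and position.
#' @param genome_id Identifier used in truth and hit records.
#' @return The modified `synthetic_genome` with `truth` and `hits` filled.
#' @export
implant_prophage <- function(host, cassette_length = 7642,
                             dif_seq = default_dif_seq(), position = NULL,
                             seed = 1, genome_id = "genome1") {
  stopifnot(inherits(host, "synthetic_genome"))
  if (nchar(dif_seq) != 28) stop("dif_seq must be exactly 28 nt")
  cassette_length <- as.integer(cassette_length)
  if (!is.null(position)) position <- as.integer(position)
  L <- nchar(host$sequence)
  ins_len <- cassette_length + 2L * 28L
  if (cassette_length < 4000) stop("cassette_length too short for the three ORFs")
  if (ins_len >= L) stop("cassette does not fit in the host genome")

  out <- .with_seed(seed, {
    pos <- position
    if (is.null(pos)) pos <- sample(seq(1000L, L - 1000L), 1)
    if (pos < 0 || pos > L) stop("position out of range")
    ## ORF layout inside the cassette (1-based, relative):
    ## rep near the start, then MCP, then spike; sizes follow the model
    ## phage proteins (rep ~330 aa, MCP 239 aa, spike 283 aa).
    rep_rel <- c(101L, 1090L)
    mcp_rel <- c(2201L, 2917L)
    spike_rel <- c(3401L, 4252L)
    gc <- host$gc
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    cassette <- paste(sample(.dna_alphabet, cassette_length, replace = TRUE,
                             prob = p), collapse = "")
    insert <- paste0(dif_seq, cassette, dif_seq)
    seqc <- paste0(substr(host$sequence, 1, pos), insert,
                   substr(host$sequence, pos + 1, L))
    ## genome coordinates
    cas_start <- pos + 28L + 1L
    cas_end <- cas_start + cassette_length - 1L
    feat <- data.frame(
      feature = c("dif_upstream", "prophage", "rep_initiator", "mcp",
                  "spike", "dif_downstream"),
      start = c(pos + 1L, cas_start, cas_start + rep_rel[1] - 1L,
                cas_start + mcp_rel[1] - 1L, cas_start + spike_rel[1] - 1L,
                cas_end + 1L),
      end = c(pos + 28L, cas_end, cas_start + rep_rel[2] - 1L,
              cas_start + mcp_rel[2] - 1L, cas_start + spike_rel[2] - 1L,
              cas_end + 28L),
      strand = c("+", "+", "+", "+", "+", "+"),
      stringsAsFactors = FALSE)
    hits <- data.frame(
      query_id = c("rep_initiator", "mcp", "spike"),
      genome_id = genome_id,
      start = feat$start[3:5], end = feat$end[3:5],
      strand = "+", score = c(180.0, 210.0, 95.0),
      stringsAsFactors = FALSE)
    list(sequence = seqc, truth = feat, hits = hits,
         cassette = cassette)
  })
  host$sequence <- out$sequence
  host$truth <- rbind(host$truth, out$truth)
  host$hits <- rbind(host$hits, out$hits)
  host$cassette <- out$cassette
  host$genome_id <- genome_id
  host
}

#' Mutated family of cassette copies with a truth alignment
#'
#' Produces n copies of a cassette under independent per-site substitution
#' and geometric-length indels, with the true multiple alignment maintained
#' by edit bookkeeping. Per-site substitution probabilities vary across
#' sites: site i mutates with probability `2 * sub_rate * v_i` with
#' `v_i ~ U(0, 1)` (mean `sub_rate`), and the truth records the
#' conservation weight `w_i = 1 - v_i`, enabling parameter-recovery tests
#' for conservation scoring. Substitutions pick uniformly among the three
#' other bases (Jukes-Cantor style).
#'
#' @param cassette Character DNA string.
#' @param n Number of copies.
#' @param sub_rate Mean per-site substitution probability in `[0, 0.5)`.
#' @param indel_rate Per-site indel initiation probability in `[0, 0.5)`,
#'   split evenly between deletions and insertions; insertion lengths are
#'   geometric with mean 2.
#' @param seed RNG seed.
#' @return Object of class `synthetic_family`: list with `sequences`
#'   (character vector), `alignment` (character matrix, rows = reference
#'   then copies, `-` for gaps), `site_weights` (per reference site
#'   conservation weight), `sub_rate`, `indel_rate`, `seed`.
#' @export
mutate_family <- function(cassette, n, sub_rate = 0.05, indel_rate = 0.0,
                          seed = 1) {
  stopifnot(n >= 1, sub_rate >= 0, sub_rate < 0.5,
            indel_rate >= 0, indel_rate < 0.5)
  ref <- strsplit(toupper(cassette), "")[[1]]
  L <- length(ref)
  .with_seed(seed, {
    v <- stats::runif(L)
    psub <- pmin(0.95, 2 * sub_rate * v)
    copies <- vector("list", n)
    inserts <- vector("list", n)   # per copy: list of (after_site, bases)
    for (ci in seq_len(n)) {
      bases <- ref
      ## substitutions
      hit <- stats::runif(L) < psub
      if (any(hit)) {
        for (i in which(hit)) {
          bases[i] <- sample(setdiff(.dna_alphabet, ref[i]), 1)
        }
      }
      ## deletions
      del <- stats::runif(L) < indel_rate / 2
      bases[del] <- NA
      ## insertions (after site i)
      insL <- stats::rgeom(L, 0.5) + 1L
      do_ins <- stats::runif(L) < indel_rate / 2
      ins <- list()
      for (i in which(do_ins)) {
        ins[[as.character(i)]] <- sample(.dna_alphabet, insL[i], replace = TRUE)
      }
      copies[[ci]] <- bases
      inserts[[ci]] <- ins
    }
    ## build the truth alignment: one column per reference site, plus
    ## insertion columns after each site (one block per copy with an
    ## insertion there; insertions from different copies do not align)
    ins_counts <- integer(L + 1)  # insertions possible after sites 0..L (0 unused)
    for (ci in seq_len(n)) {
      for (key in names(inserts[[ci]])) {
        i <- as.integer(key)
        ins_counts[i + 1L] <- ins_counts[i + 1L] + length(inserts[[ci]][[key]])
      }
    }
    ncol_total <- L + sum(ins_counts)
    aln <- matrix("-", n + 1, ncol_total)
    rn <- c("reference", sprintf("copy%03d", seq_len(n)))
    rownames(aln) <- rn
    col <- 0L
    colmap_ref <- integer(L)
    for (i in seq_len(L)) {
      col <- col + 1L
      colmap_ref[i] <- col
      aln["reference", col] <- ref[i]
      for (ci in seq_len(n)) {
        b <- copies[[ci]][i]
        aln[ci + 1L, col] <- ifelse(is.na(b), "-", b)
      }
      ## insertion block after site i
      for (ci in seq_len(n)) {
        insb <- inserts[[ci]][[as.character(i)]]
        if (!is.null(insb)) {
          aln[ci + 1L, col + seq_along(insb)] <- insb
          col <- col + length(insb)
        }
      }
    }
    aln <- aln[, seq_len(col), drop = FALSE]
    seqs <- apply(aln[-1, , drop = FALSE], 1, function(r)
      paste(r[r != "-"], collapse = ""))
    structure(list(sequences = seqs, alignment = aln,
                   site_weights = 1 - v, sub_prob = psub,
                   column_of_site = colmap_ref,
                   sub_rate = sub_rate, indel_rate = indel_rate, seed = seed),
              class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("Synthetic family: %d copies, sub_rate %.3f, indel_rate %.3f, %d alignment columns\n",
              length(x$sequences), x$sub_rate, x$indel_rate, ncol(x$alignment)))
  invisible(x)
}
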