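## Format readers and writers: STAR particle tables (RELION 3.0 loop
## dialect), FASTA via Biostrings, GFF3 feature export, and PDB pseudo-atom
## models. Coordinates are 1-based inclusive in GFF3/FASTA land.

#' Read a loop-format STAR block
#'
#' Parses the first (or named) `data_` block containing a `loop_` table.
#' Column names are preserved byte-exactly; numeric-looking columns are
#' converted.
#'
#' @param path STAR file path.
#' @param block Optional block name (without the `data_` prefix).
#' @return Object of class `star_table`: list with `block_name`, `data`
#'   (data frame).
#' @export
read_star <- function(path, block = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  i <- 1L
  n <- length(lines)
  repeat {
    while (i <= n && !grepl("^data_", lines[i])) i <- i + 1L
    if (i > n) stop("no data_ block", if (!is.null(block)) paste0(" '", block, "'"),
                    " found in ", path)
    bname <- sub("^data_", "", trimws(lines[i]))
    if (is.null(block) || bname == block) break
    i <- i + 1L
  }
  i <- i + 1L
  while (i <= n && trimws(lines[i]) == "") i <- i + 1L
  if (i > n || trimws(lines[i]) != "loop_")
    stop("malformed STAR block at line ", i, ": expected 'loop_'")
  i <- i + 1L
  cols <- character(0)
  while (i <= n && grepl("^_", trimws(lines[i]))) {
    tag <- strsplit(trimws(lines[i]), "\\s+")[[1]][1]
    cols <- c(cols, sub("^_", "", tag))
    i <- i + 1L
  }
  if (length(cols) == 0) stop("malformed STAR loop at line ", i, ": no column tags")
  rows <- list()
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^data_", ln)) break
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != length(cols))
      stop("malformed STAR row at line ", i, ": ", length(fields),
           " fields for ", length(cols), " columns")
    rows[[length(rows) + 1]] <- fields
    i <- i + 1L
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    suppressWarnings(num <- as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  structure(list(block_name = bname, data = df), class = "star_table")
}

#' Write a loop-format STAR block
#'
#' Numeric fields are written with 6 decimal places (integers as
#' integers); the round trip `read_star(write_star(x))` preserves rows and
#' column order.
#'
#' @param data Data frame (or `star_table`).
#' @param path Output path.
#' @param block Block name (without `data_` prefix).
#' @return The path, invisibly.
#' @export
write_star <- function(data, path, block = "particles") {
  if (inherits(data, "star_table")) {
    block <- data$block_name
    data <- data$data
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(data), seq_along(data)), con)
  fmt <- vapply(data, function(col) {
    if (is.numeric(col)) {
      if (all(col == round(col) & abs(col) < 1e15)) "int" else "num"
    } else "chr"
  }, character(1))
  cells <- vapply(seq_along(data), function(j) {
    col <- data[[j]]
    switch(fmt[j],
           int = sprintf("%d", as.integer(col)),
           num = sprintf("%.6f", col),
           chr = as.character(col))
  }, character(nrow(data)))
  if (nrow(data) == 1) cells <- matrix(cells, nrow = 1)
  writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  writeLines("", con)
  invisible(path)
}

## RELION 3.0 tag dialect for particle tables
.rln_map <- c(id = "rlnImageId",
              euler_rot = "rlnAngleRot", euler_tilt = "rlnAngleTilt",
              euler_psi = "rlnAnglePsi",
              origin_x = "rlnOriginX", origin_y = "rlnOriginY",
              defocus_u = "rlnDefocusU", defocus_v = "rlnDefocusV",
              image_ref = "rlnImageName",
              pixel_size = "rlnDetectorPixelSize")

#' Write particles as a RELION-dialect STAR file
#'
#' @param particles Particle data frame or `synthetic_particles`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_particles_star <- function(particles, path) {
  if (inherits(particles, "synthetic_particles")) particles <- particles$particles
  df <- particles
  keep <- intersect(names(.rln_map), names(df))
  df <- df[, keep, drop = FALSE]
  names(df) <- .rln_map[keep]
  write_star(df, path, block = "particles")
}

#' Read particles from a RELION-dialect STAR file
#'
#' Maps the RELION 3.0 tags back onto the package's particle-record
#' columns; a missing required column (e.g. the tilt angle) is an explicit
#' error naming the tag.
#'
#' @param path STAR file path.
#' @param required Columns that must be present.
#' @return Particle data frame.
#' @export
read_particles_star <- function(path,
                                required = c("euler_rot", "euler_tilt",
                                             "euler_psi", "origin_x",
                                             "origin_y", "defocus_u",
                                             "defocus_v", "pixel_size")) {
  st <- read_star(path)
  df <- st$data
  inv <- stats::setNames(names(.rln_map), .rln_map)
  keep <- intersect(names(inv), names(df))
  df <- df[, keep, drop = FALSE]
  names(df) <- inv[keep]
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("STAR file lacks required column(s): ",
         paste(.rln_map[miss], collapse = ", "))
  if (!"id" %in% names(df)) df$id <- sprintf("p%06d", seq_len(nrow(df)))
  df
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings preserving headers; duplicated ids on
#' write are an error.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector (or `XStringSet`).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named")
    if (anyDuplicated(names(seqs))) stop("duplicate FASTA ids")
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write prophage loci and dif sites as GFF3
#'
#' One `mobile_genetic_element` feature per locus with its dif sites as
#' child features; coordinates 1-based inclusive.
#'
#' @param loci Data frame from [call_prophage_loci()].
#' @param path Output path.
#' @param dif_list Optional list (parallel to rows of `loci`) of
#'   [find_dif_sites()] results.
#' @param source Source column value.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(loci, path, dif_list = NULL, source = "capsidlattice") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    id <- sprintf("prophage%03d", i)
    writeLines(paste(loci$genome_id[i], source, "mobile_genetic_element",
                     loci$start[i], loci$end[i], ".", loci$strand[i], ".",
                     sprintf("ID=%s;Name=%s", id, id), sep = "\t"), con)
    if (!is.null(dif_list) && length(dif_list) >= i && !is.null(dif_list[[i]])) {
      dd <- dif_list[[i]]
      for (side in c("dif_upstream", "dif_downstream")) {
        dm <- dd[[side]]
        if (is.null(dm)) next
        writeLines(paste(loci$genome_id[i], source, "recombination_feature",
                         dm$position, dm$position + nchar(dm$sequence) - 1L,
                         sprintf("%.3f", dm$palindrome_score), loci$strand[i], ".",
                         sprintf("ID=%s_%s;Parent=%s", id, side, id),
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Write a capsid point model as PDB pseudo-atoms
#'
#' One HETATM per point. Chains encode the capsomer type (P pentamer,
#' H hexamer, M membrane); for a typed T = 21 model the occupancy column
#' carries the trimer type, allowing downstream colouring.
#'
#' @param model A `capsid_point_model`.
#' @param path Output path.
#' @param scale Coordinate scale factor applied on output (PDB columns are
#'   8.3f; large capsids in Angstrom fit unscaled).
#' @return The path, invisibly.
#' @export
write_pdb_points <- function(model, path, scale = 1) {
  pts <- model$points
  chain <- c(pentamer = "P", hexamer = "H", membrane = "M")[pts$label]
  chain[is.na(chain)] <- "X"
  occ <- ifelse(is.na(pts$trimer_type), 0, pts$trimer_type)
  if (is.null(pts$trimer_type)) occ <- rep(0, nrow(pts))
  elem <- ifelse(pts$label == "pentamer", "P", "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   capsid point model T=%s radius=%.1f A",
                     ifelse(is.null(model$T), "?", model$T),
                     model$capsid_radius), con)
  for (i in seq_len(nrow(pts))) {
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (i - 1L) %% 99999L + 1L, substr(toupper(pts$label[i]), 1, 3), "CAP",
      chain[i], (i - 1L) %% 9999L + 1L,
      pts$x[i] * scale, pts$y[i] * scale, pts$z[i] * scale,
      occ[i], 0, elem[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}
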