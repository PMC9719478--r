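## Hexamer complexity: how many distinct hexamer fold shapes a Caspar-Klug
## design requires, and the resulting constraint analysis for capsids whose
## hexagon positions must be filled by pseudo-hexameric trimers.
##
## Each hexamer is a hexagonal tile (Voronoi cell of its lattice point) on
## the polyhedral capsid. Icosahedral edges crossing the tile are fold lines
## ("creases"). The neighbourhood of a hexamer contains no icosahedral
## vertex (the nearest vertex is one lattice spacing away, outside the
## tile's circumradius 1/sqrt(3)), so the tile and its crease pattern can be
## computed exactly in the plane by unfolding the adjacent faces.
##
## A crease is typed combinatorially, not metrically: by whether it runs
## along the tile rim (a boundary fold shared with a neighbouring capsomer)
## or cuts the interior, and by the number of the hexamer's six subunit
## wedges (the kites around the centre, one per jelly-roll-bearing subunit
## sector) that the crease touches. The hexamer signature is the multiset
## of its crease types; the hexamer complexity C^h of a design is the
## number of distinct signatures. This operationalisation is calibrated to
## reproduce the published reference values: C^h = 4 for T = 27,
## C^h <= 2 for T in {3, 7, 9, 13, 21, 25} and C^h > 2 for T in {12, 19, 27}.

## reflect point p across the line through A, B
.reflect2 <- function(p, A, B) {
  d <- (B - A) / sqrt(sum((B - A)^2))
  v <- p - A
  A + 2 * sum(v * d) * d - v
}

## all icosahedral-edge segments near the face, by unfolding neighbours
.unfolded_edges_2d <- function(tri, depth = 2) {
  tris <- list(rbind(tri$P0, tri$P1, tri$P2))
  frontier <- tris
  for (lev in seq_len(depth)) {
    nxt <- list()
    for (tt in frontier) for (i in 1:3) {
      A <- tt[i, ]; B <- tt[i %% 3 + 1, ]; C <- tt[(i + 1) %% 3 + 1, ]
      nxt[[length(nxt) + 1]] <- rbind(A, B, .reflect2(C, A, B))
    }
    tris <- c(tris, nxt)
    frontier <- nxt
  }
  segs <- list()
  for (tt in tris) for (i in 1:3) {
    A <- tt[i, ]; B <- tt[i %% 3 + 1, ]
    segs[[paste(round(sort(c(A, B)), 6), collapse = ",")]] <- rbind(A, B)
  }
  segs
}

## clip segment to a convex polygon (ccw rows); closed with tolerance;
## returns c(t0, t1) in segment parameter or NULL
.clip_seg_poly <- function(A, B, poly, tol = 1e-7) {
  d <- B - A
  t0 <- 0; t1 <- 1
  np <- nrow(poly)
  for (i in seq_len(np)) {
    V <- poly[i, ]; W <- poly[i %% np + 1, ]
    en <- c(-(W[2] - V[2]), W[1] - V[1])
    den <- sum(d * en)
    num <- sum((V - A) * en)
    if (abs(den) < 1e-12) {
      if (num > tol) return(NULL)
    } else if (den > 0) {
      t0 <- max(t0, (num - tol) / den)
    } else {
      t1 <- min(t1, (num - tol) / den)
    }
  }
  if (t1 < t0) return(NULL)
  c(t0, t1)
}

.hex_vertices_2d <- function(c0) {
  j <- 0:5
  cbind(c0[1] + cos((30 + 60 * j) * pi / 180) / sqrt(3),
        c0[2] + sin((30 + 60 * j) * pi / 180) / sqrt(3))
}

## crease type for one unfolded edge segment against the tile at c0:
## "edge<n>" rim fold or "cut<n>" interior chord, n = wedges touched;
## NULL when the edge misses the tile (or only grazes a vertex point).
.crease_type <- function(seg, c0, tol = 1e-6) {
  hex <- .hex_vertices_2d(c0)
  A <- seg[1, ]; B <- seg[2, ]
  d <- B - A
  nvec <- c(-d[2], d[1]) / sqrt(sum(d^2))
  dist_c <- abs(sum((c0 - A) * nvec))
  supp <- max(abs((hex[, 1] - c0[1]) * nvec[1] + (hex[, 2] - c0[2]) * nvec[2]))
  pen <- supp - dist_c
  if (pen <= -tol) return(NULL)
  tc <- .clip_seg_poly(A, B, hex, tol)
  if (is.null(tc) || (tc[2] - tc[1]) * sqrt(sum(d^2)) < 10 * tol) return(NULL)
  kind <- if (pen <= tol) "edge" else "cut"
  nw <- 0L
  for (j in 0:5) {
    a0 <- 60 * j * pi / 180
    a1 <- 60 * (j + 1) * pi / 180
    kite <- rbind(c0,
                  c0 + 0.5 * c(cos(a0), sin(a0)),
                  hex[j + 1, ],
                  c0 + 0.5 * c(cos(a1), sin(a1)))
    if (!is.null(.clip_seg_poly(A, B, kite, tol))) nw <- nw + 1L
  }
  paste0(kind, nw)
}

#' Hexamer fold-shape signatures of a lattice
#'
#' Computes the crease-pattern signature of every hexamer with its centre in
#' one icosahedral face (every hexamer orbit has such a representative, and
#' icosahedrally equivalent hexamers share the signature by construction).
#'
#' @param h,k Lattice indices.
#' @return Character vector of signatures, one per in-face hexamer;
#'   `"flat"` marks an uncreased tile.
#' @export
hexamer_signatures <- function(h, k) {
  t_number(h, k)
  tri <- .face_triangle_2d(h, k)
  fl <- .face_lattice_2d(h, k)
  pts <- fl$xy[!fl$corner, , drop = FALSE]
  if (nrow(pts) == 0) return(character(0))
  segs <- .unfolded_edges_2d(tri)
  apply(pts, 1, function(c0) {
    types <- character(0)
    for (seg in segs) {
      ty <- .crease_type(seg, c0)
      if (!is.null(ty)) types <- c(types, ty)
    }
    if (length(types) == 0) "flat" else paste(sort(types), collapse = "+")
  })
}

#' Hexamer complexity
#'
#' The number of distinct hexamer fold shapes (crease-pattern signatures)
#' required by the (h, k) design. Designs needing more than two hexamer
#' shapes are underrepresented among observed capsids and are treated as
#' disfavoured by the constraint analysis.
#'
#' @param h,k Lattice indices.
#' @return Integer count of distinct signatures (0 when there are no
#'   hexamers, i.e. T = 1).
#' @export
hexamer_complexity <- function(h, k) {
  length(unique(hexamer_signatures(h, k)))
}

#' Is a design available to pseudo-hexameric trimeric MCPs?
#'
#' A trimer cannot occupy a two-fold symmetric position, so any design that
#' places a hexagon on an icosahedral two-fold axis is excluded; designs
#' whose hexamer complexity exceeds `max_complexity` are excluded as
#' evolutionarily disfavoured; T = 1 has no hexagon positions at all and is
#' not a trimer-built capsid.
#'
#' @param h,k Lattice indices.
#' @param max_complexity Largest admissible hexamer complexity (default 2).
#' @param lattice Optional prebuilt `ck_lattice` for the geometric two-fold
#'   test.
#' @return List with `allowed` flag and `reasons` character vector (empty
#'   when allowed).
#' @export
allowed_for_trimeric_mcp <- function(h, k, max_complexity = 2, lattice = NULL) {
  Tn <- t_number(h, k)
  reasons <- character(0)
  if (Tn == 1) reasons <- c(reasons, "no-hexamers")
  if (Tn > 1 && hexagon_on_axis(h, k, fold = 2, lattice = lattice))
    reasons <- c(reasons, "hexagon-on-two-fold")
  if (hexamer_complexity(h, k) > max_complexity)
    reasons <- c(reasons, "complexity")
  list(allowed = length(reasons) == 0, reasons = reasons)
}

#' Atlas of capsid architectures
#'
#' One record per canonical (h, k) with T up to `t_max`: the lattice class
#' and handedness, hexagon census, axis-occupancy flags from the geometric
#' tests, hexamer complexity, the trimeric-MCP verdict, and diameter/volume
#' relative to a reference T. The relative diameter follows the
#' parameter-free surface-area scaling `D = sqrt(T / t_ref)` and volume
#' `V = D^3`.
#'
#' @param t_max Largest T to include.
#' @param t_ref Reference T for the relative dimensions (default 21).
#' @param max_complexity Complexity bound passed to the constraint test.
#' @param group Optional prebuilt `icosa_group`.
#' @return Data frame with columns `h`, `k`, `T`, `class`, `handedness`,
#'   `n_hexagons`, `hex_on_2fold`, `hex_on_3fold`, `Ch`, `allowed`,
#'   `reasons`, `D_rel`, `V_rel`.
#' @export
capsid_atlas <- function(t_max, t_ref = 21, max_complexity = 2, group = NULL) {
  idx <- ck_indices(t_max)
  if (is.null(group)) group <- build_icosahedral_group()
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    h <- idx$h[i]; k <- idx$k[i]; Tn <- idx$T[i]
    cls <- classify_lattice(h, k)
    lat <- build_capsid_lattice(h, k, group = group)
    ch <- hexamer_complexity(h, k)
    verdict <- allowed_for_trimeric_mcp(h, k, max_complexity, lattice = lat)
    data.frame(h = h, k = k, T = Tn,
               class = cls$capsid_class, handedness = cls$handedness,
               n_hexagons = 10L * (Tn - 1L),
               hex_on_2fold = hexagon_on_axis(h, k, 2, lattice = lat),
               hex_on_3fold = hexagon_on_axis(h, k, 3, lattice = lat),
               Ch = ch,
               allowed = verdict$allowed,
               reasons = paste(verdict$reasons, collapse = ";"),
               D_rel = sqrt(Tn / t_ref),
               V_rel = (Tn / t_ref)^1.5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$T, out$class), , drop = FALSE]
}

#' Write an atlas as TSV
#'
#' @param atlas Data frame from [capsid_atlas()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_atlas_tsv <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
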