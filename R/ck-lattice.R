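## Caspar-Klug lattices: construction on the icosahedron, classification,
## and the constraint analysis for capsids built from pseudo-hexameric
## trimeric major capsid proteins.
##
## Planar conventions: hexagonal lattice basis a1 = (1, 0),
## a2 = (1/2, sqrt(3)/2); the face triangle has corners P0 = origin,
## P1 = h a1 + k a2 and P2 = P1 rotated by +60 degrees. T = |P1|^2.

.ck_a1 <- c(1, 0)
.ck_a2 <- c(0.5, sqrt(3) / 2)

.rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Triangulation number
#'
#' Caspar-Klug triangulation number `T = h^2 + h k + k^2` of the lattice
#' index pair.
#'
#' @param h,k Non-negative integer lattice indices; `h = k = 0` is an error.
#' @return Integer T.
#' @export
t_number <- function(h, k) {
  stopifnot(length(h) == 1, length(k) == 1)
  if (h < 0 || k < 0 || h != round(h) || k != round(k))
    stop("lattice indices must be non-negative integers")
  if (h == 0 && k == 0) stop("lattice index (0,0) is not a capsid")
  as.integer(h^2 + h * k + k^2)
}

#' Enumerate canonical lattice indices up to a T bound
#'
#' Canonical indices have `h >= k >= 0`, `h >= 1` (the dextro representative
#' of each mirror pair), sorted by T then by class.
#'
#' @param t_max Largest T to include.
#' @return Data frame with columns `h`, `k`, `T`.
#' @export
ck_indices <- function(t_max) {
  stopifnot(t_max >= 1)
  hmax <- ceiling(sqrt(t_max))
  out <- list()
  for (h in 1:hmax) for (k in 0:h) {
    Tn <- h^2 + h * k + k^2
    if (Tn <= t_max) out[[length(out) + 1]] <- c(h, k, Tn)
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("h", "k", "T")
  df[] <- lapply(df, as.integer)
  df[order(df$T, df$k), , drop = FALSE]
}

#' Number of hexamer positions
#'
#' `N = 60 (T - 1) / 6 = 10 (T - 1)` hexagon positions for a valid
#' triangulation number; the 12 pentamer positions are fixed.
#'
#' @param T Triangulation number; values not expressible as `h^2 + h k + k^2`
#'   are an error.
#' @return Integer hexamer count.
#' @export
hexagon_count <- function(T) {
  stopifnot(length(T) == 1)
  idx <- ck_indices(max(T, 1))
  if (!T %in% idx$T)
    stop("T = ", T, " is not a triangulation number (no integer h,k solve h^2+hk+k^2)")
  as.integer(10 * (T - 1))
}

#' Classify a lattice index
#'
#' Capsid class 1 for axial lattices (`k = 0` or `h = 0`), class 3 for
#' rhombic (`h = k`), class 2 for skew lattices. Skew lattices are handed:
#' `h > k > 0` is dextro (right-handed, the convention anchored by the
#' T = 21 dextro (4,1) capsids PM2, FLiP and their ssDNA relatives),
#' `k > h > 0` laevo; classes 1 and 3 are achiral.
#'
#' @param h,k Lattice indices.
#' @return List with `capsid_class` (integer) and `handedness`
#'   ("dextro", "laevo" or "achiral").
#' @export
classify_lattice <- function(h, k) {
  t_number(h, k)  # validates
  if (h == 0 || k == 0) {
    list(capsid_class = 1L, handedness = "achiral")
  } else if (h == k) {
    list(capsid_class = 3L, handedness = "achiral")
  } else {
    list(capsid_class = 2L, handedness = if (h > k) "dextro" else "laevo")
  }
}

## Planar face-triangle helpers -------------------------------------------

.face_triangle_2d <- function(h, k) {
  P1 <- h * .ck_a1 + k * .ck_a2
  list(P0 = c(0, 0), P1 = P1, P2 = as.vector(.rot2(60) %*% P1))
}

## lattice points in the closed face triangle; corners flagged
.face_lattice_2d <- function(h, k, tol = 1e-9) {
  tri <- .face_triangle_2d(h, k)
  Minv <- solve(cbind(tri$P1, tri$P2))
  rng <- -(h + k + 1):(2 * (h + k) + 1)
  mn <- as.matrix(expand.grid(m = rng, n = rng))
  P <- cbind(mn[, 1] + 0.5 * mn[, 2], mn[, 2] * sqrt(3) / 2)
  B <- P %*% t(Minv)
  inside <- B[, 1] >= -tol & B[, 2] >= -tol & rowSums(B) <= 1 + tol
  B <- B[inside, , drop = FALSE]
  P <- P[inside, , drop = FALSE]
  corner <- (B[, 1] < tol & B[, 2] < tol) |
    (abs(B[, 1] - 1) < tol & B[, 2] < tol) |
    (B[, 1] < tol & abs(B[, 2] - 1) < tol)
  list(xy = P, bary = B, corner = corner, tri = tri)
}

#' Construct a Caspar-Klug capsid lattice on the icosahedron
#'
#' Builds the planar hexagonal lattice, cuts the icosahedral face triangle
#' with corners on lattice points separated by (h, k), maps the face onto one
#' face of the reference icosahedron and replicates it with the 60 rotation
#' operators, deduplicating shared sites. The result carries 12 pentamer
#' sites (the icosahedron vertices) and `10 (T - 1)` hexamer sites, each
#' flagged for coincidence with two- and three-fold axes and labelled with
#' its orbit.
#'
#' @param h,k Lattice indices.
#' @param group Optionally a prebuilt `icosa_group` (built on demand).
#' @param tol Relative tolerance for site deduplication and axis tests.
#' @return An object of class `ck_lattice`: list with `h`, `k`, `T`,
#'   `sites` (data frame: `x`, `y`, `z` unit position, `kind`
#'   pentamer/hexamer, `on_twofold`, `on_threefold`, `orbit_id`,
#'   `orbit_size`), `capsid_class`, `handedness`.
#' @export
build_capsid_lattice <- function(h, k, group = NULL, tol = 1e-6) {
  Tn <- t_number(h, k)
  if (is.null(group)) group <- build_icosahedral_group()
  verts <- icosahedron_vertices()
  ## one reference face: three mutually adjacent vertices
  d <- as.matrix(dist(verts))
  edge_len <- min(d[d > 1e-9])
  face <- NULL
  for (i in 1:10) {
    if (!is.null(face)) break
    for (j in (i + 1):11) {
      if (!is.null(face)) break
      for (l in (j + 1):12) {
        if (abs(d[i, j] - edge_len) < 1e-9 && abs(d[i, l] - edge_len) < 1e-9 &&
            abs(d[j, l] - edge_len) < 1e-9) {
          face <- c(i, j, l)
          break
        }
      }
    }
  }
  V <- verts[face, ]
  ## outward orientation: the face normal must point away from the origin
  nrm <- crossprod_3(V[2, ] - V[1, ], V[3, ] - V[1, ])
  if (sum(nrm * colMeans(V)) < 0) V <- V[c(1, 3, 2), ]

  fl <- .face_lattice_2d(h, k)
  ## barycentric w.r.t. (P0, P1, P2): position = (1-u-v) V1 + u V2 + v V3
  w <- cbind(1 - rowSums(fl$bary), fl$bary)
  pts3 <- w %*% V
  pts3 <- pts3 / sqrt(rowSums(pts3^2))
  kinds <- ifelse(fl$corner, "pentamer", "hexamer")

  G <- group_array(group)
  all_pts <- vector("list", 60)
  for (g in 1:60) all_pts[[g]] <- pts3 %*% t(G[, , g])
  all_pts <- do.call(rbind, all_pts)
  all_kind <- rep(kinds, 60)

  ## dedup on a rounded-key first pass, then exact greedy pass within keys
  key <- apply(round(all_pts / (10 * tol)), 1, paste, collapse = ",")
  first <- !duplicated(key)
  P <- all_pts[first, , drop = FALSE]
  K <- all_kind[first]
  ## greedy second pass to merge near-boundary duplicates
  ord <- order(round(P[, 1], 6), round(P[, 2], 6), round(P[, 3], 6))
  P <- P[ord, , drop = FALSE]; K <- K[ord]
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P))) {
    if (!keep[i]) next
    j <- i + 1
    while (j <= nrow(P) && P[j, 1] - P[i, 1] < tol * 4) {
      if (keep[j] && sum(abs(P[j, ] - P[i, ])) < tol * 4) keep[j] <- FALSE
      j <- j + 1
    }
  }
  P <- P[keep, , drop = FALSE]; K <- K[keep]

  n_pent <- sum(K == "pentamer")
  n_hex <- sum(K == "hexamer")
  if (n_pent != 12 || n_hex != 10 * (Tn - 1))
    stop("lattice census failed: ", n_pent, " pentamers, ", n_hex,
         " hexamers for T = ", Tn)

  ax <- symmetry_axes(group)
  axmat <- as.matrix(ax[, c("x", "y", "z")])
  dots <- abs(P %*% t(axmat))
  on2 <- apply(dots[, ax$fold == 2, drop = FALSE], 1, max) > 1 - tol
  on3 <- apply(dots[, ax$fold == 3, drop = FALSE], 1, max) > 1 - tol

  ## orbit decomposition
  orbit_id <- integer(nrow(P))
  orbit_size <- integer(nrow(P))
  nid <- 0L
  for (i in seq_len(nrow(P))) {
    if (orbit_id[i] > 0) next
    nid <- nid + 1L
    ob <- orbit_of(P[i, ], group, tol)
    for (m in seq_len(nrow(ob$members))) {
      dd <- rowSums(abs(P - matrix(ob$members[m, ], nrow(P), 3, byrow = TRUE)))
      hit <- which(dd < tol * 4)
      orbit_id[hit] <- nid
    }
    orbit_size[orbit_id == nid] <- nrow(ob$members)
  }

  cls <- classify_lattice(h, k)
  sites <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                      kind = K, on_twofold = on2, on_threefold = on3,
                      orbit_id = orbit_id, orbit_size = orbit_size,
                      stringsAsFactors = FALSE)
  structure(list(h = h, k = k, T = Tn, sites = sites,
                 capsid_class = cls$capsid_class, handedness = cls$handedness),
            class = "ck_lattice")
}

#' @export
print.ck_lattice <- function(x, ...) {
  cat(sprintf("Caspar-Klug lattice (h,k) = (%d,%d): T = %d, class %d %s\n",
              x$h, x$k, x$T, x$capsid_class, x$handedness))
  hx <- x$sites[x$sites$kind == "hexamer", ]
  cat(sprintf("  %d pentamers, %d hexamers in %d orbits\n",
              sum(x$sites$kind == "pentamer"), nrow(hx),
              length(unique(hx$orbit_id))))
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
crossprod_3 <- .cross3

#' Does any hexamer sit on a symmetry axis?
#'
#' Geometric test on the constructed lattice: true iff some hexamer centre
#' coincides (within tolerance) with an axis of the requested fold. For
#' Caspar-Klug lattices this is equivalent to the parity rule (fold 2: T
#' even) and the divisibility rule (fold 3: T divisible by 3), which the
#' test suite verifies by brute force.
#'
#' @param h,k Lattice indices, or `lattice` a prebuilt `ck_lattice`.
#' @param fold 2 or 3.
#' @param lattice Optional prebuilt lattice (overrides h, k).
#' @return Logical flag.
#' @export
hexagon_on_axis <- function(h, k, fold, lattice = NULL) {
  stopifnot(fold %in% c(2, 3))
  if (is.null(lattice)) lattice <- build_capsid_lattice(h, k)
  hexes <- lattice$sites[lattice$sites$kind == "hexamer", ]
  if (nrow(hexes) == 0) return(FALSE)
  if (fold == 2) any(hexes$on_twofold) else any(hexes$on_threefold)
}
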