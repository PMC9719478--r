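## The icosahedral rotation group I (order 60) and its orbit machinery.
##
## Axis convention: the icosahedron with vertices (0, +-1, +-phi) and cyclic
## permutations (phi the golden ratio), which places two-fold axes on x, y and
## z and a five-fold axis in the yz plane at (0, 1, phi)/|.|.  This is the
## common cryo-EM "I" (222) setting.

.icosa_phi <- (1 + sqrt(5)) / 2

#' Vertices of the reference icosahedron
#'
#' The 12 unit vertices of the icosahedron in the package's axis convention
#' (two-fold axes on x, y, z).
#'
#' @return A 12x3 matrix of unit vectors.
#' @export
icosahedron_vertices <- function() {
  phi <- .icosa_phi
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

#' Build the icosahedral rotation group
#'
#' Generates the 60 proper rotations of the icosahedron from one five-fold
#' generator (72 degrees about the vertex (0, 1, phi)/|.|) and one two-fold
#' generator (180 degrees about z), closing the set under multiplication.
#' Generating rather than hard-coding the matrices makes the construction
#' self-verifying: closure at order 60 is only reached if the generators are
#' consistent.
#'
#' @param tol Absolute tolerance used to deduplicate matrices.
#' @return An object of class `icosa_group`: a list with `operators`
#'   (a list of 60 3x3 matrices, the identity first) and `convention_tag`.
#' @export
build_icosahedral_group <- function(tol = 1e-9) {
  g5 <- rot_about_axis(c(0, 1, .icosa_phi), 72)
  g2 <- rot_about_axis(c(0, 0, 1), 180)
  ops <- list(diag(3))
  frontier <- list(diag(3))
  gens <- list(g5, g2)
  is_known <- function(M, ops) {
    for (O in ops) if (max(abs(M - O)) < 1e-6) return(TRUE)
    FALSE
  }
  while (length(frontier) > 0) {
    nxt <- list()
    for (F in frontier) for (G in gens) {
      M <- G %*% F
      if (!is_known(M, ops) && !is_known(M, nxt)) nxt[[length(nxt) + 1]] <- M
    }
    ops <- c(ops, nxt)
    frontier <- nxt
    if (length(ops) > 60) stop("group closure exceeded order 60; generators inconsistent")
  }
  if (length(ops) != 60) stop("group closure produced ", length(ops), " operators, expected 60")
  structure(list(operators = ops,
                 convention_tag = "I setting: 2-fold axes on x,y,z; 5-fold at (0,1,phi)"),
            class = "icosa_group")
}

#' @export
print.icosa_group <- function(x, ...) {
  cat("Icosahedral rotation group: ", length(x$operators), " operators\n",
      "convention: ", x$convention_tag, "\n", sep = "")
  invisible(x)
}

#' Stack group operators into an array
#' @param group An `icosa_group`.
#' @return A `3 x 3 x 60` array.
#' @keywords internal
group_array <- function(group) {
  array(unlist(group$operators), c(3, 3, length(group$operators)))
}

#' Verify the group axioms numerically
#'
#' Checks determinant +1 for every operator and closure of all pairwise
#' products by brute force. Called by consumers that must fail loudly on a
#' malformed group.
#'
#' @param group An `icosa_group`.
#' @param tol Tolerance for matrix equality.
#' @return `TRUE` invisibly; stops with an error on violation.
#' @export
validate_icosa_group <- function(group, tol = 1e-9) {
  ops <- group$operators
  n <- length(ops)
  if (n != 60) stop("icosahedral group must have 60 operators, found ", n)
  flat <- vapply(ops, as.vector, numeric(9))
  for (O in ops) {
    if (abs(det(O) - 1) > tol) stop("operator with determinant != +1")
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M <- as.vector(ops[[i]] %*% ops[[j]])
    if (min(colSums(abs(flat - M))) > 9 * 1e-6)
      stop("group not closed under composition at pair (", i, ",", j, ")")
  }
  invisible(TRUE)
}

#' Symmetry axes of the icosahedral group
#'
#' Extracts the rotation axes of all non-identity operators and bins them by
#' rotation fold. Antipodal directions are identified, giving the census of
#' 6 five-fold, 10 three-fold and 15 two-fold axes.
#'
#' @param group An `icosa_group`.
#' @param tol Tolerance used for angle classification and deduplication.
#' @return A data frame with columns `x`, `y`, `z` (unit direction) and
#'   `fold` (2, 3 or 5).
#' @export
symmetry_axes <- function(group, tol = 1e-6) {
  ops <- group$operators
  if (length(ops) != 60) stop("malformed group: expected 60 operators")
  ## cheap closure spot-check so a corrupted group errors out early
  flat <- vapply(ops, as.vector, numeric(9))
  for (i in c(1, 7, 23, 41, 60)) for (j in c(2, 13, 37, 59)) {
    if (i <= length(ops) && j <= length(ops)) {
      M <- as.vector(ops[[i]] %*% ops[[j]])
      if (min(colSums(abs(flat - M))) > 9 * 1e-5)
        stop("malformed group: not closed under composition")
    }
  }
  axes <- list()
  for (O in ops) {
    tr <- sum(diag(O))
    if (abs(tr - 3) < tol) next  # identity
    angle <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
    fold <- if (abs(angle - 180) < 1e-4) 2L
    else if (abs(angle - 120) < 1e-4) 3L
    else if (abs(angle - 72) < 1e-4 || abs(angle - 144) < 1e-4) 5L
    else stop("operator with unexpected rotation angle ", angle)
    if (abs(angle - 180) < 1e-4) {
      ## axis = eigenvector for eigenvalue +1
      ev <- eigen(O)
      idx <- which.min(abs(ev$values - 1))
      u <- Re(ev$vectors[, idx])
    } else {
      u <- c(O[3, 2] - O[2, 3], O[1, 3] - O[3, 1], O[2, 1] - O[1, 2])
    }
    u <- u / sqrt(sum(u^2))
    ## canonical sign: first coordinate larger than tol in order z, y, x positive
    key <- c(u[3], u[2], u[1])
    nz <- which(abs(key) > tol)[1]
    if (key[nz] < 0) u <- -u
    axes[[length(axes) + 1]] <- c(u, fold)
  }
  ax <- do.call(rbind, axes)
  keep <- !duplicated(round(ax[, 1:3], 6))
  ax <- ax[keep, , drop = FALSE]
  out <- data.frame(x = ax[, 1], y = ax[, 2], z = ax[, 3], fold = as.integer(ax[, 4]))
  out[order(out$fold, -out$z, -out$y, -out$x), , drop = FALSE]
}

#' Orbit of a point under the icosahedral group
#'
#' Applies all 60 operators to a unit vector and deduplicates coincident
#' images, yielding the orbit and the stabilizer order via the
#' orbit-stabilizer relation. Generic points give orbits of 60; points on
#' three-fold axes 20; on five-fold axes 12; on two-fold axes 30.
#'
#' @param point Numeric length-3 vector (normalised internally; zero is an
#'   error).
#' @param group An `icosa_group`.
#' @param tol Relative distance tolerance for deduplication.
#' @return A list of class `icosa_orbit` with `representative`, `members`
#'   (n x 3 matrix), `stabilizer_order`, and `op_index` (indices into the
#'   group of one operator per distinct member).
#' @export
orbit_of <- function(point, group, tol = 1e-6) {
  n <- sqrt(sum(point^2))
  if (n < 1e-12) stop("cannot take the orbit of the zero vector")
  u <- point / n
  G <- group_array(group)
  imgs <- t(apply(G, 3, function(O) O %*% u))
  ## greedy clustering within tol (robust against rounding-boundary effects)
  sel <- integer(0)
  for (i in seq_len(nrow(imgs))) {
    if (length(sel) == 0 ||
        min(sqrt(rowSums((imgs[sel, , drop = FALSE] -
                          matrix(imgs[i, ], length(sel), 3, byrow = TRUE))^2))) > tol) {
      sel <- c(sel, i)
    }
  }
  members <- imgs[sel, , drop = FALSE]
  m <- nrow(members)
  if (60 %% m != 0) stop("orbit size ", m, " does not divide the group order")
  structure(list(representative = u, members = members,
                 stabilizer_order = 60L %/% m, op_index = sel),
            class = "icosa_orbit")
}

#' Export group operators as a plain-text matrix file
#'
#' Writes the 60 operators as a whitespace-delimited 60x9 table (row-major
#' per operator) for interoperability with other tools.
#'
#' @param group An `icosa_group`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_group_matrix <- function(group, path) {
  flat <- t(vapply(group$operators, function(O) as.vector(t(O)), numeric(9)))
  utils::write.table(format(flat, digits = 15), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
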