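## Localized-reconstruction sub-particle geometry: defining capsid-frame
## sub-particle vectors, symmetry expansion with special-position
## deduplication, local-axis alignment, defocus adjustment, Cn symmetry
## relaxation and composite stitching.
##
## Frame conventions (documented once, used everywhere):
##  * A particle's Euler angles (rot, tilt, psi; ZYZ intrinsic) give
##    A = Rz(psi) Ry(tilt) Rz(rot), mapping capsid/map-frame coordinates to
##    the microscope frame; the image is the projection along the microscope
##    z axis.
##  * A sub-particle at capsid-frame site S v (S a symmetry operator, v the
##    unit site direction, r the radius in Angstrom) projects at in-plane
##    offset (x, y) of A S (r v) (converted to pixels) relative to the
##    particle centre, with z component recorded as `z_shift` (Angstrom).
##  * The sub-particle's own reconstruction frame places the local site
##    axis on z via Q = align_z_to(v) (minimal rotation, no in-plane
##    twist); its orientation matrix is A S Q.

#' Define a sub-particle vector
#'
#' A capsid-frame unit direction (a capsomer centre or symmetry axis) plus
#' an extraction radius in Angstrom.
#'
#' @param site Numeric length-3 direction, a row of a `ck_lattice` sites
#'   data frame, or a row of a [symmetry_axes()] data frame.
#' @param radius Radius in Angstrom (> 0).
#' @return Object of class `subparticle_vector`: list with unit `direction`
#'   and `radius`.
#' @export
define_subparticle_vector <- function(site, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a positive scalar (Angstrom)")
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- c(site$x, site$y, site$z)
  }
  site <- as.numeric(site)
  n <- sqrt(sum(site^2))
  if (n < 1e-12) stop("site direction must be non-zero")
  structure(list(direction = site / n, radius = radius),
            class = "subparticle_vector")
}

#' Symmetry-expand particles into sub-particle records
#'
#' For every particle, creates one sub-particle record per distinct image of
#' the sub-particle vector under the icosahedral group, deduplicating
#' coincident images within tolerance: 60 for a general-position site, 20 on
#' a three-fold axis, 12 on a five-fold axis (and 30 on a two-fold axis).
#' Orientations compose local-axis alignment, the symmetry operator and the
#' particle orientation; offsets are the in-plane projection of the rotated
#' 3D site plus the parent origin; the out-of-plane component is recorded as
#' `z_shift` for defocus adjustment.
#'
#' @param particles Data frame of particle records with columns `id`,
#'   `euler_rot`, `euler_tilt`, `euler_psi` (degrees), `origin_x`,
#'   `origin_y` (pixels), `defocus_u`, `defocus_v` (Angstrom),
#'   `pixel_size` (Angstrom/pixel), or a `synthetic_particles` object.
#' @param vector A `subparticle_vector`.
#' @param group An `icosa_group` (built on demand if `NULL`).
#' @param align_local_axis Place the local site axis on z in the
#'   sub-particle frame (default `TRUE`).
#' @param tol Relative position tolerance for special-position
#'   deduplication (scaled by the radius).
#' @return Data frame of sub-particle records: `parent_id`, `sym_index`
#'   (0-based index of the representative symmetry operator), `euler_rot`,
#'   `euler_tilt`, `euler_psi`, `offset_x`, `offset_y` (pixels),
#'   `defocus_u`, `defocus_v` (unadjusted), `z_shift` (Angstrom),
#'   `pixel_size`.
#' @export
expand_subparticles <- function(particles, vector, group = NULL,
                                align_local_axis = TRUE, tol = 1e-6) {
  if (inherits(particles, "synthetic_particles")) particles <- particles$particles
  if (nrow(particles) == 0) stop("particle table is empty")
  if (!inherits(vector, "subparticle_vector"))
    stop("vector must be a subparticle_vector")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  req <- c("id", "euler_rot", "euler_tilt", "euler_psi", "origin_x",
           "origin_y", "defocus_u", "defocus_v", "pixel_size")
  miss <- setdiff(req, names(particles))
  if (length(miss) > 0)
    stop("particle table lacks required column(s): ", paste(miss, collapse = ", "))
  if (is.null(group)) group <- build_icosahedral_group()

  v <- vector$direction
  r <- vector$radius
  ob <- orbit_of(v, group, tol)
  ops <- ob$op_index  # one representative operator per distinct image
  G <- group_array(group)

  A <- euler_to_matrix(particles$euler_rot, particles$euler_tilt,
                       particles$euler_psi)
  if (length(dim(A)) == 2) A <- array(A, c(3, 3, 1))
  n <- nrow(particles)
  Q <- if (align_local_axis) align_z_to(v) else diag(3)

  out <- vector("list", length(ops))
  for (s in seq_along(ops)) {
    S <- G[, , ops[s]]
    x <- as.vector(S %*% (r * v))
    SQ <- S %*% Q
    ## rotated site in the microscope frame, vectorised over particles
    px <- A[1, 1, ] * x[1] + A[1, 2, ] * x[2] + A[1, 3, ] * x[3]
    py <- A[2, 1, ] * x[1] + A[2, 2, ] * x[2] + A[2, 3, ] * x[3]
    pz <- A[3, 1, ] * x[1] + A[3, 2, ] * x[2] + A[3, 3, ] * x[3]
    ## orientation A %*% SQ per particle
    R <- array(0, c(3, 3, n))
    for (i in 1:3) for (j in 1:3) {
      R[i, j, ] <- A[i, 1, ] * SQ[1, j] + A[i, 2, ] * SQ[2, j] + A[i, 3, ] * SQ[3, j]
    }
    eul <- matrix_to_euler(R)
    out[[s]] <- data.frame(
      parent_id = particles$id,
      sym_index = ops[s] - 1L,
      euler_rot = eul$rot, euler_tilt = eul$tilt, euler_psi = eul$psi,
      offset_x = particles$origin_x + px / particles$pixel_size,
      offset_y = particles$origin_y + py / particles$pixel_size,
      defocus_u = particles$defocus_u,
      defocus_v = particles$defocus_v,
      z_shift = pz,
      pixel_size = particles$pixel_size,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$parent_id, particles$id), res$sym_index), ]
  rownames(res) <- NULL
  attr(res, "radius") <- r
  attr(res, "direction") <- v
  class(res) <- c("subparticle_records", "data.frame")
  res
}

#' Adjust defocus by the sub-particle depth
#'
#' Adds the sub-particle's `z_shift` to both defocus values. Sign
#' convention: positive `z_shift` means the sub-particle lies further from
#' the electron source than the particle centre, hence more underfocus and
#' a larger defocus; set `sign = "subtract"` for packages with the opposite
#' convention. Over a complete orbit the adjustments sum to zero because
#' the orbit centroid is the capsid centre.
#'
#' @param subparticles Data frame from [expand_subparticles()].
#' @param sign `"add"` (default) or `"subtract"`.
#' @return The data frame with `defocus_u`, `defocus_v` adjusted.
#' @export
adjust_defocus <- function(subparticles, sign = c("add", "subtract")) {
  sign <- match.arg(sign)
  if (!"z_shift" %in% names(subparticles)) stop("z_shift column missing")
  s <- if (sign == "add") 1 else -1
  subparticles$defocus_u <- subparticles$defocus_u + s * subparticles$z_shift
  subparticles$defocus_v <- subparticles$defocus_v + s * subparticles$z_shift
  subparticles
}

#' Cn symmetry-relaxation candidate orientations
#'
#' The n orientations of a sub-particle that are indistinguishable under a
#' local Cn symmetry axis (placed on z in the sub-particle frame): the
#' input orientation composed with map-side in-plane rotations of 360 k / n
#' degrees, k = 0 ... n-1. Classification over these candidates resolves
#' which symmetry copy an asymmetric feature (such as a tilted spike)
#' occupies.
#'
#' @param orientation Numeric `c(rot, tilt, psi)` in degrees.
#' @param n Symmetry order (>= 2).
#' @return Object of class `relaxation_set`: list with `candidates` (n x 3
#'   matrix of Euler angles) and `n`.
#' @export
relax_candidates <- function(orientation, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("n must be an integer symmetry order >= 2")
  stopifnot(length(orientation) == 3)
  rot <- (orientation[1] + 360 * (0:(n - 1)) / n) %% 360
  cand <- cbind(rot = rot,
                tilt = rep(orientation[2], n),
                psi = rep(orientation[3], n))
  structure(list(candidates = cand, n = as.integer(n)),
            class = "relaxation_set")
}

#' Stitch component models into a composite capsid
#'
#' Places each component's point model (given in its sub-particle frame,
#' local axis on z, origin at the site centre) back into the capsid frame
#' by the inverse of its sub-particle transform, replicates it over the
#' site's orbit, and resolves overlaps by mask precedence: a point of
#' component i is dropped wherever it falls inside the mask sphere of any
#' later component j > i (emulating subtracting the spike mask from the
#' penton mask before combination).
#'
#' @param components List of lists with elements `model` (data frame with
#'   `x`, `y`, `z` in Angstrom, optional `label`), `site` (length-3 capsid
#'   frame direction or `subparticle_vector`), `radius` (Angstrom; ignored
#'   if `site` is a `subparticle_vector`), `mask_diameter` (pixels).
#' @param pixel_size Angstrom per pixel; all components share it.
#' @param group An `icosa_group` (built on demand).
#' @param tol Deduplication tolerance passed to [orbit_of()].
#' @return A `capsid_point_model` whose points carry a `component` column.
#' @export
stitch_composite <- function(components, pixel_size, group = NULL, tol = 1e-6) {
  if (length(components) == 0) stop("no components to stitch")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar; components must share it")
  if (is.null(group)) group <- build_icosahedral_group()
  G <- group_array(group)

  placed <- vector("list", length(components))
  centres <- vector("list", length(components))
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    vec <- if (inherits(comp$site, "subparticle_vector")) comp$site
           else define_subparticle_vector(comp$site, comp$radius)
    v <- vec$direction; r <- vec$radius
    Q <- align_z_to(v)
    ob <- orbit_of(v, group, tol)
    M <- as.matrix(comp$model[, c("x", "y", "z")])
    lab <- if ("label" %in% names(comp$model)) comp$model$label else "point"
    pts <- vector("list", length(ob$op_index))
    ctr <- matrix(0, length(ob$op_index), 3)
    for (s in seq_along(ob$op_index)) {
      S <- G[, , ob$op_index[s]]
      X <- t(S %*% (Q %*% t(M) + r * v))
      pts[[s]] <- data.frame(x = X[, 1], y = X[, 2], z = X[, 3],
                             label = lab, component = ci,
                             copy = s, stringsAsFactors = FALSE)
      ctr[s, ] <- as.vector(S %*% (r * v))
    }
    placed[[ci]] <- do.call(rbind, pts)
    centres[[ci]] <- ctr
  }
  ## mask precedence: later components carve out earlier ones
  for (ci in seq_along(components)) {
    if (ci == length(components)) break
    pts <- placed[[ci]]
    keep <- rep(TRUE, nrow(pts))
    for (cj in (ci + 1):length(components)) {
      mask_r <- components[[cj]]$mask_diameter / 2 * pixel_size
      for (s in seq_len(nrow(centres[[cj]]))) {
        ctr <- centres[[cj]][s, ]
        dd <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2 + (pts$z - ctr[3])^2)
        keep <- keep & dd > mask_r
      }
    }
    placed[[ci]] <- pts[keep, , drop = FALSE]
  }
  allpts <- do.call(rbind, placed)
  rownames(allpts) <- NULL
  radius <- max(sqrt(allpts$x^2 + allpts$y^2 + allpts$z^2))
  structure(list(points = allpts, capsid_radius = radius,
                 membrane_radius = NA_real_, membrane_thickness = NA_real_),
            class = "capsid_point_model")
}

#' Extract a component from a capsid-frame model
#'
#' Inverse of one placement step of [stitch_composite()]: points of a
#' capsid-frame model within `mask_radius` of the site centre are moved
#' into the sub-particle frame (site centre at the origin, local axis on
#' z). Useful for round-trip tests of the transform conventions.
#'
#' @param model Data frame with `x`, `y`, `z` (Angstrom).
#' @param vector A `subparticle_vector`.
#' @param mask_radius Inclusion radius in Angstrom.
#' @return Data frame of sub-particle frame coordinates.
#' @export
extract_component <- function(model, vector, mask_radius) {
  v <- vector$direction; r <- vector$radius
  ctr <- r * v
  dd <- sqrt((model$x - ctr[1])^2 + (model$y - ctr[2])^2 + (model$z - ctr[3])^2)
  sel <- model[dd <= mask_radius, , drop = FALSE]
  Q <- align_z_to(v)
  Y <- t(t(Q) %*% (t(as.matrix(sel[, c("x", "y", "z")])) - ctr))
  out <- sel
  out$x <- Y[, 1]; out$y <- Y[, 2]; out$z <- Y[, 3]
  out
}
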