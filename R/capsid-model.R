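## Quasi-equivalence bookkeeping for the pseudo-T = 21 capsid and synthetic
## 3D point models of capsids (protein shell plus optional lipid bilayer).

#' Assign trimer types to the (4,1) lattice
#'
#' Types the 200 hexamer (trimer) positions of the pseudo-T = 21 capsid by
#' their relation to the icosahedral symmetry axes, following the structural
#' nomenclature for PM2/FLiP-like capsids: type 1 trimers are peripentonal
#' (the orbit nearest a five-fold axis), type 2 trimers flank the two-fold
#' axes (nearest-to-two-fold among the rest), type 3 trimers sit exactly on
#' the three-fold axes, and type 4 trimers are farthest from any axis.
#' Per capsid the counts are 60, 60, 20 and 60.
#'
#' @param lattice A `ck_lattice` for (h,k) = (4,1); anything else is an
#'   error, the typing scheme is specific to pseudo-T = 21.
#' @param group Optional prebuilt `icosa_group` (used for the axis list).
#' @param tol Angular tolerance (radians) used in nearest-axis ties.
#' @return The lattice's hexamer sites data frame with `trimer_type` and
#'   `copies_per_capsid` columns added.
#' @export
assign_trimer_types <- function(lattice, group = NULL, tol = 1e-9) {
  if (!inherits(lattice, "ck_lattice")) stop("lattice must be a ck_lattice")
  if (!(lattice$h == 4 && lattice$k == 1))
    stop("trimer typing is specific to the (4,1) pseudo-T = 21 lattice")
  if (is.null(group)) group <- build_icosahedral_group()
  ax <- symmetry_axes(group)
  hx <- lattice$sites[lattice$sites$kind == "hexamer", , drop = FALSE]
  P <- as.matrix(hx[, c("x", "y", "z")])
  angdist <- function(fold) {
    A <- as.matrix(ax[ax$fold == fold, c("x", "y", "z")])
    d <- abs(P %*% t(A))
    acos(pmin(1, apply(d, 1, max)))
  }
  d5 <- angdist(5); d2 <- angdist(2)
  type <- rep(NA_integer_, nrow(hx))
  type[hx$on_threefold] <- 3L
  ## orbit-level assignment: each type is one orbit
  orbits <- unique(hx$orbit_id[is.na(type)])
  orbit_d5 <- vapply(orbits, function(o) min(d5[hx$orbit_id == o]), numeric(1))
  o1 <- orbits[order(orbit_d5, orbits)][1]
  type[hx$orbit_id == o1] <- 1L
  orbits <- setdiff(orbits, o1)
  orbit_d2 <- vapply(orbits, function(o) min(d2[hx$orbit_id == o]), numeric(1))
  o2 <- orbits[order(orbit_d2, orbits)][1]
  type[hx$orbit_id == o2] <- 2L
  type[is.na(type)] <- 4L
  hx$trimer_type <- type
  hx$copies_per_capsid <- as.integer(table(type)[as.character(type)])
  hx
}

#' Asymmetric-unit composition of a trimer-built capsid
#'
#' For a lattice with odd T the asymmetric unit (1/60 of the capsid)
#' contains `(T - 1) / 2` MCP monomers, i.e. `T - 1` jelly-roll
#' beta-sandwiches (each double jelly-roll monomer carries two, V1 and V2),
#' plus one penton domain, for `T` quasi-equivalent building blocks in
#' total. Even T would imply a fractional monomer count -- the arithmetic
#' face of the rule that trimers cannot straddle a two-fold axis -- and is
#' an error.
#'
#' @param h,k Lattice indices.
#' @return List with `mcp_monomers`, `beta_sandwiches`, `penton_domains`,
#'   `building_blocks`.
#' @export
asymmetric_unit_composition <- function(h, k) {
  Tn <- t_number(h, k)
  if (Tn %% 2 == 0)
    stop("T = ", Tn, " is even: the asymmetric unit would contain a ",
         "fractional number of trimeric MCP monomers")
  monomers <- (Tn - 1L) %/% 2L
  list(mcp_monomers = monomers,
       beta_sandwiches = 2L * monomers,
       penton_domains = 1L,
       building_blocks = 2L * monomers + 1L)
}

#' Synthetic capsid point model
#'
#' Places pseudo-atoms at the capsomer positions of a lattice scaled to a
#' physical radius, optionally adding a lipid-bilayer shell sampled between
#' `membrane radius - thickness/2` and `+ thickness/2`. Deterministic given
#' its inputs (membrane points use a Fibonacci sphere, no RNG).
#'
#' @param lattice A `ck_lattice`.
#' @param capsid_radius Capsid radius in Angstrom.
#' @param membrane Optional `c(radius, thickness)` in Angstrom; the membrane
#'   radius must be smaller than the capsid radius.
#' @param points_per_capsomer Pseudo-atoms per capsomer: 1 places the
#'   centre; larger values add a small tangent-plane ring around it.
#' @param membrane_points Number of points per membrane leaflet.
#' @return Object of class `capsid_point_model`: list with `points`
#'   (data frame `x`, `y`, `z`, `label`, `trimer_type`), `capsid_radius`,
#'   `membrane_radius`, `membrane_thickness`.
#' @export
build_point_model <- function(lattice, capsid_radius,
                              membrane = NULL, points_per_capsomer = 1,
                              membrane_points = 500) {
  stopifnot(capsid_radius > 0, points_per_capsomer >= 1)
  if (!inherits(lattice, "ck_lattice")) stop("lattice must be a ck_lattice")
  sites <- lattice$sites
  trimer_type <- rep(NA_integer_, nrow(sites))
  if (lattice$h == 4 && lattice$k == 1) {
    hx <- assign_trimer_types(lattice)
    trimer_type[sites$kind == "hexamer"] <- hx$trimer_type
  }
  base <- data.frame(x = sites$x, y = sites$y, z = sites$z,
                     label = sites$kind, trimer_type = trimer_type,
                     stringsAsFactors = FALSE)
  pts <- base
  if (points_per_capsomer > 1) {
    extra <- list()
    ring_r <- 0.02  # ring radius as a fraction of the capsid radius
    for (i in seq_len(nrow(base))) {
      u <- c(base$x[i], base$y[i], base$z[i])
      e1 <- .cross3(u, c(0, 0, 1))
      if (sqrt(sum(e1^2)) < 1e-6) e1 <- .cross3(u, c(1, 0, 0))
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- .cross3(u, e1)
      for (j in seq_len(points_per_capsomer - 1)) {
        th <- 2 * pi * (j - 1) / (points_per_capsomer - 1)
        v <- u + ring_r * (cos(th) * e1 + sin(th) * e2)
        v <- v / sqrt(sum(v^2))
        extra[[length(extra) + 1]] <-
          data.frame(x = v[1], y = v[2], z = v[3],
                     label = base$label[i], trimer_type = base$trimer_type[i],
                     stringsAsFactors = FALSE)
      }
    }
    pts <- rbind(base, do.call(rbind, extra))
  }
  pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] * capsid_radius

  membrane_radius <- NA_real_
  membrane_thickness <- NA_real_
  if (!is.null(membrane)) {
    membrane_radius <- membrane[1]
    membrane_thickness <- membrane[2]
    if (membrane_thickness <= 0) stop("membrane thickness must be positive")
    if (membrane_radius >= capsid_radius)
      stop("membrane radius must be smaller than the capsid radius")
    ## two leaflets at the inner and outer faces of the bilayer
    for (r in membrane_radius + c(-0.5, 0.5) * membrane_thickness) {
      fib <- .fibonacci_sphere(membrane_points)
      pts <- rbind(pts, data.frame(x = fib[, 1] * r, y = fib[, 2] * r,
                                   z = fib[, 3] * r, label = "membrane",
                                   trimer_type = NA_integer_,
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(points = pts, capsid_radius = capsid_radius,
                 membrane_radius = membrane_radius,
                 membrane_thickness = membrane_thickness,
                 h = lattice$h, k = lattice$k, T = lattice$T),
            class = "capsid_point_model")
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.capsid_point_model <- function(x, ...) {
  cat(sprintf("Capsid point model: T = %s, radius %.1f A, %d points\n",
              ifelse(is.null(x$T), "?", x$T), x$capsid_radius, nrow(x$points)))
  if (!is.na(x$membrane_radius))
    cat(sprintf("  membrane: radius %.1f A, thickness %.1f A\n",
                x$membrane_radius, x$membrane_thickness))
  invisible(x)
}
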