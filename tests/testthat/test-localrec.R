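# Sub-particle geometry: expansion, deduplication, defocus, relaxation,
# stitching.

test_that("expansion count law: particles x orbit size", {
  ps <- gen_particle_table(37, seed = 2)
  v_gen <- define_subparticle_vector(generic_site_41(), 260)
  expect_identical(nrow(expand_subparticles(ps, v_gen, icosa)), 37L * 60L)
  v3 <- define_subparticle_vector(axis_of_fold(3), 270)
  expect_identical(nrow(expand_subparticles(ps, v3, icosa)), 37L * 20L)
  v5 <- define_subparticle_vector(axis_of_fold(5), 315)
  expect_identical(nrow(expand_subparticles(ps, v5, icosa)), 37L * 12L)
  expect_error(expand_subparticles(ps, v5, icosa, tol = -1), "tol")
  expect_error(define_subparticle_vector(c(0, 0, 0), 300), "non-zero")
  expect_error(define_subparticle_vector(axis_of_fold(5), -3), "positive")
})

test_that("identity-orientation particle reproduces the site orbit exactly", {
  p0 <- data.frame(id = "p1", euler_rot = 0, euler_tilt = 0, euler_psi = 0,
                   origin_x = 0, origin_y = 0, defocus_u = 15000,
                   defocus_v = 15000, pixel_size = 1)
  v <- define_subparticle_vector(generic_site_41(), 260)
  sp <- expand_subparticles(p0, v, icosa)
  expect_identical(nrow(sp), 60L)
  ob <- orbit_of(v$direction, icosa)
  pos <- cbind(sp$offset_x, sp$offset_y, sp$z_shift)  # pixel size 1
  for (i in seq_len(nrow(ob$members))) {
    tgt <- 260 * ob$members[i, ]
    d <- sqrt(rowSums((pos - matrix(tgt, 60, 3, byrow = TRUE))^2))
    expect_lt(min(d), 1e-6)
  }
})

test_that("recorded transform reproduces offsets and z-shift (round trip)", {
  ps <- gen_particle_table(10, seed = 9)
  v <- define_subparticle_vector(axis_of_fold(3), 270)
  sp <- expand_subparticles(ps, v, icosa)
  G <- sapply(icosa$operators, identity, simplify = "array")
  for (r in sample(nrow(sp), 30)) {
    row <- sp[r, ]
    par <- ps$particles[ps$particles$id == row$parent_id, ]
    A <- euler_to_matrix(par$euler_rot, par$euler_tilt, par$euler_psi)
    x <- A %*% (G[, , row$sym_index + 1] %*% (270 * v$direction))
    expect_equal(row$offset_x, par$origin_x + x[1] / par$pixel_size,
                 tolerance = 1e-9)
    expect_equal(row$offset_y, par$origin_y + x[2] / par$pixel_size,
                 tolerance = 1e-9)
    expect_equal(row$z_shift, x[3], tolerance = 1e-9)
    # orientation = A S Q: sub-particle matrix maps local +z to the site ray
    R <- euler_to_matrix(row$euler_rot, row$euler_tilt, row$euler_psi)
    expect_lt(max(abs(R %*% c(0, 0, 1) - x / sqrt(sum(x^2)))), 1e-9)
  }
})

test_that("expansion commutes with a global rotation of the data set", {
  ps <- gen_particle_table(8, seed = 31)
  v <- define_subparticle_vector(generic_site_41(), 300)
  sp1 <- expand_subparticles(ps, v, icosa)
  ## rotate all particle orientations by a fixed group element (map side)
  S <- icosa$operators[[17]]
  part2 <- ps$particles
  for (i in seq_len(nrow(part2))) {
    A <- euler_to_matrix(part2$euler_rot[i], part2$euler_tilt[i],
                         part2$euler_psi[i]) %*% S
    e <- matrix_to_euler(A)
    part2$euler_rot[i] <- e$rot; part2$euler_tilt[i] <- e$tilt
    part2$euler_psi[i] <- e$psi
  }
  sp2 <- expand_subparticles(part2, v, icosa)
  ## the multiset of 3D positions per particle is unchanged
  for (id in ps$particles$id[c(1, 5)]) {
    a <- sp1[sp1$parent_id == id, c("offset_x", "offset_y", "z_shift")]
    b <- sp2[sp2$parent_id == id, c("offset_x", "offset_y", "z_shift")]
    a <- a[do.call(order, a), ]; b <- b[do.call(order, b), ]
    expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-6)
  }
})

test_that("defocus adjustment: zero shift, antipodes, orbit sum", {
  ps <- gen_particle_table(5, seed = 12)
  v <- define_subparticle_vector(generic_site_41(), 260)
  sp <- expand_subparticles(ps, v, icosa)
  sp0 <- sp; sp0$z_shift <- 0
  adj0 <- adjust_defocus(sp0)
  expect_identical(adj0$defocus_u, sp0$defocus_u)
  adj <- adjust_defocus(sp)
  # per particle, adjustments over the full orbit sum to zero
  for (id in unique(sp$parent_id)) {
    d <- adj$defocus_u[adj$parent_id == id] - sp$defocus_u[sp$parent_id == id]
    expect_lt(abs(sum(d)), 1e-6)
  }
  # subtract flag inverts the sign
  adj2 <- adjust_defocus(sp, sign = "subtract")
  expect_equal(adj2$defocus_u - sp$defocus_u,
               -(adj$defocus_u - sp$defocus_u), tolerance = 1e-12)
})

test_that("relaxation candidates form the local Cn coset", {
  rs <- relax_candidates(c(0, 0, 0), 5)
  expect_identical(rs$n, 5L)
  expect_equal(sort(rs$candidates[, "rot"]), c(0, 72, 144, 216, 288))
  expect_true(all(rs$candidates[, "tilt"] == 0))
  # closure: composing any candidate with the C5 step lands on a candidate
  rs2 <- relax_candidates(c(33, 70, -12), 5)
  rots <- sort(rs2$candidates[, "rot"])
  shifted <- sort((rots + 72) %% 360)
  expect_equal(rots, shifted, tolerance = 1e-9)
  # coset property: two orientations differing by a C5 step share the set
  rs3 <- relax_candidates(c(33 + 72, 70, -12), 5)
  expect_equal(sort(rs2$candidates[, "rot"]), sort(rs3$candidates[, "rot"]),
               tolerance = 1e-9)
  rs4 <- relax_candidates(c(10, 20, 30), 2)
  expect_equal(diff(sort(rs4$candidates[, "rot"])), 180)
  expect_error(relax_candidates(c(0, 0, 0), 1), ">= 2")
})

test_that("stitching replicates components over their orbits with masks", {
  tri_model <- data.frame(x = c(0, 10, -10), y = c(0, 5, 5), z = c(0, 0, 0),
                          label = "trimer")
  comp <- list(model = tri_model, site = axis_of_fold(3), radius = 270,
               mask_diameter = 60)
  cm <- stitch_composite(list(comp), pixel_size = 1, group = icosa)
  expect_identical(nrow(cm$points), 20L * 3L)
  # mask precedence: a later component carves out an earlier one
  pent_model <- data.frame(x = 0, y = 0, z = 0, label = "penton")
  spike_model <- data.frame(x = 0, y = 0, z = 15, label = "spike")
  both <- stitch_composite(list(
    list(model = pent_model, site = axis_of_fold(5), radius = 300,
         mask_diameter = 80),
    list(model = spike_model, site = axis_of_fold(5), radius = 315,
         mask_diameter = 100)),
    pixel_size = 1, group = icosa)
  # penton centres sit 15 A from the spike centres, inside the 50 A spike
  # mask radius, so every penton point is excluded; spikes survive
  expect_identical(sum(both$points$label == "penton"), 0L)
  expect_identical(sum(both$points$label == "spike"), 12L)
  expect_error(stitch_composite(list(), 1), "no components")
})

test_that("extract-then-stitch round trip recovers positions to 1e-6 A", {
  model <- build_point_model(lat41, capsid_radius = 300)
  v <- define_subparticle_vector(axis_of_fold(3), 300)
  local <- extract_component(model$points, v, mask_radius = 60)
  expect_gt(nrow(local), 0)
  back <- stitch_composite(list(list(model = local, site = v,
                                     mask_diameter = 0)),
                           pixel_size = 1, group = icosa)
  # every original point near any three-fold site is recovered exactly
  ob <- orbit_of(v$direction, icosa)
  orig <- as.matrix(model$points[, c("x", "y", "z")])
  rec <- as.matrix(back$points[, c("x", "y", "z")])
  for (i in seq_len(nrow(local))) {
    # the local points placed at the representative site
    p <- rec[i, ]
    d <- sqrt(rowSums((orig - matrix(p, nrow(orig), 3, byrow = TRUE))^2))
    expect_lt(min(d), 1e-6)
  }
  expect_identical(nrow(back$points), nrow(local) * 20L)
})
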