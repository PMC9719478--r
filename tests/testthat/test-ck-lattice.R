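# Caspar-Klug lattice arithmetic, construction and classification.

test_that("triangulation numbers and hexagon counts", {
  expect_identical(t_number(4, 1), 21L)
  expect_identical(t_number(1, 0), 1L)
  expect_identical(t_number(3, 3), 27L)
  # (3,3) is the only canonical index with T = 27 (brute-force enumeration)
  idx <- ck_indices(27)
  sol27 <- idx[idx$T == 27, ]
  expect_identical(nrow(sol27), 1L)
  expect_identical(c(sol27$h, sol27$k), c(3L, 3L))
  expect_error(t_number(0, 0), "0,0")
  expect_error(t_number(-1, 2), "non-negative")
  expect_identical(hexagon_count(21), 200L)
  expect_identical(hexagon_count(1), 0L)
  expect_identical(hexagon_count(25), 240L)
  expect_error(hexagon_count(2), "not a triangulation number")
  expect_error(hexagon_count(23), "not a triangulation number")
})

test_that("lattice classification and handedness", {
  expect_identical(classify_lattice(4, 1),
                   list(capsid_class = 2L, handedness = "dextro"))
  expect_identical(classify_lattice(5, 0),
                   list(capsid_class = 1L, handedness = "achiral"))
  expect_identical(classify_lattice(0, 5)$capsid_class, 1L)
  expect_identical(classify_lattice(1, 4),
                   list(capsid_class = 2L, handedness = "laevo"))
  expect_identical(classify_lattice(3, 3),
                   list(capsid_class = 3L, handedness = "achiral"))
  # mirror property: swapping h and k flips handedness only
  for (hk in list(c(2, 1), c(3, 1), c(4, 1), c(3, 2))) {
    a <- classify_lattice(hk[1], hk[2])
    b <- classify_lattice(hk[2], hk[1])
    expect_identical(a$capsid_class, b$capsid_class)
    expect_identical(sort(c(a$handedness, b$handedness)), c("dextro", "laevo"))
  }
})

test_that("constructed lattices have the full capsomer census", {
  expect_identical(sum(lat41$sites$kind == "pentamer"), 12L)
  expect_identical(sum(lat41$sites$kind == "hexamer"), 200L)
  lat10 <- build_capsid_lattice(1, 0, group = icosa)
  expect_identical(sum(lat10$sites$kind == "pentamer"), 12L)
  expect_identical(sum(lat10$sites$kind == "hexamer"), 0L)
  lat21 <- build_capsid_lattice(2, 1, group = icosa)
  hx <- lat21$sites[lat21$sites$kind == "hexamer", ]
  expect_identical(nrow(hx), 60L)
  # T = 7: all hexamers in a single free orbit of 60
  expect_identical(unique(hx$orbit_size), 60L)
  expect_identical(length(unique(hx$orbit_id)), 1L)
  # census 12 + 10 (T - 1) for a spread of lattices
  for (hk in list(c(3, 0), c(2, 2), c(3, 2), c(5, 1))) {
    lat <- build_capsid_lattice(hk[1], hk[2], group = icosa)
    expect_identical(nrow(lat$sites), 12L + 10L * (lat$T - 1L))
  }
})

test_that("(4,1) hexamer orbits are {60, 60, 60, 20}", {
  hx <- lat41$sites[lat41$sites$kind == "hexamer", ]
  sizes <- sort(as.integer(table(hx$orbit_id)))
  expect_identical(sizes, c(20L, 60L, 60L, 60L))
})

test_that("pentamers sit on five-fold axes; axis flags are geometric", {
  pent <- lat41$sites[lat41$sites$kind == "pentamer", ]
  A5 <- as.matrix(icosa_ax[icosa_ax$fold == 5, c("x", "y", "z")])
  for (i in seq_len(nrow(pent))) {
    v <- as.numeric(pent[i, c("x", "y", "z")])
    expect_gt(max(abs(A5 %*% v)), 1 - 1e-9)
  }
  expect_true(hexagon_on_axis(4, 1, 3, lattice = lat41))
  expect_false(hexagon_on_axis(4, 1, 2, lattice = lat41))
  expect_true(hexagon_on_axis(2, 0, 2))
  expect_false(hexagon_on_axis(2, 1, 2))
})

test_that("geometric axis tests equal parity and divisibility rules to T = 75", {
  idx <- ck_indices(75)
  for (i in seq_len(nrow(idx))) {
    lat <- build_capsid_lattice(idx$h[i], idx$k[i], group = icosa)
    expect_identical(hexagon_on_axis(fold = 2, lattice = lat),
                     idx$T[i] %% 2 == 0,
                     info = sprintf("(%d,%d) fold 2", idx$h[i], idx$k[i]))
    expect_identical(hexagon_on_axis(fold = 3, lattice = lat),
                     idx$T[i] %% 3 == 0,
                     info = sprintf("(%d,%d) fold 3", idx$h[i], idx$k[i]))
  }
})

test_that("mirror lattices are congruent up to reflection", {
  latd <- build_capsid_lattice(3, 1, group = icosa)
  latl <- build_capsid_lattice(1, 3, group = icosa)
  expect_identical(latd$T, latl$T)
  hxd <- latd$sites[latd$sites$kind == "hexamer", ]
  hxl <- latl$sites[latl$sites$kind == "hexamer", ]
  expect_identical(sort(as.integer(table(hxd$orbit_id))),
                   sort(as.integer(table(hxl$orbit_id))))
  expect_identical(hexagon_on_axis(fold = 2, lattice = latd),
                   hexagon_on_axis(fold = 2, lattice = latl))
  expect_identical(hexagon_on_axis(fold = 3, lattice = latd),
                   hexagon_on_axis(fold = 3, lattice = latl))
  expect_identical(hexamer_complexity(3, 1), hexamer_complexity(1, 3))
  expect_identical(hexamer_complexity(4, 1), hexamer_complexity(1, 4))
})
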