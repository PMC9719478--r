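# Synthetic-data generators: determinism, declared distributions, truth
# bookkeeping.

test_that("particle tables are deterministic with in-range defoci", {
  a <- gen_particle_table(500, seed = 1)
  b <- gen_particle_table(500, seed = 1)
  expect_identical(a$particles, b$particles)
  c2 <- gen_particle_table(500, seed = 2)
  expect_false(identical(a$particles, c2$particles))
  expect_identical(nrow(a$particles), 500L)
  expect_true(all(a$particles$defocus_u >= 1000 & a$particles$defocus_u <= 22000))
  expect_true(all(a$particles$defocus_v >= 1000 & a$particles$defocus_v <= 22000))
  expect_true(all(a$particles$euler_tilt >= 0 & a$particles$euler_tilt <= 180))
  expect_true(all(a$particles$pixel_size == 1.24))
  expect_error(gen_particle_table(10, 1, defocus_range = c(2, 1)), "increasing")
  # generator does not disturb the caller's RNG stream
  set.seed(123); x1 <- stats::runif(1)
  set.seed(123); invisible(gen_particle_table(10, seed = 99)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("orientations are uniform over rotations", {
  ps <- gen_particle_table(4000, seed = 3)
  A <- euler_to_matrix(ps$particles$euler_rot, ps$particles$euler_tilt,
                       ps$particles$euler_psi)
  # Haar uniformity: mean matrix ~ 0 and cos(tilt) uniform on [-1, 1]
  expect_lt(max(abs(apply(A, c(1, 2), mean))), 0.05)
  ct <- cos(ps$particles$euler_tilt * pi / 180)
  expect_gt(stats::ks.test(ct, "punif", -1, 1)$p.value, 0.001)
})

test_that("genomes hit the requested GC within one point", {
  g <- gen_genome(100000, gc = 0.305, seed = 4)
  counts <- table(strsplit(g$sequence, "")[[1]])
  gc <- sum(counts[c("G", "C")]) / sum(counts)
  expect_lt(abs(gc - 0.305), 0.01)
  g2 <- gen_genome(100000, gc = 0.5, seed = 5)
  counts2 <- table(strsplit(g2$sequence, "")[[1]])
  at <- sum(counts2[c("A", "T")]) / sum(counts2)
  expect_lt(abs(at - 0.5), 0.01)
  expect_identical(gen_genome(10000, seed = 6)$sequence,
                   gen_genome(10000, seed = 6)$sequence)
})

test_that("implanting writes a complete, consistent truth record", {
  gen <- implant_prophage(gen_genome(30000, seed = 7), seed = 8)
  truth <- gen$truth
  pro <- truth[truth$feature == "prophage", ]
  expect_identical(pro$end - pro$start + 1L, 7642L)
  # dif copies sit immediately outside the prophage and match dif_seq
  up <- truth[truth$feature == "dif_upstream", ]
  dn <- truth[truth$feature == "dif_downstream", ]
  expect_identical(up$end + 1L, pro$start)
  expect_identical(dn$start - 1L, pro$end)
  expect_identical(substr(gen$sequence, up$start, up$end), default_dif_seq())
  expect_identical(substr(gen$sequence, dn$start, dn$end), default_dif_seq())
  # rep precedes mcp precedes spike inside the cassette
  feats <- truth[truth$feature %in% c("rep_initiator", "mcp", "spike"), ]
  expect_true(all(diff(feats$start) > 0))
  expect_true(all(feats$start >= pro$start & feats$end <= pro$end))
  # host length grew by cassette + two dif copies
  expect_identical(nchar(gen$sequence), 30000L + 7642L + 56L)
  expect_error(implant_prophage(gen_genome(30000, seed = 1),
                                dif_seq = "ACGT"), "28")
  expect_error(implant_prophage(gen_genome(5000, seed = 1)), "fit")
  # truth hit table recovers the locus through the caller
  loci <- call_prophage_loci(gen$hits)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$rep_start,
                   truth$start[truth$feature == "rep_initiator"])
  expect_identical(loci$mcp_end, truth$end[truth$feature == "mcp"])
})

test_that("family mutation: identity at rate zero, closed form otherwise", {
  cassette <- substr(gen_genome(2000, seed = 9)$sequence, 1, 800)
  fam0 <- mutate_family(cassette, n = 5, sub_rate = 0, indel_rate = 0, seed = 10)
  expect_true(all(fam0$sequences == cassette))
  # expected pairwise identity under independent per-site substitution:
  # agree = (1-p_i)^2 + p_i^2 / 3, averaged over sites
  fam <- mutate_family(cassette, n = 20, sub_rate = 0.05, indel_rate = 0,
                       seed = 11)
  p <- fam$sub_prob
  expected <- mean((1 - p)^2 + p^2 / 3)
  aln <- fam$alignment[-1, , drop = FALSE]
  pairs <- utils::combn(nrow(aln), 2)
  ids <- apply(pairs, 2, function(pr) mean(aln[pr[1], ] == aln[pr[2], ]))
  se <- sqrt(expected * (1 - expected) / ncol(aln))  # per-pair binomial scale
  expect_lt(abs(mean(ids) - expected), 4 * se)
  # indels only add columns; degapped rows equal the emitted sequences
  fam2 <- mutate_family(cassette, n = 6, sub_rate = 0.02, indel_rate = 0.01,
                        seed = 12)
  expect_gte(ncol(fam2$alignment), nchar(cassette))
  for (i in seq_along(fam2$sequences)) {
    row <- fam2$alignment[i + 1, ]
    expect_identical(paste(row[row != "-"], collapse = ""), fam2$sequences[[i]])
  }
  # reference row degapped equals the cassette
  refrow <- fam2$alignment["reference", ]
  expect_identical(paste(refrow[refrow != "-"], collapse = ""), cassette)
})
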