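# Prophage locus calling and dif-site detection.

test_that("palindrome score: perfect, impossible, spacer handling", {
  expect_equal(palindrome_score("GAATTC"), 1)
  expect_equal(palindrome_score(strrep("A", 28)), 0)
  expect_equal(palindrome_score(default_dif_seq(), spacer = c(12, 6)), 1)
  # ambiguity codes count as mismatches
  expect_lt(palindrome_score("GAATNC"), 1)
  expect_error(palindrome_score("ACGT", spacer = c(2, 6)), "shorter")
})

test_that("palindrome score is reverse-complement symmetric", {
  set.seed(88)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T"), 28, replace = TRUE), collapse = "")
    expect_equal(palindrome_score(s), palindrome_score(revcomp(s)),
                 tolerance = 1e-12)
    expect_equal(palindrome_score(s, c(12, 6)),
                 palindrome_score(revcomp(s), c(12, 6)), tolerance = 1e-12)
  }
})

test_that("locus calling pairs rep with a following mcp within the gap", {
  hits <- data.frame(
    query_id = c("rep_initiator", "mcp"),
    genome_id = "g1", start = c(1000L, 3200L), end = c(2000L, 3900L),
    strand = "+", score = c(100, 120))
  loci <- call_prophage_loci(hits)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$start, 1000L)
  expect_identical(loci$end, 3900L)
  expect_identical(as.numeric(loci$gap), 1200)
  expect_false(loci$length_in_range)  # 2901 nt, below the 5 kb floor
  # rep with no mcp within max_gap: no locus
  far <- hits; far$start[2] <- 50000L; far$end[2] <- 50700L
  expect_identical(nrow(call_prophage_loci(far)), 0L)
  # minus strand: mcp must precede rep in genome coordinates
  minus <- data.frame(
    query_id = c("rep_initiator", "mcp"),
    genome_id = "g1", start = c(8000L, 4000L), end = c(9000L, 4700L),
    strand = "-", score = c(1, 1))
  lm <- call_prophage_loci(minus)
  expect_identical(nrow(lm), 1L)
  expect_identical(lm$start, 4000L)
  expect_identical(lm$end, 9000L)
  # same hits on the plus strand do not pair (mcp is upstream of rep)
  plus <- minus; plus$strand <- "+"
  expect_identical(nrow(call_prophage_loci(plus)), 0L)
  expect_error(call_prophage_loci(data.frame(query_id = 1)), "lacks column")
})

test_that("overlapping candidates resolve greedily by gap then position", {
  hits <- data.frame(
    query_id = c("rep_initiator", "rep_initiator", "mcp"),
    genome_id = "g1",
    start = c(1000L, 2500L, 4000L), end = c(1900L, 3400L, 4700L),
    strand = "+", score = 1)
  loci <- call_prophage_loci(hits)
  # one mcp, two candidate reps: the smaller gap (rep at 2500) wins
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$rep_start, 2500L)
})

test_that("implanted cassettes are recovered exactly (20 genomes)", {
  n_found <- 0L
  for (s in 1:20) {
    gen <- implant_prophage(gen_genome(40000, gc = 0.305, seed = s),
                            seed = s + 500, genome_id = sprintf("g%02d", s))
    loci <- call_prophage_loci(gen$hits)
    expect_identical(nrow(loci), 1L)  # precision = recall = 1
    truth <- gen$truth
    dif <- find_dif_sites(gen, loci[1, ])
    expect_false(is.null(dif$dif_upstream))
    expect_false(is.null(dif$dif_downstream))
    expect_identical(dif$dif_upstream$position,
                     truth$start[truth$feature == "dif_upstream"])
    expect_identical(dif$dif_downstream$position,
                     truth$start[truth$feature == "dif_downstream"])
    expect_identical(nchar(dif$dif_upstream$sequence), 28L)
    expect_identical(dif$dif_upstream$central_hexamer,
                     substr(default_dif_seq(), 12, 17))
    ref <- refine_locus_with_dif(loci[1, ], dif)
    expect_identical(ref$start, truth$start[truth$feature == "prophage"])
    expect_identical(ref$end, truth$end[truth$feature == "prophage"])
    expect_identical(ref$length, 7642L)
    expect_true(ref$length >= 6021 && ref$length <= 8407)
    n_found <- n_found + 1L
  }
  expect_identical(n_found, 20L)
})

test_that("no dif pair is reported on unmodified random genomes", {
  fp <- 0L
  for (s in 1:25) {
    gen <- gen_genome(15000, gc = 0.4, seed = 7000 + s)
    fake_locus <- list(start = 6000L, end = 9000L)
    dif <- find_dif_sites(gen, fake_locus, min_score = 0.9)
    if (!is.null(dif$dif_upstream) && !is.null(dif$dif_downstream)) fp <- fp + 1L
  }
  expect_identical(fp, 0L)
})
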