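# shared toy fixtures: a two-group map and a small reference annotation
toy_map <- function() {
  data.frame(marker = c("p1", "p2", "p3", "q1", "q2"),
             lg = c(1L, 1L, 1L, 2L, 2L),
             pos_cM = c(0, 10, 20, 0, 15))
}
toy_gm <- function() {
  data.frame(gene_id = sprintf("g%d", 1:6),
             scaffold = c("sc1", "sc1", "sc1", "sc2", "sc2", "sc3"),
             start = c(0, 1000, 2000, 0, 1000, 0),
             end = c(500, 1500, 2500, 500, 1500, 500),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("homolog pairs keep only significant best hits and flag ties", {
  hits <- data.frame(
    marker = c("p1", "p2", "p3", "p3", "q1", "q1"),
    gene_id = c("g1", "g2", "g3", "g6", "g4", "g6"),
    e_value = c(1e-30, 1e-8, 1e-20, 5e-20, 1e-40, 1e-12))
  pairs <- homolog_pairs(toy_map(), hits, toy_gm())
  # p2's best hit misses the e < 1e-10 criterion
  expect_setequal(pairs$marker, c("p1", "p3", "q1"))
  # p3's two hits on different scaffolds are within a factor 10: multi-hit
  expect_true(pairs$multi_hit[pairs$marker == "p3"])
  # q1's secondary hit is 1e28-fold weaker: a clean single-gene homolog
  expect_false(pairs$multi_hit[pairs$marker == "q1"])
  expect_equal(pairs$ref_bp[pairs$marker == "p1"], 250)
  bad <- data.frame(marker = "p1", gene_id = "nope", e_value = 1e-30)
  expect_error(homolog_pairs(toy_map(), bad, toy_gm()), "unknown gene")
})

test_that("Oxford grid counts pairs and totals match", {
  hits <- data.frame(marker = c("p1", "p2", "q1"),
                     gene_id = c("g1", "g2", "g4"),
                     e_value = rep(1e-30, 3L))
  grid <- oxford_grid(homolog_pairs(toy_map(), hits, toy_gm()))
  expect_equal(sum(grid), 3)
  expect_equal(unclass(grid)["1", "sc1"], 2L)
  expect_equal(unclass(grid)["2", "sc2"], 1L)
  expect_equal(sum(attr(grid, "row_totals")), sum(grid))
})

test_that("published Oxford grid reproduces row totals and assignments", {
  grid <- asub_oxford_grid()
  expect_equal(sum(grid), 96)
  expect_equal(unname(attr(grid, "row_totals")[["3"]]), 9L)
  asg <- assign_synteny(grid)
  expect_identical(asg$chromosome[asg$lg == "3"], "III")
  expect_identical(asg$discordant[asg$lg == "3"], 1L)
  main <- asg$chromosome[match(as.character(1:13), asg$lg)]
  expect_length(unique(main), 13L)
})

test_that("modal assignment reports ties as unassigned", {
  m <- matrix(c(2L, 2L, 0L, 5L), 2L, 2L, byrow = TRUE,
              dimnames = list(c("1", "2"), c("A", "B")))
  asg <- assign_synteny(structure(m, class = c("oxford_grid", "matrix")))
  expect_true(is.na(asg$chromosome[[1L]]))
  expect_true(asg$tie[[1L]])
  expect_identical(asg$chromosome[[2L]], "B")
})

test_that("collinearity is orientation-invariant and matches brute force", {
  mk_pairs <- function(bp) {
    data.frame(marker = sprintf("m%d", seq_along(bp)), lg = 1L,
               pos_cM = seq(0, by = 10, length.out = length(bp)),
               ref_gene_id = sprintf("g%d", seq_along(bp)),
               ref_scaffold = "sc", ref_chromosome = "sc",
               ref_bp = bp, e_value = 1e-30, multi_hit = FALSE)
  }
  asg <- data.frame(lg = 1L, chromosome = "sc", support = 5L,
                    discordant = 0L, tie = FALSE)
  perfect <- mk_pairs(c(100, 200, 300, 400, 500))
  expect_equal(collinearity(perfect, asg)$fraction, 1)
  mirrored <- mk_pairs(rev(c(100, 200, 300, 400, 500)))
  expect_equal(collinearity(mirrored, asg)$fraction, 1)
  # independent counter: best orientation of signed interval agreements
  brute_frac <- function(bp) {
    s_bp <- sign(diff(bp))
    best <- max(sum(s_bp == 1), sum(s_bp == -1))
    best / length(s_bp)
  }
  for (perm_bp in list(c(100, 300, 200, 400, 500, 600),
                       c(600, 100, 200, 500, 400, 300),
                       c(100, 200, 500, 400, 300, 600))) {
    expect_equal(collinearity(mk_pairs(perm_bp), asg)$fraction,
                 brute_frac(perm_bp))
  }
  # an internal inversion breaks at most two intervals
  inv <- c(100, 200, 500, 400, 300, 600)
  expect_gte(collinearity(mk_pairs(inv), asg)$fraction, (5 - 2) / 5)
})

test_that("zero-length intervals are skipped, not counted against", {
  pairs <- data.frame(marker = c("a", "b", "c"), lg = 1L,
                      pos_cM = c(0, 0, 10),
                      ref_gene_id = c("g1", "g2", "g3"),
                      ref_scaffold = "sc", ref_chromosome = "sc",
                      ref_bp = c(100, 200, 300), e_value = 1e-30,
                      multi_hit = FALSE)
  asg <- data.frame(lg = 1L, chromosome = "sc", support = 3L,
                    discordant = 0L, tie = FALSE)
  res <- collinearity(pairs, asg)
  expect_equal(res$per_lg$n_intervals, 1L)
  expect_equal(res$fraction, 1)
})

test_that("synteny breaks distinguish terminal from interleaved patterns", {
  mk <- function(lg, bp) {
    data.frame(marker = sprintf("%s_%d", lg, seq_along(bp)), lg = lg,
               pos_cM = seq_along(bp), ref_gene_id = NA, ref_scaffold = "sc",
               ref_chromosome = "chr1", ref_bp = bp, e_value = 1e-30,
               multi_hit = FALSE)
  }
  asg <- data.frame(lg = c("1", "2"), chromosome = "chr1",
                    support = c(3L, 2L), discordant = 0L, tie = FALSE)
  # group 2 confined to the chromosome end, disjoint from group 1
  terminal <- rbind(mk("1", c(100, 400, 700)), mk("2", c(950, 990)))
  br <- detect_breaks(asg, terminal, chrom_lengths = c(chr1 = 1000))
  expect_identical(br$classification, "terminal")
  interleaved <- rbind(mk("1", c(100, 400, 900)), mk("2", c(500, 600)))
  br2 <- detect_breaks(asg, interleaved, chrom_lengths = c(chr1 = 1000))
  expect_identical(br2$classification, "interleaved")
  # no shared chromosome: empty report
  asg2 <- data.frame(lg = c("1", "2"), chromosome = c("chr1", "chr2"),
                     support = 2L, discordant = 0L, tie = FALSE)
  expect_identical(nrow(detect_breaks(asg2, terminal)), 0L)
})

test_that("links files round-trip and keep a header when empty", {
  hits <- data.frame(marker = c("p1", "q1"), gene_id = c("g1", "g4"),
                     e_value = 1e-30)
  pairs <- homolog_pairs(toy_map(), hits, toy_gm())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_links(pairs, path)
  back <- read_links(path)
  expect_equal(nrow(back), 2L)
  expect_setequal(back$marker, pairs$marker)
  expect_equal(back$bp_start, pairs$ref_bp)
  write_links(pairs[0L, ], path)
  expect_equal(nrow(read_links(path)), 0L)
  expect_match(readLines(path)[[1L]], "lg\tcM_start")
})
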