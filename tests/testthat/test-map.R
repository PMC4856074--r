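test_that("fitted map recovers simulated chromosomes", {
  cfg <- sim_config(seed = 91, n_chromosomes = 4,
                    chr_length_cM = c(70, 60, 55, 50), n_markers = 28,
                    n_progeny = 79, missing_rate = 0.05,
                    distortion = data.frame(chrom = 1L, pos_cM = 68, s = 0.4))
  cr <- simulate_cross(cfg)
  m <- linkage_map(cr$genotypes)
  expect_s3_class(m, "linkage_map")
  expect_true(abs(length(m$groups) - 4L) <= 1L)
  # placed + unplaced partition the marker set
  placed <- unlist(lapply(m$groups, `[[`, "markers"))
  expect_setequal(c(placed, m$unplaced$marker), cr$genotypes$markers$id)
  expect_identical(anyDuplicated(c(placed, m$unplaced$marker)), 0L)
  # each recovered group is dominated by one true chromosome
  truth <- cr$truth$markers
  for (g in m$groups) {
    chroms <- table(truth$chrom[match(g$markers, truth$id)])
    expect_gte(max(chroms) / sum(chroms), 0.8)
  }
  # positions nondecreasing from 0; length = last position
  for (g in m$groups) {
    expect_equal(g$pos[[1L]], 0)
    expect_true(all(diff(g$pos) >= 0))
    expect_equal(max(g$pos), sum(kosambi_cM(pmin(g$rfs, 0.499))))
  }
  # numbering strictly by descending map length
  lens <- vapply(m$groups, function(g) max(g$pos), numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("co-segregating markers share a position and add no length", {
  lg <- structure(list(groups = list(list(markers = paste0("m", 1:4),
                                          rfs = c(0.15, 0, 0.15),
                                          framework = rep(TRUE, 4L)))),
                  class = "linkage_map")
  g <- simulate(lg, seed = 8, n_progeny = 120)[[1L]]
  m <- linkage_map(g)
  expect_length(m$groups, 1L)
  grp <- m$groups[[1L]]
  pos <- grp$pos[match(c("m2", "m3"), grp$markers)]
  expect_equal(pos[[1L]], pos[[2L]], tolerance = 1e-6)
  m2 <- linkage_map(genotypes(g$calls[-3L, , drop = FALSE],
                              g$markers[-3L, ], g$individuals))
  expect_equal(max(m2$groups[[1L]]$pos), max(grp$pos), tolerance = 2)
})

test_that("deferred markers below the assignment LOD stay unplaced", {
  # two linked markers plus one unlinked, all codominant; the unlinked one
  # cannot reach LOD 6 to the group
  g <- make_geno(strrep("1", 30),
                 paste0(strrep("1", 28), "22"),
                 paste0(strrep("12", 15)))
  m <- linkage_map(g)
  expect_true("m03" %in% m$unplaced$marker)
  expect_identical(m$unplaced$reason[m$unplaced$marker == "m03"],
                   "unassigned")
})

test_that("crossover counts skip missing calls", {
  g <- make_geno("12", "1N", "12")  # individuals read down the columns
  ord <- c("m01", "m02", "m03")
  xo <- count_crossovers(g, ord)
  # ind 1: 1,1,1 -> 0; ind 2: 2,NA,2 -> 0 changes after dropping NA
  expect_equal(unname(xo$per_individual), c(0L, 0L))
  g2 <- make_geno("1", "N", "2")
  expect_equal(unname(count_crossovers(g2, ord)$per_individual), 1L)
  g3 <- make_geno("12", "21", "12")
  expect_equal(unname(count_crossovers(g3, ord)$per_individual), c(2L, 2L))
  expect_equal(count_crossovers(g3, ord)$mean, 2)
})

test_that("genome-length estimators behave as documented", {
  tab <- asub_lg_table()
  # per-group terminal inflation on the published table
  expect_equal(estimate_genome_length(tab, method = "per_group_inflation"),
               1996.59, tolerance = 1e-2)
  # method-of-moments estimate is bounded below by the observed map length
  cfg <- sim_config(seed = 95, n_chromosomes = 3,
                    chr_length_cM = c(70, 60, 50), n_markers = 24,
                    n_progeny = 79, missing_rate = 0.05)
  cr <- simulate_cross(cfg)
  m <- linkage_map(cr$genotypes)
  le <- estimate_genome_length(m, method = "hulbert_mom")
  expect_gte(le, sum(vapply(m$groups, function(g) max(g$pos), numeric(1))))
  expect_error(estimate_genome_length(m, lod_threshold = 1e6), "threshold")
})

test_that("coverage formula matches its closed form and edge cases", {
  expect_equal(map_coverage(10, 2458, 0), 0)
  expect_equal(map_coverage(100, 200, 1), 1)
  expect_equal(map_coverage(10, 2458, 202), 0.8080146, tolerance = 1e-6)
  expect_error(map_coverage(60, 100, 5), "2c > Le")
  # increasing in m and c, decreasing in Le
  expect_gt(map_coverage(10, 2458, 250), map_coverage(10, 2458, 202))
  expect_gt(map_coverage(15, 2458, 202), map_coverage(10, 2458, 202))
  expect_lt(map_coverage(10, 3000, 202), map_coverage(10, 2458, 202))
})

test_that("summary statistics match hand-computed values on a toy map", {
  lg <- structure(list(
    groups = list(list(markers = c("a1", "a2", "a3"), rfs = c(0.1, 0.2),
                       framework = rep(TRUE, 3L),
                       pos = cumsum(c(0, kosambi_cM(c(0.1, 0.2))))),
                  list(markers = c("b1", "b2"), rfs = 0.15,
                       framework = rep(TRUE, 2L),
                       pos = cumsum(c(0, kosambi_cM(0.15))))),
    unplaced = data.frame(marker = character(0), reason = character(0)),
    qc = data.frame(id = c("a1", "a2", "a3", "b1", "b2"),
                    distorted = c(TRUE, FALSE, FALSE, FALSE, FALSE))),
    class = "linkage_map")
  tab <- lg_summary(lg)
  l1 <- kosambi_cM(0.1) + kosambi_cM(0.2)
  l2 <- kosambi_cM(0.15)
  expect_equal(tab$length_cM, c(l1, l2, l1 + l2, (l1 + l2) / 2))
  expect_equal(tab$n_markers, c(3, 2, 5, 2.5))
  expect_equal(tab$n_distorted, c(1, 0, 1, 0.5))
  expect_equal(tab$avg_spacing_cM[1:2], c(l1 / 3, l2 / 2))
  expect_equal(tab$largest_interval_cM[1:2], c(kosambi_cM(0.2), l2))
  expect_identical(tab$lg, c("1", "2", "Total", "Mean"))
})

test_that("reversing a linkage group leaves its length invariant", {
  cfg <- sim_config(seed = 97, n_chromosomes = 1, chr_length_cM = 60,
                    n_markers = 6, n_progeny = 79, missing_rate = 0)
  cr <- simulate_cross(cfg)
  ord <- cr$truth$markers$id
  f <- estimate_interval_rfs(cr$genotypes, ord)
  r <- estimate_interval_rfs(cr$genotypes, rev(ord))
  expect_equal(sum(kosambi_cM(f$rfs)), sum(kosambi_cM(r$rfs)),
               tolerance = 1e-9)
})
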