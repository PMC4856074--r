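mk_hits <- function(coverage, identity, query = NULL, scaffold = "sc1",
                    start = 0, end = 100) {
  n <- length(coverage)
  data.frame(query = if (is.null(query)) sprintf("e%d", seq_len(n)) else query,
             scaffold = scaffold, start = start, end = end, strand = "+",
             matches = round(identity * 100), query_length = 100,
             identity = identity, coverage = coverage,
             score = identity * coverage, stringsAsFactors = FALSE)
}

test_that("score filter keeps the 60% boundary and is monotone", {
  h <- mk_hits(coverage = c(0.75, 1.00, 0.9), identity = c(0.80, 0.59, 0.9))
  kept <- filter_hits(h)
  expect_setequal(kept$query, c("e1", "e3"))  # 0.60 boundary kept, 0.59 not
  expect_identical(filter_hits(kept), kept)   # idempotent
  n_kept <- vapply(seq(0, 1, 0.1), function(s)
    nrow(filter_hits(h, min_score = s)), integer(1))
  expect_true(all(diff(n_kept) <= 0L))
})

test_that("best hit per query follows the tie-break cascade", {
  h <- mk_hits(coverage = c(0.9, 0.7), identity = c(1, 1),
               query = c("q", "q"))
  expect_equal(best_hits(h)$score, 0.9)
  # equal scores: more matches wins
  h2 <- mk_hits(coverage = c(0.8, 0.8), identity = c(0.9, 0.9),
                query = c("q", "q"))
  h2$matches <- c(50, 80)
  expect_equal(best_hits(h2)$matches, 80)
  # full tie: smallest (scaffold, start)
  h3 <- mk_hits(coverage = c(0.8, 0.8), identity = c(0.9, 0.9),
                query = c("q", "q"), scaffold = c("sc2", "sc1"))
  expect_identical(best_hits(h3)$scaffold, "sc1")
  h4 <- h3
  h4$scaffold <- "sc1"
  h4$start <- c(500, 100)
  h4$end <- c(600, 200)
  expect_identical(best_hits(h4)$start, 100)
})

test_that("gene-model overlap is half-open and tallies are consistent", {
  gm <- data.frame(gene_id = c("gA", "gB"), scaffold = "sc1",
                   start = c(150, 200), end = c(300, 300), strand = "+")
  h <- mk_hits(coverage = c(0.9, 0.9), identity = c(0.9, 0.9),
               query = c("in", "out"), start = c(100, 100),
               end = c(200, 150))
  ov <- overlap_gene_models(h, gm)
  expect_identical(ov$per_query$gene_id, c("gA", NA_character_))
  # hit ending at 200 does not reach gene starting at 200 (half-open)
  h2 <- mk_hits(coverage = 0.9, identity = 0.9, start = 100, end = 200)
  gm2 <- data.frame(gene_id = "g", scaffold = "sc1", start = 200, end = 300,
                    strand = "+")
  expect_true(is.na(overlap_gene_models(h2, gm2)$per_query$gene_id))
  t <- ov$tallies
  expect_true(all(t$n_overlapping <= t$n_mapped))
  expect_true(all(t$n_gm_overlapped <= t$n_gm))
  expect_error(overlap_gene_models(
    mk_hits(0.9, 0.9, scaffold = "unknown"), gm), "absent")
})

test_that("simulated EST placement reproduces simulator truth tallies", {
  cfg <- sim_config(seed = 41, n_chromosomes = 3, genes_per_chromosome = 40,
                    n_est = 400, est_subthreshold_fraction = 0,
                    paralog_fraction = 0)
  pair <- simulate_genome_pair(cfg)
  hits <- simulate_hits(cfg, pair)
  best <- best_hits(filter_hits(hits$est_hits))
  ov <- overlap_gene_models(best, pair$gene_models)
  expect_equal(sum(ov$tallies$n_mapped), 400L)
  # every hit sits on its true gene, so per-query overlap equals truth
  expect_identical(ov$per_query$gene_id, hits$truth$gene_id)
  expect_equal(sum(ov$tallies$n_gm_overlapped),
               length(unique(hits$truth$gene_id)))
})

test_that("window density flags extremes only on nonuniform scaffolds", {
  gm <- data.frame(gene_id = sprintf("g%03d", 1:200), scaffold = "sc1",
                   start = (0:199) * 1000, end = (0:199) * 1000 + 500,
                   strand = "+")
  # proportional occupancy: every 4th gene overlapped -> uniform
  wd <- window_density(gm, gm$gene_id[seq(1, 200, 4)], window_bp = 20000)
  expect_false(wd$scaffolds$nonuniform)
  expect_true(all(wd$windows$flag == "none"))
  expect_gt(wd$scaffolds$p_value, 0.5)
  # expected counts conserve the observed total
  expect_equal(sum(wd$windows$expected), sum(wd$windows$n_overlapped))
  # all overlapped genes forced into one window: hot spot
  wd2 <- window_density(gm, gm$gene_id[1:20], window_bp = 20000)
  expect_true(wd2$scaffolds$nonuniform)
  expect_identical(wd2$windows$flag[[1L]], "hot")
  expect_error(window_density(gm, gm$gene_id, window_bp = 0), "positive")
})

test_that("window flags are invariant to window enumeration order", {
  set.seed(7)
  gm <- data.frame(gene_id = sprintf("g%03d", 1:120), scaffold = "sc1",
                   start = (0:119) * 1000, end = (0:119) * 1000 + 500,
                   strand = "+")
  ovl <- sample(gm$gene_id, 40)
  a <- window_density(gm, ovl, window_bp = 30000)
  b <- window_density(gm[sample(nrow(gm)), ], ovl, window_bp = 30000)
  expect_equal(a$windows$flag, b$windows$flag)
  expect_equal(a$scaffolds$p_value, b$scaffolds$p_value)
})

test_that("density report totals, means and correlation behave", {
  t3 <- asub_est_tallies()
  tal <- data.frame(scaffold = t3$scaffold, n_mapped = t3$n_mapped,
                    n_overlapping = t3$n_overlapping,
                    n_gm_overlapped = t3$n_gm_overlapped,
                    n_gm = round(t3$n_gm_overlapped /
                                   (t3$pct_gm_overlapped / 100)),
                    pct_gm_overlapped = t3$pct_gm_overlapped)
  rep <- density_report(tal)
  tot <- rep$tallies[rep$tallies$scaffold == "Total", ]
  mn <- rep$tallies[rep$tallies$scaffold == "Mean", ]
  expect_equal(tot$n_mapped, 6752)
  expect_equal(tot$n_overlapping, 6570)
  expect_equal(tot$n_gm_overlapped, 3620)
  expect_equal(mn$n_mapped, 337.60)
  expect_equal(rep$correlation, stats::cor(tal$n_gm_overlapped, tal$n_gm))
  # perfectly proportional tallies give r = 1
  prop <- data.frame(scaffold = c("a", "b", "c"), n_mapped = c(10, 20, 30),
                     n_overlapping = c(10, 20, 30),
                     n_gm_overlapped = c(5, 10, 15), n_gm = c(10, 20, 30),
                     pct_gm_overlapped = 50)
  expect_equal(density_report(prop)$correlation, 1)
  # constant overlapped counts: no association, r = 0 by convention
  flat <- prop
  flat$n_gm_overlapped <- 7
  expect_equal(density_report(flat)$correlation, 0)
  expect_true(is.na(density_report(prop[1:2, ])$correlation))
})

test_that("PSL parsing derives identity and coverage from match counts", {
  path <- withr::local_tempfile(fileext = ".psl")
  psl_line <- function(q, matches, mism, qsize, t, tstart, tend)
    paste(matches, mism, 0, 0, 0, 0, 0, 0, "+", q, qsize, 0, qsize,
          t, 5000, tstart, tend, 1, qsize, 0, tstart, sep = "\t")
  writeLines(c(psl_line("estA", 90, 10, 120, "sc1", 100, 200),
               psl_line("estB", 50, 0, 100, "sc2", 0, 50)), path)
  h <- read_psl(path)
  expect_equal(h$identity, c(90 / 100, 1))
  expect_equal(h$coverage, c(100 / 120, 0.5))
  expect_equal(h$score, h$identity * h$coverage)
  expect_identical(h$scaffold, c("sc1", "sc2"))
})
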