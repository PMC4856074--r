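test_that("the simulator is deterministic given a seed", {
  cfg <- sim_config(seed = 33, n_chromosomes = 2, chr_length_cM = c(50, 40),
                    n_markers = 10, n_progeny = 15, n_est = 50,
                    genes_per_chromosome = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("missing-rate zero leaves no missing calls", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chr_length_cM = 50,
                    n_markers = 5, n_progeny = 30, missing_rate = 0)
  expect_identical(n_missing(simulate_cross(cfg)$genotypes), 0L)
})

test_that("adjacent-marker recombinants match the Kosambi-derived rate", {
  # 10 cM interval: rf = 0.0987; check the observed fraction at large n
  cfg <- sim_config(seed = 44, n_chromosomes = 1, chr_length_cM = 10,
                    n_markers = 2, n_progeny = 5000, missing_rate = 0,
                    marker_placement = "even",
                    distortion = data.frame(chrom = integer(0),
                                            pos_cM = numeric(0),
                                            s = numeric(0)))
  cr <- simulate_cross(cfg)
  ci <- ifelse(cr$genotypes$calls == "P1", 1L, 2L)
  obs <- mean(ci[1L, ] != ci[2L, ])
  true_rf <- kosambi_rf(10)
  se <- sqrt(true_rf * (1 - true_rf) / 5000)
  expect_lt(abs(obs - true_rf), 2 * se)
  # an interval implying rf >= 0.5 is rejected
  bad <- sim_config(seed = 1, n_chromosomes = 1, chr_length_cM = 10,
                    n_markers = 2, n_progeny = 5, marker_placement = "even",
                    map_function = "haldane",
                    distortion = data.frame(chrom = 1, pos_cM = 1e6, s = 0))
  expect_error(suppressWarnings(simulate_cross(bad)), "rf >= 0.5")
})

test_that("genome pair honours the rearrangement ledger", {
  cfg0 <- sim_config(seed = 3, n_chromosomes = 3, genes_per_chromosome = 20)
  p0 <- simulate_genome_pair(cfg0)
  # no rearrangement: gene orders identical
  ord_a <- split(p0$genes_a$gene_id, p0$genes_a$chrom_a)
  ord_b <- split(p0$gene_models$gene_id, p0$gene_models$scaffold)
  expect_identical(unname(lengths(ord_b)), unname(lengths(ord_a)))
  expect_identical(unlist(ord_b, use.names = FALSE),
                   unlist(ord_a, use.names = FALSE))
  # fission adds one chromosome
  cfg1 <- sim_config(seed = 3, n_chromosomes = 3, genes_per_chromosome = 20,
                     rearrangements = list(list(type = "fission", chrom = 1L,
                                                at = 10L)))
  p1 <- simulate_genome_pair(cfg1)
  expect_length(unique(p1$gene_models$scaffold), 4L)
  # fusion removes one
  cfg2 <- sim_config(seed = 3, n_chromosomes = 3, genes_per_chromosome = 20,
                     rearrangements = list(list(type = "fusion", chrom_a = 1L,
                                                chrom_b = 2L)))
  expect_length(unique(simulate_genome_pair(cfg2)$gene_models$scaffold), 2L)
  expect_error(simulate_genome_pair(
    sim_config(seed = 3, n_chromosomes = 3, genes_per_chromosome = 20,
               rearrangements = list(list(type = "fission", chrom = 1L,
                                          at = 99L)))), "breakpoint")
})

test_that("k inversions create exactly 2k adjacency breakpoints", {
  n_breakpoints <- function(p) {
    tot <- 0L
    for (sc in unique(p$gene_models$scaffold)) {
      b <- p$gene_models$gene_id[p$gene_models$scaffold == sc]
      ia <- match(b, p$genes_a$gene_id)
      adj_a <- abs(diff(p$genes_a$idx_a[ia]))
      tot <- tot + sum(adj_a != 1L)
    }
    tot
  }
  res <- list(list(type = "inversion", chrom = 1L, from = 3L, to = 8L),
              list(type = "inversion", chrom = 2L, from = 5L, to = 12L),
              list(type = "inversion", chrom = 3L, from = 2L, to = 6L))
  for (k in 1:3) {
    cfg <- sim_config(seed = 9, n_chromosomes = 3,
                      genes_per_chromosome = 20, rearrangements = res[1:k])
    expect_identical(n_breakpoints(simulate_genome_pair(cfg)), 2L * k)
  }
})

test_that("hit simulation respects paralog and threshold fractions", {
  cfg <- sim_config(seed = 12, n_chromosomes = 2, genes_per_chromosome = 25,
                    n_est = 300, paralog_fraction = 0,
                    est_subthreshold_fraction = 0)
  hits <- simulate_hits(cfg, simulate_genome_pair(cfg))
  expect_identical(anyDuplicated(hits$est_hits$query), 0L)
  expect_identical(nrow(filter_hits(hits$est_hits)), 300L)
  cfg2 <- sim_config(seed = 13, n_chromosomes = 2, genes_per_chromosome = 25,
                     n_est = 5000, paralog_fraction = 0,
                     est_subthreshold_fraction = 0.2)
  hits2 <- simulate_hits(cfg2, simulate_genome_pair(cfg2))
  kept <- nrow(filter_hits(hits2$est_hits)) / 5000
  expect_lt(abs(kept - 0.8), 2 * sqrt(0.8 * 0.2 / 5000))
  cfg3 <- sim_config(seed = 14, n_chromosomes = 2, genes_per_chromosome = 25,
                     n_est = 300, paralog_fraction = 0.5)
  hits3 <- simulate_hits(cfg3, simulate_genome_pair(cfg3))
  expect_gt(nrow(hits3$est_hits), 300L)
})

test_that("every emitted artifact is readable by the package readers", {
  cfg <- sim_config(seed = 22, n_chromosomes = 2, chr_length_cM = c(50, 40),
                    n_markers = 8, n_progeny = 12, n_est = 40,
                    genes_per_chromosome = 25)
  dir <- withr::local_tempdir()
  sim <- write_simulation(cfg, dir)
  g <- read_genotype_table(file.path(dir, "genotypes.tsv"))
  expect_identical(g$calls, sim$cross$genotypes$calls)
  profs <- read_ssi_profiles(file.path(dir, "ssi_profiles.tsv"))
  expect_length(profs, cfg$n_ssi)
  gm <- read_gene_models(file.path(dir, "gene_models.gff3"))
  expect_setequal(gm$gene_id, sim$pair$gene_models$gene_id)
  expect_equal(gm$start[order(gm$gene_id)],
               sim$pair$gene_models$start[order(sim$pair$gene_models$gene_id)])
  hits <- read_hits_tsv(file.path(dir, "est_hits.tsv"))
  expect_equal(nrow(hits), nrow(sim$hits$est_hits))
  expect_equal(sort(hits$score), sort(sim$hits$est_hits$score),
               tolerance = 1e-9)
})
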