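#' Simulation configuration
#'
#' Collects every knob of the ground-truth generator. The defaults mirror
#' the mapping-study design this package targets: 79 haploid progeny from a
#' dikaryotic hybrid, about 200 markers (40% dominant AFLPs) on 13
#' chromosomes whose genetic lengths descend from roughly 200 to 65 cM, a
#' 380-isolate spore pool in which 79% of isolates are heterokaryotic, and
#' around 9% missing genotype calls. Segregation distortion is induced by
#' viability selection at distal loci.
#'
#' @param seed integer seed; every simulator call is deterministic given the
#'   config.
#' @param n_chromosomes number of chromosomes (default 13).
#' @param chr_length_cM genetic chromosome lengths (recycled/truncated to
#'   `n_chromosomes`).
#' @param n_markers total marker count (default 202), distributed over
#'   chromosomes proportionally to genetic length.
#' @param n_progeny haploid progeny size (default 79).
#' @param missing_rate fraction of calls masked at random (default 0.09).
#' @param frac_dominant fraction of markers simulated as dominant AFLPs
#'   (default 0.40).
#' @param distortion data.frame with columns `chrom`, `pos_cM`, `s`: at each
#'   locus, a progeny carrying the `P2` allele survives with probability
#'   `1 - s` (viability selection; whole individuals are rejected and
#'   redrawn). Default: two distal loci with `s = 0.5`.
#' @param marker_placement `"uniform"` (random positions) or `"even"`
#'   (equidistant).
#' @param map_function `"kosambi"` (default) or `"haldane"`: converts true
#'   interval distances into transition recombination fractions.
#' @param n_ssi spore-pool size for the ploidy test (default 380).
#' @param heterokaryon_fraction fraction of heterokaryotic isolates in the
#'   pool (default 0.79).
#' @param ssi_panel_size number of polymorphic microsatellite loci in the
#'   ploidy panel (default 21).
#' @param genes_per_chromosome reference-genome gene count per chromosome
#'   (default 150).
#' @param gene_spacing_bp physical spacing between consecutive gene starts
#'   (default 3000; genes span half the spacing).
#' @param rearrangements list of rearrangements applied to derive the
#'   reference genome from the mapped genome's gene order; each element is a
#'   list with `type` in `{"inversion", "translocation", "fission"}` and
#'   coordinates (see [simulate_genome_pair()]).
#' @param n_est number of EST-like query sequences (default 2000).
#' @param est_subthreshold_fraction fraction of EST hits forced below the
#'   0.60 filter score (default 0.2).
#' @param paralog_fraction probability that an EST gains a secondary hit at
#'   another gene (default 0.05).
#' @param marker_no_homolog_fraction fraction of sequence-based markers with
#'   no reference homolog (default 0.23).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 13L,
                       chr_length_cM = c(202, 196, 161, 141, 138, 130, 129,
                                         113, 113, 102, 76, 70, 65),
                       n_markers = 202L, n_progeny = 79L,
                       missing_rate = 0.09, frac_dominant = 0.40,
                       distortion = NULL,
                       marker_placement = c("uniform", "even"),
                       map_function = c("kosambi", "haldane"),
                       n_ssi = 380L, heterokaryon_fraction = 0.79,
                       ssi_panel_size = 21L,
                       genes_per_chromosome = 150L, gene_spacing_bp = 3000L,
                       rearrangements = list(), n_est = 2000L,
                       est_subthreshold_fraction = 0.2,
                       paralog_fraction = 0.05,
                       marker_no_homolog_fraction = 0.23) {
  chr_length_cM <- rep_len(chr_length_cM, n_chromosomes)
  if (is.null(distortion))
    distortion <- data.frame(chrom = c(1L, min(11L, n_chromosomes)),
                             pos_cM = chr_length_cM[c(1L,
                                                      min(11L,
                                                          n_chromosomes))] - 2,
                             s = 0.5)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            frac_dominant >= 0, frac_dominant <= 1,
            heterokaryon_fraction >= 0, heterokaryon_fraction <= 1,
            all(distortion$s >= 0 & distortion$s <= 1))
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chr_length_cM = chr_length_cM, n_markers = n_markers,
                 n_progeny = n_progeny, missing_rate = missing_rate,
                 frac_dominant = frac_dominant, distortion = distortion,
                 marker_placement = match.arg(marker_placement),
                 map_function = match.arg(map_function), n_ssi = n_ssi,
                 heterokaryon_fraction = heterokaryon_fraction,
                 ssi_panel_size = ssi_panel_size,
                 genes_per_chromosome = genes_per_chromosome,
                 gene_spacing_bp = gene_spacing_bp,
                 rearrangements = rearrangements, n_est = n_est,
                 est_subthreshold_fraction = est_subthreshold_fraction,
                 paralog_fraction = paralog_fraction,
                 marker_no_homolog_fraction = marker_no_homolog_fraction),
            class = "sim_config")
}

map_rf <- function(d_cM, fun) {
  if (fun == "kosambi") kosambi_rf(d_cM) else haldane_rf(d_cM)
}

#' Simulate a haploid mapping cross
#'
#' Draws a haploid progeny from a dikaryotic hybrid. Per individual and
#' chromosome, parental origin follows a Markov chain: a fair coin at the
#' first locus, then a switch between adjacent loci with the interval's
#' recombination fraction (derived from the true cM spacing through the
#' configured map function; an interval implying rf >= 0.5 is an error).
#' Viability distortion is applied by rejection sampling of whole
#' individuals on their alleles at the distortion loci. Missing calls are
#' then masked at random, and a spore pool with heterokaryon contamination
#' is generated for the ploidy test.
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (a [genotypes] object), `ssi_profiles`
#'   and `ssi_panel` (inputs for [classify_homokaryons()]), and `truth`
#'   (list: `markers` data.frame with true `chrom`, `pos_cM`, `idx_on_chrom`;
#'   `interval_rfs` per chromosome; `origins` the unmasked call matrix;
#'   `ssi_ploidy` true labels; `distortion` the distortion table).
#' @export
simulate_cross <- function(config) {
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  len <- config$chr_length_cM
  n_by_chr <- pmax(2L, round(config$n_markers * len / sum(len)))
  markers <- do.call(rbind, lapply(seq_len(nchr), function(c) {
    m <- n_by_chr[[c]]
    pos <- if (config$marker_placement == "even")
      seq(0, len[[c]], length.out = m)
    else sort(stats::runif(m, 0, len[[c]]))
    data.frame(chrom = c, idx_on_chrom = seq_len(m), pos_cM = pos)
  }))
  markers$id <- sprintf("C%02dM%02d", markers$chrom, markers$idx_on_chrom)
  n <- config$n_progeny
  dist <- config$distortion
  origins <- matrix(NA_integer_, nrow(markers), 0L)
  interval_rfs <- vector("list", nchr)
  # chromosome-wise chains, sampled for a batch of candidate individuals
  draw_batch <- function(k) {
    per_chr <- lapply(seq_len(nchr), function(c) {
      sel <- markers$chrom == c
      pos <- markers$pos_cM[sel]
      dpos <- dist$pos_cM[dist$chrom == c]
      allpos <- sort(unique(c(pos, dpos)))
      rfs <- map_rf(diff(allpos), config$map_function)
      if (any(rfs >= 0.5))
        stop("interval too long for the map function (rf >= 0.5)")
      st <- matrix(0L, length(allpos), k)
      st[1L, ] <- stats::rbinom(k, 1L, 0.5)
      if (length(allpos) > 1L) for (j in 2L:length(allpos)) {
        st[j, ] <- (st[j - 1L, ] + stats::rbinom(k, 1L, rfs[j - 1L])) %% 2L
      }
      list(states = st, allpos = allpos, marker_rows = match(pos, allpos),
           dist_rows = match(dpos, allpos))
    })
    # viability: P2 carriers (state 1) at a distortion locus die w.p. s
    surv <- rep(1, k)
    for (c in seq_len(nchr)) {
      dr <- per_chr[[c]]$dist_rows
      ss <- dist$s[dist$chrom == c]
      for (i in seq_along(dr))
        surv <- surv * ifelse(per_chr[[c]]$states[dr[[i]], ] == 1L,
                              1 - ss[[i]], 1)
    }
    keep <- stats::runif(k) < surv
    states <- do.call(rbind, lapply(per_chr, function(p)
      p$states[p$marker_rows, , drop = FALSE]))
    list(states = states[, keep, drop = FALSE], per_chr = per_chr)
  }
  got <- NULL
  while (is.null(got) || ncol(got) < n) {
    b <- draw_batch(max(2L * n, 50L))
    got <- if (is.null(got)) b$states else cbind(got, b$states)
    per_chr <- b$per_chr
  }
  st <- got[, seq_len(n), drop = FALSE]
  for (c in seq_len(nchr)) {
    p <- per_chr[[c]]
    rfs_all <- map_rf(diff(p$allpos), config$map_function)
    # marginal rf between adjacent markers = composite over sub-intervals
    mr <- p$marker_rows
    interval_rfs[[c]] <- vapply(seq_len(length(mr) - 1L), function(j) {
      sub <- rfs_all[mr[[j]]:(mr[[j + 1L]] - 1L)]
      Reduce(function(a, b) a * (1 - b) + b * (1 - a), sub, accumulate = FALSE)
    }, numeric(1))
  }
  calls_true <- matrix(ifelse(st == 0L, "P1", "P2"), nrow(markers), n)
  calls <- calls_true
  if (config$missing_rate > 0)
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_character_
  is_dom <- stats::runif(nrow(markers)) < config$frac_dominant
  mclass <- ifelse(is_dom, "dominant_AFLP",
                   sample(c("codominant_SSR", "codominant_CAPS"),
                          nrow(markers), replace = TRUE))
  mat_chrom <- min(6L, nchr)
  mclass[which(markers$chrom == mat_chrom & !is_dom)[1L]] <- "MAT"
  carrier <- stats::runif(nrow(markers)) < 0.5
  mtab <- data.frame(id = markers$id, marker_class = mclass,
                     parent1_allele = ifelse(is_dom,
                                             ifelse(carrier, "+", "0"), "a"),
                     parent2_allele = ifelse(is_dom,
                                             ifelse(carrier, "0", "+"), "b"),
                     stringsAsFactors = FALSE)
  geno <- genotypes(calls, mtab, sprintf("E%03d", seq_len(n)))
  ssi <- simulate_ssi_pool(config)
  list(genotypes = geno, ssi_profiles = ssi$profiles,
       ssi_panel = ssi$panel,
       truth = list(markers = markers, interval_rfs = interval_rfs,
                    origins = calls_true, ssi_ploidy = ssi$ploidy,
                    distortion = dist))
}

# spore pool: homokaryons carry one haploid panel genotype, heterokaryons
# two distinguishable ones (nuclei redrawn until they differ on the panel)
simulate_ssi_pool <- function(config) {
  k <- config$ssi_panel_size
  panel <- sprintf("SubSSR%02d", seq_len(k))
  n <- config$n_ssi
  het <- stats::runif(n) < config$heterokaryon_fraction
  alle <- function(bit, locus) ifelse(bit == 1L, paste0(locus, ".b"),
                                      paste0(locus, ".a"))
  profiles <- lapply(seq_len(n), function(i) {
    g1 <- stats::rbinom(k, 1L, 0.5)
    loci <- stats::setNames(lapply(seq_len(k), function(j)
      alle(g1[[j]], panel[[j]])), panel)
    if (het[[i]]) {
      repeat {
        g2 <- stats::rbinom(k, 1L, 0.5)
        if (any(g2 != g1)) break
      }
      loci <- stats::setNames(lapply(seq_len(k), function(j)
        unique(c(alle(g1[[j]], panel[[j]]), alle(g2[[j]], panel[[j]])))),
        panel)
    }
    list(ssi_id = sprintf("SSI%03d", i), alleles_by_locus = loci)
  })
  list(profiles = profiles, panel = panel,
       ploidy = ifelse(het, "heterokaryon", "homokaryon"))
}

#' Simulate a rearranged genome pair
#'
#' Lays `genes_per_chromosome` genes on each chromosome of the mapped
#' genome (genome A), then derives the reference genome (genome B) by
#' applying the configured rearrangements, in order, to the gene order:
#' an `inversion` (`chrom`, `from`, `to`: gene indices) reverses a gene
#' interval, a `translocation` (`from_chrom`, `to_chrom`, `n_genes`) moves a
#' terminal segment, a `fission` (`chrom`, `at`) splits a chromosome after
#' gene index `at`, and a `fusion` (`chrom_a`, `chrom_b`) concatenates two
#' chromosomes (so that two linkage groups of the mapped genome share one
#' reference chromosome, the karyotype signature left by a fission in the
#' mapped lineage). Physical coordinates are re-laid with fixed gene
#' spacing. Sequence-based markers of the cross are anchored to genes at
#' their genetic position, a configured fraction being left without
#' homolog.
#'
#' @param config a [sim_config()].
#' @param cross output of [simulate_cross()] (for marker anchoring);
#'   optional: when omitted only the genomes are generated.
#' @return A list with `genes_a` (data.frame `gene_id`, `chrom_a`, `idx_a`),
#'   `gene_models` (genome-B models: `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, 0-based half-open), `marker_genes` (data.frame `marker`,
#'   `gene_id`; `NA` gene for markers without homolog), and `ledger` (the
#'   rearrangement list).
#' @export
simulate_genome_pair <- function(config, cross = NULL) {
  set.seed(config$seed + 1L)
  nchr <- config$n_chromosomes
  npg <- config$genes_per_chromosome
  genes_a <- do.call(rbind, lapply(seq_len(nchr), function(c)
    data.frame(gene_id = sprintf("g%02d.%03d", c, seq_len(npg)),
               chrom_a = c, idx_a = seq_len(npg),
               stringsAsFactors = FALSE)))
  # genome B as an ordered list of (gene_id, strand) per chromosome
  B <- lapply(seq_len(nchr), function(c)
    data.frame(gene_id = genes_a$gene_id[genes_a$chrom_a == c],
               strand = "+", stringsAsFactors = FALSE))
  names(B) <- sprintf("chrB%02d", seq_len(nchr))
  for (re in config$rearrangements) B <- apply_rearrangement(B, re)
  sp <- config$gene_spacing_bp
  gene_models <- do.call(rbind, lapply(names(B), function(nm) {
    d <- B[[nm]]
    if (!nrow(d)) return(NULL)
    start <- (seq_len(nrow(d)) - 1L) * sp
    data.frame(gene_id = d$gene_id, scaffold = nm, start = start,
               end = start + sp %/% 2L, strand = d$strand,
               stringsAsFactors = FALSE)
  }))
  marker_genes <- NULL
  if (!is.null(cross)) {
    mk <- cross$truth$markers
    cls <- cross$genotypes$markers$marker_class[match(mk$id,
                                                     cross$genotypes$markers$id)]
    seq_based <- cls != "dominant_AFLP"
    len <- config$chr_length_cM
    gene_idx <- pmin(pmax(round(mk$pos_cM / len[mk$chrom] * (npg - 1L)) + 1L,
                          1L), npg)
    # markers on one chromosome must anchor distinct genes in genetic order
    for (c in seq_len(nchr)) {
      sel <- which(mk$chrom == c)
      gene_idx[sel] <- fix_monotone(gene_idx[sel], npg)
    }
    gid <- genes_a$gene_id[(mk$chrom - 1L) * npg + gene_idx]
    no_hom <- stats::runif(nrow(mk)) < config$marker_no_homolog_fraction
    gid[!seq_based | no_hom] <- NA_character_
    marker_genes <- data.frame(marker = mk$id, gene_id = gid,
                               stringsAsFactors = FALSE)
  }
  list(genes_a = genes_a, gene_models = gene_models,
       marker_genes = marker_genes, ledger = config$rearrangements)
}

# strictly increasing gene indices, preserving order, within 1..npg
fix_monotone <- function(idx, npg) {
  for (i in seq_along(idx)[-1L])
    if (idx[[i]] <= idx[[i - 1L]]) idx[[i]] <- idx[[i - 1L]] + 1L
  if (any(idx > npg)) idx <- idx - (max(idx) - npg)
  idx
}

apply_rearrangement <- function(B, re) {
  type <- re$type
  if (type == "inversion") {
    nm <- names(B)[[re$chrom]]
    d <- B[[nm]]
    if (re$from < 1L || re$to > nrow(d) || re$from >= re$to)
      stop("inversion breakpoints outside chromosome")
    seg <- re$from:re$to
    d[seg, ] <- d[rev(seg), ]
    d$strand[seg] <- ifelse(d$strand[seg] == "+", "-", "+")
    B[[nm]] <- d
  } else if (type == "translocation") {
    from <- names(B)[[re$from_chrom]]; to <- names(B)[[re$to_chrom]]
    d <- B[[from]]
    if (re$n_genes < 1L || re$n_genes >= nrow(d))
      stop("translocation segment outside chromosome")
    seg <- (nrow(d) - re$n_genes + 1L):nrow(d)
    B[[to]] <- rbind(B[[to]], d[seg, ])
    B[[from]] <- d[-seg, ]
  } else if (type == "fusion") {
    a <- names(B)[[re$chrom_a]]; b <- names(B)[[re$chrom_b]]
    B[[a]] <- rbind(B[[a]], B[[b]])
    B[[b]] <- NULL
  } else if (type == "fission") {
    nm <- names(B)[[re$chrom]]
    d <- B[[nm]]
    if (re$at < 1L || re$at >= nrow(d))
      stop("fission breakpoint outside chromosome")
    new_nm <- sprintf("%s.f", nm)
    B[[new_nm]] <- d[(re$at + 1L):nrow(d), , drop = FALSE]
    B[[nm]] <- d[seq_len(re$at), , drop = FALSE]
  } else stop("unknown rearrangement type: ", type)
  B
}

#' Simulate alignment hit tables
#'
#' Generates the two kinds of homology evidence consumed by the synteny and
#' density stages: (1) an EST-to-genome hit table in the simplified dialect
#' of [read_hits_tsv()], with one primary hit per EST at its true gene
#' (coverage and identity drawn high for reliable hits, and a configured
#' fraction forced below the 0.60 composite-score threshold) plus optional
#' paralogous secondary hits; (2) a marker-level blast-like table
#' (`marker`, `gene_id`, `e_value`) for the mapped sequence-based markers.
#'
#' @param config a [sim_config()].
#' @param pair output of [simulate_genome_pair()].
#' @return A list with `est_hits` (hit table), `marker_hits`, and `truth`
#'   (data.frame `query`, `gene_id`, `subthreshold`).
#' @export
simulate_hits <- function(config, pair) {
  set.seed(config$seed + 2L)
  gm <- pair$gene_models
  n <- config$n_est
  gene <- sample(nrow(gm), n, replace = TRUE)
  sub <- stats::runif(n) < config$est_subthreshold_fraction
  identity <- ifelse(sub, stats::runif(n, 0.3, 0.75),
                     stats::runif(n, 0.85, 1))
  coverage <- ifelse(sub, stats::runif(n, 0.3, 0.75),
                     stats::runif(n, 0.8, 1))
  qlen <- 500L
  span <- pmax(1L, round(coverage * qlen))
  start <- gm$start[gene]
  est_hits <- hit_table(query = sprintf("EST%05d", seq_len(n)),
                        scaffold = gm$scaffold[gene], start = start,
                        end = start + span,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        matches = round(identity * span),
                        query_length = qlen, identity = identity,
                        coverage = coverage)
  par <- which(stats::runif(n) < config$paralog_fraction)
  if (length(par)) {
    tgt <- sample(nrow(gm), length(par), replace = TRUE)
    sec <- hit_table(query = sprintf("EST%05d", par),
                     scaffold = gm$scaffold[tgt], start = gm$start[tgt],
                     end = gm$start[tgt] + span[par],
                     strand = "+", matches = round(identity[par] * span[par] *
                                                     0.9),
                     query_length = qlen,
                     identity = pmax(identity[par] - 0.05, 0.01),
                     coverage = coverage[par])
    est_hits <- rbind(est_hits, sec)
  }
  marker_hits <- NULL
  if (!is.null(pair$marker_genes)) {
    mg <- pair$marker_genes[!is.na(pair$marker_genes$gene_id), ]
    marker_hits <- data.frame(marker = mg$marker, gene_id = mg$gene_id,
                              e_value = 10^stats::runif(nrow(mg), -60, -15),
                              stringsAsFactors = FALSE)
  }
  list(est_hits = est_hits, marker_hits = marker_hits,
       truth = data.frame(query = sprintf("EST%05d", seq_len(n)),
                          gene_id = gm$gene_id[gene], subthreshold = sub,
                          stringsAsFactors = FALSE))
}

#' Write a hit table in the simplified TSV dialect
#' @param hits hit table.
#' @param path output file path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits[, c("query", "scaffold", "start", "end", "strand",
                              "matches", "query_length", "identity",
                              "coverage")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full simulator and write every artifact
#'
#' Convenience driver: simulates the cross, the genome pair and the hit
#' tables, and writes the genotype table, SSI profiles, gene models (GFF3),
#' EST and marker hit tables, and truth ledgers into a directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of simulated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cross <- simulate_cross(config)
  pair <- simulate_genome_pair(config, cross)
  hits <- simulate_hits(config, pair)
  write_genotype_table(cross$genotypes, file.path(dir, "genotypes.tsv"))
  write_ssi_profiles(cross$ssi_profiles, file.path(dir, "ssi_profiles.tsv"))
  write_gene_models(pair$gene_models, file.path(dir, "gene_models.gff3"))
  write_hits_tsv(hits$est_hits, file.path(dir, "est_hits.tsv"))
  utils::write.table(hits$marker_hits, file.path(dir, "marker_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cross$truth$markers, file.path(dir, "truth_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(ssi_id = vapply(cross$ssi_profiles, `[[`,
                                                character(1), "ssi_id"),
                                ploidy = cross$truth$ssi_ploidy),
                     file.path(dir, "truth_ssi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cross = cross, pair = pair, hits = hits))
}
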