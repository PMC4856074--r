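#' Read EST-to-genome alignment hits
#'
#' `read_psl()` parses the standard 21-column PSL tab format produced by
#' BLAT (with or without the 5-line header), deriving per-hit identity
#' (`matches / (matches + misMatches)`) and query coverage
#' (`(matches + misMatches) / qSize`). `read_hits_tsv()` reads a simplified
#' dialect with explicit columns `query`, `scaffold`, `start`, `end`,
#' `strand`, `matches`, `query_length`, `identity`, `coverage`.
#' Both return the same hit table shape; the composite `score` column is
#' identity times coverage.
#'
#' @param path input file path.
#' @return data.frame with columns `query`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `matches`, `query_length`, `identity`,
#'   `coverage`, `score`.
#' @export
read_psl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- grep("^[0-9]", lines, value = TRUE)
  if (!length(body)) stop("no alignment records in ", path)
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 17L)) stop("malformed PSL records in ", path)
  g <- function(i, num = TRUE) {
    v <- vapply(f, `[[`, character(1), i)
    if (num) as.numeric(v) else v
  }
  matches <- g(1); mism <- g(2)
  qsize <- g(11)
  hit_table(query = g(10, FALSE), scaffold = g(14, FALSE),
            start = g(16), end = g(17), strand = g(9, FALSE),
            matches = matches, query_length = qsize,
            identity = matches / pmax(matches + mism, 1),
            coverage = (matches + mism) / qsize)
}

#' @rdname read_psl
#' @export
read_hits_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("query", "scaffold", "start", "end", "identity", "coverage")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hit table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  if (!"matches" %in% names(tab)) tab$matches <- NA_real_
  if (!"query_length" %in% names(tab)) tab$query_length <- NA_real_
  hit_table(tab$query, tab$scaffold, tab$start, tab$end, tab$strand,
            tab$matches, tab$query_length, tab$identity, tab$coverage)
}

hit_table <- function(query, scaffold, start, end, strand, matches,
                      query_length, identity, coverage) {
  if (any(start >= end)) stop("hit with start >= end")
  if (any(identity < 0 | identity > 1 | coverage < 0 | coverage > 1,
          na.rm = TRUE))
    stop("identity and coverage must lie in [0, 1]")
  data.frame(query = query, scaffold = scaffold, start = start, end = end,
             strand = strand, matches = matches,
             query_length = query_length, identity = identity,
             coverage = coverage, score = identity * coverage,
             stringsAsFactors = FALSE)
}

#' Filter alignment hits on the composite score
#'
#' Keeps hits whose score (query coverage times identity) is at least
#' `min_score`. The default 0.60 boundary keeps a hit with coverage 0.75 and
#' identity 0.80 exactly at threshold. Idempotent, and the kept set shrinks
#' monotonically as `min_score` grows.
#'
#' @param hits hit table from [read_psl()] / [read_hits_tsv()].
#' @param min_score minimum composite score (default 0.60).
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, min_score = 0.60) {
  hits[hits$score >= min_score, , drop = FALSE]
}

#' Best hit per query
#'
#' Selects one hit per query: maximal score, ties broken by maximal match
#' count, remaining ties by lexicographically smallest (scaffold, start),
#' so the winner is deterministic.
#'
#' @param hits hit table (typically after [filter_hits()]).
#' @return One row per query.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  matches <- ifelse(is.na(hits$matches), 0, hits$matches)
  ord <- order(hits$query, -hits$score, -matches, hits$scaffold, hits$start)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Read gene models from GFF3
#'
#' Imports `gene`-type features (falling back to all features when no `gene`
#' type is present) and converts the 1-based inclusive GFF coordinates to
#' the package's internal 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("gene" %in% unique(gr$type)) gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(seq_along(gr))
  gm <- data.frame(gene_id = ids,
                   scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene id(s) in ", path)
  gm
}

#' Write gene models to GFF3
#' @param gm gene-model data.frame (0-based half-open coordinates).
#' @param path output file path.
#' @export
write_gene_models <- function(gm, path) {
  gr <- GenomicRanges::GRanges(gm$scaffold,
                               IRanges::IRanges(gm$start + 1L, gm$end),
                               strand = ifelse(gm$strand %in% c("+", "-"),
                                               gm$strand, "*"))
  gr$type <- "gene"
  gr$ID <- gm$gene_id
  gr$source <- "haplomap"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Overlap best hits with gene models
#'
#' Associates each best hit with the annotated gene(s) it overlaps (at least
#' one shared base under 0-based half-open coordinates) and tallies, per
#' scaffold: sequences mapped, sequences overlapping a gene model, distinct
#' gene models overlapped, and the percentage of that scaffold's gene models
#' overlapped.
#'
#' @param best best-hit table from [best_hits()].
#' @param gene_models gene-model data.frame.
#' @return A list with `per_query` (data.frame `query`, `gene_id`; `NA`
#'   when no overlap), `tallies` (per-scaffold data.frame `scaffold`,
#'   `n_mapped`, `n_overlapping`, `n_gm_overlapped`, `n_gm`,
#'   `pct_gm_overlapped`), and `overlapped_gene_ids`.
#' @export
overlap_gene_models <- function(best, gene_models) {
  unknown <- setdiff(unique(best$scaffold), unique(gene_models$scaffold))
  if (length(unknown))
    stop("hit scaffold(s) absent from gene models: ",
         paste(unknown, collapse = ", "))
  hg <- GenomicRanges::GRanges(best$scaffold,
                               IRanges::IRanges(best$start + 1L, best$end))
  gg <- GenomicRanges::GRanges(gene_models$scaffold,
                               IRanges::IRanges(gene_models$start + 1L,
                                                gene_models$end))
  ov <- GenomicRanges::findOverlaps(hg, gg)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  first <- !duplicated(qh)
  per_query <- data.frame(query = best$query, gene_id = NA_character_,
                          stringsAsFactors = FALSE)
  per_query$gene_id[qh[first]] <- gene_models$gene_id[sh[first]]
  overlapped <- unique(gene_models$gene_id[sh])
  scafs <- sort(unique(gene_models$scaffold))
  tallies <- do.call(rbind, lapply(scafs, function(s) {
    hit_idx <- which(best$scaffold == s)
    gm_idx <- which(gene_models$scaffold == s)
    n_gm_ov <- length(intersect(gene_models$gene_id[gm_idx], overlapped))
    data.frame(scaffold = s, n_mapped = length(hit_idx),
               n_overlapping = sum(!is.na(per_query$gene_id[hit_idx])),
               n_gm_overlapped = n_gm_ov, n_gm = length(gm_idx),
               pct_gm_overlapped = 100 * n_gm_ov / max(length(gm_idx), 1L),
               stringsAsFactors = FALSE)
  }))
  list(per_query = per_query, tallies = tallies,
       overlapped_gene_ids = overlapped)
}

#' Homolog density per genomic window
#'
#' Examines, scaffold by scaffold, whether homolog-bearing gene models are
#' spread proportionally to all gene models. Genes are binned by midpoint
#' into consecutive windows of `window_bp`; the expected number of
#' overlapped genes in a window is the scaffold total scaled by the window's
#' share of gene models. Windows with expected count below 1 are merged into
#' their nearest neighbour before the chi-square test. A scaffold is flagged
#' nonuniform at `p < alpha`, and only then are its windows flagged `hot`
#' (Pearson residual above `z_cut`) or `cold` (below `-z_cut`).
#'
#' @param gene_models gene-model data.frame.
#' @param overlapped_ids character vector of overlapped gene ids.
#' @param window_bp window size in bases (default 50000).
#' @param alpha scaffold-level significance threshold (default 0.01).
#' @param z_cut residual cutoff for window flags (default 2.576, two-sided
#'   1%).
#' @return A list with `windows` (data.frame: `scaffold`, `window`,
#'   `start`, `end`, `n_gm`, `n_overlapped`, `expected`,
#'   `pearson_residual`, `flag`) and `scaffolds` (data.frame: `scaffold`,
#'   `chi2`, `df`, `p_value`, `nonuniform`).
#' @export
window_density <- function(gene_models, overlapped_ids, window_bp = 50000,
                           alpha = 0.01, z_cut = stats::qnorm(0.995)) {
  if (window_bp <= 0) stop("window_bp must be positive")
  win_list <- list(); scaf_list <- list()
  for (s in sort(unique(gene_models$scaffold))) {
    gm <- gene_models[gene_models$scaffold == s, ]
    if (!nrow(gm)) { warning("scaffold ", s, " has no gene models"); next }
    mid <- (gm$start + gm$end) / 2
    w <- floor(mid / window_bp)
    n_win <- max(w) + 1L
    n_gm <- tabulate(w + 1L, nbins = n_win)
    ov <- gm$gene_id %in% overlapped_ids
    n_ov <- vapply(seq_len(n_win) - 1L,
                   function(k) sum(ov[w == k]), integer(1))
    total_ov <- sum(n_ov)
    expected <- total_ov * n_gm / sum(n_gm)
    # merge sparse windows (expected < 1) into their nearest neighbour
    grp <- merge_sparse(expected)
    obs_m <- tapply(n_ov, grp, sum)
    exp_m <- tapply(expected, grp, sum)
    valid <- exp_m > 0
    chi2 <- sum((obs_m[valid] - exp_m[valid])^2 / exp_m[valid])
    df <- max(sum(valid) - 1L, 1L)
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
    nonuni <- sum(valid) > 1L && p < alpha
    resid_m <- ifelse(exp_m > 0, (obs_m - exp_m) / sqrt(exp_m), 0)
    resid <- as.numeric(resid_m[match(grp, names(resid_m))])
    flag <- rep("none", n_win)
    if (nonuni) {
      flag[resid > z_cut] <- "hot"
      flag[resid < -z_cut] <- "cold"
    }
    win_list[[s]] <- data.frame(scaffold = s, window = seq_len(n_win) - 1L,
                                start = (seq_len(n_win) - 1L) * window_bp,
                                end = seq_len(n_win) * window_bp,
                                n_gm = n_gm, n_overlapped = n_ov,
                                expected = expected,
                                pearson_residual = resid, flag = flag,
                                stringsAsFactors = FALSE)
    scaf_list[[s]] <- data.frame(scaffold = s, chi2 = chi2, df = df,
                                 p_value = p, nonuniform = nonuni,
                                 stringsAsFactors = FALSE)
  }
  list(windows = do.call(rbind, c(win_list, list(make.row.names = FALSE))),
       scaffolds = do.call(rbind, c(scaf_list, list(make.row.names = FALSE))))
}

# assign each window to a merged bin so that every bin's expected count is
# >= 1 (or the whole scaffold collapses to one bin)
merge_sparse <- function(expected) {
  n <- length(expected)
  grp <- seq_len(n)
  e <- expected
  repeat {
    bins <- tapply(e, grp, sum)
    small <- names(bins)[bins < 1]
    if (!length(small) || length(bins) == 1L) break
    b <- small[[1L]]
    ids <- sort(unique(grp))
    i <- match(as.integer(b), ids)
    nb <- if (i == 1L) ids[[2L]] else if (i == length(ids)) ids[[i - 1L]]
          else { # nearest neighbour by expected mass: prefer the smaller
            if (bins[[i - 1L]] <= bins[[i + 1L]]) ids[[i - 1L]]
            else ids[[i + 1L]]
          }
    grp[grp == as.integer(b)] <- nb
  }
  grp
}

#' Homolog-density report
#'
#' Assembles the per-scaffold tally table, the window table, and the
#' correlation between overlapped and total gene-model counts per
#' chromosome (scaffolds aggregated through `chrom_map` when given).
#'
#' @param tallies per-scaffold tallies from [overlap_gene_models()].
#' @param windows window table from [window_density()] (optional).
#' @param chrom_map optional data.frame with `scaffold`, `chromosome`.
#' @return A list with `tallies` (with `Total` and `Mean` rows appended),
#'   `windows`, and `correlation` (Pearson r of overlapped vs total gene
#'   models per chromosome; `NA` when fewer than 3 units).
#' @export
density_report <- function(tallies, windows = NULL, chrom_map = NULL) {
  t2 <- tallies
  unit <- if (is.null(chrom_map)) t2$scaffold else
    chrom_map$chromosome[match(t2$scaffold, chrom_map$scaffold)]
  ov <- tapply(t2$n_gm_overlapped, unit, sum)
  tot <- tapply(t2$n_gm, unit, sum)
  r <- if (length(ov) < 3L) NA_real_
  else if (stats::sd(ov) == 0 || stats::sd(tot) == 0) 0  # no association
  else stats::cor(ov, tot)
  total <- data.frame(scaffold = "Total", n_mapped = sum(t2$n_mapped),
                      n_overlapping = sum(t2$n_overlapping),
                      n_gm_overlapped = sum(t2$n_gm_overlapped),
                      n_gm = sum(t2$n_gm), pct_gm_overlapped = NA_real_)
  mn <- data.frame(scaffold = "Mean", n_mapped = mean(t2$n_mapped),
                   n_overlapping = mean(t2$n_overlapping),
                   n_gm_overlapped = mean(t2$n_gm_overlapped),
                   n_gm = mean(t2$n_gm),
                   pct_gm_overlapped = mean(t2$pct_gm_overlapped))
  list(tallies = rbind(t2, total, mn), windows = windows, correlation = r)
}
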