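#' Build marker-to-reference homolog pairs
#'
#' Joins mapped sequence-based markers to their homologous genes in a
#' reference genome, from a marker-level similarity hit table. Only hits
#' below the e-value threshold qualify; each marker keeps its single
#' best-scoring (smallest e-value) qualifying hit. A marker whose two best
#' qualifying hits on different scaffolds have e-values within a factor of
#' `tie_ratio` is flagged multi-hit (a paralogy signature, e.g. markers
#' derived from multigene families) and is excluded from downstream
#' collinearity scoring.
#'
#' @param map a [linkage_map] or a data.frame with columns `marker`, `lg`,
#'   `pos_cM`.
#' @param hits data.frame with columns `marker`, `gene_id`, `e_value` (other
#'   columns are carried along).
#' @param gene_models data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end` (as from [read_gene_models()]); the gene's physical position is
#'   taken as the midpoint of its span.
#' @param chrom_map optional data.frame mapping `scaffold` to `chromosome`
#'   labels; defaults to chromosome = scaffold.
#' @param e_max e-value threshold for a significant hit (default 1e-10).
#' @param tie_ratio e-value ratio under which two hits count as equally
#'   likely (default 10).
#' @return A data.frame of homolog pairs: `marker`, `lg`, `pos_cM`,
#'   `ref_gene_id`, `ref_scaffold`, `ref_chromosome`, `ref_bp` (gene
#'   midpoint), `e_value`, `multi_hit`.
#' @export
homolog_pairs <- function(map, hits, gene_models, chrom_map = NULL,
                          e_max = 1e-10, tie_ratio = 10) {
  mp <- if (inherits(map, "linkage_map")) as.data.frame(map) else
    as.data.frame(map)
  unknown <- setdiff(hits$gene_id, gene_models$gene_id)
  if (length(unknown))
    stop("hit(s) reference unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  hits <- hits[hits$marker %in% mp$marker & hits$e_value < e_max, ,
               drop = FALSE]
  if (!nrow(hits)) return(empty_pairs())
  gm <- gene_models
  gm$midpoint <- (gm$start + gm$end) / 2
  rows <- lapply(split(hits, hits$marker), function(h) {
    h <- h[order(h$e_value), , drop = FALSE]
    best <- h[1L, ]
    scaf <- gm$scaffold[match(h$gene_id, gm$gene_id)]
    multi <- nrow(h) > 1L &&
      any(h$e_value[-1L] < best$e_value * tie_ratio & scaf[-1L] != scaf[[1L]])
    i <- match(best$gene_id, gm$gene_id)
    j <- match(best$marker, mp$marker)
    data.frame(marker = best$marker, lg = mp$lg[[j]],
               pos_cM = mp$pos_cM[[j]], ref_gene_id = best$gene_id,
               ref_scaffold = gm$scaffold[[i]],
               ref_bp = gm$midpoint[[i]], e_value = best$e_value,
               multi_hit = multi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ref_chromosome <- if (is.null(chrom_map)) out$ref_scaffold else
    chrom_map$chromosome[match(out$ref_scaffold, chrom_map$scaffold)]
  out[order(out$lg, out$pos_cM, out$marker), ]
}

empty_pairs <- function() {
  data.frame(marker = character(0), lg = integer(0), pos_cM = numeric(0),
             ref_gene_id = character(0), ref_scaffold = character(0),
             ref_bp = numeric(0), e_value = numeric(0),
             multi_hit = logical(0), ref_chromosome = character(0),
             stringsAsFactors = FALSE)
}

#' Oxford grid of homolog-pair counts
#'
#' Cross-tabulates homolog pairs by linkage group (rows) and reference
#' chromosome (columns); the classic visual test of macrosynteny. The grand
#' total equals the number of pairs with both coordinates known.
#'
#' @param pairs homolog pairs from [homolog_pairs()].
#' @return An object of class `oxford_grid`: integer matrix with `lg` rows
#'   and chromosome columns; attributes `row_totals`, `col_totals`.
#' @export
oxford_grid <- function(pairs) {
  ok <- !is.na(pairs$lg) & !is.na(pairs$ref_chromosome)
  p <- pairs[ok, ]
  counts <- table(lg = p$lg, chromosome = p$ref_chromosome)
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  structure(m, row_totals = rowSums(m), col_totals = colSums(m),
            class = c("oxford_grid", "matrix"))
}

#' @export
print.oxford_grid <- function(x, ...) {
  m <- unclass(x)
  attr(m, "row_totals") <- attr(m, "col_totals") <- NULL
  out <- rbind(cbind(m, Total = rowSums(m)),
               Total = c(colSums(m), sum(m)))
  cat("Oxford grid (", nrow(m), " LG x ", ncol(m),
      " chromosomes, ", sum(m), " homologous pairs)\n", sep = "")
  print(out)
  invisible(x)
}

#' Syntenic chromosome assignment per linkage group
#'
#' Assigns to each linkage group its modal reference chromosome in the
#' Oxford grid; pairs on any other chromosome are counted discordant. Ties
#' for the mode leave the group unassigned.
#'
#' @param grid an [oxford_grid()].
#' @return data.frame with columns `lg`, `chromosome` (`NA` on tie),
#'   `support` (pairs on the assigned chromosome), `discordant`, `tie`.
#' @export
assign_synteny <- function(grid) {
  m <- unclass(grid)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    mx <- max(v)
    winners <- colnames(m)[v == mx]
    tie <- length(winners) > 1L
    data.frame(lg = rownames(m)[[i]],
               chromosome = if (tie) NA_character_ else winners,
               support = mx, discordant = sum(v) - mx, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collinearity of genetic and physical marker orders
#'
#' For each linkage group, orders its homolog pairs by map position and asks
#' whether each adjacent interval runs the same way on the assigned
#' chromosome. A block orientation (+1/-1) is chosen per linkage group to
#' maximise agreement, so a globally reversed group (or a mirrored
#' chromosome coordinate system) is still fully collinear. An interval is
#' collinear iff `sign(delta bp) * orientation == sign(delta cM)`; intervals
#' with zero change in either coordinate are skipped, as are pairs flagged
#' multi-hit or lying on a non-assigned (discordant) chromosome.
#'
#' @param pairs homolog pairs from [homolog_pairs()].
#' @param assignments output of [assign_synteny()].
#' @return A list with `per_lg` (data.frame: `lg`, `chromosome`,
#'   `orientation`, `n_intervals`, `n_collinear`) and `fraction` (global
#'   collinear fraction over all evaluated intervals).
#' @export
collinearity <- function(pairs, assignments) {
  per <- lapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i, ]
    if (is.na(a$chromosome)) return(NULL)
    p <- pairs[pairs$lg == a$lg & pairs$ref_chromosome == a$chromosome &
                 !pairs$multi_hit, , drop = FALSE]
    if (nrow(p) < 2L) return(NULL)
    p <- p[order(p$pos_cM, p$marker), ]
    s_cM <- sign(diff(p$pos_cM))
    s_bp <- sign(diff(p$ref_bp))
    ok <- s_cM != 0 & s_bp != 0
    if (!any(ok)) return(NULL)
    agree_fwd <- sum(s_bp[ok] == s_cM[ok])
    agree_rev <- sum(-s_bp[ok] == s_cM[ok])
    orientation <- if (agree_fwd >= agree_rev) 1L else -1L
    data.frame(lg = a$lg, chromosome = a$chromosome,
               orientation = orientation, n_intervals = sum(ok),
               n_collinear = max(agree_fwd, agree_rev),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  frac <- if (is.null(per) || !nrow(per)) NA_real_ else
    sum(per$n_collinear) / sum(per$n_intervals)
  list(per_lg = per, fraction = frac)
}

#' Classify synteny breaks on shared chromosomes
#'
#' When two or more linkage groups are assigned to one reference chromosome,
#' the arrangement of their homolog spans distinguishes rearrangement
#' signatures: disjoint spans with one group confined to a chromosome end
#' indicate a chromosome fission or terminal translocation (`"terminal"`);
#' overlapping spans with one group's homologs flanked by the other's
#' indicate an interleaved (e.g. insertional) pattern (`"interleaved"`).
#'
#' @param assignments output of [assign_synteny()].
#' @param pairs homolog pairs from [homolog_pairs()].
#' @param end_tol fraction of the chromosome length counted as an "end"
#'   (default 0.10).
#' @param chrom_lengths optional named vector of chromosome lengths in bp
#'   (defaults to the maximal homolog coordinate per chromosome).
#' @return data.frame with one row per linkage-group pair sharing a
#'   chromosome: `chromosome`, `lg_a`, `lg_b`, spans, and `classification`
#'   in `{"terminal", "interleaved", "disjoint"}`; zero rows when no
#'   chromosome is shared.
#' @export
detect_breaks <- function(assignments, pairs, end_tol = 0.10,
                          chrom_lengths = NULL) {
  asg <- assignments[!is.na(assignments$chromosome), ]
  shared <- names(which(table(asg$chromosome) >= 2L))
  out <- list()
  for (chrom in shared) {
    lgs <- asg$lg[asg$chromosome == chrom]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else
      max(pairs$ref_bp[pairs$ref_chromosome == chrom])
    span <- lapply(lgs, function(l) {
      bp <- pairs$ref_bp[pairs$lg == l & pairs$ref_chromosome == chrom]
      range(bp)
    })
    for (i in seq_along(lgs)[-length(lgs)]) for (j in (i + 1L):length(lgs)) {
      sa <- span[[i]]; sb <- span[[j]]
      overlap <- sa[1L] <= sb[2L] && sb[1L] <= sa[2L]
      cls <- if (overlap) "interleaved" else {
        outer_span <- if (sa[1L] < sb[1L]) sb else sa
        at_end <- outer_span[1L] <= end_tol * len ||
          outer_span[2L] >= (1 - end_tol) * len
        if (at_end) "terminal" else "disjoint"
      }
      out[[length(out) + 1L]] <-
        data.frame(chromosome = chrom, lg_a = lgs[[i]], lg_b = lgs[[j]],
                   span_a_start = sa[1L], span_a_end = sa[2L],
                   span_b_start = sb[1L], span_b_end = sb[2L],
                   classification = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), lg_a = character(0),
                      lg_b = character(0), span_a_start = numeric(0),
                      span_a_end = numeric(0), span_b_start = numeric(0),
                      span_b_end = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write a Circos-style links file
#'
#' One line per homolog pair: linkage group, cM start/end (point interval),
#' chromosome, bp start/end. A tab-separated header line is always written,
#' so an empty pair set yields a header-only file.
#'
#' @param pairs homolog pairs from [homolog_pairs()].
#' @param path output file path.
#' @export
write_links <- function(pairs, path) {
  out <- data.frame(lg = pairs$lg, cM_start = pairs$pos_cM,
                    cM_end = pairs$pos_cM,
                    chromosome = pairs$ref_chromosome,
                    bp_start = pairs$ref_bp, bp_end = pairs$ref_bp,
                    marker = pairs$marker, gene_id = pairs$ref_gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a links file written by [write_links()]
#' @param path path to a links TSV.
#' @return data.frame with the written columns.
#' @export
read_links <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write an Oxford grid as CSV with marginal totals
#' @param grid an [oxford_grid()].
#' @param path output file path.
#' @export
write_oxford_grid <- function(grid, path) {
  m <- unclass(grid)
  attr(m, "row_totals") <- attr(m, "col_totals") <- NULL
  out <- rbind(cbind(m, Total = rowSums(m)), Total = c(colSums(m), sum(m)))
  utils::write.csv(out, path, quote = FALSE)
  invisible(path)
}

#' One-call macrosynteny analysis
#'
#' Convenience wrapper chaining [homolog_pairs()], [oxford_grid()],
#' [assign_synteny()], [collinearity()] and [detect_breaks()].
#'
#' @inheritParams homolog_pairs
#' @inheritParams detect_breaks
#' @return An object of class `synteny_analysis` with elements `pairs`,
#'   `grid`, `assignments`, `collinearity`, `breaks`.
#' @export
synteny_analysis <- function(map, hits, gene_models, chrom_map = NULL,
                             e_max = 1e-10, tie_ratio = 10,
                             end_tol = 0.10) {
  pairs <- homolog_pairs(map, hits, gene_models, chrom_map = chrom_map,
                         e_max = e_max, tie_ratio = tie_ratio)
  grid <- oxford_grid(pairs)
  asg <- assign_synteny(grid)
  structure(list(pairs = pairs, grid = grid, assignments = asg,
                 collinearity = collinearity(pairs, asg),
                 breaks = detect_breaks(asg, pairs, end_tol = end_tol)),
            class = "synteny_analysis")
}

#' @export
print.synteny_analysis <- function(x, ...) {
  cat("Macrosynteny analysis\n")
  cat("  homolog pairs:", nrow(x$pairs),
      "(multi-hit:", sum(x$pairs$multi_hit), ")\n")
  asg <- x$assignments
  cat("  linkage groups assigned:", sum(!is.na(asg$chromosome)), "of",
      nrow(asg), "\n")
  cat("  discordant pairs:", sum(asg$discordant), "\n")
  if (!is.na(x$collinearity$fraction))
    cat(sprintf("  collinear intervals: %d/%d (%.1f%%)\n",
                sum(x$collinearity$per_lg$n_collinear),
                sum(x$collinearity$per_lg$n_intervals),
                100 * x$collinearity$fraction))
  if (nrow(x$breaks))
    cat("  synteny breaks:",
        paste(sprintf("%s/%s-%s (%s)", x$breaks$chromosome, x$breaks$lg_a,
                      x$breaks$lg_b, x$breaks$classification),
              collapse = "; "), "\n")
  invisible(x)
}
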