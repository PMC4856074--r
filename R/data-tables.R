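# Published summary tables for the Agaricus subrufescens linkage map and its
# comparison with the Agaricus bisporus reference genome, shipped as plain
# TSV/CSV under extdata. They serve as worked-example inputs for the
# desk-arithmetic functions (lg_summary, assign_synteny, density_report).

extdata <- function(name) {
  system.file("extdata", name, package = "haplomap", mustWork = TRUE)
}

#' Published A. subrufescens linkage-group characteristics
#'
#' Per linkage group: map length (cM), marker count, distorted-marker count
#' and largest inter-marker interval, for the 16-group, 202-marker,
#' 1701 cM A. subrufescens map. Feed to [lg_summary()] to reproduce the
#' published spacing and totals.
#'
#' @return data.frame with columns `lg`, `length_cM`, `n_markers`,
#'   `n_distorted`, `largest_interval_cM`.
#' @export
asub_lg_table <- function() {
  utils::read.table(extdata("asub_lg_table.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Published Oxford grid: A. subrufescens LGs vs A. bisporus chromosomes
#'
#' Counts of homologous locus pairs per linkage group (rows) and reference
#' chromosome (columns); 96 pairs in total.
#'
#' @return An [oxford_grid()]-classed integer matrix.
#' @export
asub_oxford_grid <- function() {
  tab <- utils::read.csv(extdata("asub_oxford_grid.csv"), check.names = FALSE)
  m <- as.matrix(tab[, -1L])
  rownames(m) <- as.character(tab$lg)
  storage.mode(m) <- "integer"
  structure(m, row_totals = rowSums(m), col_totals = colSums(m),
            class = c("oxford_grid", "matrix"))
}

#' Published EST-vs-gene-model tallies per A. bisporus scaffold
#'
#' Per-scaffold counts of electronically mapped A. subrufescens sequences,
#' sequences overlapping a gene model, gene models overlapped, and the
#' percentage of gene models overlapped (6752 mapped sequences and 3620
#' overlapped gene models over the 20 scaffold rows).
#'
#' @return data.frame with columns `chromosome`, `scaffold`, `n_mapped`,
#'   `n_overlapping`, `n_gm_overlapped`, `pct_gm_overlapped`.
#' @export
asub_est_tallies <- function() {
  utils::read.table(extdata("asub_est_tallies.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}
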