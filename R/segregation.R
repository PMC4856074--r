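#' Chi-square test of the haploid 1:1 segregation ratio
#'
#' A haploid progeny of a dikaryotic hybrid is expected to receive either
#' parental allele with equal probability, so each marker is tested against
#' the Mendelian 1:1 ratio. The statistic is the plain Pearson chi-square
#' with one degree of freedom and no continuity correction:
#' \deqn{\chi^2 = (a - n/2)^2/(n/2) + (b - n/2)^2/(n/2), \quad n = a + b.}
#'
#' @param count_P1,count_P2 nonnegative allele counts (vectorised).
#' @return A data.frame with columns `chi2` and `p_value`.
#' @examples
#' chi_square_1to1(50, 25)  # chi2 = 8.33, p = 0.0039
#' @export
chi_square_1to1 <- function(count_P1, count_P2) {
  n <- count_P1 + count_P2
  if (any(n < 1L)) stop("both counts zero: no scored individuals")
  e <- n / 2
  chi2 <- (count_P1 - e)^2 / e + (count_P2 - e)^2 / e
  data.frame(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1,
                                                  lower.tail = FALSE))
}

#' Per-marker segregation quality control
#'
#' Computes allele counts, missing fraction, and the 1:1 segregation test for
#' every marker of a genotype matrix. A marker is flagged distorted when its
#' raw segregation p-value falls below `alpha`; no multiple-testing
#' correction is applied, matching conventional practice in linkage mapping
#' where the flag feeds a staged filtering rule rather than an inference.
#'
#' @param x a [genotypes] object.
#' @param alpha distortion significance threshold (default 0.05).
#' @return A data.frame of class `marker_qc` with one row per marker:
#'   `id`, `marker_class`, `n_called`, `n_missing`, `count_P1`, `count_P2`,
#'   `chi2`, `p_value`, `distorted`, `missing_frac`. Attributes `n_distorted`
#'   (all markers) and `n_distorted_called` (markers with at least one call)
#'   summarise the flag counts.
#' @export
marker_qc <- function(x, alpha = 0.05) {
  ci <- calls_int(x)
  a <- rowSums(ci == 1L, na.rm = TRUE)
  b <- rowSums(ci == 2L, na.rm = TRUE)
  miss <- rowSums(is.na(ci))
  n <- a + b
  chi2 <- p <- rep(NA_real_, length(n))
  ok <- n >= 1L
  if (any(ok)) {
    cs <- chi_square_1to1(a[ok], b[ok])
    chi2[ok] <- cs$chi2
    p[ok] <- cs$p_value
  }
  out <- data.frame(id = x$markers$id, marker_class = x$markers$marker_class,
                    n_called = n, n_missing = miss, count_P1 = a,
                    count_P2 = b, chi2 = chi2, p_value = p,
                    distorted = !is.na(p) & p < alpha,
                    missing_frac = miss / ncol(ci),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_distorted") <- sum(out$distorted)
  attr(out, "n_distorted_called") <- sum(out$distorted[out$n_called > 0L])
  class(out) <- c("marker_qc", "data.frame")
  out
}

#' Staged marker selection for mapping
#'
#' Partitions markers into the sets entering each mapping round. The first
#' (framework) round admits only the most reliable markers: codominant ones
#' with at most `missing_max` missing data and no significant segregation
#' distortion. Dominant AFLP markers are held out of the framework round;
#' those with balanced segregation are deferred to the sequential placement
#' stage, while distorted AFLPs are removed permanently. Distorted or
#' high-missing codominant markers are deferred (they may still be placed in
#' the second stage).
#'
#' @param qc a [marker_qc] table.
#' @param missing_max maximum tolerated missing fraction for the framework
#'   round (default 0.30; strictly greater excludes).
#' @param alpha segregation distortion threshold (default 0.05).
#' @return A list with character vectors `round1`, `deferred`, `dropped`
#'   forming an exhaustive, disjoint partition of the marker ids.
#' @export
select_round1 <- function(qc, missing_max = 0.30, alpha = 0.05) {
  codom <- qc$marker_class != "dominant_AFLP"
  distorted <- !is.na(qc$p_value) & qc$p_value < alpha
  round1 <- codom & qc$missing_frac <= missing_max & !distorted
  dropped <- !codom & distorted
  deferred <- !round1 & !dropped
  list(round1 = qc$id[round1], deferred = qc$id[deferred],
       dropped = qc$id[dropped])
}

#' @export
print.marker_qc <- function(x, ...) {
  cat("Segregation QC for", nrow(x), "markers (alpha =",
      attr(x, "alpha"), ")\n")
  cat("  distorted:", attr(x, "n_distorted"),
      sprintf("(%.1f%%)", 100 * attr(x, "n_distorted") / nrow(x)), "\n")
  cat("  median missing fraction:",
      sprintf("%.3f", stats::median(x$missing_frac)), "\n")
  NextMethod()
}

#' Write the QC table as TSV
#' @param qc a [marker_qc] table.
#' @param path output file path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(as.data.frame(qc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
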