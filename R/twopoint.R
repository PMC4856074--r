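#' Two-point linkage estimate for a haploid progeny
#'
#' For two markers scored in a haploid progeny, the informative individuals
#' are those with both calls present; `R` of the `N` informative individuals
#' are recombinant (parental origins differ). The maximum-likelihood
#' recombination fraction is `R/N`, and the LOD score is the log10 likelihood
#' ratio of linkage at the estimate against free recombination (rf = 0.5):
#' \deqn{LOD = R \log_{10}\hat r + (N-R)\log_{10}(1-\hat r) + N \log_{10} 2,}
#' with the convention \eqn{0 \cdot \log_{10} 0 = 0}. Estimates at or above
#' 0.5 are reported as rf = 0.5 with LOD 0 (no evidence of linkage).
#'
#' @param x a [genotypes] object.
#' @param a,b marker ids.
#' @return A one-row data.frame with columns `marker_a`, `marker_b`,
#'   `n_informative`, `n_recomb`, `rf`, `lod`, `d_cM` (Kosambi; `Inf` at
#'   rf = 0.5).
#' @examples
#' \dontrun{two_point(geno, "m1", "m2")}
#' @export
two_point <- function(x, a, b) {
  ci <- calls_int(x)
  ia <- ci[match(a, x$markers$id), ]
  ib <- ci[match(b, x$markers$id), ]
  if (anyNA(match(c(a, b), x$markers$id))) stop("unknown marker id")
  inf <- !is.na(ia) & !is.na(ib)
  n <- sum(inf)
  if (n == 0L) stop("no informative individuals for pair ", a, " / ", b)
  r <- sum(ia[inf] != ib[inf])
  tp <- two_point_stats(r, n)
  data.frame(marker_a = a, marker_b = b, n_informative = n, n_recomb = r,
             rf = tp$rf, lod = tp$lod, d_cM = tp$d_cM,
             stringsAsFactors = FALSE)
}

# vectorised core: recombinants R out of N informative
two_point_stats <- function(R, N) {
  rhat <- R / N
  t1 <- ifelse(R == 0, 0, R * log10(rhat))
  t2 <- ifelse(N - R == 0, 0, (N - R) * log10(1 - rhat))
  lod <- t1 + t2 + N * log10(2)
  capped <- rhat >= 0.5
  rf <- ifelse(capped, 0.5, rhat)
  lod <- ifelse(capped, 0, lod)
  d <- rep(Inf, length(rf))
  d[!capped] <- kosambi_cM(rf[!capped])
  list(rf = rf, lod = lod, d_cM = d)
}

#' All pairwise two-point estimates
#'
#' Computes [two_point()] statistics for every marker pair by matrix algebra
#' on the 0/1 parental-origin indicators, which keeps the full 200-marker
#' table fast. Pairs with no informative individuals are returned with `NA`
#' statistics.
#'
#' @param x a [genotypes] object.
#' @return A data.frame with one row per unordered marker pair (columns as in
#'   [two_point()]).
#' @export
pairwise_linkage <- function(x) {
  ci <- calls_int(x)
  A <- t(!is.na(ci) & ci == 1L) * 1   # individuals x markers
  B <- t(!is.na(ci) & ci == 2L) * 1
  obs <- A + B
  N <- crossprod(obs)                 # informative counts
  R <- crossprod(A, B) + crossprod(B, A)
  idx <- which(upper.tri(N), arr.ind = TRUE)
  n <- N[idx]; r <- R[idx]
  out <- data.frame(marker_a = x$markers$id[idx[, 1L]],
                    marker_b = x$markers$id[idx[, 2L]],
                    n_informative = n, n_recomb = r,
                    rf = NA_real_, lod = NA_real_, d_cM = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- n > 0
  if (any(ok)) {
    tp <- two_point_stats(r[ok], n[ok])
    out$rf[ok] <- tp$rf; out$lod[ok] <- tp$lod; out$d_cM[ok] <- tp$d_cM
  }
  out
}

#' Linkage grouping by single-linkage transitive closure
#'
#' Two markers are directly linked when their two-point LOD is at least
#' `lod_min` and their Kosambi distance at most `dmax_cM`; linkage groups are
#' the connected components of this graph (single-linkage closure), so two
#' markers fall in one group whenever a chain of above-threshold links
#' connects them. Markers with no qualifying link are reported as singletons.
#'
#' @param pairs pairwise table from [pairwise_linkage()].
#' @param lod_min minimum LOD for a link (default 4.0).
#' @param dmax_cM maximum Kosambi distance for a link in cM (default 30).
#' @param markers optional character vector of marker ids to group (defaults
#'   to all ids appearing in `pairs`).
#' @return A list with `groups` (list of character vectors, each a candidate
#'   linkage group of size >= 2, ordered by decreasing size) and `singletons`.
#' @export
group_markers <- function(pairs, lod_min = 4.0, dmax_cM = 30,
                          markers = NULL) {
  if (is.null(markers))
    markers <- unique(c(pairs$marker_a, pairs$marker_b))
  keep <- pairs$marker_a %in% markers & pairs$marker_b %in% markers &
    !is.na(pairs$lod) & pairs$lod >= lod_min & pairs$d_cM <= dmax_cM
  g <- igraph::graph_from_data_frame(pairs[keep, c("marker_a", "marker_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  sets <- split(markers, comp$membership)
  sizes <- lengths(sets)
  ord <- order(-sizes, vapply(sets, function(s) sort(s)[[1L]], character(1)))
  sets <- sets[ord]
  list(groups = unname(sets[lengths(sets) >= 2L]),
       singletons = unlist(sets[lengths(sets) == 1L], use.names = FALSE))
}
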