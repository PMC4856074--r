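#' Fit a genetic linkage map to a haploid progeny
#'
#' The full staged mapping pipeline. Round one builds a framework map from
#' the most reliable markers (codominant, low missingness, undistorted;
#' see [select_round1()]): candidate groups are formed by two-point linkage
#' at `lod_group`/`dmax_cM` ([group_markers()]), each group is ordered by
#' multipoint maximum likelihood ([order_group()]) and confirmed by
#' [ripple()]. In the second stage the deferred markers (dominant AFLPs,
#' distorted or gappy markers) are assigned to framework groups at
#' `lod_assign` and placed sequentially at their best-likelihood interval;
#' markers whose best placement is not decisively better than the runner-up
#' are dropped as ambiguous. A deferred marker linking two framework groups
#' at the grouping thresholds triggers their merger. Finally groups are
#' renumbered in descending order of Kosambi map length.
#'
#' @param x a [genotypes] object.
#' @param lod_group minimum two-point LOD for grouping (default 4.0).
#' @param dmax_cM maximum two-point Kosambi distance for grouping, cM
#'   (default 30).
#' @param lod_assign minimum LOD to assign a deferred marker to a group
#'   (default 6.0).
#' @param ripple_window window size for order confirmation (default 5).
#' @param ambiguity_delta minimum log10-likelihood margin between the best
#'   and second-best distinct placement of a deferred marker (default 2.0).
#' @param missing_max maximum missing fraction for round-one markers
#'   (default 0.30).
#' @param alpha segregation-distortion threshold (default 0.05).
#' @param exhaustive_max largest group ordered exhaustively (default 7).
#' @param criterion ordering criterion, see [order_group()].
#' @param min_group_size smallest reported linkage group (default 2; smaller
#'   sets are reported unplaced as `"singleton"`).
#' @return An object of class `linkage_map`: list with `groups` (each with
#'   `markers`, `pos` in cM from 0, `rfs`, `framework` flags), `unplaced`
#'   (data.frame of marker and reason), `qc`, `pairs`, and `params`.
#' @seealso [summary.linkage_map()], [lg_summary()], [plot.linkage_map()],
#'   [simulate.linkage_map()]
#' @export
linkage_map <- function(x, lod_group = 4.0, dmax_cM = 30, lod_assign = 6.0,
                        ripple_window = 5L, ambiguity_delta = 2.0,
                        missing_max = 0.30, alpha = 0.05,
                        exhaustive_max = 7L,
                        criterion = c("loglik", "rf_sum"),
                        min_group_size = 2L) {
  criterion <- match.arg(criterion)
  cl <- match.call()
  qc <- marker_qc(x, alpha = alpha)
  sel <- select_round1(qc, missing_max = missing_max, alpha = alpha)
  pairs <- pairwise_linkage(x)
  unplaced <- data.frame(marker = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(sel$dropped))
    unplaced <- rbind(unplaced,
                      data.frame(marker = sel$dropped,
                                 reason = "distorted dominant marker"))
  grp <- group_markers(pairs, lod_min = lod_group, dmax_cM = dmax_cM,
                       markers = sel$round1)
  groups <- lapply(grp$groups, function(g) {
    og <- order_group(x, g, pairs = pairs, exhaustive_max = exhaustive_max,
                      criterion = criterion, ripple_window = ripple_window)
    rp <- ripple(x, og$order, window = ripple_window, criterion = criterion,
                 pairs = pairs)
    list(markers = rp$order, rfs = rp$rfs,
         framework = rep(TRUE, length(rp$order)))
  })
  deferred <- c(sel$deferred, grp$singletons)
  res <- place_deferred(x, groups, deferred, pairs,
                        lod_assign = lod_assign, lod_group = lod_group,
                        dmax_cM = dmax_cM, ambiguity_delta = ambiguity_delta,
                        criterion = criterion, ripple_window = ripple_window)
  groups <- res$groups
  unplaced <- rbind(unplaced, res$unplaced)
  # second grouping round: markers that could not be assigned to a framework
  # group may still be linked among themselves (e.g. a cluster of distorted
  # markers) and then form a linkage group of their own
  left <- unplaced$marker[unplaced$reason == "unassigned"]
  if (length(left) >= 2L) {
    grp2 <- group_markers(pairs, lod_min = lod_group, dmax_cM = dmax_cM,
                          markers = left)
    for (g in grp2$groups) {
      if (length(g) < min_group_size) next
      og <- order_group(x, g, pairs = pairs,
                        exhaustive_max = exhaustive_max,
                        criterion = criterion,
                        ripple_window = ripple_window)
      groups[[length(groups) + 1L]] <-
        list(markers = og$order, rfs = og$rfs,
             framework = rep(FALSE, length(og$order)))
      unplaced <- unplaced[!(unplaced$marker %in% g), ]
    }
  }
  # orders confirmed once more after sequential placement
  groups <- lapply(groups, function(g) {
    if (length(g$markers) < 3L) return(g)
    rp <- ripple(x, g$markers, window = ripple_window, criterion = criterion,
                 pairs = pairs)
    fw <- stats::setNames(g$framework, g$markers)
    list(markers = rp$order, rfs = rp$rfs, framework = unname(fw[rp$order]))
  })
  small <- vapply(groups, function(g) length(g$markers) < min_group_size,
                  logical(1))
  if (any(small)) {
    for (g in groups[small])
      unplaced <- rbind(unplaced,
                        data.frame(marker = g$markers, reason = "singleton"))
    groups <- groups[!small]
  }
  groups <- lapply(groups, finalize_group)
  groups <- renumber_groups(groups)
  structure(list(groups = groups, unplaced = unplaced, qc = qc,
                 pairs = pairs,
                 params = list(lod_group = lod_group, dmax_cM = dmax_cM,
                               lod_assign = lod_assign,
                               ripple_window = ripple_window,
                               ambiguity_delta = ambiguity_delta,
                               missing_max = missing_max, alpha = alpha,
                               criterion = criterion),
                 call = cl),
            class = "linkage_map")
}

finalize_group <- function(g) {
  ord <- canonical_order(g$markers)
  if (!identical(ord, g$markers)) {
    g$rfs <- rev(g$rfs)
    g$framework <- rev(g$framework)
    g$markers <- ord
  }
  g$pos <- cumsum(c(0, kosambi_cM(pmin(g$rfs, 0.499))))
  g
}

renumber_groups <- function(groups) {
  len <- vapply(groups, function(g) max(g$pos), numeric(1))
  n <- vapply(groups, function(g) length(g$markers), integer(1))
  first <- vapply(groups, function(g) g$markers[[1L]], character(1))
  groups[order(-len, -n, first)]
}

#' Sequential placement of deferred markers onto a framework map
#'
#' Implements the assignment/placement stage of [linkage_map()]; exposed for
#' step-by-step use. Each deferred marker is assigned to the group holding
#' its strongest two-point linkage when that LOD exceeds `lod_assign`, then
#' inserted at the interval maximising the multipoint likelihood. When the
#' best and second-best placements at genuinely different map positions are
#' separated by less than `ambiguity_delta` log10-likelihood units the
#' marker is dropped as ambiguous (placements that tie because they are the
#' same map point, e.g. either side of a co-segregating marker, do not count
#' as ambiguity). A deferred marker linked at grouping thresholds to two
#' framework groups merges them before placement.
#'
#' @param x a [genotypes] object.
#' @param groups list of group structures (`markers`, `rfs`, `framework`).
#' @param deferred character vector of marker ids to place.
#' @param pairs [pairwise_linkage()] table.
#' @inheritParams linkage_map
#' @return list with updated `groups` and an `unplaced` data.frame.
#' @export
place_deferred <- function(x, groups, deferred, pairs, lod_assign = 6.0,
                           lod_group = 4.0, dmax_cM = 30,
                           ambiguity_delta = 2.0, criterion = "loglik",
                           ripple_window = 5L) {
  unplaced <- data.frame(marker = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (!length(deferred) || !length(groups))
    return(list(groups = groups,
                unplaced = rbind(unplaced, if (length(deferred))
                  data.frame(marker = deferred, reason = "unassigned"))))
  lookup <- best_lod_by_group <- function(marker) {
    rows <- pairs[(pairs$marker_a == marker | pairs$marker_b == marker) &
                    !is.na(pairs$lod), ]
    other <- ifelse(rows$marker_a == marker, rows$marker_b, rows$marker_a)
    vapply(groups, function(g) {
      hit <- other %in% g$markers
      if (!any(hit)) -Inf else max(rows$lod[hit])
    }, numeric(1))
  }
  # group mergers driven by deferred markers linking two framework groups
  repeat {
    merged <- FALSE
    for (marker in deferred) {
      links <- linked_groups(marker, groups, pairs, lod_group, dmax_cM)
      if (length(links) >= 2L) {
        gi <- links[[1L]]; gj <- links[[2L]]
        groups[[gi]] <- merge_groups(x, groups[[gi]], groups[[gj]], pairs,
                                     criterion, ripple_window)
        groups[[gj]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # strongest-linked markers placed first
  best <- vapply(deferred, function(m) {
    l <- lookup(m); if (all(!is.finite(l))) -Inf else max(l)
  }, numeric(1))
  for (marker in deferred[order(-best)]) {
    lods <- lookup(marker)
    if (!any(is.finite(lods)) || max(lods) <= lod_assign) {
      unplaced <- rbind(unplaced,
                        data.frame(marker = marker, reason = "unassigned"))
      next
    }
    gi <- which.max(lods)
    ins <- try_placements(x, groups[[gi]], marker)
    if (ins$ambiguity < ambiguity_delta) {
      unplaced <- rbind(unplaced,
                        data.frame(marker = marker,
                                   reason = "ambiguous placement"))
      next
    }
    groups[[gi]] <- ins$group
  }
  list(groups = groups, unplaced = unplaced)
}

linked_groups <- function(marker, groups, pairs, lod_group, dmax_cM) {
  rows <- pairs[(pairs$marker_a == marker | pairs$marker_b == marker) &
                  !is.na(pairs$lod) & pairs$lod >= lod_group &
                  pairs$d_cM <= dmax_cM, ]
  other <- ifelse(rows$marker_a == marker, rows$marker_b, rows$marker_a)
  which(vapply(groups, function(g) any(other %in% g$markers), logical(1)))
}

merge_groups <- function(x, ga, gb, pairs, criterion, ripple_window) {
  cands <- list(c(ga$markers, gb$markers),
                c(ga$markers, rev(gb$markers)),
                c(rev(ga$markers), gb$markers),
                c(rev(ga$markers), rev(gb$markers)))
  evs <- lapply(cands, function(o) eval_order(x, o))
  best <- which.max(vapply(evs, `[[`, numeric(1), "loglik"))
  rp <- ripple(x, cands[[best]], window = ripple_window,
               criterion = criterion, pairs = pairs)
  fw <- c(ga$framework, gb$framework)
  names(fw) <- c(ga$markers, gb$markers)
  list(markers = rp$order, rfs = rp$rfs,
       framework = unname(fw[rp$order]))
}

# evaluate all insertion positions of one marker into a group
try_placements <- function(x, g, marker) {
  m <- length(g$markers)
  cands <- lapply(0L:m, function(pos) append(g$markers, marker, after = pos))
  evs <- lapply(cands, function(o)
    eval_order(x, o, tol = 1e-6, max_iter = 100L))
  lls <- vapply(evs, `[[`, numeric(1), "loglik")
  posns <- vapply(evs, function(e) {
    p <- cumsum(c(0, kosambi_cM(pmin(e$rfs, 0.499))))
    p[[match(marker, e$order)]]
  }, numeric(1))
  best <- which.max(lls)
  # second-best among placements at a genuinely different map position
  distinct <- abs(posns - posns[[best]]) > 1e-6
  ambiguity <- if (any(distinct)) lls[[best]] - max(lls[distinct]) else Inf
  ev <- evs[[best]]
  fw <- c(stats::setNames(g$framework, g$markers),
          stats::setNames(FALSE, marker))
  list(group = list(markers = ev$order, rfs = ev$rfs,
                    framework = unname(fw[ev$order])),
       ambiguity = ambiguity)
}

#' Crossover counts along a linkage group
#'
#' Counts, for each individual, the parental-origin switches between
#' consecutive non-missing calls along the ordered markers of a linkage
#' group; missing calls are skipped, so `P1, missing, P2` scores one
#' crossover.
#'
#' @param x a [genotypes] object.
#' @param markers ordered marker ids of the group (or a group structure from
#'   a [linkage_map]).
#' @return A list with `per_individual` (named integer vector) and `mean`.
#' @export
count_crossovers <- function(x, markers) {
  if (is.list(markers)) markers <- markers$markers
  O <- order_obs(x, markers)
  per <- apply(O, 1L, function(row) {
    v <- row[!is.na(row)]
    if (length(v) < 2L) 0L else sum(diff(v) != 0L)
  })
  list(per_individual = per, mean = mean(per))
}

#' Estimated genome length from linkage data
#'
#' Two method-of-moments estimators of the total genome length `Le` in cM.
#' `"hulbert_mom"` uses the pairwise linkage table: with `N` mapped markers,
#' `K` marker pairs at LOD >= `lod_threshold`, and `X` the largest Kosambi
#' distance among those pairs, `Le = N (N - 1) X / K`. The rationale is
#' method-of-moments: markers placed at random on a genome of length `Le`
#' yield `N (N - 1) X / Le` pairs closer than `X`, and `K` estimates that
#' count. `"per_group_inflation"` expands each linkage
#' group's observed length for the chromosome ends beyond the terminal
#' markers: `Le = sum_i length_i (m_i + 1) / (m_i - 1)`.
#'
#' @param map a [linkage_map], or (for `"per_group_inflation"`) a data.frame
#'   with columns `length_cM` and `n_markers`.
#' @param pairs [pairwise_linkage()] table (required for `"hulbert_mom"`).
#' @param method estimator variant.
#' @param lod_threshold LOD cutoff defining a significant pair (default 4).
#' @return Estimated genome length in cM.
#' @export
estimate_genome_length <- function(map, pairs = NULL,
                                   method = c("hulbert_mom",
                                              "per_group_inflation"),
                                   lod_threshold = 4.0) {
  method <- match.arg(method)
  if (method == "per_group_inflation") {
    tab <- if (inherits(map, "linkage_map")) {
      data.frame(length_cM = vapply(map$groups, function(g) max(g$pos),
                                    numeric(1)),
                 n_markers = vapply(map$groups, function(g)
                   length(g$markers), integer(1)))
    } else as.data.frame(map)
    tab <- tab[tab$n_markers >= 2L, ]
    return(sum(tab$length_cM * (tab$n_markers + 1) / (tab$n_markers - 1)))
  }
  if (!inherits(map, "linkage_map"))
    stop("hulbert_mom needs a fitted linkage_map")
  if (is.null(pairs)) pairs <- map$pairs
  placed <- unlist(lapply(map$groups, `[[`, "markers"), use.names = FALSE)
  keep <- pairs$marker_a %in% placed & pairs$marker_b %in% placed &
    !is.na(pairs$lod) & pairs$lod >= lod_threshold & is.finite(pairs$d_cM)
  K <- sum(keep)
  if (K == 0L) stop("no marker pair reaches the LOD threshold")
  N <- length(placed)
  N * (N - 1) * max(pairs$d_cM[keep]) / K
}

#' Expected map coverage
#'
#' Proportion of the genome lying within `c_cM` of at least one of `m`
#' randomly placed markers on a genome of length `Le`:
#' \eqn{P = 1 - (1 - 2c/L_e)^m}.
#'
#' @param c_cM half-window around each marker, cM.
#' @param Le estimated genome length, cM.
#' @param m number of informative markers.
#' @return Coverage proportion in `[0, 1]`.
#' @examples
#' map_coverage(10, 2458, 202)
#' @export
map_coverage <- function(c_cM, Le, m) {
  if (2 * c_cM > Le) stop("window exceeds genome length (2c > Le)")
  if (c_cM <= 0) stop("c_cM must be positive")
  if (m < 0) stop("m must be nonnegative")
  1 - (1 - 2 * c_cM / Le)^m
}
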