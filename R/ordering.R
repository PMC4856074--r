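# Marker ordering within a linkage group: exhaustive search on small groups,
# greedy seriation plus ripple on larger ones. The ordering criterion is the
# multipoint log10-likelihood with EM re-estimated interval rfs; a fast
# sum-of-adjacent-rf criterion is available as a configuration alternative.

# all permutations of 1..n as a matrix (n! rows); n <= 8 expected
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 0L
  for (i in seq_len(n)) {
    rows <- k + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    k <- k + nrow(sub)
  }
  out
}

#' Canonical orientation of a marker order
#'
#' A marker order and its reversal describe the same map; the canonical
#' representative puts the lexicographically smaller endpoint first.
#'
#' @param order character vector of marker ids.
#' @return `order` or its reversal.
#' @export
canonical_order <- function(order) {
  if (length(order) > 1L && order[[length(order)]] < order[[1L]])
    rev(order) else order
}

# score an order; returns list(order, rfs, loglik)
eval_order <- function(x, order, rf_mat = NULL, tol = 1e-4, max_iter = 30L) {
  init <- if (is.null(rf_mat)) NULL else adjacent_from_matrix(rf_mat, order)
  O <- order_obs(x, order)
  if (is.null(init)) init <- adjacent_twopoint_rfs(x, order)
  em <- em_rfs(O, pmin(pmax(init, 0.001), 0.49), tol = tol,
               max_iter = max_iter)
  list(order = order, rfs = em$rfs, loglik = em$loglik)
}

rf_matrix <- function(pairs, ids) {
  M <- matrix(0.45, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- pairs$marker_a %in% ids & pairs$marker_b %in% ids
  p <- pairs[keep, ]
  M[cbind(p$marker_a, p$marker_b)] <- p$rf
  M[cbind(p$marker_b, p$marker_a)] <- p$rf
  diag(M) <- 0
  M
}

adjacent_from_matrix <- function(rf_mat, order) {
  m <- length(order)
  rf_mat[cbind(order[-m], order[-1L])]
}

#' Order the markers of a candidate linkage group
#'
#' Establishes the most likely marker order. Groups of at most
#' `exhaustive_max` markers are solved exactly by enumerating all orders up
#' to reversal and maximising the multipoint likelihood. Larger groups are
#' seeded with an exhaustively ordered five-marker core (chosen by maximin
#' two-point distance, so the core spans the group), extended by inserting
#' each remaining marker at its best-likelihood position (markers taken in
#' decreasing order of their strongest linkage to the placed set), and
#' polished with [ripple()]. Equal-likelihood ties are broken by canonical
#' marker-id order, so the result is deterministic.
#'
#' @param x a [genotypes] object.
#' @param group character vector of marker ids (size >= 2).
#' @param pairs optional [pairwise_linkage()] table used for initial values
#'   (computed on the fly when absent).
#' @param exhaustive_max largest group ordered by full enumeration
#'   (default 7).
#' @param criterion `"loglik"` (multipoint maximum likelihood, default) or
#'   `"rf_sum"` (minimise the sum of adjacent two-point rfs; fast screen).
#' @param ripple_window window size passed to [ripple()] for greedy orders.
#' @return A list with `order` (canonical), `rfs` (EM interval estimates at
#'   tolerance 1e-6), `loglik`, and `method` (`"exhaustive"` or `"greedy"`).
#' @export
order_group <- function(x, group, pairs = NULL, exhaustive_max = 7L,
                        criterion = c("loglik", "rf_sum"),
                        ripple_window = 5L) {
  criterion <- match.arg(criterion)
  group <- sort(unique(group))
  if (length(group) < 2L) stop("group must contain at least two markers")
  if (is.null(pairs)) pairs <- pairwise_linkage(subset_markers(x, group))
  M <- rf_matrix(pairs, group)
  if (length(group) <= exhaustive_max) {
    ord <- exhaustive_order(x, group, M, criterion)
    method <- "exhaustive"
  } else {
    ord <- greedy_order(x, group, M, pairs, criterion)
    rp <- ripple(x, ord$order, window = ripple_window, criterion = criterion,
                 pairs = pairs)
    ord <- list(order = rp$order, loglik = rp$loglik)
    method <- "greedy"
  }
  final <- eval_order(x, canonical_order(ord$order), tol = 1e-6,
                      max_iter = 100L)
  c(final, list(method = method))
}

exhaustive_order <- function(x, group, M, criterion) {
  m <- length(group)
  P <- perms(m)
  P <- P[P[, 1L] < P[, m], , drop = FALSE]   # up to reversal
  if (criterion == "rf_sum") {
    sums <- apply(P, 1L, function(p) sum(M[cbind(group[p[-m]], group[p[-1L]])]))
    best <- which.min(sums)
    return(list(order = group[P[best, ]], loglik = NA_real_))
  }
  best_ll <- -Inf; best_ord <- NULL
  for (i in seq_len(nrow(P))) {
    ord <- group[P[i, ]]
    ev <- eval_order(x, ord, rf_mat = M)
    if (ev$loglik > best_ll + 1e-9) { best_ll <- ev$loglik; best_ord <- ord }
  }
  list(order = best_ord, loglik = best_ll)
}

greedy_order <- function(x, group, M, pairs, criterion) {
  core <- maximin_core(M, group, 5L)
  seed <- exhaustive_order(x, core, M, criterion)$order
  rest <- setdiff(group, core)
  # strongest-linked first: smallest rf to any placed marker
  while (length(rest)) {
    link <- vapply(rest, function(id) min(M[id, seed]), numeric(1))
    nxt <- rest[[which.min(link)]]
    seed <- best_insertion(x, seed, nxt, M, criterion)
    rest <- setdiff(rest, nxt)
  }
  ev <- if (criterion == "loglik") eval_order(x, seed, rf_mat = M)
        else list(order = seed, loglik = NA_real_)
  list(order = seed, loglik = ev$loglik)
}

maximin_core <- function(M, group, k) {
  if (length(group) <= k) return(group)
  D <- M[group, group]
  first <- which(D == max(D), arr.ind = TRUE)[1L, ]
  core <- group[first]
  while (length(core) < k) {
    cand <- setdiff(group, core)
    score <- vapply(cand, function(id) min(M[id, core]), numeric(1))
    core <- c(core, cand[[which.max(score)]])
  }
  sort(core)
}

best_insertion <- function(x, order, marker, M, criterion) {
  m <- length(order)
  cands <- lapply(0L:m, function(pos) append(order, marker, after = pos))
  if (criterion == "rf_sum") {
    sums <- vapply(cands, function(o)
      sum(adjacent_from_matrix(M, o)), numeric(1))
    return(cands[[which.min(sums)]])
  }
  lls <- vapply(cands, function(o) eval_order(x, o, rf_mat = M)$loglik,
                numeric(1))
  cands[[which.max(lls)]]
}

#' Local reordering by window permutation (ripple)
#'
#' Slides a window of `window` consecutive markers along the order, testing
#' every permutation within the window and accepting a permutation only when
#' the multipoint log10-likelihood strictly improves. Passes repeat until a
#' full pass changes nothing, so the output likelihood is never below the
#' input likelihood and the result is a fixed point of the procedure.
#'
#' @param x a [genotypes] object.
#' @param order character vector of marker ids.
#' @param window window size (>= 2; clamped to the group size; default 5).
#' @param criterion as in [order_group()].
#' @param pairs optional pairwise table for initial rfs.
#' @return A list with `order` (canonical), `rfs`, `loglik`, `n_passes`.
#' @export
ripple <- function(x, order, window = 5L, criterion = c("loglik", "rf_sum"),
                   pairs = NULL) {
  criterion <- match.arg(criterion)
  m <- length(order)
  window <- max(2L, min(window, m))
  if (is.null(pairs)) pairs <- pairwise_linkage(subset_markers(x, order))
  M <- rf_matrix(pairs, sort(order))
  score <- function(o) {
    if (criterion == "rf_sum") -sum(adjacent_from_matrix(M, o))
    else eval_order(x, o, rf_mat = M)$loglik
  }
  cur <- order
  cur_ll <- score(cur)
  P <- perms(window)
  n_passes <- 0L
  repeat {
    n_passes <- n_passes + 1L
    changed <- FALSE
    for (start in seq_len(m - window + 1L)) {
      idx <- start:(start + window - 1L)
      for (i in seq_len(nrow(P))) {
        cand <- cur
        cand[idx] <- cur[idx][P[i, ]]
        if (identical(cand, cur)) next
        ll <- score(cand)
        if (ll > cur_ll + 1e-9) {
          cur <- cand; cur_ll <- ll; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cur <- canonical_order(cur)
  final <- eval_order(x, cur, rf_mat = M, tol = 1e-6, max_iter = 100L)
  list(order = cur, rfs = final$rfs,
       loglik = if (criterion == "loglik") final$loglik else cur_ll,
       n_passes = n_passes)
}
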