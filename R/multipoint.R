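#' Multipoint likelihood of a marker order for haploid progeny
#'
#' Along a fixed marker order, each haploid individual's parental origins
#' form a two-state Markov chain: the transition probability between
#' adjacent markers is that interval's recombination fraction. Missing calls
#' are marginalised exactly by the forward algorithm. The returned value is
#' the summed log10 likelihood, conditional on each individual's first
#' observed state (so an individual with no recombinant interval and
#' interval rfs all `r` contributes `(m-1) * log10(1 - r)`, and an entirely
#' missing individual contributes 0).
#'
#' @param x a [genotypes] object.
#' @param order character vector of marker ids defining the order.
#' @param rfs numeric vector of interval recombination fractions,
#'   `length(order) - 1`, each in `[0, 0.5)`.
#' @return Summed log10-likelihood (scalar).
#' @export
multipoint_loglik <- function(x, order, rfs) {
  O <- order_obs(x, order)
  check_rfs(rfs, length(order))
  fwd <- chain_forward(O, rfs)
  sum(fwd$log10_scale) + log10(2) * sum(rowSums(!is.na(O)) > 0L)
}

# observation matrix (individuals x markers) for a marker order
order_obs <- function(x, order) {
  idx <- match(order, x$markers$id)
  if (anyNA(idx))
    stop("order references unknown marker(s): ",
         paste(order[is.na(idx)], collapse = ", "))
  t(calls_int(x)[idx, , drop = FALSE])
}

check_rfs <- function(rfs, m) {
  if (length(rfs) != m - 1L)
    stop("need ", m - 1L, " interval rfs, got ", length(rfs))
  if (any(rfs < 0 | rfs >= 0.5))
    stop("interval rfs must lie in [0, 0.5)")
  invisible(rfs)
}

# Scaled forward pass, vectorised over individuals.
# Returns per-step scaled state probabilities and per-individual summed
# log10 scale factors (the full-chain log10 likelihood incl. the 1/2 prior).
chain_forward <- function(O, rfs, keep_alpha = FALSE) {
  n <- nrow(O); m <- ncol(O)
  e1 <- (is.na(O) | O == 1L) * 1
  e2 <- (is.na(O) | O == 2L) * 1
  a1 <- 0.5 * e1[, 1L]; a2 <- 0.5 * e2[, 1L]
  s <- a1 + a2
  lsc <- log10(s)
  a1 <- a1 / s; a2 <- a2 / s
  A1 <- A2 <- NULL
  if (keep_alpha) {
    A1 <- matrix(0, n, m); A2 <- matrix(0, n, m)
    A1[, 1L] <- a1; A2[, 1L] <- a2
  }
  if (m > 1L) for (j in 2L:m) {
    r <- rfs[j - 1L]
    b1 <- (a1 * (1 - r) + a2 * r) * e1[, j]
    b2 <- (a1 * r + a2 * (1 - r)) * e2[, j]
    s <- b1 + b2
    if (any(s == 0)) {            # impossible under rf = 0 with a switch
      lsc <- lsc + ifelse(s == 0, -Inf, log10(pmax(s, 1e-300)))
      s[s == 0] <- 1
    } else lsc <- lsc + log10(s)
    a1 <- b1 / s; a2 <- b2 / s
    if (keep_alpha) { A1[, j] <- a1; A2[, j] <- a2 }
  }
  list(log10_scale = lsc, A1 = A1, A2 = A2, e1 = e1, e2 = e2)
}

#' EM re-estimation of interval recombination fractions for a fixed order
#'
#' Maximum-likelihood interval recombination fractions under the haploid
#' Markov-chain model, with missing calls handled by the forward-backward
#' algorithm (Baum-Welch). The E-step computes each individual's posterior
#' probability of a parental-origin switch on each interval; the M-step
#' averages these over the individuals informative for that interval (those
#' with at least one observed call on each side; the remainder carry no
#' information and their posterior equals the current estimate). With no
#' missing data the first iteration already lands on the observed adjacent
#' recombinant fractions.
#'
#' @inheritParams multipoint_loglik
#' @param init optional initial rfs (defaults to adjacent two-point
#'   estimates, clamped to `[0.001, 0.49]`).
#' @param tol convergence tolerance on `max |delta rf|` (default 1e-6).
#' @param max_iter maximum EM iterations (default 100).
#' @return A list with `rfs`, `loglik` (conditional log10-likelihood as in
#'   [multipoint_loglik()]), `n_iter`, `converged` (a warning is raised when
#'   the iteration cap is hit).
#' @export
estimate_interval_rfs <- function(x, order, init = NULL, tol = 1e-6,
                                  max_iter = 100L) {
  O <- order_obs(x, order)
  m <- length(order)
  if (m < 2L) return(list(rfs = numeric(0), loglik = 0, n_iter = 0L,
                          converged = TRUE))
  if (is.null(init)) init <- adjacent_twopoint_rfs(x, order)
  rfs <- pmin(pmax(init, 0), 0.499)
  em <- em_rfs(O, rfs, tol = tol, max_iter = max_iter)
  if (!em$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  em
}

adjacent_twopoint_rfs <- function(x, order) {
  O <- order_obs(x, order)
  m <- ncol(O)
  vapply(seq_len(m - 1L), function(j) {
    inf <- !is.na(O[, j]) & !is.na(O[, j + 1L])
    if (!any(inf)) return(0.25)
    min(max(sum(O[inf, j] != O[inf, j + 1L]) / sum(inf), 0.001), 0.49)
  }, numeric(1))
}

# core EM loop on an observation matrix; rfs clamped inside (0, 0.5)
em_rfs <- function(O, rfs, tol = 1e-6, max_iter = 100L) {
  n <- nrow(O); m <- ncol(O)
  obs <- !is.na(O)
  left <- t(apply(obs, 1L, cumsum)) > 0          # observed at <= j
  right <- t(apply(obs[, m:1, drop = FALSE], 1L, cumsum))[, m:1, drop = FALSE] > 0
  # informative for interval j: observed somewhere at <= j and at > j
  W <- left[, -m, drop = FALSE] & right[, -1L, drop = FALSE]
  denom <- colSums(W)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    cur <- pmin(pmax(rfs, 1e-9), 0.5 - 1e-9)
    fwd <- chain_forward(O, cur, keep_alpha = TRUE)
    xi <- posterior_switch(fwd, cur)             # n x (m-1)
    new <- unname(ifelse(denom > 0, colSums(xi * W) / pmax(denom, 1L), rfs))
    new <- pmin(pmax(new, 0), 0.499)
    delta <- max(abs(new - rfs))
    rfs <- new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  fin <- chain_forward(O, pmin(pmax(rfs, 1e-12), 0.5 - 1e-12))
  ll <- sum(fin$log10_scale) + log10(2) * sum(rowSums(obs) > 0L)
  list(rfs = rfs, loglik = ll, n_iter = it, converged = converged)
}

# posterior switch probabilities per individual and interval (backward pass
# fused with the stored forward probabilities); each row of xi normalised
# over the four origin combinations.
posterior_switch <- function(fwd, rfs) {
  A1 <- fwd$A1; A2 <- fwd$A2; e1 <- fwd$e1; e2 <- fwd$e2
  n <- nrow(A1); m <- ncol(A1)
  xi <- matrix(0, n, m - 1L)
  b1 <- rep(1, n); b2 <- rep(1, n)
  for (j in (m - 1L):1L) {
    r <- rfs[j]
    g1 <- e1[, j + 1L] * b1        # beta through emission at j+1
    g2 <- e2[, j + 1L] * b2
    x11 <- A1[, j] * (1 - r) * g1
    x12 <- A1[, j] * r * g2
    x21 <- A2[, j] * r * g1
    x22 <- A2[, j] * (1 - r) * g2
    tot <- x11 + x12 + x21 + x22
    tot[tot == 0] <- 1
    xi[, j] <- (x12 + x21) / tot
    nb1 <- (1 - r) * g1 + r * g2   # new beta at j (unscaled, then normalise)
    nb2 <- r * g1 + (1 - r) * g2
    s <- nb1 + nb2
    s[s == 0] <- 1
    b1 <- nb1 / s; b2 <- nb2 / s
  }
  xi
}
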