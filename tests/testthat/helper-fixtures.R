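# small in-code fixtures shared across test files

# genotype matrix from per-marker call strings, e.g. "1122" -> P1,P1,P2,P2
make_geno <- function(..., classes = NULL, ids = NULL) {
  rows <- list(...)
  calls <- do.call(rbind, lapply(rows, function(s) {
    v <- strsplit(s, "")[[1L]]
    ifelse(v == "1", "P1", ifelse(v == "2", "P2", NA_character_))
  }))
  n <- length(rows)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(n))
  if (is.null(classes)) classes <- rep("codominant_SSR", n)
  genotypes(calls,
            data.frame(id = ids, marker_class = classes,
                       parent1_allele = "a", parent2_allele = "b",
                       stringsAsFactors = FALSE),
            sprintf("i%02d", seq_len(ncol(calls))))
}

# independent brute-force multipoint likelihood: enumerate every completion
# of the missing calls and sum exact chain probabilities (conditional on the
# first observed state, matching multipoint_loglik's convention)
brute_loglik <- function(calls_int, rfs) {
  chain_p <- function(states, rfs) {
    p <- 0.5
    for (j in seq_along(rfs))
      p <- p * if (states[j] != states[j + 1L]) rfs[j] else 1 - rfs[j]
    p
  }
  total <- 0
  for (i in seq_len(nrow(calls_int))) {
    row <- calls_int[i, ]
    nas <- which(is.na(row))
    p <- 0
    fills <- if (length(nas))
      as.matrix(expand.grid(rep(list(1:2), length(nas))))
    else matrix(nrow = 1L, ncol = 0L)
    for (k in seq_len(nrow(fills))) {
      full <- row
      if (length(nas)) full[nas] <- fills[k, ]
      p <- p + chain_p(full, rfs)
    }
    if (any(!is.na(row))) p <- p * 2   # drop the 1/2 prior
    total <- total + log10(p)
  }
  total
}

# deterministic sub-seed derivation for multi-part stochastic tests
sub_seed <- function(base, k) (base * 1000L + k) %% .Machine$integer.max
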