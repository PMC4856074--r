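#' @export
print.linkage_map <- function(x, ...) {
  n_placed <- sum(vapply(x$groups, function(g) length(g$markers), integer(1)))
  len <- vapply(x$groups, function(g) max(g$pos), numeric(1))
  cat("Genetic linkage map\n")
  cat("  linkage groups:", length(x$groups), "\n")
  cat("  markers placed:", n_placed, " (unplaced:", nrow(x$unplaced), ")\n")
  cat(sprintf("  total length: %.1f cM\n", sum(len)))
  if (length(len))
    cat(sprintf("  group lengths: %s cM\n",
                paste(sprintf("%.0f", len), collapse = ", ")))
  invisible(x)
}

#' Linkage-group summary table
#'
#' Builds the conventional per-group characteristics table: map length,
#' marker count, distorted-marker count, average marker spacing and largest
#' inter-marker interval, with `Total` and `Mean` rows appended. The average
#' spacing of a group is defined as length divided by marker count (the
#' convention that reproduces published per-group values such as
#' 202 cM / 26 markers = 7.8 cM), and the `Mean` spacing row is the
#' arithmetic mean of the per-group spacings.
#'
#' @param x a [linkage_map], or a data.frame with columns `lg`, `length_cM`,
#'   `n_markers` and optionally `n_distorted`, `largest_interval_cM`.
#' @param ... unused.
#' @return A data.frame with one row per linkage group plus `Total` and
#'   `Mean` rows; columns `lg`, `length_cM`, `n_markers`, `n_distorted`,
#'   `avg_spacing_cM`, `largest_interval_cM`.
#' @export
lg_summary <- function(x, ...) UseMethod("lg_summary")

#' @rdname lg_summary
#' @export
lg_summary.linkage_map <- function(x, ...) {
  rows <- lapply(seq_along(x$groups), function(i) {
    g <- x$groups[[i]]
    dist_ids <- x$qc$id[x$qc$distorted]
    data.frame(lg = as.character(i),
               length_cM = max(g$pos),
               n_markers = length(g$markers),
               n_distorted = sum(g$markers %in% dist_ids),
               largest_interval_cM = if (length(g$pos) > 1L)
                 max(diff(g$pos)) else 0)
  })
  lg_summary.data.frame(do.call(rbind, rows))
}

#' @rdname lg_summary
#' @export
lg_summary.data.frame <- function(x, ...) {
  tab <- as.data.frame(x)
  if (!"n_distorted" %in% names(tab)) tab$n_distorted <- NA_integer_
  if (!"largest_interval_cM" %in% names(tab))
    tab$largest_interval_cM <- NA_real_
  if (!"lg" %in% names(tab)) tab$lg <- as.character(seq_len(nrow(tab)))
  tab$avg_spacing_cM <- tab$length_cM / tab$n_markers
  tab <- tab[, c("lg", "length_cM", "n_markers", "n_distorted",
                 "avg_spacing_cM", "largest_interval_cM")]
  total <- data.frame(lg = "Total", length_cM = sum(tab$length_cM),
                      n_markers = sum(tab$n_markers),
                      n_distorted = sum(tab$n_distorted),
                      avg_spacing_cM = NA_real_,
                      largest_interval_cM = NA_real_)
  mn <- data.frame(lg = "Mean", length_cM = mean(tab$length_cM),
                   n_markers = mean(tab$n_markers),
                   n_distorted = mean(tab$n_distorted),
                   avg_spacing_cM = mean(tab$avg_spacing_cM),
                   largest_interval_cM = mean(tab$largest_interval_cM))
  out <- rbind(tab, total, mn)
  rownames(out) <- NULL
  class(out) <- c("lg_summary", "data.frame")
  out
}

#' @export
print.lg_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @method summary linkage_map
#' @export
#' @rdname linkage_map
#' @param object a fitted `linkage_map`.
#' @param genotypes optionally, the [genotypes] the map was fitted to; when
#'   supplied, per-group mean crossover counts are included in the summary.
summary.linkage_map <- function(object, genotypes = NULL, ...) {
  tab <- lg_summary(object)
  xo <- if (is.null(genotypes)) rep(NA_real_, length(object$groups))
        else vapply(object$groups, function(g)
          count_crossovers(genotypes, g)$mean, numeric(1))
  structure(list(table = tab, n_groups = length(object$groups),
                 unplaced = object$unplaced, mean_crossovers = xo),
            class = "summary.linkage_map")
}

#' @export
print.summary.linkage_map <- function(x, ...) {
  print(x$table)
  if (nrow(x$unplaced)) {
    cat("\nUnplaced markers:\n")
    print(table(x$unplaced$reason))
  }
  invisible(x)
}

#' Plot a linkage map
#'
#' Draws each linkage group as a vertical bar with marker positions as
#' tick marks, in the style of conventional map-chart figures.
#'
#' @param x a [linkage_map].
#' @param label_markers draw marker ids next to ticks (default only when the
#'   map holds fewer than 60 markers).
#' @param ... passed to [graphics::plot()].
#' @method plot linkage_map
#' @export
plot.linkage_map <- function(x, label_markers = NULL, ...) {
  ng <- length(x$groups)
  if (ng == 0L) stop("empty map")
  maxlen <- max(vapply(x$groups, function(g) max(g$pos), numeric(1)))
  n_mark <- sum(vapply(x$groups, function(g) length(g$markers), integer(1)))
  if (is.null(label_markers)) label_markers <- n_mark < 60L
  graphics::plot(NA, xlim = c(0.5, ng + 0.5), ylim = c(maxlen * 1.05, 0),
                 xlab = "Linkage group", ylab = "Position (cM)", xaxt = "n",
                 ...)
  graphics::axis(1, at = seq_len(ng), labels = seq_len(ng))
  for (i in seq_len(ng)) {
    g <- x$groups[[i]]
    graphics::segments(i, 0, i, max(g$pos), lwd = 3, col = "grey40")
    graphics::segments(i - 0.12, g$pos, i + 0.12, g$pos)
    if (label_markers)
      graphics::text(i + 0.16, g$pos, g$markers, adj = 0, cex = 0.55)
  }
  invisible(x)
}

#' Simulate progeny genotypes from a fitted map
#'
#' Draws new haploid progeny from the fitted map's marker orders and EM
#' interval recombination fractions (parametric simulation under the
#' no-interference Markov model used for fitting).
#'
#' @param object a [linkage_map].
#' @param nsim number of genotype matrices to simulate (default 1).
#' @param seed optional integer seed.
#' @param n_progeny progeny size per simulated matrix (default 79).
#' @param missing_rate fraction of calls masked at random (default 0).
#' @param ... unused.
#' @return A list of [genotypes] objects (length `nsim`).
#' @export
simulate.linkage_map <- function(object, nsim = 1, seed = NULL,
                                 n_progeny = 79L, missing_rate = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k) {
    calls <- do.call(rbind, lapply(object$groups, function(g)
      sim_chain_calls(length(g$markers), g$rfs, n_progeny)))
    if (missing_rate > 0)
      calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
    ids <- unlist(lapply(object$groups, `[[`, "markers"), use.names = FALSE)
    genotypes(calls,
              data.frame(id = ids, marker_class = "codominant_SSR",
                         parent1_allele = "P1", parent2_allele = "P2",
                         stringsAsFactors = FALSE),
              sprintf("sim%03d", seq_len(n_progeny)))
  })
}

# markers x individuals character call matrix from a Markov origin chain
sim_chain_calls <- function(m, rfs, n) {
  st <- matrix(0L, m, n)
  st[1L, ] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) for (j in 2L:m) {
    sw <- stats::rbinom(n, 1L, rfs[j - 1L])
    st[j, ] <- (st[j - 1L, ] + sw) %% 2L
  }
  matrix(ifelse(st == 0L, "P1", "P2"), m, n)
}

#' Write the fitted map as a TSV table
#'
#' One row per placed marker: linkage group, position in cM, framework flag
#' and distortion flag.
#'
#' @param map a [linkage_map].
#' @param path output file path.
#' @export
write_map_table <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Placed markers of a fitted map as a data.frame
#' @param x a [linkage_map].
#' @param ... unused.
#' @return data.frame with columns `marker`, `lg`, `pos_cM`, `framework`,
#'   `distorted`.
#' @method as.data.frame linkage_map
#' @export
as.data.frame.linkage_map <- function(x, ...) {
  dist_ids <- x$qc$id[x$qc$distorted]
  rows <- lapply(seq_along(x$groups), function(i) {
    g <- x$groups[[i]]
    data.frame(marker = g$markers, lg = i, pos_cM = g$pos,
               framework = g$framework,
               distorted = g$markers %in% dist_ids,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
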