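#' Haploid progeny genotype matrix
#'
#' Container for parental-origin coded genotype calls of a haploid progeny.
#' Each call records which parental homokaryon contributed the allele observed
#' in a single-spore isolate: `"P1"`, `"P2"`, or `NA` (missing). Dominant
#' (presence/absence) markers are still binary in a haploid progeny, because
#' absence of the band identifies the non-carrying parent's nucleus; the
#' marker class is retained so that staged mapping can treat dominant markers
#' differently.
#'
#' @param calls character matrix with entries `"P1"`, `"P2"` or `NA`; one row
#'   per marker, one column per individual.
#' @param markers data.frame with one row per marker and columns `id`,
#'   `marker_class` (one of `"codominant_SSR"`, `"codominant_CAPS"`,
#'   `"dominant_AFLP"`, `"MAT"`), `parent1_allele`, `parent2_allele`, and
#'   optionally `homolog_hint` (reference gene id, or `NA`).
#' @param individuals character vector of progeny identifiers (defaults to the
#'   column names of `calls`).
#' @return An object of class `genotypes`: a list with elements `calls`
#'   (character matrix), `markers` (data.frame) and `individuals`.
#' @examples
#' g <- genotypes(matrix(c("P1", "P2", "P2", NA), 2, 2,
#'                       dimnames = list(c("m1", "m2"), c("i1", "i2"))),
#'                markers = data.frame(id = c("m1", "m2"),
#'                                     marker_class = "codominant_SSR",
#'                                     parent1_allele = "a",
#'                                     parent2_allele = "b"))
#' n_missing(g)
#' @export
genotypes <- function(calls, markers, individuals = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (nrow(calls) == 0L || ncol(calls) == 0L)
    stop("empty genotype matrix")
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(calls)))
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!"id" %in% names(markers)) stop("markers must have an 'id' column")
  if (anyDuplicated(markers$id))
    stop("duplicate marker id(s): ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (nrow(markers) != nrow(calls))
    stop("markers table and call matrix disagree on the number of markers")
  if (length(individuals) != ncol(calls))
    stop("individual ids and call matrix disagree on the number of individuals")
  if (!"marker_class" %in% names(markers)) markers$marker_class <- "codominant_SSR"
  bad_class <- setdiff(unique(markers$marker_class), marker_classes())
  if (length(bad_class))
    stop("unknown marker class(es): ", paste(bad_class, collapse = ", "))
  if (!"homolog_hint" %in% names(markers)) markers$homolog_hint <- NA_character_
  bad <- !(calls %in% c("P1", "P2") | is.na(calls))
  if (any(bad))
    stop("invalid call token(s): ", paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(markers$id, individuals)
  structure(list(calls = calls, markers = markers,
                 individuals = as.character(individuals)),
            class = "genotypes")
}

marker_classes <- function() {
  c("codominant_SSR", "codominant_CAPS", "dominant_AFLP", "MAT")
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' @export
print.genotypes <- function(x, ...) {
  cls <- table(x$markers$marker_class)
  cat("Haploid genotype matrix: ", nrow(x$calls), " markers x ",
      ncol(x$calls), " individuals\n", sep = "")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  missing calls:", n_missing(x),
      sprintf("(%.1f%%)", 100 * n_missing(x) / length(x$calls)), "\n")
  invisible(x)
}

#' @rdname genotypes
#' @param x a `genotypes` object.
#' @export
n_missing <- function(x) sum(is.na(x$calls))

#' Integer-coded calls (1 = P1, 2 = P2, NA = missing), markers in rows
#' @noRd
calls_int <- function(x) {
  m <- matrix(NA_integer_, nrow(x$calls), ncol(x$calls),
              dimnames = dimnames(x$calls))
  m[x$calls == "P1"] <- 1L
  m[x$calls == "P2"] <- 2L
  m
}

#' Subset a genotype matrix by marker ids and/or individuals
#' @noRd
subset_markers <- function(x, ids) {
  keep <- match(ids, x$markers$id)
  if (anyNA(keep)) stop("unknown marker id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  genotypes(x$calls[keep, , drop = FALSE],
            x$markers[keep, , drop = FALSE], x$individuals)
}

#' Read a haploid genotype table
#'
#' Parses a delimited text file with one row per marker. The first columns
#' carry marker metadata (`id`, `marker_class`, `parent1_allele`,
#' `parent2_allele`, optionally `homolog_hint`); the remaining columns, one
#' per progeny individual, carry the observed allele labels. Calls are
#' phase-coded at parse time against the declared parental alleles: a call
#' equal to `parent1_allele` becomes `P1`, equal to `parent2_allele` becomes
#' `P2`; tokens in `missing_tokens` (and empty fields) become missing. A
#' non-missing call matching neither declared parental allele is coded
#' missing with a warning, since a haploid progeny of a biallelic locus
#' admits no third state.
#'
#' Files may also be pre-coded directly in `P1`/`P2` tokens, in which case the
#' parental alleles are accepted verbatim.
#'
#' @param path path to a TSV/CSV file (delimiter auto-detected from the
#'   header line unless `sep` is given).
#' @param sep field delimiter; default guesses `\t` then `,`.
#' @param missing_tokens character vector of tokens mapped to missing calls.
#' @return A [genotypes] object.
#' @export
read_genotype_table <- function(path, sep = NULL,
                                missing_tokens = c("-", "NA", "")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty genotype table: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_fields <- function(x) strsplit(x, sep, fixed = TRUE)
  fields <- split_fields(lines)
  header <- fields[[1L]]
  nf <- lengths(fields)
  if (any(nf[-1L] != length(header)))
    stop("ragged rows in genotype table (expected ", length(header),
         " fields): lines ", paste(which(nf != length(header)), collapse = ", "))
  meta_cols <- intersect(c("id", "marker_class", "parent1_allele",
                           "parent2_allele", "homolog_hint"), header)
  if (!"id" %in% meta_cols) stop("genotype table header must contain 'id'")
  body <- do.call(rbind, fields[-1L])
  colnames(body) <- header
  ind_cols <- setdiff(header, meta_cols)
  if (length(ind_cols) == 0L) stop("no individual columns in genotype table")
  markers <- as.data.frame(body[, meta_cols, drop = FALSE],
                           stringsAsFactors = FALSE)
  if ("homolog_hint" %in% names(markers))
    markers$homolog_hint[markers$homolog_hint == "-"] <- NA_character_
  if (!"marker_class" %in% names(markers)) markers$marker_class <- "codominant_SSR"
  if (!"parent1_allele" %in% names(markers)) markers$parent1_allele <- "P1"
  if (!"parent2_allele" %in% names(markers)) markers$parent2_allele <- "P2"
  raw <- body[, ind_cols, drop = FALSE]
  calls <- matrix(NA_character_, nrow(raw), ncol(raw))
  n_unrec <- 0L
  for (i in seq_len(nrow(raw))) {
    p1 <- markers$parent1_allele[i]; p2 <- markers$parent2_allele[i]
    row <- raw[i, ]
    out <- rep(NA_character_, length(row))
    out[row == p1 | row == "P1"] <- "P1"
    out[row == p2 | row == "P2"] <- "P2"
    unrec <- is.na(out) & !(row %in% missing_tokens)
    n_unrec <- n_unrec + sum(unrec)
    calls[i, ] <- out
  }
  if (n_unrec > 0L)
    warning(n_unrec, " call(s) matched neither declared parental allele; ",
            "coded as missing")
  genotypes(calls, markers, ind_cols)
}

#' Write a haploid genotype table
#'
#' Inverse of [read_genotype_table()]: emits a TSV with marker metadata
#' columns followed by one column per individual, calls written as the
#' declared parental allele labels and missing as `-`. Round-trips losslessly
#' through [read_genotype_table()].
#'
#' @param x a [genotypes] object.
#' @param path output file path.
#' @export
write_genotype_table <- function(x, path) {
  m <- x$markers
  alle <- ifelse(x$calls == "P1", m$parent1_allele[row(x$calls)],
                 m$parent2_allele[row(x$calls)])
  alle[is.na(x$calls)] <- "-"
  dim(alle) <- dim(x$calls)
  out <- cbind(id = m$id, marker_class = m$marker_class,
               parent1_allele = m$parent1_allele,
               parent2_allele = m$parent2_allele,
               homolog_hint = ifelse(is.na(m$homolog_hint), "-",
                                     m$homolog_hint),
               alle)
  colnames(out)[-(1:5)] <- x$individuals
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Export genotypes in the classic MapMaker raw format
#'
#' Writes the historical `data type ri self` text format used by early
#' mapping software: haploid calls coded `A` (parent 1), `B` (parent 2) and
#' `-` (missing), one `*locus` record per marker.
#'
#' @param x a [genotypes] object.
#' @param path output file path.
#' @export
write_mapmaker_raw <- function(x, path) {
  if (length(x$individuals) == 0L) stop("no individuals to export")
  bad <- grepl("[[:space:]*#]", x$markers$id)
  if (any(bad))
    stop("marker id(s) not representable in mapmaker format: ",
         paste(x$markers$id[bad], collapse = ", "))
  sym <- ifelse(is.na(x$calls), "-", ifelse(x$calls == "P1", "A", "B"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("data type ri self", con)
  writeLines(sprintf("%d %d 0", ncol(x$calls), nrow(x$calls)), con)
  for (i in seq_len(nrow(x$calls)))
    writeLines(paste0("*", x$markers$id[i], " ",
                      paste(sym[i, ], collapse = "")), con)
  invisible(path)
}

#' Read the MapMaker raw export back into a genotype matrix
#'
#' Minimal reader for the format emitted by [write_mapmaker_raw()]; marker
#' classes and parental allele labels are not represented in that format and
#' default to codominant with `P1`/`P2` labels.
#'
#' @param path path to a mapmaker raw file.
#' @return A [genotypes] object.
#' @export
read_mapmaker_raw <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  loci <- grep("^\\*", lines, value = TRUE)
  if (!length(loci)) stop("no locus records in ", path)
  ids <- sub("^\\*(\\S+)\\s.*$", "\\1", loci)
  sym <- strsplit(sub("^\\*\\S+\\s+", "", loci), "")
  n_ind <- unique(lengths(sym))
  if (length(n_ind) != 1L) stop("ragged locus records in ", path)
  calls <- do.call(rbind, lapply(sym, function(s)
    ifelse(s == "A", "P1", ifelse(s == "B", "P2", NA_character_))))
  genotypes(calls,
            data.frame(id = ids, marker_class = "codominant_SSR",
                       parent1_allele = "P1", parent2_allele = "P2",
                       stringsAsFactors = FALSE),
            paste0("ind", seq_len(n_ind)))
}
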