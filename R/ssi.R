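#' Classify single-spore isolates as homokaryons or heterokaryons
#'
#' An amphithallic mushroom sheds both homokaryotic (n) and heterokaryotic
#' (n + n) spores. Only homokaryons are usable as haploid mapping progeny.
#' Classification uses a multilocus genotype test over a panel of
#' microsatellite loci that are polymorphic between the parental homokaryons:
#' an isolate is a homokaryon iff every scored panel locus shows exactly one
#' allele; one or more heteromorphic (two-allele) loci identify a
#' heterokaryon carrying both parental nuclei.
#'
#' @param profiles a list of SSI profiles, each a list with elements `ssi_id`
#'   and `alleles_by_locus` (a named list mapping locus id to a character
#'   vector of observed allele labels, length 1 or 2), as returned by
#'   [read_ssi_profiles()] or the simulator.
#' @param panel character vector of panel locus ids; loci outside the panel
#'   are ignored.
#' @return A data.frame with columns `ssi_id`, `n_loci` (panel loci scored),
#'   `n_heteromorphic`, and `ploidy` (`"homokaryon"` or `"heterokaryon"`).
#' @examples
#' p <- list(list(ssi_id = "E1",
#'                alleles_by_locus = list(L1 = "a", L2 = c("a", "b"))))
#' classify_homokaryons(p, panel = c("L1", "L2"))
#' @export
classify_homokaryons <- function(profiles, panel) {
  res <- lapply(profiles, function(p) {
    loci <- intersect(names(p$alleles_by_locus), panel)
    if (length(loci) == 0L)
      stop("SSI '", p$ssi_id, "' covers no panel locus (uninformative)")
    sizes <- vapply(p$alleles_by_locus[loci],
                    function(a) length(unique(a)), integer(1))
    if (any(sizes < 1L))
      stop("SSI '", p$ssi_id, "' has an empty allele set")
    data.frame(ssi_id = p$ssi_id, n_loci = length(loci),
               n_heteromorphic = sum(sizes >= 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$ploidy <- ifelse(out$n_heteromorphic > 0L, "heterokaryon", "homokaryon")
  out
}

#' Read SSI multilocus allele profiles
#'
#' Expects a long-format TSV with columns `ssi_id`, `locus`, `allele`; a
#' heteromorphic locus appears on two rows (one per allele).
#'
#' @param path path to a TSV file.
#' @return A list of profiles suitable for [classify_homokaryons()].
#' @export
read_ssi_profiles <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("ssi_id", "locus", "allele")
  if (!all(need %in% names(tab)))
    stop("SSI profile table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$ssi_id)[unique(tab$ssi_id)], function(d)
    list(ssi_id = d$ssi_id[[1L]],
         alleles_by_locus = lapply(split(d$allele, d$locus), unique)))
}

#' Write SSI profiles in the long TSV format read by [read_ssi_profiles()]
#' @param profiles list of SSI profiles.
#' @param path output file path.
#' @export
write_ssi_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    loci <- names(p$alleles_by_locus)
    do.call(rbind, lapply(loci, function(l)
      data.frame(ssi_id = p$ssi_id, locus = l,
                 allele = p$alleles_by_locus[[l]], stringsAsFactors = FALSE)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
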