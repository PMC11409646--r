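## Reporting: half-up percentage rounding, the printed-counts fixture with
## its derived ratio statistics, and interoperability exports.

#' Percentage with half-up rounding to one decimal
#'
#' 100 * numerator / denominator, rounded half-up to 1 decimal (so 17.456%
#' prints as 17.5, unlike banker's rounding). Vectorized.
#'
#' @param numerator,denominator non-negative numbers; denominator > 0.
#' @return Numeric percentage(s) with one decimal.
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  p <- 100 * numerator / denominator
  floor(p * 10 + 0.5 + 1e-9) / 10
}

#' Printed-counts fixture of the source cohort
#'
#' The published headline counts of the 1,083-MAG wastewater cohort, bundled
#' so the derived ratio statistics can be recomputed exactly without the
#' (unavailable) genomes: total MAGs, nosZ-positive MAGs, clade I / clade II
#' MAGs, the three largest clade II phyla, non-denitrifying N2O reducers,
#' and the DNRA co-occurrence counts per clade.
#'
#' @param ... named overrides of individual counts.
#' @return Validated named list of non-negative integer counts.
#' @export
paperCountsFixture <- function(...) {
  fx <- list(total_mags = 1083L, nosz_positive_mags = 527L,
             cladeI_mags = 27L, cladeII_mags = 401L,
             bacteroidota_cladeII = 283L, pseudomonadota_cladeII = 26L,
             chloroflexota_cladeII = 22L, non_denitrifiers = 146L,
             cladeI_dnra_capable = 20L, cladeII_dnra_capable = 126L,
             cladeII_dnra_no_norBC = 70L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(fx))
  if (length(bad)) stop("unknown fixture field(s): ",
                        paste(bad, collapse = ", "))
  fx[names(dots)] <- lapply(dots, as.integer)
  if (any(vapply(fx, function(x) is.na(x) || x < 0, TRUE)))
    stop("fixture counts must be non-negative integers")
  if (fx$nosz_positive_mags > fx$total_mags)
    stop("nosz_positive_mags exceeds total_mags")
  fx
}

#' Ratio statistics derived from the printed-counts fixture
#'
#' Emits each named statistic with its numerator, explicit denominator and
#' half-up percentage: nosZ prevalence among all MAGs, the clade I/II split
#' among clade-assigned MAGs, the non-denitrifier community share, the three
#' largest phylum shares within clade II, and the DNRA co-occurrence shares
#' per clade.
#'
#' @param fixture a [paperCountsFixture()].
#' @return data.frame with columns statistic, numerator, denominator,
#'   percent.
#' @export
paperFixtureSummary <- function(fixture = paperCountsFixture()) {
  clade_total <- fixture$cladeI_mags + fixture$cladeII_mags
  rows <- list(
    c("nosZ_prevalence", fixture$nosz_positive_mags, fixture$total_mags),
    c("cladeI_share", fixture$cladeI_mags, clade_total),
    c("cladeII_share", fixture$cladeII_mags, clade_total),
    c("non_denitrifier_share", fixture$non_denitrifiers,
      fixture$total_mags),
    c("bacteroidota_cladeII_share", fixture$bacteroidota_cladeII,
      fixture$cladeII_mags),
    c("pseudomonadota_cladeII_share", fixture$pseudomonadota_cladeII,
      fixture$cladeII_mags),
    c("chloroflexota_cladeII_share", fixture$chloroflexota_cladeII,
      fixture$cladeII_mags),
    c("cladeI_dnra_share", fixture$cladeI_dnra_capable,
      fixture$cladeI_mags),
    c("cladeII_dnra_share", fixture$cladeII_dnra_capable,
      fixture$cladeII_mags),
    c("cladeII_dnra_no_norBC_share", fixture$cladeII_dnra_no_norBC,
      fixture$cladeII_mags))
  out <- data.frame(
    statistic = vapply(rows, `[[`, "", 1L),
    numerator = as.numeric(vapply(rows, `[[`, "", 2L)),
    denominator = as.numeric(vapply(rows, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  if (any(out$numerator > out$denominator))
    stop("fixture numerator exceeds its denominator")
  out$percent <- percentage(out$numerator, out$denominator)
  out
}

#' Export nosZ hits for interoperability
#'
#' Writes a hit TSV plus nucleotide and protein FASTA files with structured
#' headers `genome_id|gene_id|clade|secretion|nosB|nosR`, ready for external
#' alignment/tree building; an optional alignment is written alongside.
#'
#' @param hits non-empty hit data.frame from [classifyGenomeNosz()].
#' @param dir output directory.
#' @param alignment optional named character vector / AAStringSet of aligned
#'   sequences to export as MSA-ready FASTA.
#' @return Invisibly, a named list of file paths.
#' @export
exportInterop <- function(hits, dir, alignment = NULL) {
  if (is.null(hits) || nrow(hits) == 0L)
    stop("no hits to export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  headers <- formatNoszHeader(hits)
  paths <- list(tsv = file.path(dir, "nosz_hits.tsv"),
                nt = file.path(dir, "nosz_nt.fasta"),
                aa = file.path(dir, "nosz_aa.fasta"))
  flat <- hits[, setdiff(names(hits), c("nt_seq", "aa_seq")), drop = FALSE]
  write.table(flat, paths$tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(hits$nt_seq), headers), paths$nt)
  Biostrings::writeXStringSet(
    setNames(Biostrings::AAStringSet(hits$aa_seq), headers), paths$aa)
  if (!is.null(alignment)) {
    paths$msa <- file.path(dir, "nosz_msa.fasta")
    if (is.character(alignment))
      alignment <- Biostrings::AAStringSet(alignment)
    Biostrings::writeXStringSet(alignment, paths$msa)
  }
  invisible(paths)
}

#' Structured FASTA headers for nosZ hits
#'
#' @param hits hit data.frame.
#' @return Character vector `genome_id|gene_id|clade|secretion|nosB|nosR`
#'   (absent offsets encoded as ".").
#' @export
formatNoszHeader <- function(hits) {
  enc <- function(x) ifelse(is.na(x), ".", as.character(x))
  sprintf("%s|%s|%s|%s|%s|%s", hits$genome_id, hits$gene_id, hits$clade,
          hits$secretion, enc(hits$nosB_offset), enc(hits$nosR_offset))
}

#' Parse structured nosZ FASTA headers
#'
#' Inverse of [formatNoszHeader()].
#'
#' @param headers character vector of structured headers.
#' @return data.frame with genome_id, gene_id, clade, secretion,
#'   nosB_offset, nosR_offset.
#' @export
parseNoszHeader <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 6L)) stop("malformed nosZ header")
  dec <- function(x) ifelse(x == ".", NA_integer_, as.integer(x))
  data.frame(
    genome_id = vapply(parts, `[[`, "", 1L),
    gene_id = vapply(parts, `[[`, "", 2L),
    clade = vapply(parts, `[[`, "", 3L),
    secretion = vapply(parts, `[[`, "", 4L),
    nosB_offset = dec(vapply(parts, `[[`, "", 5L)),
    nosR_offset = dec(vapply(parts, `[[`, "", 6L)),
    stringsAsFactors = FALSE)
}
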