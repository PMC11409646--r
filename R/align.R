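## Alignment backends.
##
## Protein: normalized Smith-Waterman scores against a reference panel via
## Biostrings::pairwiseAlignment (BLOSUM62, affine gaps, BLAST-like penalties:
## a gap of length L costs gapOpening + L * gapExtension with open = 11,
## ext = 1). Scores are normalized by the self-alignment score of the
## reference, which for BLOSUM62 (all-positive diagonal) equals the sum of
## diagonal scores over the reference residues, so a query identical to a
## reference scores exactly 1.
##
## DNA: identity and edit distance from the unit-cost global alignment
## computed by utils::adist(counts = TRUE): identity = matches / alignment
## length, where matches = nchar(x) - substitutions - deletions and
## alignment length = matches + substitutions + insertions + deletions.

SW_GAP_OPEN <- 11
SW_GAP_EXT <- 1

.blosum62 <- function() {
  if (is.null(.iupac_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .iupac_env$blosum62 <- e$BLOSUM62
  }
  .iupac_env$blosum62
}

.selfScore <- function(aa_seq) {
  mat <- .blosum62()
  chars <- strsplit(toupper(aa_seq), "")[[1]]
  sum(mat[cbind(chars, chars)])
}

#' Score a protein against a clade reference panel
#'
#' Computes the best local-alignment score of `aa_seq` against every panel
#' member (BLOSUM62, affine gaps) and normalizes each score by the
#' self-alignment score of the respective reference, yielding scores in
#' about \[0, 1\]: 1 for a query identical to a reference, near 0 for
#' unrelated sequences. Deterministic; ties on the best reference are broken
#' by reference id.
#'
#' @param aa_seq amino-acid sequence (case-insensitive).
#' @param panel a [ReferencePanel-class].
#' @return List with `score` (best normalized score), `ref_id` (best
#'   reference), and `scores` (named vector over all panel members).
#' @export
scoreAgainstPanel <- function(aa_seq, panel) {
  stopifnot(is(panel, "ReferencePanel"))
  if (length(panel@sequences) == 0L) stop("empty reference panel")
  aa_seq <- toupper(as.character(aa_seq))
  if (!nzchar(aa_seq)) stop("empty query sequence")
  raw <- Biostrings::pairwiseAlignment(
    pattern = panel@sequences, subject = Biostrings::AAString(aa_seq),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT, scoreOnly = TRUE)
  norm <- pmax(0, raw / panel@selfScores)
  names(norm) <- names(panel@sequences)
  ord <- order(-norm, names(norm))
  list(score = unname(norm[ord[1]]), ref_id = names(norm)[ord[1]],
       scores = norm)
}

## adist-based identity: matches / alignment length of the unit-cost global
## alignment. `a` is a single string, `b` a character vector.
alignmentIdentity <- function(a, b) {
  cnt <- attr(adist(a, b, counts = TRUE), "counts")
  ins <- cnt[1, , "ins"]; del <- cnt[1, , "del"]; sub <- cnt[1, , "sub"]
  matches <- nchar(a) - sub - del
  unname(matches / (matches + sub + ins + del))
}

#' Edit distance between sequences
#'
#' Plain Levenshtein distance (unit costs), as used by the denoising skew
#' criterion.
#'
#' @param a single sequence string.
#' @param b character vector of sequences.
#' @return Integer vector of edit distances.
#' @export
editDistance <- function(a, b) {
  as.integer(adist(a, b))
}
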