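## IUPAC nucleotide ambiguity-code utilities.
## The code table comes from Biostrings::IUPAC_CODE_MAP; a 15x15 logical
## compatibility matrix (sets intersect) is cached at load time for fast
## primer/template scanning.

.iupac_env <- new.env(parent = emptyenv())

.iupacSets <- function() {
  if (is.null(.iupac_env$sets)) {
    map <- Biostrings::IUPAC_CODE_MAP
    .iupac_env$sets <- lapply(map, function(x) strsplit(x, "")[[1]])
    codes <- names(map)
    compat <- matrix(FALSE, length(codes), length(codes),
                     dimnames = list(codes, codes))
    for (a in codes) for (b in codes)
      compat[a, b] <- length(intersect(.iupac_env$sets[[a]],
                                       .iupac_env$sets[[b]])) > 0L
    .iupac_env$compat <- compat
    inv <- vapply(.iupac_env$sets,
                  function(s) paste(sort(s), collapse = ""), "")
    .iupac_env$inverse <- setNames(names(inv), inv)
  }
  .iupac_env
}

#' Expand an IUPAC code to its concrete bases
#'
#' @param code single IUPAC nucleotide code.
#' @return Character vector of the concrete bases (A/C/G/T) the code covers.
#' @export
iupacBases <- function(code) {
  env <- .iupacSets()
  code <- toupper(code)
  if (!code %in% names(env$sets)) stop("invalid IUPAC code: ", code)
  env$sets[[code]]
}

#' IUPAC code covering exactly a set of bases
#'
#' @param bases character vector of concrete bases (A/C/G/T).
#' @return The single IUPAC code whose base set equals `unique(bases)`.
#' @export
iupacCode <- function(bases) {
  env <- .iupacSets()
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- env$inverse[key]
  if (is.na(code)) stop("no IUPAC code for base set: ", key)
  unname(code)
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff their base sets intersect (so N matches everything and
#' R matches A or G but not C/T). Vectorized over both arguments.
#'
#' @param primer_base,template_base IUPAC nucleotide codes.
#' @return Logical vector.
#' @export
iupacMatch <- function(primer_base, template_base) {
  env <- .iupacSets()
  a <- toupper(primer_base); b <- toupper(template_base)
  bad <- setdiff(unique(c(a, b)), rownames(env$compat))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ","))
  env$compat[cbind(a, b)]
}

#' Fold-degeneracy of an IUPAC sequence
#'
#' @param iupac_seq IUPAC nucleotide string.
#' @return Product of per-position base-set cardinalities.
#' @export
iupacFold <- function(iupac_seq) {
  env <- .iupacSets()
  chars <- strsplit(toupper(iupac_seq), "")[[1]]
  bad <- setdiff(chars, names(env$sets))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ","))
  prod(lengths(env$sets[chars]))
}

#' Reverse complement of an IUPAC sequence
#'
#' @param iupac_seq IUPAC nucleotide string.
#' @return Reverse-complemented string (ambiguity codes mapped accordingly).
#' @export
reverseComplementIupac <- function(iupac_seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(iupac_seq))))
}

#' Enumerate all concrete expansions of an IUPAC sequence
#'
#' @param iupac_seq IUPAC nucleotide string.
#' @param max_fold refuse to enumerate beyond this many expansions.
#' @return Character vector of all concrete (A/C/G/T) sequences in the pool.
#' @export
expandIupac <- function(iupac_seq, max_fold = 4096) {
  fold <- iupacFold(iupac_seq)
  if (fold > max_fold)
    stop("fold-degeneracy ", fold, " exceeds max_fold = ", max_fold)
  sets <- lapply(strsplit(toupper(iupac_seq), "")[[1]], iupacBases)
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}
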