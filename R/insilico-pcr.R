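## Mismatch-tolerant, IUPAC-aware in-silico PCR: binding-site scan on both
## strands and convergent-pair amplicon prediction. A degenerate primer's
## mismatch count at a site is the minimum over its concrete expansions,
## which per-position set-intersection matching computes directly.

.primerSeq <- function(primer) {
  if (is(primer, "DegeneratePrimer")) primer@seq else toupper(primer)
}

#' Find primer binding sites on a template
#'
#' Scans both strands of the template; a site qualifies iff its mismatch
#' fraction (mismatches / primer length) is strictly below
#' `max_mismatch_fraction`. Mismatches are counted IUPAC-aware (base sets
#' intersect = match), so a degenerate primer scores as its best-matching
#' pool member. A minus-strand site means the primer anneals to the plus
#' strand in reverse-complement orientation; its coordinates are reported on
#' the plus strand.
#'
#' @param template single template sequence (character or DNAString), or a
#'   named character vector of length 1.
#' @param primer IUPAC primer string or [DegeneratePrimer-class].
#' @param max_mismatch_fraction strict upper bound on the mismatch fraction
#'   (default 0.2, i.e. "< 20% mismatch").
#' @param template_id identifier used in the output.
#' @return data.frame of binding sites: template_id, start (0-based), end
#'   (half-open), strand, mismatches, mismatch_fraction; sorted by start.
#' @export
findBindingSites <- function(template, primer, max_mismatch_fraction = 0.2,
                             template_id = NULL) {
  tseq <- toupper(as.character(template))
  if (is.null(template_id))
    template_id <- if (!is.null(names(template))) names(template)[1] else "template"
  pseq <- .primerSeq(primer)
  k <- nchar(pseq)
  L <- nchar(tseq)
  if (L < k) stop("template shorter than primer")
  env <- .iupacSets()
  tchars <- strsplit(tseq, "")[[1]]
  bad <- setdiff(unique(tchars), rownames(env$compat))
  if (length(bad)) stop("invalid IUPAC code(s) in template: ",
                        paste(bad, collapse = ","))
  scan <- function(primer_chars) {
    S <- L - k + 1L
    ## k x S matrix of template characters under each offset
    idx <- outer(seq_len(k) - 1L, seq_len(S), "+")
    compat <- matrix(env$compat[cbind(rep(primer_chars, S),
                                      tchars[idx])], nrow = k)
    k - colSums(compat)
  }
  pchars <- strsplit(pseq, "")[[1]]
  bad <- setdiff(unique(pchars), rownames(env$compat))
  if (length(bad)) stop("invalid IUPAC code(s) in primer: ",
                        paste(bad, collapse = ","))
  mm_plus <- scan(pchars)
  mm_minus <- scan(strsplit(reverseComplementIupac(pseq), "")[[1]])
  build <- function(mm, strand) {
    hit <- which(mm / k < max_mismatch_fraction)
    if (!length(hit)) return(NULL)
    data.frame(template_id = template_id, start = hit - 1L,
               end = hit - 1L + k, strand = strand,
               mismatches = as.integer(mm[hit]),
               mismatch_fraction = mm[hit] / k, stringsAsFactors = FALSE)
  }
  out <- rbind(build(mm_plus, "+"), build(mm_minus, "-"))
  if (is.null(out))
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), mismatch_fraction = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict PCR products of a primer pair on a template
#'
#' Enumerates convergent binding-site combinations: the forward primer
#' annealing on one strand and the reverse primer on the other, facing each
#' other, with product length (outer site distance) strictly greater than
#' `min_product` (and at most `max_product` if given). Product sequences are
#' reported on the plus strand of the template, so amplifying the
#' reverse-complemented template yields the reverse-complemented products.
#'
#' @param template single template sequence (character or DNAString).
#' @param pair a [PrimerPair-class], or a list with elements `forward` and
#'   `reverse` (IUPAC strings, both 5'->3' as synthesized).
#' @param max_mismatch_fraction strict per-primer mismatch bound.
#' @param min_product product length must exceed this (strict).
#' @param max_product optional upper bound (inclusive).
#' @param template_id identifier used in the output.
#' @return data.frame of predicted amplicons: template_id, strand,
#'   fwd_start, fwd_mismatches, rev_start, rev_mismatches, product_len,
#'   product_seq.
#' @export
amplify <- function(template, pair, max_mismatch_fraction = 0.2,
                    min_product = 1000, max_product = NULL,
                    template_id = NULL) {
  tseq <- toupper(as.character(template))
  if (is.null(template_id))
    template_id <- if (!is.null(names(template))) names(template)[1] else "template"
  fwd <- if (is(pair, "PrimerPair")) pair@forward@seq else .primerSeq(pair$forward)
  rev <- if (is(pair, "PrimerPair")) pair@reverse@seq else .primerSeq(pair$reverse)
  sf <- findBindingSites(tseq, fwd, max_mismatch_fraction, template_id)
  sr <- findBindingSites(tseq, rev, max_mismatch_fraction, template_id)
  out <- list()
  emit <- function(a, b, strand, fwd_site, rev_site) {
    ## a: 5' site on the plus strand, b: 3' site (primer on minus strand);
    ## fwd_site/rev_site are the same two sites attributed to the primers.
    plen <- b$end - a$start
    if (plen <= min_product) return()
    if (!is.null(max_product) && plen > max_product) return()
    ## products are reported on the plus strand of the template; `strand`
    ## records which primer initiates on it
    seq <- substr(tseq, a$start + 1L, b$end)
    out[[length(out) + 1L]] <<- data.frame(
      template_id = template_id, strand = strand,
      fwd_start = fwd_site$start, fwd_mismatches = fwd_site$mismatches,
      rev_start = rev_site$start, rev_mismatches = rev_site$mismatches,
      product_len = plen, product_seq = seq, stringsAsFactors = FALSE)
  }
  fp <- sf[sf$strand == "+", , drop = FALSE]
  rm_ <- sr[sr$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm_)))
    if (fp$start[i] < rm_$start[j])
      emit(fp[i, ], rm_[j, ], "+", fp[i, ], rm_[j, ])
  rp <- sr[sr$strand == "+", , drop = FALSE]
  fm <- sf[sf$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(rp))) for (j in seq_len(nrow(fm)))
    if (rp$start[i] < fm$start[j])
      emit(rp[i, ], fm[j, ], "-", fm[j, ], rp[i, ])
  if (!length(out))
    return(data.frame(template_id = character(), strand = character(),
                      fwd_start = integer(), fwd_mismatches = integer(),
                      rev_start = integer(), rev_mismatches = integer(),
                      product_len = integer(), product_seq = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$fwd_start, res$rev_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
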