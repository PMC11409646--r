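## Degenerate primer design on subclade alignments: distance-based subclade
## clustering, per-window IUPAC consensus, GC-count Tm model, and
## constraint-filtered forward/reverse pairing.

.asCharVec <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  toupper(unname(seqs))
}

#' Pairwise distance matrix of nucleotide sequences
#'
#' Distance = 1 - identity, where identity is matches / alignment length of
#' the unit-cost global alignment. Symmetric with a zero diagonal.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] (>= 2).
#' @return Symmetric numeric matrix of distances in \[0, 1\].
#' @export
pairwiseDistanceMatrix <- function(seqs) {
  x <- .asCharVec(seqs)
  if (length(x) < 2L) stop("need at least 2 sequences")
  n <- length(x)
  D <- matrix(0, n, n)
  if (!is.null(names(seqs))) dimnames(D) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1L)) {
    ident <- alignmentIdentity(x[i], x[(i + 1L):n])
    D[i, (i + 1L):n] <- 1 - ident
    D[(i + 1L):n, i] <- 1 - ident
  }
  D
}

#' Cluster sequences into subclades
#'
#' Average-linkage agglomerative clustering on the pairwise distance matrix,
#' cut at the given height. Deterministic.
#'
#' @param seqs character vector or DNAStringSet (>= 2).
#' @param distance_threshold cut height in distance units (0..1).
#' @return List of integer index vectors, one per subclade, ordered by the
#'   lowest member index.
#' @export
clusterSubclades <- function(seqs, distance_threshold) {
  D <- pairwiseDistanceMatrix(seqs)
  hc <- hclust(stats::as.dist(D), method = "average")
  k <- cutree(hc, h = distance_threshold)
  groups <- split(seq_along(k), k)
  groups <- groups[order(vapply(groups, min, 0L))]
  unname(groups)
}

#' Melting temperature interval of an IUPAC primer
#'
#' GC-count linear model Tm = 64.9 + 41 * (nGC - 16.4) / L, evaluated at the
#' minimum-GC and maximum-GC concrete expansions of the degenerate sequence
#' (both extremes are attained by actual pool members).
#'
#' @param iupac_seq primer sequence (length >= 14).
#' @return Numeric `c(tm_min, tm_max)` in deg C.
#' @export
primerTm <- function(iupac_seq) {
  chars <- strsplit(toupper(iupac_seq), "")[[1]]
  L <- length(chars)
  if (L < 14L) stop("primer shorter than 14 nt")
  sets <- lapply(chars, iupacBases)
  minGC <- sum(vapply(sets, function(s) all(s %in% c("G", "C")), TRUE))
  maxGC <- sum(vapply(sets, function(s) any(s %in% c("G", "C")), TRUE))
  tm <- function(n) 64.9 + 41 * (n - 16.4) / L
  c(tm(minGC), tm(maxGC))
}

.gcRangeIupac <- function(chars) {
  sets <- lapply(chars, iupacBases)
  minGC <- sum(vapply(sets, function(s) all(s %in% c("G", "C")), TRUE))
  maxGC <- sum(vapply(sets, function(s) any(s %in% c("G", "C")), TRUE))
  c(minGC, maxGC) / length(chars)
}

#' Degenerate IUPAC consensus of an alignment window
#'
#' Per column, the IUPAC code covering exactly the observed bases, so every
#' input row matches the consensus with zero mismatches. Windows containing
#' gap characters are rejected.
#'
#' @param msa_window character vector of equal-length gapless strings.
#' @param aln_start 0-based alignment column of the window start.
#' @return A [DegeneratePrimer-class].
#' @export
degenerateConsensus <- function(msa_window, aln_start = 0L) {
  rows <- .asCharVec(msa_window)
  if (length(unique(nchar(rows))) != 1L)
    stop("window rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, ""))
  if (any(mat %in% c("-", ".")))
    stop("gap character in window; window rejected")
  cons <- apply(mat, 2L, function(col) iupacCode(col))
  chars <- unname(cons)
  seq <- paste(chars, collapse = "")
  fold <- prod(vapply(chars, function(b) length(iupacBases(b)), 0))
  tm <- if (length(chars) >= 14L) primerTm(seq) else c(NA_real_, NA_real_)
  new("DegeneratePrimer", seq = seq, alnStart = as.integer(aln_start),
      fold = fold, tmRange = tm, gcRange = .gcRangeIupac(chars))
}

## Count mismatches of an IUPAC primer against aligned member rows (same
## columns). Used for the max-mismatch constraint.
.memberMismatches <- function(primer_chars, mat) {
  apply(mat, 1L, function(row) sum(!iupacMatch(primer_chars, row)))
}

#' Design clade-specific degenerate primer pairs on a subclade alignment
#'
#' Slides windows of `lenMin..lenMax` nt over gapless alignment columns;
#' keeps windows whose degenerate consensus satisfies the fold-degeneracy,
#' GC and Tm constraints and matches every subclade member with at most
#' `maxMismatch` mismatches; pairs forward windows with downstream reverse
#' windows (reverse primer = reverse complement of the window consensus)
#' whose template span exceeds `minProduct` nt in every member; ranks pairs
#' by (total fold ascending, total Tm-interval width ascending, minimum
#' product length descending).
#'
#' @param subclade_msa aligned nucleotide sequences (character vector or
#'   DNAStringSet; equal lengths, "-" for gaps).
#' @param constraints a [DesignConstraints-class].
#' @param subclade_id identifier stored in the returned pairs.
#' @param max_windows cap on candidate windows entering the pairing stage
#'   (best-ranked kept).
#' @param max_pairs cap on returned pairs.
#' @return List of [PrimerPair-class], ranked; empty list with a
#'   `diagnostic` attribute naming the binding constraint when no valid pair
#'   exists.
#' @export
designPrimers <- function(subclade_msa, constraints = designConstraints(),
                          subclade_id = "subclade", max_windows = 300L,
                          max_pairs = 50L) {
  rows <- .asCharVec(subclade_msa)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length")
  rows <- sort(rows)  # row-order invariance
  mat <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(mat)
  colsets <- apply(mat, 2L, function(col) sort(unique(col)), simplify = FALSE)
  has_gap <- vapply(colsets, function(s) any(s %in% c("-", ".")), TRUE)
  card <- vapply(colsets, length, 0L)
  col_minGC <- vapply(colsets, function(s) all(s %in% c("G", "C")), TRUE)
  col_maxGC <- vapply(colsets, function(s) any(s %in% c("G", "C")), TRUE)
  eliminated <- c(gap = 0L, fold = 0L, gc = 0L, tm = 0L, mismatch = 0L)
  windows <- list()
  for (len in seq(constraints@lenMin, constraints@lenMax)) {
    if (len > L) next
    for (start in seq_len(L - len + 1L)) {
      cols <- start:(start + len - 1L)
      if (any(has_gap[cols])) { eliminated["gap"] <- eliminated["gap"] + 1L; next }
      fold <- prod(card[cols])
      if (fold > constraints@maxDegeneracy) {
        eliminated["fold"] <- eliminated["fold"] + 1L; next }
      gc <- c(sum(col_minGC[cols]), sum(col_maxGC[cols])) / len
      if (gc[1] < constraints@gcMin || gc[2] > constraints@gcMax) {
        eliminated["gc"] <- eliminated["gc"] + 1L; next }
      nGC <- c(sum(col_minGC[cols]), sum(col_maxGC[cols]))
      tm <- 64.9 + 41 * (nGC - 16.4) / len
      if (tm[1] < constraints@tmMin || tm[2] > constraints@tmMax) {
        eliminated["tm"] <- eliminated["tm"] + 1L; next }
      cons <- vapply(colsets[cols], iupacCode, "")
      mism <- .memberMismatches(cons, mat[, cols, drop = FALSE])
      if (max(mism) > constraints@maxMismatch) {
        eliminated["mismatch"] <- eliminated["mismatch"] + 1L; next }
      windows[[length(windows) + 1L]] <- list(
        start = start, len = len, seq = paste(cons, collapse = ""),
        fold = fold, tm = tm, gc = gc)
    }
  }
  emptyResult <- function() {
    res <- list()
    binding <- names(eliminated)[which.max(eliminated)]
    attr(res, "diagnostic") <- sprintf(
      "no valid primer pair; most windows eliminated by the '%s' filter (%s)",
      binding,
      paste(sprintf("%s=%d", names(eliminated), eliminated), collapse = ", "))
    res
  }
  if (!length(windows)) return(emptyResult())
  wdf <- data.frame(
    start = vapply(windows, `[[`, 0, "start"),
    len = vapply(windows, `[[`, 0, "len"),
    fold = vapply(windows, `[[`, 0, "fold"),
    tmw = vapply(windows, function(w) diff(w$tm), 0))
  ## two candidate pools so that both template ends stay represented:
  ## forward primers prefer early windows, reverse primers late windows
  half <- max_windows %/% 2L
  fwd_keep <- head(order(wdf$fold, wdf$tmw, wdf$start, wdf$len), half)
  rev_keep <- head(order(wdf$fold, wdf$tmw, -wdf$start, wdf$len), half)
  ## per-member cumulative non-gap counts: ungapped template span lookup
  nongap <- apply(mat != "-" & mat != ".", 1L, cumsum)  # L x n_members
  spanLen <- function(c1, c2) nongap[c2, ] - if (c1 > 1L) nongap[c1 - 1L, ] else 0
  pairs <- list()
  for (i in fwd_keep) {
    wf <- windows[[i]]
    for (j in rev_keep) {
      wr <- windows[[j]]
      if (wr$start <= wf$start + wf$len - 1L) next
      span <- spanLen(wf$start, wr$start + wr$len - 1L)
      if (min(span) <= constraints@minProduct) next
      pairs[[length(pairs) + 1L]] <- list(f = wf, r = wr, span = span)
    }
  }
  if (!length(pairs)) {
    eliminated["product_span"] <- length(windows)^2L
    return(emptyResult())
  }
  key <- data.frame(
    fold = vapply(pairs, function(p) p$f$fold * p$r$fold, 0),
    tmw = vapply(pairs, function(p) diff(p$f$tm) + diff(p$r$tm), 0),
    prod = vapply(pairs, function(p) min(p$span), 0))
  ord <- order(key$fold, key$tmw, -key$prod,
               vapply(pairs, function(p) p$f$start, 0),
               vapply(pairs, function(p) p$r$start, 0))
  pairs <- pairs[head(ord, max_pairs)]
  lapply(pairs, function(p) {
    fwd <- new("DegeneratePrimer", seq = p$f$seq,
               alnStart = as.integer(p$f$start - 1L), fold = p$f$fold,
               tmRange = p$f$tm, gcRange = p$f$gc)
    rseq <- reverseComplementIupac(p$r$seq)
    rev <- new("DegeneratePrimer", seq = rseq,
               alnStart = as.integer(p$r$start - 1L), fold = p$r$fold,
               tmRange = p$r$tm, gcRange = p$r$gc)
    new("PrimerPair", forward = fwd, reverse = rev,
        productRange = range(p$span), subcladeId = subclade_id)
  })
}

#' Primer pairs as a table
#'
#' @param pairs list of [PrimerPair-class] from [designPrimers()].
#' @return data.frame mirroring a primer supplementary table: name, forward
#'   and reverse sequence 5'->3', degeneracy, Tm ranges, predicted product
#'   range and target subclade.
#' @export
primerTable <- function(pairs) {
  if (!length(pairs))
    return(data.frame(name = character(), forward = character(),
                      reverse = character(), fold = numeric(),
                      tm_min = numeric(), tm_max = numeric(),
                      product_min = numeric(), product_max = numeric(),
                      subclade = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(name = sprintf("pair_%02d", i), forward = p@forward@seq,
               reverse = p@reverse@seq,
               fold = p@forward@fold * p@reverse@fold,
               tm_min = min(p@forward@tmRange[1], p@reverse@tmRange[1]),
               tm_max = max(p@forward@tmRange[2], p@reverse@tmRange[2]),
               product_min = p@productRange[1],
               product_max = p@productRange[2],
               subclade = p@subcladeId, stringsAsFactors = FALSE)
  }))
}
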