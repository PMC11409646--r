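## Long-read amplicon pipeline: quality/length filtering, UNOISE-style
## greedy denoising into OTUs, consensus taxonomy against a
## lineage-annotated reference database, unassigned export.

#' Read amplicon reads from FASTQ
#'
#' @param fastq_path demultiplexed, adapter-trimmed FASTQ.
#' @return data.frame with read_id, seq, mean_q (mean per-base Phred score)
#'   and length.
#' @export
readAmpliconFastq <- function(fastq_path) {
  x <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  mean_q <- vapply(as(Biostrings::PhredQuality(q), "IntegerList"), mean, 0)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x), mean_q = mean_q,
             length = Biostrings::width(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter reads by length and mean quality
#'
#' Keeps reads with `min_len <= length <= max_len` (inclusive) and mean
#' Phred quality strictly greater than `min_q`; reads without a quality are
#' kept if their length passes.
#'
#' @param reads data.frame with columns seq, optionally mean_q and length.
#' @param min_len,max_len inclusive length bounds (defaults 800, 2500 nt).
#' @param min_q strict lower bound on mean Phred quality (default 7).
#' @return The filtered data.frame.
#' @export
filterReads <- function(reads, min_len = 800, max_len = 2500, min_q = 7) {
  if (is.null(reads$length)) reads$length <- nchar(reads$seq)
  len_ok <- reads$length >= min_len & reads$length <= max_len
  q <- if (is.null(reads$mean_q)) rep(NA_real_, nrow(reads)) else reads$mean_q
  q_ok <- is.na(q) | q > min_q
  out <- reads[len_ok & q_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Denoise and cluster reads into OTUs
#'
#' Emulation of greedy abundance-ranked denoising with the published
#' abundance-skew criterion: reads are dereplicated (identical sequences
#' pooled with summed abundance), unique sequences are processed in
#' descending (abundance, length, sequence) order, and a sequence merges
#' into the first existing centroid for which its global-alignment identity
#' is at least `id_threshold` AND its abundance ratio a/A satisfies
#' a/A <= beta(d) = 1 / 2^(alpha * d + 1), where d is the edit distance to
#' the centroid; otherwise it founds a new centroid (minimum founding
#' abundance 1). Deterministic and invariant to input read order.
#'
#' @param reads data.frame with columns read_id and seq (e.g. from
#'   [filterReads()]), or a character vector of sequences.
#' @param alpha skew steepness (default 2).
#' @param id_threshold minimum identity for merging (default 0.97).
#' @return data.frame with otu_id, centroid_seq, abundance and a list-column
#'   member_ids; the centroid is always a member. Total abundance equals the
#'   number of input reads.
#' @export
denoiseCluster <- function(reads, alpha = 2.0, id_threshold = 0.97) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  empty <- data.frame(otu_id = character(), centroid_seq = character(),
                      abundance = integer(), stringsAsFactors = FALSE)
  empty$member_ids <- list()
  if (nrow(reads) == 0L) return(empty)
  derep <- split(reads$read_id, reads$seq)
  useq <- names(derep)
  ab <- lengths(derep)
  ord <- order(-ab, -nchar(useq), -xtfrm(useq))
  useq <- useq[ord]; ab <- unname(ab[ord]); derep <- derep[ord]
  cent_seq <- character(); cent_ab <- integer(); cent_members <- list()
  max_len <- max(nchar(useq))
  for (u in seq_along(useq)) {
    merged <- FALSE
    for (ci in seq_along(cent_seq)) {
      ## abundance skew bound: merging needs d <= d_max; d >= 1 always here
      d_max <- (log2(cent_ab[ci] / ab[u]) - 1) / alpha
      if (d_max < 1) next
      if (abs(nchar(useq[u]) - nchar(cent_seq[ci])) >
          (1 - id_threshold) * max_len) next
      d <- editDistance(useq[u], cent_seq[ci])
      if (d > d_max) next
      if (alignmentIdentity(useq[u], cent_seq[ci]) < id_threshold) next
      cent_ab[ci] <- cent_ab[ci] + ab[u]
      cent_members[[ci]] <- c(cent_members[[ci]], derep[[u]])
      merged <- TRUE
      break
    }
    if (!merged) {
      cent_seq <- c(cent_seq, useq[u])
      cent_ab <- c(cent_ab, ab[u])
      cent_members[[length(cent_seq)]] <- derep[[u]]
    }
  }
  out <- data.frame(otu_id = sprintf("OTU_%04d", seq_along(cent_seq)),
                    centroid_seq = cent_seq, abundance = cent_ab,
                    stringsAsFactors = FALSE)
  out$member_ids <- cent_members
  out
}

#' Read a lineage-annotated taxonomy database from FASTA
#'
#' Headers carry the lineage after the id:
#' `id lineage=d__...;p__...;c__...;o__...;f__...;g__...` (a trailing
#' `s__...` species field is accepted; missing trailing ranks are stored as
#' "").
#'
#' @param fasta_path reference FASTA.
#' @return data.frame with id, seq and one column per rank (domain..species).
#' @export
readTaxonomyDatabase <- function(fasta_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(x))
  lin_str <- sub("^\\S+\\s*", "", names(x))
  ranks <- parseLineageStrings(lin_str, ids)
  cbind(data.frame(id = ids, seq = as.character(x), stringsAsFactors = FALSE,
                   row.names = NULL), ranks)
}

## parse "lineage=d__X;p__Y;..." strings into a 7-rank data.frame
parseLineageStrings <- function(lin_str, ids) {
  prefixes <- c("d", "p", "c", "o", "f", "g", "s")
  out <- matrix("", length(lin_str), 7L,
                dimnames = list(NULL, LINEAGE_RANKS))
  for (i in seq_along(lin_str)) {
    s <- sub("^lineage=", "", lin_str[i])
    if (!nzchar(s) || s == lin_str[i] && !grepl("__", s))
      stop("malformed lineage for entry '", ids[i], "': ", lin_str[i])
    fields <- strsplit(s, ";", fixed = TRUE)[[1]]
    for (f in fields) {
      m <- regmatches(f, regexec("^([dpcofgs])__(.*)$", f))[[1]]
      if (length(m) != 3L)
        stop("malformed lineage field '", f, "' for entry '", ids[i], "'")
      out[i, match(m[2], prefixes)] <- m[3]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

## format rank values back into a d__..;p__.. string (empty ranks dropped)
formatLineage <- function(ranks) {
  prefixes <- c("d", "p", "c", "o", "f", "g", "s")
  keep <- nzchar(ranks)
  paste(sprintf("%s__%s", prefixes[keep], ranks[keep]), collapse = ";")
}

#' Consensus taxonomy assignment of OTU centroids
#'
#' For each centroid, takes the up-to-`max_accepts` best hits with identity
#' at least `min_identity` against the reference database, then walks the
#' ranks from domain downward keeping the value shared by at least
#' `consensus_fraction` of the hits, truncating at the first rank without
#' consensus. Centroids with zero accepted hits are `unassigned`.
#'
#' @param otus OTU data.frame from [denoiseCluster()].
#' @param ref_db reference data.frame from [readTaxonomyDatabase()].
#' @param min_identity minimum global-alignment identity for a hit
#'   (default 0.8).
#' @param max_accepts maximum hits used per centroid (default 10).
#' @param consensus_fraction minimum agreeing fraction per rank
#'   (default 0.51).
#' @return data.frame with otu_id, the 7 rank columns, lineage (formatted
#'   string), top_identity, n_hits_used and status (assigned/unassigned).
#' @export
classifyConsensus <- function(otus, ref_db, min_identity = 0.8,
                              max_accepts = 10, consensus_fraction = 0.51) {
  stopifnot(all(c("id", "seq") %in% names(ref_db)),
            all(LINEAGE_RANKS %in% names(ref_db)))
  res <- lapply(seq_len(nrow(otus)), function(i) {
    ident <- alignmentIdentity(otus$centroid_seq[i], ref_db$seq)
    ord <- order(-ident, ref_db$id)
    acc <- ord[ident[ord] >= min_identity]
    acc <- head(acc, max_accepts)
    ranks <- setNames(rep("", 7L), LINEAGE_RANKS)
    status <- "unassigned"; top <- NA_real_
    if (length(acc)) {
      top <- max(ident[acc])
      for (r in LINEAGE_RANKS) {
        vals <- ref_db[[r]][acc]
        vals <- vals[nzchar(vals)]
        if (!length(vals)) break
        tab <- sort(table(vals), decreasing = TRUE)
        if (tab[1] / length(acc) >= consensus_fraction)
          ranks[r] <- names(tab)[1]
        else break
      }
      if (nzchar(ranks["domain"])) status <- "assigned"
    }
    out <- data.frame(otu_id = otus$otu_id[i], stringsAsFactors = FALSE)
    for (r in LINEAGE_RANKS) out[[r]] <- unname(ranks[r])
    out$lineage <- formatLineage(ranks)
    out$top_identity <- top
    out$n_hits_used <- length(acc)
    out$status <- status
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export unassigned OTU centroids to FASTA
#'
#' Writes the centroids whose consensus classification failed (status
#' `unassigned`) for external follow-up; an empty assignment set yields an
#' empty file.
#'
#' @param assignments data.frame from [classifyConsensus()].
#' @param otus OTU data.frame from [denoiseCluster()].
#' @param path output FASTA path.
#' @return Invisibly, the character vector of exported otu_ids.
#' @export
reportUnassigned <- function(assignments, otus, path) {
  un <- assignments$otu_id[assignments$status == "unassigned"]
  keep <- otus[otus$otu_id %in% un, , drop = FALSE]
  seqs <- setNames(Biostrings::DNAStringSet(keep$centroid_seq), keep$otu_id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(keep$otu_id)
}
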