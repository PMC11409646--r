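## Synthetic long-read simulator: substitution + indel errors at controlled
## rates, per-read mean quality, optional 3' truncation. Deterministic given
## the seed; realism (homopolymer bias etc.) is out of scope.

.mutateRead <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  sub_at <- which(runif(n) < sub_rate)
  for (k in sub_at)
    chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
  if (indel_rate > 0) {
    r <- runif(n)
    dels <- r < indel_rate / 2
    ins <- r >= indel_rate / 2 & r < indel_rate
    out <- character(0)
    for (k in seq_len(n)) {
      if (ins[k]) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
      if (!dels[k]) out <- c(out, chars[k])
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Simulate error-bearing amplicon reads from templates
#'
#' Per read: substitutions at `sub_rate` and insertions/deletions at
#' `indel_rate` (split evenly), an optional 3' truncation with probability
#' `trunc_prob` (retaining a uniform 50-95% of the read), and a mean Phred
#' quality drawn from a normal model. Deterministic given the seed.
#'
#' @param templates named character vector of template sequences.
#' @param n_reads reads per template.
#' @param sub_rate,indel_rate per-base error rates (each in \[0, 0.3\]).
#' @param seed RNG seed.
#' @param mean_q_mean,mean_q_sd normal model for per-read mean quality.
#' @param trunc_prob probability a read is 3'-truncated (default 0).
#' @return data.frame with read_id, template_id, seq, mean_q, length.
#' @export
simulateReads <- function(templates, n_reads, sub_rate = 0.0,
                          indel_rate = 0.0, seed = 1L, mean_q_mean = 12,
                          mean_q_sd = 2, trunc_prob = 0) {
  stopifnot(length(templates) > 0, sub_rate >= 0, sub_rate <= 0.3,
            indel_rate >= 0, indel_rate <= 0.3)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  if (n_reads == 0L)
    return(data.frame(read_id = character(), template_id = character(),
                      seq = character(), mean_q = numeric(),
                      length = integer(), stringsAsFactors = FALSE))
  withSeed(seed, {
    rows <- list()
    for (t in names(templates)) {
      for (i in seq_len(n_reads)) {
        seq <- .mutateRead(toupper(templates[[t]]), sub_rate, indel_rate)
        if (trunc_prob > 0 && runif(1) < trunc_prob)
          seq <- substr(seq, 1L, ceiling(nchar(seq) * runif(1, 0.5, 0.95)))
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_read%04d", t, i), template_id = t,
          seq = seq, mean_q = round(rnorm(1, mean_q_mean, mean_q_sd), 1),
          length = nchar(seq), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write simulated reads to FASTQ
#'
#' Per-base qualities are constant at the read's (rounded) mean quality.
#'
#' @param reads data.frame from [simulateReads()].
#' @param path output FASTQ path.
#' @return Invisibly, `path`.
#' @export
writeReadsFastq <- function(reads, path) {
  seqs <- setNames(Biostrings::DNAStringSet(reads$seq), reads$read_id)
  q <- vapply(seq_len(nrow(reads)), function(i) {
    ch <- rawToChar(as.raw(33L + max(0L, min(41L, round(reads$mean_q[i])))))
    strrep(ch, reads$length[i])
  }, "")
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(q))
  invisible(path)
}
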