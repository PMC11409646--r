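## Independent oracles and small fixture builders used across the suite.

.blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## Quadratic Gotoh local-alignment DP, written independently of the package
## path (affine gaps: a gap of length L costs open + L * ext).
swGotohOracle <- function(a, b, open = 11, ext = 1) {
  mat <- .blosum62_test
  A <- match(strsplit(a, "")[[1]], rownames(mat))
  B <- match(strsplit(b, "")[[1]], rownames(mat))
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    ai <- A[i - 1]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      h <- H[i - 1, j - 1] + mat[ai, B[j - 1]]
      H[i, j] <- max(0, h, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## Brute-force binding-site oracle: enumerate every concrete expansion of
## the IUPAC primer (own expansion code), slide it literally over both
## strands, and take the minimum mismatch count per offset.
expandIupacOracle <- function(iupac) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- lapply(strsplit(toupper(iupac), "")[[1]],
                 function(b) strsplit(map[[b]], "")[[1]])
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

revcompOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

bruteBindingSites <- function(template, primer, max_mm_frac = 0.2) {
  k <- nchar(primer)
  tchars <- strsplit(toupper(template), "")[[1]]
  scan1 <- function(p) {
    exps <- lapply(expandIupacOracle(p), function(e) strsplit(e, "")[[1]])
    vapply(seq_len(length(tchars) - k + 1L), function(s) {
      win <- tchars[s:(s + k - 1L)]
      min(vapply(exps, function(e) sum(e != win), 0L))
    }, 0L)
  }
  rows <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else revcompOracle(primer)
    mm <- scan1(p)
    hit <- which(mm / k < max_mm_frac)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        start = hit - 1L, strand = strand, mismatches = mm[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

## substitute-only nucleotide mutator (independent of the generator)
mutateNtTest <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  i <- which(runif(length(ch)) < rate)
  for (k in i) ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1L)
  paste(ch, collapse = "")
}

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

randomAa <- function(n) {
  paste(sample(rownames(.blosum62_test)[1:20], n, replace = TRUE),
        collapse = "")
}

## Build a one-contig GenomeAnnotation from a vector of label sets; gene k
## gets a 100-aa dummy protein and sequential coordinates.
toyGenome <- function(label_sets, genome_id = "toy", aa_len = 100,
                      lineage = rep("", 7)) {
  n <- length(label_sets)
  aa <- vapply(seq_len(n), function(i) {
    set.seed(1000 + i); randomAa(aa_len)
  }, "")
  nt <- vapply(aa, noszpipe::backTranslate, "")
  start <- cumsum(c(1L, rep(nchar(nt[1]) + 50L, n - 1L)))
  genes <- data.frame(
    gene_id = sprintf("%s_g%02d", genome_id, seq_len(n)),
    contig_id = "c1", index = 0L, start = start,
    end = start + nchar(nt) - 1L, strand = "+",
    nt_seq = unname(nt), aa_seq = aa, stringsAsFactors = FALSE)
  genes$labels <- lapply(label_sets, as.character)
  makeGenomeAnnotation(genome_id, lineage, genes)
}
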