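## Distances, subclade clustering, degenerate consensus, Tm model and the
## constraint-filtered primer designer.

test_that("pairwise distances are 1 - identity, symmetric, zero-diagonal", {
  a <- strrep("ACGT", 25)
  expect_equal(pairwiseDistanceMatrix(c(a, a))[1, 2], 0)
  b <- a
  substr(b, 1, 1) <- "T"; substr(b, 11, 11) <- "A"; substr(b, 21, 21) <- "C"
  substr(b, 31, 31) <- "C"; substr(b, 41, 41) <- "T"
  D <- pairwiseDistanceMatrix(c(a, b))        # 5 of 100 columns differ
  expect_equal(D[1, 2], 0.05)
  set.seed(4)
  seqs <- vapply(1:5, function(i) randomDna(80), "")
  D <- pairwiseDistanceMatrix(seqs)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 5))
  expect_error(pairwiseDistanceMatrix("ACGT"), "at least 2")
})

test_that("average-linkage clustering separates families at the threshold", {
  set.seed(8)
  anc1 <- randomDna(300)
  anc2 <- mutateNtTest(anc1, 0.4)             # ~40% inter-family distance
  fam1 <- vapply(1:4, function(i) mutateNtTest(anc1, 0.03), "")
  fam2 <- vapply(1:4, function(i) mutateNtTest(anc2, 0.03), "")
  cl <- clusterSubclades(c(fam1, fam2), 0.2)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]], 1:4)
  expect_setequal(cl[[2]], 5:8)
  expect_length(clusterSubclades(rep(anc1, 3), 0.2), 1L)   # all identical
  expect_length(clusterSubclades(c(fam1, fam2), 1.0), 1L)  # maximal cut
})

test_that("degenerate consensus covers exactly the observed bases", {
  p <- degenerateConsensus(c("ACGT", "ACGT"))
  expect_equal(p@seq, "ACGT"); expect_equal(p@fold, 1)
  p <- degenerateConsensus(c("ACGA", "ACGC", "ACGG"))
  expect_equal(p@seq, "ACGV"); expect_equal(p@fold, 3)
  p <- degenerateConsensus(c("AAAA", "TTTT"))
  expect_equal(p@seq, "WWWW"); expect_equal(p@fold, 16)
  expect_error(degenerateConsensus(c("AC-T", "ACGT")), "gap")
  ## every input row matches the consensus with zero mismatches
  set.seed(12)
  rows <- vapply(1:4, function(i) randomDna(20), "")
  cons <- strsplit(degenerateConsensus(rows)@seq, "")[[1]]
  for (r in rows)
    expect_equal(sum(!iupacMatch(cons, strsplit(r, "")[[1]])), 0L)
})

test_that("the GC-count Tm model matches its closed form", {
  expect_equal(primerTm(paste0(strrep("AT", 5), strrep("GC", 5)))[1],
               64.9 + 41 * (10 - 16.4) / 20)  # 51.78
  expect_equal(unique(primerTm(strrep("G", 20))), 72.28)
  ## one GC-ambiguous position (R = A/G) widens the interval by 41/L
  tm <- primerTm("ACGTACGTACGTACGTACGR")
  expect_equal(diff(tm), 41 / 20)
  ## S = G/C is unambiguously GC, so the interval stays a point
  tmS <- primerTm("ACGTACGTACGTACGTACGS")
  expect_equal(diff(tmS), 0)
  expect_error(primerTm("ACGTACGTACGT"), "14")
})

test_that("Tm interval endpoints are attained by concrete expansions", {
  set.seed(19)
  for (rep in 1:5) {
    base <- randomDna(18)
    i <- sample(18, 2)
    ch <- strsplit(base, "")[[1]]
    ch[i] <- sample(c("R", "Y", "S", "W", "N"), 2, replace = TRUE)
    pr <- paste(ch, collapse = "")
    if (iupacFold(pr) > 64) next
    tm_exp <- vapply(expandIupac(pr), function(e) primerTm(e)[1], 0)
    expect_equal(range(tm_exp), primerTm(pr))
  }
})

designFixture <- function(n_members = 3, len = 1300, div = 0) {
  set.seed(77)
  anc <- randomDna(len, gc = 0.5)
  vapply(seq_len(n_members), function(i) mutateNtTest(anc, div), "")
}

test_that("valid templates yield ranked constraint-satisfying pairs", {
  msa <- designFixture()
  pairs <- designPrimers(msa)
  expect_gt(length(pairs), 0L)
  cs <- designConstraints()
  for (p in pairs[seq_len(min(3, length(pairs)))]) {
    for (pr in list(p@forward, p@reverse)) {
      expect_lte(pr@fold, cs@maxDegeneracy)
      expect_gte(pr@tmRange[1], cs@tmMin); expect_lte(pr@tmRange[2], cs@tmMax)
      expect_gte(pr@gcRange[1], cs@gcMin); expect_lte(pr@gcRange[2], cs@gcMax)
    }
    expect_gt(p@productRange[1], cs@minProduct)
  }
  ## ranking: non-decreasing total fold
  folds <- vapply(pairs, function(p) p@forward@fold * p@reverse@fold, 0)
  expect_true(all(diff(folds) >= 0))
})

test_that("short templates cannot satisfy the product-length constraint", {
  msa <- designFixture(len = 900)   # no window pair can span > 1000 nt
  pairs <- designPrimers(msa)
  expect_length(pairs, 0L)
  expect_match(attr(pairs, "diagnostic"), "product_span|no valid")
})

test_that("high-fold windows are excluded and rows may permute freely", {
  msa <- designFixture(n_members = 4, div = 0.01)
  p1 <- primerTable(designPrimers(msa))
  p2 <- primerTable(designPrimers(rev(msa)))
  expect_equal(p1, p2)
  ## windows with fold 16 can never appear
  folds <- c(p1$fold)
  expect_true(all(folds <= designConstraints()@maxDegeneracy^2))
})
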