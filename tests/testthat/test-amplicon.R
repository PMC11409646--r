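## Read filtering, UNOISE-style denoising and consensus taxonomy.

mkReads <- function(seqs, ids = NULL, mean_q = NULL) {
  d <- data.frame(read_id = if (is.null(ids)) sprintf("r%d", seq_along(seqs))
                  else ids,
                  seq = seqs, stringsAsFactors = FALSE)
  if (!is.null(mean_q)) d$mean_q <- mean_q
  d$length <- nchar(d$seq)
  d
}

test_that("read filtering uses inclusive length bounds and strict quality", {
  set.seed(1)
  reads <- mkReads(c(randomDna(800), randomDna(799), randomDna(2500),
                     randomDna(2501), randomDna(1000), randomDna(1000)),
                   mean_q = c(8, 20, 8, 20, 7.0, 7.1))
  out <- filterReads(reads)
  expect_equal(out$read_id, c("r1", "r3", "r6"))
  ## reads without quality are kept on length alone
  out2 <- filterReads(mkReads(c(randomDna(900), randomDna(100))))
  expect_equal(nrow(out2), 1L)
})

test_that("dereplication pools identical reads into one OTU", {
  reads <- mkReads(rep(strrep("ACGT", 50), 10))
  otus <- denoiseCluster(reads)
  expect_equal(nrow(otus), 1L)
  expect_equal(otus$abundance, 10L)
  expect_length(otus$member_ids[[1]], 10L)
  expect_equal(nrow(denoiseCluster(mkReads(character()))), 0L)
})

test_that("the abundance-skew criterion decides merge vs new centroid", {
  base <- strrep("ACGTTGCA", 25)           # 200 nt
  variant <- base; substr(variant, 51, 51) <- "C"   # d = 1 (G -> C)
  ## beta(1) = 1/2^(2*1+1) = 0.125: ratio 10/100 merges
  reads <- mkReads(c(rep(base, 100), rep(variant, 10)))
  otus <- denoiseCluster(reads)
  expect_equal(nrow(otus), 1L)
  expect_equal(otus$abundance, 110L)
  expect_equal(otus$centroid_seq, base)
  ## ratio 20/100 = 0.20 > 0.125 founds a second OTU
  reads2 <- mkReads(c(rep(base, 100), rep(variant, 20)))
  otus2 <- denoiseCluster(reads2)
  expect_equal(nrow(otus2), 2L)
  expect_setequal(otus2$abundance, c(100L, 20L))
})

test_that("identity gates merging even when the skew test passes", {
  base <- strrep("ACGTTGCAGT", 5)                  # 50 nt
  v1 <- base; substr(v1, 10, 10) <- "A"            # d = 1, identity 0.98
  v2 <- v1;   substr(v2, 25, 25) <- "A"            # d = 2, identity 0.96
  ## both skew ratios 1/500 pass beta; only the d=1 variant may merge
  otus1 <- denoiseCluster(mkReads(c(rep(base, 500), v1)))
  expect_equal(nrow(otus1), 1L)
  otus2 <- denoiseCluster(mkReads(c(rep(base, 500), v2)))
  expect_equal(nrow(otus2), 2L)
})

test_that("clustering conserves abundance and ignores read order", {
  set.seed(44)
  base <- randomDna(300)
  pool <- c(rep(base, 30),
            vapply(1:15, function(i) mutateNtTest(base, 0.01), ""),
            vapply(1:5, function(i) randomDna(300), ""))
  reads <- mkReads(pool)
  otus <- denoiseCluster(reads)
  expect_equal(sum(otus$abundance), nrow(reads))
  perm <- reads[sample(nrow(reads)), ]
  otus_p <- denoiseCluster(perm)
  expect_equal(otus$centroid_seq, otus_p$centroid_seq)
  expect_equal(otus$abundance, otus_p$abundance)
})

mkRefDb <- function(seqs, genera, family = "Fam") {
  d <- data.frame(id = paste0("ref", seq_along(seqs)), seq = seqs,
                  domain = "Bacteria", phylum = "Bacteroidota",
                  class = "Cls", order = "Ord", family = family,
                  genus = genera, species = "", stringsAsFactors = FALSE)
  d
}

test_that("consensus taxonomy keeps majority ranks and truncates below", {
  set.seed(9)
  tmpl <- randomDna(400)
  near <- function() mutateNtTest(tmpl, 0.02)
  otus <- denoiseCluster(mkReads(tmpl))
  ## unanimity -> full lineage to genus
  db <- mkRefDb(c(near(), near(), near()), rep("Rhodoferax", 3))
  a <- classifyConsensus(otus, db)
  expect_equal(a$status, "assigned")
  expect_equal(a$genus, "Rhodoferax")
  ## 2 genus A / 1 genus B with shared family: 2/3 >= 0.51 keeps genus A
  db2 <- mkRefDb(c(near(), near(), near()), c("GenA", "GenA", "GenB"))
  a2 <- classifyConsensus(otus, db2)
  expect_equal(a2$genus, "GenA")
  expect_equal(a2$family, "Fam")
  ## 1/1 split truncates at genus but keeps the shared family
  db3 <- mkRefDb(c(near(), near()), c("GenA", "GenB"))
  a3 <- classifyConsensus(otus, db3)
  expect_equal(a3$genus, "")
  expect_equal(a3$family, "Fam")
  ## best identity below the acceptance floor -> unassigned
  db4 <- mkRefDb(mutateNtTest(tmpl, 0.35), "GenA")
  a4 <- classifyConsensus(otus, db4)
  expect_equal(a4$status, "unassigned")
  expect_equal(a4$n_hits_used, 0L)
})

test_that("lineage-annotated databases round-trip through FASTA", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">refA lineage=d__Bacteria;p__Bacteroidota;c__C;o__O;f__F;g__Terrimonas",
    strrep("ACGT", 30),
    ">refB lineage=d__Bacteria;p__Pseudomonadota;c__C;o__O;f__F2;g__Zoogloea;s__sp1",
    strrep("TTGA", 30)), path)
  db <- readTaxonomyDatabase(path)
  expect_equal(db$genus, c("Terrimonas", "Zoogloea"))
  expect_equal(db$species, c("", "sp1"))
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">refC lineage=domain_Bacteria", "ACGT"), bad)
  expect_error(readTaxonomyDatabase(bad), "refC")
})

test_that("unassigned centroids are exported as FASTA records", {
  set.seed(10)
  tmpl <- randomDna(300)
  otus <- denoiseCluster(mkReads(c(tmpl, randomDna(300))))
  db <- mkRefDb(mutateNtTest(tmpl, 0.02), "GenA")
  a <- classifyConsensus(otus, db)
  path <- withr::local_tempfile(fileext = ".fasta")
  un <- reportUnassigned(a, otus, path)
  got <- Biostrings::readDNAStringSet(path)
  expect_equal(length(got), length(un))
  expect_setequal(names(got), a$otu_id[a$status == "unassigned"])
  ## no unassigned -> empty file, still success
  a_all <- a; a_all$status <- "assigned"
  path2 <- withr::local_tempfile(fileext = ".fasta")
  expect_length(reportUnassigned(a_all, otus, path2), 0L)
  expect_equal(length(Biostrings::readDNAStringSet(path2)), 0L)
})

test_that("FASTQ reads round-trip with mean qualities", {
  reads <- simulateReads(c(t1 = randomDna(900)), 5, sub_rate = 0.01,
                         seed = 2, mean_q_mean = 12)
  path <- withr::local_tempfile(fileext = ".fastq")
  writeReadsFastq(reads, path)
  back <- readAmpliconFastq(path)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$mean_q, round(reads$mean_q), tolerance = 0.51)
})
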