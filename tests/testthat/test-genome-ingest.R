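## Genome ingestion: GFF3/FASTA parsing, gene ordering, neighborhoods.

writeToyFiles <- function(dir, gff_lines, nt, aa) {
  paths <- list(gff = file.path(dir, "g.gff3"), nt = file.path(dir, "g.fna"),
                aa = file.path(dir, "g.faa"))
  fastaLines <- function(x)
    as.character(unlist(lapply(names(x),
                               function(i) c(paste0(">", i), x[[i]]))))
  writeLines(c("##gff-version 3", gff_lines), paths$gff)
  writeLines(fastaLines(nt), paths$nt)
  writeLines(fastaLines(aa), paths$aa)
  paths
}

cdsLine <- function(ctg, start, end, id, strand = "+", extra = "") {
  sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s%s",
          ctg, start, end, strand, id, extra)
}

test_that("genes are grouped per contig, sorted by start and 0-indexed", {
  d <- withr::local_tempdir()
  nt <- list(a = "ATGAAATAA", b = "ATGCCCTAA", c = "ATGGGGTAA")
  aa <- list(a = "MK", b = "MP", c = "MG")
  ## deliberately shuffled file order
  paths <- writeToyFiles(d, c(cdsLine("c1", 900, 908, "c"),
                              cdsLine("c1", 10, 18, "a"),
                              cdsLine("c1", 500, 508, "b")), nt, aa)
  g <- readGenome(paths$gff, paths$nt, paths$aa)
  gd <- genes(g)
  expect_equal(gd$gene_id, c("a", "b", "c"))
  expect_equal(gd$index, 0:2)
  expect_equal(gd$start, c(10L, 500L, 900L))
})

test_that("empty inputs yield a genome with zero contigs", {
  d <- withr::local_tempdir()
  paths <- writeToyFiles(d, character(), list(), list())
  g <- readGenome(paths$gff, paths$nt, paths$aa)
  expect_s4_class(g, "GenomeAnnotation")
  expect_equal(nrow(genes(g)), 0L)
  expect_length(contigNames(g), 0L)
})

test_that("coordinate violations and identifier problems are hard errors", {
  d <- withr::local_tempdir()
  nt <- list(a = "ATGAAATAA"); aa <- list(a = "MK")
  p1 <- writeToyFiles(d, cdsLine("c1", 100, 90, "a"), nt, aa)
  expect_error(readGenome(p1$gff, p1$nt, p1$aa))
  d2 <- withr::local_tempdir()
  p2 <- writeToyFiles(d2, cdsLine("c1", 10, 18, "zz"), nt, aa)
  expect_error(readGenome(p2$gff, p2$nt, p2$aa), "zz")
  d3 <- withr::local_tempdir()
  p3 <- writeToyFiles(d3, c(cdsLine("c1", 10, 18, "a"),
                            cdsLine("c1", 50, 58, "a")), nt, aa)
  expect_error(readGenome(p3$gff, p3$nt, p3$aa), "duplicate")
})

test_that("labels merge GFF attributes with the annotation table and map KOs", {
  d <- withr::local_tempdir()
  nt <- list(a = "ATGAAATAA"); aa <- list(a = "MK")
  paths <- writeToyFiles(d, cdsLine("c1", 10, 18, "a",
                                    extra = ";labels=K00376"), nt, aa)
  ann <- file.path(d, "ann.tsv")
  write.table(data.frame(gene_id = "a", label = "norB"), ann, sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- readGenome(paths$gff, paths$nt, paths$aa, ann)
  expect_setequal(genes(g)$labels[[1]], c("nosZ", "norB"))
})

test_that("write + re-read round-trips gene count, coordinates and strands", {
  co <- makeCohort(21, n_genomes = 2)
  g <- co$genomes[[1]]
  d <- withr::local_tempdir()
  paths <- writeGenomeFiles(g, d)
  g2 <- readGenome(paths$gff, paths$nt, paths$aa, paths$annotations,
                   genome_id = genomeId(g))
  expect_equal(nrow(genes(g2)), nrow(genes(g)))
  expect_equal(genes(g2)$start, genes(g)$start)
  expect_equal(genes(g2)$end, genes(g)$end)
  expect_equal(genes(g2)$strand, genes(g)$strand)
  expect_equal(genes(g2)$gene_id, genes(g)$gene_id)
})

test_that("geneNeighbors honors the window and contig boundaries", {
  g <- toyGenome(rep(list(character()), 20))
  ids <- genes(g)$gene_id
  expect_equal(nrow(geneNeighbors(g, ids[11], 0)), 0L)   # zero window
  nb <- geneNeighbors(g, ids[11], 3)                     # index 10
  expect_equal(sort(nb$offset), c(-3:-1, 1:3))
  expect_setequal(nb$gene_id, ids[c(8:10, 12:14)])
  g4 <- toyGenome(rep(list(character()), 4))
  nb4 <- geneNeighbors(g4, genes(g4)$gene_id[1], 7)      # index 0, truncation
  expect_equal(sort(nb4$offset), 1:3)
  expect_error(geneNeighbors(g, "nope", 3), "unknown gene_id")
})

test_that("neighborhoods never exceed 2*window nor cross contigs", {
  set.seed(42)
  for (rep in 1:5) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    genes1 <- genes(toyGenome(rep(list(character()), n1), "a"))
    genes2 <- genes(toyGenome(rep(list(character()), n2), "b"))
    genes2$contig_id <- "c2"
    both <- rbind(genes1, genes2)
    both$gene_id <- sprintf("g%02d", seq_len(nrow(both)))
    g <- makeGenomeAnnotation("two", rep("", 7), both)
    w <- sample(0:8, 1)
    gid <- sample(genes(g)$gene_id, 1)
    nb <- geneNeighbors(g, gid, w)
    expect_lte(nrow(nb), 2 * w)
    ctg <- genes(g)$contig_id[genes(g)$gene_id == gid]
    expect_true(all(nb$contig_id == ctg))
  }
})
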