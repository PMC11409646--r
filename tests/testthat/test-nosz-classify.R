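## Panel scoring, length screen, clade call, secretion call, accessory
## detection and the per-genome hit table.

panels <- makeReferencePanels(7)

test_that("panel scores are self-normalized and detect non-homology", {
  member <- as.character(panelSequences(panels$panelI)[[3]])
  sc <- scoreAgainstPanel(member, panels$panelI)
  expect_equal(sc$score, 1.0)
  expect_equal(sc$ref_id, "cladeI_ref03")
  polyG <- strrep("G", 60)
  panelW <- newReferencePanel("I", c(w1 = strrep("W", 50)))
  expect_lt(scoreAgainstPanel(polyG, panelW)$score, 0.05)
  expect_error(scoreAgainstPanel("", panels$panelI), "empty")
})

test_that("scores equal the independent Gotoh DP oracle on mutated queries", {
  set.seed(9)
  for (rep in 1:6) {
    ref <- randomAa(sample(60:150, 1))
    q <- strsplit(ref, "")[[1]]
    i <- sample(length(q), ceiling(length(q) * 0.1))
    for (k in i) q[k] <- sample(rownames(.blosum62_test)[1:20], 1)
    q <- paste(q, collapse = "")
    panel <- newReferencePanel("I", c(r1 = ref))
    got <- scoreAgainstPanel(q, panel)$score
    want <- swGotohOracle(q, ref) / sum(diag(.blosum62_test)[
      match(strsplit(ref, "")[[1]], rownames(.blosum62_test))])
    expect_equal(got, want, tolerance = 1e-12)
    expect_gt(got, 0.05); expect_lt(got, 1)
  }
})

test_that("clade calls follow the margin rule and ignore panel order and case", {
  member <- as.character(panelSequences(panels$panelII)[[5]])
  cl <- assignClade(member, panels$panelI, panels$panelII)
  expect_equal(cl$clade, "II")
  ## case invariance
  expect_equal(assignClade(tolower(member), panels$panelI,
                           panels$panelII)$clade, "II")
  ## panel entry order invariance
  shuf <- newReferencePanel("II", rev(as.character(
    panelSequences(panels$panelII))))
  expect_equal(assignClade(member, panels$panelI, shuf)$clade, "II")
  ## exact tie -> unclassified (same sequence as both panels)
  same <- newReferencePanel("I", c(x = member))
  sameII <- newReferencePanel("II", c(y = member))
  expect_equal(assignClade(member, same, sameII)$clade, "unclassified")
})

test_that("degenerate panels cannot separate clades", {
  p0 <- makeReferencePanels(5, inter_clade_div = 0)
  clI <- assignClade(p0$ancestors[["I"]], p0$panelI, p0$panelII)
  expect_equal(clI$clade, "unclassified")
})

test_that("length screen uses inclusive OR semantics across nt/aa ranges", {
  cfg <- classifierConfig()
  expect_true(lengthFilter(1050, NA, cfg))           # lower nt bound
  expect_true(lengthFilter(2200, NA, cfg))           # upper nt bound
  expect_false(lengthFilter(1049, 349, cfg))         # just below both
  expect_true(lengthFilter(2300, 760, cfg))          # OR: aa rescues nt
  expect_false(lengthFilter(2300, 801, cfg))
})

test_that("secretion calls follow the tat motif and sec heuristic", {
  core <- strrep("DEQNSTHPYC", 8)  # featureless 80-aa core
  expect_equal(detectSecretionPathway(paste0("MSRRQFLKGAGA", core)), "tat")
  expect_equal(detectSecretionPathway(paste0("MKKLLLLLLLAQA", core)), "sec")
  expect_equal(detectSecretionPathway(paste0("MDDEED", core)), "none")
  expect_warning(out <- detectSecretionPathway("MSRRQFLKGAGA"), "40")
  expect_equal(out, "none")
  ## tat motif outside the first 35 residues does not count
  expect_equal(detectSecretionPathway(paste0("MDDEED", strrep("Q", 30),
                                             "SRRQFL", core)), "none")
})

accessoryGenome <- function(offsets) {
  ## 21 genes; nosZ at index 10; `offsets` = named list label -> offset
  labels <- rep(list(character()), 21)
  labels[[11]] <- "nosZ"
  for (lab in names(offsets))
    for (off in offsets[[lab]])
      labels[[11 + off]] <- c(labels[[11 + off]], lab)
  toyGenome(labels)
}

test_that("accessory detection honors windows and the nearest/downstream rule", {
  g <- accessoryGenome(list(nosB = 7))
  id <- genes(g)$gene_id[11]
  expect_equal(detectAccessory(g, id)$nosB_offset, 7L)    # inclusive window
  g <- accessoryGenome(list(nosB = 8))
  expect_true(is.na(detectAccessory(g, id)$nosB_offset))  # outside window
  g <- accessoryGenome(list(nosR = c(-3, 2)))
  expect_equal(detectAccessory(g, id)$nosR_offset, 2L)    # nearest wins
  g <- accessoryGenome(list(nosR = c(-2, 2)))
  expect_equal(detectAccessory(g, id)$nosR_offset, 2L)    # tie -> downstream
  g <- accessoryGenome(list(nosR = 4))
  expect_true(is.na(detectAccessory(g, id)$nosR_offset))
})

test_that("accessory offsets never exceed their window and vanish with the gene", {
  cfg <- classifierConfig()
  set.seed(31)
  for (rep in 1:5) {
    off <- sample(c(-7:-1, 1:7), 1)
    g <- accessoryGenome(list(nosB = off))
    id <- genes(g)$gene_id[11]
    got <- detectAccessory(g, id, cfg)$nosB_offset
    expect_equal(got, off)
    expect_lte(abs(got), cfg@nosBWindow)
    ## removing the accessory flips the call to absent
    g0 <- accessoryGenome(list())
    expect_true(is.na(detectAccessory(g0, id, cfg)$nosB_offset))
  }
})

test_that("genome classification recovers implanted facts and multi-copy genes", {
  spec <- genomeSpec("m1", "non_denitrifying_N2O_reducer", clades = "II",
                     divergence = 0.05, secretion = "sec", nosB_offset = 1L)
  g <- makeGenome(spec, panels, seed = 5)
  hits <- classifyGenomeNosz(g$genome, panels$panelI, panels$panelII)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$clade, "II")
  expect_equal(hits$secretion, "sec")
  expect_equal(hits$nosB_offset, 1L)
  expect_true(is.na(hits$nosR_offset))
  expect_true(hits$length_pass)

  ## genome without nosZ-like genes -> empty hit table
  g0 <- makeGenome(genomeSpec("m0", "no_N2O_reduction"), panels, seed = 6)
  expect_equal(nrow(classifyGenomeNosz(g0$genome, panels$panelI,
                                       panels$panelII)), 0L)

  ## two divergent clade II genes -> two hits with distinct ids
  spec2 <- genomeSpec("m2", "partial_denitrifier", clades = c("II", "II"),
                      divergence = 0.08)
  g2 <- makeGenome(spec2, panels, seed = 7)
  hits2 <- classifyGenomeNosz(g2$genome, panels$panelI, panels$panelII)
  expect_equal(nrow(hits2), 2L)
  expect_equal(length(unique(hits2$gene_id)), 2L)
  expect_false(hits2$nt_seq[1] == hits2$nt_seq[2])
  expect_equal(nrow(uniqueNoszGenes(hits2)), 2L)
})

test_that("unlabeled nosZ genes are discovered by panel score", {
  spec <- genomeSpec("m3", "non_denitrifying_N2O_reducer", clades = "II",
                     divergence = 0.05, label_nosz = FALSE)
  g <- makeGenome(spec, panels, seed = 8)
  hits <- classifyGenomeNosz(g$genome, panels$panelI, panels$panelII)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$clade, "II")
})

test_that("external hit tables apply the e-value cutoff", {
  tab <- data.frame(query_id = c("q1", "q1", "q2", "q3"),
                    ref_id = c("r1", "r2", "r1", "r9"),
                    evalue = c(1e-30, 1e-50, 1e-9, 1e-12))
  out <- applyExternalHits(tab)
  expect_setequal(out$query_id, c("q1", "q3"))
  expect_equal(out$ref_id[out$query_id == "q1"], "r2")  # best e-value wins
})
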