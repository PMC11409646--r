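## Synthetic cohort generator: reference panels, annotated genomes with
## implanted nosZ / accessory / pathway genes, and per-genome truth records.
## Controllability, not biological realism, is the goal: mutations are
## uniform substitutions and nucleotide genes are back-translations under a
## fixed (~50% GC) codon table.

## evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

CODON_TABLE <- c(
  A = "GCA", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGT", H = "CAT", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "AGC", T = "ACA", W = "TGG",
  Y = "TAC", V = "GTC")

SIGNAL_PREFIXES <- c(
  tat = "MSRRQFLKGAGALA",      # twin-arginine motif SRRQFL at offset 1
  sec = "MKKLAVILAVLAAFSA",    # K in positions 1-6 + long hydrophobic run
  none = "MDDEEDTSQA")         # acidic N-terminus, no signal features

randomProtein <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

## uniform substitution model: each position mutates with prob `rate` to one
## of the 19 other residues
mutateProtein <- function(aa_seq, rate) {
  chars <- strsplit(aa_seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (k in hit)
    chars[k] <- sample(setdiff(AA_STANDARD, chars[k]), 1L)
  paste(chars, collapse = "")
}

#' Back-translate a protein to a nucleotide gene
#'
#' Deterministic back-translation under a fixed, GC-balanced codon table
#' (one codon per amino acid), with a TAA stop appended.
#'
#' @param aa_seq protein sequence (20 standard residues).
#' @return Nucleotide coding sequence of length 3 * nchar(aa_seq) + 3.
#' @export
backTranslate <- function(aa_seq) {
  chars <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- setdiff(chars, names(CODON_TABLE))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(bad, collapse = ","))
  paste0(paste(CODON_TABLE[chars], collapse = ""), "TAA")
}

#' Generate clade I / clade II reference panels with known ancestors
#'
#' Two ancestor proteins (~640 and ~660 aa) are diverged to the requested
#' inter-clade distance; panel members are drawn by mutating each ancestor
#' at half the requested intra-clade divergence per member, so the expected
#' pairwise intra-panel divergence is about `intra_clade_div`. Deterministic
#' given the seed.
#'
#' @param seed RNG seed.
#' @param n_cladeI,n_cladeII panel sizes (defaults 20 and 46).
#' @param inter_clade_div substitutions/site between the two ancestors
#'   (default 0.45).
#' @param intra_clade_div expected pairwise divergence within a panel
#'   (default 0.15).
#' @param len_cladeI,len_cladeII ancestor lengths (defaults 640 and 660 aa).
#' @return List with `panelI`, `panelII` ([ReferencePanel-class]) and
#'   `ancestors` (named character vector "I", "II").
#' @export
makeReferencePanels <- function(seed, n_cladeI = 20, n_cladeII = 46,
                                inter_clade_div = 0.45,
                                intra_clade_div = 0.15,
                                len_cladeI = 640, len_cladeII = 660) {
  withSeed(seed, {
    root <- randomProtein(len_cladeI)
    ancI <- root
    ancII <- paste0(mutateProtein(root, inter_clade_div),
                    randomProtein(max(0L, len_cladeII - len_cladeI)))
    member_rate <- intra_clade_div / 2
    mkpanel <- function(anc, n, clade) {
      seqs <- vapply(seq_len(n), function(i) mutateProtein(anc, member_rate),
                     "")
      names(seqs) <- sprintf("clade%s_ref%02d", clade, seq_len(n))
      newReferencePanel(clade, seqs)
    }
    list(panelI = mkpanel(ancI, n_cladeI, "I"),
         panelII = mkpanel(ancII, n_cladeII, "II"),
         ancestors = c(I = ancI, II = ancII))
  })
}

## decoy ORF: shuffled-composition protein guaranteed < 20% identity to both
## ancestors (rejection-sampled)
.decoyProtein <- function(len, ancestors, max_identity = 0.20) {
  repeat {
    aa <- randomProtein(len)
    if (all(alignmentIdentity(aa, unname(ancestors)) < max_identity))
      return(aa)
  }
}

#' Specification of one synthetic genome
#'
#' @param genome_id genome identifier.
#' @param phenotype one of the five phenotype labels (see
#'   [phenotypeProfile()]).
#' @param clades character vector of nosZ clades to implant ("I"/"II"; empty
#'   for no nosZ, two entries for a two-gene genome).
#' @param divergence substitutions/site of each implanted nosZ from its
#'   clade ancestor (0..0.5).
#' @param secretion secretion class per implanted nosZ ("tat", "sec",
#'   "none"); recycled.
#' @param nosB_offset,nosR_offset signed gene-index offsets for the
#'   accessory genes relative to the first nosZ (NA = absent; |offset| <= 10).
#' @param dnra,anr implant a complete DNRA / assimilatory nitrate reduction
#'   gene set.
#' @param n_decoys number of decoy ORFs (default 10).
#' @param label_nosz attach the "nosZ" annotation label to implanted nosZ
#'   genes (default TRUE; FALSE exercises score-based discovery).
#' @param lineage up to 7 taxonomy ranks.
#' @return A validated `genomeSpec` list.
#' @export
genomeSpec <- function(genome_id, phenotype, clades = character(),
                       divergence = 0.05, secretion = "sec",
                       nosB_offset = NA, nosR_offset = NA, dnra = FALSE,
                       anr = FALSE, n_decoys = 10L, label_nosz = TRUE,
                       lineage = rep("", 7)) {
  phenotype <- match.arg(phenotype, PHENOTYPE_LEVELS)
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  for (off in c(nosB_offset, nosR_offset))
    if (!is.na(off) && (off == 0 || abs(off) > 10))
      stop("accessory offsets must be non-zero and within +/-10")
  if (phenotype == "no_N2O_reduction" && length(clades))
    stop("inconsistent spec: no_N2O_reduction phenotype with a nosZ clade")
  if (phenotype != "no_N2O_reduction" && !length(clades))
    stop("inconsistent spec: nosZ-positive phenotype without a clade")
  if (!all(clades %in% c("I", "II"))) stop("clades must be 'I' or 'II'")
  if (length(clades) && any(!secretion %in% names(SIGNAL_PREFIXES)))
    stop("secretion must be tat, sec or none")
  structure(list(genome_id = genome_id, phenotype = phenotype,
                 clades = clades,
                 divergence = divergence,
                 secretion = rep(secretion, length.out = length(clades)),
                 nosB_offset = nosB_offset, nosR_offset = nosR_offset,
                 dnra = dnra, anr = anr, n_decoys = as.integer(n_decoys),
                 label_nosz = label_nosz, lineage = lineage),
            class = "genomeSpec")
}

## pathway gene labels implanting the requested phenotype (deterministic
## given the RNG state)
.phenotypeGeneSets <- function(spec) {
  sets <- list()
  add <- function(labels) sets[[length(sets) + 1L]] <<- labels
  ph <- spec$phenotype
  if (ph %in% c("complete_denitrifier_NO3", "complete_denitrifier_NO2")) {
    add(sample(list("nirK", "nirS"), 1L)[[1]])
    add(sample(list("norB", "norC"), 1L)[[1]])
  }
  if (ph == "complete_denitrifier_NO3")
    add(sample(list(c("napA", "napB"), c("narG", "narH", "narI")), 1L)[[1]])
  if (ph == "partial_denitrifier")
    add(sample(list("nirK", "nirS", "norB", "norC"), 1L)[[1]])
  if (spec$dnra)
    add(sample(list(c("nrfA", "nrfH"), c("nirB", "nirD")), 1L)[[1]])
  if (spec$anr)
    add(sample(list(c("nasA", "nasB"), "NR"), 1L)[[1]])
  unlist(sets)
}

#' Build one synthetic annotated genome with its truth record
#'
#' Lays out a single contig of decoy ORFs plus the gene complement realizing
#' the requested phenotype, one nosZ gene per requested clade (ancestor
#' mutated at the requested divergence, with the requested N-terminal
#' signal), and accessory nosB/nosR at the requested index offsets relative
#' to the first nosZ. Inconsistent specifications raise an error in
#' [genomeSpec()].
#'
#' @param spec a [genomeSpec()].
#' @param panels output of [makeReferencePanels()] (ancestors are used).
#' @param seed RNG seed.
#' @return List with `genome` ([GenomeAnnotation-class]) and `truth` (one-row
#'   data.frame of every implanted fact).
#' @export
makeGenome <- function(spec, panels, seed) {
  stopifnot(inherits(spec, "genomeSpec"))
  anc <- panels$ancestors
  withSeed(seed, {
    entries <- list()  # each: list(aa, labels, is_nosz)
    gene <- function(aa, labels = character(), is_nosz = FALSE)
      list(aa = aa, labels = labels, is_nosz = is_nosz)
    for (k in seq_along(spec$clades)) {
      core <- mutateProtein(anc[[spec$clades[k]]], spec$divergence)
      aa <- paste0(SIGNAL_PREFIXES[[spec$secretion[k]]], core)
      entries[[length(entries) + 1L]] <-
        gene(aa, if (spec$label_nosz) "nosZ" else character(), TRUE)
    }
    for (lab in .phenotypeGeneSets(spec))
      entries[[length(entries) + 1L]] <-
        gene(.decoyProtein(sample(200:320, 1L), anc), lab)
    accessory <- list()
    if (!is.na(spec$nosB_offset))
      accessory$nosB <- spec$nosB_offset
    if (!is.na(spec$nosR_offset))
      accessory$nosR <- spec$nosR_offset
    n_other <- length(entries) - length(spec$clades)
    n_decoys <- max(spec$n_decoys, 2L)
    ## slot layout: nosZ genes placed with >= 11 ranks between them so that
    ## accessory windows never overlap the other nosZ
    n_slots <- n_other + n_decoys + length(spec$clades) + 40L
    nosz_slot <- 12L
    slots <- vector("list", n_slots)
    if (length(spec$clades) >= 1L) slots[[nosz_slot]] <- entries[[1]]
    if (length(spec$clades) > 1L)
      slots[[nosz_slot + 24L]] <- entries[[2]]
    for (accname in names(accessory)) {
      at <- nosz_slot + accessory[[accname]]
      stopifnot(at >= 1L, at <= n_slots, is.null(slots[[at]]))
      slots[[at]] <- gene(.decoyProtein(sample(150:250, 1L), anc), accname)
    }
    free <- which(vapply(slots, is.null, TRUE))
    others <- entries[-seq_along(spec$clades)]
    if (length(others)) {
      put <- sample(free, length(others))
      for (k in seq_along(others)) slots[[put[k]]] <- others[[k]]
      free <- setdiff(free, put)
    }
    for (k in free)
      slots[[k]] <- gene(.decoyProtein(sample(80:300, 1L), anc))
    ## lay out coordinates
    pos <- 1L
    rows <- list()
    for (k in seq_along(slots)) {
      s <- slots[[k]]
      nt <- backTranslate(s$aa)
      start <- pos + sample(20:200, 1L)
      end <- start + nchar(nt) - 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("%s_g%03d", spec$genome_id, k),
        contig_id = paste0(spec$genome_id, "_c1"), index = 0L,
        start = start, end = end, strand = sample(c("+", "-"), 1L),
        nt_seq = nt, aa_seq = s$aa, stringsAsFactors = FALSE)
      rows[[k]]$labels <- list(s$labels)
      pos <- end
    }
    genes <- do.call(rbind, rows)
    genome <- makeGenomeAnnotation(spec$genome_id, spec$lineage, genes)
    is_nosz <- vapply(slots, function(s) isTRUE(s$is_nosz), TRUE)
    truth <- data.frame(
      genome_id = spec$genome_id, phenotype = spec$phenotype,
      n_nosz = length(spec$clades),
      clades = paste(sort(spec$clades), collapse = "+"),
      divergence = spec$divergence,
      secretion = paste(spec$secretion, collapse = "+"),
      nosB_offset = spec$nosB_offset, nosR_offset = spec$nosR_offset,
      dnra = spec$dnra, anr = spec$anr,
      nosz_gene_ids = paste(sprintf("%s_g%03d", spec$genome_id,
                                    which(is_nosz)), collapse = ","),
      stringsAsFactors = FALSE)
    list(genome = genome, truth = truth)
  })
}

#' Generate a synthetic cohort emulating an activated-sludge MAG collection
#'
#' Samples per-genome specifications (phenotype mix, clade split skewed to
#' clade II, clade-typical secretion and accessory placement, divergence
#' drawn from `divergence_range`), builds every genome, and returns genomes
#' plus the combined truth table. Deterministic given the seed.
#'
#' @param seed RNG seed.
#' @param n_genomes cohort size (default 120).
#' @param divergence_range range of nosZ divergence from the clade ancestor
#'   (default 0.02-0.10).
#' @param panels optional panels from [makeReferencePanels()]; generated
#'   from the same seed when NULL.
#' @param p_two_nosz probability of a second (clade II) nosZ gene in a
#'   clade II genome (default 0.05).
#' @return List with `genomes` (list of [GenomeAnnotation-class]), `truth`
#'   (data.frame) and `panels`.
#' @export
makeCohort <- function(seed, n_genomes = 120,
                       divergence_range = c(0.02, 0.10), panels = NULL,
                       p_two_nosz = 0.05) {
  if (is.null(panels)) panels <- makeReferencePanels(seed)
  phyla_II <- c("Bacteroidota", "Chloroflexota", "Myxococcota",
                "Gemmatimonadota", "Latescibacterota", "Pseudomonadota")
  p_phyla_II <- c(0.55, 0.1, 0.08, 0.07, 0.06, 0.14)
  specs <- withSeed(seed + 1L, {
    lapply(seq_len(n_genomes), function(i) {
      ph <- sample(PHENOTYPE_LEVELS, 1L,
                   prob = c(0.03, 0.06, 0.23, 0.17, 0.51))
      if (ph == "no_N2O_reduction")
        return(genomeSpec(sprintf("mag%03d", i), ph,
                          n_decoys = sample(6:12, 1L),
                          lineage = c("Bacteria",
                                      sample(phyla_II, 1L), "", "", "", "", "")))
      clade <- sample(c("I", "II"), 1L, prob = c(0.08, 0.92))
      two <- clade == "II" && runif(1) < p_two_nosz
      clades <- c(clade, if (two) "II")
      secretion <- ifelse(clades == "I", "tat", "sec")
      nosB <- if (clade == "II" && runif(1) < 0.9)
        sample(c(-7:-1, 1:7), 1L) else NA
      nosR <- if (clade == "I" && runif(1) < 0.9)
        sample(c(-3:-1, 1:3), 1L) else NA
      phylum <- if (clade == "I") "Pseudomonadota"
        else sample(phyla_II, 1L, prob = p_phyla_II)
      genomeSpec(sprintf("mag%03d", i), ph, clades = clades,
                 divergence = runif(1, divergence_range[1],
                                    divergence_range[2]),
                 secretion = secretion, nosB_offset = nosB,
                 nosR_offset = nosR, dnra = runif(1) < 0.3,
                 anr = runif(1) < 0.1, n_decoys = sample(6:12, 1L),
                 lineage = c("Bacteria", phylum, "", "", "", "", ""))
    })
  })
  built <- lapply(seq_along(specs), function(i)
    makeGenome(specs[[i]], panels, seed + 1000L + i))
  truth <- do.call(rbind, lapply(built, `[[`, "truth"))
  rownames(truth) <- NULL
  list(genomes = lapply(built, `[[`, "genome"), truth = truth,
       panels = panels)
}

#' Score pipeline recovery of generator truth
#'
#' Runs the classifier and phenotype profiler over a synthetic cohort and
#' compares every recoverable fact (clade per gene, secretion, accessory
#' offsets, phenotype) with the generator's truth records.
#'
#' @param genomes list of [GenomeAnnotation-class] from [makeCohort()].
#' @param truth truth data.frame from [makeCohort()].
#' @param panels panels from [makeReferencePanels()].
#' @param cfg a [ClassifierConfig-class].
#' @return List with per-fact accuracies (fractions), the hit table and the
#'   profile table.
#' @export
evaluateCohortRecovery <- function(genomes, truth, panels,
                                   cfg = classifierConfig()) {
  hits <- classifyCohortNosz(genomes, panels$panelI, panels$panelII, cfg)
  profiles <- do.call(rbind, lapply(genomes, function(g)
    phenotypeProfile(g, hits)))
  m <- match(truth$genome_id, profiles$genome_id)
  phen_ok <- profiles$phenotype[m] == truth$phenotype
  per_genome <- function(field) {
    vapply(seq_len(nrow(truth)), function(i) {
      mine <- hits[hits$genome_id == truth$genome_id[i], , drop = FALSE]
      tr <- truth[i, ]
      if (tr$n_nosz == 0L) return(nrow(mine) == 0L)
      if (nrow(mine) != tr$n_nosz) return(FALSE)
      switch(field,
        clade = paste(sort(mine$clade), collapse = "+") == tr$clades,
        secretion = paste(mine$secretion[order(mine$gene_id)],
                          collapse = "+") == tr$secretion,
        nosB = {
          first <- mine[order(mine$gene_id), ][1, ]
          identical(is.na(first$nosB_offset), is.na(tr$nosB_offset)) &&
            (is.na(tr$nosB_offset) ||
               first$nosB_offset == tr$nosB_offset)
        },
        nosR = {
          first <- mine[order(mine$gene_id), ][1, ]
          identical(is.na(first$nosR_offset), is.na(tr$nosR_offset)) &&
            (is.na(tr$nosR_offset) ||
               first$nosR_offset == tr$nosR_offset)
        })
    }, TRUE)
  }
  list(clade_accuracy = mean(per_genome("clade")),
       secretion_accuracy = mean(per_genome("secretion")),
       nosB_accuracy = mean(per_genome("nosB")),
       nosR_accuracy = mean(per_genome("nosR")),
       phenotype_accuracy = mean(phen_ok),
       hits = hits, profiles = profiles)
}
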