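## nosZ detection and clade assignment: panel scoring, length screen,
## secretion-pathway call, accessory-gene proximity, per-genome hit tables.

#' Read a clade reference panel from FASTA
#'
#' @param fasta_path protein FASTA of curated full-length NosZ sequences.
#' @param clade "I" or "II".
#' @return A [ReferencePanel-class].
#' @export
readReferencePanel <- function(fasta_path, clade) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  newReferencePanel(clade, seqs)
}

#' Construct a reference panel from sequences
#'
#' @param clade "I" or "II".
#' @param sequences named [Biostrings::AAStringSet] or named character vector.
#' @return A [ReferencePanel-class] with cached self-alignment scores.
#' @export
newReferencePanel <- function(clade, sequences) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  self <- vapply(as.character(sequences), .selfScore, 0)
  new("ReferencePanel", clade = clade, sequences = sequences,
      selfScores = unname(self))
}

#' Length screen for candidate nosZ genes
#'
#' A gene passes iff its nucleotide length is in \[minNt, maxNt\] OR its
#' amino-acid length is in \[minAa, maxAa\] (inclusive bounds, OR semantics).
#'
#' @param nt_len,aa_len sequence lengths (either may be NA/0 when absent).
#' @param cfg a [ClassifierConfig-class].
#' @return Logical.
#' @export
lengthFilter <- function(nt_len, aa_len = NA, cfg = classifierConfig()) {
  nt_ok <- !is.na(nt_len) & nt_len > 0 & nt_len >= cfg@minNt & nt_len <= cfg@maxNt
  aa_ok <- !is.na(aa_len) & aa_len > 0 & aa_len >= cfg@minAa & aa_len <= cfg@maxAa
  nt_ok | aa_ok
}

#' Assign a NosZ protein to clade I or II
#'
#' Scores the query against both panels ([scoreAgainstPanel()]); the clade of
#' the higher score is called iff the best score reaches `minPanelScore` and
#' the relative margin |sI - sII| / max reaches `scoreMargin`, otherwise
#' "unclassified" (ties included).
#'
#' @param aa_seq query protein.
#' @param panelI,panelII clade I / clade II [ReferencePanel-class] objects.
#' @param cfg a [ClassifierConfig-class].
#' @return List with `clade` ("I", "II" or "unclassified"), `score_cladeI`,
#'   `score_cladeII`, `best_ref`.
#' @export
assignClade <- function(aa_seq, panelI, panelII, cfg = classifierConfig()) {
  sI <- scoreAgainstPanel(aa_seq, panelI)
  sII <- scoreAgainstPanel(aa_seq, panelII)
  best <- max(sI$score, sII$score)
  clade <- "unclassified"
  if (best >= cfg@minPanelScore && best > 0 &&
      abs(sI$score - sII$score) / best >= cfg@scoreMargin)
    clade <- if (sI$score > sII$score) "I" else "II"
  list(clade = clade, score_cladeI = sI$score, score_cladeII = sII$score,
       best_ref = if (sI$score >= sII$score) sI$ref_id else sII$ref_id)
}

#' Call the secretion pathway from the N-terminal protein sequence
#'
#' Motif heuristic standing in for a full signal-peptide predictor: the
#' protein is called `tat` if the twin-arginine consensus
#' `[ST]RR.[FGAVML][LITMVF]` occurs within the first 35 residues; otherwise
#' `sec` if the first 6 residues contain K or R and the first 30 residues
#' contain a run of >= 7 hydrophobic residues (A,F,G,I,L,M,V,W); otherwise
#' `none`. Proteins shorter than 40 residues return `none` with a warning.
#'
#' @param aa_seq protein sequence.
#' @return "tat", "sec" or "none".
#' @export
detectSecretionPathway <- function(aa_seq) {
  aa_seq <- toupper(as.character(aa_seq))
  if (nchar(aa_seq) < 40L) {
    warning("sequence shorter than 40 residues; secretion call is 'none'")
    return("none")
  }
  head35 <- substr(aa_seq, 1L, 35L)
  m <- regexpr("[ST]RR.[FGAVML][LITMVF]", head35, perl = TRUE)
  if (m > 0L && (m + 5L) <= 35L) return("tat")
  if (grepl("[KR]", substr(aa_seq, 1L, 6L)) &&
      grepl("[AFGILMVW]{7,}", substr(aa_seq, 1L, 30L)))
    return("sec")
  "none"
}

#' Detect accessory nosB / nosR genes near a nosZ gene
#'
#' Searches the gene neighborhood (window 7 for nosB, 3 for nosR by default)
#' for genes whose normalized labels contain nosB / nosR and returns the
#' signed index offset of the nearest match (downstream positive); ties at
#' equal |offset| go downstream. NA when absent.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param nosz_gene_id focal nosZ gene id.
#' @param cfg a [ClassifierConfig-class].
#' @return List with `nosB_offset` and `nosR_offset` (integer or NA).
#' @export
detectAccessory <- function(genome, nosz_gene_id, cfg = classifierConfig()) {
  nearest <- function(window, label) {
    nb <- geneNeighbors(genome, nosz_gene_id, window)
    if (nrow(nb) == 0L) return(NA_integer_)
    hit <- vapply(nb$labels, function(l) label %in% normalizeLabels(l), TRUE)
    if (!any(hit)) return(NA_integer_)
    off <- nb$offset[hit]
    off[order(abs(off), -sign(off))][1]  # nearest; downstream wins ties
  }
  list(nosB_offset = nearest(cfg@nosBWindow, "nosB"),
       nosR_offset = nearest(cfg@nosRWindow, "nosR"))
}

.emptyHits <- function() {
  data.frame(genome_id = character(), gene_id = character(),
             contig_id = character(), clade = character(),
             score_cladeI = numeric(), score_cladeII = numeric(),
             best_ref = character(), length_pass = logical(),
             secretion = character(), nosB_offset = integer(),
             nosR_offset = integer(), nt_len = integer(),
             aa_len = integer(), nt_seq = character(),
             aa_seq = character(), stringsAsFactors = FALSE)
}

#' Detect and classify all nosZ genes of a genome
#'
#' Candidate genes are (a) every gene whose labels contain nosZ (KO ids
#' normalized) and (b) every unlabeled gene that passes the length screen and
#' scores at least `minPanelScore` against either clade panel. Each candidate
#' yields one hit row with both clade scores, the clade call, the length
#' flag, the secretion pathway and the accessory nosB/nosR offsets. Genes
#' failing the length screen are reported with clade "unclassified" and
#' `length_pass = FALSE`, so a clade call always implies a passing length.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param panelI,panelII clade reference panels.
#' @param cfg a [ClassifierConfig-class].
#' @return data.frame of nosZ hits (possibly 0 rows); genomes may yield
#'   several hits, one per qualifying gene.
#' @export
classifyGenomeNosz <- function(genome, panelI, panelII,
                               cfg = classifierConfig()) {
  g <- genes(genome)
  if (nrow(g) == 0L) return(.emptyHits())
  labeled <- vapply(g$labels, function(l) "nosZ" %in% normalizeLabels(l), TRUE)
  pass <- lengthFilter(nchar(g$nt_seq), nchar(g$aa_seq), cfg)
  hits <- list()
  for (k in seq_len(nrow(g))) {
    if (!labeled[k] && !pass[k]) next
    if (!nzchar(g$aa_seq[k])) next
    cl <- assignClade(g$aa_seq[k], panelI, panelII, cfg)
    if (!labeled[k] &&
        max(cl$score_cladeI, cl$score_cladeII) < cfg@minPanelScore) next
    if (!pass[k]) cl$clade <- "unclassified"
    acc <- detectAccessory(genome, g$gene_id[k], cfg)
    hits[[length(hits) + 1L]] <- data.frame(
      genome_id = genomeId(genome), gene_id = g$gene_id[k],
      contig_id = g$contig_id[k], clade = cl$clade,
      score_cladeI = cl$score_cladeI, score_cladeII = cl$score_cladeII,
      best_ref = cl$best_ref, length_pass = pass[k],
      secretion = detectSecretionPathway(g$aa_seq[k]),
      nosB_offset = acc$nosB_offset, nosR_offset = acc$nosR_offset,
      nt_len = nchar(g$nt_seq[k]), aa_len = nchar(g$aa_seq[k]),
      nt_seq = g$nt_seq[k], aa_seq = g$aa_seq[k],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(.emptyHits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Classify nosZ genes across a cohort of genomes
#'
#' @param genomes list of [GenomeAnnotation-class] objects.
#' @param panelI,panelII clade reference panels.
#' @param cfg a [ClassifierConfig-class].
#' @return Combined hit data.frame over all genomes.
#' @export
classifyCohortNosz <- function(genomes, panelI, panelII,
                               cfg = classifierConfig()) {
  out <- do.call(rbind, lapply(genomes, classifyGenomeNosz,
                               panelI = panelI, panelII = panelII, cfg = cfg))
  if (is.null(out)) out <- .emptyHits()
  rownames(out) <- NULL
  out
}

#' Apply an externally computed hit table instead of panel scoring
#'
#' Escape hatch for users who ran an external homology search: accepts a
#' table (query_id, ref_id, evalue) and flags the queries passing an e-value
#' cutoff (default 1e-10, the conventional screen).
#'
#' @param hit_table data.frame or TSV path with columns query_id, ref_id,
#'   evalue.
#' @param evalue_cutoff maximum e-value accepted.
#' @return data.frame (query_id, ref_id, evalue) of accepted best hits, one
#'   row per query (lowest e-value; ties by ref_id).
#' @export
applyExternalHits <- function(hit_table, evalue_cutoff = 1e-10) {
  if (is.character(hit_table)) hit_table <- read.delim(hit_table)
  if (!all(c("query_id", "ref_id", "evalue") %in% names(hit_table)))
    stop("hit table needs columns query_id, ref_id, evalue")
  keep <- hit_table[hit_table$evalue <= evalue_cutoff, , drop = FALSE]
  keep <- keep[order(keep$query_id, keep$evalue, keep$ref_id), , drop = FALSE]
  out <- keep[!duplicated(keep$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse hits to unique genes at 100% sequence identity
#'
#' @param hits hit data.frame from [classifyGenomeNosz()].
#' @return The hits with exact duplicate nucleotide sequences removed (first
#'   occurrence kept).
#' @export
uniqueNoszGenes <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits[!duplicated(hits$nt_seq), , drop = FALSE]
}
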