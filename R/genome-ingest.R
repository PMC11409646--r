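## Genome ingestion: GFF3 gene calls + nucleotide/protein FASTA + optional
## tabular functional annotations -> GenomeAnnotation.

#' KO-to-gene-symbol synonym map
#'
#' Annotation inputs mix KEGG orthology ids and gene symbols; this bundled
#' map normalizes the nitrogen-metabolism KOs used by the phenotype rules to
#' their conventional gene symbols. Symbols pass through unchanged.
#'
#' @return Named character vector (names = KO ids, values = gene symbols).
#' @export
koSynonyms <- function() {
  c(K00376 = "nosZ", K04561 = "norB", K02305 = "norC",
    K00368 = "nirK", K15864 = "nirS",
    K02567 = "napA", K02568 = "napB",
    K00370 = "narG", K00371 = "narH", K00374 = "narI",
    K03385 = "nrfA", K15876 = "nrfH",
    K00362 = "nirB", K00363 = "nirD",
    K00372 = "nasA", K00360 = "nasB", K10534 = "NR",
    K19339 = "nosB", K02448 = "nosR")
}

#' Normalize annotation labels
#'
#' Maps known KO ids to gene symbols via [koSynonyms()] and drops duplicates;
#' all other labels are kept verbatim.
#'
#' @param labels character vector of annotation symbols.
#' @return Character vector of normalized labels.
#' @export
normalizeLabels <- function(labels) {
  if (!length(labels)) return(character())
  syn <- koSynonyms()
  hit <- labels %in% names(syn)
  labels[hit] <- syn[labels[hit]]
  unique(labels)
}

.emptyGenes <- function() {
  d <- data.frame(gene_id = character(), contig_id = character(),
                  index = integer(), start = integer(), end = integer(),
                  strand = character(), nt_seq = character(),
                  aa_seq = character(), stringsAsFactors = FALSE)
  d$labels <- list()
  d
}

## Sort genes by (contig, start, end, gene_id), assign 0-based per-contig
## index, and build a validated GenomeAnnotation.
makeGenomeAnnotation <- function(genome_id, lineage = rep("", 7), genes) {
  if (is.null(genes) || nrow(genes) == 0L) genes <- .emptyGenes()
  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$index <- as.integer(
    stats::ave(seq_len(nrow(genes)), genes$contig_id, FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  if (length(lineage) != 7L) {
    lin <- rep("", 7L); lin[seq_along(lineage)] <- lineage; lineage <- lin
  }
  names(lineage) <- LINEAGE_RANKS
  new("GenomeAnnotation", genomeId = genome_id, lineage = lineage,
      genes = genes)
}

.readFastaSafe <- function(path, reader) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  x <- reader(path)
  ids <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), ids)
}

#' Read an annotated genome
#'
#' Reads CDS gene calls from GFF3 (1-based inclusive coordinates, `ID`
#' attribute), the matching nucleotide and protein FASTA files, and an
#' optional tabular annotation file (columns `gene_id`, `label`). Genes are
#' grouped per contig, sorted by (start, end, gene_id) and given a 0-based
#' per-contig index; labels merge the GFF `labels` attribute (|-separated)
#' with the annotation table and are KO-normalized.
#'
#' @param gff_path GFF3 file of CDS features.
#' @param nt_fasta_path nucleotide FASTA keyed by gene id.
#' @param aa_fasta_path protein FASTA keyed by gene id.
#' @param annotation_table_path optional TSV with columns gene_id, label.
#' @param genome_id genome identifier (default: GFF basename).
#' @param lineage up to 7 taxonomy ranks, domain..species.
#' @return A [GenomeAnnotation-class].
#' @export
readGenome <- function(gff_path, nt_fasta_path, aa_fasta_path,
                       annotation_table_path = NULL, genome_id = NULL,
                       lineage = rep("", 7)) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(gff_path))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  nt <- .readFastaSafe(nt_fasta_path, Biostrings::readDNAStringSet)
  aa <- .readFastaSafe(aa_fasta_path, Biostrings::readAAStringSet)
  if (length(gr) == 0L)
    return(makeGenomeAnnotation(genome_id, lineage, .emptyGenes()))
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("every CDS feature needs an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in GFF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_nt <- setdiff(ids, names(nt))
  if (length(missing_nt))
    stop("gene id(s) in GFF absent from nucleotide FASTA: ",
         paste(missing_nt, collapse = ", "))
  missing_aa <- setdiff(ids, names(aa))
  if (length(missing_aa))
    stop("gene id(s) in GFF absent from protein FASTA: ",
         paste(missing_aa, collapse = ", "))
  labels <- rep(list(character()), length(ids))
  gff_labels <- S4Vectors::mcols(gr)$labels
  if (!is.null(gff_labels)) {
    has <- !is.na(gff_labels) & nzchar(gff_labels)
    labels[has] <- strsplit(gff_labels[has], "|", fixed = TRUE)
  }
  if (!is.null(annotation_table_path)) {
    ann <- read.delim(annotation_table_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "label") %in% names(ann)))
      stop("annotation table needs columns gene_id, label")
    extra <- split(ann$label, ann$gene_id)
    hit <- match(names(extra), ids)
    for (k in which(!is.na(hit)))
      labels[[hit[k]]] <- c(labels[[hit[k]]], extra[[k]])
  }
  labels <- lapply(labels, normalizeLabels)
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    index = 0L,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    nt_seq = unname(nt[ids]),
    aa_seq = unname(aa[ids]),
    stringsAsFactors = FALSE)
  genes$labels <- labels
  makeGenomeAnnotation(genome_id, lineage, genes)
}

#' Write a genome back to GFF3 + FASTA + annotation TSV
#'
#' Inverse of [readGenome()]: serializes gene coordinates and strands to
#' GFF3, gene sequences to nucleotide/protein FASTA and labels to a TSV, so
#' that re-reading round-trips gene count, coordinates and strands exactly.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default: the genome id).
#' @return Invisibly, a named list of the four file paths.
#' @export
writeGenomeFiles <- function(genome, dir, prefix = genomeId(genome)) {
  stopifnot(is(genome, "GenomeAnnotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genes(genome)
  paths <- list(gff = file.path(dir, paste0(prefix, ".gff3")),
                nt = file.path(dir, paste0(prefix, ".fna")),
                aa = file.path(dir, paste0(prefix, ".faa")),
                annotations = file.path(dir, paste0(prefix, "_labels.tsv")))
  if (nrow(g) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig_id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand)
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$phase <- 0L
    S4Vectors::mcols(gr)$ID <- g$gene_id
    rtracklayer::export(gr, paths$gff, format = "gff3")
    Biostrings::writeXStringSet(
      setNames(Biostrings::DNAStringSet(g$nt_seq), g$gene_id), paths$nt)
    Biostrings::writeXStringSet(
      setNames(Biostrings::AAStringSet(g$aa_seq), g$gene_id), paths$aa)
    lab <- data.frame(
      gene_id = rep(g$gene_id, lengths(g$labels)),
      label = unlist(g$labels, use.names = FALSE),
      stringsAsFactors = FALSE)
    write.table(lab, paths$annotations, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    writeLines("##gff-version 3", paths$gff)
    file.create(paths$nt); file.create(paths$aa)
    write.table(data.frame(gene_id = character(), label = character()),
                paths$annotations, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Genes in the neighborhood of a focal gene
#'
#' Returns all genes on the same contig whose index offset from the focal
#' gene satisfies 0 < |offset| <= window, regardless of strand. Never crosses
#' contig boundaries.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param gene_id focal gene id (must exist).
#' @param window non-negative integer window in gene-rank units.
#' @return data.frame of neighboring gene records, with an extra `offset`
#'   column (downstream in gene-order = positive).
#' @export
geneNeighbors <- function(genome, gene_id, window) {
  stopifnot(is(genome, "GenomeAnnotation"), window >= 0)
  g <- genes(genome)
  k <- match(gene_id, g$gene_id)
  if (is.na(k)) stop("unknown gene_id: ", gene_id)
  ctg <- g$contig_id[k]
  same <- g[g$contig_id == ctg, , drop = FALSE]
  offset <- same$index - g$index[k]
  keep <- offset != 0L & abs(offset) <= window
  out <- same[keep, , drop = FALSE]
  out$offset <- offset[keep]
  rownames(out) <- NULL
  out
}
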