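#' @import methods
#' @importFrom stats hclust cutree rbinom rnorm runif setNames ave as.dist
#' @importFrom utils adist read.delim write.table head
#' @importClassesFrom Biostrings AAStringSet XStringSet
NULL

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

GENE_COLUMNS <- c("gene_id", "contig_id", "index", "start", "end", "strand",
                  "nt_seq", "aa_seq")

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                   "species")

PHENOTYPE_LEVELS <- c("complete_denitrifier_NO3", "complete_denitrifier_NO2",
                      "partial_denitrifier", "non_denitrifying_N2O_reducer",
                      "no_N2O_reduction")

#' GenomeAnnotation: one annotated genome or MAG
#'
#' Container for a single (metagenome-assembled) genome: a genome identifier,
#' a 7-rank taxonomy lineage (domain..genus, species; placeholders allowed),
#' and the ordered protein-coding gene calls of every contig. Genes live in a
#' single data.frame (`genes` slot) with 1-based inclusive GFF3-style
#' coordinates, a 0-based per-contig `index` giving the rank of each gene
#' along its contig, nucleotide and amino-acid sequences, and a list-column
#' `labels` of functional annotation symbols (gene symbols and/or KO ids).
#'
#' @slot genomeId single genome identifier string.
#' @slot lineage character(7), named domain..species; "" marks missing ranks.
#' @slot genes data.frame with columns gene_id, contig_id, index, start, end,
#'   strand, nt_seq, aa_seq and list-column labels, sorted by
#'   (contig_id, start, end, gene_id).
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", lineage = "character",
                 genes = "data.frame"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    return("genomeId must be a single non-NA string")
  if (length(object@lineage) != 7L)
    return("lineage must have 7 ranks (domain..species)")
  if (!all(GENE_COLUMNS %in% names(g)) || !("labels" %in% names(g)))
    return(paste("genes must have columns",
                 paste(c(GENE_COLUMNS, "labels"), collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("duplicate gene_id")
  if (any(g$end < g$start)) return("gene with end < start")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  for (ctg in unique(g$contig_id)) {
    idx <- g$index[g$contig_id == ctg]
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      return(sprintf("indices on contig '%s' not 0-based contiguous ascending",
                     ctg))
  }
  both <- nzchar(g$nt_seq) & nzchar(g$aa_seq)
  if (any(nchar(g$nt_seq[both]) < 3L * nchar(g$aa_seq[both])))
    return("nt_seq shorter than 3 * aa_seq for a gene with both sequences")
  TRUE
})

#' ReferencePanel: curated full-length NosZ proteins of one clade
#'
#' @slot clade "I" or "II".
#' @slot sequences named [Biostrings::AAStringSet] of panel members.
#' @slot selfScores numeric self-alignment scores (used to normalize
#'   local-alignment scores to the 0..1 range).
#' @export
setClass("ReferencePanel",
  representation(clade = "character", sequences = "AAStringSet",
                 selfScores = "numeric"))

setValidity("ReferencePanel", function(object) {
  if (!object@clade %in% c("I", "II")) return("clade must be 'I' or 'II'")
  if (length(object@sequences) == 0L) return("panel must be non-empty")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("panel sequences must have unique names")
  if (length(object@selfScores) != length(object@sequences))
    return("one self-score per sequence required")
  ltrs <- unique(strsplit(paste(as.character(object@sequences), collapse = ""),
                          "")[[1]])
  if (!all(ltrs %in% AA_STANDARD))
    return("panel sequences must use the 20 standard amino acids")
  TRUE
})

#' ClassifierConfig: thresholds for nosZ detection and clade assignment
#'
#' Defaults implement the published screen: candidate genes must be
#' 1,050-2,200 bp or 350-800 aa; a clade call requires the best normalized
#' panel score to reach `minPanelScore` and the two clade scores to differ by
#' a relative margin of at least `scoreMargin`; accessory genes are accepted
#' within 7 (nosB) or 3 (nosR) genes up- or downstream of nosZ.
#'
#' @slot minAa,maxAa amino-acid length screen bounds (inclusive).
#' @slot minNt,maxNt nucleotide length screen bounds (inclusive).
#' @slot scoreMargin minimum relative margin |sI - sII| / max(sI, sII).
#' @slot minPanelScore minimum normalized panel score for any clade call.
#' @slot nosBWindow,nosRWindow gene-neighborhood windows for nosB / nosR.
#' @export
setClass("ClassifierConfig",
  representation(minAa = "numeric", maxAa = "numeric",
                 minNt = "numeric", maxNt = "numeric",
                 scoreMargin = "numeric", minPanelScore = "numeric",
                 nosBWindow = "integer", nosRWindow = "integer"),
  prototype(minAa = 350, maxAa = 800, minNt = 1050, maxNt = 2200,
            scoreMargin = 0.1, minPanelScore = 0.35,
            nosBWindow = 7L, nosRWindow = 3L))

setValidity("ClassifierConfig", function(object) {
  if (object@minAa >= object@maxAa) return("minAa must be < maxAa")
  if (object@minNt >= object@maxNt) return("minNt must be < maxNt")
  if (object@nosBWindow <= 0L || object@nosRWindow <= 0L)
    return("accessory windows must be > 0")
  if (object@scoreMargin < 0 || object@minPanelScore < 0)
    return("thresholds must be non-negative")
  TRUE
})

#' Create a classifier configuration
#'
#' @param minAa,maxAa,minNt,maxNt length-screen bounds (inclusive).
#' @param scoreMargin relative margin required between the two clade scores.
#' @param minPanelScore minimum normalized panel score for a clade call.
#' @param nosBWindow,nosRWindow accessory-gene proximity windows.
#' @return A validated [ClassifierConfig-class] object.
#' @export
classifierConfig <- function(minAa = 350, maxAa = 800, minNt = 1050,
                             maxNt = 2200, scoreMargin = 0.1,
                             minPanelScore = 0.35, nosBWindow = 7L,
                             nosRWindow = 3L) {
  new("ClassifierConfig", minAa = minAa, maxAa = maxAa, minNt = minNt,
      maxNt = maxNt, scoreMargin = scoreMargin,
      minPanelScore = minPanelScore, nosBWindow = as.integer(nosBWindow),
      nosRWindow = as.integer(nosRWindow))
}

#' DegeneratePrimer: an IUPAC-coded primer with its summary statistics
#'
#' @slot seq primer sequence 5'->3' over IUPAC nucleotide codes.
#' @slot alnStart 0-based column of the source alignment window.
#' @slot fold total fold-degeneracy (product of per-position alternatives).
#' @slot tmRange melting-temperature interval (deg C) over all expansions.
#' @slot gcRange GC-fraction interval over all expansions.
#' @export
setClass("DegeneratePrimer",
  representation(seq = "character", alnStart = "integer", fold = "numeric",
                 tmRange = "numeric", gcRange = "numeric"))

setValidity("DegeneratePrimer", function(object) {
  if (length(object@seq) != 1L || !nzchar(object@seq))
    return("seq must be a single non-empty string")
  bad <- setdiff(strsplit(toupper(object@seq), "")[[1]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) return(paste("invalid IUPAC code(s):",
                                paste(bad, collapse = ",")))
  card <- vapply(strsplit(toupper(object@seq), "")[[1]],
                 function(b) nchar(Biostrings::IUPAC_CODE_MAP[[b]]), 0)
  if (abs(prod(card) - object@fold) > 1e-6)
    return("fold must equal the product of per-position cardinalities")
  if (length(object@tmRange) != 2L || length(object@gcRange) != 2L)
    return("tmRange and gcRange must be length-2 intervals")
  TRUE
})

#' PrimerPair: a forward/reverse degenerate primer pair
#'
#' The reverse primer is stored 5'->3' on the minus strand (i.e. as it would
#' be synthesized).
#'
#' @slot forward,reverse [DegeneratePrimer-class] objects.
#' @slot productRange predicted product-length interval across the intended
#'   templates (nt).
#' @slot subcladeId identifier of the targeted subclade.
#' @export
setClass("PrimerPair",
  representation(forward = "DegeneratePrimer", reverse = "DegeneratePrimer",
                 productRange = "numeric", subcladeId = "character"))

#' DesignConstraints: primer-design constraints
#'
#' Defaults implement the published criteria: Tm between 51 and 58 deg C, GC
#' content between 40% and 60%, fold-degeneracy at most 3, at most 3
#' mismatches against any intended template, and target fragments strictly
#' longer than 1,000 bp.
#'
#' @slot tmMin,tmMax melting-temperature bounds (deg C).
#' @slot gcMin,gcMax GC-fraction bounds.
#' @slot maxDegeneracy maximum total fold-degeneracy.
#' @slot maxMismatch maximum mismatches against any intended template.
#' @slot minProduct minimum product length (strict, nt).
#' @slot lenMin,lenMax primer length range (nt).
#' @export
setClass("DesignConstraints",
  representation(tmMin = "numeric", tmMax = "numeric", gcMin = "numeric",
                 gcMax = "numeric", maxDegeneracy = "numeric",
                 maxMismatch = "integer", minProduct = "numeric",
                 lenMin = "integer", lenMax = "integer"),
  prototype(tmMin = 51, tmMax = 58, gcMin = 0.40, gcMax = 0.60,
            maxDegeneracy = 3, maxMismatch = 3L, minProduct = 1000,
            lenMin = 18L, lenMax = 25L))

setValidity("DesignConstraints", function(object) {
  if (object@tmMin >= object@tmMax) return("tmMin must be < tmMax")
  if (object@gcMin <= 0 || object@gcMax >= 1 || object@gcMin >= object@gcMax)
    return("gc bounds must satisfy 0 < gcMin < gcMax < 1")
  if (object@maxDegeneracy < 1) return("maxDegeneracy must be >= 1")
  if (object@lenMin < 14L || object@lenMax < object@lenMin)
    return("primer length range invalid")
  TRUE
})

#' Create primer-design constraints
#'
#' @param tmMin,tmMax,gcMin,gcMax,maxDegeneracy,maxMismatch,minProduct,lenMin,lenMax
#'   see [DesignConstraints-class]; defaults are the published criteria.
#' @return A validated [DesignConstraints-class] object.
#' @export
designConstraints <- function(tmMin = 51, tmMax = 58, gcMin = 0.40,
                              gcMax = 0.60, maxDegeneracy = 3,
                              maxMismatch = 3L, minProduct = 1000,
                              lenMin = 18L, lenMax = 25L) {
  new("DesignConstraints", tmMin = tmMin, tmMax = tmMax, gcMin = gcMin,
      gcMax = gcMax, maxDegeneracy = maxDegeneracy,
      maxMismatch = as.integer(maxMismatch), minProduct = minProduct,
      lenMin = as.integer(lenMin), lenMax = as.integer(lenMax))
}

## ---- generics & accessors ----

#' @rdname GenomeAnnotation-class
#' @param object,x a GenomeAnnotation.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname GenomeAnnotation-class
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GenomeAnnotation-class
#' @export
setGeneric("contigNames", function(x) standardGeneric("contigNames"))
#' @rdname ReferencePanel-class
#' @export
setGeneric("cladeLabel", function(x) standardGeneric("cladeLabel"))
#' @rdname ReferencePanel-class
#' @export
setGeneric("panelSequences", function(x) standardGeneric("panelSequences"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)
#' @rdname GenomeAnnotation-class
#' @export
setMethod("lineage", "GenomeAnnotation", function(x) x@lineage)
#' @rdname GenomeAnnotation-class
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname GenomeAnnotation-class
#' @export
setMethod("contigNames", "GenomeAnnotation",
          function(x) unique(x@genes$contig_id))
#' @rdname ReferencePanel-class
#' @param x a ReferencePanel.
#' @export
setMethod("cladeLabel", "ReferencePanel", function(x) x@clade)
#' @rdname ReferencePanel-class
#' @export
setMethod("panelSequences", "ReferencePanel", function(x) x@sequences)

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation '%s': %d gene(s) on %d contig(s)\n",
              object@genomeId, nrow(object@genes),
              length(unique(object@genes$contig_id))))
  lin <- object@lineage[nzchar(object@lineage)]
  if (length(lin))
    cat("  lineage:", paste(lin, collapse = "; "), "\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel clade %s: %d sequence(s), %d-%d aa\n",
              object@clade, length(object@sequences),
              min(Biostrings::width(object@sequences)),
              max(Biostrings::width(object@sequences))))
})

setMethod("show", "DegeneratePrimer", function(object) {
  cat(sprintf("DegeneratePrimer %s (fold %g, Tm %.2f-%.2f, GC %.2f-%.2f)\n",
              object@seq, object@fold, object@tmRange[1], object@tmRange[2],
              object@gcRange[1], object@gcRange[2]))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair [%s]\n  F: %s\n  R: %s\n  product %g-%g nt\n",
              object@subcladeId, object@forward@seq, object@reverse@seq,
              object@productRange[1], object@productRange[2]))
})
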