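## Genotype-to-phenotype profiling of nitrogen metabolism: module
## completeness (100% rule) + the phenotype decision table.

#' Define a metabolic module
#'
#' A module is an ordered list of steps; each step is a set of alternative
#' label groups; a group is a set of labels that must ALL be present (e.g.
#' the nitrate-reduction step is satisfied by napA+napB or by
#' narG+narH+narI).
#'
#' @param module_id module identifier.
#' @param steps list of steps, each a list of character vectors (groups).
#' @return A `nitrogenModule` list object.
#' @export
nitrogenModule <- function(module_id, steps) {
  if (!length(steps)) stop("module '", module_id, "' has no steps")
  for (st in steps) {
    if (!length(st) || any(!lengths(st)))
      stop("module '", module_id, "' has an empty step or group")
  }
  structure(list(module_id = module_id, steps = steps),
            class = "nitrogenModule")
}

#' Bundled nitrogen-metabolism module definitions
#'
#' Transparent, config-overridable stand-ins for the curated KEGG-module
#' lists: nitrate reduction to nitrite (nap/nar), nitrite to NO (nirK|nirS),
#' NO to N2O (norB|norC, any-of), N2O to N2 (nosZ), DNRA
#' (nrfA+nrfH | nirB+nirD) and assimilatory nitrate reduction
#' (nasA+nasB | NR).
#'
#' @return Named list of [nitrogenModule()] definitions.
#' @export
defaultNitrogenModules <- function() {
  list(
    nap_nar = nitrogenModule("nap_nar",
      list(list(c("napA", "napB"), c("narG", "narH", "narI")))),
    nir = nitrogenModule("nir", list(list("nirK", "nirS"))),
    nor = nitrogenModule("nor", list(list("norB", "norC"))),
    nos = nitrogenModule("nos", list(list("nosZ"))),
    dnra = nitrogenModule("dnra",
      list(list(c("nrfA", "nrfH"), c("nirB", "nirD")))),
    anr = nitrogenModule("anr", list(list(c("nasA", "nasB"), "NR"))))
}

#' Read module definitions from a YAML config
#'
#' Expected structure: a mapping module_id -> list of steps, each step a
#' list of groups, each group a list of labels.
#'
#' @param path YAML file.
#' @return Named list of [nitrogenModule()] definitions.
#' @export
readModuleDefinitions <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    steps <- lapply(raw[[id]], function(st) lapply(st, as.character))
    nitrogenModule(id, steps)
  })
  setNames(out, names(raw))
}

#' Is a module 100% complete given a label set?
#'
#' TRUE iff every step of the module has at least one alternative group
#' whose labels are all present (the 100%-completeness rule). Monotone in
#' the label set.
#'
#' @param labels character vector of present annotation labels.
#' @param module a [nitrogenModule()].
#' @return Logical.
#' @export
moduleComplete <- function(labels, module) {
  if (!inherits(module, "nitrogenModule")) stop("not a nitrogenModule")
  labels <- normalizeLabels(labels)
  all(vapply(module$steps, function(step) {
    any(vapply(step, function(group) all(group %in% labels), TRUE))
  }, TRUE))
}

#' Genome labels pooled over all genes
#'
#' @param genome a [GenomeAnnotation-class].
#' @return Character vector of normalized labels present in the genome.
#' @export
genomeLabels <- function(genome) {
  normalizeLabels(unlist(genes(genome)$labels, use.names = FALSE))
}

#' Nitrogen-metabolism phenotype of one genome
#'
#' Derives presence booleans from the genome's pooled labels plus the nosZ
#' hit table, then applies the decision table: nosZ & nirK/S & norB/C &
#' nap/nar -> complete denitrifier from NO3; nosZ & nirK/S & norB/C ->
#' complete denitrifier from NO2; nosZ lacking both norB/C and nirK/S ->
#' non-denitrifying N2O reducer (nap/nar presence does not demote); any
#' other nosZ-positive genome -> partial denitrifier; no nosZ -> no N2O
#' reduction. Exactly one label per genome.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param nosz_hits hit data.frame for this genome from
#'   [classifyGenomeNosz()]; if NULL, nosZ presence falls back to the labels.
#' @param modules module definitions, see [defaultNitrogenModules()].
#' @return One-row data.frame (a phenotype profile).
#' @export
phenotypeProfile <- function(genome, nosz_hits = NULL,
                             modules = defaultNitrogenModules()) {
  labels <- genomeLabels(genome)
  if (is.null(nosz_hits)) {
    has_nosZ <- "nosZ" %in% labels
    clades <- ""
  } else {
    mine <- nosz_hits[nosz_hits$genome_id == genomeId(genome), , drop = FALSE]
    has_nosZ <- nrow(mine) > 0L
    clades <- paste(sort(unique(mine$clade[mine$clade %in% c("I", "II")])),
                    collapse = "+")
  }
  has_nirKS <- any(c("nirK", "nirS") %in% labels)
  has_norBC <- any(c("norB", "norC") %in% labels)
  has_napnar <- moduleComplete(labels, modules$nap_nar)
  dnra <- moduleComplete(labels, modules$dnra)
  anr <- moduleComplete(labels, modules$anr)
  phenotype <-
    if (!has_nosZ) "no_N2O_reduction"
    else if (has_nirKS && has_norBC && has_napnar) "complete_denitrifier_NO3"
    else if (has_nirKS && has_norBC) "complete_denitrifier_NO2"
    else if (!has_nirKS && !has_norBC) "non_denitrifying_N2O_reducer"
    else "partial_denitrifier"
  data.frame(genome_id = genomeId(genome),
             phylum = unname(lineage(genome)["phylum"]),
             has_nosZ = has_nosZ, clades = clades, has_nirKS = has_nirKS,
             has_norBC = has_norBC, has_napnar = has_napnar,
             dnra_complete = dnra, anr_complete = anr,
             phenotype = phenotype, stringsAsFactors = FALSE)
}

#' Cohort summary of phenotypes, clades and phyla
#'
#' Counts are exact; every percentage row carries its numerator and explicit
#' denominator and is rounded half-up to 1 decimal via [percentage()].
#'
#' @param profiles data.frame of rbind-ed [phenotypeProfile()] rows.
#' @param hits optional combined hit table; adds clade and unique-gene rows.
#' @return data.frame with columns section, level, count, denominator,
#'   percent.
#' @export
cohortSummary <- function(profiles, hits = NULL) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("cohortSummary needs at least one profile")
  n <- nrow(profiles)
  row <- function(section, level, count, den)
    data.frame(section = section, level = level, count = count,
               denominator = den,
               percent = percentage(count, den), stringsAsFactors = FALSE)
  out <- list(row("cohort", "nosZ_positive", sum(profiles$has_nosZ), n))
  for (ph in PHENOTYPE_LEVELS)
    out[[length(out) + 1L]] <-
      row("phenotype", ph, sum(profiles$phenotype == ph), n)
  if (!is.null(hits) && nrow(hits) > 0L) {
    byg <- split(hits$clade, hits$genome_id)
    gI <- sum(vapply(byg, function(x) "I" %in% x, TRUE))
    gII <- sum(vapply(byg, function(x) "II" %in% x, TRUE))
    den <- sum(vapply(byg, function(x) any(x %in% c("I", "II")), TRUE))
    if (den > 0L) {
      out[[length(out) + 1L]] <- row("clade", "I", gI, den)
      out[[length(out) + 1L]] <- row("clade", "II", gII, den)
    }
    uniq <- uniqueNoszGenes(hits)
    out[[length(out) + 1L]] <-
      row("genes", "unique_nosZ", nrow(uniq), nrow(hits))
    cladeII_gen <- profiles$genome_id %in%
      names(byg)[vapply(byg, function(x) "II" %in% x, TRUE)]
    if (any(cladeII_gen)) {
      phyla <- profiles$phylum[cladeII_gen]
      for (p in sort(unique(phyla)))
        out[[length(out) + 1L]] <-
          row("phylum_cladeII", p, sum(phyla == p), sum(cladeII_gen))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
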