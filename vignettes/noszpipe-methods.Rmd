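---
title: "noszpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{noszpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Nitrous oxide reductase (NosZ) is the only known enzymatic sink for the
greenhouse gas N2O. Its gene, *nosZ*, falls into two major phylogenetic
clades: clade I typically exports the folded protein via the twin-arginine
(tat) pathway and carries the accessory gene *nosR* nearby; clade II uses
the general secretory (sec) pathway and carries *nosB*, usually directly
downstream. Organisms carrying *nosZ* but lacking nitrite reductase
(*nirK*/*nirS*) and NO reductase (*norB*/*norC*) are non-denitrifying N2O
reducers: they can consume N2O without producing it, which makes them
attractive targets in engineered systems such as activated sludge.

`noszpipe` implements the desk-scale core of a *nosZ* profiling workflow on
annotated genome assemblies:

1. **genome ingest** — GFF3 gene calls plus nucleotide/protein FASTA and a
   tabular annotation file become a `GenomeAnnotation` object: per-contig,
   start-sorted gene records with a 0-based rank index. The rank index is
   the axis on which all "within *k* genes" rules operate.
2. **nosZ classification** — candidate genes are scored against curated
   clade I/II reference panels by local alignment; a clade call requires a
   minimum normalized score and a relative margin between the two clade
   scores. A length screen, a secretion-pathway call and accessory-gene
   proximity checks complete each hit.
3. **phenotype profiling** — KEGG-style module completeness (the 100% rule)
   plus a decision table assign each genome one of five nitrogen-metabolism
   phenotypes.
4. **primer design** — degenerate long-fragment primer pairs on subclade
   alignments under Tm/GC/degeneracy/mismatch/product-length constraints.
5. **in-silico PCR** — IUPAC-aware, mismatch-tolerant binding-site search
   and amplicon prediction used to validate the designed primers.
6. **amplicon pipeline** — long-read filtering, UNOISE-style denoising into
   OTUs, and consensus taxonomy against a lineage-annotated *nosZ*
   database.
7. **synthetic data** — generators for panels, genomes and reads with known
   truth, so every stage is testable end to end without any download.

# Alignment scoring and clade assignment

`scoreAgainstPanel()` computes Smith–Waterman local alignments (BLOSUM62,
affine gaps: a gap of length L costs 11 + L) via
`Biostrings::pairwiseAlignment` and divides each raw score by the
self-alignment score of the reference. The normalized score is 1 for a
query identical to a reference and near 0 for unrelated sequences, giving
thresholds a scale that is independent of reference length. This replaces
e-value machinery with two explicit knobs:

* `minPanelScore = 0.35` — the best normalized score a query must reach
  before any clade call is made. Random proteins score well below 0.1
  against the bundled panels; genuine homologs at 30% divergence still
  score around 0.5.
* `scoreMargin = 0.1` — the relative margin `|sI - sII| / max` required
  between the clade scores. Exact ties are therefore always unclassified.

For users who ran an external homology search instead,
`applyExternalHits()` consumes a (query, reference, e-value) table and
applies the conventional 1e-10 cutoff.

The length screen (1,050–2,200 bp **or** 350–800 aa, inclusive) is a literal
reading of the published rule, with OR semantics across the two ranges. A
gene that fails it is still reported when annotated as *nosZ*, but always as
`unclassified` with `length_pass = FALSE`, so a clade call implies a
passing length.

Unlabeled genes are panel-scored only if they pass the length screen first;
a gene outside the length range can never receive a clade call, so scoring
short decoy ORFs against the panels would add cost without changing any
result. Annotated *nosZ* genes are always scored.

# Secretion and accessory-gene evidence

The secretion pathway is called by a documented motif heuristic (a named,
swappable stand-in for a full signal-peptide predictor): a protein is `tat`
if the twin-arginine consensus `[ST]RR.[FGAVML][LITMVF]` occurs within the
first 35 residues, else `sec` if the first 6 residues contain K/R and the
first 30 contain a hydrophobic run of at least 7 residues, else `none`.
Proteins shorter than 40 residues yield `none` with a warning.

Accessory genes are searched in the gene-rank neighborhood: *nosB* within 7
genes up- or downstream of *nosZ*, *nosR* within 3, counting genes on both
strands (the source rule does not state a strand restriction; counting all
genes is the simpler, documented choice). The nearest match wins; an exact
distance tie is resolved downstream, reflecting the canonical position of
*nosB* directly downstream of clade II *nosZ*.

# Phenotype decision table

Module completeness is monotone and literal: a module is present iff every
step has at least one alternative gene group fully present. The bundled
module set (overridable from YAML) covers nitrate reduction
(napA+napB | narG+narH+narI), nitrite reduction (nirK | nirS), NO reduction
(norB | norC — any-of, so "lacking norB/C" means lacking both), N2O
reduction (nosZ), DNRA (nrfA+nrfH | nirB+nirD) and assimilatory nitrate
reduction (nasA+nasB | NR). The decision table is, in order: complete
denitrifier from NO3 (nosZ, nirK/S, norB/C, nap/nar), complete denitrifier
from NO2, non-denitrifying N2O reducer (nosZ without norB/C and without
nirK/S — nap/nar presence does *not* demote), partial denitrifier (any other
nosZ-positive genome), no N2O reduction. The five labels are mutually
exclusive and exhaustive.

# Primer design

Windows of 18–25 nt (a standard long-amplicon range; the constraint set
itself fixes Tm 51–58 °C, GC 40–60%, fold-degeneracy ≤ 3, ≤ 3 mismatches
per template, product > 1,000 bp) slide over gapless alignment columns. The
per-window consensus uses the exact IUPAC code of the observed bases, so
degeneracy is never wasted: every subclade member matches its consensus
with zero mismatches, and total fold-degeneracy is the product of
per-position alternative counts ("allowed degeneracy of 3" is read as a
bound on that product). Melting temperature uses the GC-count linear model
`Tm = 64.9 + 41 (nGC − 16.4) / L`, evaluated at the minimum- and
maximum-GC concrete expansions; both interval endpoints are attained by
actual pool members. A nearest-neighbor model is deliberately out of scope
and the Tm component is swappable.

Forward windows pair with downstream reverse windows (the reverse primer is
stored 5'→3' on the minus strand) when the ungapped template span exceeds
1,000 nt in every member; pairs are ranked by total fold, then total Tm
interval width, then product length. When nothing passes, the empty result
carries a diagnostic naming the filter that eliminated the most windows.

# In-silico PCR

Binding sites are scanned on both strands with set-intersection IUPAC
matching, which makes the mismatch count of a degenerate primer equal the
minimum over its concrete expansions (a pool contains its best-matching
member). The mismatch-fraction bound is strict (`< 0.20`), applied per
primer, and every position weighs equally (3'-clamp effects are not
modeled, matching the semantics of the standard in-silico screening tools).
Products are reported on the plus strand of the template with the
initiating-primer orientation in a `strand` column, so amplifying a
reverse-complemented template yields exactly the reverse-complemented
products.

# Amplicon pipeline

Reads are kept when 800–2,500 nt long (inclusive) and mean Phred quality is
strictly above 7; reads without quality information pass on length alone.
The published conflation of "80% accuracy" with "Q > 7" is resolved in
favor of the strict Q cutoff.

Denoising follows the published UNOISE skew criterion: after
dereplication, unique sequences are processed in descending (abundance,
length, sequence) order and merge into the first centroid for which
identity ≥ 0.97 **and** abundance ratio ≤ β(d) = 1/2^(αd + 1) with α = 2
and d the edit distance. Identity is matches / alignment length of the
unit-cost global alignment. Because β shrinks geometrically in d, a
variant can only merge when its abundance is far below the centroid's;
the implementation exploits this by skipping alignments whose merge is
arithmetically impossible, which changes nothing in the output. With
minimum founding abundance 1, low-coverage error reads found their own
OTUs — the same behavior as the emulated flag combination.

Consensus taxonomy takes the up-to-10 best hits at ≥ 0.8 identity and walks
domain → species keeping any rank value shared by ≥ 51% of the hits,
truncating at the first rank without consensus; centroids without hits are
unassigned and exportable for external follow-up.

# Synthetic data: what it emulates, and what it does not

The generator is a controllability tool, not a sequence-evolution model.
Panels derive from two random ancestor proteins (640 and 660 aa, echoing
full-length NosZ) separated by 0.45 substitutions/site, with 20 clade I and
46 clade II members drawn at half the intra-clade divergence each (so
pairwise intra-panel identity averages ~85%). Genomes are single contigs of
decoy ORFs (rejection-sampled below 20% identity to the ancestors, 80–330
aa so they cannot enter the length screen) plus the implanted gene
complement realizing the requested phenotype, nosZ gene(s) with the
requested signal prefix and divergence, and accessory genes at exact rank
offsets. Back-translation uses a fixed codon table chosen at ~50% GC so
that generated nucleotide genes contain windows satisfying the primer
GC/Tm constraints. Reads receive uniform substitutions and indels and a
normally distributed per-read mean quality.

Consequently, passing the end-to-end suites shows that the *rules* are
implemented exactly and recoverably — it does not show robustness to
homopolymer error profiles, compositional bias, horizontal transfer or
phylogenetically correlated divergence, which real data exhibit and the
generator deliberately omits.

Problem sizes used by the validation suites, chosen to exercise each stage
at realistic desk scale: a 120-genome cohort at 2–10% divergence (plus a
40-genome control at 28–30%), 6-member subclades at 1% divergence for
primer closure, and 5 templates × 200 reads at 2% total error (1.5%
substitutions + 0.5% indels) on 900-nt amplicon-scale templates whose
mutual divergence (~30%) keeps consensus classification unambiguous.

# Numerical choices and degenerate inputs

* Gene order ties (equal start) break by end, then gene id — indices are
  independent of file order.
* Percentages round half-up to one decimal (70/401 → 17.5), matching the
  reporting style of the printed statistics; banker's rounding would flip
  edge cases.
* `assignClade` on indistinguishable panels (inter-clade divergence 0)
  returns `unclassified` by the margin rule — the degenerate control.
* Empty inputs: an empty GFF yields a zero-contig genome; an empty read set
  yields an empty OTU table; an empty hit table is an export error.
* Lineages carry 7 ranks (domain…genus, species); species may be empty, and
  6-field database headers are accepted.

# Known limitations

* The clade II sub-split suggested by dual clade II reference models is not
  exposed; calls are I / II / unclassified only.
* PRED-TAT-class signal-peptide accuracy is not claimed; the motif
  heuristic is a labeled stand-in and swappable.
* Tree building (MUSCLE/IQ-TREE) is out of scope; `exportInterop()` writes
  MSA-ready FASTA for external tools.
* Primer thermodynamics beyond the GC-count Tm model (dimers, hairpins,
  3'-clamping) are not modeled.
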