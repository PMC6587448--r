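---
title: "Models and methods in panforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in panforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`panforge` implements a pan-genome analysis workflow for several
varieties of a single plant species — the kind of study in which a few
re-sequenced or independently assembled genotypes of one crop are
compared to split the gene complement into a *core* set (present in every
variety) and a *dispensable* set (present in some), and to ask which
genes arose by whole-genome or tandem duplication and which evolve under
unusual selective pressure. This vignette documents the models behind
each stage, the tunable parameters, the numerical choices, and the
limits of what the synthetic-data experiments can show.

## 1. The synthetic study system

Real pan-genome studies start from assemblies and annotations that are
far too large for routine testing. `panforge` therefore ships a
first-class generator, `simulate_pangenome()`, which produces a complete
five-variety study system with known truth:

* **Panel and tree.** The default panel has five varieties — two modern
  Chinese cultivar analogs (`zz13`, `yz11`), two landrace analogs
  (`bzm`, `mszm`) and one Indian cultivar analog (`swetha`) — related by
  the rooted tree `((((zz13,yz11),bzm),mszm),swetha)`. Node heights
  mirror divergence times of roughly 0.9, 4.7, 5.5 and 14.2 MY, and
  branch lengths assume a uniform 0.01 substitutions/codon/MY, giving a
  maximal intra-panel divergence of ~9% at the nucleotide level —
  comfortably within what a single similarity cutoff clusters.
* **Families.** 500 core and 100 dispensable families by default
  (tests at roughly 3,000 genes overall). Each family descends from a
  random ancestral coding sequence of 300 codons evolved along the tree
  under a GY94 codon model (default ω = 0.2, κ = 2.5, uniform codon
  frequencies). Dispensable families are evolved on the full tree and
  then restricted to a random proper subset of **at least two**
  varieties; singleton families would be indistinguishable from
  variety-specific genes, which are modelled separately.
* **Variety-specific genes.** 40 per variety by default, generated as
  fresh random codon sequences. Two independent random coding sequences
  share ~25% nucleotide identity, far below any clustering threshold, so
  these genes are guaranteed to stay unclustered. The generator does not
  model the biological origin of such genes (gain vs loss along the
  tree); they are simply present without homologs.
* **Duplications.** Tandem arrays insert diverged copies (2% point
  divergence, stop codons rejected) directly next to a donor gene.
  Duplicated blocks copy a run of consecutive family genes onto another
  chromosome in order. The outgroup used for collinearity is a shuffled
  family order in which only the planted block regions stay contiguous,
  so chains of ≥ 15 anchors exist exactly where blocks were planted.
* **Layout.** Genes occupy 13 chromosomes with fixed 200 bp intergenic
  spacers; coordinates are 0-based half-open internally and 1-based
  inclusive in GFF3 output. Each variety gets an independent family
  order: planted syntenic runs must remain variety-specific for the
  planted truth to be recoverable, so cross-variety gene-order
  conservation is deliberately not modelled (and nothing downstream
  relies on it — collinearity is only assessed against the outgroup).

What the synthetic data deliberately do **not** contain: repeats and
transposons, fragmented or chimeric gene models, alignment errors,
unequal gene lengths within a family, or assembly gaps. Passing the
planted-truth tests therefore demonstrates that the algorithms are
implemented correctly, not that the pipeline is robust to the noise of
real annotation projects.

## 2. Scaffolding

`place_fragments()` implements reference-assisted placement with a
best/second-best score-ratio rule (default 1.05, **inclusive**, so a
ratio of exactly 1.05 places). Hits from one fragment to one
chromosome/strand are first merged when their reference positions fall
within one fragment length, summing scores; this approximates a
whole-fragment placement score from local alignments. Placed fragments
are joined with 100-N linkers in anchor order (ties broken by fragment
id); everything else lands in an unplaced bin, so no sequence is ever
lost. `assembly_stats()` reports N50 by the cumulative-sum definition.

## 3. Gene-set refinement

`refine_gene_set()` applies three rules, in order: (i) two consecutive
same-strand genes whose only evidence is one shared homolog, hitting
non-overlapping parts of it, are merged into a single model (CDS
interval union — re-alignment of the merged locus is out of scope);
(ii) genes whose CDS is covered ≥ 50% (inclusive) by the union of
protein and transcript evidence are kept; (iii) genes below 50% are
kept only when both ab initio sources predicted them. Protein and
transcript evidence count as one union; the refinement is idempotent
and adding evidence can only help a gene.

## 4. Ortholog clustering

Similarity edges come either from Smith–Waterman alignment (BLOSUM62,
affine gaps 11/1) with Karlin–Altschul e-values (fixed gapped-BLOSUM62
constants λ = 0.267, K = 0.041), or from any externally computed
outfmt-6 table. `mcl_cluster()` is a from-scratch Markov clustering:
edge weights are −log10(e-value) capped at 300, reciprocal edges are
averaged, self-loops are added at each node's maximum incident weight,
and the column-stochastic matrix is alternately squared (expansion) and
entrywise powered (inflation, default 1.5) with pruning below 1e-6
until idempotence within 1e-8 or 200 iterations. Clusters are the
connected components of the converged matrix's support; singletons are
reported as unclustered, which is also the operational definition of
*variety-specific* genes. The full OrthoMCL within/between-species
weight normalisation is deliberately not reproduced — the package is
validated against planted truth, not against OrthoMCL bit-for-bit.

## 5. Pan-genome composition

A cluster is *core* iff every panel variety contributes at least one
member; everything else is *dispensable* (including clusters confined
to one variety). Percentages are computed over clusters only;
unclustered genes are reported separately and added to the per-variety
dispensable gene counts. For genome regions, each alignment block
contributes its longest member span exactly once (non-redundant
accounting, which is the only convention under which core + dispensable
can exceed any single genome but stay far below the summed genome
sizes), and per-variety unaligned sequence counts as dispensable.
Overlapping spans within a variety are merged before length accounting.

## 6. Duplication origin

Tandem arrays are maximal single-linkage groups of homologous genes
(self-hits at e ≤ 1e-20) separated by fewer than `max_gap` intervening
genes; the default `max_gap = 1` means strictly adjacent. Collinear
blocks are found by dynamic-programming chaining of anchor pairs with
per-step gaps ≤ 1 gene on both genomes, both orientations, keeping
maximal chains of ≥ 15 anchors (anchor-count scoring); each anchor
joins at most one block, longest chain first. A gene in a block anchor
is WGD-type, a gene in an array is TD-type, and TD wins when both
apply — the published per-class percentages are disjoint, so a
precedence is required, and the tandem array is the more specific
signal.

## 7. Codon models and the selection screens

The substitution model is GY94: single-nucleotide codon changes with
transition bias κ and nonsynonymous bias ω, target-codon frequencies
from F3x4 (per-position nucleotide frequencies; F1x4 and uniform are
available — the simulator uses uniform by default, and simulator and
estimator agree on whichever is chosen). Rate matrices are normalised
to one expected substitution per codon; **in site-class mixtures the
normalisation is shared across classes per branch** (each class runs at
μ_c/μ̄ times the branch rate). This convention matters: normalising each
class separately removes the substitution surplus that positively
selected sites carry and with it most of the branch-site test's power.

Likelihoods use Felsenstein pruning over the 61 sense codons with site
pattern compression and log-space rescaling; gap/ambiguous codons are
missing data. Fits maximise over κ, the model's ω parameters, mixture
proportions and **all branch lengths** (re-estimated per model) with
bounded L-BFGS-B; rooted input trees are unrooted first (the model is
reversible), preserving PAML-style `#1` foreground tags by matching
clade tip sets. Initialisation follows common practice: κ = 2.5,
ω = 0.2, branch-site alternative ω₂ = 1.5. The branch-site alternative
surface is multimodal, so `fit_branchsite_models()` tries several ω₂
starts and keeps the best; when the optimum still falls below the null
the MLE is taken at the ω₂ = 1 boundary (the null solution).

The screens follow the three-hypothesis design: H0 (one ω), H1
(foreground branch ω vs background ω), H2 (free ω per branch). A family
is *fast-evolving* when BH-adjusted p(H1 vs H0, df = 1) < 0.01, the
adjusted p(H2 vs H1) is **not** significant, and ω̂_fg > ω̂_bg. The df
for H2 vs H1 is taken as (branches − 2), the difference in free ω
parameters. A family is *positively selected* when the branch-site
alternative beats its null (df = 1, plain χ²₁ — conservative relative
to the 50:50 boundary mixture) with BH-adjusted p < 0.01 and ω̂₂ > 1.
BH is used wherever FDR correction is required.

`ng86_dnds()` is the independent counting cross-check: NG86 site
counts, pathway-averaged differences (stop-passing pathways excluded),
Jukes–Cantor correction. NG86 weights mutational pathways equally, so
it is consistent only without transition bias; its Monte-Carlo
recovery checks simulate at κ = 1, while the likelihood fits are
checked at the study κ of 2.5 (at κ = 2.5 NG86 is biased by roughly
10%, a textbook property, not a defect).

Calibration experiments run at deliberately desk-sized settings: the
null calibration uses 200 replicates of 2 kb alignments on a four-taxon
tagged tree (type-I error must stay within three binomial standard
errors of the nominal 0.01), and the power experiment uses 50
replicates of 5 kb with foreground ω 0.8 against background 0.2
(≥ 80% of families called). Four taxa are the smallest tree with a
distinct internal foreground branch; power grows with both taxa and
alignment length, so these sizes are the conservative end.

## 8. Phylogeny and dating

The tree stage replaces heavy ML search and Bayesian dating with
deterministic desk-scale counterparts, validated by simulation
recovery rather than by re-estimating any published dataset:

* `align_family()`: center-star progressive protein alignment
  (Needleman–Wunsch to the longest sequence, gap patterns merged),
  back-translated to codons. Equal-length in-frame input is treated as
  already aligned, which is exactly what the simulator produces.
* `filter_columns()`: an explicit two-rule site filter — drop columns
  with any gap (configurable fraction) and columns whose majority
  residue frequency falls below 0.5. Block-level heuristics of
  conservation filters are intentionally not reproduced; the published
  filtered-site count is therefore not a target.
* `gtr_distances()`: the closed-form GTR distance
  d = −tr(Π log(Π⁻¹ F)) on the symmetrised divergence matrix, with a
  Tamura–Nei fallback when the matrix logarithm is undefined and a cap
  (default 5) for saturated pairs.
* `nj_tree()`: neighbor-joining with negative branch lengths clamped
  to zero (deficit moved to the sibling edge) and outgroup rooting.
* `fourfold_sites()`: third positions of codon sites whose first two
  positions are identical in every taxon and define a fourfold
  degenerate box — a conservative extraction suited to dating.
* `strict_clock_dating()`: node ages and a single rate minimising the
  squared difference between r·(age_root − age_node) and the observed
  root-to-node path lengths, under parent>child ordering and hard
  calibration boxes. Calibration bounds are propagated through the
  order constraints (a child's minimum lifts its ancestors' minima)
  before a coordinate-descent inner solver runs inside a golden-section
  search over the rate; the procedure is fully deterministic. With an
  interval calibration and an exactly clock-like tree the rate is only
  identified up to the interval — a property of the problem, not of the
  solver; point calibrations recover ages exactly.

Two recovery experiments back this stage. First, the solver itself:
random 12-taxon trees with known ages (root scaled to a 66 MY analog)
and exactly clock-like branch lengths are dated from the true root
age; every node age returns within 5% (in practice, exactly). Second,
the full sequence pipeline: 20,000 codons simulated on a clock tree
whose node heights mimic the five-variety panel plus seven outgroup
lineages (0.9 / 4.7 / 5.5 / 14.2 / 66 / 117 / 160 MY, rate 0.003
substitutions/codon/MY), fourfold-degenerate sites extracted, the tree
rebuilt by NJ and dated from the true root age. Deep nodes return
within ~10%. A single deep calibration propagates its rate uncertainty
multiplicatively — a 0.3% rate error moves a 0.9 MY node by more than
its own age — so shallow nodes estimated this way carry a few MY of
sampling noise at this alignment size; that is a property of
deep-calibration strict-clock dating, not of the solver. Rooting on an
outgroup places the root at the depth-balancing point of the stem edge
(pairwise distances cannot locate it within that edge).

## 9. Problem sizes and determinism

Every stochastic component is driven by explicit seeds; identical
configuration and seed give byte-identical output files (checksummed
manifests make this testable). The shipped experiments use: a ~3,000
gene five-variety dataset for pipeline recovery, 200 × 2 kb null
replicates and 50 × 5 kb power replicates for LRT calibration, 8 × 10
kb pairs per ω for NG86 recovery, and one 20,000-codon 12-taxon
alignment for phylogeny and dating. These sizes were chosen so the
entire validation runs comfortably on a single CPU while keeping
Monte-Carlo error well inside the asserted tolerances.

## 10. Known limitations

* The branch-site screen has modest power on very small trees; with
  four taxa even strong planted signals are often absorbed by the
  null's free neutral-class proportion. Six or more taxa with a few
  background branches behave much better (and the study design this
  package mirrors used ten species).
* NG86 is biased under transition bias (see §7) and undefined when
  dS = 0; the `omega_defined` flag reports this.
* The center-star aligner is adequate for closely related in-frame
  sequences, not a general MSA tool.
* The scaffolder's hit merging is a stated approximation of
  whole-fragment placement; no misassembly detection is attempted.
* Strict-clock dating assumes a single rate; rate variation across
  branches maps directly into age error.
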