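---
title: "Tracing the evolution of NBS-encoding resistance gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the evolution of NBS-encoding resistance gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrtrace)
```

## Background

Plant disease-resistance (R) genes with a nucleotide-binding site (NB-ARC)
domain — NBS-encoding or NLR genes — form large, fast-evolving families.
Comparative studies of closely related genomes classify each gene by its
domain architecture (TIR-, CC- or RPW8-type N-terminus ahead of the NBS and
LRR domains, giving the TNL, CNL and RNL subclasses), describe how the genes
pack into tandem clusters on chromosomes, profile the conserved motifs of the
NBS domain, and reconcile gene trees with the species tree to count the
duplication and loss events that produced today's copy numbers.

`nlrtrace` implements that analysis chain as composable, tested functions.
The gene trees themselves are inputs (maximum-likelihood inference is out of
scope), as are the domain-hit tables (no BLAST/HMMER is run): the package
starts where the external search and inference tools stop. Every stage has a
matching simulator that generates its inputs with ground-truth labels, which
is how the test suite validates the pipeline without any genome download.

## Architecture classification

Domain hits on a protein are mapped to single letters (TIR→T, CC→C, RPW8→R,
NBS→N, LRR→L) in alignment order. When two hits overlap by at least half of
the shorter hit, only the lower-E-value hit is retained; maximal runs of one
letter are then collapsed, so a row of consecutive LRR repeats reads `L` but
interleaved architectures such as `CNLCNL` survive intact. The collapse is
idempotent and the category partition (`intact`, `TN`/`CN`/`RN`, `NL`, `N`,
`Other`) is exhaustive and mutually exclusive by construction.

Subclass follows the N-terminal domain with precedence T, then R, then C.
Truncated genes (`N`, `NL`) carry no N-terminal evidence; they adopt the
subclass of a declared nearest relative (a neighbor-hint table, mirroring the
closest-relative BLASTp strategy) and fall back to CNL — by far the most
abundant subclass in these families — when no hint exists. Architectures
carrying both TIR and RPW8 are contradictory; they are categorised `Other`
and classified by the first N-terminal letter, with a warning.

Percentages in family summaries are rounded half-up to two decimals and mean
lengths to whole base pairs, matching how such tables are usually printed.

## Cluster detection

Two neighboring NBS genes on one chromosome belong to the same cluster when
their intergenic gap (`start(next) − end(prev) − 1`) is at most the window,
250 kb by default, inclusive at the boundary; clusters are the transitive
closure of that relation. The gap-based reading is the strictest
interpretation of "located within 250 kb"; start-to-start measurement is
available as `distance_mode = "start"` because the literature is not always
explicit about which is meant. Genes on unanchored scaffolds must be removed
before clustering (they still count in family totals). Clusters may mix
subclasses: the criterion is purely positional.

The implementation is validated against an all-pairs union-find oracle on
random layouts and recovers constructed layouts (intra-cluster gaps of
200 kb, inter-locus gaps of 300 kb) exactly.

## Motif signatures

The six conserved NBS-domain motifs — P-loop, Kinase-2, Kinase-3, RNBS-C,
GLPL and RNBS-D, in fixed N→C order — are located by seeded scanning rather
than de-novo discovery: the motifs are canonical, so packaged per-subclass
consensus seeds (widths 9, 8, 8, 8, 6 and 11) define both the search matrices
and the position numbering. Each window is scored by log-odds against a
uniform background using a mixture of the three subclass consensi
(`p_match = 0.7` on the consensus residue); windows below a quarter of the
maximum attainable score are discarded, and one occurrence per motif is
chosen by dynamic programming that maximises total score subject to the
canonical order and non-overlap. Sequences shorter than 190 residues — under two-thirds of a regular NBS
domain, too fragmentary to align reliably — are excluded.

Per-subclass position-frequency matrices use a pseudocount of 0.01 per
residue, so no residue ever has zero probability. A position is *diagnostic*
for a subclass when its modal residue reaches frequency 0.5 and differs from
the modal residues of both other subclasses; 0.5 reflects the single
dominant residues visible in published sequence logos, which come with no
stated cutoff. The packaged default diagnostics are the published signatures:
W at RNBS-C 7 and C at RNBS-D 7 (CNL), F at RNBS-D 11 plus the terminal
Kinase-2 aspartate (TNL), S at P-loop 4 and E at RNBS-D 2 (RNL). Subclass
prediction is a majority vote over matched diagnostics; ties and zero
matches return "ambiguous" rather than a guess.

## Reconciliation, lineages and the copy-number ledger

The core algorithm is LCA-mapping reconciliation under duplication/loss
parsimony with unit costs. Every gene-tree leaf maps to its species; every
internal node maps to the species-tree LCA of its children's mappings; a node
is a duplication exactly when it maps to the same species node as one of its
children. For a gene-tree edge whose mapping descends through `d`
species-tree edges, `d − 1` losses are implied (`d` when the parent is a
duplication mapping higher), each charged to the sibling branch skipped at
the corresponding speciation, highest first. Support-threshold rearrangement
of weak edges is deliberately not implemented: plain LCA reconciliation is the deterministic
core, and rearrangement would make results depend on an arbitrary support
threshold. Polytomies must be resolved upstream.

Two conventions deserve comment:

* **Origination at the root.** The gene family is assumed present at the
  species-tree root, so when the gene-tree root maps below it, one loss is
  charged per sibling branch skipped on the way down (`origin = "mapped"`
  disables this). Without the convention, branches above the root mapping
  can never receive inferred losses, which biases per-branch totals; with
  it, single-gene families are also meaningfully reconciled.
* **Stem duplications and lineages.** An ancestral lineage at a reference
  node (say the Sapindaceae most recent common ancestor) is the set of
  extant genes descending from one gene copy present at that ancestor. A
  duplication node that maps exactly to the reference node occurs on the
  branch *leading to* it — before the speciation — so each of its children
  founds a separate lineage. This is what lets a few dozen inherited genes
  expand into hundreds of ancestral lineages on the stem branch; counting
  such duplications as post-speciation events would cap the lineage count at
  the inherited gene count.

On birth–death simulations the reconciliation is a true lower bound: per
family, inferred duplications and losses never exceed the simulated truth
(extinct subtrees are invisible to parsimony), and lineage counts equal the
simulator's surviving ancestor copy number exactly when the loss rate is
zero, falling to a lower bound otherwise.

Rooting by event minimisation scores every edge of the unrooted gene tree as
a candidate root and keeps the rooting with the fewest duplications plus
losses; ties prefer fewer duplications, then the lexicographically smallest
leaf set of the smaller root child, making the choice deterministic.

The ledger applies `count(child) = count(parent) + duplications − losses`
down the species tree from an ancestral count, refuses negative counts, and
labels each branch expansion/contraction/stable; per-tip pattern strings
("expansion -> contraction") reproduce the vocabulary used to describe
genome-specific evolutionary modes.

## Collinearity and duplicate typing

Collinear (synteny) blocks are found by chaining homolog-pair anchors on the
gene-rank dot-plot: consecutive anchors must be within 25 ranks on both axes
(`max_gap`), strictly monotone (same or inverted orientation), and a chain
needs at least 5 anchors (`min_anchors`) to be reported — the defaults of
the standard MCScanX tool. Overlapping chains are resolved greedily by
descending anchor count. This is a deliberate simplification: no statistical
significance model is attached to blocks.

Duplicate typing mirrors the MCScanX classifier hierarchy: a gene with no
chromosome is `unanchored`; else an anchor of any within-genome block is
`WGD/segmental`; else a homolog within one rank on the same chromosome makes
it `tandem` (`tandem_max_rank_gap` is the maximum rank difference — the
proximal category of some classifiers can be folded in by raising it); any
remaining homolog makes it `dispersed`, and homolog-less genes are dispersed
with a `singleton_origin` flag. The priority order makes calls independent
of input order. Cross-genome block anchors where both ends are NBS genes
give the syntenic-pair table, labelled singleton/cluster by each end's
cluster status, and NBS genes inside block spans without a syntenic partner
are counted as presence/absence polymorphic.

## The simulators, and what they do not emulate

* `simulate_gene_family` runs a continuous-time birth–death process
  (exponential waiting times) per copy per branch over the packaged 4-taxon
  species tree with unit branch lengths — no calibrated divergence times
  are assumed, and none are needed by the downstream parsimony methods. The
  continuous-time choice makes the closed-form expectation
  `E[N_tip] = root_copies · e^{(λ−µ)t}` available as an analytic check.
* `simulate_genome_layout` builds layouts with exact intra/inter-locus gaps;
  defaults (39 clusters, 44 singletons, 15 chromosomes, ~3.4 genes per
  cluster) echo the organization reported for a real Sapindaceae genome.
* `simulate_architectures` realises a Table-style (subclass × category)
  census, with repeated LRR hits to exercise collapsing; defaults follow the
  180-gene census of the smallest genome.
* `simulate_motif_alignment` plants the per-subclass motif consensi in
  random scaffolds with 20% per-position substitution noise by default.
* `simulate_synteny` plants tandem arrays, a segmental duplication and
  dispersed copies in rank slots spaced beyond `max_gap`, so planted
  features cannot chain into one another, plus an orthologous second genome
  with a few deleted NBS orthologs for presence/absence cases.

None of the simulators evolve sequences under substitution models, model
assembly fragmentation, or generate incongruent gene trees (the reconciled
tree is always the true pruned tree). Passing tests therefore demonstrate
algorithmic correctness against known truth, not robustness to gene-tree
estimation error or annotation noise in real data.

## Numerical choices and problem sizes

All generators are deterministic under a fixed seed. Percentages round
half-up (2 decimals in family summaries, 1 in duplication-type tables);
clustered/singleton ratios and mean cluster sizes round to 2 decimals; a
genome with no singletons reports an infinite ratio rather than an error.
The test suite checks reconciliation against a brute-force ancestor-list
oracle on 500 random gene trees of up to 8 leaves, rooting against
exhaustive enumeration on 100 six-leaf trees, parameter recovery on 200
birth–death families at rates 0.1, clustering against all-pairs union-find
on 100 random layouts, chaining against exhaustive search on instances of up
to 10 anchors, and motif classification on 500 simulated domains — sizes
chosen to exercise each property thoroughly while keeping the whole suite
around a minute.

## Limitations

* Reconciliation assumes the input gene tree is correct and binary; there is
  no support-aware rearrangement, no non-binary handling and no dating.
* Collinearity detection has no significance statistic; block calls at the
  `min_anchors` boundary are sensitive to the homolog-pair input.
* The motif scanner is seeded, not discovery-based: motifs diverging far
  from the packaged consensi would be reported absent.
* Lineage bookkeeping at the outgroup ancestor is exposed only as the
  inheritance step (ancestral count minus stem losses); no attempt is made
  to assign a fate to every individual outgroup-era lineage.
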