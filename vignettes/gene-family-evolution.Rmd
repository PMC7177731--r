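---
title: "Models and methods behind genefamevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genefamevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamevo)
```

# Scope

`genefamevo` packages the computational core of a gene-family evolution
study of the kind performed on plant nitrogen-metabolism enzymes
(glutamine synthetase, GS, and phosphoenolpyruvate carboxylase, PEPC) in
narrow-leafed lupin and related legumes: family assembly from homology
hits, alignment quality control, gene-tree inference, duplication/loss
reconciliation against a species tree, selection-pressure scans, droplet
digital PCR (ddPCR) copy-number estimation, and genome-region
characterization. Every stage is exercised against simulated gene
families with known ground truth, so the statistical behaviour of the
whole chain is testable without any genome downloads.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the simulation-based tests do
and do not demonstrate about real data.

# The simulator (`simulate_gene_tree`, `simulate_codon_alignment`)

Gene families arise from a single ancestral gene entering the species
tree at its stem. Along every species branch each gene lineage undergoes
a Gillespie birth--death process with duplication rate `birth` and loss
rate `death` (events per lineage per unit time). Whole-genome
duplications (WGDs) are placed on named branches at a relative time
point; they act instantaneously on *all* lineages alive at that moment,
and each extra copy (one for a duplication, two for a triplication) is
retained independently with the event's retention probability. This
mirrors the standard picture of polyploidy followed by selective
fractionation, including the genistoid whole-genome triplication
scenario (multiplicity 3 is supported; whether that event was one
triplication or two successive duplications is left open -- the
simulator can express both). A `tandem_fraction` of ordinary birth
events is labeled "tandem" in the event log; the label is ground truth
for timing classification and has no genomic coordinates attached
(intergenic structure is out of scope).

The event log is the simulator's contract with the rest of the package:
every internal node of the returned gene tree appears exactly once as a
speciation or duplication-type event, and for every species the number
of surviving gene copies equals
`1 + duplications - losses` counted along the root path
(`check_event_conservation()` asserts this identity on every run).

Codon sequences evolve along the simulated gene tree under a
Goldman--Yang-style (GY94) 61-state model: single-nucleotide changes
only, target-codon frequencies $\pi$, transition/transversion ratio
$\kappa$, and $\omega = dN/dS$ multiplying nonsynonymous rates. Stop
codons are excluded from the state space outright, so no simulated
sequence ever contains one. Sites fall into three classes: purifying
($\omega_0 \in (0,1]$), neutral ($\omega_1 = 1$), and positively
selected ($\omega_2 \ge 1$) on designated foreground branches. On
background branches class-2 sites evolve neutrally -- exactly the
class-2b behaviour of the branch-site "model A" used downstream, which
keeps simulator and inference consistent by construction. Branch lengths
are expected substitutions per codon site under the background mixture;
the same normalization is used by the likelihood engine.

Default study conditions used by the calibration suites: $\kappa = 2$,
equal codon frequencies, 300-codon alignments for null calibration and
500 for power, a six-taxon tree with branch lengths between 0.03 and
0.27 substitutions/codon, WGD retention 0.8, and birth/death rates of
0.02/0.01 per lineage per time unit for the timing-recovery study.
These are desk-scale renditions of the empirical setting (hundreds of
sequences, 163 branch tests) chosen once and kept fixed.

What the simulator does *not* emulate: alignment error (its alignments
are true alignments; multiple-sequence alignment is upstream of this
package's scope), intron/intergenic sequence, codon-usage bias beyond
$\pi$, rate variation beyond the three-class mixture, and assembly or
annotation artifacts. A green calibration therefore speaks to the
correctness and statistical behaviour of the implementations, not to
robustness against misalignment or annotation noise -- which is exactly
why the alignment-QC stage (outlier removal, occupancy trimming) exists
for real inputs.

# Family assembly (`homology`)

Hits from an all-vs-all search arrive as 12-column tabular rows; search
itself is a commodity and is not re-implemented. Filtering keeps hits
with e-value at most `1e-20` and coverage of a designated reference
(experimentally sequenced family member) of at least 40%. Edge weights
are `min(-log10 E, cap)` with `cap = 200` (an e-value of zero maps to
the cap); reciprocal hits merge by maximum.

Markov clustering is implemented in-package: self-loops set to each
node's maximum incident weight, column-stochastic normalization, then
alternating expansion (matrix squaring) and inflation (elementwise power
followed by renormalization), pruning entries below `1e-6`, until the
maximum column change falls below `1e-8` (at most 200 iterations,
non-convergence is an error reporting the residual). Clusters are read
off as connected components of the converged matrix's support. The
inflation parameter is selected by the averaged silhouette width over a
candidate grid, by default {1.2, 1.4, 2, 4, 6} -- the published analysis
reports 1.4 as optimal on its data; the grid itself is an artifact
choice since the original candidate set is not stated. Silhouette needs
a distance: we use the bounded transform `d = 1 - w/cap` (1 for
non-adjacent pairs), the minimal choice consistent with the capped
log-e-value weights; singleton clusters contribute width 0, and a
candidate that yields a single cluster has undefined silhouette and is
skipped. Ties go to the smallest inflation (coarsest clustering), for
determinism.

Single-copy marker selection for species-tree work keeps loci whose
fraction of genomes with exactly one copy strictly exceeds 0.95.

# Alignment QC (`msa_qc`)

Gap-pattern outliers are detected from the Hamming distances between
per-codon-column gap masks. The published pipeline used OD-seq, whose
exact parameters are not reported; we adopt a fully specified rule with
the same intent: flag sequence $i$ when its mean distance to the others
exceeds the mean plus `z = 2.5` standard deviations of the per-sequence
means computed without $i$, in a single pass. Occupancy trimming removes
whole codon columns below a threshold (70% for species-tree work; a
permissive 1%-gap preset is available for the pre-screening round), and
the 30% rare-codon rule used before selection scans is scoped to a
named clade, matching its published formulation. Back-translation maps
each aligned residue to its source codon, strips terminal stop codons
(CDS lengths count the stop, protein lengths do not: 1299 bp
corresponds to 432 aa), and treats internal stops or any
residue/codon mismatch as hard errors. The codon-triple semantics of
the occupancy rule is an adopted convention -- the original report does
not say whether it was applied to protein or codon columns.

# Trees (`phylo`)

Desk-scale gene and species trees come from pairwise-deletion
nucleotide distances (p-distance or Jukes--Cantor; saturated JC pairs at
$p \ge 3/4$ receive a configurable ceiling of 5.0 substitutions/site
and a flag) and neighbor joining via `ape::nj`, with negative branch
lengths clamped to zero. The published maximum-likelihood searches
(codon models, free-rate heterogeneity, ultrafast bootstrap) are
deliberately out of scope: the bespoke stages of the analysis --
reconciliation and the selection tests -- consume trees and work with
externally computed Newick input wherever a tree is expected.
Nonparametric bootstrap support resamples codon columns with
replacement and counts bipartitions over NJ replicates; a fixed seed
gives identical supports. Rooting uses a declared outgroup (which must
be monophyletic) and can prune it afterwards, the usual preparation
before reconciliation.

# Reconciliation (`reconcile`)

Reconciliation is duplication/loss-only (transfers disabled), unit
costs, on rooted binary trees -- the configuration matching the
published "minimum cost, no horizontal transfer" setting. The LCA
mapping sends every gene-tree node to the species-tree last common
ancestor of its descendants' species; a node is a duplication exactly
when it maps to the same species node as one of its children. Losses
follow the classic depth-gap rule per gene edge (parent $p$, child $c$,
gap $k$ = depth difference of the mappings): a speciation parent
contributes $k - 1$ losses, a duplication parent $k$, each attributed
to the off-path species branch. For rooted binary inputs this is the
unique minimum-cost reconciliation; the test suite verifies the cost
against an exhaustive enumeration over all valid mappings for a
thousand random cases. Input polytomies are resolved deterministically
(sorted-label caterpillars, zero-length branches) and flagged.

Duplication timing is read off the mapping: a duplication on a terminal
branch is "lineage-specific"; internal branches can be named (e.g.
"ancestral-legume") via `clade_labels`; tandem flags from synteny or a
simulation log propagate; and labels can be restricted to duplications
whose subtending branch reaches a support threshold (default 90%),
mirroring the well-supported-clade gating of the published summary
tables. `choose_reconstruction` picks the minimum-cost candidate (ties:
fewer duplications, then input order) among alternative reconstructions
of the same family, the criterion the original analysis used to choose
codon alignments over protein ones.

# Selection (`selection`)

Pairwise Ka/Ks uses Nei--Gojobori (1986) counting: per-codon synonymous
site fractions (averaged over the two sequences), multi-step codon
differences averaged over all shortest mutational pathways excluding
those through stop codons, and Jukes--Cantor correction. Two
conventions are worth stating. Changes *to* stop codons count as
nonsynonymous in site counting, which keeps the identity
$N + S = 3 \times$ (codon count) exact. And if every pathway between two
codons passes through a stop (rare), the stop exclusion is relaxed for
that pair rather than dropping it. Proportions at or above $3/4$ are
saturated and reported as `NA` with a flag; the ratio is `NA` when
$K_s = 0$. Classification bands for the pair tables default to
purifying $< 0.5$, positive $> 1.5$, neutral between -- artifact
choices motivated by published usage of "neutral" for a ratio of 0.87;
the published estimator itself is the DnaSP-style counting method,
which NG86 specifies exactly.

The branch-site test follows the standard model-A parameterization:
site classes 0, 1, 2a, 2b with proportions $(p_0, p_1, p_{2a}, p_{2b})$,
$p_{2a}/p_{2b} = p_0/p_1$, $\omega_1 = 1$ fixed, and $\omega_2$ free
($\ge 1$) on the foreground in the alternative, fixed at 1 in the
nested null. Codon frequencies default to F3x4 from the alignment
("equal" available for calibration). The likelihood is computed by
Felsenstein pruning over the 61-state space (compiled code; the rate
matrices are scaled so the background mixture has mean rate 1, the same
convention as the simulator), per-site, mixed over classes.
Optimization is bounded quasi-Newton (`nlminb`) over
$(\kappa, \omega_0, p_0{+}p_1, p_0/(p_0{+}p_1)[, \omega_2])$ with a
relative tolerance of `1e-8` on the log-likelihood; the alternative fit
is warm-started from the null fit, and additional seeded starts are
available via `n_starts`. A single deterministic start is the default:
with branch lengths held fixed the surface is well-behaved, and the
warm start already guards the nested fit; restart count is exposed
rather than hard-coded. Branch lengths are taken from the input tree
and held fixed for both hypotheses (the published description is silent
on re-optimization; `estimate_scale = TRUE` first fits a global scale
under a single-class model). The LRT statistic is clamped at zero and
referred to a chi-square with one degree of freedom -- the plain
chi-square, not the 50:50 boundary mixture, following the published
procedure -- making the test conservative; the type-I calibration band
in the acceptance suite (rejection rate in [0.01, 0.08] at
$\alpha = 0.05$) reflects that. Site identification is naive empirical
Bayes at the alternative-model point estimates with a 0.95 posterior
threshold; Bayes empirical Bayes is out of scope. No multiple-testing
correction is applied across foregrounds by default, mirroring the
per-test $\alpha$; callers can apply `p.adjust` to the returned
p-values.

# ddPCR (`ddpcr`)

Template molecules partition into droplets independently, so the
per-droplet copy number is Poisson and
$\hat\lambda = -\ln(n_{neg}/n_{tot})$. The default 95% interval
propagates the binomial error of the negative fraction through the log
transform (delta method); an exact Clopper--Pearson option is provided.
All-positive assays are a saturation error (dilute); all-negative gives
$\lambda = 0$ with a one-sided exact upper bound. Copy number is the
target/reference concentration ratio times the reference copy count,
with a delta-method interval on the log scale; the reference gene plays
the role the single-copy aspartate aminotransferase locus played in the
published assays (about 17,000 accepted droplets per reaction, the
problem size used in the round-trip checks). Copies-per-microliter
conversion activates only when droplet volume metadata is supplied --
relative copy number needs no volume.

# Genome regions and microsynteny (`genomics`)

GC percent excludes ambiguity codes from numerator and denominator;
repeat fractions use merged masked intervals (0-based half-open input,
as produced by repeat-detection tools, which are inputs here, not
re-implementations). Gene-structure summaries convert complete CDS
lengths to protein lengths as `cds/3 - 1` and report modal exon counts
with ties kept. The published region tables count CDS per region;
their per-100-Mbp phrasing appears to be a units slip for ~100-kbp
regions, so the package reports counts per region and does not attempt
the ambiguous normalized figure.

Microsynteny blocks are maximal chains of homology anchors monotone in
both regions (or reversed in one, for inversions), with ordinal index
gaps of at most `max_gap = 5` between consecutive anchors, scored by
summed anchor score and extracted by weighted
longest-increasing-subsequence dynamic programming -- best chain first,
then repeated on the remaining anchors -- discarding chains shorter
than `min_block = 3`. This greedy-free DP replaces heuristic chaining;
the anchor-generation settings of the published comparative mapping
(e-value 1e-20, word size 8) are provenance for the anchor inputs, not
parameters of the chaining itself.

# Numerical and degenerate-input choices

- The GY94 rate matrix is reversible; transition probabilities come
  from the symmetrized eigendecomposition, with tiny negative entries
  clamped to zero. Eigendecompositions are cached by $(\kappa, \omega)$
  during optimization; the mixture scale is applied to branch lengths
  so the cache stays valid as proportions move.
- Pruning scales conditional likelihoods per internal edge by column
  sums to prevent underflow; per-site log scale factors are
  accumulated.
- MCL floor `1e-6`, convergence `1e-8`, maximum 200 iterations; all
  exposed as arguments.
- Distance saturation ceiling 5.0 substitutions/site, configurable.
- Empty families are returned as a `NULL` tree with a loss-only event
  log; bundles for them contain empty FASTA files and a warning.
- One master seed drives a run; every stochastic sub-operation derives
  a child seed deterministically (`derive_seed`), so full runs replay
  byte-identically.

# Problem sizes used by the verification suites

The acceptance suites run at the sizes chosen for the package's own
calibration studies: 1,000 exhaustive reconciliation cases (gene trees
up to 6 leaves over 3--4-taxon species trees), 500 random codon pairs
against the NG86 path-enumeration oracle, 200 null and 100 positive
branch-site replicates on the fixed six-taxon tree, 50 planted
clustering instances, 200 simulated WGD families for timing recovery,
100 ddPCR round trips at 17,000 droplets, and 50 random additive
matrices for neighbor joining. `scripts/acceptance.R` recomputes a
summary of the same quantities from scratch for any seed.

# Known limitations

Branch lengths are not re-estimated per hypothesis in the branch-site
test (only a global scale, optionally); the NEB site list uses point
estimates and inherits their uncertainty; NG86 is a counting estimator
and is biased for extreme $\kappa$ or strong codon-frequency bias (its
neutral-regime calibration band in the tests is correspondingly wide);
NJ is a stand-in for likelihood tree search and should be replaced by
external ML trees for publication-grade gene trees; and the simulator's
clean alignments mean QC stages are validated on constructed, not
organic, failure modes.
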