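---
title: "Methods: models, estimators and design choices in mitochronos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitochronos reconstructs matrilineal population history from aligned
whole mitogenomes. This vignette explains the statistical models behind
each stage, the tunable parameters and their defaults, the simulator
that supplies ground truth, and the numerical and design choices a
maintainer should know about.

## Coordinates, variants and haplotypes

All interfaces report 1-based inclusive positions in the reference
mitogenome's numbering. Alignment columns where the reference carries a
gap (insertions relative to the reference) are anchored to the preceding
reference base with a positive `subpos` sub-index, so insertion calls
never shift the coordinate frame.

Substitution effects are classified under the vertebrate mitochondrial
genetic code (NCBI table 2: AGA/AGG stop, ATA = Met, TGA = Trp) against
the *reference* codon, honouring gene strand. The code table is built
from the conventional 64-codon listing and is unit-tested against an
independent implementation.

Haplotype identity uses substitution variants only. Columns containing
an alignment gap in any record are excluded, because indel placement is
an artifact of the aligner and mitogenome length variation is tracked
separately from point variation. Two modes govern `N`:

* **strict** (default): sequences differing only by `N` stay distinct.
  This is conservative — coverage artifacts can inflate the haplotype
  count, but never merge genuinely different sequences — and the
  condition is logged when it occurs.
* **lax** (`strict = FALSE`): `N` matches anything and records merge
  greedily in input order into the first compatible haplotype.

How the original swamp-buffalo study treated `N`s when counting its 87
haplotypes is not recorded; strict mode is this package's default, not a
claim about that study.

Haplogroup labels come from user-supplied diagnostic-motif rules forming
a tree (child motifs must extend their parent's). Assignment returns the
deepest fully-matched rule; an exact tie between branches returns
`conflict:<labels>` rather than silently picking one. The shipped rule
file `inst/extdata/haplogroup_rules_synthetic.tsv` uses the published
haplogroup nomenclature (SA..SE and sublineages, with the control-region
position 16066 marking SA1a) but **synthetic motifs** — it exists to
exercise the machinery in tests, not to classify real data.

## Diversity statistics

* `Hd = n/(n-1) (1 - Σ pᵢ²)` — the unbiased probability that two random
  records differ in haplotype.
* Pairwise differences are counted with pairwise deletion (per pair,
  columns with gap or `N` in either sequence are skipped); the reported
  dispersion is the population SD over the `C(n,2)` pair values. Whether
  published "± x" dispersions of this statistic are SDs across pairs is
  rarely stated; this one is, and is labelled as such.
* π is mean pairwise differences divided by the effective length — the
  number of alignment columns whose consensus is a base — and is
  reported both raw and ×100. The percent scale is the one on which a
  mean pairwise difference of ~69 over a ~16.35 kb molecule gives the
  familiar "π ≈ 0.42" magnitude for livestock mitogenomes.
* The synonymous/non-synonymous ratio counts *distinct* coding
  substitutions, keyed by (position, alternate allele), so recurrent
  changes shared by haplotypes are counted once.

## Synonymous masking

The coding alignment concatenates the 13 protein-coding genes in genomic
order; minus-strand genes (ND6) are reverse-complemented into the common
reading direction. Terminal stop codons are removed — complete 3-nt
stops, and the 1–2-base incomplete stops completed by polyadenylation in
vivo; the trim per gene can be overridden with a `trim3` gene-map
column, otherwise it is inferred from the reference (trailing in-frame
stop, or the remainder modulo 3). After trimming, a stop-free reference
reading frame is enforced per gene; a violation names the gene.

Ancestral bases come either from the outgroup consensus (default; ties
resolved alphabetically, columns with no outgroup base flagged
unresolved) or from a Fitch reconstruction at the root of a supplied
tree with ties broken toward the outgroup state. Both modes are offered
because the original study does not say how its ancestral bases were
obtained.

Masking evaluates each codon against the ancestral codon: a codon is
kept only if it encodes the ancestral amino acid *and* every single-base
step from the ancestral codon toward it is itself synonymous. Multi-hit
codons are therefore treated conservatively — if any step in the joint
path is non-synonymous, all differing bases revert. This makes masking
idempotent and guarantees the masked alignment translates identically to
the ancestral protein, which the tests verify by full translation scans.
Bases that cannot be classified (`N`, gaps) are left untouched.

## Maximum parsimony

Characters are bit-encoded (A/C/G/T = one bit each; gap and `N` =
full wildcard) and scored by the Fitch algorithm, exact on binary trees.
Search strategy:

* **≤ 8 taxa**: exact branch-and-bound over taxon-addition trees;
  partial trees are pruned only when strictly worse than the incumbent,
  so all equally parsimonious trees are visited, and ties are broken by
  the lexicographically smallest canonical newick for reproducibility.
  Eight is this package's cut-off because enumeration cost grows as the
  double factorial (≈2×10⁶ topologies at ten taxa); on every tested
  instance up to seven taxa the heuristic finds the same optimum as
  exhaustive enumeration, so little is lost.
* **larger**: seeded random-order stepwise addition (outgroup taxa
  placed first), then NNI hill climbing, then up to three SPR sweeps
  interleaved with NNI. Same seed, same tree.

Monophyly constraints (the major haplogroups are treated as monophyletic
for dating, as in the source workflow) are enforced during search by
rejecting violating placements and moves; mutually overlapping,
non-nested constraint sets are rejected before searching.

Mutations are mapped to branches by a deterministic Fitch backtrace:
the final state of a node is its parent's state whenever that state is
in the node's Fitch set (ties at the root go to the supplied ancestral
base, else alphabetically). This yields exactly the Fitch count per
column, so branch counts sum to tree length — a conservation law the
tests assert. Equally parsimonious reconstructions exist; the
deterministic rule favours placing changes away from the root state,
which matches how diagnostic mutations are conventionally polarised.

## The calibrated Poisson clock

Given per-branch synonymous counts `k_b` and node ages `t`, the model is

```
k_b ~ Poisson(r · L · Δt_b),   Δt_b = t(parent) − t(child)
```

with `L` the number of sites (codons by default, nucleotides on request
— the published per-nucleotide rate applied over codons is exactly a
factor-3 relabelling, and both unit conventions are exposed to avoid
that ambiguity). The likelihood is maximized over `r` and all free node
ages; `r` is profiled analytically (`r̂ = K / (L·ΣΔt)`), and ages are
parameterized as root age × nested logistic fractions so every child is
automatically younger than its parent and dated tips are respected.
Multi-start optimization (5 seeded starts, BFGS/Nelder–Mead) guards
against local optima.

Calibrations:

* **fixed** — the node age is pinned.
* **gaussian** — the printed "±" value is interpreted as an SE (the
  published 95% CIs equal mean ± 1.96×SD for both calibration points,
  which justifies that reading) and enters as a log-density penalty.
  The penalty is truncated at ±4σ: without truncation the likelihood
  has a degenerate mode in which the entire tree collapses onto a fixed
  ancient-tip age with a wildly inconsistent rate, because the Poisson
  profile likelihood is nearly scale-free and a weak Gaussian penalty
  alone cannot always exclude that mode. Truncated calibration priors
  are standard practice and remove only the pathology.
* **tip** — a calibration naming a single tip fixes the tip's age at
  the calibration mean; at 6.7 ± 0.2 Ky the age uncertainty is
  negligible against node-age SEs.

Standard errors come from the observed information: the Hessian of the
negative penalized log-likelihood is computed numerically on the
unconstrained transformed parameters (log rate + age transform), where
ordering constraints cannot be violated, and mapped to (rate, ages) by
the delta method. Fixed-calibration nodes and tip ages report SE 0 and
"n.a." respectively; 95% CIs are `age ± 1.96·SE`. On 200 simulated
count data sets the true rate falls inside the CI in ≈95–99% of
replicates.

The strict-clock likelihood-ratio test compares the free model (one
expected count per branch, saturating at `k_b`) with the clock model
(shared rate, ultrametric ages): `2(llfree − llclock)` against
chi-square with `#branches − #clock parameters` degrees of freedom
(`n − 1` for a binary rooted tree of contemporaneous tips).

Known limitation: branch counts are Fitch parsimony counts, which
undercount multiple hits on deep, saturated branches (the distant
outgroups). With the root calibrated deep, this deflates the rate and
biases shallow node ages upward — visible on synthetic fixtures where
the estimated ingroup TMRCA overshoots the truth while remaining inside
its CI. The published workflow corrected multiple hits with a
codon-model likelihood; reproducing that estimator class is out of
scope here, and the recovery tests therefore validate the clock on
Poisson-generated counts, where the model is exact.

## Bayesian skyline

The dated genealogy (coalescent times in years, ancient tips supported)
is converted to generations with generation time `g` (default 6 years, a
standard bovid value, configurable). Coalescent intervals are
partitioned into `m` contiguous groups (default 10) sharing one `Ne`
each; the log-likelihood per group is `−A_j/Ne_j − c_j log Ne_j`, where
`A_j` sums `k(k−1)/2 · Δτ` over the group's intervals — precomputed once
per genealogy, making each MCMC iteration O(1) per updated group.
An event falling exactly on a group boundary belongs to the earlier
group (the grouping convention), and the generic likelihood follows the
same rule.

The sampler mixes multiplicative scale proposals on a random group's
`Ne` (log-uniform prior on [10⁻², 10⁹]; prior and Hastings factors
cancel exactly for this move) with single-event boundary shifts (70/30).
Defaults are 5×10⁵ iterations thinned by 100 with 10% burn-in — sized so
a desk run takes seconds; the original study's 5×10⁷/10⁴ settings are
reachable through the same arguments. The trajectory reports, on a
uniform time grid, the posterior median and the 95% HPD computed by the
shortest-interval method; convergence is monitored by an
autocorrelation-based effective sample size of the log-likelihood trace,
with a prominent warning (and a `converged` attribute) below ESS 100.

The skyline operates on a *fixed* input genealogy — the dated MP tree of
haplotype representatives — not jointly with the sequence likelihood as
a fully Bayesian analysis would. Consequences: credible intervals ignore
phylogenetic uncertainty, and because representatives drop haplotype
multiplicities, the most recent trajectory segment is weakly informed.
Validation is therefore by simulation recovery (HPD coverage of a
constant truth; sign recovery of a bottleneck-then-expansion history),
not by matching any published curve.

Trend classification compares the median trajectory at an epoch's older
and more recent bounds; changes within a relative tolerance (default
10%) are "flat".

## The synthetic-data generator

`simulate_genealogy()` draws standard backwards-in-time coalescent
genealogies under piecewise-constant demography (rate `k(k−1)/(2Ne(τ))`,
waiting times integrated across epoch boundaries, serial tips entering
at their ages). It matches closed-form coalescent moments (pairwise
`E[T₂] = Ne`, total length `2Ne Σ 1/(k−1)`) within Monte-Carlo error in
the tests.

`simulate_sequences()` evolves an HKY+Γ+I process site-by-site along the
tree by exact thinning of the per-site Markov jump chain, so multiple
hits, back mutations and codon-context interactions arise naturally.
Defaults (study-like orders of magnitude, fixture choices rather than
claims about any real data set): rate 2×10⁻⁸ subs/site/yr, κ = 20, Γ
shape 0.5 with 8 categories, 30% invariant sites, control region 5×
faster than coding, coding block 11,370 nt in 13 codon-structured genes
(one minus-strand), 900 nt control region. Purifying selection is
modelled as rejection of a fixed fraction (default 0.9) of proposed
amino-acid-changing substitutions — chosen to give synonymous/
non-synonymous ratios in the 3–5 range typical of mammalian mitogenome
polymorphism — and proposals that create or destroy a stop codon are
always rejected, with terminal stop codons frozen: nonsense changes are
lethal in reality, and without this rule simulated references would
violate the stop-free reading frame that real mitogenomes satisfy.
True per-branch substitution counts are recorded.

What the generator does *not* emulate: context-dependent mutation
(CpG-like effects), the D-loop's site-specific hypervariability
structure, heteroplasmy, sequencing error, and alignment gaps (output is
gap-free). Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those artifacts.

`make_study_like_dataset()` assembles the full fixture: ~100 ingroup
tips under a bottleneck-then-expansion demography (epoch boundaries at
3, 11, 25, 130 and 200 Ky echoing a glacial/Neolithic/domestication
history), a river-type outgroup joining the ingroup stem at 0.9 My, a
distant pair — one modern, one ancient tip at 6.7 Ky — and a root at
8.8 My matching the deep fossil calibration, plus metadata, gene map,
calibration table and truth bundle. Everything is a deterministic
function of one seed.

## Pipeline orchestration

`run_pipeline()` executes
collapse → diversity → mask → tree → date → skyline from a single YAML
config (any subset of stages can be toggled), persisting every
intermediate artifact (haplotype table, diversity TSV, masked FASTA +
audit log, newick trees, dated ages, skyline trajectory) plus a
deterministic `report.json` (input MD5 checksums, parameters, stage
outputs; wall times go to `pipeline.log` so identical configs yield
byte-identical reports). A stage failure halts the run naming the stage,
with earlier artifacts already on disk. YAML is used for the config
format; diversity statistics are computed on the swamp-type records, the
tree is searched on haplotype representatives for speed (multiplicities
retained in the haplotype table), and the skyline runs on the dated
representatives' genealogy.

## Problem sizes in the shipped tests

The test-suite simulations are sized for a single core: 50 enumerable
parsimony instances of 5–7 taxa; 50 random genealogies for the
likelihood oracle (tolerance 10⁻¹⁰); 200 clock replicates (8 tips,
L = 1000) and 200 skyline replicates (30 tips, 8,000 iterations) for
coverage; 10 pooled replicates of 120 tips for bottleneck phase
recovery; and end-to-end fixtures of 12–60 ingroup tips. The acceptance
script uses the same sizes and derives all randomness from its `--seed`
argument.
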