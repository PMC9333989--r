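---
title: "Methods: evolutionary motif analysis and assay quantification"
author: "EvoMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary motif analysis and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

EvoMotif studies short functional motifs in a protein family through four
evolutionary lenses — conservation, residue covariation, site-wise selection,
and ancestral reconstruction — and pairs them with the quantification
procedures used for functional follow-up assays (membrane-fraction
profiles, IL-2 dose responses, phospho-intensity responder analysis). This
vignette records the models, the tunable parameters, the numerical choices,
and the design decisions taken where the methodology was genuinely open.

## Alignments and reference numbering

All analyses run on a masked alignment: every column in which the chosen
reference sequence carries a gap is removed, so surviving columns map
one-to-one onto reference residues, numbered `refStart, refStart + 1, ...`.
Internally columns are 0-based indices; every reported table uses 1-based
reference numbering via this map. The mask is idempotent and an optional
`refEnd` window supports datasets trimmed to different 3' end points (for
instance a full-family alignment ending at a conserved cysteine versus a
subset alignment running to the reference stop codon). The gap symbol is
`-` (with `.` converted on read); ambiguous residues (`X`, `B`, `Z`;
codon `NNN`) are excluded from frequency denominators and treated as
missing data in all likelihoods, which avoids biasing counts at the cost
of slightly smaller effective sample sizes.

## Sequence weights and conservation

Redundant taxon sampling is corrected by sequence weights shared between
the conservation and covariation modules. The default scheme clusters
sequences by single-linkage at 62% pairwise identity and assigns each
sequence `1 / cluster size` (the style used by covariation servers);
Henikoff position-based weights are available. Weights are normalized to
mean 1 so that effective counts stay on the scale of the number of
sequences.

Per-column conservation is scored information-theoretically. The default
`jsd` score is the negative Jensen–Shannon divergence between the weighted
column residue distribution and a background distribution (BLOSUM62
marginal frequencies); `weighted_entropy` is the weighted Shannon entropy
in bits. Raw scores are z-normalized across scored columns to mean 0 and
SD 1 (population SD, so the invariants hold exactly), signed so that
**lower = more conserved** — the scale convention of ConSurf output that
the covariation calling rule consumes. We deliberately do not replicate
ConSurf's empirical-Bayes phylogenetic rate estimation: the downstream
rule uses only the normalized scale and sign convention, and an
information-theoretic surrogate keeps the module dependency-free and
exactly testable. Columns whose weighted non-gap fraction falls below 0.5
are flagged not-scored and excluded from the normalization.

## Covariation: MI, APC, permutation z, and the two-tier rule

Raw covariation between columns *i* and *j* is weighted mutual information
in bits over the 20 amino-acid states,

$$\mathrm{MI}(i,j) = \sum_{a,b} p_{ab}\,\log_2\frac{p_{ab}}{p_a\,p_b},$$

with an additive pseudocount of 0.05 per joint cell and marginals derived
from the pseudocounted joint table (so MI is exact at pseudocount 0 and
shrunk toward independence otherwise). Each pair uses the sequences
observed at both columns. The average-product correction
`APC(i,j) = mean_i * mean_j / mean` (diagonal excluded) is subtracted to
remove the shared entropic and phylogenetic background — the correction
that defines the MIp family of scores.

Because raw MI in bits is bounded by log2(20) ≈ 4.3, covariation-calling
thresholds of 4 and 8 cannot refer to raw bits; servers report a
normalized score. Here the normalization is an explicit permutation null:
residues are shuffled within each column independently (destroying
covariation, preserving composition and occupancy), MI + APC are recomputed
per permutation (100 by default), and each pair's observed APC-corrected MI
is standardized by its null mean and SD. On independent,
identically-distributed alignments this z is well calibrated (about 5% of
pairs beyond |z| = 2). The thresholds then apply to z. This interpretive
step — thresholds on the permutation z-score — is the module's main design
decision and is stated openly rather than hidden.

Two practical rules guard the null:

* Columns with a single observed residue state cannot covary — their MI is
  identical under every permutation, so their null variance comes only from
  the APC background term and would otherwise produce spuriously extreme
  z-scores. Such columns are excluded from covariation scoring (they remain
  scored for conservation).
* Pairs whose null SD is numerically zero get z = 0.

Calling uses the two-tier conservation-gated rule: tier 1 calls a pair at
z > 4 when **both** residues have conservation z below −0.5; tier 2 at
z > 8 when both are below −0.3 (common phrasings of this rule do not say whether
one or both residues must satisfy the tier-2 bound; symmetry with tier 1
argues for both, which is also the stricter reading). If the called set
exceeds 0.5% of all scored pairs, only the top-z pairs up to that cap are
kept (ties broken by lower positions; the cap never suppresses the single
best pair, so small worked examples remain callable). The cap is applied
after threshold filtering because the order of operations is otherwise
unspecified.

## Site-wise selection (FEL style)

Selection is tested per codon under an MG94xHKY model on the 61 sense
codons of the universal code: single-nucleotide changes at rate
proportional to the target-nucleotide frequency, transitions weighted by
kappa, synonymous changes scaled by a site-specific rate alpha (dS) and
nonsynonymous changes by beta (dN). F1x4 frequencies are the default.
Kappa and a global branch-length multiplier are fitted once on the whole
alignment under the neutral model (alpha = beta = 1) and then held fixed;
the rate matrix is normalized by the neutral mean rate so branch lengths
keep their units. Per site, the alternative model fits (alpha, beta) —
plus a free background beta when a foreground branch set is declared, in
which case only the foreground beta is tested — by bounded Nelder–Mead
(rates in [1e-6, 50], restarts from (1,1), (0.1,1), (1,0.1), relative
tolerance 1e-8); the null constrains beta = alpha, which for the
unpartitioned test reduces to a one-dimensional rate search solved by
Brent's method on a single eigendecomposition. The likelihood-ratio
statistic is referred to chi-square(1), sites are classified purifying
(beta < alpha) or diversifying (beta > alpha) at p < 0.1 with no
multiple-testing correction — the per-site display convention for
selection tracks along a sequence. Columns with at most one observed codon state
short-circuit to the null result (rates at the lower bound, p = 1).

Foreground branch sets are declared by tip labels; the set comprises every
edge inside the spanned clade including its stem edge, mirroring
branch-set semantics in the HyPhy implementation this style of test comes
from. When the foreground covers all edges the partitioned machinery is
bypassed and results equal the unpartitioned test exactly.

All pruning (codon and amino acid) runs on an eigendecomposition of the
symmetrized reversible generator, with per-edge rescaling of partial
likelihoods to prevent underflow and delta-vector shortcuts at the tips.
Likelihoods that underflow to zero are floored at log-likelihood −1e8.

## Ancestral reconstruction

Marginal ancestral reconstruction uses JTT with a 20-category
discrete-gamma rate model (equal-probability bins, category-mean rates —
the standard mean-category convention; rates renormalized to mean exactly
1). The gamma shape can be estimated by profiling the total likelihood
over a log-spaced grid on [0.1, 10] refined by golden-section search; an
alignment with no variable columns has no rate signal and returns the
default shape 1 with a warning. Posteriors come from one inside pass
(pruning) and one outside pass per rate category, combined with per-site
log-scale bookkeeping so categories mix correctly; per-node posteriors are
exact marginals (they match brute-force Bayes sums to 1e-8 on small
trees). The MAP residue is reported per site with ties broken
alphabetically. Node identity requires a root even though the likelihood
is root-invariant (verified via the pulley principle): unrooted inputs are
rooted at a user-supplied outgroup, or by midpoint as a fallback. Sites
where every descendant leaf of a node is gapped are reported as `-`
(insertion/deletion handling by partial-order graphs, as in dedicated ASR
tools, is deliberately not replicated); sites whose descendants are all
ambiguous report `X`.

## Synthetic data: what it emulates and what it does not

The simulators provide ground truth for every stage:

* **Trees** — Yule trees rescaled to a root-to-tip height, or balanced
  trees; tips `t1..tn`.
* **Protein alignments** — sites evolve independently under JTT +
  discrete-gamma by exact (Gillespie) simulation along each edge, so true
  ancestral states are recorded at every node. Planted coevolving pairs
  evolve as a joint 400-state chain: a random compatibility bijection
  sigma is drawn per pair, rates toward compatible combinations (a,
  sigma(a)) are multiplied by the coupling kappa_c and others divided by
  it. The joint generator is rescaled so the pair substitutes at the pace
  of two independent sites — without this, strong coupling mostly freezes
  the pair instead of correlating it — and the root state is drawn from
  the chain's stationary distribution. kappa_c = 1 recovers independence
  exactly. Planted pairs evolve at the mean rate (no gamma) so that
  recovery measures coupling, not rate class.
* **Codon alignments** — MG94xHKY with per-site omega classes, again
  simulated exactly; substitution events are tallied by ts/tv and
  syn/nonsyn for design checks.
* **Assay tables** — fraction profiles place a designed mass fraction in
  a DRM-like peak (fractions 3–4) and the remainder in a DSM-like peak
  (fractions 8–9) with fraction 1 at zero, under multiplicative
  log-normal noise; dose tables evaluate a 4-parameter logistic on the
  1:3 titration from 30 uM with additive noise; histograms mix a
  log-normal null population with a log-normally shifted responder
  fraction, 10,000 cells per condition, binned on shared linear edges.

The generators do **not** emulate indels, alignment error, compositional
heterogeneity across lineages, or instrument-specific artifacts
(autofluorescence, spillover). Passing recovery tests therefore validates
the estimators under their assumed models, not robustness to those
real-data complications.

## Validation conditions and why they were chosen

The whole-pipeline checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use these problem sizes, chosen to exercise each
method at realistic scale while keeping a full run in minutes on one CPU:

* Pruning and posterior oracles: 50 random codon quartets and 10 random
  protein quartets against brute-force enumeration, tolerance 1e-8.
* ASR accuracy: 16 taxa, 200 sites, tree height 0.5, homogeneous rates.
  Homogeneous rates isolate reconstruction fidelity: with strong rate
  heterogeneity (gamma shape around 1) a Bayes-optimal reconstruction
  tops out near 94% because fast sites are intrinsically uncertain — the
  reconstruction is well calibrated (accuracy tracks the mean MAP
  posterior), so accuracy is a property of the simulation conditions,
  not the estimator. Rate-class machinery is validated by the exact
  posterior oracle (which uses a gamma mixture) and the shape-recovery
  test.
* FEL: 500 neutral sites on a 16-taxon height-2 tree for size, and a
  250-site alignment with 20% of sites at omega = 0.1 on a 32-taxon
  height-5 tree for purifying power. Both use deep divergence on purpose:
  it matches the saturated synonymous divergence of a family spanning
  hundreds of millions of years, purifying detection needs enough
  synonymous events to anchor alpha, and the chi-square(1) reference for
  the likelihood-ratio statistic is mildly liberal at the 0.1 tail on
  shallow trees (realized size ~0.13 at height 1 versus ~0.11 at height
  2 and beyond, while the 0.05 tail is near-nominal throughout) — a
  finite-sample property of this test family, not something the
  implementation can remove.
* Covariation: 32 taxa at height 1.25 (deep, family-level divergence so
  columns are variable), 200 sites, 10 planted pairs at kappa_c = 20, 100
  permutations. Recovery is measured as rank-AUC of planted versus
  background pairs among scored pairs — an invariant planted column is
  undetectable by any covariation statistic and is excluded by the
  diversity rule above. At kappa_c = 1 the planted positions are checked
  to be indistinguishable from the null (KS test).
* Assay: exact recoveries in the no-noise limit, and responder-fraction
  recovery within 2 percentage points at 10,000 cells.

## Known limitations

* Conservation scores are information-theoretic surrogates on the ConSurf
  scale convention; exact ConSurf values are not reproduced.
* The 4/8 covariation thresholds are interpreted on the permutation
  z-scale; pair lists produced by server-based analyses are a
  qualitative, not numerical, reproduction target.
* FEL here does not model synonymous rate variation across sites beyond
  the per-site alpha, and makes no claim of numerical equality with HyPhy.
* The phylogenetic correlation of nearby lineages inflates the tails of
  the covariation null on tree-generated data relative to the iid case;
  the conservation gate and the 0.5% cap are the practical guards.
* Dose–response AUC integrates the mean response over log10 dose with
  zero doses excluded; it is not a model-based EC50 fit.
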