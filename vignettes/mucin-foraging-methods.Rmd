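---
title: "Methods: inferring mucin glycan foraging from genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring mucin glycan foraging from genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinforage)
```

## The inference problem

The colonic mucus layer is built from the heavily O-glycosylated mucin
MUC2. Gut microbes forage these O-glycans in two spatially separated
stages: extracellular glycoside hydrolases (GHs) cleave glycans down to
monosaccharides, and cytoplasmic catabolic pathways (CPs) ferment the five
constituent sugars — Fuc, Gal, GalNAc, GlcNAc and Neu5Ac. Because many
genomes encode only one of the two stages, the community is wired for
cross-feeding: some organisms release sugars they cannot eat, others eat
sugars they cannot release.

`mucinforage` turns binary per-genome annotations (GH classes, pathway
genes, transporters) into this foraging picture: pathway presence calls,
per-glycan cleavability, presence-pattern statistics, donor/acceptor roles
and mutualistic pair predictions. Everything downstream of annotation is
deterministic rule application; the package deliberately contains no
sequence analysis and no orthology inference.

## Pathway presence: the gap rule

A CP is an ordered chain of reactions from the intracellular sugar to an
intermediate of central metabolism. Each step lists canonical gene symbols
and accepted non-orthologous replacements (e.g. *galY* for *galT*); a step
is covered when any of them is present (case-insensitive). A *gap* is a
maximal run of consecutive uncovered steps, and a pathway is called
**present** when there are at most two gaps, each spanning at most one
reaction:

$$\text{present} \iff \#\{\text{gaps}\} \le 2 \;\wedge\; \max_i \text{len}(\text{gap}_i) \le 1.$$

Equivalently: at most two steps are missing and no two missing steps are
adjacent. On a 5-step chain exactly 12 of the 32 missing-step subsets
satisfy the rule ($\binom{5}{0} + \binom{5}{1} + 6$ non-adjacent pairs);
the test suite checks the implementation against this enumeration for all
chain lengths up to 7.

Design choices that were genuinely open:

* **Replacements are honored before gap counting.** The annotation
  workflow this models re-evaluates pathways after searching for
  non-orthologous displacements, so a replacement gene and its canonical
  counterpart must yield identical decisions (property-tested).
* **Terminal gaps are ordinary gaps.** Nothing in the rule's statement
  distinguishes chain ends, so the first and last step are treated like
  any other position.
* **Transporters never veto.** Known cohorts include genomes with complete
  CPs but no recognizable transporter; transporter presence is therefore
  reported alongside the decision, not folded into it.
* **Branching routes are linearized.** Where alternative routes converge
  (Leloir vs. tagatose-6P galactose catabolism; NanE vs. NanE-II sialic
  acid routes; the lacto-/galacto-N-biose disaccharide entries), each route
  is its own variant with the shared tail repeated in its chain, and a
  monosaccharide is catabolizable when **any** variant is present. This
  keeps the gap rule well defined on ordered chains.

## Glycan cleavability

A glycan is modeled as a *multiset of typed bonds* (donor sugar, linkage
label, acceptor), not as a tree: the cleavability criterion is pure
bond-type coverage, so topology would add structure the rule never
consults. A genome cleaves glycan $g$ iff

$$\mathrm{bonds}(g) \setminus \{\text{GalNAc–Ser/Thr}\} \subseteq
  \bigcup_{c \,\in\, \mathrm{GH}(\text{genome})} \mathrm{cleaves}(c).$$

The peptide attachment is excluded by default because the
endo-acting enzymes that cleave it are rare; the `exclude_peptide` flag
restores it. Sulfation of GlcNAc is carried as a flag and does **not**
block cleavability by default — 6-sulfation plausibly protects glycans, so
a `strict_sulfatase` mode exists that additionally requires the
mucin-desulfating sulfatase (GlcNAc-6-sulfatase), which the package treats
as a recognized feature id rather than a GH-map entry since it cleaves no
glycosidic bond.

The shipped defaults are replaceable data, not logic: a 20-bond alphabet
(19 glycosidic linkages enumerable for intestinal mucin plus the peptide
attachment), an 8-class GH map (fucosidase, sialidase, two galactosidases,
two N-acetylhexosaminidases for the alpha linkages, the dual-specificity
beta-N-hexosaminidase mapped to both beta-GalNAc and beta-GlcNAc bonds, and
the endo-acting peptide-bond enzyme), and a 17-structure glycan library
covering the four O-glycan cores with sialylated, fucosylated,
blood-group-like, poly-lacto-N-biose and sulfated elaborations. Full
experimental catalogues run to ~56 structures; users with such a catalogue
should load it with `load_glycan_library()`. Degrader bins follow the
published absolute edges (1–3 specialist, 5–13 intermediate, 21+
generalist); the counts 4 and 14–20 fall between bins and are reported as
`"unbinned"` rather than silently merged, with an optional nearest-edge
`snap` (ties to the lower bin).

## Pattern statistics

Each genome yields a 5-bit CP vector and a 5-bit GH vector over the
alphabetically ordered monosaccharides (a GH counts toward every sugar it
releases). Frequencies are tabulated over the **full** category spaces —
all $2^5 = 32$ one-sided and $2^{10} = 1024$ combined patterns, keeping
structural zeros — and tested against a uniform expectation with Pearson's
chi-squared statistic, $X^2 = \sum_k (O_k - E_k)^2 / E_k$ with
$E_k = N/K$, giving $df = 31$ and $df = 1023$. Uniform (rather than
margin-based) expectations were chosen because they are the convention
these degrees of freedom imply. No continuity correction is applied, and
p-values below machine precision print as `< 2.2e-16`. The statistic's
closed form $N(K-1)$ when all genomes share one pattern, and its
invariance under category relabeling, are property-tested.

`pattern_frequencies_from_matrix()` accepts a precomputed per-genome 0/1
pattern matrix, so cohorts annotated outside the package drop into the
same statistics.

## Cross-feeding roles and mutualistic pairs

Per monosaccharide, a genome with a releasing GH but no CP is a **donor**;
with a CP but no releasing GH an **acceptor**; with both, self-sufficient
(and deliberately edge-free — only partial pathways create feeding
opportunities). Edges connect every donor to every acceptor of a shared
sugar.

For an unordered genome pair, the *summary pattern* is the union of the
two individual cleavage patterns, and the *mutualistic pattern* is the
pattern of the pooled GH repertoire. The pair is mutualistic when the
mutualistic pattern strictly exceeds the summary — pooling unlocks glycans
neither member degrades alone — and highly beneficial when the pooled
repertoire covers the entire active library (generalized from "all 56" to
the loaded library's size). Pairs containing a member that already
degrades the whole library are excluded up front. The quadratic search
skips pairs whose pooled bond capability (and, in strict mode, sulfatase
capability) adds nothing over one member; the skip is sound because a
nested capability can never gain (also property-tested directly).

## The synthetic cohort generator

The generator emulates the statistical shape of real annotation cohorts:
taxon-structured Bernoulli presence (genomes assigned round-robin to taxon
blocks, each block with its own per-feature probabilities), plus a
within-genome coupling between same-sugar GH and CP features. The coupling
is a Gaussian-copula tilt: each genome draws one latent per
monosaccharide; a feature's uniform is
$\Phi(s\sqrt{|\rho|}\,\bar z + \sqrt{1-|\rho|}\,\varepsilon)$ with the
sign $s$ applied on the GH side, so marginal probabilities are preserved
exactly while the GH–CP latent correlation approaches $\rho$. Tests verify
near-zero empirical correlation at $\rho = 0$ (|r| < 0.05 at n = 2000),
sign and magnitude recovery at $\rho = 0.6$, and 3-sigma binomial
convergence of marginals.

Defaults were fixed once as plausible study conditions: 200 genomes, 8
taxon blocks, taxon baselines graded 0.25–0.75 (gene probabilities +0.1),
transporter probability 0.3, coupling 0.3. With high marginal gene
probabilities most genomes carry at least one GH and one CP, mirroring
cohorts where both fractions approach 90%.

`plant_mutualistic_pairs()` constructs ground truth: for a target glycan
it searches for a two-way split of covering GH classes such that neither
side covers all required bonds (one side is a single class, the other a
greedy cover of the remainder), then appends two genomes carrying the two
halves. Planted pairs are recoverable by construction; incidental
mutualistic pairs — including cross-pairs between planted genomes — may
coexist, so recovery is asserted as superset, not equality.

What the generator does **not** emulate: phylogenetic covariance beyond
taxon blocks, annotation error, genome incompleteness, and operon-level
gene correlation. Passing tests on synthetic data therefore validate the
inference rules, not the upstream annotation quality real data would add.

## Numerical and engineering choices

* All randomness flows through explicit integer seeds; each generator
  component seeds its own substream and restores the caller's RNG state,
  so adding a stage never perturbs another stage's draws.
* Linkage labels normalize to lowercase ASCII (`a1,2`, `b1,4`); bond
  equality is string equality after normalization.
* Pair lists sort by gain size descending, then lexicographic ids — a
  deterministic tie-break that makes outputs byte-reproducible.
* Degenerate inputs fail fast with named offenders: empty cohorts, unknown
  GH ids, bonds missing from the alphabet, malformed table rows (with line
  numbers).
* Problem sizes in the shipped tests and acceptance script (cohorts of
  5–200 genomes, libraries of 12–50 glycans, 100-seed planting sweeps)
  were chosen so each statistical check has conventional power while the
  whole suite stays interactive.

## Limitations

Cleavability is a Boolean coverage rule: it ignores enzyme expression,
secretion, kinetics, steric accessibility and cleavage order, and a
bond-multiset model cannot distinguish isomeric topologies. Pathway calls
tolerate up to two single-reaction gaps by design, so they overcall
relative to strict completeness. The default glycan library is a curated
subset; headline fractions (degraders, participants) depend on library
breadth and should be read relative to the loaded library. Pair
predictions are combinatorial hypotheses about capability, not
demonstrations of ecological co-occurrence.
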