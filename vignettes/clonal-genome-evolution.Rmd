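---
title: "Quantifying clonal genome evolution: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal genome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clonalkit)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open. It states
no empirical result that the test suite and the analysis scripts do not
themselves compute.

## The scientific question

When a bacterial population is physically cut off — from other populations
and from environmental DNA — its genomes stop acquiring diversity through
homologous recombination and gene gain. Diversification then proceeds
clonally: point mutations accumulate along a tree of vertical descent, drift
rather than recombination decides their fate, and genes that no longer earn
their keep decay into pseudogenes. The package quantifies this regime in a
set of closely related genomes through four measurable signatures:

1. a low ratio of recombination-derived to mutation-derived substitutions
   (r/m) in the core genome;
2. per-branch dN/dS (ω) mildly elevated toward relaxed purifying selection;
3. an elevated pseudogene load, correlated with ω;
4. few singleton genes (recent acquisitions) in the pangenome.

## The recombination model

The core of the package is a per-branch two-state hidden Markov model over
the columns of the core-genome alignment. After ancestral states have been
reconstructed on the clonal genealogy, each branch yields a binary track:
does the child differ from the parent at this site? The hidden state says
whether the site sits in DNA imported by homologous recombination on that
branch:

* emission: unimported sites mismatch with probability `1 − exp(−b)`, where
  `b` is the branch's clonal length in expected substitutions/site (free per
  branch); imported sites mismatch with probability ν, the mean divergence
  of the donor DNA;
* transitions: the chain enters the imported state with probability
  `1 − exp(−(R/θ)·b)` per site and leaves it with probability `1/δ`, giving
  imports geometric lengths with mean δ.

R/θ, δ and ν are shared across branches and estimated by EM. The E-step
(forward–backward, implemented in C++) accumulates expected transition
counts and state occupancies; the M-step updates ν and δ in closed form and
maximizes the coupled (R/θ, b₁…b_k) terms by coordinate ascent with Brent's
method, accepting an update only when it improves the expected complete-data
log-likelihood — a generalized EM, so the observed log-likelihood is
non-decreasing at every iteration (a property the test suite asserts on
every fit). The initial state distribution is fixed at (½, ½) so the
objective decomposes exactly over the remaining parameters.

The summary statistic is the identity `r/m = (R/θ) × δ × ν`: initiations per
mutation, times bases per initiation, times substitutions per imported base.
Import segments are reported by thresholding the posterior at 0.5 (Viterbi
decoding is available behind a flag); posterior decoding was preferred
because it makes the mean posterior of each segment reportable. Missing and
gapped sites are removed from a branch's track before the HMM runs, so a
single transition bridges each gap and decoded segments merge across them.

Numerical choices: EM tolerance defaults to 10⁻⁶ log-likelihood units with
at most 500 iterations. Parameter estimates stabilize long before the
log-likelihood microconverges, so the heavier test fixtures and the analysis
scripts pass `tol = 1e-3, max_iter = 200–300` as their problem-size choice;
the estimates agree to well within the tolerances asserted anywhere. An
all-zero track set returns R/θ = 0 with ν and δ flagged undefined rather
than fitting a degenerate model.

Within-group runs (`group_recombination()`) rebuild the genealogy per group
from the group's sub-alignment, mirroring the practice of running
recombination detection separately per strain set. Recombination from
outside the compared set (external imports) is deliberately not modeled.

## The synthetic-data generator

`simulate_dataset()` is the package's study-conditions generator, not a
convenience fixture. An ancestral chromosome of configurable length and GC
content is packed with non-overlapping intact ORFs (ATG start, sense codons,
stop; random strand). Evolution proceeds along a rooted binary genealogy
(balanced, with every root-to-leaf path summing exactly to `total_depth`, or
a rescaled random coalescent). Branch lengths are in expected
substitutions/site (`theta_site` defaults to 1), and along a branch of
length `b`, in fixed order:

1. **imports** initiate at `(R/θ)·θ·b` per site; tract lengths are geometric
   with mean δ (matching the HMM's geometric exit), overlapping initiations
   are merged; each tract site is redrawn with probability ν to a different
   base, a Jukes–Cantor-style diverged-donor model — the import is
   characterized only by its mean divergence, which is all the estimator
   assumes;
2. **substitutions** arrive Poisson at `θ·b` per site, each to a uniformly
   chosen different base;
3. **pseudogenization** hits each intact gene at its own rate; the mechanism
   is a premature stop (placed uniformly within the first 75% of codons, so
   every such event loses more than 20% of the ORF and is detectable by the
   downstream rule) or a terminal truncation deleting a uniform 25–55% of
   the gene; the truth table records the *realized* intact-ORF length after
   the event, so detector recall is judged against what actually happened to
   the sequence;
4. **indels** arrive at `indel_rate·b` per site with geometric lengths,
   biased into genes (configurable weight, default 0.8) to emulate the
   concentration of indels in coding regions observed in decaying genomes;
   gene coordinates are remapped through every insertion and deletion, and
   genes wholly deleted are dropped from the annotation.

Every event is recorded per branch in an `evolution_truth` object, which
makes three oracle checks possible: truth-based r/m (imported ÷ clonal
substitutions), per-leaf inherited pseudogenization sets, and exact pairwise
SNP/indel counts in the no-overlap regime. One consequence of merging
overlapping initiations: the recorded tract-length distribution matches the
geometric law only when tract coverage of the genome is low, so the
distributional checks on realized tracts run at ~5% coverage (where the
merge-induced inflation of the mean is far below sampling error) alongside a
direct large-sample check of the generating law itself.

What the generator does **not** emulate: gene gain and horizontal transfer
of novel genes, rearrangements, codon-level selection (substitutions are
neutral, so simulated ω hovers near 1 and the ω-group contrast must be
constructed at the codon level in tests rather than read off genome
simulations), sequencing error, and assembly fragmentation (one contig per
genome). Passing tests on simulated data therefore demonstrate estimator
correctness under the stated model, not robustness to real-data artifacts
like misassembly or annotation error.

A subtlety the analysis scripts surface deliberately: gene-decay events
write stop codons — up to three adjacent mismatches — into the core
alignment, which the HMM reads as very short, high-divergence segments. In
decay-rich configurations this biases R/θ upward and δ downward while
leaving the r/m *ordering* between groups intact. Recombination parameters
are therefore best estimated on alignments where decay is rare or masked,
and the acceptance-grade parameter-recovery checks use recombination-only
configurations.

## Core genome, orthology, ANI

Orthologs are defined operationally: reference genes for which every genome
has exactly one hit above 30% amino-acid similarity — multi-hit reference
genes (paralogs) are excluded wholesale. "Similarity" is interpreted as
percent identity over the local-alignment length (BLOSUM62, gap open 10,
extend 0.5); the threshold is strict (>0.30). Because unrelated proteins
routinely reach ~30% identity over short local segments, a hit must also
cover at least half of the shorter protein — the counterpart of the
significance filter a BLASTp workflow applies implicitly. The reference
genome defaults to the lexicographically first (in the analysis scripts the
simulated ancestor plays the closed reference genome's role; with real data
one would choose the closed assembly).

Family alignment is center-star: each member aligned globally to the
reference member and merged on its coordinates. For the >90%-identical
inputs of near-clonal core genes this is equivalent to a full progressive
aligner at a fraction of the complexity; it is not intended for distant
homologs. Concatenation records per-family boundaries so the codon view can
be reconstructed gene by gene.

The pangenome uses single-linkage components of the similarity graph at 0.9
identity in place of inflation-based Markov clustering: at near-clonal
divergences both produce the same partition, and the quantity of interest —
the singleton count and its fraction of the flexible genome — depends only
on the partition. ANI follows the ANIb convention: 1,000-bp fragments, best
blastn hit, fragments kept at ≥70% coverage, mean percent identity.

## Selection and decay

dN/dS uses the Nei–Gojobori counting estimator on the in-frame codon
alignment, applied to every (parent, child) pair of the genealogy so each
genome's ω is its terminal branch's value. Site counting excludes changes
into stop codons from the per-position denominator (syn fraction =
synonymous / viable single-step changes), which keeps N + S = 3 × codons and
makes neutrality on the sense-codon chain give ω = 1 — the convention the
brute-force enumeration oracle in the test suite mirrors. Observed
differences between codons differing at multiple positions are averaged over
shortest mutational paths, excluding paths through stops when any stop-free
path exists. Proportions are Jukes–Cantor corrected; ω is flagged undefined
when dS = 0 and the correction is flagged at saturation (p ≥ 0.75). This
counting estimator summarizes per-branch selection strength; it does not
reproduce random-effects ω-class machinery, and no numeric equality with
likelihood-based branch-site methods is claimed — the reproduced quantity is
the per-branch ω summary and its group contrast.

Pseudogenes are called by one rule: a gene whose realized intact ORF — codons
walked from the annotated start in the coding frame, up to the reference
ortholog's length, ending at the first stop — has lost more than 20% of the
reference length. Mechanisms are classified (frameshift when the annotated
CDS is no longer a codon multiple, premature stop, truncation), and
reference genes with no annotated copy are screened against the genome by
local alignment (fragments covering >30% of the gene at high identity, with
no intact copy, are called truncations). Stop codons written by ordinary
point mutation are genuine disruptions, not detector errors; the
false-positive-rate check therefore runs on datasets where pseudogenization
is the only gene-disrupting process.

## Phylogeny

Full maximum-likelihood tree search is replaced by neighbor joining on
Jukes–Cantor distances with pairwise deletion: at core-genome divergences
below ~1% the two recover the same topology (the test suite checks exact
recovery of the true simulated topology across seeds), and NJ's cost is
negligible at these sizes. Negative NJ branches are clamped to zero with the
length shifted to the sibling edge. Rooting is midpoint, a stated choice
where the original rooting is unknowable. Ancestral states use Fitch
parsimony with fixed tie-breaks — prefer the parent's state; at the root,
lexicographic (A < C < G < T) — with gaps treated as missing so they inherit
by parsimony; a marginal maximum-likelihood reconstruction under JC is
available as `method = "marginal-jc"`.

## Population dynamics and laboratory-generation arithmetic

The drift null model is deliberately minimal: expected pairwise differences
`D = factor × μ_bp × L × G`, linear in generations, with `factor = 2` by
default (both lineages of a pair accumulate mutations since their common
ancestor) and `factor = 1` available for divergence from a fixed reference —
both conventions are exposed because published curve families do not always
state theirs, and the two bracket the question being asked. Drake's rule
(one mutation per 300 genome replications) ships as a named rate preset.
Generation bookkeeping composes fixed doubling counts with colony
expansions (`log2(cells per colony)`); the enrichment-stage doubling count
is treated as a given input (it derives from abundance measurements, not
from elapsed time). An indel "event" in pairwise diversity is one maximal
run of columns gapped in exactly one of the pair; adjacent runs separated by
a single non-gap column count separately.

## Statistical tests

Welch's t test, ANOSIM and OLS are thin wrappers over the standard
implementations (`t.test`, `vegan::anosim`, `lm`), with conventions pinned
down: two-sided p-values throughout; the zero-variance equal-means corner
returns t = 0, p = 1; ANOSIM uses 999 permutations by default with a
recorded seed, so the smallest attainable p is 1/1000; pseudogene
composition is compared on presence/absence with the Jaccard distance
(Bray–Curtis behind a flag), a choice made explicit because the distance
underlying published composition tests is often unstated.

## Problem sizes

The shipped analysis runs on two simulated groups of 8 genomes × 100 kb
carrying 40 genes, and the acceptance-grade parameter-recovery check on a
12-taxon, 1-Mb recombination-only alignment with ten 150-kb replicates for
the group contrast — sizes chosen so the full chain re-runs in minutes on a
single core while keeping per-branch event counts (thousands of
substitutions, dozens to hundreds of imports) in the regime where the
estimators' sampling error is small relative to the 30% recovery tolerance.
The decay rates of the two demonstration groups (80 and 8 events per gene
per unit branch length) are set so the decay contrast stands clearly above
the disruption background that mutation and recombination themselves
generate; the recombination parameters of the two groups are the published
group presets carried by `recomb_presets()`.

## Known limitations

* The HMM shares R/θ, δ, ν across branches; per-branch recombination
  parameters are out of scope.
* The transition parameterization is a deliberate simplification of the
  full ClonalFrame-style model; conceptual agreement, not numeric equality
  with any specific implementation, is the design goal.
* The aligner and orthology machinery assume near-clonal inputs; neither is
  suitable for cross-genus comparisons.
* ω from counting methods is unreliable when dS ≈ 0 (flagged, not fixed):
  very recent divergences simply carry little synonymous signal.
* The simulator's neutrality at the codon level means genome-scale
  simulations cannot produce an ω contrast between groups; codon-level
  constructions are used for that purpose in the tests.
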