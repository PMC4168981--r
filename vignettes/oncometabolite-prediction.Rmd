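---
title: "Predicting oncometabolites from context-specific metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oncometabolites from context-specific metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Mutant metabolic enzymes can drive oncogenesis through the metabolites they
accumulate or create: loss of succinate dehydrogenase or fumarase piles up
succinate and fumarate, and neomorphic isocitrate-dehydrogenase mutants
reduce alpha-ketoglutarate to 2-hydroxyglutarate. `oncoflux` implements a
two-armed in silico screen for such oncometabolites.

The loss-of-function (LoF) arm reasons about flux. A genome-scale metabolic
model is a stoichiometric matrix $S$ with flux bounds and boolean
gene-protein-reaction (GPR) rules; the feasible steady states are
$\{v : Sv = 0,\ lb \le v \le ub\}$. Cancer and normal context models are cut
from a parent network with presence/absence expression calls and a
GIMME-style extraction; an enzyme-deficient model is the cancer model with
one screened gene deleted through its GPRs. The flux spaces of the deficient
and the matched normal model are then sampled uniformly (hit-and-run at 90%
optimality) and compared reaction by reaction; metabolites surrounded by
significantly shifted reactions adjacent to the broken enzyme are the LoF
calls.

The gain-of-function (GoF) arm reasons about structure. Recurrently
missense-mutated enzymes may catalyze near-native chemistry on near-native
substrates. Candidate substrates are library compounds whose path-based
fingerprint is Tanimoto-similar to the native substrates; generic
biochemical reaction operators (SMIRKS transforms with assigned cofactors)
enumerate the reactions a promiscuous mutant could perform; synthetic
reactions whose segmented reaction fingerprint stays within a calibrated
dissimilarity of the native reaction are saved as promiscuity pairs, and
maximum-common-substructure analysis summarizes the dominant scaffolds.

## Statistical machinery

**Flux-shift P-value.** For each reaction, with the comparison set's median
as center, we estimate the probability of finding a flux value in one
condition at least as extreme as a value drawn from the other, symmetrized
over both orderings and capped at 1. Identical distributions give exactly 1;
disjoint supports give approximately 0. An $O(n^2)$ double-loop computation
of the same quantity is the test oracle; the shipped implementation is the
sorted $O(n\log n)$ equivalent. P-values are Benjamini-Hochberg adjusted;
downstream calling uses the raw `p < 0.001` with effect fold
$\max(r, 1/r) \ge 2$ on mean absolute normalized flux (both thresholds are
arguments, and the q-value is carried in every table, since the method is
described with both a raw-P rule and an FDR rule).

**Normalization.** After dropping reactions that carry no flux in either
condition and reactions that can cycle with all exchanges closed
(closed-exchange flux variability), each sample point is divided by its
total flux magnitude, so $\sum_r |v_r| = 1$ per point. Filtering precedes
normalization so removed loops cannot distort the denominator.

**Validation statistics.** Single-gene knockouts are classified by growth
ratio (essential below 0.90, mildly reduced in [0.90, 0.99), unchanged
otherwise; the 0.90 boundary itself is not essential under the strict
"more than 10%" reading). Enrichment of experimental essential genes among
predictions is an upper-tail hypergeometric test reported as
$z = \Phi^{-1}(1-P)$. Flux-direction vs expression-direction concordance is
scored as $(TP+TN)/(TP+TN+FP+FN)$ after removing direction-ambiguous genes
and isoenzyme-catalyzed reactions, with a label-permutation null.

## Tunable parameters

* `detection_threshold` (expression units, default 10) and `consensus`
  (default 0.99, strict `>`): a gene is present when detected in more than
  99% of samples, mirroring RNA-seq detection at 10 mapped reads.
* `required_fraction` (default 0.9): GIMME preserves at least this fraction
  of the objective optimum. The same 0.9 is the sampler's optimality bound,
  so context extraction and sampling describe the same sub-optimal space.
* Normal-context objective: biomass and ATP demand scaled each by its
  maximum achievable flux, weights $a = b = 1$; $b = 0$ recovers plain
  biomass maximization (the cancer objective).
* Sampler: `n_points` 5000, `n_steps` 100 (thinning), warmup from $2n$
  randomized-objective corners. The mixed-fraction diagnostic compares the
  half-way and final chain snapshots against per-reaction medians; values
  near 0.5 indicate forgetting of the initial state.
* Screen: recurrence at `>= 5%` of samples per arm (nonsense/frameshift/
  splice-site for LoF, missense for GoF; silent and in-frame indels count
  toward neither); FIS aggregate is the maximum per gene with default
  cutoff 1.9 (the "medium impact" convention); transporter-only genes are
  excluded; fully OR-substitutable genes are excluded.
* GoF: fingerprints are 1024-bit path fingerprints over linear fragments up
  to 6 bonds, 2 hash bits per fragment; reaction fingerprints have 8
  sections (4 substrate + 4 product slots, sorted by structure key).
  Candidate selection uses substrate TCdiss cutoff (default 0.6 in the
  analysis scripts); pair calling uses a cutoff calibrated at run time as
  the dissimilarity of the packaged isocitrate-oxidation vs
  alpha-ketoglutarate-reduction pair plus a 0.05 margin. Enumerations
  exceeding 30,000 activities per native reaction are excluded.

## The synthetic cohort and what passing it shows

The generator plants ground truth in a 3-compartment, ~30-reaction network:
glucose uptake, lumped glycolysis, a TCA-like cycle coupled through a
generic 2H carrier to oxidative phosphorylation, anaplerosis, overflow
secretion valves for lactate/succinate/fumarate, ATP maintenance, and a
biomass reaction. `g_sdh` and `g_fh` carry recurrent LoF mutations and
their deletions reroute TCA flux into the secretion branches; `g_idh`
carries recurrent missense mutations with the alpha-ketoglutarate to
2-hydroxyglutarate reduction as the planted promiscuous pair; decoys cover
every filter (an OR-isoenzyme pair, a pure transporter, a silent-only gene,
a low-FIS recurrent gene, sub-threshold genes). Expression encodes the
planted presence/absence structure (absent genes at 1% of the detection
threshold, unambiguous by construction) plus log-normal noise, and
multiplicative cancer shifts for genes whose reactions carry more flux when
the biosynthetic bypass disappears — emulating the hypothesis that flux
changes follow expression changes.

What the synthetic data does *not* emulate: realistic RNA-seq counts or
array intensities, mutational signatures, genome-scale network size
(thousands of reactions), medium-dependent secretion phenotypes, or the
cross-cancer heterogeneity of nine real cohorts. Recovery of the planted
truth therefore demonstrates the correctness of the pipeline's logic, not
clinical performance on real tumors.

A deliberate property of the toy network is that the biosynthetic bypass is
energetically neutral at the optimum, so the cancer and normal context
models differ structurally (bypass vs lactate branches) while their shared
reactions shift only mildly; the flux-vs-expression demonstration in the
analysis scripts consequently uses permissive thresholds, while the
oncometabolite calls themselves always use the strict defaults.

## Numerical choices

* **LP solver.** All flux programs (FBA, FVA, the GIMME penalty program)
  run on a bounded-variable two-phase revised simplex with Bland's rule
  implemented in the package. Flux LPs are heavily degenerate — conserved
  moieties (NAD/NADH, ATP/ADP) make $S$ row-deficient and gene deletions
  create zero-width bounds — and the general-purpose dense simplex routines
  available in the R ecosystem fail on exactly these structures, so the
  pivoting is kept under our control. Tests cross-check every fixture
  against an independent simplex formulation. Feasibility tolerance 1e-9,
  reporting tolerance 1e-6; "infinite" bounds are encoded as ±1000.
* **GIMME.** |v| is linearized with auxiliary magnitude variables on
  penalized reactions only; penalties are uniform (1.0) because calls are
  binary. Reactions with empty GPRs (exchanges, spontaneous steps) are
  never penalized and never removed; only absent-GPR reactions with zero
  flux in the penalty optimum are dropped. This follows the extraction
  algorithm's own convention where a literal reading of "keep nonzero-flux
  plus present reactions" would silently delete idle exchange reactions.
* **Sampler.** Chains move along directions between a random chain and the
  running center, staying in the null space of $S$ by construction; chord
  intersections are computed against the bound and optimality half-spaces
  with an 1e-11 direction tolerance, and points are clamped onto the box to
  absorb last-bit overshoot. Determinism is per seed.
* **Chemistry.** SMILES parsing goes through OpenBabel (via ChemmineR) into
  a hydrogen-suppressed graph; implicit hydrogens are refilled from
  standard valences. Supported chemistry is neutral Kekulé organic
  structures; charges and aromatic bond types are out of scope, and the
  packaged libraries respect that. Structure identity uses
  Weisfeiler-Lehman refinement with double content hashing (per-molecule
  rank compression is not comparable across molecules and was rejected).
  Mass balance is checked on heavy atoms plus hydrogens; charge balance is
  off, and the cofactor stand-ins (formaldehyde/methanol as the 2H acceptor
  pair, water, CO2, ammonia, O2, orthophosphate) are chosen so every
  packaged operator balances neutrally. The operator SMIRKS dialect is the
  subset the engine documents: bracket atoms with element, total-H count
  and map class, acyclic patterns, 1-3 bond orders; unmapped reactant atoms
  leave with cofactor products, unmapped product atoms are created.
* **MCS.** Pairwise maximum common connected subgraph by McGregor-style
  backtracking with a best-so-far bound and a 200,000-node cap; the
  multi-compound summary folds compounds greedily starting from the most
  similar pair. Support is the fraction of compounds containing the final
  pattern; dominance needs support ≥ 0.5 and ≥ 3 atoms.
* **Adjacency rule for calling.** "Surrounded by" is one reaction step from
  the deficient enzyme's reactions, computed on non-currency metabolites
  (ATP, NAD(H), CO2, water and friends would otherwise make everything
  adjacent); currency species are also excluded from the emitted calls.
  The currency list is configuration.

## Problem sizes

The packaged studies run at toy scale, chosen so the full suite completes
comfortably on one CPU: ~30 reactions, 40+40 samples, 1000-5000 sample
points per flux space, 20-seed recovery sweeps, a 16-compound library and
12 operators. All sizes are arguments; nothing in the implementation is
specific to these values.

## Known limitations

* The LP core is dense; genome-scale models (thousands of reactions) would
  need a sparse factorized solver behind the same `lp_solve` surface.
* The overlap P-value is conservative for on/off reactions whose active
  distribution hugs zero; such reactions are better caught by the fold
  filter.
* Reaction fingerprints use 4+4 sorted compound slots; reactions with more
  than four non-cofactor participants are rejected rather than truncated.
* The operator library is a curated 12-operator set standing in for the
  much larger proprietary collections used in the enzyme-promiscuity
  literature; user libraries in the same TSV format are accepted.
* Detection calls are a single-threshold substitute for platform-specific
  call algorithms; array-style calls should be emulated by pre-scaling.
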