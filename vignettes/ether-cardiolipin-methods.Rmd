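---
title: "Methods: annotating and modelling alkyl ether cardiolipins"
author: "etherCDL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and modelling alkyl ether cardiolipins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etherCDL)
```

# Scope and model

`etherCDL` annotates positive-mode high-resolution LC-MS/MS peak lists
for a membrane lipidome dominated by ether-linked glycerophospholipids:
PE and PG with dialkyl (DEG), alkyl/acyl (AEG) and diacyl (DAG) cores,
the corresponding lyso forms (MEG/MAG), and cardiolipins carrying zero
to four ether-bound chains, including their mono- and dilyso forms. It
also implements a generative model of CDL biosynthesis by condensation
of two parent phospholipids.

This vignette records the package's own design decisions: the
conventions the arithmetic follows, the choices made where the problem
was genuinely open, the numerical tolerances, and what the simulation
benchmark does and does not demonstrate.

# Mass arithmetic conventions

* Monoisotopic atomic masses are embedded constants (C 12 exactly,
  H 1.00782503207, N 14.0030740048, O 15.9949146196, P 30.97376163,
  Na 22.9897692809; electron 0.00054857991 Da). Reproducing printed ion
  masses at the sub-ppm level requires at least six decimals, which is
  why these are not taken from a coarser table.
* Ion compositions include the adduct atoms: the protonated form of a
  C~73~H~150~O~13~P~2~ cardiolipin is written C~73~H~151~O~13~P~2~, and
  its m/z is the atom sum minus one electron mass. Adducts
  ([M+H]^+^, [M+H−H~2~O]^+^, [M+NH~4~]^+^, [M+Na]^+^) are applied as
  signed formula deltas *before* mass evaluation, so every printed ion
  composition is also a valid formula in the engine.
* ppm errors are signed, observed minus theoretical, over theoretical.
* The first-isotopologue ratio `m1_ratio()` is the abundance-weighted
  atom count Σ n~E~·r~E~ with r = minor/major abundance for the +1 Da
  isotopes (¹³C 0.010816, ²H 0.000156, ¹⁵N 0.003676, ¹⁷O 0.000380;
  IUPAC 2021). This linear form is the single-substitution
  approximation — adequate here because it is only used to fold the
  M+1 area of an XIC back into an abundance, not to fit isotope
  patterns. Full fine structure and charge states beyond +1 are out of
  scope.

A note on internal consistency of reference values: a few printed
observed masses in the source data deviate from their own assigned
compositions by more than 3 ppm (e.g. 554.566 observed for
C~36~H~74~O~3~, theoretical 554.5638, ≈ 4 ppm). The engine always
reports theoretical masses and leaves such reconciliation to the
matching tolerances.

# The lipid space

A species is a head group plus one or two core glycerides, each with
one or two radyl chains. Neutral formulas are assembled from scaffold
constants — glycerol C~3~H~8~O~3~; PE C~5~H~14~NO~6~P; PG
C~6~H~15~O~8~P; the cardiolipin family C~9~H~22~O~13~P~2~ — plus
per-chain substitutions: an ether chain of n carbons adds C~n~H~2n~, a
saturated acyl chain adds C~n~H~2n−2~O, each double bond removes H~2~.

Three conventions matter:

* **Acyl chain length includes the carbonyl carbon.** An ether↔ester
  substitution at fixed n then changes the formula by −2H +1O
  (+13.9793 Da per added ester oxygen on the detected-mass axis) and
  leaves carbon totals unchanged, which is how the mixed ether/ester
  series ladder arises.
* **sn positions and methyl branching are metadata.** Odd-carbon chains
  are annotated as 10-methyl-branched (e.g. C17 = 10-Me-C16) and placed
  at *sn*-1 by convention, reflecting how such chains are assigned by
  GC-MS of hydrolysed cores; MS cannot distinguish this and it has no
  mass consequence. The convention is only consulted as a late
  annotation tie-break.
* **Dilyso cardiolipins exist in two mass-isomeric variants** — two
  single-chain cores bridged by the phosphatidyl-glycero-phosphatidyl
  (PGP) moiety, or one intact two-chain core on a PGPG head. Both are
  enumerated as distinct species sharing a formula; disambiguation is
  deferred to fragment evidence.

The default enumeration (chains 14–17, saturated, all head groups,
lyso species included) yields 1114 species; CDL carbon totals span
56–68. Chain unsaturation is supported for externally observed species
(e.g. a C34:1 diether) but defaults to zero, matching the fully
saturated lipidome this models. The stated chain range cannot produce
two-chain totals above 34, so the enumeration's PE/PG totals run 28–34.

# Fragmentation rules

From the [M+H]^+^ precursor of a cardiolipin-family species the
predictor emits:

* **R1** — loss of one water, attributed to the free hydroxyl of the
  central glycerol. Whether lyso species with additional free hydroxyls
  lose water multiply is not established; a single loss is emitted.
* **R2** — for each core, the neutral loss of its diradylglycerol
  (glycerol + chains), leaving the complementary phosphatidyl-PG ion.
  Identical cores are emitted once.
* **R3** — each R2 ion further loses HPO~3~ (79.9663 Da).
* **R4** — the glycerophosphate C~3~H~8~O~5~P^+^ and glycerodiphosphate
  C~3~H~9~O~8~P~2~^+^ head-group ions.
* **R5** — per ether-bound chain of n carbons, the alkyl-related ion
  C~n+3~H~2n+7~O^+^ (255.268 / 283.300 / 297.315 for n = 14/16/17).
* **R6** (off by default) — generic chain rules for PE/PG (acyl loss as
  fatty acid and as ketene; ether loss as alkylglycerol) and protonated
  monoradylglycerol ions for free glycerides under [M+NH~4~]^+^. These
  extrapolate beyond the cardiolipin-specific scheme — PE/PG chain
  composition is ordinarily read from their own spectra but no explicit
  rule set is printed for them — hence the switch.

Every neutral-loss entry has a companion ion entry whose formula sums
to the precursor ion composition, giving exact mass conservation by
construction (asserted to 1e-9 Da in the tests). Fragments requiring
the loss of an acyl-containing core while an all-ether core is present
carry `abundance_hint = "low"`, encoding the qualitative observation
that mixed ether/ester CDL spectra are dominated by ions representing
their acyl cores; no quantitative intensity model is attempted.

# Annotation

MS¹ precursor matching uses 3 ppm, the identification tolerance of the
modelled workflow. MS² fragment matching uses 5 ppm: observed fragment
annotations in the reference spectra reach ≈3.5 ppm, so the MS¹
tolerance would clip genuine matches.

Candidates for an MS² spectrum are all enumerated species whose
[M+H]^+^ matches the precursor. Each candidate is scored by the number
of **distinct spectrum peaks explained** by its predicted ions. Scoring
explained peaks rather than matched prediction entries avoids two
artefacts: rule entries that coincide in mass cannot double-count, and
symmetric cardiolipins (identical cores, hence deduplicated fragment
lists) are not out-scored by asymmetric chain splits whose duplicated
core losses coincide at the same mass.

Ties are broken by, in order: fewer predicted-but-unmatched entries
(applied only when the candidate matched anything — with zero fragment
evidence there is nothing to penalise); fewer violations of the
branched-chain-at-*sn*-1 convention; smaller precursor |ppm|. The
unmatched-entry key is what lets a fully-explained candidate outrank a
larger species whose fragment set merely contains the observed peaks
as a subset; without it, the species ↔ spectrum round trip is not
identifiable even on noiseless data. Candidates still tied after all
keys are mass-degenerate structures with identical observable evidence
(for example, a diacyl core's chain split, which produces no
chain-specific ion); they are reported together as one `isomer_set`,
mirroring how co-trapped isomers are reported jointly in practice.
Chain-split identity is therefore claimed exactly when fragments
support it; otherwise the claim stops at (head group, ether count,
total carbons), which the isomer set shares.

Retention-time ordering (more ether bonds elute earlier within a
class/carbon group) is a post-hoc consistency check only — no
quantitative retention model is available, so it never enters the
score.

# Quantification

Abundances are sums of integrated XIC areas over a per-class adduct
map (PE/PG: [M+H]^+^ + [M+NH~4~]^+^; cardiolipin family: [M+H]^+^,
[M+H−H~2~O]^+^, [M+NH~4~]^+^, [M+Na]^+^), fully overridable — the
appropriate adduct set is instrument- and method-dependent. For the
cardiolipin family the ¹³C first-isotopologue area of [M+H]^+^ is also
used: at ~70+ carbons the M+1 peak carries as much current as the
monoisotopic peak (`m1_ratio ≈ 0.82`), so ignoring it discards a large,
class-dependent share of signal. Two policies are provided:

* `"sum"` (default): add the M+1 area to the adduct sum, recapturing
  the signal split onto the isotope peak;
* `"scale"`: divide the combined monoisotopic + M+1 area of [M+H]^+^ by
  (1 + m1_ratio). This is the standard isotopologue correction and, by
  construction, equals ignoring the M+1 peak when its area is exactly
  theoretical — the package defines the policy this way because the
  naive alternative (dividing the M+1 area by the ratio and adding)
  would count the monoisotopic signal twice.

No cross-class response-factor correction is applied: phospholipid
classes (and core structures within a class) ionise with different
efficiency, so reported percentages are composition *as measured*; the
output carries a `response_corrected = FALSE` attribute to make this
explicit. Peak integration itself (profile data → areas) is out of
scope; the module consumes integrated areas.

# Condensation model

Cardiolipin synthases condense two parent phospholipids; assuming ester
bonds are not reduced to ethers after CDL formation, a CDL's ether
count is the sum of two independent draws from the parents' ether-count
distributions, i.e. the CDL ether-class distribution is a discrete
convolution. Parent distributions are read off measured core-class
percentages (DEG → 2 ethers, AEG → 1, DAG → 0).

Lyso classes (MEG/MAG) are **excluded and the remainder renormalised**
by default: only intact two-chain cores contribute a full phosphatidyl
moiety to a four-chain CDL. This is a modelling choice the data cannot
settle directly, but it is the one under which both anchor predictions
(tetraethers ≈ half of CDLs under PG+PG, diester/diethers ≈ half under
PE+PG) come out; `include_lyso = TRUE` is available for sensitivity
analysis. The default granularity is the ether-count marginal; a
carbon-resolved joint mode (matrix convolution over a uniform carbon
grid) exists, but no printed inputs are available to validate it
against, so it is exercised only by consistency properties
(marginalisation, normalisation). Scenario `"mix"` is a fixed weighted
sum (default 50–50) of the PE+PG and PG+PG results; fitting the weights
to data is deliberately not offered — the comparison (`L1` distance to
a measured distribution) is a fixed confrontation, not an optimisation.

# The simulator and what the benchmark shows

`simulate_lipidome()` draws species from the enumeration with
probabilities shaped by class fractions × ether-class weights ×
chain-length weights, then rescales log-normal within-group variation
so every drawn (class, ether) bin hits its configured share exactly.
The defaults encode the modelled organism's membrane: PG 32 / PE 24 /
CDL 23 / monolyso-CDL 12 / dilyso-CDL 2 % with the small remainder in
lyso-PE/PG; CDL ether classes at 9/12/28/18/33 % (e0..e4); PE cores
DAG-dominated and PG cores DEG-dominated in their measured ratios;
chain weights 0.35/0.05/0.30/0.30 over C14/C15/C16/C17, which puts the
two-chain total-carbon mode at 31. Monolyso and dilyso ether weights
(0.10/0.35/0.20/0.35 and 0.15/0.25/0.60) follow the qualitative
dominance of the tri/monoether monolyso and diether dilyso forms; these
two vectors are the generator's own calibration where no percentages
are printed.

`simulate_spectra()` emulates acquisition: per class, the species
abundance is split across adduct channels in fixed shares (summing
to 1, so the configured adduct sum recovers the abundance); masses are
perturbed multiplicatively by Gaussian ppm noise (default σ = 1 ppm);
MS² spectra contain the predicted ions (R6 on, since PE/PG chain splits
are otherwise encoded in no observable signal) plus uniform-m/z decoy
peaks (default 10%); retention times follow a deterministic
class/carbon/ether model (−0.5 min per ether bond) with a
structure-specific offset; species co-eluting within the 1 Da
co-isolation window contribute their fragments to each other's spectra,
scaled by abundance ratio. The ¹³C M+1 peak is emitted only for the
cardiolipin-family [M+H]^+^ channel — exactly where the quantification
policy consumes it. That asymmetry is a deliberate simplification: it
makes the noiseless simulate → annotate → quantify round trip exact,
which the test suite asserts, at the cost of not modelling isotope
losses on the other channels.

The benchmark (`pipeline_benchmark()`) annotates every simulated MS²
spectrum against the full 1114-species index and quantifies the
mass-annotated MS¹ features. Its metrics are defined at the resolution
the tool claims: precision counts a spectrum as correct when an
unambiguous top candidate is a contributor to that spectrum
(co-isolated species included, as co-trapped identifications are
reported jointly), or when an isomer-set claim matches a contributor's
(head group, ether count, carbons); recall counts a ground-truth
species as recovered when it appears, at full chain-split resolution,
in the reported candidate set of its own spectrum. Class fractions are
compared against the generator's ground truth after quantification.
The acceptance-level run uses 250 species, 1 ppm noise and 10% decoys;
unit tests use 10–200 species draws. These sizes are the package's
benchmark conditions, chosen to exercise every class including the 2%
dilyso pool.

What passing does **not** show about real data: the simulator draws
decoys uniformly in m/z (no chemically plausible near-isobars), models
no chromatographic peak shape, in-source fragmentation, or
class-dependent response factors beyond the fixed adduct shares, and
same-formula isomers are integrated as separate ground-truth features
rather than merged XICs. Benchmark precision/recall therefore bound the
method's behaviour under its own assumptions, not instrument reality.

# Numerical choices and degenerate inputs

* Formula subtraction with a negative result raises an error — an
  impossible neutral loss is a structural contradiction, not a warning.
* Candidate ordering ends with an alphabetical label key, making
  annotation output deterministic; isomer-set membership is decided by
  exact key equality (|ppm| compared at 1e-12).
* `composition_report()` normalises within declared groups to 100;
  empty inputs and all-zero parent compositions are errors.
* MGF writing uses fixed 4-decimal formatting (0.1 mDa, ≈ 0.08 ppm at
  m/z 1300 — an order below the matching tolerances), giving
  byte-identical output under a fixed seed; parsing reports the line
  number of any malformed content, and a block without PEPMASS is
  loaded but rejected at annotation time.
* All randomness flows through explicit integer seeds; the pipeline
  benchmark derives its two stage seeds as `seed` and `seed + 1`.

# Known limitations

Negative-ion mode, charge states beyond +1, plasmalogens (vinyl
ethers), sphingolipids and head groups beyond PE/PG/CDL are out of
scope. Intensity prediction and collision-energy modelling are not
attempted (`abundance_hint` is qualitative). Branch position and
*sn*-stereochemistry are annotations, not inferences. False-discovery
estimation for annotations and chimeric-spectrum deconvolution are not
provided; co-isolation is handled by reporting contributors jointly,
not by spectral unmixing.
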