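---
title: "Designing miRNA-activated CRISPR guides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing miRNA-activated CRISPR guides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirswitch)
```

## The device and its model

A standard SpCas9 single guide is a spacer (17-20 nt, complementary to the
genomic protospacer) fused to a scaffold whose repeat:antirepeat duplex and
stem-loops are required for Cas9 loading. `mirswitch` builds *conditional*
guides: a miRNA-binding site is placed immediately 5' of the spacer and a
*shield* sequence — partially complementary to the binding site, the spacer
and the first G of the repeat — closes a trigger hairpin over them. While
the hairpin is intact the spacer is sequestered and Cas9 is OFF; binding of
the trigger miRNA (presented by Argonaute) to the site opens the hairpin and
restores activity.

The package models this with equilibrium RNA secondary-structure
thermodynamics only:

* the **OFF state** is the unconstrained equilibrium ensemble of the guide;
  sequestration is quantified by the fraction of spacer positions whose
  pairing probability exceeds a threshold (default 0.5);
* the **ON state** is approximated by re-folding with every binding-site
  position forced unpaired. This "site occupied" surrogate deliberately
  avoids modelling AGO energetics — the protein-mediated activation
  mechanism is not fully understood, and any explicit AGO term would be
  speculation. The proxy is conservative: it frees the site but not the
  shield, so reported ON gains understate the activation an AGO-mediated
  shield displacement would produce;
* **seed invasion cost** is the ensemble free-energy difference between
  folding with the seed-facing site positions forced open and unconstrained
  folding — a proxy for how hard AGO's seed-first target engagement has to
  work against the hairpin;
* **strand displacement** by the *free* (protein-less) miRNA is a two-state
  comparison: MFE(guide) + MFE(miRNA) against duplex(miRNA::site) +
  MFE(guide | site unpaired).

### Assumptions

Nested structures only (no pseudoknots), one molecule at a time except for
the two-state displacement test, no kinetics, no cellular RNA-binding
proteins. Within those limits every number the package reports is an
equilibrium quantity of the nearest-neighbour model described next.

## The folding engine

The engine (C++ via Rcpp) implements a compact Turner-style nearest-
neighbour parameter set at 37 °C: the full 6x6 stacking table including GU
wobble rows, size-dependent hairpin/bulge/internal-loop initiations with
Jacobson–Stockmayer log extrapolation, a linear multiloop model
(a = 3.4, b = 0.4, c = 0 kcal/mol), terminal AU/GU penalties, and constant
5'/3' dangle contributions on exterior/multiloop helix ends ("some" dangle
mode; "none" disables them). GU wobble counts as a pair throughout, so a
designed "mismatch" is a residue pair that is neither Watson–Crick nor GU.

On that model it provides:

* `fold_mfe()` — Zuker dynamic programming with deterministic 5'-most
  traceback (energies are integers in 0.01 kcal/mol, so ties are exact and
  reproducible bit for bit);
* `partition_function()` — McCaskill inside–outside recursions yielding the
  ensemble free energy and the full base-pair probability matrix. Arrays
  are rescaled per nucleotide (anchored at the MFE) so the computation is
  overflow-safe to at least 200 nt;
* `constrained_fold()` / constrained ensembles — per-position
  forced-unpaired and forced-paired masks, applied identically in the MFE
  and partition recursions;
* `cofold_mfe()` — a cotranscriptional variant in which every energy term
  attributed to a pair (i, j) is scaled by
  gamma(d) = alpha * exp(-d / tau) + (1 - alpha), d = j - i
  (defaults alpha = 0.5, tau = 640 nt). With alpha = 0 the code path
  reduces to the equilibrium fold exactly, which the tests assert bitwise;
* `enumerate_structures()` — an exhaustive generator for short sequences
  that scores every nested structure by explicit loop decomposition. The
  decomposition scorer shares the parameter table with the DP but none of
  its recursions, so agreement between the two (MFE, Z, and every entry of
  the probability matrix, at relative tolerance 1e-6 over hundreds of
  random sequences up to 22 nt) is a genuine cross-check.

Two model boundaries worth knowing: interior/bulge loops are capped at 30
unpaired nucleotides (the standard Zuker restriction, enforced identically
in DP and scorer, so the cap is a property of the model rather than an
approximation), and the parameter table is defined at 37 °C — temperature
enters only through RT in Boltzmann weights. Salt (1 M monovalent, the
table's reference condition) is recorded but never corrected for.

## The design grammar

A full-length design reads 5'→3':
`shield | loop | proximal binding site | spacer | scaffold`.
The binding site is the reverse complement of the miRNA; the shield covers
only the site residues facing miRNA positions 1–16 (the rest of the site
forms the hairpin loop), then the spacer, then the first repeat G. Two
mismatch layers are distinguished:

* **site layer** — positions, numbered by the miRNA they face, where the
  site deliberately fails to pair the miRNA (defaults: 2/9/17 for
  full-length sites, the preset that activates best; 10/11 ablates AGO
  cleavage while preserving activation; seed-only sites carry a single
  mismatch at position 2). The shield is built as the complement of the
  *perfect* site, so a site-layer mismatch frustrates the stem exactly as
  it frustrates the miRNA;
* **shield layer** — positions along the sequestered arm where the shield
  fails to pair, used to tune the hairpin free energy. The hard spacing
  rule is at most 3 mismatches in any window of 4 designed pairs; a
  substitution always picks the first of A, C, G, U that neither pairs nor
  wobbles with the facing residue, so the folding engine cannot silently
  re-pair it.

Mismatches may face the binding site and the spacer alike. This is forced
by the physics: the 16-bp site:shield sub-stem alone folds near
-20 kcal/mol, so a -15 kcal/mol trigger hairpin cannot exist unless the
site-facing side is also frustrated.

Architecture variants: `assemble_seed_only()` covers only the miRNA seed
and closes the hairpin with a GAAA tetraloop; `assemble_tetraloop_shield()`
moves the shield and site into the tetraloop of stem-loop 1 (the spacer
stays at the 5' end and is sequestered by long-range pairing; the internal
order — spacer/G-facing shield segment first, site-facing segment second,
then the site — is the unique one whose designed pairs all nest);
`assemble_split_and_gate()` emits a crRNA unit (hairpin over the spacer,
sensing miRNA A) and a tracrRNA unit (hairpin over the antirepeat, sensing
miRNA B), giving AND logic. The tracr unit senses its miRNA through a
full-length site, mirroring the crRNA unit; its arm has no terminal G
because the tracr tail does not start with one. Where the main text leaves
these internal layouts open they are config-driven and documented here as
inferences.

Backbone handling: the optimized scaffold is *derived* from the standard
one in code — a 5-bp extension of the repeat:antirepeat duplex plus one
U→C substitution placed at the centre of the uracil run by `fix_poly_u()`
(one substitution per run, repeated until no run exceeds 3 U, which makes
the operation idempotent). The standard scaffold is the canonical published
SpCas9 sequence; the optimized variant is this package's programmatic
construction of the described modifications, not a transcription of any
specific plasmid.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `dg_window` | [-18, -12] | kcal/mol | centred on -15, the stability at which switching is best; more stable hairpins resist AGO-mediated opening, weaker ones leak |
| `pair_prob_target` | 0.90 | probability | per-pair hybridisation target balancing a leak-free OFF state against sensitivity; enforced on the *median* designed pair (equilibrium pair probabilities are bimodal, so a per-pair band is not attainable — see below) |
| `max_seed_duplex_run` | 6 | bp | longest continuous duplex over the spacer seed (PAM-proximal 10 nt) that still activates; longer blocks suppress activity even at constant ΔG |
| `prob_threshold` | 0.5 | probability | paired/accessible classification |
| `temperature` | 37 | °C | parameter-table condition |
| cofold `alpha`, `tau` | 0.5, 640 | —, nt | literature defaults for distance-scaled cotranscriptional folding |
| displacement `c_ref` | 5e-8 | mol/L | effective duplex initiation 4.09 + RT·ln(1/c_ref): the 50 nM reference matches typical transfection concentrations |

## The deterministic tuner and optimizer

`assemble_full_length()` with `pattern = NULL` runs a greedy tuner that
reproduces the design workflow: start from the mismatch-free (very stable)
stem; fix the continuous duplex over the spacer seed to the requested
length by breaking the stem just 5' of the protected run; then repeatedly
add the single shield-layer mismatch that moves the trigger-hairpin MFE
closest to the window centre, rejecting candidates that change the
*realized* (MFE) seed run. Ties go to the smallest arm position, so the
result is deterministic. `design_stability_series()` retargets the same
tuner at -15/-19/-25/-30 kcal/mol (fewer mismatches = more base pairs =
more stable), and `design_seed_block_series()` holds -15 while fixing the
seed run to 6/8/10 bp with compensating mismatches elsewhere.

`optimize_design()` explores the neighbourhood of the tuned pattern
(add/remove/swap moves; optionally exhaustive or seeded-annealed), drops
candidates violating the grammar, the ΔG window or the seed-run cap, and
ranks the rest by closeness of the median designed-pair probability to the
target and of ΔG to the window centre, with lexicographic sequence order as
the final tie-break — two runs with the same configuration return identical
rankings.

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` draws 21–23-nt miRNAs and 17-nt spacers at 30–70% GC
and always appends adversarial cases: a self-complementary spacer, a spacer
containing a long U run (Pol III terminator hazard), and two distinct
miRNAs sharing a seed (the muscle/heart co-expression situation that makes
seed-only designs respond to both family members). It does **not** emulate
miRNA expression or activity levels, AGO loading biases, cellular RNA
structure context, or chromatin accessibility of the DNA target — so a
design that passes every in-silico check here still needs its trigger
validated against measured miRNA *activity* (expression alone does not
predict activity).

The Stoplight-style reporter simulator covers the readout logic only: an
INDEL activates the two out-of-frame fluorescent ORFs iff its net shift is
not a multiple of 3; with sizes uniform on ±1..9 that expectation is
exactly 2/3. The default uniform size distribution is a stand-in — real
NHEJ spectra are locus-dependent — which is why the simulator takes an
arbitrary size distribution.

## Numerical choices and degenerate inputs

Integer centi-kcal energies make MFE tracebacks exact; traceback prefers
the 5'-most pairing, interior candidates in (k asc, l asc) order, stacking
before hairpins. The partition function is computed with per-nucleotide
rescaling anchored at `exp(-1.07·MFE/(RT·n))`, which is algebraically
equivalent to a log-space formulation for every reported ratio and keeps
doubles in range beyond 200 nt. Probability conservation
(`p_paired + p_unpaired = 1`) holds to 1e-9 in the tests. Sequences too
short to form any pair fold to the open chain at 0 kcal/mol; constraint
sets admitting no structure raise an error rather than returning nonsense;
hairpin loops shorter than 4 nt that would arise from a seed-only site on
a hypothetical 16-nt miRNA are padded with a GAAA tetraloop.

## Known limitations

* Per-pair equilibrium probabilities in a mismatch-tuned stem are bimodal:
  segments between mismatches either hold (p near 1) or fray (p well below
  0.85). A target enforced pair-by-pair is therefore unattainable; the
  package states and tests the target on the median designed pair.
* The two-state displacement test depends strongly on the bimolecular
  reference concentration. At the 50 nM default a full-length site's
  23-bp duplex (even with three mismatches) outweighs the opening cost of
  a deliberately weakened -15 kcal/mol hairpin, so full-length designs
  report displacement as marginally favorable; seed-only designs, whose
  7-bp duplex cannot pay the initiation penalty, are robustly
  displacement-resistant. In cells, displacement resistance additionally
  rests on the scarcity of free (non-AGO) miRNA and on kinetics (no
  accessible toehold), neither of which a two-state free-energy comparison
  captures.
* The ON proxy frees the binding site but not the shield; reported ON
  gains are conservative lower bounds, most visibly for the
  tetraloop-shield architecture, where the spacer-facing shield segment is
  untouched by site occupancy and the proxy gain is near zero.
* The energy table is a compact published-style set, not a verbatim copy
  of any laboratory's tables; absolute ΔG values carry the usual ±1-2
  kcal/mol parameterisation uncertainty, which is why design targets are
  windows.

## Problem sizes

The test suite folds hundreds of random 8–22-nt sequences against the
exhaustive oracle, and the acceptance script re-derives the stability
series, the seed-coverage series, the optimized base design, displacement
on seed-only and weak-toy designs, pathway robustness over nine assembled
designs, a 100,000-event reporter simulation, and a 60-sequence oracle
sweep; the full suite runs in about a minute on one core.
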