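# mirswitch

Design and thermodynamic analysis of miRNA-sensing CRISPR single-guide
RNAs in R.

Cell-type-specific gene editing needs a guide that is inert until it meets
a molecular signature of the right cell. Endogenous miRNAs are such a
signature, and a guide RNA can be engineered to read them: a miRNA-binding
site is placed just 5' of the spacer and a partially complementary
*shield* sequence folds back over the binding site, the spacer and the
first repeat G, forming a trigger hairpin that sequesters the spacer and
keeps Cas9 OFF. Argonaute-presented binding of the trigger miRNA opens the
hairpin and switches editing ON. `mirswitch` is a toolkit for people
engineering such guides: it assembles the designs, tunes their stability,
and evaluates their switching behaviour with an internal RNA
thermodynamics engine.

## What is inside

* **Design grammar** — full-length and seed-only binding sites
  (`assemble_full_length()`, `assemble_seed_only()`), a tetraloop-shield
  variant (`assemble_tetraloop_shield()`), and a two-miRNA split AND gate
  (`assemble_split_and_gate()`); rule-based mismatch placement (at most 3
  mismatches per 4 designed pairs; shield coverage never beyond miRNA
  position 16), scaffold backbone fixes (`fix_poly_u()`), and DNA template
  emission (`emit_dna_template()`). `validate_design()` returns grammar
  violations as data.
* **Folding engine** (Rcpp) — nearest-neighbour model with GU wobble:
  minimum-free-energy folding with deterministic traceback (`fold_mfe()`),
  McCaskill partition function and base-pair probabilities
  (`partition_function()`), per-position constraints
  (`constrained_fold()`), distance-scaled cotranscriptional folding
  (`cofold_mfe()`, gamma(d) = alpha·exp(-d/tau) + 1 - alpha), and an
  exhaustive enumeration oracle (`enumerate_structures()`) that the test
  suite checks the dynamic programming against.
* **Switch diagnostics** — OFF-state spacer sequestration, an ON-state
  proxy (binding site forced open), seed-invasion cost, a two-state
  strand-displacement test against the free miRNA, folding-pathway
  robustness (equilibrium vs. cotranscriptional structure), and a
  deterministic aggregate score (`switch_report()`, `switch_score()`).
* **Optimizer** — deterministic stability tuner plus neighbourhood search
  over mismatch patterns (`optimize_design()`), the free-energy series
  -15/-19/-25/-30 kcal/mol (`design_stability_series()`), and 6/8/10-bp
  seed-coverage variants at constant stability
  (`design_seed_block_series()`).
* **I/O and fixtures** — FASTA/TSV readers, byte-stable FASTA/TSV/JSON
  reports, a bundled trigger-miRNA catalogue, seeded synthetic panels with
  adversarial cases (`generate_fixtures()`), and a frameshift-reporter
  simulator (`simulate_stoplight()`). A thin CLI lives in
  `inst/cli/mirswitch`.

Results come back as tibbles or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods, so everything chains with the pipe.

## Worked example

Design a miR-17-5p-activated guide for the demonstration spacer and ask
how it switches:

```r
library(mirswitch)
mir    <- catalogue_mirna("miR-17-5p")
spc    <- example_spacer()
design <- assemble_full_length(mir, spc)
design
#> <miR-guide, full_length_5prime_hairpin, 150 nt, trigger 1-75>
#> CUUAGCAAGACUAAGAUCCAACGUACUUACAAUGCUACCUACACUGUACGCACUUAGGACCUGAGUCAUGCUAA...
#> shield[1-34] loop[35-41] binding_site[42-57] spacer[58-74] scaffold[75-150]

switch_report(design)
#> <switch report>
#>   OFF spacer paired fraction: 0.82
#>   ON spacer accessible fraction: 0.29 (gain 0.12)
#>   trigger dG: -15.69 kcal/mol; seed duplex run: 6
#>   seed invasion cost: 1.77 kcal/mol
#>   displacement dG: -3.46 (favorable)
#>   pathway robust: TRUE
```

Reading the report: 82% of spacer positions are sequestered at equilibrium
(the OFF state), the trigger hairpin sits at -15.7 kcal/mol inside the
default design window, only 6 continuous base pairs block the spacer seed
(longer blocks kill activation), forcing the binding site open (the ON
proxy for AGO-miRNA occupancy) raises spacer accessibility by 0.12, and
the predicted structure is identical whether folded at equilibrium or
cotranscriptionally. The strand-displacement line shows the free-miRNA
two-state test at the 50 nM reference: full-length sites are marginal by
that test, while seed-only designs (`assemble_seed_only()`) are robustly
displacement-resistant — see the methods vignette for why, and
`switch_score(report)$checks` for the per-criterion verdicts.

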