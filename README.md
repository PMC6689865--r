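# ionstate

Rule-based enumeration of the major ionization states of drug-like small
molecules over a pH range, for virtual-screening library preparation — plus
the accuracy-evaluation harness (correct/excess/incorrect taxonomy,
precision-factor sweeps, per-moiety cross-validation) that goes with it.

## Who this is for

Docking a ligand in the wrong protonation state costs real accuracy: charged
and neutral forms of the same molecule bind differently, and many drug-like
compounds populate several forms near physiological pH. `ionstate` turns one
input SMILES into the set of protomers worth docking, fast enough for whole
libraries, with batch-safe behavior (bad records are skipped and logged, the
run continues).

## The method

Each of 38 ionizable substructures (SMARTS rules, applied in priority order
with atom masking so every atom belongs to at most one moiety) carries an
empirical pKa mean and standard deviation. For precision factor *n* (default
1.0), the plausible-pKa interval of a site is

```
range_pKa = [mu - n*sigma, mu + n*sigma]
```

and against the pH window `[pH_min, pH_max]` (default `[6.4, 8.4]`):

* `range_pKa` entirely below the window → the site is deprotonated;
* entirely above → protonated;
* overlap (boundaries included) → **both** forms are generated.

The output set is the Cartesian product over sites: *i* overlapping
monoprotic sites yield 2^*i* protomers (capped at `max_variants`, default
128). Phosphates and phosphonates carry two ordered dissociation constants
and can emit all three of their forms (fully protonated, singly
deprotonated, doubly deprotonated). Nitro groups store a sentinel mean of
−1000 so their oxygens are always written charge-separated and anionic.
Edits are *absolute*: `CC(=O)O` and `CC(=O)[O-]` produce identical output
sets.

The Henderson–Hasselbalch utility gives exact single-site fractions:
`hh_fraction(4.0, 7.4)` → 0.9996 (a pKa-4 acid is 99.96% deprotonated at
pH 7.4).

## Installation and requirements

SMILES/SMARTS handling runs in RDKit through a bundled Python helper, so a
`python` with the `rdkit` package must be on the PATH (or set
`options(ionstate.python = "/path/to/python")`).

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "ionstate", load_package = "installed")'
```

## Worked example

```r
library(ionstate)

enumerate_protomers("CCN(CC)CC(=O)Nc1c(C)cccc1C", identifier = "lidocaine")
#> Protomer set: 2 protomer(s) from 1 input(s) [pH 6.40-8.40, n = 1.00]
#>                       input identifier                       protomer
#>  CCN(CC)CC(=O)Nc1c(C)cccc1C  lidocaine     CCN(CC)CC(=O)Nc1c(C)cccc1C
#>  CCN(CC)CC(=O)Nc1c(C)cccc1C  lidocaine CC[NH+](CC)CC(=O)Nc1c(C)cccc1C
```

Lidocaine's amide nitrogen is claimed by the higher-priority amide rule
(emitted neutral — amide N–H pKa values sit far above the window), while the
tertiary amine's interval straddles physiological pH, so both the neutral
and the ammonium form come out: exactly the two forms that matter for
docking this anesthetic.

Site diagnostics show the masking at work:

```r
detect_sites("OC(=O)c1ccccc1O")     # salicylic acid
#> Ionizable sites of O=C(O)c1ccccc1O:
#>          rule class atom site_no
#>  benzoic_acid  acid    3       1
#>        phenol  acid   10       1
```

At defaults the benzoic-acid site is always deprotonated (its interval lies
below pH 6.4) and the phenol is emitted both ways, giving two protomers that
share the carboxylate.

The evaluation harness runs on labeled data — here a seeded synthetic
benchmark (540 compounds, 12 moieties) from the package's own generator:

```r
ds <- make_labeled_dataset(count_per_moiety = 45, seed = 11)
sweep_precision(ds)
#>     n n_total  correct    excess incorrect
#> 1 0.0     540 81.29630  5.925926  12.77778
#> 2 0.5     540 81.29630  5.925926  12.77778
#> 3 1.0     540 55.00000 45.000000   0.00000
#> 4 1.5     540 55.00000 45.000000   0.00000
#> 5 2.0     540 55.00000 45.000000   0.00000
#> 6 2.5     540 55.00000 45.000000   0.00000
#> 7 3.0     540 38.33333 61.666667   0.00000
```

Widening the intervals (larger *n*) converts incorrect assignments into
excess ones and excess never recedes — the monotone trade-off between
library size and the risk of missing a relevant state. `incorrect` is the
percentage to watch: those compounds would never be docked in a state they
actually populate.

Command-line wrappers live in `exec/`:

```sh
Rscript exec/ionstate-protonate --smiles "Oc1ccccc1"
Rscript exec/ionstate-protonate --smiles-file library.smi --min-ph 6.4 --max-ph 8.4 --pka-precision 1.0 --output out.smi
Rscript exec/ionstate-evaluate --dataset labeled.csv --sweep-n 0,0.5,1,1.5,2,2.5,3
```

## Package layout

* `R/` — rule table and configuration, standardization/IO, site detection
  with masking, the enumeration engine, the evaluation harness, synthetic
  fixtures, CLI drivers.
* `inst/extdata/ionizable_substructures.tsv` — the 38-rule table (name,
  priority, SMARTS, ionizable-atom positions, mu/sigma per dissociation).
* `inst/python/chem_backend.py` — the batched RDKit structure service.
* `vignettes/ionization-states.Rmd` — the model, its assumptions, numerical
  choices, and limitations.
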