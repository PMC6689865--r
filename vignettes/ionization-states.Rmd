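---
title: "Enumerating small-molecule ionization states over a pH range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating small-molecule ionization states over a pH range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-based virtual screening docks each candidate ligand in the
protonation state(s) it actually populates near the pH of interest. Most
drug-like molecules are ionizable, and which form dominates depends on the
acid dissociation constant of each site: by the Henderson–Hasselbalch
relation, a monoprotic site with constant $\mathrm{p}K_a$ at pH $p$ is
deprotonated with fraction $1/(1 + 10^{\mathrm{p}K_a - p})$. A site whose
$\mathrm{p}K_a$ is far from the pH window can safely be fixed in one state;
a site near the window must be enumerated in both, because either form may be
the one that binds.

`ionstate` prepares SMILES libraries accordingly. It does **not** predict
per-molecule $\mathrm{p}K_a$ values. Instead, every ionizable *moiety* (a
functional-group substructure: carboxylic acid, phenol, tertiary amine, ...)
carries an empirical $\mathrm{p}K_a$ mean $\mu$ and standard deviation
$\sigma$ summarizing how compounds bearing that group titrate in water, and
the engine reasons about the interval

$$\mathrm{range}_{\mathrm{p}K_a} = [\mu - n\sigma,\; \mu + n\sigma],$$

where $n \ge 0$ is a user-set *precision factor* (default 1). Against the pH
window $[\mathrm{pH_{min}}, \mathrm{pH_{max}}]$ (default $[6.4, 8.4]$,
bracketing physiological pH) the decision is a trichotomy:

* interval entirely **below** the window &rarr; the site is emitted
  deprotonated;
* interval entirely **above** &rarr; emitted protonated;
* any **overlap** &rarr; both forms are emitted, and the molecule's output
  set is the Cartesian product over such sites ($2^i$ protomers for $i$
  overlapping monoprotic sites).

Boundary contact ($\mu + n\sigma = \mathrm{pH_{min}}$, or the symmetric
case) counts as overlap: the one-sided decisions use strict inequalities, so
the conservative both-states branch takes every tie. Larger $n$ therefore
only ever widens intervals and adds states; it never removes one
(`enumerate_protomers()` output sets are monotone in $n$, a property the
test suite checks).

## The rule table

Sites are located with SMARTS patterns, applied in a fixed priority order
with *atom masking*: once a match claims its atoms, those atoms are
invisible to every lower-priority rule. This is what keeps an amide nitrogen
from also being classified as an amine, and a phenyl carboxylate from also
being a plain carboxylate. Masking uses the full matched atom set, not just
the ionizable atom, which is the stronger and safer reading: any atom that
helped define a high-priority context cannot anchor a lower-priority site.

The shipped table (`load_default_rules()`,
`inst/extdata/ionizable_substructures.tsv`) has 38 rules. Each line carries
the rule name, integer priority, SMARTS, the 1-based position(s) of the
ionizable atom(s) in the pattern, and one $(\mu, \sigma)$ pair — or two
ordered pairs for the diprotic phosphate and phosphonate rules, whose single
site spans two oxygens and three ionization levels (fully protonated, singly
deprotonated, doubly deprotonated). The intermediate level always removes
the *first* proton only; a state deprotonated at the second constant but
protonated at the first is never generated.

Three table-design points deserve comment:

* **Parameters are reconstructed estimates.** The table's SMARTS and
  $(\mu, \sigma)$ values were written for this package as realistic
  summaries of aqueous near-room-temperature experimental $\mathrm{p}K_a$
  distributions per moiety; they are static data, not fitted by the package.
  Anchored values: phenol $\mu = 7.07$, $\sigma = 3.28$; azide
  $\mathrm{p}K_a$ 4.65; amine classes carry $\sigma \approx 2.2$–$2.5$
  (amine $\mathrm{p}K_a$ spreads are wide), which makes their intervals
  overlap the default window at $n = 1$ — the behavior that matters for
  molecules like lidocaine, whose amine ($\mathrm{p}K_a$ 8.01) genuinely
  populates both forms at physiological pH. Users with their own curated
  data can recompute $\mu/\sigma$ per moiety (the evaluation module's
  cross-validation does exactly this) and ship a modified table via
  `read_rule_table()`.
* **The nitro sentinel.** Nitro groups are written charge-separated
  (`[N+](=O)[O-]`) and must stay that way; rather than special-casing them,
  the rule stores $\mu = -1000$, $\sigma = 0$. The generic decision logic
  then always lands in the "deprotonate" branch for any sensible pH window,
  and the "edit" is a no-op on the already-anionic oxygen.
* **Every SMARTS matches both drawn forms.** Patterns accept the protonated
  and the deprotonated spelling of their group (e.g.
  `[$([OX2H1]),$([OX1-])]`), because the engine's edits are *absolute*: the
  output states are determined by pH alone, never by how the user drew the
  proton. `CC(=O)O` and `CC(=O)[O-]` give identical output sets under every
  configuration.

## Standardization

SMARTS matching needs one notation per group, so parsing
(`parse_smiles()`) standardizes before matching: aromaticity is perceived
(Kekulé and aromatic spellings converge), the four written azide variants
(`N[N+]#N`, `N=[N+]=N`, `NN#N`, `N=N=N` — the last two are formally
hypervalent and are repaired before valence checking) collapse to
`N=[N+]=[N-]`, and uncharged nitro `N(=O)=O` becomes `[N+](=O)[O-]`.
Standardization is idempotent. Multi-fragment inputs keep their largest
fragment (with a message): screening libraries often still contain
counter-ions even though curated datasets have salts removed, and trimming
is more useful than rejection. Input stereochemistry passes through edits
untouched.

These primitives — parsing, SMARTS matching with matched-atom indices,
formal-charge/hydrogen edits, canonicalization — run in RDKit through a
bundled Python helper (`inst/python/chem_backend.py`), invoked once per
batch with a JSON payload. The helper is a pure structure service; it never
sees a pH. All decisions, masking, enumeration, and evaluation logic are R
code. Aromatic-nitrogen edits carry an explicit hydrogen count (implicit
valence rules cannot restore a ring N–H); if a protonated aromatic nitrogen
cannot be kept aromatic the combination fails sanitization and is skipped
with a log entry rather than aborting the molecule.

## Enumeration mechanics and numerical choices

For each molecule: standardize &rarr; detect sites &rarr; per-site state
sets &rarr; Cartesian product &rarr; absolute edits &rarr; canonicalize
&rarr; deduplicate &rarr; sort &rarr; truncate.

* **Determinism.** Matches are ordered by their sorted atom-index sets;
  symmetric duplicate matches of one rule on the same atoms collapse;
  output protomers are sorted byte-wise (C locale). Identical invocations
  are byte-identical.
* **Output cap.** `max_variants` defaults to 128 ($2^7$): polyprotic
  enumeration is exponential, and a power-of-two cap keeps enumerations for
  up to seven overlapping sites complete. Truncation keeps the
  lexicographically first canonical strings — reproducibility is preferred
  over any heuristic notion of importance. Internally at most
  `max(max_variants, 4096)` combinations are ever realized.
* **Degenerate inputs.** A molecule with no ionizable site returns exactly
  its standardized self. Unparseable records in a batch are skipped with a
  message and do not abort the run. An edit that is chemically impossible
  (e.g. deprotonating a site with no removable hydrogen) skips that one
  combination.

## The evaluation harness

Given compounds with experimentally known $\mathrm{p}K_a$ and a moiety
label, each prediction is one of three outcomes. The *required* set comes
from the experimental value against the window ($\mathrm{p}K_a <
\mathrm{pH_{min}}$: deprotonated only; above the window: protonated only;
inside, boundaries included: both). **Correct** means emitted = required;
**excess** means a strict superset (harmless for accuracy, costly for
library size); **incorrect** means a required state is missing (a relevant
state is never docked). Diprotic compounds build the required set from both
constants over the three ordered levels with the same thresholds.

Curation filters (`curate()`) mirror how such benchmarks are assembled:
salts out; per-site replicate values averaged when their span is at most
1.0 and discarded otherwise; values kept only inside $[-1.74, 15.7]$
(hydronium to water) unless the moiety is exception-listed (sulfonates and
sulfates measured below the floor; alcohols, amides, and protonated
aromatic nitrogens above the ceiling); nitro compounds get the sentinel.

Two structural facts make the harness's headline trends provable rather
than empirical: as $n$ grows, a one-sided interval stays one-sided until it
overlaps, and once it overlaps both states are emitted forever after. Hence
per compound the outcome path is monotone, so the excess percentage is
non-decreasing and the incorrect percentage non-increasing in $n$ on *any*
fixed dataset, reaching incorrect = 0 once every interval overlaps the
window.

Cross-validation (`crossvalidate_moiety()`) re-estimates $\mu/\sigma$ per
moiety from two-thirds of the compounds and classifies the held-out third,
over $k = 3$ folds. Folds are built by an explicitly seeded shuffle
followed by an index-modulo-$k$ split; the seed is a recorded argument, and
the caller's RNG state is never touched.

## The synthetic generator, and what passing tests do not show

The evaluation needs labeled data, and no public per-moiety
$\mathrm{p}K_a$ database ships with the package, so
`make_moiety_compounds()` generates one: each moiety has a hand-written
bank of template molecules guaranteed (and tested) to contain exactly one
instance of that moiety and nothing else ionizable, and $\mathrm{p}K_a$
values are drawn from the rule's own Normal($\mu, \sigma$), truncated by
rejection to the curation bounds unless exception-listed. Diprotic draws
are ordered. `make_polyprotic_molecule(i)` builds an asymmetric chain
polyamine — segment lengths grow along the chain and the two ends differ —
so that all $2^i$ protonation patterns are graph-distinct molecules; a
symmetric chain would collapse equivalent patterns under canonicalization.

This emulates the *statistical* structure the harness assumes, not real
chemistry: real datasets have moieties whose empirical distributions are
skewed or multi-modal, compounds with several interacting sites,
measurement error, and context effects (a phenol flanked by halogens
titrates far from $\mu_{\text{phenol}}$). Passing the harness on synthetic
data validates the *procedure* — the taxonomy, the monotone trends, the
cross-validation plumbing — and says nothing about accuracy on real
measured compounds. On a fixed synthetic benchmark (540 compounds, 12
moieties) the sweep reproduces the expected shape: incorrect assignments
shrink to zero by $n \approx 1$ and excess assignments grow toward wide-$n$
saturation; a cross-validated all-low-$\mathrm{p}K_a$ acid moiety (we use
sulfinic acids, $\mu = 1.8$, $\sigma = 0.7$, comfortably below any
physiological window) scores 100.0 ± 0.0 / 0.0 ± 0.0 / 0.0 ± 0.0, the
always-deprotonated row.

Problem sizes used by the shipped tests and acceptance script: 540-compound
sweeps, 60-compound cross-validations, $10^4$-draw oracle comparisons, and
polyprotic enumeration up to $2^7$ — sizes at which every quantity is exact
or statistically forced, and a full run takes well under a minute.

## A note on one worked fraction

The standard relation gives, for $\mathrm{p}K_a = 7.3$ at pH 7.4, a
*deprotonated* fraction of 55.73% and a *protonated* fraction of 44.27%.
The 44.27% figure is sometimes quoted as the deprotonated fraction of
2,2,2-trifluoroethanethiol; `hh_fraction()` implements the standard
relation, under which 44.27% is the protonated fraction, and the package's
tests pin it that way rather than silently relabeling either form.

## Known limitations

* Ionization only: no tautomer enumeration (combine with a dedicated
  tautomer tool when both are needed), no population weighting of the
  emitted protomers, no 3D structures, no InChI/SDF in this version.
* Sites are judged independently; interactions between nearby ionizable
  groups (salicylic acid's hydrogen-bonded phenol, $\mathrm{p}K_a$ 13.3,
  which the phenol rule still emits in both forms) are exactly the cases a
  substructure-interval method gets wrong.
* The shipped $(\mu, \sigma)$ values are reconstructed summaries, not fits
  to a distributed database; treat per-moiety accuracy numbers on synthetic
  data as procedure checks, not benchmarks.
* Chemically equivalent sites (hydroquinone's two phenols) are enumerated
  as independent sites; no symmetry reduction is attempted beyond duplicate
  match collapsing, so symmetric molecules can yield fewer *distinct*
  protomers than $2^i$.
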