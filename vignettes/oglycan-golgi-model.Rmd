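---
title: "A kinetic model of mucin-type O-glycan biosynthesis in the Golgi"
author: "oglycosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of mucin-type O-glycan biosynthesis in the Golgi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oglycosim)
```

## The biological problem

Mucin-type *O*-glycosylation decorates serine/threonine residues of secreted
and membrane proteins with short branched sugar chains.  Biosynthesis starts
from the Tn antigen (a single GalNAc on the peptide; in reduced
mass-spectrometric profiles it appears as `GalNAcol`) and proceeds as the
protein transits the Golgi: core structures are built first (core 1,
Gal&beta;1-3GalNAc; core 3, GlcNAc&beta;1-3GalNAc; cores 2 and 4 by
&beta;1-6-branching), then elongated with LacNAc units, and finally capped by
sialylation, fucosylation or sulfation.  Which structures accumulate depends
on the glycosyltransferase complement of the cell; transiently transfecting
CHO cells with different enzyme combinations reprograms the profile.

`oglycosim` models this process in three layers:

1. **Rule-based network generation** — a bundled table of 20 model enzymes
   and 30 reaction rules is applied exhaustively, starting from the Tn
   antigen, to enumerate every structure reachable under a given active
   enzyme set.
2. **Four-compartment Golgi kinetics** — the network is simulated through
   cis, medial, trans and TGN compartments with competing-substrate
   Michaelis–Menten kinetics, clamped donor sugars and binary enzyme
   localization.
3. **Evolution-strategy estimation** — unknown kinetic constants and
   compartmental enzyme concentrations are fitted to observed TGN profiles.

The initiation step (GalNAc-polypeptide transfer) is deliberately outside the
model: it depends on protein structure and site accessibility, and the >53
potential sites of the PSGL-1 reporter are treated as one pooled acceptor.

## Structures and the string dialect

Glycans are rooted trees of monosaccharide nodes (root: GalNAc).  The I/O
dialect is condensed IUPAC, e.g.
`NeuAcα2-3Galβ1-4(Fucα1-3)GlcNAcβ1-3GalNAcol` for sialyl-Lewis&nbsp;X on
core 3.  Parsing accepts Greek or ASCII anomer letters and both root
spellings (`GalNAcol`, `GalNAcα1-`); canonical output always uses Greek
letters and `GalNAcol`.  Canonicalization picks the *deepest* child subtree
as the backbone (ties broken by lowest attachment position) and prints the
remaining branches parenthesized in ascending position order — this
reproduces the conventional spelling in which fucose always appears
parenthesized while the sialylated LacNAc arm runs the main chain.
6-O-sulfation is written as a `6S` prefix on the carrier GlcNAc and stored
as a sulfate leaf at position 6; sulfate counts as a substituent, not a
residue, and contributes one negative charge like NeuAc/NeuGc.

## The reaction rule set

The bundled set (`default_ruleset()`, `inst/extdata/rules.json`) has 20
enzymes and 30 rules; 12 enzymes are flagged as transfectable.  Families
catalyzing one reaction (B3GNT, B4GALT, ST3GAL, ST6GALNAC) are collapsed
into single model enzymes, and enzymes acting on several substrate contexts
carry suffixed sub-rules.  The sub-rule split is a reconstruction: the
core-synthesis, elongation and capping rules follow the pathway narrative
directly (C1GALT1/B3GNT6 competing for the Tn root; GCNT1/GCNT3 branching
cores 1 and 3; B3GNT3 extending core 1; B4GALT/B3GALT5 building type-2/
type-1 chains; B4GALNT3 for LacdiNAc; A4GNT, A3GALT, A4GALT for terminal
epitopes; FUT2/3/4/7 for fucosylation; ST3GAL_a/_b, ST6GAL1 and
ST6GALNAC_a/_b/_c for sialylation), and CHST4 is given four sub-rules
(`_a`–`_d`: 6-O-sulfation of uncapped, type-2-capped, type-1-capped and
LacdiNAc GlcNAc), which closes the inventory at exactly 30 while matching
the `_a/b/c/d` sub-rule naming of the localization table.  The rule file is
data, not code, so corrections are one-line edits.

Network generation is a breadth-first closure with de-duplication by
canonical string.  The closure is confluent (rule order cannot change the
species set) and is truncated at `max_residues = 10` monosaccharides —
without a cutoff the poly-LacNAc rules make the space infinite; 10 leaves
ample headroom over every profiled structure (at most 7 residues).  Species
at the cutoff are kept but not expanded.

## Kinetics

Each reaction instance (rule $r$ of enzyme $e$ acting on substrate $S_j$ in
compartment $c$) proceeds at

$$
v \;=\; \frac{k_f^{(r)}\,E_{e,c}\;\dfrac{D_{d,c}}{K_{md}^{(e)}}\;\dfrac{S_j}{K_m^{(r)}}}
       {\Bigl(1+\dfrac{D_{d,c}}{K_{md}^{(e)}}\Bigr)\Bigl(1+\sum_k \dfrac{S_k}{K_m^{(k)}}\Bigr)}
$$

where the sum runs over all species–rule pairs of the same enzyme present in
the compartment.  This is the rapid-equilibrium random-order bi-substrate
form with acceptor competition: it uses exactly the three named constants
($k_f$, turnover, min^-1^; $K_m$, acceptor half-saturation; $K_{md}$, donor
half-saturation, µM), reduces to classical Michaelis–Menten in the
saturating-donor single-substrate limit (verified against the closed-form
batch solution in the tests), and encodes the substrate competition that
shapes the pathway (e.g. C1GALT1 vs B3GNT6 for the Tn antigen).  The law is
isolated in one function (`reaction_rate()` / the internal rate tables), so
an alternative form is a local change.

Donor sugars are clamped constants per compartment (µM), zero where the
sugar is not donated — a rule whose donor is absent from a compartment is
silently inactive there.  Enzyme localization is binary; concentrations
$E_{e,c}$ exist only where the localization matrix is 1 and are forced to 0
elsewhere.  The bundled localization follows the division of labor: core
synthesis (C1GALT1, B3GNT6) in cis, branching (GCNT1/3) in medial,
fucosylation in medial/trans, elongation and capping in trans/TGN, and
CHST4 everywhere except cis; it is chosen to be consistent with the donor
table (an enzyme is never placed where its donor is zero, except that
trans/TGN elongation by GlcNAc-transferases stops in the TGN where
UDP-GlcNAc is exhausted).

**Transport.** The default schedule is sequential batch (plug flow): the
entire glycan pool starts in cis at 100 (configured face value, nominally
µmol/µL, converted 1:1 to internal concentration units since only relative
abundances matter), reacts for one residence time $\tau = 5.56$ min, is
transferred wholesale to the next compartment, and the run stops at
$4\tau = 22.24$ min, when the TGN content is read out as percentages.  A
continuous CSTR-chain mode (`mode = "cstr"`, inter-compartment flux
$(S_{c-1}-S_c)/\tau$, no TGN efflux) is provided as an option, since the
classical Golgi models are CSTR chains; the mode is recorded in the result.
Which of the two the original study used is not decidable from its text, so
neither mode claims figure-level fidelity.

**Numerics.** Parameters drawn over eleven decades produce extremely stiff
systems (local rates up to ~10^10^ µM/min).  The integrator is therefore
LSODE in pure-BDF mode with an analytically assembled Jacobian —
method-switching heuristics (LSODA) fail on the boundary layers at
compartment hand-offs.  The competition sum uses a smooth positive-part
(C^∞ through zero) so the Newton corrector never sees a kink, while the
numerator keeps the raw concentration: a tiny negative excursion produces a
negative (refilling) rate and self-corrects.  Default tolerances are
`rtol = 1e-8`, `atol = 1e-10` relative to the initial amount; total glycan
is conserved to ~10^-15^ relative and negative excursions stay below
10^-8^ of the initial concentration.  Profile entries below 10^-12^ µM are
reported as 0% to suppress integrator noise.

## Parameter estimation

Free parameters are $k_f$ and $K_m$ per active rule, $K_{md}$ per enzyme,
and $E_{e,c}$ per enzyme and localized compartment, all bounded in
$[10^{-6}, 10^5]$.  The objective is the weighted sum of squared residuals
between simulated and observed TGN percentages over the observed structures,
with per-experiment weight $1/\sigma^2$ where $\sigma$ is the standard
deviation of the observed values — the "standard deviation" weighting of
the common parameter-estimation tools (the observed profiles carry no
replicate errors, so within-profile dispersion is the only available
scale).  Matching is on relative abundance: absolute TGN concentrations are
unidentifiable from relative MS intensities, so the global normalization
constant is deliberately dropped.

The optimizer is a $(\mu,\lambda)$ evolution strategy with stochastic
ranking, searched in $\log_{10}$ space (all constants are scale
parameters): log-uniform initialization, self-adaptive per-parameter
step sizes with intermediate recombination, bound repair by reflection,
truncation selection (with box bounds only, stochastic ranking reduces to
objective sorting), and best-ever elitism in the returned result.  Defaults
are population 20, at most 500 generations with early stopping when the
best objective improves by less than 10^-10^ over 50 generations — that
keeps the wild-type problem (18 free parameters) under a minute on one
core.  Failed simulations yield an infinite objective and the candidate is
rejected.  Every fit is deterministic given its seed.

Joint fits across experiments share one parameter vector; enzymes absent
from an experiment have their concentrations masked to zero in that
experiment's simulation regardless of the candidate value.

**Non-identifiability.** Repeating the wild-type fit from independent seeds
reproduces a characteristic phenomenon: the achieved misfits are all
essentially zero relative to the no-fit scale, while individual rate
constants scatter over several orders of magnitude.  With 18 free
parameters constrained by a handful of relative abundances this is
expected, and the test suite asserts it quantitatively (the relative
dispersion of a turnover constant across 20 restarts exceeds the relative
dispersion of the objectives — normalized by the misfit of an unprocessed
profile — by far more than tenfold).

## Synthetic profiles

The measured abundances behind the original experiments were published only
as figures, so the bundled observed profiles are synthetic stand-ins,
labelled as such.  `generate_scenario()` draws a ground-truth parameter set
log-uniformly within the estimation bounds, simulates the experiment's
network, and uses the TGN profile (optionally with truncated-Gaussian noise
on the percentage scale, renormalized to 100; default $\sigma = 0$ so that
recovery tests are exact).  Draws in which the root retains more than 99%
are rejected as uninformative and redrawn (up to 100 times).  Generation is
a pure function of (experiment, seed, noise level).
`four_experiment_suite()` builds the four jointly modeled cell lines
(CHO-WT, Slex on C3, Slex on exC1, A4GlcNAc on C1) from a single shared
truth with per-experiment enzyme masking.

What the generator emulates: profile sparsity (3–10 structures), closure
under the experiment's network, exact simulability.  What it does not
emulate: measurement noise structure of MS intensities, ionization bias
(the package's charge adjustment corrects that bias in *real* raw data:
intensities × 0.3 for singly and × 0.4 for doubly charged species, then
renormalization; charges above 2 are rejected because no factor is defined
for them), missed intermediates, or site-level heterogeneity of the protein
carrier.  Passing recovery tests therefore demonstrates correctness of the
machinery, not predictive accuracy on real profiles.

## Experiment bundle

`load_experiments()` returns the 25 transfection configurations.  The
transfected enzyme lists follow the published experiment table; the active
rule sets add the minimal endogenous ("required") rules that make every
structure of the bundled observed list reachable — the same construction
the original modeling used, computed here with `reachability_report()` and
frozen into the bundle.  A per-configuration test re-verifies reachability.

## Problem sizes and defaults used by the tests

The test-suite and acceptance computations use the wild-type network
(6 species, 7 reactions, 18 free parameters) for conservation (20 random
draws), recovery (population 20, up to 200 generations) and repeat-fit
dispersion (20 restarts at 40 generations each); these sizes were chosen as
the smallest that exercise every code path of the published study design —
the wild-type cell line is also the study's own minimal model.

## Known limitations

* The Appendix-level rule list of the original study is not public; the
  bundled 30-rule reconstruction matches all printed counts and pathway
  statements but individual sub-rule splits (in particular CHST4's four
  contexts, and whether CMP-NeuGc shares the NeuAc rules) are choices.
  NeuGc is reserved in the dialect and donor table but no bundled rule uses
  it, mirroring the absence of any printed NeuGc structure.
* Whether GCNT3 is active in any of the 25 experiments cannot be read from
  the published tables; the bundle never activates it, but its rules exist.
* Golgi pH effects, enzyme redistribution, recycling and hypoxia-driven
  donor changes are out of scope, as is the initiation step.
* The batch-vs-CSTR transport question is left open by design; both modes
  are provided.
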