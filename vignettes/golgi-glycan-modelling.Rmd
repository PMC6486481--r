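---
title: "Modelling Golgi N-glycan processing with golgisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Golgi N-glycan processing with golgisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgisim)
```

## The model

N-linked glycans leave the endoplasmic reticulum as a small set of
high-mannose species (Man8, Man9 and glucosylated Man9) and are remodelled
during passage through the Golgi stack by competing glycosidases and
glycosyltransferases.  `golgisim` models one glycan at a time as a rooted
tree of monosaccharide residues passing through an ordered sequence of
cisternae.  Within a cisterna, every enzyme rule that matches the current
structure defines a reaction instance with propensity

$$ r_i = k_{e(i),c} \cdot s_i, $$

where $k_{e,c}$ is the *effective rate* of enzyme $e$ in cisterna $c$
(min^-1^) and $s_i$ an optional substrate-specific scale factor.  The
effective rate is deliberately a composite of enzyme level,
nucleotide-sugar availability and intrinsic catalysis; only relative
values are meaningful, which is also why relative (percent) glycan
abundances suffice for fitting.  The simulation is the classic Gillespie
algorithm with a deadline: waiting times are exponential with mean $1/R$,
$R = \sum_i r_i$; reaction $i$ fires with probability $r_i/R$; and when
the clock would cross the cisterna residence time (default 10 min) the
glycan instead moves on, the overshooting step discarded.  The
within-cisterna clock restarts at each entry — the simplest reading of a
per-cisterna time limit; carrying residual time across cisternae would
only reshuffle a fraction of one waiting time per transit.

Three modelling assumptions are worth stating explicitly.  Enzyme
competition is implicit (all matching rules compete for the same glycan),
but glycans do not compete with each other for enzymes: each of the
10,000 default input glycans is processed independently.  Second, an
*oligomannose quench* pseudo-enzyme marks oligomannose structures as
permanently unprocessable; it lumps mannose-6-phosphate tagging of
lysosomal proteins with retrograde retrieval of ER residents, and is
fitted exactly like a real enzyme.  Third, the ER-exit mixture defaults
to 80% Man8, 15% Man9 and 5% Man9Glc: the 80% figure is the standard
input assumption, while the split of the remaining 20% is a package
choice (configurable) since no measured split is available.

## Glycan notation

Structures are written root-first in a linear notation: linkage codes
(`4.1`, `3.1`, `6.1`, `2.1`, `6.2`) join residues, brackets hold separate
branches, `_m`-style markers resume the chain outside a bracket group,
`:` ends a branch and `@` ends the glycan:

```{r}
man5 <- glycan_parse("GlcNAc4.1GlcNAc4.1Man(3.1Man:)_m6.1Man(3.1Man:)_m6.1Man:@")
man5
```

`Sia` is accepted as a synonym for NeuAc on input and used on output.
Serialization is canonical — the children of every residue are ordered by
(linkage code, canonical subtree string) — so structural isomers written
in any sibling order compare equal, and `parse(serialize(g))` is the
identity on canonical forms.  Compositions fold Man and Gal into `Hex`
the way mass spectrometry sees them, and fold the Glc of glucosylated
species into Hex as well (so Man9Glc is keyed `Hex10HexNAc2`), because a
hexose is a hexose at the spectrometer; internally Glc stays a separate
count so the endo-mannosidase rule can recognise its substrate.

## The default rule set

Published rule tables for this pathway are not redistributable, so the
package documents and ships its own mammalian set
(`default_mammalian_rules()`, mirrored exactly by
`inst/extdata/rules_default.yaml`): MAN1 trimming of terminal
$\alpha$1,2-mannoses; endo-mannosidase removal of the Glc-bearing
terminal unit (a single enzymatic event that removes the Glc–Man
disaccharide); MGAT1/2/4/5 antenna addition; MAN2 removal of the two
6-arm mannoses of hybrid structures; GalT galactosylation; SiaT
sialylation (6.2 linkage, one per antenna); FUT8 core fucosylation;
grouped antenna fucosyltransferases (`antFUT`, complex glycans only,
non-sialylated antennae only — the sialylation-versus-fucosylation
ordering is not settled, and this is the conservative default); and the
OM-quench pseudo-enzyme.  Antennae are capped at four: the modelled cell
lines show no penta-antennary species, and the cap is configurable.

Four scale factors modify effective rates in specific contexts: the slow
Man6-to-Man5 trimming step (0.2), slow FUT8 action on Man5 substrates
(0.1, which also lets core-fucosylated Man5 appear when MAN2 is
inhibited), reduced galactosylation of tri-/tetra-antennary glycans
(0.5) and a separate sialylation rate for 6-arm antennae (0.5).  The
branching transferases MGAT4/MGAT5 require their arm's 2.1-antenna to be
an unextended GlcNAc — the standard substrate requirement — which is what
lets galactosylation close the branching window and produces the
monotone GalT-titration behaviour checked in the tests.

Rule application is implemented as tree rewriting on canonical
structures.  Because additions are capped and removals only shrink, the
set of structures reachable from the ER inputs is finite (about 3,600
states under the full rule set); `compile_network()` closes it once and
the production simulator then runs on integer state ids in compiled
code, drawing per-glycan random substreams from `(seed, glycan index)`
so that results are bit-reproducible and independent of execution order.
A direct tree-level simulator (`simulate_glycan()`) provides the
reference path, and the test suite checks the two sample the same law.

## Fitting by rejection ABC

A simulated profile is compared with an observed one by

$$ \mathrm{score} = \sum_i \big(\mathrm{sem}_i - |obs_i - sim_i|\big)^2
   \quad\text{with zero contribution when } |obs_i - sim_i| < \mathrm{sem}_i, $$

summed over the union of composition keys (missing entries count as
zero abundance; observed entries without an SEM receive
$\max(0.1, 0.05\,obs_i)$ percent by default).  A profile inside the SEM
band everywhere scores exactly zero.

`golgi_abc()` draws parameter sets from the priors, simulates, and
accepts draws scoring at or below the current threshold.  Priors follow
the localization layout: a log-normal where an enzyme predominantly
resides (80% of its total rate by default) and an exponential-decay
prior elsewhere.  The initial threshold is the median score of a
200-proposal pilot (the paper-style schedule needs *some* starting
point; a pilot quantile makes it scale-free).  The threshold then shrinks
by 10% whenever the acceptance rate over a sliding window of the last
1,000 proposal scores — re-evaluated under the current threshold —
exceeds 7%, until it reaches the final threshold (by default the pilot's
10% quantile), after which sampling continues at that fixed threshold
until the target number of acceptances.  Only fixed-phase acceptances
form the posterior; shrink-phase acceptances are logged.  Chains are
independent with disjoint seed ranges, so merging order is irrelevant.

Convergence is monitored with the Gelman-Rubin statistic
(`gelman_rubin()`), and `prior_shift_test()` runs the Mann-Whitney
rank-sum comparison of prior versus posterior per parameter.
Re-centring a flagged prior on its posterior (`recenter_priors()`:
meanlog to the posterior log-mean for log-normals, rate to the
reciprocal posterior mean for exponentials) is an explicit user step
between runs, never automatic — silent prior drift inside a run would
make the posterior uninterpretable.

## The synthetic generator

`make_scenario()` provides ground-truth models whose regimes mirror the
study conditions: a 3-cisterna oligomannose-dominated model (>90%
oligomannose output), a 4-cisterna complex-rich model, its MAN2-null
(mannosidase-II-inhibited) and Cog4-knockout-like perturbations, and a
reduced 3-cisterna/5-enzyme model for parameter-recovery studies whose
true rates follow the same 80%-in-home-cisterna layout the priors
encode.  The preset rates are package choices, frozen as regression
targets; `synth_observed()` simulates triplicate profiles at the truth
and reports per-key mean and SEM.  Replicate noise is purely the
SSA's finite-sample noise — no measurement-noise model is layered on
top — so passing recovery tests demonstrates that the inference
machinery works when the model is correctly specified, not that it is
robust to mass-spectrometric artifacts (permethylation efficiency,
ionization bias, isotope overlap), which are out of scope.

## Numerical choices and problem sizes

Profiles collate structural isoforms by composition key, convert counts
to percentages and drop entries below 0.1%; the filtered mass is not
renormalized (toggleable), so a profile's total reports what survived
the filter.  Tie-breaks are everywhere deterministic: canonical sibling
order in trees, radix-sorted keys in profiles and flux maps, substrate
key as the tie-break in flux rankings.  Condition-versus-control flux
ratios divide the per-edge ratio by the normalizing enzyme's total-flux
ratio; the multiplied variant is available behind a flag because both
conventions appear in the literature, but the divided form is what makes
"ratio > 1 means preference in the condition" read correctly.

The test suite runs its heavy checks at deliberately reduced sizes
chosen to keep Monte-Carlo error well below the asserted effects:
SSA-law checks at 10,000 draws (3-sigma bands), mechanistic limits at
10,000 glycans, and parameter recovery as 10 repeats of a
3-cisterna/5-enzyme fit at 2,000 glycans per proposal and 500 accepted
draws over 4 chains.  Production fits would use the defaults (10,000
glycans, 10,000 acceptances).

## Known limitations

The rule set is a documented reconstruction, not a transcription of any
published supplementary table; hybrid-glycan substrate specificities in
particular are simplified.  Cisternal transport is a fixed-residence
conveyor — no maturation-versus-vesicular-transport distinction, no
glycan-glycan competition, no nucleotide-sugar depletion.  The ABC
scheme is plain rejection with an adaptive threshold; SMC or MCMC
kernels would be more sample-efficient in high dimensions but are
intentionally out of scope.  Off-home (exponential-prior) rate
parameters are only weakly identified at small simulation sizes; their
posteriors legitimately resemble their priors, which is why the
recovery tests assert contraction for the home-cisterna parameters.
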