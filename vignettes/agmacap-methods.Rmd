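---
title: "Predicting microbial agmatine production capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbial agmatine production capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agmacap)
```

## The scientific problem

Agmatine, the decarboxylation product of arginine, is a bacterial effector
metabolite: its production by gut bacteria links drug exposure (notably the
antidiabetic biguanide metformin) and dietary context to host lipid
metabolism and lifespan. `agmacap` implements the in-silico side of that
analysis: given genome-scale metabolic models of gut bacterial strains, a
participant's taxon relative abundances, and a participant-specific diet, it
predicts how much agmatine the whole community can export per gram of
microbiota per day, attributes that production to species, quantifies
metabolic side products, and screens nutrients for their effect on the
prediction. It also implements the statistics of the companion four-way
host-microbe-drug-nutrient plate screen.

All community fluxes are expressed in mmol per gram microbiota per day
(mmol/gM/d): dietary intake is normalised by an assumed 200 g of colonic
microbial biomass, so a flux of 1 means one millimole available to (or
produced by) the community per gram of gut bacteria per day.

## Flux balance analysis with a total-flux penalty

A metabolic model is a stoichiometric matrix $S$ (metabolites x reactions)
with flux bounds $l \le v \le u$. Flux balance analysis (FBA) maximises one
reaction's flux subject to steady state, $S v = 0$, and the bounds. The
production capacity objective adds a small penalty on the total absolute
flux:

$$\max_v \; v_{\text{target}} - \varepsilon \sum_j |v_j|, \qquad
\varepsilon = 10^{-6},$$

which, among the usually degenerate alternate optima, selects a
parsimonious flux distribution and suppresses thermodynamically meaningless
flux loops. The absolute values are linearised by splitting every flux into
two non-negative directional variables ($v = v^+ - v^-$); because both
directions are penalised, $v^+ v^- = 0$ holds at any optimum and
$\sum (v^+ + v^-) = \sum |v|$ without any complementarity constraint. The
reported `primary_objective` is the target flux itself, not the penalised
objective value; by objective algebra it differs from the unpenalised
optimum by at most $\varepsilon \sum_j |v_j|$.

The LP itself is solved by a dense two-phase primal simplex implemented in
compiled code in this package. Determinism matters more than raw speed
here: variables are kept in a fixed (id-sorted) order, the entering
variable is the most negative reduced cost with smallest-index tie-break,
and the solver falls back to Bland's rule after an iteration budget so it
cannot cycle. Constraint rows are equilibrated (scaled by their largest
coefficient) before solving, so extreme coupling factors do not defeat the
fixed pivot tolerances (feasibility $10^{-9}$, optimality $10^{-7}$).
Only the objective value is contractual: individual fluxes of degenerate
alternate optima are not. Infinite bounds are boxed at $\pm 10^6$ and a
solution pinned to that artificial box is reported as unbounded, naming the
offending reaction.

Sign conventions follow the gut-reconstruction ecosystem: an exchange
reaction touches exactly one metabolite with coefficient $-1$, negative
flux is uptake, positive flux is secretion, and unannotated reactions
default to bounds $[-1000, 1000]$ (irreversible: $[0, 1000]$).

## Homology-driven model refinement

Published strain reconstructions typically lack agmatine transport. The
refinement module adds it from homology evidence in BLAST tabular form:

* a reversible agmatine transporter (`AGMT`, cytosol <-> exterior) for every
  strain with a transporter-query hit of bitscore strictly above 50 and
  query coverage of at least 75%;
* an extracellular arginine decarboxylase (`ARGDC_EXT`), copying the
  cytosolic `ARGDC` stoichiometry into the extracellular compartment, for
  strains with a cell-wall decarboxylase (speA-type) hit of bitscore
  strictly above 200 — this enzyme faces the cell exterior, so its reaction
  belongs there;
* an irreversible agmatine outflow for every strain that received either
  feature.

The threshold readings deserve a note: "above 50" and the "cut-off of 200"
are implemented strictly ($>$), while the coverage threshold is inclusive
($\ge 75$), and all three are arguments. Refinement is idempotent, never
removes reactions or alters existing bounds, and its report aggregates
strain flags to species counts. Two screens follow: strains must reach a
maximal biomass flux of at least 0.01 mmol/gM/d on the diet (inclusive
cutoff) to stay in the analysis, and a strain is a producer when its
maximal agmatine outflow exceeds $10^{-9}$. Both denominators (all strains,
and growth-passing strains) are reported, since producer counts are
meaningful relative to either.

## Participant diets from food-frequency records

The diet builder converts grams-per-day food records into exchange fluxes:

1. **Map and convert** — recorded compounds are mapped to exchange
   identifiers and converted by
   $(\text{g/day} / \text{MW}) \cdot 1000 / 200$ into mmol/gM/d. A mapped
   compound without a molecular weight is a hard error: silently dropping
   it would bias the community's nitrogen supply.
2. **Augment nucleotides** — food tables report purines only. Per food
   item, adenosine-class and guanosine-class contents (mmol per gram food)
   are summed over the record; missing items are imputed with the average
   of the nearest populated level of their food-group hierarchy. Pyrimidine
   contents are extrapolated by the identities: thymidine + uracil equals
   the adenosine-class total (split 50/50 by default, configurable, since
   only the combined identity is constrained) and cytosine equals the
   guanosine-class total.
3. **Augment polyamines** — measured cadaverine, putrescine, spermidine and
   spermine contents are added per item; ornithine, poorly covered by food
   tables, is taken as measured where available and otherwise extrapolated
   as 3.28 (the median ornithine-to-polyamine ratio among fully measured
   foods) times the item's total polyamine content.
4. **Caloric normalisation** — all amounts are scaled to a common caloric
   value (default 8799 kJ, a cohort median), making diets comparable.
5. **Reference blending** — 90% of the recorded diet plus 10% of a
   reference ("Western") diet, so compounds that the record does not cover
   are never entirely absent; growth-limiting minerals (phosphate, copper,
   manganese, zinc, iron(3+), chloride) retain the reference value
   unchanged. The split and the retained list are configuration.
6. **Absorption adjustment** (optional) — each compound is reduced by the
   fraction absorbed in the small intestine before reaching the colonic
   community.

Pipeline order is augmentation, then caloric normalisation, then blending:
the derivation naturally runs in that order, and since every step is
linear, reordering the two scalings would change absolute fluxes but not
capacity ratios. The division by 200 g is applied at the mass-to-mole step;
the provenance log attached to every built diet records each step's totals
so any reordering would be auditable. Augmented trace compounds are treated
as calorically negligible and do not enter the caloric value.

## Community models

For each participant the strain abundances (normalised to sum to one) pass
a presence cutoff — 0.1% for 16S amplicon profiles, 0.01% for metagenomes,
reflecting their different read depths — and the surviving fractions are
renormalised so they can serve as biomass coefficients. Member models are
tagged with their strain id and joined through a shared lumen compartment
`"u"`: every member boundary reaction becomes a transport between the
member and the lumen (exchanges reversible; an irreversible outflow keeps
its orientation), and fresh community exchanges `EX_<compound>_u` connect
the lumen to the environment, where the diet is applied. Each member's own
biomass outflow is blocked at $[0, 0]$ and a community biomass reaction
consumes member biomass in exact proportion to the observed fractions
$f_k$, so the optimisation cannot silently re-weight the community. The
community biomass outflow is bounded to $[0.4, 1.0]$ per day by default —
roughly one gut turnover per day, a convention of the community-modeling
literature; the source analyses do not state their value, so it is a
configurable argument and a sensitivity knob rather than a constant.

Coupling constraints tie each member reaction's flux to that member's
biomass production, $|v_j| \le c \cdot v_{\text{biomass},k} + u$, with
defaults $c = 400$ and $u = 0.01$ taken from the community-modeling
literature the pipeline builds on (again configurable, for the same
reason). They prevent "ghost" members: with biomass forced to zero, a
member's entire flux range collapses to $\pm u$.

## Capacity, attribution, side products, supplementation

The production capacity is the penalised-FBA optimum of the community
agmatine exchange. Species contributions are the members' net transport
fluxes of agmatine into the lumen, summed per species; lumen mass balance
makes them sum exactly to the capacity, which the tests assert to
$10^{-6}$ on random communities. Side products are community-level
secretions at the same optimum, expressed in moles per mole of agmatine;
because they are read from the penalised optimum they inherit its
alternate-optima caveat, which is why only stoichiometrically forced yields
(such as the 1:1 CO2 of the decarboxylase route) are asserted exactly.

Supplementation screens relax one compound's community uptake bound by a
fixed additional amount (1 mmol/gM/d for communities; +5 mmol/L for the
single-organism growth-medium screen) and report the capacity ratio
against baseline. Relaxing a constraint can never decrease an LP maximum,
so ratios are bounded below by 1 — asserted across randomized screens — and
a baseline of zero yields a missing ratio rather than an infinity. Group
differences in capacity are tested with two-sided Wilcoxon rank-sum tests
over all group pairs with Benjamini-Hochberg adjustment; `wilcox.test`
enumerates exactly for small untied samples and uses the tie-corrected
normal approximation otherwise.

## Four-way screen statistics

Bacterial growth is summarised as the log2 of the trapezoidal area under
the OD curve on the observed time grid (no smoothing); worm reporter
expression as the 90th percentile (Q90) of the log2 per-worm intensity
distribution, a robust maximum for strongly non-normal segmented-reporter
intensities. The quantile uses linear interpolation between order
statistics — the common default, configurable because no specific
definition is mandated. Each nutrient's drug interaction is estimated from
the 2x2 design (base medium and nutrient, with and without drug, base
wells shared across nutrients). By default one saturated cell-means model
is fitted to the whole plate, so contrasts are tested against a
plate-pooled residual variance — the screen fits a single linear model and
performs multiple univariate tests — with a per-nutrient 16-well `lm()`
fit available as an option; the two give identical estimates and differ
only in error degrees of freedom. Interaction p-values are BH-adjusted
across nutrients; a significant positive interaction (nutrient suppresses
the drug effect) is called antagonistic, a negative one synergistic.
Metabolite-class enrichment among hits uses the upper-tail hypergeometric
test with BH adjustment, and the association between predicted capacity
ratios and measured screen readouts is an ordinary least-squares fit.

## What the synthetic data emulate — and what they do not

Every input has a generator, so the full pipeline runs without any
external resource:

* **Toy strain models** share a sugar-to-biomass core; producers add
  arginine uptake, a cytosolic decarboxylase and (after refinement)
  agmatine transport and outflow. Strains are paired into species. The
  template diet is arginine-replete, so community production is limited by
  the coupling to member biomass — i.e. by producer abundance — keeping
  per-participant capacities continuous rather than piling up at a diet
  bound (mass ties at a saturation point would degrade the rank-sum
  test's finite-sample behaviour).
* **Cohorts** are Dirichlet-distributed compositions (normalised gamma
  draws; concentrations 0.4 for producers, 1.6 for others across 8
  strains), with producer concentrations multiplied by the effect size
  (default 3) in the treated group and 30 participants per group — the
  planted analogue of a metformin-associated producer enrichment.
* **Food records** cover a two-level group hierarchy with deliberately
  missing purine/polyamine entries to exercise imputation and the
  ornithine factor.
* **Screen data** are either direct log2 responses on the 2x2 design
  (337 nutrients, 4 replicates, noise sigma 0.2, planted +1 log2
  interactions on 30 nutrients) or raw logistic growth curves
  $K/(1+e^{-r(t-t_0)})$ plus noise and log-normal per-worm intensities,
  with drug, nutrient and interaction effects acting on $\log_2 K$ and on
  the intensity location.
* A **nitrogen-gated family** synthesises agmatine from four ammonium
  units; supplement compounds release 1-4 ammonium (or only carbon), so
  capacity gains form discrete steps ordered by transferable nitrogen — the
  qualitative signature that separates nitrogen sources from sugars.

Every generator draws from a substream seed derived from one master seed
and a fixed label through an avalanche (murmur-style) integer mix, so
adding a generator never shifts the others and nearby master seeds give
effectively independent replicates — a plain lattice of seeds measurably
correlates replicate outcomes in the tail.

Fidelity is structural, not biochemical: real reconstructions have
thousands of reactions, cross-feeding is pervasive rather than designed,
abundance data carry compositional noise and read-mapping error, and real
diets are far richer than the toy compound set. Passing tests therefore
demonstrate that the machinery — parsing, refinement rules, community
assembly, the penalised LP, the statistics — behaves correctly under
controlled conditions; they are not evidence about any real cohort.

## Numerical and design choices

* LP tolerances: feasibility $10^{-9}$, optimality $10^{-7}$; steady state
  asserted to $10^{-6}$ per metabolite.
* Penalty handling guarantees $|{\rm primary} - {\rm plain}| <
  \varepsilon \sum|v|$; the suite checks $\varepsilon \in \{10^{-6},
  10^{-8}\}$.
* Ties at refinement thresholds: strictly above for both bitscore cutoffs,
  inclusive for coverage and the biomass cutoff (a boundary strain grows).
* Degenerate inputs: empty diets close all uptake; a diet compound without
  an exchange is recorded, not fatal; an abundance profile with nothing
  above the cutoff is an error (there is no community to build); a
  zero-capacity baseline makes supplementation ratios missing.
* Simulation sizes in the shipped tests — 50 oracle networks, 20
  conservation communities, 200 supplementation triples, 100-seed
  detection/null/power studies — were chosen to estimate each rate with a
  standard error of a few percent while the whole suite stays comfortably
  re-runnable on a laptop.

## Known limitations

* Alternate optima: only objective values are reproducible across LP
  implementations; flux-level quantities (species attribution, side
  products) are reported from the penalised optimum and can differ at
  degenerate vertices.
* The dense simplex targets the package's model sizes (hundreds of
  reactions); genome-scale community models of thousands of reactions
  would need a sparse industrial solver behind the same interface.
* The coupling constants and community biomass bounds are literature
  conventions, not fitted quantities; capacities should be read relative
  to a fixed configuration, and both knobs are exposed for sensitivity
  analysis.
* The screen's interaction models are fixed-effects; a random-effect per
  replicate (plate batch) is the natural extension and is deliberately out
  of scope here.
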