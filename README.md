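# agmacap

Constraint-based prediction of the **agmatine production capacity** of gut
microbial communities, and the statistics of a four-way
host–microbe–drug–nutrient screen.

Agmatine — decarboxylated arginine — is a bacterial effector metabolite
linking drug exposure (notably metformin) and diet to host lipid metabolism
and lifespan. Given genome-scale metabolic models of gut bacterial strains,
a participant's taxon relative abundances, and a participant-specific diet,
`agmacap` predicts how much agmatine the whole community can export,
attributes production to species, quantifies side products, and screens
nutrients for their effect on the prediction. A synthetic-data module
generates every input the pipeline consumes, so the complete analysis runs
and is tested without any external data resource.

## The model

A strain model is a stoichiometric matrix *S* with flux bounds; community
models join member strains through a shared lumen compartment, block each
member's own biomass outflow, and add a community biomass reaction that
consumes member biomass in the observed relative proportions *f_k*.
Coupling constraints |v_j| ≤ c·v_biomass,k + u (defaults c = 400,
u = 0.01) silence members that do not grow. Capacity is the optimum of

    max  v_agmatine_outflow − ε·Σ_j |v_j|,   ε = 10⁻⁶,

subject to S·v = 0, the diet-constrained exchange bounds, and the coupling
constraints — flux balance analysis with a small total-flux penalty that
picks a parsimonious optimum. All community fluxes are in mmol per gram
microbiota per day (mmol/gM/d; dietary intake normalised by 200 g of gut
microbiota). The LP is solved by a deterministic dense two-phase simplex
implemented in the package.

Around that core the package implements homology-driven model refinement
(agmatine transporters at bitscore > 50 and coverage ≥ 75%, extracellular
arginine decarboxylase at bitscore > 200, outflows for refined strains,
growth screen at 0.01 mmol/gM/d), the food-frequency-to-diet pipeline
(mass→mole conversion, purine/pyrimidine and polyamine augmentation with
the 3.28 ornithine factor, caloric normalisation to 8799 kJ, 90/10
reference blending with retained minerals, absorption adjustment), and the
plate-screen statistics (log₂ growth AUC, Q90 fluorescence, drug×nutrient
interaction linear models with BH-adjusted antagonism/synergy calls,
hypergeometric class enrichment).

## Worked example

```r
library(agmacap)

cfg <- sim_config(seed = 1)          # 8 strains, 30 participants/group,
                                     # 3x producer enrichment when treated
res <- run_cohort_pipeline(cfg)      # refine -> communities -> capacities
res$comparison
#>    group1    group2 n1 n2  median1  median2 statistic            p          fdr
#> 1 control metformin 30 30 69.93514 168.9245       144 1.875028e-06 1.875028e-06
```

The pipeline refines raw strain models from generated homology evidence,
assembles a diet-constrained coupled community per synthetic participant,
predicts each community's agmatine capacity (here medians of 70 vs 169
mmol/gM/d), and the planted treated-group producer enrichment is detected
by the Wilcoxon rank-sum test (p = 1.9e-06).

Single-community analysis:

```r
xf <- make_cross_feeding_pair()      # feeder secretes arginine, converter
comm <- assemble_participant(xf$models, xf$profile, xf$diet)
pc <- predict_capacity(comm)
pc$capacity                          # 9.6 mmol/gM/d: neither strain alone
                                     #   produces any agmatine
species_contributions(pc)            # all of it from the converter species
#> Toyobacter converter    Toyobacter feeder
#>                  9.6                  0.0
side_product_yields(pc)              # CO2 stoichiometrically coupled 1:1
#> co2
#>   1
```

Nutrient screens on a single organism (growth-medium scale, +5 mmol/L):

```r
nt <- make_nitrogen_toy()
op50_supplement_screen(nt$model, nt$ngm_diet, nt$compounds$compound)
#>   compound baseline_capacity supplemented_capacity ratio
#> 1    pep1n               0.5                  1.75   3.5
#> 2    pep2n               0.5                  3.00   6.0
#> 3    pep3n               0.5                  4.25   8.5
#> 4    pep4n               0.5                  5.50  11.0
#> 5   sugar1               0.5                  0.50   1.0
```

Capacity gains form discrete steps ordered by the nitrogen atoms each
compound donates; the sugar leaves capacity unchanged — nitrogen, not
carbon, gates agmatine synthesis.

## Documentation

The methods vignette (`vignettes/agmacap-methods.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, what
the synthetic generators do and do not emulate, numerical choices, and
known limitations.
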