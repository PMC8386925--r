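# aadiet — amino-acid compound-specific isotope dietary reconstruction

`aadiet` reconstructs individual human diets from the stable carbon and
nitrogen isotope values of bone-collagen amino acids. It is written for
archaeological scientists and isotope ecologists who have (or want to
prototype against) compound-specific GC-C-IRMS data and need quantitative,
per-individual diet estimates with honest uncertainties rather than
qualitative bulk-isotope scatterplots.

The package covers the whole chain:

* **GC-C-IRMS reduction** — norleucine normalisation, nitrogen calibration
  curves, correction of derivative carbon by isotope mass balance
  (`n_DC δ13C_DC = n_C δ13C_C + n_D δ13C_D`), and full error propagation;
* **cereal prediction** — per-amino-acid values for charred archaeological
  grains from bulk values via modern-grain AA-minus-bulk offsets with
  charring correction;
* **mixing models** — concentration-dependent Bayesian mixing with
  metabolic routing. For diet fractions `f` on the simplex, each signal
  `s` mixes source values `v_si` with weights
  `w_si = f_i q_si / Σ_j f_j q_sj` (`q_si` = carrier concentration), giving
  a Gaussian likelihood around `μ_s = Σ_i w_si v_si + o_s`. A flat
  Dirichlet prior, analytically marginalised Gaussian source values and
  offsets, and a component-wise random-walk Metropolis-Hastings sampler on
  logit-simplex coordinates (5000 burn-in + 10000 retained) complete the
  model. Four structures are provided: bulk protein-routed (`model0p`),
  bulk whole-diet (`model0wd`), source amino acids (`model1`, shares of
  dietary protein), and whole diet with trophic amino acids (`model2`,
  shares of dry weight), plus an optional lipid-only olive-oil source;
* **cohort statistics** — two-sided Wilcoxon rank-sum contrasts of
  per-individual posterior medians by sex;
* **synthetic data** — seeded generators for sources, consumers, raw GC
  sessions and grain sets, so every stage runs and is tested without any
  measured input.

See `vignettes/dietary-reconstruction.Rmd` for the models, routing
classes, defaults and limitations.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study
(seed 1: 17 consumers, 11 male / 6 female, three food groups) and write
their tables under `results/study/`:

```sh
Rscript analysis/01_simulate.R        # sources, cohort, GC session, grains
Rscript analysis/02_reduce_gc.R       # raw peaks -> corrected AA table
Rscript analysis/03_predict_cereals.R # offsets -> archaeological AA values
Rscript analysis/04_fit_models.R      # models 1 & 2 per individual + oil
Rscript analysis/05_cohort_report.R   # sex contrasts + figure
```

Stage 4 prints, for this seed:

```
Model 1: 95% CI coverage 100%, mean |median-truth| 7.5 pp
Model 2: 95% CI coverage 100%, mean |median-truth| 7.6 pp
Cross-check: 68% intervals overlap in 51 of 51 cells
model0p (bulk, cohort average): mean 68% interval width 0.37
model0wd (bulk, cohort average): mean 68% interval width 0.41
model1 (AA, cohort average widths): 0.34
Olive oil permitted: median 10% (68% CI 3-24%)
```

that is: the true per-individual diet fractions sit inside the 95%
credible intervals throughout, posterior medians land within ~8
percentage points of truth on average, the whole-diet model's implied
protein shares agree with the protein model for every individual and
source, and the bulk-isotope baselines deliver systematically wider
intervals than the amino-acid model. Stage 5 then contrasts the sexes on
the model-1 medians (fractions of dietary protein):

```
               source mean_male mean_female ratio_male_female p_value
1             cereals     0.328       0.467             0.702  0.0145
2 terrestrial_animals     0.387       0.327             1.182  0.2561
3         marine_fish     0.280       0.194             1.443  0.0616
```

The generator draws male diets with 1.6× the female marine-protein share;
with n = 17 and realistic measurement noise a single cohort recovers a
ratio of 1.44 with borderline significance — which is exactly why the
package's calibration checks average over 100 seeded cohorts rather than
trusting one.

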