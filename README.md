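# brillquant

Quantitative analysis of confocal Brillouin microscopy maps of
cartilaginous tissue, for researchers studying tissue mechanics during
development, regeneration or enzymatic perturbation — in particular maps
of the cartilaginous digit skeleton of juvenile axolotls, where the
collagen-rich extracellular matrix (ECM), embedded chondrocytes,
interstitial space and epidermis can all be resolved mechanically.

## The science in brief

A Brillouin microscope measures, per pixel, the frequency shift ν_B of
light scattered off thermally excited acoustic phonons. The shift relates
to the longitudinal storage modulus M′ of the material:

    ν_B = (2n/λ0) · sqrt(M′/ρ) · sin(θ/2)

(n refractive index, ρ density, λ0 = 780.24 nm, θ = 180° backscattering).
The longitudinal compressibility is κ_L = 1/M′, and for isotropic samples
M′ = K′ + 4/3·G′. Since n and ρ are rarely known per pixel, maps are
analysed on the dimensionless **Brillouin elastic contrast**

    ν̄_B = ν_B / ν_B^water − 1,     ν_B^water = 5.066 GHz,

which is instrument-independent and needs no material constants.

The package provides:

* **physics** — conversions shift ↔ contrast ↔ modulus/compressibility;
* **mapio** — CSV readers/writers for shift maps, label masks and cohort
  tables (bit-exact round trips), plus deterministic heat-map PNGs;
* **quantify** — ROI means, per-cell vs ECM mask means, five-line
  averaged transversal profiles with size normalization (edges at the
  0.006 contrast of the surrounding medium mapped to ±100 %), and
  day-0-normalized digit-length ratios;
* **stats** — the small-sample nonparametric suite: Friedman + Kendall's
  W, Kruskal–Wallis (+ tie correction) + rank η², exact enumerated
  Mann–Whitney with continuity-corrected Z and effect size r, Dunn's
  Bonferroni post hoc tests, pooled-variance t-test, and a Chen–Shapiro
  normality screen with Monte-Carlo critical values;
* **phantoms** — a synthetic digit-phantom generator (known label ground
  truth, Gaussian pixel noise, per-animal random effects) emulating three
  experiments: collagenase digestion (0/30/45 min), digit development
  (stages 45–53) and digit regeneration (0/15/30 dpa);
* **experiments** — end-to-end orchestration
  (generate → quantify → test → report) with full determinism: identical
  seeds give byte-identical report trees.

## Worked example

Render a mature-digit phantom, quantify cells against ECM, then run the
collagenase experiment end to end:

```r
library(brillquant)

ph <- render_digit_phantom(mature_digit_spec(seed = 42))
cm <- to_contrast_map(ph$map)
mm <- mask_means(cm, ph$mask)
sprintf("ECM mean %.4f over %d px; %d cells, grand mean %.4f",
        mm$ecm_mean, mm$ecm_n, nrow(mm$cells), mean(mm$cells$mean))
#> "ECM mean 0.0598 over 1368 px; 13 cells, grand mean 0.0451"

b <- run_experiment("collagenase", seed = 42,
                    config = list(render_png = FALSE))
cohort_to_matrix(b$cohort)
#>          0min      30min      45min
#> A1 0.04324090 0.03858221 0.03448270
#> A2 0.04646467 0.04179226 0.03767012
#> A3 0.04294653 0.03838614 0.03394025
#> A4 0.04312410 0.03852197 0.03429006
#> A5 0.04489215 0.04037059 0.03608016

b$tests$friedman
#>       Friedman rank ANOVA for repeated measures
#>
#> chi-squared = 10, df = 2, p = 0.0067379
#> effect size Kendall's W = 1
#> post hoc (Dunn, Bonferroni):
#>  pair_i pair_j      z         p p_adjusted
#>    0min  30min 1.5811 0.1138463  0.3415389
#>    0min  45min 3.1623 0.0015654  0.0046962
#>   30min  45min 1.5811 0.1138463  0.3415389
```

Reading the output: the ECM is stiffer (higher contrast) than the
chondrocytes it embeds, as expected for mature cartilage. Every phantom
animal's whole-map contrast decreases strictly with digestion time, so
the Friedman test reaches complete concordance — χ² = 10 at N_A = 5,
k = 3, p = e^(−5) = 0.0067, Kendall's W = 1 — and Dunn's post hoc flags
only the 0 min vs 45 min pair (adjusted p = 0.0047).

The same pipeline is scriptable headlessly:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","brillquant.R",package="brillquant"))')" \
    run --experiment regeneration --seed 1 --outdir report/
```

which writes `maps/` (CSV + PNG + label masks), `cohorts/`, `stats/`
(JSON test results) and a deterministic `log.txt`.

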