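---
title: "Methods: quantifying Brillouin microscopy maps of cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Brillouin microscopy maps of cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brillquant)
```

## The measurement and its physics

Confocal Brillouin microscopy probes tissue mechanics optically: incident
photons scatter inelastically off thermally excited acoustic phonons, and
the resulting frequency shift $\nu_B$ of the scattered light reports on
the hypersonic sound velocity, hence on the longitudinal storage modulus
$M'$ of the sample:

$$\nu_B = \frac{2 n}{\lambda_0} \sqrt{\frac{M'}{\rho}} \sin(\theta/2),$$

with refractive index $n$, mass density $\rho$, incident wavelength
$\lambda_0$ and scattering angle $\theta$. In backscattering
($\theta = 180^\circ$, the package default) $\sin(\theta/2) = 1$. The
longitudinal compressibility is the reciprocal modulus,
$\kappa_L = 1/M'$, and for an isotropic sample
$M' = K' + \tfrac{4}{3} G'$ relates $M'$ to the bulk modulus $K'$ and
shear modulus $G'$.

Because $n$ and $\rho$ are rarely known per pixel — and their influence on
shift changes is negligible for low-lipid tissue — maps are analysed on
the dimensionless **Brillouin elastic contrast**

$$\bar\nu_B = \frac{\nu_B}{\nu_B^{water}} - 1, \qquad
  \nu_B^{water} = 5.066\ \mathrm{GHz},$$

which removes the wavelength dependence and needs no material constants.
`shift_to_contrast()` and `contrast_to_shift()` implement this pair;
`shift_to_longitudinal_modulus()`, `modulus_to_shift()`,
`longitudinal_to_compressibility()` and `bulk_from_longitudinal()` provide
the full conversions for users who do supply $n$ and $\rho$. The package
deliberately ships **no tissue defaults** for $n$ or $\rho$: they are not
established for axolotl cartilage, so the modulus operations are pure
conversions. Linewidth-based viscosity analysis is out of scope.

Units are held as reported throughout — shifts in GHz, wavelengths in nm,
lengths in µm, moduli in Pa — with the single GHz·nm → m/s collapse done
inside the modulus conversion (the $10^9 \times 10^{-9}$ prefactors cancel
exactly, which the tests exploit as a unit-tracking oracle).

## Grid conventions and file formats

A map is a rectangular grid of square pixels. Matrix rows index $y$
(downward), columns $x$ (rightward); coordinates are pixel centres in µm
with the origin at the top-left pixel centre. The original evaluation
software exports per-pixel values as CSV, so the on-disk formats here are
long-format CSVs (`x_um,y_um,shift_GHz`; masks add `label,cell_id`;
cohorts are `animal_id,condition,value`). Numbers are serialized at
`%.17g`, making write→read round trips bit-exact — an invariant the test
suite asserts. Readers validate completeness (every lattice point present
exactly once, uniform square pitch) and report the offending data row on
failure. Heat maps are rendered with a fixed viridis ramp and clamped
colour limits; rendering is byte-deterministic, which the end-to-end
determinism tests rely on.

## Spatial quantification

* **ROI means** (`roi_mean()`): pixel membership is by pixel-centre
  inclusion in a half-open rectangle $[x, x+w) \times [y, y+h)$. The
  convention is declared rather than inferred (the source material never
  fixes one); half-open membership makes tiled ROIs partition the map, and
  a full-map ROI provably equals the grid mean.
* **Cell vs ECM** (`mask_means()`): one mean per chondrocyte (`cell_id`)
  and one over all ECM pixels, with counts; label classes absent from a
  mask are flagged absent, never silently reported as 0.
* **Transversal profiles** (`transversal_profiles()`): five parallel lines
  of nominal 1 µm width separated by 5 µm, averaged position-wise into one
  profile per map. On the instrument's 2–5 µm grids a 1 µm line is
  sub-pixel, so each line is realized as a single pixel column and the
  spacing is rounded to a whole-pixel offset; the realized spacing is
  recorded on the result so nothing is silently approximated.
* **Size normalization** (`normalize_profile()`): structure edges are the
  outermost profile positions with contrast at or above 0.006 — the
  contrast of the surrounding benzocaine bath — the centre maps to 0 and
  the edges to ±100 %. No interpolation or smoothing is applied, and
  interior sub-threshold dips do not move the edges (outermost-crossing
  semantics; the alternative — treating any dip as an edge — would make
  the normalization unstable under single-pixel noise). The operation is
  idempotent and translation-invariant, both property-tested.
* **Digit lengths** (`digit_length_ratio()`): each digit is normalized to
  its own day-0 length, so regrowth and contralateral growth share a
  scale.

## The statistics suite

All tests operate on midranks and return a uniform result object
(statistic, df, p, effect size, post hoc pairs) serializable as JSON.

| test | statistic | p-value | effect size |
|---|---|---|---|
| `friedman_rank_test()` | $\chi^2 = \frac{12}{Nk(k+1)}\sum_j R_j^2 - 3N(k+1)$ | $\chi^2_{k-1}$ upper tail | Kendall's $W = \chi^2 / (N_A(k-1))$ |
| `kruskal_wallis_test()` | $H$ with tie-correction divisor $1-\sum(t^3-t)/(N^3-N)$ | $\chi^2_{k-1}$ upper tail | $\eta^2 = (H-k+1)/(N-k)$ |
| `mann_whitney_exact()` | $U = \min(U_x, U_y)$ | exact enumeration ($N \le 20$) | $r = |Z|/\sqrt{N}$ |
| `students_t_two_sample()` | pooled-variance $t$ | $t_{n_x+n_y-2}$ | — |

Numerical choices that matter, all pinned by tests:

* **Chi-squared approximation, not exact permutation tables**, for
  Friedman and Kruskal–Wallis p-values: at these designs the upper-tail
  chi-square is the convention of the original analyses (e.g.
  $p = e^{-10/2} = 0.00674$ at $\chi^2_2 = 10$), and
  `chisq_upper_tail(x, 2)` equals $e^{-x/2}$ exactly, which the suite
  uses as a closed-form cross-check. The cost is conservatism at small
  $N$: under a simulated null at $N_A = 5, k = 3$ the realized type-I
  error at nominal 5 % sits near 4 % (property-tested band 2–6 %).
* **Mann–Whitney Z with a 0.5 continuity correction toward the mean**:
  $(U - n_xn_y/2 \pm 0.5)/\sqrt{n_xn_y(N+1)/12}$, giving
  $Z = -2.16506$ for two fully separated groups of four; the uncorrected
  score would be $-2.3094$. The exact two-sided p doubles the lower tail
  of the enumerated one-group $U$ null ($2/70 = 0.02857$ in that
  configuration), matching `wilcox.test(exact = TRUE)`.
* **Dunn's post hoc**: mean-rank differences standardized by
  $\sqrt{k(k+1)/(6N_A)}$ (repeated measures) or the tie-corrected
  pooled-rank variance (independent groups), two-sided normal p,
  Bonferroni over all $k(k-1)/2$ pairs, capped at 1, pairs reported in
  declared condition order.
* **Effect-size conventions**: $W$ from the Friedman statistic (so
  $W = 1$ iff complete concordance, a bound the suite proves on random
  tables); $\eta^2$ may be slightly negative for $H < k-1$ and is
  reported as computed; $r$ uses the total observation count $N$ and is
  reported at full precision (0.7655 for the separated-groups case — two
  printed decimals of 0.76 reflect the source's rounding, not ours).
* **Chen–Shapiro normality screen**: $QH$ from normalized order-statistic
  spacings with Blom plotting positions
  $M_i = \Phi^{-1}((i - 3/8)/(n + 1/4))$; rejection when $QH$ falls below
  the lower-$\alpha$ quantile of a Monte-Carlo null (10⁴ standard-normal
  samples per $n$, fixed internal seed 20220078, cached). The statistic is
  location-scale invariant, so the standard normal is the complete null.
* **Analysis policy** (`analysis_policy()`): $n \le 30$ or a normality
  rejection routes to the nonparametric branch (Friedman / Mann–Whitney /
  Kruskal–Wallis by design); larger normal-passing two-sample data uses
  the pooled t-test. Designs with three or more independent groups stay on
  ranks even at large $n$ — the suite intentionally contains no
  parametric ANOVA.

## The phantom generator: what it emulates, and what it does not

Real maps are unavailable (the source work deposited software, not data),
so every downstream stage is exercised on synthetic digit phantoms with
known ground truth. A phantom is a horizontal cartilage band containing
non-overlapping oval chondrocytes on a jittered lattice, wrapped in
interstitial space, an epidermis layer and surrounding medium; per-pixel
contrast is the region mean plus independent Gaussian noise, stored as a
shift map plus a label mask. Gaussian pixel noise is the minimal
assumption (no noise model is reported for the instrument) and keeps all
region means unbiased, so mask-based recovery of the specified means
within $3\,\mathrm{sd}/\sqrt{n}$ is a meaningful test.

Anchored versus chosen values:

* **Anchored to printed values**: medium contrast 0.006 (benzocaine bath,
  also the profile edge threshold); map geometries 148 × 80 µm at 2 µm
  (collagenase), 5 µm steps (development), 200 × 80 µm at 2.5 µm
  (regeneration); cohort sizes 5 / ≥4 / 4; condition *orderings* (ECM
  degradation with digestion time; stiffening with developmental stage;
  dip at 15 dpa then partial recovery at 30 dpa; developing chondrocytes
  stiffer than their immature ECM, mature ECM stiffer than its cells).
* **Chosen once, config-exposed, non-authoritative**: mature ECM mean
  0.060 and chondrocyte mean 0.045; layer thicknesses (medium 4,
  epidermis 6, interstitial 6 µm per side); 13 cells of 8 × 5 µm
  semi-axes; per-animal random-effect sd 0.002 and residual sd 0.001 in
  the cohort model; development stage means 0.012/0.024/0.032/0.040/0.048
  for the cartilage core. The stage-45 bud mean was set from the
  noise-free geometry so that the ROI-mean gap between stages 45 and 47
  comfortably exceeds the animal-level noise — with a smaller gap the
  strict stage ordering would hinge on the seed, which would make the
  ordering tests meaningless. The whole-map expected mean of the mature
  default (~0.045) sits close to, but below, the reported in vivo
  cartilage mean (0.0535); only orderings, not magnitudes, are treated as
  anchored.

"Rounding up" of cells at 45 min of digestion is modelled by equalizing
the oval semi-axes at preserved area, and the reported drop in cell
density by a lower cell count. Stage 45 renders a homogeneous bud with no
cartilage labels at all; stage 53 adds a `joint` strip of locally elevated
contrast.

A green phantom test therefore establishes that the *pipeline* —
conversion, masking, ROI extraction, profile normalization, ranking,
p-values — is correct and deterministic. It does **not** validate the
biological magnitudes: phantoms have no optical sectioning artefacts, no
spatially correlated noise, no irregular anatomy, and their effect sizes
are constructions, not measurements.

## Determinism and seeds

Every generator takes a single integer seed, split deterministically per
animal/map by an affine hash kept inside 32-bit range; RNG state is
restored after each draw, so package calls never perturb the caller's
stream. Reports contain no timestamps, and two runs of
`run_experiment()` with the same seed produce byte-identical file trees —
asserted with checksums in the acceptance tests.

## Known limitations

* The CSV schema is declared by this package, not inferred from the
  original export format, which is undocumented.
* Chondrocyte masks come from phantom ground truth or user files; there is
  no automated segmentation of contrast maps (the original workflow masked
  manually).
* The edge rule for profile normalization uses hard outermost threshold
  crossings; profiles whose bath noise straddles 0.006 can shift an edge
  by one sample. With the averaging over five lines this was never
  observed to change a normalized profile qualitatively, but the
  sensitivity is inherent to the rule.
* The ex vivo/in vivo comparison t-test reported in the source cannot be
  reproduced exactly (group sizes and the meaning of the printed ± values
  are unstated) and is not attempted.
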