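# osteoprofile

Quantitative biological profiling of fragmentary human long-bone
assemblages.

Skeletal assemblages from anthropogenically processed Pleistocene deposits
are typically a few dozen bone fragments representing a handful of
individuals. `osteoprofile` is for bioarchaeologists and
palaeoanthropologists who need to extract defensible quantitative
statements from such material: whether the demographic composition of the
assemblage could be a random draw from a normally dying population, how
tall the individuals were, how robust their diaphyses were, and how the
cross-sectional shape of their long bones compares between groups.

## What it computes

**Composition test.** The observed assemblage composition
$n = (n_F, n_M, n_J)$ — adult/adolescent females, adult/adolescent males,
juveniles (0–14 y) — is tested against a reference population of $N$
individuals (default 60) built from a mortality profile $p$ by
largest-remainder rounding. The probability of drawing exactly $n$ in MNI
draws is computed analytically,

- with replacement (multinomial):
  $P(n) = \binom{\mathrm{MNI}}{n_F\,n_M\,n_J}\prod_i p_i^{n_i}$
- without replacement (multivariate hypergeometric):
  $P(n) = \prod_i \binom{K_i}{n_i} / \binom{N}{\mathrm{MNI}}$

and by seeded Monte Carlo resampling (default 10,000 draws), the
traditional formulation, which the closed forms serve as oracles for.
Probabilities are flagged `*` (p < 0.05) and `**` (p < 0.01).

**Stature.** Sjøvold-type regressions on maximum length
(femur $2.71\,\mathrm{MaxL_{cm}} + 45.86$, SEE 4.49 cm; tibia
$3.29\,\mathrm{MaxL_{cm}} + 47.34$, SEE 4.15 cm; user-overridable), the
femoral conversion $\mathrm{MaxL} = 1.037\,\mathrm{BML} + 11.2$ mm for
incomplete bones, a femur-over-tibia priority rule per individual, and
Welch's t-test from group summary statistics.

**Cross-sectional geometry.** Exact Green's-theorem polygon moments of
periosteal/endosteal contour pairs with composite subtraction of the
medullary cavity: CA, TA, $I_x$, $I_y$, $I_{\max}$, $I_{\min}$, $\theta$,
$J$, and the polar section modulus $Z_p = J/r_{\max}$, at the standard
diaphyseal locations (femur 35/50/80% of biomechanical length from the
distal end, tibia 20/35/50%, radius at the interosseous crest).

**Cross-sectional shape.** 42 equiangular semilandmarks (21 periosteal +
21 endosteal) extracted on rays from the cortical centroid, generalized
Procrustes superimposition, PCA of the Procrustes coordinates, 95% group
confidence ellipses and ±0.1 wireframes.

**Synthetic data.** Parametric cortical-ring generators (annuli,
elliptical annuli, eccentric canals, buttressed rings) with closed-form
oracles, selection-biased assemblage draws, and two-group shape samples —
every pipeline stage is testable without scan data.

## Worked example

```r
library(osteoprofile)

# -- composition test: 4 females, 0 males, 2 juveniles (MNI = 6) against a
#    60-individual population scaled from a 3:4:5 reference profile
profile <- profile_from_counts(c(3, 4, 5), "reference_3_4_5")
refpop  <- build_reference_population(profile, 60)
refpop
#> Reference population (N = 60 ): reference_3_4_5
#>   F   M JUV
#>  15  20  25
observed <- assemblage_composition(c(4, 0, 2), "observed")
composition_test_table(list(observed), list(profile), method = "analytic")
#>   assemblage           model mode       p flag   method n_iter seed
#> 1   observed reference_3_4_5    R 0.01017    * analytic     NA    1
#> 2   observed reference_3_4_5  noR 0.00818   ** analytic     NA    1
```

A female-and-juvenile-only composition of this kind arises in fewer than
1% of random draws without replacement (p = 0.0082, flagged `**`) — strong
evidence of selection rather than random sampling of a dying population.

```r
# -- stature from five bones of five individuals
meas <- data.frame(
  specimen_id = c("FemA", "FemB", "TibA", "TibB", "TibC"),
  element     = c("femur", "femur", "tibia", "tibia", "tibia"),
  maxl_mm     = c(408, 398, 324, 292, 313),
  individual  = c("i1", "i2", "i3", "i4", "i5"))
est <- estimate_statures(meas)
est[, c("specimen_id", "source_element", "stature_cm", "see_cm")]
#>   specimen_id source_element stature_cm see_cm
#> 1        FemA          femur     156.43   4.49
#> 2        FemB          femur     153.72   4.49
#> 3        TibA          tibia     153.94   4.15
#> 4        TibB          tibia     143.41   4.15
#> 5        TibC          tibia     150.32   4.15
s <- group_stature_summary(est)      # mean 151.56 cm, sd 5.05 cm (n = 5)
welch_t_test(s$mean_cm, s$sd_cm, s$n, 162.89, 8.20, 17)
#> Welch t = 3.76, df = 11.0, p = 0.0031
```

The group averages 151.56 ± 5.05 cm — significantly shorter than a
comparative sample entered as published summary statistics
(162.89 ± 8.20 cm, n = 17).

```r
# -- CSG of a synthetic femoral midshaft with an eccentric medullary canal
gs <- generate_section(section_spec("eccentric_canal", outer = c(15, 12),
                                    inner = c(8, 7), canal_offset = c(2, 1)),
                       "synthetic_femur", "femur", location_label = "50")
csg_properties(gs$section)
#> CSG synthetic_femur femur @50: CA 389.55 TA 565.48 mm^2;
#>     Imax 27997.2 Imin 17920.7 mm^4; Zp 2884.4 mm^3

# -- shape: circular vs anteroposteriorly elongated ring groups
configs <- generate_shape_sample(
  section_spec("elliptical_annulus", outer = c(15, 15),   inner = c(9, 9)),
  section_spec("elliptical_annulus", outer = c(15, 22.5), inner = c(9, 13.5)),
  n_per_group = 20, seed = 42)
pca <- shape_pca(generalized_procrustes(configs))
pca
#> Shape PCA: 40 specimens; PC1 98.2%, PC2 0.2% of variance
```

PC1 carries 98% of the shape variance and separates the two groups with
no overlap — the circularity contrast the generator encodes.

A command-line wrapper over the same functions ships in
`inst/cli/osteoprofile.R`
(`Rscript inst/cli/osteoprofile.R composition-test --assemblages a.csv
--models m.csv --out results.csv`, with subcommands `stature`, `csg`,
`shape-pca` and `simulate`).

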