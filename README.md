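# ausr

**Fragment-size thresholds from landscape-scale species incidence.**

Studies of habitat fragmentation routinely split fragments into "small"
and "large" classes before comparing biodiversity, ecosystem services or
specialist occurrence between them — usually at an arbitrary cut such as
the median fragment size. `ausr` implements an *ecologically defined*
threshold instead: the fragment area at which a fragment is expected to
contain species at the same incidence frequencies as the landscape as a
whole. It requires nothing beyond the data needed for an island
species–area relationship: a fragment-by-species presence–absence matrix
and fragment areas.

## The metric

For a landscape of *n* fragments, the **incidence** of species *s* is
the fraction of fragments it occupies — a landscape-scale range-size
proxy. The **MSLIP** (mean species landscape-scale incidence per patch)
of fragment *i* is the geometric mean of the incidences of the species
found in it. A fragment of richness *k* is then compared with a
resampling null: 1000 draws of *k* incidence values sampled with
replacement from all species' incidences, each reduced to its geometric
mean, give a reference distribution with mean and SD from which a
standardised effect size is computed:

```
MSLIP_SES = (MSLIP_obs − mean_ref) / SD_ref
```

Positive values mark fragments holding more widespread species than
expected given their richness; negative values mark over-representation
of narrow-range species. Regressing SES on log area (controlling for
residual richness *res*, the deviation from the ISAR prediction
`SR = c·area^z`, or from mean richness under standardised sampling),

```
SES_i = β0 + β1·ln(area_i) + β2·res_i + ε_i,
```

the fragment size where the fitted line (at `res = 0`) crosses zero is
the **area for unbiased species representation (A_USR)** — the proposed
objective boundary between "small" and "large" fragments. The package
also fits the truncated power-law ranked species occupancy curve
`O_R = a·R^b·e^(−cR)` (a positive *b* flags a bimodal occupancy
frequency distribution), and provides a second-stage generalised
least-squares analysis of per-study slopes on moderators with an
exponential variance structure, Type-3 Wald tests and pairwise
least-squares-means contrasts.

## Worked example

A five-fragment example landscape ships with the package. Species `b`
occurs in 4 of the 5 fragments (incidence 0.8); the 5-ha fragment `f2`
holds exactly the three species with incidences {1.0, 0.8, 0.6}, so its
observed MSLIP is (1.0·0.8·0.6)^(1/3) = 0.78.

```r
library(ausr)
bundle <- run_ausr(
  system.file("extdata", "landscape_matrix.csv",  package = "ausr"),
  system.file("extdata", "landscape_metadata.csv", package = "ausr"),
  output_dir = "demo_out", n_draws = 1000, seed = 42, bootstrap = 999)

bundle$mslip_table
#>   fragment_id area_ha richness mslip_obs null_mean null_sd    ses
#> 1          f1       1        2     0.894     0.511  0.1638  2.344
#> 2          f2       5        3     0.783     0.512  0.1355  1.997
#> 3          f3      12        5     0.649     0.501  0.1048  1.411
#> 4          f4      40        6     0.599     0.504  0.0941  1.010
#> 5          f5     150        6     0.444     0.504  0.0941 -0.632

bundle$isar
#> ISAR fit (effort_controlled): SR = 2.209 * area^0.2362  (R^2 = 0.874, n = 5)

bundle$ausr
#> A_USR = 106.3 ha (within observed area range [1, 150] ha)
#>   area slope sign: negative
#>   bootstrap CI: [35.09, 1.603e+05] (90% of 999 resamples defined)
```

Small fragments carry positive SES (widespread species over-represented)
and the largest fragment a negative one; the fitted SES–ln(area) line
(slope −0.57, 95% CI excluding zero) crosses zero at about 106 ha, so
`f1`–`f4` classify as "small" and `f5` as "large". With only five
fragments the bootstrap interval is, as it should be, enormous — the
example illustrates mechanics, not inference.

A command-line wrapper with `validate`, `ausr`, `simulate` and `meta`
subcommands is installed at
`system.file("cli", "ausr.R", package = "ausr")`.

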