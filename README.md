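# morbidmap

Bayesian geo-additive multinomial modelling of overlapping childhood
illnesses (diarrhoea, fever, cough) for DHS-style survey data, with
disease mapping over administrative regions.

## Who this is for

Epidemiologists and biostatisticians analysing child-morbidity surveys in
which several illnesses co-occur and cluster geographically.  Instead of
fitting one logistic model per illness, the three binary indicators are
collapsed into an eight-level *co-morbidity* outcome — one level per
combination, "no illness" as reference — and modelled jointly.

## The model

For child *i* in region *r(i)* and each non-reference category
*k = 1..7*:

```
P(Y_i = k) = exp(eta_ik) / (1 + sum_l exp(eta_il))
eta_ik     = z_i' beta_k + f_k(v_i) + theta_{k,r(i)} + phi_{k,r(i)}
```

* `z_i' beta_k` — reference-cell fixed effects (age group, sex, residence,
  wealth quintile, ...);
* `f_k` — optional P-spline smooths of metrical covariates (cubic
  B-splines, second-order random-walk penalty); the default model is
  linear-effects-only;
* `theta_k` — structured spatial effect with an intrinsic CAR (Markov
  random field) prior on the region adjacency graph, precision `Q = D - A`;
* `phi_k` — unstructured (exchangeable) region heterogeneity.

Estimation is fully Bayesian: block Metropolis–Hastings with IWLS-mode
proposals (compiled, RcppArmadillo), conjugate inverse-gamma updates for
all variances, sum-to-zero constraints each sweep.  Results are posterior
odds-ratio tables (`exp` of summarised log-odds coefficients with 95%
equal-tailed credible intervals) and per-region spatial-effect tables for
choropleth mapping.  A curated adjacency of Egypt's 27 governorates ships
as the default fixture; any edge list can be substituted.

A synthetic-data generator (`generate_survey()`) draws surveys from the
same model with known ground truth, so the whole pipeline is testable
without any external data.  See the vignette
(`vignettes/geoadditive-comorbidity.Rmd`) for the full methods account.

## Worked example

```r
library(morbidmap)
g <- egypt_graph()

# synthetic survey: 2,000 children, girls less likely to have all three
# illnesses (true log-odds -0.7, i.e. OR 0.50), moderate spatial structure
cov_spec <- list(list(name = "sex", levels = c("male", "female"),
                      probs = c(0.51, 0.49)))
betas <- matrix(0, 2, 7); betas[2, 1] <- -0.7
tr <- truth_config(2000, betas, covariate_spec = cov_spec,
                   spatial_var = 0.3, unstructured_var = 0.1,
                   graph = g, seed = 42)
sv <- generate_survey(tr)

d <- build_design(sv$records, terms = "sex", graph = g,
                  reference_levels = list(sex = "male"))
k <- encode_outcome(sv$records$diarrhoea[d$rows], sv$records$fever[d$rows],
                    sv$records$cough[d$rows])
fit <- run_mcmc(d, k, model_spec(n_iterations = 4000, burn_in = 1000,
                                 thinning = 5, seed = 42))

ors <- or_table(fit)
ors[ors$category %in% 1:2, c("category", "category_label", "label",
                             "or", "ci_low", "ci_high", "significant")]
#>  category        category_label     label    or ci_low ci_high significant
#>         1 diarrhoea_fever_cough sexfemale 0.507  0.351   0.726        TRUE
#>         2       diarrhoea_fever sexfemale 0.771  0.551   1.087       FALSE

sp <- spatial_effect_table(fit, 1)
head(sp[order(-sp$mean), c("region_id", "region_name", "or",
                           "or_low", "or_high")], 3)
#>  region_id region_name   or or_low or_high
#>         26 North Sinai 2.48  1.218    4.63
#>         27 South Sinai 1.93  1.050    3.55
#>          3   Port Said 1.72  0.992    2.85
```

The recovered odds ratio for girls in the all-three-illnesses category
(0.507, CI 0.35–0.73) matches the generating value `exp(-0.7) = 0.50` and
is flagged significant; the same contrast for a category generated with a
null effect (0.77, CI 0.55–1.09) is not.  The spatial table ranks regions
by their structured effect on the log-odds scale, here reported as
posterior ORs with 95% intervals — the rows a mapping tool consumes.

For survey files, `read_survey()` (CSV canonical; SPSS SAV via a YAML
column-map profile) plus `recode_covariates()` produce the analysis view,
and `run_pipeline()` drives all stages from a single config with a
reproducibility manifest.

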