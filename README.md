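# hcineq

Measuring — and explaining — socioeconomic inequality in the use of health
care services from household-survey microdata.

Epidemiologists and health economists routinely ask whether physician
visits, hospitalisations or screening tests are concentrated among the rich
or the poor, how that concentration evolves across survey waves and
regions, and which observable factors (insurance, education, need) account
for it. `hcineq` implements that entire workflow for binary utilisation
outcomes:

* **Weighted fractional income ranks** `fractional_rank()`:
  R_i = (W_{<i} + w_i/2)/W over household income per capita, with tied
  incomes sharing their block's weighted mid-rank.
* **Concentration curves and indices** `concentration_curve()`,
  `concentration_index()`, `erreygers_index()`, `wagstaff_index()`:
  the standard index C(h) = 2 cov_w(h, R)/h̄, the Erreygers correction for
  bounded outcomes E(h) = 8 cov_w(h, R)/(h_max − h_min) (mirror-symmetric,
  transfer-sensitive, increment- and scale-invariant), and the Wagstaff
  normalization W(h) = C(h)/(1 − h̄), linked by E = 4 h̄(1 − h̄) W.
* **Uncertainty** `index_ci()`: convenient-regression (WLS on the rank,
  HC1 robust) or clustered percentile bootstrap with within-resample
  re-ranking; significance stars and pro-rich / pro-poor / indeterminate
  classification from the interval.
* **Decomposition** `decompose_index()`: weighted probit, averaged partial
  effects β_j^m (subgroup rule for binary covariates, conventional AME
  stored alongside), generalized concentration indices
  GC(x) = 2 cov_w(x, R), contributions 4 β_j^m GC(x_j) and an exactly
  additive residual 4 GC(e), with Andersen-role subtotals.
* **Synthetic survey generator** `generate_survey()`: five-region,
  log-normal-income, gamma-weight microdata with a fully known latent
  utilisation model (ground truth returned), eligibility markers and a
  labour-and-delivery admission process — the validation bed for everything
  above.
* **Study pipeline** `run_study()` / `render_report()`: eligibility filters
  (adults 18+; Pap smears women 25–59; mammograms women 50–69;
  delivery-only admissions recoded, not dropped), prevalence, indices by
  wave and region (re-ranked within region), decompositions, rendered to
  CSV/JSON/markdown byte-reproducibly.

## Worked example

Generate a survey wave, restrict to screening-eligible women, and measure
mammography inequality:

```r
library(hcineq)

g   <- generate_survey(generator_config(n_persons = 20000, seed = 42))
d   <- filter_adults(g$data)$data
mam <- eligibility_filter(d, "mammogram")$data

rk  <- fractional_rank(mam$income_pc, mam$weight)
est <- index_ci(mam$mammogram, rk, mam$weight, variant = "erreygers",
                method = "bootstrap", n_boot = 500, seed = 1,
                cluster_id = mam$psu_id)
est
#> <index_estimate> erreygers concentration index
#>   value = 0.3009  (mean outcome = 0.5142, effective n = 1438.1)
#>   se = 0.0279, 95% CI [0.2466, 0.3571] (bootstrap)
classify_inequality(est)
#> [1] "pro-rich"
```

About 51% of eligible women were screened, but screening is strongly
concentrated among richer women: E(h) = 0.30 with a CI well above zero.
Decomposing the index attributes it to observable factors:

```r
des <- covariate_design(mam,
  c("insurance", "education_secondary", "chronic_condition", "urban"),
  roles = c(insurance = "enabling", education_secondary = "enabling",
            chronic_condition = "need", urban = "predisposing"))
dec <- decompose_index(mam$mammogram, des, rk, mam$weight)
dec
#> <decomposition> Erreygers index E(h) = 0.3009
#>                 term         role  beta_m      gc contribution   share
#>            insurance     enabling  0.3106  0.1117       0.1387  0.4610
#>  education_secondary     enabling  0.2008  0.0789       0.0634  0.2107
#>    chronic_condition         need -0.0118 -0.0125       0.0006  0.0020
#>                urban predisposing -0.0497  0.0437      -0.0087 -0.0289
#>   residual contribution 4*GC(e) = 0.1069
contribution_shares(dec, "role")
#>           term contribution  share_pct
#> 1     enabling  0.202103207 67.1701341
#> 2         need  0.000588107  0.1954607
#> 3 predisposing -0.008693646 -2.8893820
#> 4     residual  0.106884874 35.5237873
```

Each contribution is 4 β_j^m GC(x_j) — sensitivity of utilisation to the
factor times the factor's own income gradient. Here the enabling factors
(insurance and education, both concentrated among the rich and both
predictive of screening) account for about two thirds of the measured
inequality; contributions plus the residual reassemble E(h) exactly.

`run_study()` wraps this loop over all outcomes, waves and regions and
`render_report()` writes the prevalence/index/decomposition tables; a thin
command-line front-end lives at `inst/cli/hcineq.R`
(`simulate`, `index`, `report`).

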