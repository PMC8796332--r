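# wisnstaff

Workload-based health-workforce requirement estimation with national-level
modelling, for health-systems researchers and workforce planners.

Staffing norms for primary and community health centres (PHCs and CHCs) are
often fixed per centre type, regardless of how much care a centre actually
delivers. The WHO **Workload Indicators of Staffing Needs (WISN)** method
instead converts a facility's annual service volumes and activity time
standards into the number of staff its workload requires. `wisnstaff`
implements the full analysis chain from facility activity data to national
policy metrics:

1. **Facility WISN** — for each facility × year × cadre observation,

   - available working time `AWT = [A − (B + C + D + E)] × F` hours/year
     (working days minus annual, sick, public-holiday and other leave,
     times hours per day);
   - health-service requirement `HSA = Σ_s workload_s / standard workload_s`,
     where a service's standard workload is `AWT` divided by its unit time;
   - category allowance factor `CAF = 1 / (1 − CAS/100)` for support
     activities done by all cadre members (CAS = percent of AWT);
   - individual allowance factor `IAF = Σ (hours × staff) / AWT` for
     additional activities done by select members;
   - `WISN = HSA × CAF + IAF`, rounded to whole staff (half-up by default).

   Records are filtered before modelling: facilities under half the 48 h
   standard workweek, null WISN values, and nurse records with a null
   additional-activity component are excluded with an audit trail.

2. **National thresholds** — after a Kruskal–Wallis check of across-state
   heterogeneity, a population-averaged (GEE) Poisson model
   `log E(WISN_ij) = β0 + β1·State + β2·Year`, clustered on facility, is
   fitted under independence, exchangeable and AR(1) working correlations;
   the fit with the lowest QIC supplies the marginal mean requirement per
   centre with a 95% CI, rounded to the integer threshold used downstream.

3. **Projections** — against a state staffing table (in-position staff `P`,
   sanctioned posts `S`, functional centres `N`): the WISN ratio
   `P/(WISN×N)`, WISN differences `P/N − WISN` and `P − WISN×N`,
   sanctioning differences with `S`, and their categorical readings
   (shortage/balance/surplus; workload pressure from very high to none;
   under/optimal/over-sanctioning).

4. **Agreement** — Spearman rank correlations (pairwise and partial) of
   state-level WISN ratios across cadres, and Lin's concordance correlation
   (with bias-correction factor) between sanctioned posts and
   workload-based requirements.

A synthetic-data module generates facility panels (negative-binomial service
volumes, state/year effects, unbalanced missingness) and state staffing
tables with configurable under-sanctioning, so the whole pipeline is
testable without access to facility survey data.

## Worked example

One PHC-nurse observation: 52 000 outpatient visits, 18 000 immunisations
and 1 900 deliveries in a year, 20% of working time on support activities,
and an outreach programme of 528 h/year involving 2 nurses:

```r
library(wisnstaff)

rec <- data.frame(
  facility_id = "PHC_017", state = "OD", year = 2012, centre_type = "PHC",
  cadre = "nurses", weekly_hours = 48,
  svc_outpatient = 52000, svc_immunisation = 18000, svc_delivery = 1900,
  cas_records = 0.08, cas_meetings = 0.07, cas_upkeep = 0.05,
  ias_outreach_hours = 528, ias_outreach_staff = 2)

res <- compute_facility_wisn(rec, default_standards(), leave_policy())
t(round(res[, c("awt_hours", "hsa_requirement", "total_cas_pct", "caf",
                "iaf", "wisn_raw", "wisn_rounded")], 3))
#> awt_hours       2112.000
#> hsa_requirement    8.033
#> total_cas_pct     20.000
#> caf                1.250
#> iaf                0.500
#> wisn_raw          10.542
#> wisn_rounded      11.000
```

Reading: the default leave policy gives 2112 available hours per year; the
service volumes alone need 8.03 nurses; inflating by the 20% support
allowance (CAF 1.25) and adding the 0.5 full-time-equivalents of outreach
gives a requirement of 10.5, i.e. 11 nurses at this facility — against an
IPHS-style fixed norm of 3–4.

The full pipeline runs from a single configuration (here in simulate mode):

```r
scen <- sanctioning_scenario(
  true_requirement_per_centre = setNames(c(15, 2, 45, 4, 2, 2, 2, 2),
                                         default_combos()$combo),
  sanction_bias = 0.7, fill_rate = 0.6,
  n_centres_by_state = setNames(rep(c(60, 150, 420, 800, 90, 260), 5),
                                sprintf("S%02d", 1:30)),
  fill_noise_sd = 0.12)

out <- run_pipeline(run_config(
  simulate = list(config = simulation_config(), scenario = scen),
  seed = 1, output_dir = "wisn_out"))

out$thresholds[, c("combo", "n", "mean_rounded", "wisn_threshold", "structure")]
out$projection[out$projection$state == "India", ]
out$agreement
```

which writes `facility_wisn.csv`, `thresholds.csv`, `projection.csv`,
`agreement.csv`, `correlations.csv` and a JSON run manifest to
`wisn_out/`. A thin command-line wrapper is installed at
`inst/scripts/wisn-national.R` (`run --config run.yaml`, `simulate --seed 7
--out panel.csv`).

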