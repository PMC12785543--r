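# edflow

Discrete-event simulation of emergency-department (ED) patient flow for
triage Level III/IV patients, built to compare physician-allocation
policies and to tune a slack-based dynamic dispatching rule.

## The problem

EDs route moderate- and low-acuity patients through two physician
visits: an initial consultation and, for the ~60% who need diagnostic
examinations, a follow-up consultation once every report is in. The
same physician pool serves three competing queues — Level III initials
(30-min clinical wait target), Level IV initials (120-min target), and
follow-ups — under shift-varying staffing and time-varying Poisson
arrivals with a weekly cycle. How should a freed physician pick their
next patient?

`edflow` implements three allocation rules at every decision epoch *t*
over the queue demands $D_{init,3}$, $D_{init,4}$, $D_{follow}$ and
free physicians $R$:

* **IFP** (Initial-First): $N_3 = \min(D_3, R)$,
  $N_4 = \min(D_4, R - N_3)$, $N_f = \min(D_f, R - N_3 - N_4)$.
* **ALT** (Alternating 1:1): at most $\lfloor R/2 \rfloor$ physicians
  to initial consultations (Level III first), the rest to follow-ups,
  with unused quota redistributed.
* **SBP** (Slack-Based): patient $i$ is *urgent* when
  $w_i(t) \ge T_l - k_l$; priority is
  $U_3 > U_4 > F > H$ (follow-ups outrank non-urgent initials), FIFO
  within each set. The tolerances $(k_1, k_2)$ are tuned by a
  two-stage grid search minimizing the overall mean wait
  $\bar W_{total}(k_1,k_2)$ subject to service-level floors
  $SL_l \ge SL_l^{min}$.

The package ships the full baseline scenario (168-cell arrival-rate
table, triage mix, truncated-exponential consultation times, exam
probabilities and report delays, three-shift staffing), a deterministic
C++ event engine fed by pre-sampled patient attributes (so common
random numbers across policies are exact), the KPI layer (journey
waits, delay rates/service levels, utilizations), paired *t* /
Bonferroni / Cohen's *d* comparison statistics, and arrival-rate,
staffing and service-distribution sensitivity analyses.

## Worked example

```r
library(edflow)
sc <- baseline_scenario()

# one simulated week under the optimized slack-based rule
rep1 <- run_replication(sc, ed_policy("SBP", 13.1, 2.1), seed = 2)
rep1
#> ED replication (policy SBP, seed 2): 2216 arrivals, 2211 completed, 5 censored

round(replication_metrics(rep1, sc)[, c("w_total", "w_journey3",
                                        "w_journey4", "delay4", "u_doc")], 3)
#>   w_total w_journey3 w_journey4 delay4 u_doc
#> 1    39.1      7.429      49.74  0.093 0.864

# the three-policy comparison, 100 paired replications
cmp <- compare_policies(sc, list(ed_policy("IFP"), ed_policy("ALT"),
                                 ed_policy("SBP", 13.1, 2.1)), n_reps = 100)
cmp
#> Policy comparison (100 CRN replications, alpha_adj = 0.0167)
#>   IFP          overall wait  46.81 min  (L3  44.94, L4  47.43)
#>   ALT          overall wait  37.86 min  (L3   6.12, L4  48.51)
#>   SBP(13.1,2.1) overall wait  39.05 min  (L3  10.02, L4  48.78)
#>     a             b mean_diff      t         p significant cohens_d
#> 1 IFP           ALT     8.946  30.76 1.831e-52        TRUE    3.076
#> 2 IFP SBP(13.1,2.1)     7.753  34.10 1.583e-56        TRUE    3.410
#> 3 ALT SBP(13.1,2.1)    -1.193 -10.91 1.121e-18        TRUE   -1.091
```

Reading the numbers: a week sees ~2,200 patients. Under Initial-First,
initial consultations are served almost immediately but exam patients
then sit in the follow-up queue, so the mean *journey* wait (initial
wait + follow-up wait per patient) is ~47 min for both levels. The
alternating rule moves capacity to follow-ups and cuts Level III
journeys to ~6 min at the cost of a ~10% Level IV delay rate. The
slack-based rule keeps Level III fast (~10 min) while capping Level IV
excursions via the urgency sets. All pairwise differences are
significant far below the Bonferroni-adjusted threshold, with very
large effect sizes ($d = t/\sqrt{n}$). Physician utilization is ~86%;
the diagnostic devices stay below 20% — the physicians, not the
equipment, are the bottleneck.

Tuning the slack tolerances and the sensitivity studies:

```r
policies <- list(ed_policy("IFP"), ed_policy("ALT"), ed_policy("SBP", 13.1, 2.1))
opt <- two_stage_optimize(sc)          # coarse step 1 on [0,40]^2, fine step 0.1
arr <- arrival_sensitivity(sc, policies, n_reps = 30)   # ±15% load in 3% steps
stf <- staffing_sensitivity(sc, policies, n_reps = 30)  # S0 (5,5,3) ... S6 (7,7,5)
ln  <- distribution_robustness(sc, policies)            # truncated-lognormal services
```

A command-line wrapper (`inst/exec/edflow`) exposes the same
operations: `edflow run|compare|optimize|sensitivity --flag value ...`,
reading human-editable YAML scenarios (`save_scenario()` /
`load_scenario()`) and writing CSV tables plus a JSON manifest with the
seeds and scenario hash needed for exact reruns.

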