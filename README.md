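# ekcdm — ordered-level cognitive diagnosis

`ekcdm` is an R package for diagnosing learners' knowledge states from
binary test responses when items are tagged, per exercise–knowledge pair,
with an **ordered cognitive requirement level** (0–6 on the revised Bloom
cognitive-process taxonomy) instead of a plain binary Q-matrix entry.  It is
aimed at psychometricians and education researchers who want cognitive
diagnosis whose output reads as "this learner handles *Apply*-level tasks on
fractions, but not *Analyze*" rather than "mastered / not mastered".

## The model

Each exercise `e` requires concept `k` at level `a_ek ∈ {0,…,6}` (0 = not
required).  A learner's latent state is an ordered profile
`β ∈ {0,…,L_max}^K`.  The deterministic part is a noisy-AND (DINA-type)
ideal response

    π_e(β) = ∏_k 1(a_ek ≤ β_k),

perturbed by per-item slip `s_e = P(wrong | π = 1)` and guess
`g_e = P(right | π = 0)`.  Slip and guess are estimated by marginal
maximum likelihood with an EM algorithm over all `(L_max+1)^K` profiles
(mixing proportions re-estimated each M step by default); learner profiles
are then inferred by MAP with explicit handling of exact posterior ties,
per-concept marginal level posteriors, 95% credible intervals, and
adjacent-level separability diagnostics that flag which level distinctions
the item bank can actually support.  With binary requirements the model is
exactly DINA.

The package also ships the surrounding machinery as first-class, tested
components: a Monte Carlo parameter-recovery harness (Gaussian-distributed
ordered levels, four-parameter-beta slip/guess, Bernoulli responses, scored
by MAE/MSE and pattern/attribute match ratios), ordinal inter-rater
reliability for the human level-tagging step (Krippendorff's α, quadratic
weighted kappa, bootstrap CIs), and a construct-validity battery against
external cognitive-domain labels (tie-corrected Kruskal–Wallis with rank
ε², Spearman trend tests).

## Worked example

A deliberately well-designed bank of 12 items pins every adjacent level
pair of two concepts with two boundary items each; 400 learners respond
with slip/guess in [0.05, 0.15]:

```r
library(ekcdm)
a <- rbind(cbind(rep(1:3, 2), 0L), cbind(0L, rep(1:3, 2)))
req <- requirement_map(a, L_max = 3)
profiles <- sample_levels(400, 2, mean = 1.5, var = 1, L_max = 3, seed = 2)
params   <- sample_item_params(12, sg_range = c(0.05, 0.15), seed = 3)
R <- simulate_responses(req, profiles, params, seed = 4)

d <- diagnose(R, req)
d$fit
#> EM fit: U = 400 learners, E = 12 exercises, K = 2 concepts (N = 16 profiles)
#>   prior: empirical | iterations: 68 (converged)
#>   loglik = -2267.85 | AIC = 4613.7 | BIC = 4769.4 (n_params = 39)
#>   slip  in [0.028, 0.125], guess in [0.002, 0.204]

d$separability
#>  concept_id   gate nq2 nq3 n_pair indet_rate median_abs_log_odds p_delta_small
#>         KC1 Strong   2   2    207      0.179                4.36         0.101
#>         KC2 Strong   2   2    204      0.137                6.18         0.044

recovery_metrics(list(params = params, profiles = profiles),
                 d$fit$item_params, d$reported)[c("mae_s", "mae_g", "pmr", "aamr")]
#> $mae_s 0.015   $mae_g 0.024   $pmr 0.762   $aamr 0.870
```

Reading the output: both concepts pass the `Strong` identifiability gate
(two items at level 2 and two at level 3 each), the Understand/Apply
boundary is cleanly separated (median |log-odds| > 4, under 18% of
borderline learners have credible intervals spanning both levels), item
slip/guess are recovered to about ±0.02, and 76% of learners get their
whole two-concept profile exactly right (87% of individual cells).  On
sparse banks the same report honestly degrades: gates turn `Weak`,
indeterminacy rates rise toward 1, and credible intervals widen —
that behaviour is the point of the diagnostics.

Each learner's row of `d$reported` / `d$ci` gives the point level and
credible bounds per concept; `d$marginals` holds the full per-level
posteriors.

## Command-line use

`inst/cli/ekcdm.R` wraps the same functions as subcommands:

```sh
Rscript inst/cli/ekcdm.R fit      --responses responses.csv --requirements ekc.csv --out-dir out
Rscript inst/cli/ekcdm.R diagnose --responses responses.csv --requirements ekc.csv --out-dir out
Rscript inst/cli/ekcdm.R simulate --reps 10 --learners 5000 --seed 1 --out-dir out
Rscript inst/cli/ekcdm.R irr      --ratings ratings.csv --out-dir out
Rscript inst/cli/ekcdm.R validity --requirements ekc.csv --domains domains.csv --out-dir out
```

CSV/JSON formats are documented in the reader functions
(`read_requirement_map()`, `read_response_matrix()`,
`read_rating_table()`); every stochastic run records its seed and chart
data are exported as JSON.

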