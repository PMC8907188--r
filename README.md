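# bystanderRL

A desk-scale computational pipeline for **adaptive virtual-reality bystander
experiments**. In the experiment this package emulates, a participant watches
a scripted pub confrontation between a perpetrator and a victim while a
tabular reinforcement-learning agent decides, every 10 seconds, which
virtual-character action to trigger — the victim looking at the participant
(`VictimLookAt`), the perpetrator doing the same (`PerpLookAt`), or a virtual
bystander speaking an encouraging utterance (`BystandersUtter`) — with the
goal of eliciting a helping intervention. The package replaces the human
participants with a synthetic generative model so that the full loop — agent,
study design, and Bayesian analysis — can be run, tested and calibrated on a
laptop.

It is aimed at researchers designing RL-in-the-loop behavioural experiments
who want to rehearse the analysis pipeline, check parameter recovery, and
explore design choices before collecting human data.

## What is inside

**The agent** is Watkins' Q(λ) with accumulating eligibility traces and
ε-greedy selection over a 3 × 3 state–action space. The state is the
participant's proxemic band — `Intervention` (< 0.5 m, within arm's reach),
`Active` (0.5–1 m), `Passive` (≥ 1 m). Rewards per 10 s window: +1 per
intervention type observed (verbal, physical; max 2), −0.1 for none.
Parameters α = 0.2, γ = 1, λ = 0.2. The study design runs three cohorts of
15 participants at ε = 1 (None), 0.66 (Medium) and 0.33 (High), averaging
each cohort's final Q tables into the next cohort's initial values so that
knowledge accumulates across groups.

**The synthetic participants** respond according to a Bernoulli logistic
model with subject effects,

    P(respond to action a) = inv_logit(u + b_a),   u ~ Normal(0, 1),

with action weights `b = (0.59, 0.29, 0.12)` on the unit simplex, plus a
sticky Markov movement model over the three distance bands (a window spent
closer than 0.5 m automatically counts as a physical intervention).

**The analysis models** are fitted by MCMC (JAGS via rjags):

1. *Counts on proprandom* — `resp_i ~ BetaBinomial(N = 13, p_i φ, (1 − p_i) φ)`
   with `p_i = inv_logit(β₀ + β₁·proprandom_i)`, where `proprandom` is the
   realised share of randomly chosen actions. Priors: Normal(0, 10) on
   coefficients, Gamma(2, 0.1) on φ.
2. *Counts on learning level* — same likelihood with
   `p_i = inv_logit(γ₀ + γ₁ M_i + γ₂ H_i)` and derived per-level response
   probabilities `p_none = inv_logit(γ₀)`, `p_medium = inv_logit(γ₀ + γ₁)`,
   `p_high = inv_logit(γ₀ + γ₂)`, transformed draw by draw.
3. *Per-trial action effects* — `y_i ~ Bernoulli(inv_logit(u_id + b·x_i))`
   with `b` constrained to the simplex (Dirichlet(1,1,1) prior, needed
   because the one-hot action indicators sum to 1) and `u_k ~ Normal(0, 1)`.

Posterior summaries (mean, SD, 95% equal-tail interval, Prob > threshold),
split-chain Rhat, posterior predictive simulation of counts and trials, and
the point-biserial model-fit correlation are included, along with
parameter-recovery calibration loops.

## Worked example

```r
library(bystanderRL)

study <- run_study(master_seed = 42)
study
#> Three-cohort study, 45 participants, 585 trials (master seed 42 )
#> Mean interventions: None 9.93 | Medium 10 | High 9.27

fit <- fit_action_model(study$trials, mcmc = mcmc_config(8000L, 4L, seed = 42))
posterior_summary(fit, threshold = 0.5, params = c("b_vl", "b_pl", "b_bu"))
#>   parameter  mean    sd   q2.5 q97.5 prob_gt
#> 1      b_vl 0.681 0.119 0.4334  0.89   0.933
#> 2      b_pl 0.252 0.114 0.0462  0.48   0.017
#> 3      b_bu 0.067 0.061 0.0017  0.23   0.000

pm <- posterior_predictive_y(fit, study$trials, type = "mean_prob")
point_biserial(study$trials$y, pm)$r
#> [1] 0.4380587
```

The simulated study produces 45 participants (13 trials each); the
simplex-constrained model then recovers the ordering of the generating
action weights (0.59, 0.29, 0.12): the victim's gaze is credibly the most
effective prompt (posterior mean 0.68, and `Prob > 0.5` = 0.93), bystander
utterances the least. The point-biserial correlation between observed
responses and their posterior predictive mean probabilities (0.44 here)
summarises model fit; it grows with subject heterogeneity. Group-mean
intervention differences between learning levels are small under this
generator — a single 45-participant study, as above, often does not show
the High > Medium > None ordering that holds in expectation.

The same pipeline is available from a shell:

```sh
Rscript inst/scripts/bystander-cli.R simulate --seed 42 --out out/
Rscript inst/scripts/bystander-cli.R fit --model c --trials out/trials.csv --out out/
Rscript inst/scripts/bystander-cli.R recover --model a --replicates 20 --out out/
```

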