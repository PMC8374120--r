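# Cohort with covariates from the default case mix (optionally scaled)
# and outcome labels drawn from a given risk model, so the
# data-generating model is known exactly.
model_cohort <- function(model, n_scale = 1, seed = 1,
                         params = default_subgroup_params()) {
  if (n_scale != 1)
    params <- lapply(params, function(g) {
      g$n <- as.integer(round(g$n * n_scale)); g
    })
  co <- simulate_cohort(params, seed = seed)
  co$hcc <- simulate(model, seed = seed + 1000L, newdata = co)$sim_1
  co
}

# O(n^2) pairwise concordance oracle: case/control pairs, ties 0.5.
cstat_brute <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  g <- outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "==")
  mean(g)
}
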