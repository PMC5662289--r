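# Shared fixtures, built in code.

default_machines <- slot_machines()

# A complete simulated session: agent trials plus observer self choices.
make_session <- function(seed = 1, n_agent = 100, n_self = 50,
                         condition = "similar",
                         model = "inverse_rl",
                         params = list(eps = c(0.9, 0.5, 0.1), beta = 6)) {
  sch <- build_schedule(n_agent, n_self, seed = seed)
  ag <- simulate_agent_session(default_machines, sch, condition = condition,
                               seed = seed + 1000L)
  observer_simulate(model, params, ag, seed = seed + 2000L)
}

# A tiny hand-written session log for brute-force oracles. Trial layout:
#   1 agent  M1 vs M2, agent chose M1 (outcome rank 1)
#   2 self   M1 vs M3, self  chose M1
#   3 agent  M2 vs M3, agent chose M2 (outcome rank 2)
#   4 self   M2 vs M3, self  chose M3
#   5 agent  M1 vs M3, agent chose M1 (outcome rank 1)
#   6 self   M1 vs M2, self  chose M1
hand_session <- function(condition = "similar") {
  sch <- data.frame(trial = 1:6,
                    kind = c("agent", "self", "agent", "self", "agent", "self"),
                    machine_a = c("M1", "M1", "M2", "M2", "M1", "M1"),
                    machine_b = c("M2", "M3", "M3", "M3", "M3", "M2"))
  ap <- preference_profile("agent", c("o1", "o2", "o3"))
  op <- if (condition == "similar") similar_profile(ap) else dissimilar_profile(ap)
  log <- obsirl:::new_session_log(sch, condition, default_machines, ap, op)
  log$chosen <- c("M1", "M1", "M2", "M3", "M1", "M1")
  log$outcome_rank <- c(1L, NA, 2L, NA, 1L, NA)
  log
}

# Monotone-eps sampler: identifiable inverse-RL observers (clear best/mid/
# worst discrimination), used for cohorts that must show competent learning.
monotone_eps_sampler <- function(model) {
  function() list(eps = c(runif(1, 0.75, 0.95), runif(1, 0.45, 0.6),
                          runif(1, 0.05, 0.25)),
                  beta = runif(1, 4, 12))
}

well_separated_sampler <- function(model) {
  switch(model,
    inverse_rl = monotone_eps_sampler(model),
    imitation = function() list(eta = runif(1, 0.2, 0.6),
                                theta = runif(1, 0.8, 1),
                                beta = runif(1, 4, 12)),
    default_param_sampler(model))
}
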