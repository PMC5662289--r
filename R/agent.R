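#' Pairwise softmax choice probability
#'
#' The probability of choosing the first of two options under a logit
#' (softmax) rule on the value difference:
#' `1 / (1 + exp(-beta * (v_chosen - v_unchosen)))`. This single rule is
#' shared by the simulated agent and by every observer model's self-choice
#' policy.
#'
#' @param v_chosen,v_unchosen option values (vectorized).
#' @param beta exploitation intensity (inverse temperature), strictly
#'   positive.
#' @return probability (or vector of probabilities) of choosing the first
#'   option.
#' @examples
#' softmax_pair_prob(1, 0, 2)  # 1/(1 + exp(-2))
#' @export
softmax_pair_prob <- function(v_chosen, v_unchosen, beta) {
  if (!is.numeric(beta) || any(beta <= 0))
    stop("`beta` must be strictly positive")
  plogis(beta * (v_chosen - v_unchosen))
}

#' Agent choice and value update rules
#'
#' The two primitives of the simulated agent: a softmax choice between the
#' two displayed machines, and a prediction-error value update of the chosen
#' machine after its outcome is revealed,
#' `V_chosen <- V_chosen + alpha * (outcome_code - V_chosen)` (other machines
#' untouched). Outcome codes run from 1 to 3 with increasing preference.
#'
#' @param values numeric vector of machine values.
#' @param pair indices (into `values`) of the two displayed machines.
#' @param beta exploitation intensity (> 0).
#' @param seed optional integer seed.
#' @return `agent_choose`: the index of the chosen machine.
#' @export
agent_choose <- function(values, pair, beta, seed = NULL) {
  if (length(pair) != 2L || anyNA(values[pair]))
    stop("`pair` must index two machines in the set")
  p_first <- softmax_pair_prob(values[pair[1]], values[pair[2]], beta)
  with_seed(seed, if (runif(1) < p_first) pair[1] else pair[2])
}

#' @rdname agent_choose
#' @param chosen index of the chosen machine.
#' @param outcome_code scalar outcome code in `{1, 2, 3}`.
#' @param alpha learning rate in \[0, 1\].
#' @return `agent_update`: the updated value vector.
#' @export
agent_update <- function(values, chosen, outcome_code, alpha) {
  if (!outcome_code %in% 1:3) stop("`outcome_code` must be 1, 2 or 3")
  if (is.na(values[chosen])) stop("`chosen` must index a machine in the set")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  values[chosen] <- values[chosen] + alpha * (outcome_code - values[chosen])
  values
}

#' Simulate the observed agent's session
#'
#' The agent is a softmax prediction-error learner over machine values: values
#' start flat at 1/3 per machine, choices are softmax on the value difference
#' of the displayed pair, and after each revealed outcome the chosen machine's
#' value moves toward the outcome's scalar code by a fraction `alpha`.
#' Outcomes are coded by increasing preference from 1 to 3, i.e.
#' `code = 4 - rank` for preference rank 1..3. The agent sees its outcomes;
#' the observer never does, so the log records outcomes as hidden bookkeeping
#' only. Agent behavior does not depend on the condition: the same learner is
#' simulated for similar and dissimilar sessions.
#'
#' Self-choice trials are left unfilled for an observer model (see
#' [observer_simulate()]).
#'
#' @param machines a [slot_machines()] object.
#' @param schedule a [build_schedule()] trial schedule.
#' @param alpha agent learning rate in \[0, 1\].
#' @param beta_agent agent exploitation intensity (> 0).
#' @param condition "similar" or "dissimilar" (label + observer profile).
#' @param agent_profile,observer_profile [preference_profile()] objects;
#'   defaults build the agent profile over outcomes `o1..o3` and mirror or
#'   copy it for the observer according to `condition`.
#' @param seed optional integer seed.
#' @return A `session_log` with agent trials filled.
#' @examples
#' s <- simulate_agent_session(slot_machines(), build_schedule(seed = 1), seed = 2)
#' choice_ratio(s, "agent")
#' @export
simulate_agent_session <- function(machines = slot_machines(),
                                   schedule = build_schedule(),
                                   alpha = 0.3, beta_agent = 3,
                                   condition = c("similar", "dissimilar"),
                                   agent_profile = NULL,
                                   observer_profile = NULL,
                                   seed = NULL) {
  condition <- match.arg(condition)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (beta_agent <= 0) stop("`beta_agent` must be strictly positive")
  if (is.null(agent_profile))
    agent_profile <- preference_profile("agent", machines$outcomes)
  if (is.null(observer_profile))
    observer_profile <- if (condition == "similar") similar_profile(agent_profile)
                        else dissimilar_profile(agent_profile)
  log <- new_session_log(schedule, condition, machines,
                         agent_profile, observer_profile)
  ids <- machines$machine_ids
  a <- match(log$machine_a, ids)
  b <- match(log$machine_b, ids)
  probs <- machines$true_probs
  check_simplex_rows(probs)
  with_seed(seed, {
    v <- rep(1 / 3, 3)
    for (t in seq_len(nrow(log))) {
      if (log$kind[t] != "agent") next
      ch <- agent_choose(v, c(a[t], b[t]), beta_agent)
      rank <- sample.int(3L, 1L, prob = probs[ch, ])
      v <- agent_update(v, ch, 4 - rank, alpha)
      log$chosen[t] <- ids[ch]
      log$outcome_rank[t] <- rank
    }
    attr(log, "agent_params") <- list(alpha = alpha, beta_agent = beta_agent)
    attr(log, "agent_values_final") <- setNames(v, ids)
    log
  })
}
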