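test_that("multiplicative belief update renormalizes and spares the unoffered row", {
  b <- matrix(1 / 3, 3, 3)
  up <- irl_update(b, 1, 2, c(0.9, 0.5, 0.1))
  expect_equal(up[1, ], c(0.9, 0.5, 0.1) / 1.5)            # (0.6, 1/3, 1/15)
  expect_equal(up[2, ], c(0.1, 0.5, 0.9) / 1.5)            # flipped constants
  expect_equal(up[3, ], b[3, ])                            # unoffered untouched
  # equal constants cancel after renormalization, for any k in (0,1)
  for (k in c(0.1, 0.5, 0.9))
    expect_equal(irl_update(up, 2, 3, rep(k, 3)), up)
  expect_error(irl_update(b, 1, 1, c(0.9, 0.5, 0.1)), "distinct")
  expect_error(irl_update(b, 1, 2, c(1.2, 0.5, 0.1)), "open interval")
})

test_that("belief rows stay on the simplex and strictly positive under random updates", {
  set.seed(3)
  b <- matrix(1 / 3, 3, 3)
  for (i in 1:1000) {
    pair <- sample(1:3, 2)
    b <- irl_update(b, pair[1], pair[2], runif(3, 0.01, 0.99))
    expect_lt(max(abs(rowSums(b) - 1)), 1e-10)
    expect_true(all(b > 0))
  }
})

test_that("expected machine values are belief-weighted preference values", {
  b <- matrix(1 / 3, 3, 3)
  expect_equal(irl_expected_values(b, c(3, 2, 1)), rep(2, 3))
  b[1, ] <- c(1, 0, 0)
  expect_equal(irl_expected_values(b, c(3, 2, 1))[1], 3)
  # dissimilar observer values the agent's best outcome least
  row <- c(0.9, 0.5, 0.1) / 1.5
  expect_equal(sum(row * c(1, 2, 3)), 0.6 * 1 + (1 / 3) * 2 + (1 / 15) * 3)
  expect_equal(irl_expected_values(rbind(row, row, row), c(1, 2, 3))[1],
               1.466667, tolerance = 1e-6)
})

test_that("KL update signal matches direct arithmetic and is asymmetric", {
  u <- rep(1 / 3, 3)
  expect_equal(irl_kl_signal(u, u), 0)
  post <- c(0.9, 0.5, 0.1) / 1.5
  oracle <- sum(post * log(post / u))    # independent term-by-term evaluation
  expect_equal(irl_kl_signal(u, post), oracle)
  expect_gt(oracle, 0)
  expect_false(isTRUE(all.equal(irl_kl_signal(u, post), irl_kl_signal(post, u))))
  expect_error(irl_kl_signal(c(0, 0.5, 0.5), c(0.2, 0.4, 0.4)), "zero mass")
})

test_that("imitation updates and inversion follow their stated arithmetic", {
  v <- rep(0.5, 3)
  expect_equal(imitation_update(v, 1, eta = 0.5)[1], 0.75)
  vc <- imitation_update(v, 1, 2, eta = 0.5, counterfactual = TRUE,
                         eta_unchosen = 0.5)
  expect_equal(vc, c(0.75, 0.25, 0.5))
  expect_equal(imitation_update(v, 2, eta = 0), v)
  expect_error(imitation_update(v, 1, eta = 0.5, counterfactual = TRUE),
               "eta_unchosen")
  # inversion fixed points
  x <- seq(0, 1, by = 0.1)
  expect_equal(imitation_invert(x, 0), x)
  expect_equal(imitation_invert(x, 1), 1 - x)
  expect_equal(imitation_invert(x, 0.5), rep(0.5, length(x)))
  expect_error(imitation_invert(1.2, 0.5), "0, 1")
})

test_that("rank-belief update agrees with an exhaustive Bayes oracle", {
  # independent enumeration of the 6 orderings, coded from scratch here
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  score <- function(p, m) 4 - match(m, p)
  oracle_update <- function(w, c, u, kappa) {
    lik <- vapply(perms, function(p)
      1 / (1 + exp(-kappa * (score(p, c) - score(p, u)))), numeric(1))
    w * lik / sum(w * lik)
  }
  w0 <- rep(1 / 6, 6)
  for (kappa in c(0.3, 1, 2.5)) {
    expect_equal(rank_belief_update(w0, 1, 2, kappa),
                 oracle_update(w0, 1, 2, kappa))
    w_mixed <- c(0.3, 0.05, 0.2, 0.15, 0.1, 0.2)
    expect_equal(rank_belief_update(w_mixed, 3, 1, kappa),
                 oracle_update(w_mixed, 3, 1, kappa))
  }
  # one observation of 1 over 2 puts majority mass on orderings ranking 1 above 2
  w1 <- rank_belief_update(w0, 1, 2, kappa = 1)
  above <- vapply(perms, function(p) match(1, p) < match(2, p), logical(1))
  expect_gt(sum(w1[above]), 0.5)
  # flat likelihood limit
  expect_equal(rank_belief_update(w0, 1, 2, kappa = 0), w0)
})

test_that("rank-belief policy matches brute-force expected scores and flips sign", {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  w <- c(0.3, 0.05, 0.2, 0.15, 0.1, 0.2)
  ms <- vapply(1:3, function(m)
    sum(w * vapply(perms, function(p) 4 - match(m, p), numeric(1))), numeric(1))
  beta <- 3
  expect_equal(rank_belief_policy(w, c(1, 2), beta),
               1 / (1 + exp(-beta * (ms[1] - ms[2]))))
  expect_equal(rank_belief_policy(rep(1 / 6, 6), c(2, 3), beta), 0.5)
  # concentrated belief: higher-ranked member preferred; flip reverses it
  wc <- c(1, 0, 0, 0, 0, 0)   # ordering 1 > 2 > 3
  expect_gt(rank_belief_policy(wc, c(1, 3), beta, flip = 1), 0.5)
  expect_lt(rank_belief_policy(wc, c(1, 3), beta, flip = -1), 0.5)
})

test_that("observer simulation honors update-cancellation, imitation limits and seeds", {
  ag <- simulate_agent_session(schedule = build_schedule(seed = 20), seed = 21)
  # equal eps: beliefs never leave uniform, so every self choice is at chance
  obs <- observer_simulate("inverse_rl", list(eps = rep(0.4, 3), beta = 8),
                           ag, seed = 22)
  expect_equal(nll_self_choices("inverse_rl", list(eps = rep(0.4, 3), beta = 8),
                                obs), 50 * log(2))
  # pure imitation at near-deterministic beta copies the agent's majority
  # choice within each pair: agent block with clear majorities, then self
  # probes of every pair
  sch <- data.frame(trial = 1:33,
                    kind = c(rep("agent", 30), rep("self", 3)),
                    machine_a = c(rep(c("M1", "M1", "M2"), 10),
                                  "M1", "M1", "M2"),
                    machine_b = c(rep(c("M2", "M3", "M3"), 10),
                                  "M2", "M3", "M3"))
  ap <- preference_profile("agent", c("o1", "o2", "o3"))
  hand <- obsirl:::new_session_log(sch, "similar", default_machines, ap,
                                   similar_profile(ap))
  # agent chose M1 in 18/20 of its pairs, M2 in 8/10 of (M2, M3)
  hand$chosen[1:30] <- rep(c("M1", "M1", "M2"), 10)
  hand$chosen[c(3, 6)] <- "M3"
  hand$chosen[c(10, 22)] <- "M2"
  hand$outcome_rank[1:30] <- 1L
  obs_im <- observer_simulate("imitation",
                              list(eta = 0.1, theta = 0, beta = 22),
                              hand, seed = 23)
  expect_equal(obs_im$chosen[31:33], c("M1", "M1", "M2"))
  expect_identical(
    as.data.frame(observer_simulate("imitation",
                                    list(eta = 0.3, theta = 0.7, beta = 5),
                                    ag, seed = 9)),
    as.data.frame(observer_simulate("imitation",
                                    list(eta = 0.3, theta = 0.7, beta = 5),
                                    ag, seed = 9)))
  expect_error(observer_simulate("not_a_model", list(beta = 3), ag),
               "should be one of")
})

test_that("trial signals: KL positivity, value bounds, condition-invariant agent values", {
  params <- list(eps = c(0.9, 0.5, 0.1), beta = 6)
  sch <- build_schedule(seed = 30)
  ag_sim <- simulate_agent_session(schedule = sch, condition = "similar",
                                   seed = 31)
  ag_dis <- simulate_agent_session(schedule = sch, condition = "dissimilar",
                                   seed = 31)
  # identical agent behavior across conditions (condition never touches the agent)
  expect_identical(ag_sim$chosen, ag_dis$chosen)

  o_sim <- observer_simulate("inverse_rl", params, ag_sim, seed = 32)
  o_dis <- observer_simulate("inverse_rl", params, ag_dis, seed = 32)
  sig_s <- trial_signals(o_sim)
  sig_d <- trial_signals(o_dis)
  agent_rows <- sig_s$kind == "agent"
  # agent-space value trajectories identical across conditions
  expect_equal(sig_s$value_agent_chosen[agent_rows],
               sig_d$value_agent_chosen[agent_rows])
  expect_equal(sig_s$value_agent_unchosen[agent_rows],
               sig_d$value_agent_unchosen[agent_rows])
  expect_equal(sig_s$kl_update[agent_rows], sig_d$kl_update[agent_rows])
  # KL signal strictly positive whenever the chosen row moved (eps not all equal)
  expect_true(all(sig_s$kl_update[agent_rows] > 0))
  # values bounded by the span of the relevant preference values
  expect_true(all(sig_s$value_agent_chosen[agent_rows] >= 1 - 1e-9 &
                  sig_s$value_agent_chosen[agent_rows] <= 3 + 1e-9))
  self_rows <- sig_d$kind == "self"
  expect_true(all(sig_d$value_self_chosen[self_rows] >= 1 - 1e-9 &
                  sig_d$value_self_chosen[self_rows] <= 3 + 1e-9))
  # KL is zero iff the update left the chosen row unchanged
  o_flat <- observer_simulate("inverse_rl", list(eps = rep(0.5, 3), beta = 6),
                              ag_sim, seed = 33)
  expect_equal(max(abs(trial_signals(o_flat)$kl_update), na.rm = TRUE), 0)
  # signals export round-trips to CSV
  dir <- withr::local_tempdir()
  f <- write_trial_signals(sig_s, file.path(dir, "sig.csv"),
                           model = "inverse_rl", params = params)
  expect_equal(nrow(read.csv(f)), nrow(sig_s))
})
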