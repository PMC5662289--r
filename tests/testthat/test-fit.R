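test_that("self-choice NLL matches closed forms and a hand-chained oracle", {
  s <- make_session(seed = 40)
  # any uniform policy over 50 self trials
  expect_equal(nll_self_choices("inverse_rl",
                                list(eps = rep(0.7, 3), beta = 5), s),
               50 * log(2))
  expect_equal(nll_self_choices("imitation",
                                list(eta = 0.4, theta = 0.5, beta = 5), s),
               50 * log(2))

  # hand-chained probabilities on the 6-trial fixture, imitation model
  hs <- hand_session()
  eta <- 0.4; theta <- 0.2; beta <- 3
  v <- rep(0.5, 3)
  inv <- function(v) (1 - theta) * v + theta * (1 - v)
  p <- function(i, j) 1 / (1 + exp(-beta * (inv(v)[i] - inv(v)[j])))
  v[1] <- v[1] + eta * (1 - v[1])              # trial 1: agent chose M1
  p2 <- p(1, 3)                                # trial 2: self chose M1 vs M3
  v[2] <- v[2] + eta * (1 - v[2])              # trial 3: agent chose M2
  p4 <- 1 - p(2, 3)                            # trial 4: self chose M3 of (M2,M3)
  v[1] <- v[1] + eta * (1 - v[1])              # trial 5: agent chose M1
  p6 <- p(1, 2)                                # trial 6: self chose M1 vs M2
  expect_equal(nll_self_choices("imitation",
                                list(eta = eta, theta = theta, beta = beta), hs),
               -(log(p2) + log(p4) + log(p6)))
  expect_error(nll_self_choices("imitation", list(eta = 1.5, theta = 0, beta = 3),
                                hs), "\\[0, 1\\]")
})

test_that("BIC arithmetic and monotonicity", {
  expect_equal(bic(50 * log(2), 2, 50), 100 * log(2) + 2 * log(50))
  expect_equal(bic(50 * log(2), 2, 50), 77.138, tolerance = 1e-4)
  expect_equal(bic(10, 0, 50), 20)
  ks <- 0:5
  expect_true(all(diff(vapply(ks, function(k) bic(10, k, 50), numeric(1))) > 0))
  expect_error(bic(10, 2, 0), "at least 1")
})

test_that("ML fitting is optimal on the box, deterministic, and flags failure", {
  gen <- list(eta = 0.5, theta = 0.9, beta = 8)
  ag <- simulate_agent_session(schedule = build_schedule(seed = 50),
                               condition = "dissimilar", seed = 51)
  obs <- observer_simulate("imitation", gen, ag, seed = 52)
  f1 <- fit_observer(obs, "imitation", seed = 53)
  f2 <- fit_observer(obs, "imitation", seed = 53)
  expect_identical(coef(f1), coef(f2))
  # optimality: at least as good as the generating parameters
  expect_lte(f1$nll, nll_self_choices("imitation", gen, obs) + 1e-6)
  # direction: strongly inverting generator recovered as theta > 0.5
  expect_gt(coef(f1)["theta"], 0.5)
  expect_equal(f1$bic, 2 * f1$nll + 3 * log(50))
  expect_equal(f1$nll, min(f1$start_nlls, na.rm = TRUE))
  # logLik bridge
  ll <- logLik(f1)
  expect_equal(as.numeric(ll), -f1$nll)
  expect_equal(attr(ll, "df"), f1$k)
  expect_equal(stats::BIC(f1), f1$bic)
})

test_that("NLL at the optimum never increases when the box widens", {
  obs <- make_session(seed = 60, model = "imitation",
                      params = list(eta = 0.5, theta = 0.8, beta = 15))
  narrow <- fit_observer(obs, "imitation", seed = 61,
                         lower = c(0.2, 0.2, 4), upper = c(0.8, 0.8, 12))
  mid <- fit_observer(obs, "imitation", seed = 61,
                      lower = c(0.1, 0.1, 3), upper = c(0.9, 0.9, 18))
  wide <- fit_observer(obs, "imitation", seed = 61)
  expect_lte(mid$nll, narrow$nll + 1e-6)
  expect_lte(wide$nll, mid$nll + 1e-6)
})

test_that("integer forgetting windows are fitted by candidate iteration", {
  obs <- make_session(seed = 70)
  f <- fit_observer(obs, "inverse_rl", seed = 71, decay = c(5L, 100L))
  expect_true(f$decay %in% c(5L, 100L))
  expect_equal(f$k, 5L)  # decay counts as an extra parameter
  expect_error(fit_observer(obs, "imitation", decay = 10L), "inverse-RL")
  expect_error(fit_observer(obs, "inverse_rl", decay = 150L), "\\[1, 100\\]")
  # a short window actually restricts the beliefs that drive the likelihood
  p_full <- nll_self_choices("inverse_rl",
                             list(eps = c(0.9, 0.5, 0.1), beta = 6), obs)
  p_win <- nll_self_choices("inverse_rl",
                            list(eps = c(0.9, 0.5, 0.1), beta = 6, decay = 3L),
                            obs)
  expect_false(isTRUE(all.equal(p_full, p_win)))
})

test_that("fit methods: predict, residuals, simulate round-trip", {
  obs <- make_session(seed = 80, n_agent = 40, n_self = 20)
  f <- fit_observer(obs, "inverse_rl", seed = 81)
  pr <- predict(f)
  expect_equal(nrow(pr), 20L)
  expect_true(all(pr$prob_a >= 0 & pr$prob_a <= 1))
  expect_equal(pr$prob_a + pr$prob_b, rep(1, 20))
  expect_equal(-sum(log(pmax(pr$prob_chosen, 1e-12))), f$nll, tolerance = 1e-8)
  expect_length(residuals(f), 20L)
  sims <- simulate(f, nsim = 2, seed = 82)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "session_log")
  expect_false(anyNA(sims[[1]]$chosen[sims[[1]]$kind == "self"]))
})
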