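test_that("referential reordering sorts machines by actor-specific expected value", {
  m <- default_machines
  ap <- preference_profile("agent", c("o1", "o2", "o3"))
  ratios <- c(M1 = 0.7, M2 = 0.5, M3 = 0.2)
  # similar observer: same ordering as the agent
  expect_equal(referential_reorder(ratios, similar_profile(ap), m),
               c(M1 = 0.7, M2 = 0.5, M3 = 0.2))
  # dissimilar observer: exactly reversed on the default (monotone) matrix
  expect_equal(referential_reorder(ratios, dissimilar_profile(ap), m),
               c(M3 = 0.2, M2 = 0.5, M1 = 0.7))
  # hand-built matrix where the mid machine swaps position across spaces;
  # oracle: brute-force expected-value sort
  probs <- matrix(c(0.7, 0.0, 0.3,
                    0.1, 0.8, 0.1,
                    0.2, 0.2, 0.6), 3, 3, byrow = TRUE)
  mm <- slot_machines(probs)
  for (prof in list(similar_profile(ap), dissimilar_profile(ap))) {
    v <- prof$values[match(mm$outcomes, prof$ranking)]
    ev <- as.vector(probs %*% v)
    oracle_order <- mm$machine_ids[order(-ev, mm$machine_ids)]
    expect_equal(names(referential_reorder(ratios, prof, mm)), oracle_order)
  }
  # ties broken deterministically by label, with a message
  tied <- slot_machines(matrix(1 / 3, 3, 3))
  expect_message(out <- referential_reorder(ratios, ap, tied), "ties")
  expect_equal(names(out), c("M1", "M2", "M3"))
})

test_that("pooled agent-observer Spearman matches a hand rank computation", {
  ag <- simulate_agent_session(schedule = build_schedule(30, 15, seed = 1),
                               seed = 2)
  cohort <- lapply(1:3, function(i)
    observer_simulate("inverse_rl", list(eps = c(0.9, 0.5, 0.1), beta = 8),
                      ag, seed = 10 + i))
  rs <- spearman_agent_observer(cohort)
  # independent rank-and-correlate computation
  obs <- unlist(lapply(cohort, function(s)
    referential_reorder(choice_ratio(s, "self"),
                        attr(s, "observer_profile"), attr(s, "machines"))))
  agf <- unlist(lapply(cohort, function(s)
    referential_reorder(choice_ratio(s, "agent"),
                        attr(s, "agent_profile"), attr(s, "machines"))))
  expect_equal(as.numeric(rs), cor(rank(obs), rank(agf)))
  expect_equal(attr(rs, "n_pairs"), 9L)
  expect_error(spearman_agent_observer(cohort[1]), "2 subjects")

  # perfect concordance / discordance through hand-built ratio patterns:
  # self choices mimicking the agent's per-pair majorities give rs = 1,
  # exactly reversed self choices give rs = -1
  hs1 <- hand_session()
  hs1$chosen[4] <- "M2"       # self ratios (1, 0.5, 0) == agent ratios
  expect_equal(as.numeric(spearman_agent_observer(list(hs1, hs1))), 1)
  hs2 <- hand_session()
  hs2$chosen[c(2, 4, 6)] <- c("M3", "M3", "M2")  # self ratios (0, 0.5, 1)
  expect_equal(as.numeric(spearman_agent_observer(list(hs2, hs2))), -1)
})

test_that("Fisher comparison of correlations has its closed-form behavior", {
  expect_equal(fisher_compare(0.5, 0.5, 40, 40)$p, 0.5)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  z <- fisher_compare(0.7, 0.6, 40, 40)$z
  expect_equal(z, (atanh(0.7) - atanh(0.6)) / sqrt(2 / 37))
  # p decreases monotonically as the gap grows
  ps <- vapply(c(0.6, 0.7, 0.8, 0.9), function(r)
    fisher_compare(r, 0.5, 40, 40)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_compare(1, 0.5, 40, 40), "diverges")
  expect_error(fisher_compare(0.5, 0.4, 3, 40), "at least 4")
})

test_that("plateau ratios window the session correctly", {
  s <- make_session(seed = 90)
  expect_equal(plateau_ratios(s, cutoff = 1), choice_ratio(s, "self"))
  expect_error(plateau_ratios(s, cutoff = 151), "empty")
  # mid-session behavioral switch: late window sees only post-switch choices
  hs <- hand_session()
  late <- plateau_ratios(hs, cutoff = 4)
  # brute force over trials 4-6: self trials 4 (chose M3 of M2,M3) and 6
  # (chose M1 of M1,M2)
  expect_equal(late, c(M1 = 1, M2 = 0, M3 = 1))
})

test_that("SI index anchors, oracle arithmetic and symmetry", {
  # identical ordered distributions => SI = 1; disjoint support => SI = 0
  # via js divergence on the underlying helper
  jsd <- obsirl:::js_divergence2
  expect_equal(jsd(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 0)
  expect_equal(jsd(c(1, 0, 0), c(0, 0, 1)), 1)
  # term-by-term oracle for the stated example pair
  p <- c(0.6, 0.3, 0.1); q <- c(0.5, 0.3, 0.2)
  m <- (p + q) / 2
  oracle <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m))
  expect_equal(jsd(p, q), oracle)
  expect_equal(jsd(q, p), oracle)   # symmetric
  # end-to-end SI on a session whose self choices exactly mirror the agent's
  hs <- hand_session()
  expect_lte(si_index(hs), 1)
  expect_gte(si_index(hs), 0)
})

test_that("SI separates inference from mimicry under a dissimilar agent", {
  irl_si <- vapply(1:12, function(i) {
    ag <- simulate_agent_session(schedule = build_schedule(seed = 100 + i),
                                 condition = "dissimilar", seed = 200 + i)
    si_index(observer_simulate("inverse_rl",
                               list(eps = c(0.9, 0.5, 0.1), beta = 8),
                               ag, seed = 300 + i))
  }, numeric(1))
  mimic_si <- vapply(1:12, function(i) {
    ag <- simulate_agent_session(schedule = build_schedule(seed = 100 + i),
                                 condition = "dissimilar", seed = 200 + i)
    si_index(observer_simulate("imitation",
                               list(eta = 0.4, theta = 0, beta = 8),
                               ag, seed = 300 + i))
  }, numeric(1))
  expect_gt(mean(irl_si), mean(mimic_si))
  expect_true(all(irl_si >= 0 & irl_si <= 1))
  expect_true(all(mimic_si >= 0 & mimic_si <= 1))
})

test_that("SI correlates positively with the mid-over-worst choice tendency", {
  # heterogeneous observers in the dissimilar condition
  set.seed(7)
  res <- t(vapply(1:30, function(i) {
    eps <- sort(runif(3, 0.05, 0.95), decreasing = TRUE)
    ag <- simulate_agent_session(schedule = build_schedule(seed = 400 + i),
                                 condition = "dissimilar", seed = 500 + i)
    s <- observer_simulate("inverse_rl",
                           list(eps = eps, beta = runif(1, 2, 22)),
                           ag, seed = 600 + i)
    at <- obsirl:::session_attrs(s)
    ord <- names(referential_reorder(
      c(M1 = 1, M2 = 2, M3 = 3)[at$machines$machine_ids],
      at$observer_profile, at$machines))
    mid <- ord[2]; worst <- ord[3]
    sr <- s[s$kind == "self", ]
    mw <- sr[(sr$machine_a == mid & sr$machine_b == worst) |
             (sr$machine_a == worst & sr$machine_b == mid), ]
    c(si = si_index(s), mid_over_worst = mean(mw$chosen == mid))
  }, numeric(2)))
  keep <- stats::complete.cases(res)
  expect_gt(cor(res[keep, "si"], res[keep, "mid_over_worst"],
                method = "spearman"), 0)
})
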