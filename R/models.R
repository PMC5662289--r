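#' Approximate inverse-RL belief update
#'
#' The observer tracks a 3x3 matrix of posterior-mean outcome probabilities
#' (rows: machines; columns: outcomes in agent preference-rank order). When
#' the agent is seen choosing `chosen` over `unchosen`, the chosen machine's
#' row is multiplied elementwise by the updating constants
#' `eps = (eps1, eps2, eps3)` and renormalized to the simplex; the unchosen
#' machine's row is multiplied by the *reversed* vector `(eps3, eps2, eps1)`
#' and renormalized. The machine not offered on that trial is left untouched.
#' With monotonically decreasing `eps` this shifts the chosen machine's belief
#' mass toward the agent's preferred outcomes and the unchosen machine's mass
#' away from them.
#'
#' Renormalization keeps each row a probability vector; because of it, scaling
#' all three constants by a common factor leaves the update unchanged — only
#' the ratios of the `eps` are identified (see the methods vignette).
#'
#' @param beliefs 3x3 matrix of row-stochastic outcome beliefs.
#' @param chosen,unchosen row indices (or machine labels if `beliefs` has
#'   rownames) of the chosen and unchosen machine.
#' @param eps numeric vector of 3 updating constants, each in (0, 1).
#' @return the updated belief matrix.
#' @examples
#' b <- matrix(1/3, 3, 3)
#' irl_update(b, 1, 2, c(0.9, 0.5, 0.1))
#' @export
irl_update <- function(beliefs, chosen, unchosen, eps) {
  if (length(eps) != 3L || any(eps <= 0) || any(eps >= 1))
    stop("`eps` must be 3 constants in the open interval (0, 1)")
  if (is.character(chosen)) chosen <- match(chosen, rownames(beliefs))
  if (is.character(unchosen)) unchosen <- match(unchosen, rownames(beliefs))
  if (is.na(chosen) || is.na(unchosen) || chosen == unchosen)
    stop("`chosen` and `unchosen` must be two distinct machines")
  rc <- beliefs[chosen, ] * eps
  beliefs[chosen, ] <- rc / sum(rc)
  ru <- beliefs[unchosen, ] * rev(eps)
  beliefs[unchosen, ] <- ru / sum(ru)
  beliefs
}

#' Expected machine values under outcome beliefs
#'
#' Machine values are the outcome beliefs weighted by a preference-value
#' vector: `V(m) = sum_i beliefs[m, i] * values[i]`. Called with the agent's
#' values this gives agent-referential expectations (the trial-wise value
#' regressor); called with the observer's own values (mapped through the
#' condition's outcome-identity correspondence) it drives self choices.
#'
#' @param beliefs 3x3 row-stochastic belief matrix.
#' @param values numeric preference-value vector of length 3 (by agent
#'   preference rank).
#' @return numeric vector of 3 machine values.
#' @export
irl_expected_values <- function(beliefs, values) {
  if (length(values) != 3L) stop("`values` must have length 3")
  as.vector(beliefs %*% values)
}

#' KL-divergence belief-update signal
#'
#' The learning signal attached to an observed agent choice: the
#' Kullback-Leibler divergence, in nats, between the posterior and prior
#' outcome distribution of the chosen machine,
#' `D_KL(posterior || prior) = sum_i post_i * log(post_i / prior_i)`.
#'
#' @param prior_row,posterior_row probability vectors on the 3-simplex;
#'   the prior must be strictly positive wherever the posterior is (the
#'   multiplicative update with eps in (0,1) preserves strict positivity).
#' @return nonnegative scalar divergence in nats.
#' @export
irl_kl_signal <- function(prior_row, posterior_row) {
  check_simplex_rows(rbind(prior_row, posterior_row))
  if (any(prior_row <= 0 & posterior_row > 0))
    stop("prior has zero mass where the posterior is positive")
  pos <- posterior_row > 0
  sum(posterior_row[pos] * log(posterior_row[pos] / prior_row[pos]))
}

#' Imitation value update
#'
#' Imitation RL learns a value per machine directly from the agent's choice
#' frequencies. Values start at 0.5 per machine. When the agent's choice is
#' revealed, the chosen machine's value moves toward 1 by prediction error:
#' `V <- V + eta * (1 - V)`. The counterfactual variant additionally decays
#' the unchosen (but offered) machine's value toward 0 with its own learning
#' rate: `V <- V + eta_unchosen * (0 - V)`. The unoffered machine is
#' untouched.
#'
#' @param values numeric vector of 3 machine values in \[0, 1\].
#' @param chosen,unchosen indices of the chosen / unchosen machine.
#' @param eta learning rate in \[0, 1\].
#' @param counterfactual if `TRUE`, also update the unchosen machine.
#' @param eta_unchosen counterfactual learning rate in \[0, 1\]; required when
#'   `counterfactual` is `TRUE`.
#' @return updated value vector.
#' @export
imitation_update <- function(values, chosen, unchosen = NULL, eta,
                             counterfactual = FALSE, eta_unchosen = NULL) {
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]")
  values[chosen] <- values[chosen] + eta * (1 - values[chosen])
  if (counterfactual) {
    if (is.null(eta_unchosen))
      stop("counterfactual update requires `eta_unchosen`")
    if (is.null(unchosen)) stop("counterfactual update requires `unchosen`")
    if (eta_unchosen < 0 || eta_unchosen > 1)
      stop("`eta_unchosen` must lie in [0, 1]")
    values[unchosen] <- values[unchosen] + eta_unchosen * (0 - values[unchosen])
  }
  values
}

#' Imitation inversion for self choices
#'
#' On self-choice trials the imitation learner can invert its learned values
#' according to how dissimilar it believes the agent's preferences to be:
#' `V_self = (1 - theta) * V_obs + theta * (1 - V_obs)`. `theta = 0` keeps the
#' agent's value function (pure imitation), `theta = 1` fully inverts it, and
#' `theta = 0.5` collapses every value to 0.5.
#'
#' @param v_obs observational value(s) in \[0, 1\] (vectorized).
#' @param theta inversion parameter in \[0, 1\].
#' @return inverted value(s) in \[0, 1\].
#' @export
imitation_invert <- function(v_obs, theta) {
  if (any(v_obs < 0) || any(v_obs > 1)) stop("`v_obs` must lie in [0, 1]")
  if (theta < 0 || theta > 1) stop("`theta` must lie in [0, 1]")
  (1 - theta) * v_obs + theta * (1 - v_obs)
}

# The 6 strict orderings of 3 machines; row = ordering, entry = machine index
# by rank (best first). Score of machine m under ordering p is 4 - rank.
rank_orderings <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  scores <- matrix(0, 6, 3)
  for (p in 1:6) scores[p, perms[p, ]] <- c(3, 2, 1)  # 4 - rank
  list(perms = perms, scores = scores)
}

#' Preference-ranking learner: belief update and policy
#'
#' An alternative observer who tracks a probability distribution over the six
#' strict preference orderings of the three machines, without modeling outcome
#' distributions at all. Seeing the agent choose `chosen` over `unchosen`
#' reweights each ordering by the softmax likelihood of that choice under the
#' ordering's rank scores (`score = 4 - rank`, sharpness `kappa`):
#' `belief(p) <- belief(p) * plogis(kappa * (s_p(chosen) - s_p(unchosen)))`,
#' then renormalizes (Bayes rule with a softmax likelihood). The self-choice
#' policy scores each machine by its belief-averaged rank score, multiplied by
#' the condition orientation `flip` (+1 when the agent is similar, -1 when
#' dissimilar), and chooses by pairwise softmax with intensity `beta`.
#'
#' @param belief probability vector over the 6 orderings (rows of
#'   `rank_orderings()$perms`); initialized uniform at 1/6.
#' @param chosen,unchosen machine indices in 1..3.
#' @param kappa evidence sharpness (> 0, 0 allowed as the flat-likelihood
#'   limit).
#' @return `rank_belief_update`: the renormalized posterior belief vector.
#' @export
rank_belief_update <- function(belief, chosen, unchosen, kappa) {
  if (kappa < 0) stop("`kappa` must be nonnegative")
  sc <- rank_orderings()$scores
  lik <- plogis(kappa * (sc[, chosen] - sc[, unchosen]))
  post <- belief * lik
  post / sum(post)
}

#' @rdname rank_belief_update
#' @param pair integer vector of 2 machine indices on offer.
#' @param beta self-choice exploitation intensity (> 0).
#' @param flip orientation in `{+1, -1}`: +1 seeks the agent's preferred
#'   machines (similar agent), -1 avoids them (dissimilar agent).
#' @return `rank_belief_policy`: probability of choosing `pair[1]`.
#' @export
rank_belief_policy <- function(belief, pair, beta, flip = 1) {
  if (!flip %in% c(-1, 1)) stop("`flip` must be +1 or -1")
  sc <- rank_orderings()$scores
  ms <- flip * as.vector(belief %*% sc)
  softmax_pair_prob(ms[pair[1]], ms[pair[2]], beta)
}
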