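# Canonical observer models. Each replays the agent trials of a session in
# order to drive its internal state and emits a self-choice policy; the same
# engine backs the likelihood, generative simulation and signal export.

OBSERVER_MODELS <- c("inverse_rl", "imitation", "imitation_cf", "rank_learner")

check_observer_params <- function(model, params) {
  model <- match.arg(model, OBSERVER_MODELS)
  p <- as.list(params)
  need <- function(nm) {
    if (is.null(p[[nm]])) stop("model '", model, "' requires parameter `", nm, "`")
    p[[nm]]
  }
  if (is.null(p$beta) || p$beta <= 0) stop("`beta` must be strictly positive")
  switch(model,
    inverse_rl = {
      eps <- need("eps")
      if (length(eps) != 3L || any(eps <= 0) || any(eps >= 1))
        stop("`eps` must be 3 constants in (0, 1)")
      if (!is.null(p$decay)) {
        d <- p$decay
        if (length(d) != 1L || d != round(d) || d < 1 || d > 100)
          stop("`decay` must be a single integer in [1, 100]")
      }
    },
    imitation = {
      th <- need("theta"); et <- need("eta")
      if (et < 0 || et > 1) stop("`eta` must lie in [0, 1]")
      if (th < 0 || th > 1) stop("`theta` must lie in [0, 1]")
    },
    imitation_cf = {
      th <- need("theta"); et <- need("eta"); eu <- need("eta_unchosen")
      if (et < 0 || et > 1) stop("`eta` must lie in [0, 1]")
      if (eu < 0 || eu > 1) stop("`eta_unchosen` must lie in [0, 1]")
      if (th < 0 || th > 1) stop("`theta` must lie in [0, 1]")
    },
    rank_learner = {
      k <- need("kappa")
      if (k < 0) stop("`kappa` must be nonnegative")
    })
  p
}

# Replay a session under an observer model. Belief/value state is driven by
# the observed agent choices only; self-choice trials read the policy without
# touching the state, so self-choice probabilities do not depend on the
# observer's own (possibly unrecorded) choices.
#
# Returns per-trial policy probabilities for machine_a on self trials, the
# model's option values on every trial, and the KL update signal on agent
# trials (inverse RL only).
observer_replay <- function(model, params, session, signals = FALSE) {
  model <- match.arg(model, OBSERVER_MODELS)
  p <- check_observer_params(model, params)
  at <- session_attrs(session)
  ids <- at$machines$machine_ids
  a <- match(session$machine_a, ids)
  b <- match(session$machine_b, ids)
  is_agent <- session$kind == "agent"
  ch <- match(session$chosen, ids)
  if (any(is_agent & is.na(ch)))
    stop("agent trials must have recorded choices")
  n <- nrow(session)
  va <- at$agent_profile$values
  vs <- profile_column_values(at$observer_profile, at$machines)
  p_a <- rep(NA_real_, n)
  v_first <- rep(NA_real_, n)   # model value of machine_a (self) / chosen (agent)
  v_second <- rep(NA_real_, n)  # machine_b (self) / unchosen (agent)
  kl <- rep(NA_real_, n)

  if (model == "inverse_rl") {
    beliefs <- matrix(1 / 3, 3, 3)
    eps <- p$eps
    reps <- rev(eps)
    decay <- p$decay
    hist_c <- integer(0); hist_u <- integer(0)
    for (t in seq_len(n)) {
      if (is_agent[t]) {
        c_t <- ch[t]
        u_t <- if (a[t] == c_t) b[t] else a[t]
        vag <- beliefs %*% va
        v_first[t] <- vag[c_t]; v_second[t] <- vag[u_t]
        prior <- beliefs[c_t, ]
        if (is.null(decay)) {
          rc <- beliefs[c_t, ] * eps
          beliefs[c_t, ] <- rc / sum(rc)
          ru <- beliefs[u_t, ] * reps
          beliefs[u_t, ] <- ru / sum(ru)
        } else {
          hist_c <- c(hist_c, c_t); hist_u <- c(hist_u, u_t)
          from <- max(1L, length(hist_c) - as.integer(decay) + 1L)
          beliefs <- matrix(1 / 3, 3, 3)
          for (j in from:length(hist_c)) {
            rc <- beliefs[hist_c[j], ] * eps
            beliefs[hist_c[j], ] <- rc / sum(rc)
            ru <- beliefs[hist_u[j], ] * reps
            beliefs[hist_u[j], ] <- ru / sum(ru)
          }
        }
        if (signals) {
          post <- beliefs[c_t, ]
          kl[t] <- sum(post * log(post / prior))
        }
      } else {
        vs_all <- beliefs %*% vs
        v_first[t] <- vs_all[a[t]]; v_second[t] <- vs_all[b[t]]
        p_a[t] <- plogis(p$beta * (v_first[t] - v_second[t]))
      }
    }
  } else if (model %in% c("imitation", "imitation_cf")) {
    v <- rep(0.5, 3)
    cf <- model == "imitation_cf"
    for (t in seq_len(n)) {
      if (is_agent[t]) {
        c_t <- ch[t]
        u_t <- if (a[t] == c_t) b[t] else a[t]
        v_first[t] <- v[c_t]; v_second[t] <- v[u_t]
        v[c_t] <- v[c_t] + p$eta * (1 - v[c_t])
        if (cf) v[u_t] <- v[u_t] + p$eta_unchosen * (0 - v[u_t])
      } else {
        vself <- (1 - p$theta) * v + p$theta * (1 - v)
        v_first[t] <- vself[a[t]]; v_second[t] <- vself[b[t]]
        p_a[t] <- plogis(p$beta * (v_first[t] - v_second[t]))
      }
    }
  } else { # rank_learner
    sc <- rank_orderings()$scores
    w <- rep(1 / 6, 6)
    flip <- if (identical(at$condition, "dissimilar")) -1 else 1
    for (t in seq_len(n)) {
      ms <- flip * as.vector(w %*% sc)
      if (is_agent[t]) {
        c_t <- ch[t]
        u_t <- if (a[t] == c_t) b[t] else a[t]
        v_first[t] <- ms[c_t]; v_second[t] <- ms[u_t]
        lik <- plogis(p$kappa * (sc[, c_t] - sc[, u_t]))
        w <- w * lik
        w <- w / sum(w)
      } else {
        v_first[t] <- ms[a[t]]; v_second[t] <- ms[b[t]]
        p_a[t] <- plogis(p$beta * (v_first[t] - v_second[t]))
      }
    }
  }
  list(p_a = p_a, v_first = v_first, v_second = v_second, kl = kl,
       is_agent = is_agent, a = a, b = b, chosen = ch, ids = ids)
}

#' Negative log-likelihood of recorded self choices
#'
#' Replays the session's agent trials to drive the observer model's state and
#' accumulates `-log P(recorded self choice)` over self-choice trials only
#' (agent trials carry no observer likelihood). Per-trial likelihoods are
#' floored at 1e-12 to guard against underflow at extreme parameter values.
#'
#' @param model one of `"inverse_rl"`, `"imitation"`, `"imitation_cf"`,
#'   `"rank_learner"`.
#' @param params named list of model parameters (see [fit_observer()] for the
#'   parameterization of each model).
#' @param session a `session_log` with agent trials and self choices recorded.
#' @return nonnegative scalar negative log-likelihood.
#' @export
nll_self_choices <- function(model, params, session) {
  rep_ <- observer_replay(model, params, session)
  sel <- which(!rep_$is_agent)
  if (length(sel) == 0L) stop("session contains no self-choice trials")
  ch <- rep_$chosen[sel]
  if (any(is.na(ch))) stop("self-choice trials lack recorded choices")
  p_a <- rep_$p_a[sel]
  p_choice <- ifelse(ch == rep_$a[sel], p_a, 1 - p_a)
  p_choice <- pmax(p_choice, 1e-12)
  -sum(log(p_choice))
}

#' Simulate an observer's self choices under a model
#'
#' The generative counterpart of each fitted model: replays the recorded
#' agent trials in order to drive the model's internal state, samples each
#' self choice from the model's softmax policy, and attaches the trial-wise
#' model signals (see [trial_signals()]).
#'
#' @inheritParams nll_self_choices
#' @param agent_log a `session_log` with agent trials filled (self choices
#'   are overwritten).
#' @param seed optional integer seed.
#' @return a `session_log` with self choices filled; the generating model,
#'   parameters and a `TrialSignals` data.frame are stored as attributes.
#' @examples
#' s <- simulate_agent_session(schedule = build_schedule(seed = 1), seed = 2)
#' obs <- observer_simulate("inverse_rl",
#'                          list(eps = c(0.9, 0.5, 0.1), beta = 6), s, seed = 3)
#' choice_ratio(obs, "self")
#' @export
observer_simulate <- function(model, params, agent_log, seed = NULL) {
  rep_ <- observer_replay(model, params, agent_log, signals = TRUE)
  sel <- which(!rep_$is_agent)
  out <- agent_log
  if (length(sel)) {
    draws <- with_seed(seed, runif(length(sel)))
    pick_a <- draws < rep_$p_a[sel]
    out$chosen[sel] <- ifelse(pick_a, out$machine_a[sel], out$machine_b[sel])
  }
  attr(out, "observer_model") <- model
  attr(out, "observer_params") <- as.list(params)
  attr(out, "signals") <- build_signals(rep_, out)
  out
}

# Assemble the TrialSignals table from a replay, using recorded choices to
# orient chosen/unchosen values on self trials.
build_signals <- function(rep_, session) {
  n <- length(rep_$is_agent)
  vsc <- rep(NA_real_, n); vsu <- rep(NA_real_, n)
  sel <- which(!rep_$is_agent)
  if (length(sel)) {
    ch <- match(session$chosen[sel], rep_$ids)
    picked_a <- ch == rep_$a[sel]
    vsc[sel] <- ifelse(picked_a, rep_$v_first[sel], rep_$v_second[sel])
    vsu[sel] <- ifelse(picked_a, rep_$v_second[sel], rep_$v_first[sel])
  }
  data.frame(trial = session$trial,
             kind = session$kind,
             condition = attr(session, "condition"),
             value_agent_chosen = ifelse(rep_$is_agent, rep_$v_first, NA_real_),
             value_agent_unchosen = ifelse(rep_$is_agent, rep_$v_second, NA_real_),
             kl_update = rep_$kl,
             value_self_chosen = vsc,
             value_self_unchosen = vsu)
}

#' Trial-wise model signals
#'
#' Per-trial model-derived quantities suitable as parametric regressors: on
#' agent-observation trials, the agent-referential expected value of the
#' chosen and unchosen machine (beliefs weighted by the *agent's* preference
#' values, taken at the moment of the observed choice) and, for the inverse-RL
#' model, the KL divergence between the chosen machine's posterior and prior
#' outcome distribution; on self-choice trials, the model's self-referential
#' values of the chosen and unchosen machine.
#'
#' @param session a `session_log`. If it was produced by
#'   [observer_simulate()], the stored signals are returned; otherwise
#'   `model` and `params` must be supplied and signals are recomputed from
#'   the recorded choices.
#' @inheritParams nll_self_choices
#' @return data.frame with columns `trial`, `kind`, `condition`,
#'   `value_agent_chosen`, `value_agent_unchosen`, `kl_update`,
#'   `value_self_chosen`, `value_self_unchosen`.
#' @export
trial_signals <- function(session, model = NULL, params = NULL) {
  if (is.null(model) && !is.null(attr(session, "signals")) && is.null(params))
    return(attr(session, "signals"))
  if (is.null(model)) model <- attr(session, "observer_model")
  if (is.null(params)) params <- attr(session, "observer_params")
  if (is.null(model) || is.null(params))
    stop("supply `model` and `params` for a session without stored signals")
  rep_ <- observer_replay(model, params, session, signals = TRUE)
  build_signals(rep_, session)
}

#' Export trial signals as a regressor CSV
#'
#' Writes the [trial_signals()] table to CSV with a JSON sidecar echoing the
#' model id and parameters, for consumption by downstream GLM software.
#'
#' @param signals a trial-signals data.frame.
#' @param file CSV path.
#' @param model,params model id and parameters to echo in the sidecar.
#' @param meta_file JSON sidecar path.
#' @return `file`, invisibly.
#' @export
write_trial_signals <- function(signals, file, model = NULL, params = NULL,
                                meta_file = paste0(file, ".json")) {
  write.csv(signals, file, row.names = FALSE)
  jsonlite::write_json(list(model = model, params = params),
                       meta_file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
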