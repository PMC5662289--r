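# Constraint boxes and BIC parameter counts (raw fitted parameters) per
# model. The rank learner's orientation is set by condition and is not a
# fitted parameter; its kappa starts are drawn log-uniformly because uniform
# draws mostly land on the saturated-likelihood plateau.
model_info <- function(model) {
  switch(match.arg(model, OBSERVER_MODELS),
    inverse_rl = list(
      par_names = c("eps1", "eps2", "eps3", "beta"),
      lower = c(1e-4, 1e-4, 1e-4, 2), upper = c(1 - 1e-4, 1 - 1e-4, 1 - 1e-4, 22),
      k_bic = 4L),
    imitation = list(
      par_names = c("eta", "theta", "beta"),
      lower = c(0, 0, 2), upper = c(1, 1, 22),
      k_bic = 3L),
    imitation_cf = list(
      par_names = c("eta", "eta_unchosen", "theta", "beta"),
      lower = c(0, 0, 0, 2), upper = c(1, 1, 1, 22),
      k_bic = 4L),
    rank_learner = list(
      par_names = c("kappa", "beta"),
      lower = c(1e-3, 2), upper = c(10, 22),
      k_bic = 2L))
}

par_to_params <- function(model, par, decay = NULL) {
  switch(model,
    inverse_rl = list(eps = unname(par[1:3]), beta = unname(par[4]),
                      decay = decay),
    imitation = list(eta = unname(par[1]), theta = unname(par[2]),
                     beta = unname(par[3])),
    imitation_cf = list(eta = unname(par[1]), eta_unchosen = unname(par[2]),
                        theta = unname(par[3]), beta = unname(par[4])),
    rank_learner = list(kappa = unname(par[1]), beta = unname(par[2])))
}

#' Bayesian Information Criterion
#'
#' `BIC = 2 * nll + k * log(n)`, with `n` the number of choices entering the
#' likelihood (the self-choice trials). Lower is better; `-BIC/2` is the
#' log-evidence approximation handed to [rfx_bms()].
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k_params number of (effective) free parameters.
#' @param n_choices number of choices in the likelihood (>= 1).
#' @return scalar BIC.
#' @export
bic <- function(nll, k_params, n_choices) {
  if (n_choices < 1) stop("`n_choices` must be at least 1")
  2 * nll + k_params * log(n_choices)
}

#' Fit an observer model to a session by constrained maximum likelihood
#'
#' Minimizes [nll_self_choices()] over the model's constraint box with
#' `optim(method = "L-BFGS-B")`, restarted from `n_starts` random points drawn
#' uniformly within the box. Parameterizations and boxes:
#'
#' * `inverse_rl`: `eps1, eps2, eps3` in (0, 1), `beta` in \[2, 22\]. Note
#'   that a common rescaling of the eps triple cancels under renormalization,
#'   so only the eps ratios are identified.
#' * `imitation`: `eta` in \[0, 1\], inversion `theta` in \[0, 1\], `beta` in
#'   \[2, 22\].
#' * `imitation_cf`: adds `eta_unchosen` in \[0, 1\].
#' * `rank_learner`: `kappa` in (0, 10\], `beta` in \[2, 22\]; orientation
#'   follows the session's condition.
#'
#' An optional integer forgetting window `decay` in \[1, 100\] (inverse RL
#' only, disabled by default) restricts belief updates to the most recent
#' observations; because it is integer-valued, the continuous fit is repeated
#' for each candidate value and the best is kept (the BIC then counts one
#' extra parameter).
#'
#' @param session a `session_log` with recorded self choices.
#' @param model model id.
#' @param n_starts number of random multistart points (default 3).
#' @param seed optional integer seed controlling the starting points.
#' @param decay `NULL` (no forgetting) or an integer vector of candidate
#'   window lengths in \[1, 100\].
#' @param lower,upper optional overrides of the model's constraint box (must
#'   lie inside the default box).
#' @param control passed to [stats::optim()].
#' @return an object of class `observer_fit`: coefficients, `nll`, `bic`,
#'   per-start NLLs, convergence flags and the fitted session. If every start
#'   fails the fit is flagged (`convergence = FALSE`) with `nll = NA`, never a
#'   silent `NaN`.
#' @examples
#' s <- simulate_agent_session(schedule = build_schedule(30, 15, seed = 1), seed = 2)
#' obs <- observer_simulate("imitation", list(eta = 0.4, theta = 0, beta = 8),
#'                          s, seed = 3)
#' fit <- fit_observer(obs, "imitation", seed = 4)
#' coef(fit)
#' @export
fit_observer <- function(session, model = OBSERVER_MODELS, n_starts = 3,
                         seed = NULL, decay = NULL, lower = NULL, upper = NULL,
                         control = list()) {
  model <- match.arg(model)
  info <- model_info(model)
  if (!is.null(lower)) info$lower <- rep_len(lower, length(info$lower))
  if (!is.null(upper)) info$upper <- rep_len(upper, length(info$upper))
  if (any(info$lower >= info$upper)) stop("invalid constraint box")
  if (!is.null(decay)) {
    if (model != "inverse_rl")
      stop("the forgetting window is only defined for the inverse-RL model")
    if (any(decay != round(decay)) || any(decay < 1) || any(decay > 100))
      stop("`decay` candidates must be integers in [1, 100]")
  }
  n_self <- sum(session$kind == "self" & !is.na(session$chosen))
  if (n_self < 1) stop("session has no recorded self choices to fit")
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * length(info$lower), info$lower, info$upper),
                nrow = n_starts, byrow = TRUE)
    if (model == "rank_learner")  # log-uniform kappa starts (see model_info)
      m[, 1] <- exp(runif(n_starts, log(info$lower[1]), log(info$upper[1])))
    m
  })
  decay_cands <- if (is.null(decay)) list(NULL) else as.list(as.integer(decay))
  best <- NULL
  start_nlls <- rep(NA_real_, n_starts)
  for (d in decay_cands) {
    fn <- function(par) nll_self_choices(model, par_to_params(model, par, d),
                                         session)
    for (s in seq_len(n_starts)) {
      res <- tryCatch(
        optim(starts[s, ], fn, method = "L-BFGS-B",
              lower = info$lower, upper = info$upper, control = control),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.na(start_nlls[s]) || res$value < start_nlls[s])
        start_nlls[s] <- res$value
      if (is.null(best) || res$value < best$value) {
        best <- res
        best$decay <- d
      }
    }
  }
  if (is.null(best)) {
    fit <- list(model = model, coefficients = setNames(
                  rep(NA_real_, length(info$par_names)), info$par_names),
                params = NULL, nll = NA_real_, n_choices = n_self,
                k = info$k_bic, bic = NA_real_, start_nlls = start_nlls,
                decay = NULL, convergence = FALSE, session = session)
    class(fit) <- "observer_fit"
    return(fit)
  }
  k <- info$k_bic + (!is.null(best$decay))
  fit <- list(model = model,
              coefficients = setNames(best$par, info$par_names),
              params = par_to_params(model, best$par, best$decay),
              nll = best$value,
              n_choices = n_self,
              k = k,
              bic = bic(best$value, k, n_self),
              start_nlls = start_nlls,
              decay = best$decay,
              convergence = TRUE,
              session = session)
  class(fit) <- "observer_fit"
  fit
}

#' @export
print.observer_fit <- function(x, digits = 4, ...) {
  cat("Observer model fit:", x$model, "\n")
  if (!x$convergence) {
    cat("  optimization failed on all starts\n")
    return(invisible(x))
  }
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$decay)) cat("  forgetting window:", x$decay, "trials\n")
  cat(sprintf("  NLL %.*f on %d self choices; BIC %.*f (k = %d)\n",
              digits, x$nll, x$n_choices, digits, x$bic, x$k))
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, ...) {
  structure(list(model = object$model, coefficients = object$coefficients,
                 nll = object$nll, bic = object$bic, k = object$k,
                 n_choices = object$n_choices,
                 start_nlls = object$start_nlls,
                 condition = attr(object$session, "condition"),
                 convergence = object$convergence),
            class = "summary.observer_fit")
}

#' @export
print.summary.observer_fit <- function(x, digits = 4, ...) {
  cat("Observer model:", x$model, " (", x$condition, " condition)\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("NLL %.4f | BIC %.4f | k %d | n %d\n", x$nll, x$bic, x$k,
              x$n_choices))
  cat("per-start NLLs:", paste(round(x$start_nlls, digits), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.observer_fit <- function(object, ...) object$coefficients

#' @export
logLik.observer_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n_choices,
            class = "logLik")
}

#' Predicted self-choice probabilities from a fitted observer model
#'
#' @param object an `observer_fit`.
#' @param newdata optional `session_log` to score (defaults to the fitted
#'   session).
#' @param ... unused.
#' @return data.frame over self trials: offered pair, predicted probability
#'   of each pair member, recorded choice and its predicted probability.
#' @export
predict.observer_fit <- function(object, newdata = NULL, ...) {
  if (!object$convergence) stop("cannot predict from a failed fit")
  session <- if (is.null(newdata)) object$session else newdata
  rep_ <- observer_replay(object$model, object$params, session)
  sel <- which(!rep_$is_agent)
  ch <- session$chosen[sel]
  p_a <- rep_$p_a[sel]
  data.frame(trial = session$trial[sel],
             machine_a = session$machine_a[sel],
             machine_b = session$machine_b[sel],
             prob_a = p_a, prob_b = 1 - p_a,
             chosen = ch,
             prob_chosen = ifelse(is.na(ch), NA_real_,
                                  ifelse(ch == session$machine_a[sel],
                                         p_a, 1 - p_a)))
}

#' @export
residuals.observer_fit <- function(object, ...) {
  pr <- predict(object)
  y <- as.numeric(pr$chosen == pr$machine_a)
  (y - pr$prob_a) / sqrt(pmax(pr$prob_a * (1 - pr$prob_a), 1e-12))
}

#' Simulate self choices from a fitted observer model
#'
#' Regenerates the self choices of the fitted session under the fitted
#' parameters (the agent trials are replayed unchanged).
#'
#' @param object an `observer_fit`.
#' @param nsim number of simulated sessions.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` `session_log`s.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$convergence) stop("cannot simulate from a failed fit")
  seeds <- if (is.null(seed)) rep(list(NULL), nsim) else
    as.list(derive_seeds(seed, nsim))
  lapply(seq_len(nsim), function(i)
    observer_simulate(object$model, object$params, object$session,
                      seed = seeds[[i]]))
}

#' @export
plot.observer_fit <- function(x, ...) {
  pr <- predict(x)
  graphics::plot(pr$trial, pr$prob_chosen, type = "h", ylim = c(0, 1),
                 xlab = "trial", ylab = "P(recorded self choice)",
                 main = paste("Fitted", x$model), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
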