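#' Random-effects Bayesian model selection
#'
#' Group-level model comparison treating the model identity as a random
#' effect across subjects. Model frequencies `r` get a Dirichlet prior
#' (uniform, `alpha0 = 1` per model); per-subject model evidences enter as
#' log evidences (here approximated as `-BIC/2`). The Dirichlet posterior is
#' obtained by the standard variational fixed-point iteration
#' (posterior assignment weights `g_nk` proportional to
#' `exp(log_evidence_nk + digamma(alpha_k) - digamma(sum(alpha)))`, then
#' `alpha = alpha0 + colSums(g)`), and exceedance probabilities — the
#' posterior probability that each model is the most frequent in the
#' population — by Monte-Carlo sampling of the posterior Dirichlet.
#'
#' At small group sizes the variational posterior is noticeably
#' overconfident, so when the per-subject model-assignment space is small
#' enough to enumerate (`n_models^n_subjects <= 2048` under
#' `method = "auto"`) the exact posterior — a mixture of Dirichlets over
#' assignments — is computed instead; the variational scheme is used at group
#' scale, where enumeration is infeasible and its approximation is accurate.
#'
#' @param log_evidence numeric matrix, subjects x models, of log model
#'   evidences; column names label the models.
#' @param alpha0 Dirichlet prior counts (scalar or per-model vector).
#' @param n_samples Monte-Carlo samples for the exceedance probabilities.
#' @param seed optional integer seed for the Monte-Carlo step.
#' @param method "auto", "vb" (variational) or "exact" (assignment
#'   enumeration).
#' @param tol,max_iter convergence control for the variational iteration.
#' @return an object of class `bms_result` with elements `alpha`
#'   (Dirichlet posterior counts; under `"exact"` the mixture-averaged
#'   counts), `expected_freq` (posterior mean model frequencies),
#'   `exceedance_prob`, `method`, `n_samples`, `n_subjects`.
#' @examples
#' le <- cbind(m1 = rep(-30, 8), m2 = rep(-33, 8))
#' rfx_bms(le, seed = 1)
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e5, seed = NULL,
                    method = c("auto", "vb", "exact"),
                    tol = 1e-8, max_iter = 500) {
  log_evidence <- as.matrix(log_evidence)
  n <- nrow(log_evidence)
  k <- ncol(log_evidence)
  if (k < 2) stop("model selection requires at least 2 models")
  method <- match.arg(method)
  if (method == "auto")
    method <- if (k^n <= 2048) "exact" else "vb"
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("model", seq_len(k))
  alpha0 <- rep_len(alpha0, k)

  if (method == "exact") {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    counts <- vapply(seq_len(k), function(j) rowSums(grid == j),
                     numeric(nrow(grid)))
    lnB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
    lw <- vapply(seq_len(nrow(grid)), function(i) {
      sum(log_evidence[cbind(seq_len(n), grid[i, ])]) +
        lnB(alpha0 + counts[i, ]) - lnB(alpha0)
    }, numeric(1))
    w <- exp(lw - max(lw)); w <- w / sum(w)
    alpha_mix <- sweep(counts, 2, alpha0, "+")
    ef <- colSums(w * alpha_mix / rowSums(alpha_mix))
    alpha <- alpha0 + colSums(w * counts)
    ep <- with_seed(seed, {
      comp <- sample.int(nrow(grid), n_samples, replace = TRUE, prob = w)
      draws <- matrix(rgamma(n_samples * k, shape = alpha_mix[comp, ]),
                      nrow = n_samples)
      tabulate(max.col(draws, ties.method = "random"), nbins = k) / n_samples
    })
    return(structure(list(alpha = setNames(alpha, models),
                          expected_freq = setNames(ef, models),
                          exceedance_prob = setNames(ep, models),
                          assignment = NULL,
                          method = "exact",
                          n_samples = n_samples,
                          n_subjects = n),
                     class = "bms_result"))
  }

  alpha <- alpha0 + n / k
  for (it in seq_len(max_iter)) {
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- exp(w - apply(w, 1, max))
    g <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  ep <- with_seed(seed, {
    draws <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws, ties.method = "random"), nbins = k) / n_samples
  })
  structure(list(alpha = setNames(alpha, models),
                 expected_freq = setNames(alpha / sum(alpha), models),
                 exceedance_prob = setNames(ep, models),
                 assignment = g,
                 method = "vb",
                 n_samples = n_samples,
                 n_subjects = n),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects BMS over %d subjects, %d models\n",
              x$n_subjects, length(x$alpha)))
  tab <- rbind(`Dirichlet alpha` = x$alpha,
               `expected frequency` = x$expected_freq,
               `exceedance prob` = x$exceedance_prob)
  print(round(tab, digits))
  invisible(x)
}

#' Default generating-parameter samplers
#'
#' Draws generating parameters for synthetic observers: each eps component
#' uniform on (0.05, 0.95); eta, eta_unchosen and theta uniform on (0, 1);
#' kappa uniform on (0.2, 3); beta uniform on (2, 22), matching the fitting
#' box. Sampling spans the constraint space without informative bias.
#'
#' @param model model id.
#' @return a function of no arguments returning a parameter list.
#' @export
default_param_sampler <- function(model) {
  model <- match.arg(model, OBSERVER_MODELS)
  switch(model,
    inverse_rl = function() list(eps = runif(3, 0.05, 0.95),
                                 beta = runif(1, 2, 22)),
    imitation = function() list(eta = runif(1), theta = runif(1),
                                beta = runif(1, 2, 22)),
    imitation_cf = function() list(eta = runif(1), eta_unchosen = runif(1),
                                   theta = runif(1), beta = runif(1, 2, 22)),
    rank_learner = function() list(kappa = runif(1, 0.2, 3),
                                   beta = runif(1, 2, 22)))
}

#' Generate-and-recover confusion study
#'
#' For each generating model: draw subject-level parameters, simulate full
#' sessions (fresh agent and schedule per subject), refit every candidate
#' model by maximum likelihood, convert BICs to log evidences (`-BIC/2`) and
#' run [rfx_bms()]. The resulting matrix of exceedance probabilities
#' (generators in rows, fitted models in columns) shows whether the models
#' are mutually identifiable: a diagonal-dominant matrix means they are not
#' confused.
#'
#' @param generators character vector of generating model ids.
#' @param fit_models character vector of candidate models fitted to each
#'   simulated subject (default: the generators).
#' @param n_subjects simulated subjects per generating model.
#' @param param_sampler function(model) returning a no-argument sampler, as
#'   [default_param_sampler()].
#' @param condition session condition for the simulated cohorts.
#' @param n_agent,n_self trial counts per session.
#' @param n_starts multistart count per fit.
#' @param seed master integer seed.
#' @return an object of class `confusion_matrix`: the EP matrix plus per-cell
#'   metadata (subject counts, seeds, ground-truth parameter table).
#' @export
confusion_study <- function(generators = c("inverse_rl", "imitation"),
                            fit_models = generators,
                            n_subjects = 30,
                            param_sampler = default_param_sampler,
                            condition = "dissimilar",
                            n_agent = 100, n_self = 50,
                            n_starts = 3, seed = NULL) {
  seeds <- derive_seeds(seed, length(generators))
  ep <- matrix(NA_real_, length(generators), length(fit_models),
               dimnames = list(generator = generators, fitted = fit_models))
  truth <- list()
  failures <- list()
  for (gi in seq_along(generators)) {
    gen <- generators[gi]
    sub_seeds <- derive_seeds(seeds[gi], 4 * n_subjects)
    sampler <- param_sampler(gen)
    le <- matrix(NA_real_, n_subjects, length(fit_models),
                 dimnames = list(NULL, fit_models))
    for (s in seq_len(n_subjects)) {
      sd4 <- sub_seeds[(4 * (s - 1) + 1):(4 * s)]
      pars <- with_seed(sd4[1], sampler())
      sch <- build_schedule(n_agent, n_self, seed = sd4[2])
      ag <- simulate_agent_session(schedule = sch, condition = condition,
                                   seed = sd4[3])
      obs <- observer_simulate(gen, pars, ag, seed = sd4[4])
      for (fm in fit_models) {
        f <- fit_observer(obs, fm, n_starts = n_starts, seed = sd4[4])
        if (f$convergence) le[s, fm] <- -f$bic / 2
        else failures[[length(failures) + 1]] <-
          list(generator = gen, subject = s, model = fm)
      }
      truth[[length(truth) + 1]] <-
        data.frame(generator = gen, subject = s,
                   param = names(unlist(pars)), value = unlist(pars))
    }
    ok <- stats::complete.cases(le)
    ep[gi, ] <- rfx_bms(le[ok, , drop = FALSE], seed = seeds[gi])$exceedance_prob
  }
  structure(list(ep = ep,
                 n_subjects = n_subjects,
                 condition = condition,
                 seed = seed,
                 ground_truth = do.call(rbind, truth),
                 failures = failures),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Model-recovery confusion matrix (%d subjects per generator, %s condition)\n",
    x$n_subjects, x$condition))
  cat("Exceedance probabilities (rows: generating model):\n")
  print(round(x$ep, digits))
  if (length(x$failures))
    cat(length(x$failures), "fit failures (see $failures)\n")
  invisible(x)
}
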