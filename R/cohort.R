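#' Specify a synthetic cohort
#'
#' A cohort emulates the study structure: each subject plays two sessions —
#' one with a similar and one with a dissimilar agent — of 150 trials each
#' (100 agent observations, 50 self choices) by default, with the default
#' cohort size of 43 included subjects. Observer behavior is generated by a
#' named model with parameters drawn per subject from
#' [default_param_sampler()] (or a supplied sampler); every generated session
#' is stored alongside its ground-truth parameters.
#'
#' @param n_subjects number of subjects (default 43).
#' @param model generating model id, or a vector of length `n_subjects` for
#'   mixed-generator cohorts.
#' @param n_agent,n_self trial counts per session.
#' @param machines a [slot_machines()] object shared by all sessions.
#' @param agent_alpha,agent_beta simulated agent learning rate and softmax
#'   intensity.
#' @param param_sampler function(model) returning a no-argument sampler; the
#'   default spans the fitting constraint boxes uniformly.
#' @param seed master integer seed; all per-subject seeds derive from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 43, model = "inverse_rl",
                        n_agent = 100, n_self = 50,
                        machines = slot_machines(),
                        agent_alpha = 0.3, agent_beta = 3,
                        param_sampler = default_param_sampler,
                        seed = 1) {
  model <- as.character(model)
  if (!length(model) %in% c(1L, n_subjects))
    stop("`model` must name one generating model or one per subject")
  if (!all(model %in% OBSERVER_MODELS))
    stop("unknown generating model(s): ",
         paste(setdiff(model, OBSERVER_MODELS), collapse = ", "))
  structure(list(n_subjects = n_subjects,
                 model = rep_len(model, n_subjects),
                 n_agent = n_agent, n_self = n_self,
                 machines = machines,
                 agent_alpha = agent_alpha, agent_beta = agent_beta,
                 param_sampler = param_sampler,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' For each subject and condition: build a fresh schedule, simulate the agent
#' session, then simulate the subject's self choices under their generating
#' model with per-subject ground-truth parameters (the same parameters in
#' both conditions). Fully deterministic given the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: `subjects` (a list with per-condition
#'   `session_log`s and ground-truth parameters) and `ground_truth` (a tidy
#'   per-subject parameter table).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 4, seed = 1))
#' cohort_summary(co)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 7L * spec$n_subjects)
  subjects <- vector("list", spec$n_subjects)
  gt <- list()
  for (i in seq_len(spec$n_subjects)) {
    sd7 <- seeds[(7L * (i - 1L) + 1L):(7L * i)]
    model <- spec$model[i]
    pars <- with_seed(sd7[1], spec$param_sampler(model)())
    sessions <- list()
    for (ci in 1:2) {
      cond <- c("similar", "dissimilar")[ci]
      sch <- build_schedule(spec$n_agent, spec$n_self,
                            spec$machines$machine_ids, seed = sd7[1 + ci])
      ag <- simulate_agent_session(spec$machines, sch,
                                   alpha = spec$agent_alpha,
                                   beta_agent = spec$agent_beta,
                                   condition = cond, seed = sd7[3 + ci])
      sessions[[cond]] <- observer_simulate(model, pars, ag, seed = sd7[5 + ci])
    }
    subjects[[i]] <- list(subject = i, model = model, params = pars,
                          sessions = sessions)
    gt[[i]] <- data.frame(subject = i, model = model,
                          param = names(unlist(pars)),
                          value = unname(unlist(pars)))
  }
  structure(list(subjects = subjects,
                 ground_truth = do.call(rbind, gt),
                 spec = spec),
            class = "cohort")
}

# Flatten a cohort into a list of session logs (both conditions).
cohort_sessions <- function(cohort, condition = NULL) {
  out <- list()
  for (sub in cohort$subjects)
    for (cond in names(sub$sessions))
      if (is.null(condition) || cond == condition)
        out[[length(out) + 1L]] <- sub$sessions[[cond]]
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x 2 conditions (%d + %d trials)\n",
              x$spec$n_subjects, x$spec$n_agent, x$spec$n_self))
  cat("generating models:",
      paste(sprintf("%s (%d)", names(table(x$spec$model)),
                    table(x$spec$model)), collapse = ", "), "\n")
  invisible(x)
}

#' Condition-level choice-ratio summary of a cohort
#'
#' Mean and SEM choice ratios per machine rank and condition: agent ratios in
#' agent-referential space, observer (self) ratios in self-referential space.
#'
#' @param cohort a `cohort`.
#' @return data.frame with columns `condition`, `actor`, `position`
#'   (best/mid/worst in the actor's space), `mean`, `sem`.
#' @export
cohort_summary <- function(cohort) {
  rows <- list()
  for (cond in c("similar", "dissimilar")) {
    ss <- cohort_sessions(cohort, cond)
    for (actor in c("agent", "self")) {
      mat <- t(vapply(ss, function(s) {
        at <- session_attrs(s)
        prof <- if (actor == "agent") at$agent_profile else at$observer_profile
        referential_reorder(choice_ratio(s, actor), prof, at$machines)
      }, numeric(3)))
      for (j in 1:3)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, actor = actor,
          position = c("best", "mid", "worst")[j],
          mean = mean(mat[, j], na.rm = TRUE),
          sem = sd(mat[, j], na.rm = TRUE) / sqrt(sum(!is.na(mat[, j]))))
    }
  }
  do.call(rbind, rows)
}

#' Fit candidate models to every session of a cohort
#'
#' @param cohort a `cohort`.
#' @param models candidate model ids to fit.
#' @param n_starts multistart count per fit.
#' @param seed master integer seed for the multistarts.
#' @return list with `bic` (array subject x model x condition), `nll` (same
#'   shape), and `fits` (nested list of `observer_fit`s).
#' @export
fit_cohort <- function(cohort, models = c("inverse_rl", "imitation"),
                       n_starts = 3, seed = NULL) {
  n <- length(cohort$subjects)
  conds <- c("similar", "dissimilar")
  bic_arr <- array(NA_real_, c(n, length(models), 2),
                   dimnames = list(NULL, models, conds))
  nll_arr <- bic_arr
  seeds <- derive_seeds(seed, n * length(models) * 2)
  k <- 0L
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- list()
    for (cond in conds) {
      for (m in models) {
        k <- k + 1L
        f <- fit_observer(cohort$subjects[[i]]$sessions[[cond]], m,
                          n_starts = n_starts, seed = seeds[k])
        fits[[i]][[cond]][[m]] <- f
        if (f$convergence) {
          bic_arr[i, m, cond] <- f$bic
          nll_arr[i, m, cond] <- f$nll
        }
      }
    }
  }
  list(bic = bic_arr, nll = nll_arr, fits = fits, models = models)
}

#' Write or read a cohort as per-subject CSV directories
#'
#' One directory per subject holding per-condition session CSVs (with JSON
#' sidecars) and a ground-truth JSON; a cohort manifest YAML at the root.
#'
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    sdir <- file.path(dir, sprintf("subject_%03d", sub$subject))
    dir.create(sdir, showWarnings = FALSE)
    for (cond in names(sub$sessions))
      write_session(sub$sessions[[cond]],
                    file.path(sdir, paste0(cond, ".csv")))
    jsonlite::write_json(list(subject = sub$subject, model = sub$model,
                              params = sub$params),
                         file.path(sdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(n_subjects = cohort$spec$n_subjects,
                   n_agent = cohort$spec$n_agent,
                   n_self = cohort$spec$n_self,
                   seed = cohort$spec$seed,
                   models = as.list(cohort$spec$model))
  yaml::write_yaml(manifest, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- vector("list", length(sdirs))
  gt <- list()
  for (i in seq_along(sdirs)) {
    meta <- jsonlite::read_json(file.path(sdirs[i], "ground_truth.json"),
                                simplifyVector = TRUE)
    sessions <- list()
    for (cond in c("similar", "dissimilar")) {
      f <- file.path(sdirs[i], paste0(cond, ".csv"))
      if (file.exists(f)) sessions[[cond]] <- read_session(f)
    }
    params <- as.list(meta$params)
    if (!is.null(params$eps)) params$eps <- as.numeric(params$eps)
    subjects[[i]] <- list(subject = meta$subject, model = meta$model,
                          params = params, sessions = sessions)
    gt[[i]] <- data.frame(subject = meta$subject, model = meta$model,
                          param = names(unlist(params)),
                          value = unname(unlist(params)))
  }
  spec <- cohort_spec(n_subjects = manifest$n_subjects,
                      model = unlist(manifest$models),
                      n_agent = manifest$n_agent, n_self = manifest$n_self,
                      seed = manifest$seed)
  structure(list(subjects = subjects, ground_truth = do.call(rbind, gt),
                 spec = spec),
            class = "cohort")
}
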