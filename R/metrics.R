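#' Reorder per-machine quantities into an actor's referential space
#'
#' Machines are ranked by the expected value they carry for the given actor —
#' the true outcome probabilities weighted by the actor's own preference
#' values — and the input vector is returned in best/mid/worst order for that
#' actor. Ties in expected value are broken deterministically by machine
#' label (with a message).
#'
#' @param ratios named per-machine vector (e.g. from [choice_ratio()]).
#' @param profile the actor's [preference_profile()].
#' @param machines the session's [slot_machines()].
#' @return the reordered vector, names preserved, best machine first.
#' @export
referential_reorder <- function(ratios, profile, machines) {
  v <- profile_column_values(profile, machines)
  ev <- as.vector(machines$true_probs %*% v)
  if (anyDuplicated(ev))
    message("ties in expected machine value; breaking by machine label")
  ord <- order(-ev, machines$machine_ids)
  out <- ratios[machines$machine_ids][ord]
  names(out) <- machines$machine_ids[ord]
  out
}

#' Cohort-level agent-observer rank correlation
#'
#' Spearman correlation between observers' self-choice ratios (each subject's
#' ratios reordered into their own referential space) and the corresponding
#' agent choice ratios (in agent-referential space), pooled over subject x
#' machine pairs.
#'
#' @param sessions a list of `session_log`s (or a `cohort`), each with agent
#'   and self choices recorded.
#' @param condition optional condition filter ("similar" or "dissimilar").
#' @return Spearman's rs, with the number of pooled pairs in attribute
#'   `n_pairs`; `NA` (with a warning) if either pooled vector is constant.
#' @export
spearman_agent_observer <- function(sessions, condition = NULL) {
  if (inherits(sessions, "cohort")) sessions <- cohort_sessions(sessions)
  if (!is.null(condition))
    sessions <- Filter(function(s) attr(s, "condition") == condition, sessions)
  if (length(sessions) < 2) stop("need at least 2 subjects")
  obs <- agent <- numeric(0)
  for (s in sessions) {
    at <- session_attrs(s)
    obs <- c(obs, referential_reorder(choice_ratio(s, "self"),
                                      at$observer_profile, at$machines))
    agent <- c(agent, referential_reorder(choice_ratio(s, "agent"),
                                          at$agent_profile, at$machines))
  }
  keep <- stats::complete.cases(obs, agent)
  if (sd(obs[keep]) == 0 || sd(agent[keep]) == 0) {
    warning("constant ratio vector; rank correlation undefined")
    return(structure(NA_real_, n_pairs = sum(keep)))
  }
  rs <- cor(obs[keep], agent[keep], method = "spearman")
  structure(rs, n_pairs = sum(keep))
}

#' Compare two correlations after Fisher transform
#'
#' `z = (atanh(rs_a) - atanh(rs_b)) / sqrt(1/(n_a - 3) + 1/(n_b - 3))`, with a
#' one-tailed normal p-value for the alternative `rs_a > rs_b`.
#'
#' @param rs_a,rs_b the two correlations (strictly inside (-1, 1)).
#' @param n_a,n_b sample sizes (>= 4).
#' @return list with elements `z` and `p` (one-tailed).
#' @export
fisher_compare <- function(rs_a, rs_b, n_a, n_b) {
  if (abs(rs_a) >= 1 || abs(rs_b) >= 1)
    stop("the Fisher transform diverges at |r| = 1")
  if (n_a < 4 || n_b < 4) stop("sample sizes must be at least 4")
  z <- (atanh(rs_a) - atanh(rs_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Choice ratios over the late (plateau) window
#'
#' Restricts [choice_ratio()] to trials at or after a cutoff, by default
#' trial 76 — the second half of a default 150-trial session, taken as the
#' window in which the observed agent's learning has plateaued.
#'
#' @param session a `session_log`.
#' @param cutoff first trial index of the window.
#' @param chooser "self" or "agent".
#' @return named per-machine ratio vector over the window.
#' @export
plateau_ratios <- function(session, cutoff = 76, chooser = c("self", "agent")) {
  chooser <- match.arg(chooser)
  win <- session[session$trial >= cutoff, , drop = FALSE]
  if (nrow(win) == 0L) stop("plateau window is empty (cutoff beyond last trial)")
  for (a in c("condition", "machines", "agent_profile", "observer_profile"))
    attr(win, a) <- attr(session, a)
  class(win) <- class(session)
  choice_ratio(win, chooser)
}

# Base-2 Jensen-Shannon divergence between probability vectors (bounded by 1).
js_divergence2 <- function(p, q) {
  m <- (p + q) / 2
  kl2 <- function(x, y) {
    pos <- x > 0
    sum(x[pos] * log2(x[pos] / y[pos]))
  }
  (kl2(p, m) + kl2(q, m)) / 2
}

#' Social-information-integration (SI) index
#'
#' A bounded similarity score between the agent's and the observer's choice
#' behavior, each expressed in its *own* referential space: the two per-
#' machine choice-ratio vectors are reordered (agent ratios by agent
#' preference, observer ratios by observer preference), normalized to sum to
#' one, and compared by base-2 Jensen-Shannon divergence; `SI = 1 - JSD`.
#' An observer who transfers the inferred outcome knowledge into their own
#' preference space scores near 1 even with a dissimilar agent, whereas an
#' observer who simply mimics a dissimilar agent scores near 0.
#'
#' @param agent_log `session_log` carrying the agent trials.
#' @param observer_log `session_log` carrying the self trials (defaults to
#'   `agent_log`, the usual single-session case).
#' @param machines,agent_profile,observer_profile defaults taken from
#'   `agent_log` / `observer_log` attributes.
#' @return scalar SI in \[0, 1\].
#' @export
si_index <- function(agent_log, observer_log = agent_log,
                     machines = attr(agent_log, "machines"),
                     agent_profile = attr(agent_log, "agent_profile"),
                     observer_profile = attr(observer_log, "observer_profile")) {
  ra <- referential_reorder(choice_ratio(agent_log, "agent"),
                            agent_profile, machines)
  ro <- referential_reorder(choice_ratio(observer_log, "self"),
                            observer_profile, machines)
  if (anyNA(ra) || anyNA(ro))
    stop("both actors must have defined ratios for all machines")
  if (sum(ra) == 0 || sum(ro) == 0)
    stop("cannot normalize an all-zero choice-ratio vector")
  1 - js_divergence2(unname(ra / sum(ra)), unname(ro / sum(ro)))
}

#' Descriptive behavioral metrics for a cohort
#'
#' The cohort-level report: per condition, the pooled agent-observer Spearman
#' correlation, mean plateau choice ratios (in self-referential space) and
#' mean SI index; plus the Fisher-transform comparison of the two
#' correlations and per-machine plateau ratio contrasts (two-sample t-tests)
#' across conditions.
#'
#' @param cohort a `cohort` (see [generate_cohort()]) or list of
#'   `session_log`s covering both conditions.
#' @param plateau_cutoff first trial of the plateau window.
#' @return an object of class `metrics_report`.
#' @export
cohort_metrics <- function(cohort, plateau_cutoff = 76) {
  sessions <- if (inherits(cohort, "cohort")) cohort_sessions(cohort) else cohort
  conds <- c("similar", "dissimilar")
  per <- lapply(conds, function(cond) {
    ss <- Filter(function(s) attr(s, "condition") == cond, sessions)
    rs <- spearman_agent_observer(ss)
    plats <- t(vapply(ss, function(s)
      referential_reorder(plateau_ratios(s, plateau_cutoff),
                          attr(s, "observer_profile"), attr(s, "machines")),
      numeric(3)))
    colnames(plats) <- c("best", "mid", "worst")
    si <- vapply(ss, function(s) si_index(s), numeric(1))
    list(n_subjects = length(ss), rs = as.numeric(rs),
         n_pairs = attr(rs, "n_pairs"),
         plateau = plats,
         plateau_mean = colMeans(plats),
         plateau_sem = apply(plats, 2, sd) / sqrt(nrow(plats)),
         si = si, si_mean = mean(si))
  })
  names(per) <- conds
  fis <- fisher_compare(per$similar$rs, per$dissimilar$rs,
                        per$similar$n_pairs, per$dissimilar$n_pairs)
  contrasts <- lapply(c("best", "mid", "worst"), function(m) {
    tt <- t.test(per$similar$plateau[, m], per$dissimilar$plateau[, m])
    list(machine = m,
         mean_similar = mean(per$similar$plateau[, m]),
         mean_dissimilar = mean(per$dissimilar$plateau[, m]),
         t = unname(tt$statistic), p = tt$p.value)
  })
  names(contrasts) <- c("best", "mid", "worst")
  structure(list(conditions = per, fisher = fis, contrasts = contrasts,
                 plateau_cutoff = plateau_cutoff),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  for (cond in names(x$conditions)) {
    p <- x$conditions[[cond]]
    cat(sprintf("%s condition (n = %d): rs = %.3f, mean SI = %.3f\n",
                cond, p$n_subjects, p$rs, p$si_mean))
    cat("  plateau ratios (self space): ",
        paste(sprintf("%s %.3f", names(p$plateau_mean),
                      p$plateau_mean), collapse = ", "), "\n")
  }
  cat(sprintf("Fisher comparison (similar > dissimilar): z = %.3f, one-tailed p = %.4f\n",
              x$fisher$z, x$fisher$p))
  for (m in names(x$contrasts)) {
    ct <- x$contrasts[[m]]
    cat(sprintf("  %s machine: sim %.3f vs dis %.3f (t = %.2f, p = %.4f)\n",
                m, ct$mean_similar, ct$mean_dissimilar, ct$t, ct$p))
  }
  invisible(x)
}
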