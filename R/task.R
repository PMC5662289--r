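#' Define the set of three slot machines
#'
#' A session uses three slot machines, each paying out one of three food
#' outcomes with fixed (but hidden) probabilities. Outcomes are indexed by the
#' *agent's* preference rank: column 1 is the agent's most preferred food,
#' column 3 its least preferred. The default matrix gives a clear best / mid /
#' worst machine in the agent's preference space (and, mirrored, in a
#' dissimilar observer's space).
#'
#' @param true_probs 3x3 numeric matrix of outcome probabilities; rows are
#'   machines, columns are outcomes in agent preference-rank order. Each row
#'   must lie on the probability simplex.
#' @param machine_ids character vector of 3 machine labels.
#' @param outcomes character vector of 3 outcome (food) identities, in agent
#'   preference-rank order.
#' @return An object of class `slot_machines`.
#' @examples
#' m <- slot_machines()
#' m$true_probs
#' @export
slot_machines <- function(true_probs = NULL,
                          machine_ids = c("M1", "M2", "M3"),
                          outcomes = c("o1", "o2", "o3")) {
  if (is.null(true_probs)) {
    true_probs <- matrix(c(0.6, 0.3, 0.1,
                           0.3, 0.4, 0.3,
                           0.1, 0.3, 0.6), nrow = 3, byrow = TRUE)
  }
  true_probs <- as.matrix(true_probs)
  if (!identical(dim(true_probs), c(3L, 3L)))
    stop("`true_probs` must be a 3x3 matrix")
  if (any(true_probs < 0) || any(true_probs > 1))
    stop("`true_probs` entries must lie in [0, 1]")
  check_simplex_rows(true_probs)
  if (length(machine_ids) != 3L || anyDuplicated(machine_ids))
    stop("`machine_ids` must be 3 distinct labels")
  if (length(outcomes) != 3L || anyDuplicated(outcomes))
    stop("`outcomes` must be 3 distinct labels")
  dimnames(true_probs) <- list(machine_ids, outcomes)
  structure(list(machine_ids = machine_ids,
                 outcomes = outcomes,
                 true_probs = true_probs),
            class = "slot_machines")
}

check_simplex_rows <- function(m, tol = 1e-8) {
  if (any(abs(rowSums(m) - 1) > tol))
    stop("each probability row must sum to 1 (within ", tol, ")")
  invisible(m)
}

#' Define an actor's preference profile over the three outcomes
#'
#' An actor (the observed agent or the observer) ranks the three food outcomes
#' from most to least preferred and assigns strictly decreasing numeric values
#' to the ranks (default 3, 2, 1: the scalar outcome coding used throughout).
#'
#' @param actor_id label for the actor.
#' @param ranking character permutation of the 3 outcome identities, most
#'   preferred first.
#' @param values numeric vector of length 3, strictly decreasing; `values[r]`
#'   is the worth of the actor's rank-`r` outcome.
#' @return An object of class `preference_profile`.
#' @examples
#' ag <- preference_profile("agent", c("o1", "o2", "o3"))
#' dissimilar_profile(ag, "observer")
#' @export
preference_profile <- function(actor_id, ranking, values = c(3, 2, 1)) {
  if (length(ranking) != 3L || anyDuplicated(ranking))
    stop("`ranking` must be a strict permutation of the 3 outcome identities")
  if (length(values) != 3L || any(diff(values) >= 0))
    stop("`values` must be 3 strictly decreasing numbers")
  structure(list(actor_id = actor_id,
                 ranking = as.character(ranking),
                 values = as.numeric(values)),
            class = "preference_profile")
}

#' @rdname preference_profile
#' @param profile a `preference_profile` to mirror or copy.
#' @export
similar_profile <- function(profile, actor_id = "observer") {
  preference_profile(actor_id, profile$ranking, profile$values)
}

#' @rdname preference_profile
#' @export
dissimilar_profile <- function(profile, actor_id = "observer") {
  preference_profile(actor_id, rev(profile$ranking), profile$values)
}

# Value each outcome column of `machines` carries for `profile`.
# Columns are in agent-rank order; map through outcome identities.
profile_column_values <- function(profile, machines) {
  profile$values[match(machines$outcomes, profile$ranking)]
}

#' Build a trial schedule
#'
#' A session interleaves agent-observation trials and self-choice trials
#' (default 100 and 50, i.e. 150 trials with observations on 2/3 of trials).
#' Within each trial kind the three unordered machine pairs are balanced
#' (each pair appears `floor(n/3)` or `ceiling(n/3)` times), then the trial
#' order is a single seeded shuffle.
#'
#' @param n_agent number of agent-observation trials (>= 1).
#' @param n_self number of self-choice trials (>= 1).
#' @param machine_ids character vector of 3 machine labels.
#' @param seed optional integer seed; identical seeds give identical schedules.
#' @return A data.frame of class `trial_schedule` with columns `trial`,
#'   `kind` ("agent" or "self"), `machine_a`, `machine_b`.
#' @examples
#' sch <- build_schedule(seed = 1)
#' table(sch$kind)
#' @export
build_schedule <- function(n_agent = 100, n_self = 50,
                           machine_ids = c("M1", "M2", "M3"), seed = NULL) {
  if (n_agent < 1 || n_self < 1)
    stop("`n_agent` and `n_self` must both be at least 1")
  if (length(machine_ids) != 3L)
    stop("exactly 3 machines are required")
  pairs <- combn(machine_ids, 2)        # 3 unordered pairs
  with_seed(seed, {
    draw_kind <- function(n) {
      base <- n %/% 3L
      extra <- n %% 3L
      idx <- rep(seq_len(3L), base)
      if (extra > 0) idx <- c(idx, sample.int(3L, extra))
      idx
    }
    idx <- c(draw_kind(n_agent), draw_kind(n_self))
    kind <- c(rep("agent", n_agent), rep("self", n_self))
    ord <- sample.int(length(idx))
    out <- data.frame(trial = seq_along(idx),
                      kind = kind[ord],
                      machine_a = pairs[1, idx[ord]],
                      machine_b = pairs[2, idx[ord]],
                      stringsAsFactors = FALSE)
    class(out) <- c("trial_schedule", "data.frame")
    out
  })
}

#' Sample an outcome from a machine
#'
#' Draws outcome preference-rank indices from a machine's fixed outcome
#' distribution.
#'
#' @param machine machine label.
#' @param machines a [slot_machines()] object.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return integer vector of outcome rank indices in 1..3 (1 = agent's most
#'   preferred outcome).
#' @export
sample_outcome <- function(machine, machines, n = 1, seed = NULL) {
  i <- match(machine, machines$machine_ids)
  if (is.na(i)) stop("unknown machine: ", machine)
  row <- machines$true_probs[i, ]
  check_simplex_rows(matrix(row, 1))
  with_seed(seed, sample.int(3L, n, replace = TRUE, prob = row))
}

#' Per-machine choice ratio
#'
#' The choice ratio of a machine is its choice frequency divided by its total
#' number of presentations to the given chooser. Machines never offered to
#' that chooser get `NA` (undefined), not 0.
#'
#' @param session a `session_log`.
#' @param chooser "agent" or "self".
#' @return named numeric vector of 3 ratios (possibly `NA`).
#' @export
choice_ratio <- function(session, chooser = c("agent", "self")) {
  chooser <- match.arg(chooser)
  rows <- session[session$chooser == chooser & !is.na(session$chosen), ,
                  drop = FALSE]
  if (nrow(rows) == 0L)
    stop("session contains no completed trials with chooser = ", chooser)
  ids <- attr(session, "machines")$machine_ids
  offered <- vapply(ids, function(m) sum(rows$machine_a == m | rows$machine_b == m),
                    numeric(1))
  chosen <- vapply(ids, function(m) sum(rows$chosen == m), numeric(1))
  ratio <- ifelse(offered > 0, chosen / offered, NA_real_)
  setNames(ratio, ids)
}

# Construct an (unfilled) session log from a schedule.
new_session_log <- function(schedule, condition, machines,
                            agent_profile, observer_profile) {
  log <- data.frame(trial = schedule$trial,
                    kind = schedule$kind,
                    machine_a = schedule$machine_a,
                    machine_b = schedule$machine_b,
                    chooser = ifelse(schedule$kind == "agent", "agent", "self"),
                    chosen = NA_character_,
                    outcome_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  structure(log,
            condition = condition,
            machines = machines,
            agent_profile = agent_profile,
            observer_profile = observer_profile,
            class = c("session_log", "data.frame"))
}

session_attrs <- function(session) {
  list(condition = attr(session, "condition"),
       machines = attr(session, "machines"),
       agent_profile = attr(session, "agent_profile"),
       observer_profile = attr(session, "observer_profile"))
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log (%s condition): %d trials (%d agent, %d self)\n",
              attr(x, "condition"), nrow(x),
              sum(x$kind == "agent"), sum(x$kind == "self")))
  cat(sprintf("  self choices recorded: %d\n",
              sum(x$kind == "self" & !is.na(x$chosen))))
  invisible(x)
}

#' Write or read a session log as CSV with a JSON metadata sidecar
#'
#' The CSV carries the per-trial record (trial, kind, condition, machine pair,
#' chooser, chosen machine, outcome rank — empty on self trials); machine set,
#' preference profiles, condition and any seed travel in a JSON sidecar so the
#' log round-trips losslessly.
#'
#' @param session a `session_log`.
#' @param file CSV path.
#' @param meta_file JSON sidecar path (default `<file>.json`).
#' @param seed optional seed to record in the sidecar.
#' @return `write_session` returns `file` invisibly; `read_session` returns a
#'   `session_log`.
#' @export
write_session <- function(session, file, meta_file = paste0(file, ".json"),
                          seed = NULL) {
  at <- session_attrs(session)
  out <- data.frame(trial = session$trial, kind = session$kind,
                    condition = at$condition,
                    machine_a = session$machine_a, machine_b = session$machine_b,
                    chooser = session$chooser, chosen = session$chosen,
                    outcome_rank = session$outcome_rank)
  write.csv(out, file, row.names = FALSE)
  meta <- list(condition = at$condition,
               machine_ids = at$machines$machine_ids,
               outcomes = at$machines$outcomes,
               true_probs = at$machines$true_probs,
               agent_profile = unclass(at$agent_profile),
               observer_profile = unclass(at$observer_profile),
               seed = seed)
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(file)
}

#' @rdname write_session
#' @export
read_session <- function(file, meta_file = paste0(file, ".json")) {
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = c(outcome_rank = "integer"))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  machines <- slot_machines(matrix(unlist(meta$true_probs), 3, 3, byrow = TRUE),
                            machine_ids = meta$machine_ids,
                            outcomes = meta$outcomes)
  ap <- preference_profile(meta$agent_profile$actor_id,
                           meta$agent_profile$ranking,
                           meta$agent_profile$values)
  op <- preference_profile(meta$observer_profile$actor_id,
                           meta$observer_profile$ranking,
                           meta$observer_profile$values)
  log <- data.frame(trial = df$trial, kind = df$kind,
                    machine_a = df$machine_a, machine_b = df$machine_b,
                    chooser = df$chooser,
                    chosen = ifelse(is.na(df$chosen) | df$chosen == "",
                                    NA_character_, df$chosen),
                    outcome_rank = df$outcome_rank,
                    stringsAsFactors = FALSE)
  structure(log, condition = meta$condition, machines = machines,
            agent_profile = ap, observer_profile = op,
            class = c("session_log", "data.frame"))
}
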