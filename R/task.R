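#' Task payoffs
#'
#' Point values of the three event types: querying an internal node costs
#' points, choosing a wrong leaf costs points, and finding the target earns
#' points. Defaults are the task's standard contingencies (-1, -3, +10).
#' \code{query_scale} and \code{requery_scale} are multipliers in (0, 1]
#' used by the planner's modified-payoff variants (e.g. internal queries at
#' 30% of their true cost, or re-queries at 5%).
#'
#' @param query cost of one internal-node query (positive number of points
#'   lost), default 1
#' @param wrong_leaf cost of choosing a non-target leaf, default 3
#' @param target reward for finding the target, default 10
#' @param query_scale multiplier on the query cost, default 1
#' @param requery_scale multiplier on the query cost for immediate re-queries
#'   (same internal node twice in a row), default \code{query_scale}
#' @return an object of class \code{"payoffs"}
#' @export
payoffs <- function(query = 1, wrong_leaf = 3, target = 10,
                    query_scale = 1, requery_scale = query_scale) {
  stopifnot(query > 0, wrong_leaf > 0, target > 0,
            query_scale > 0, query_scale <= 1,
            requery_scale > 0, requery_scale <= 1)
  structure(list(query = query, wrong_leaf = wrong_leaf, target = target,
                 query_scale = query_scale, requery_scale = requery_scale),
            class = "payoffs")
}

#' Evidence (sensory) parameters
#'
#' Parameters of the Gaussian momentary-evidence model. A query of an
#' internal node with coherence \code{c} (proportion) and direction
#' \code{d} (+1 right / -1 left) returns one evidence pulse
#' \deqn{e \sim N(\kappa d c t,\; t(1 + c\gamma)),}
#' where \eqn{t} is the pulse duration in seconds. \eqn{\kappa} is the
#' signal-to-noise (units 1/(coherence x s)) and \eqn{\gamma} the slope of
#' the variance on coherence.
#'
#' @param kappa signal-to-noise, > 0
#' @param gamma variance slope on coherence, >= 0
#' @param t pulse duration in seconds (default 0.227)
#' @return object of class \code{"evidence_params"}
#' @export
evidence_params <- function(kappa, gamma = 0, t = 0.227) {
  stopifnot(kappa > 0, gamma >= 0, t > 0)
  structure(list(kappa = kappa, gamma = gamma, t = t),
            class = "evidence_params")
}

#' @rdname evidence_params
#' @param c coherence(s), proportion in [0, 1]
#' @param d direction(s), -1 or +1
#' @param ep an [evidence_params()] object
#' @export
evidence_mean <- function(c, d, ep) ep$kappa * d * c * ep$t

#' @rdname evidence_params
#' @export
evidence_sd <- function(c, ep) sqrt(ep$t * (1 + c * ep$gamma))

#' Sample motion-evidence pulses
#'
#' Draws one Gaussian evidence pulse per (coherence, direction) pair.
#' Vectorized over \code{c} and \code{d}.
#'
#' @inheritParams evidence_mean
#' @param n number of pulses (default \code{length(c)})
#' @return numeric vector of evidence values
#' @export
sample_evidence <- function(c, d, ep, n = length(c)) {
  stopifnot(all(c >= 0), all(d %in% c(-1, 1)))
  stats::rnorm(n, mean = evidence_mean(c, d, ep), sd = evidence_sd(c, ep))
}

#' Task configuration
#'
#' Bundles the stimulus statistics and payoffs that define the task. The
#' default coherence list is the task's five levels, stored as proportions
#' (3.2% ... 51.2%); percent inputs (values > 1) are converted.
#'
#' @param coherences coherence levels (proportions, or percents if > 1)
#' @param pulse_duration_s evidence pulse duration in seconds
#' @param pay a [payoffs()] object
#' @return object of class \code{"task_config"}
#' @export
task_config <- function(coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                        pulse_duration_s = 0.227, pay = payoffs()) {
  stopifnot(length(coherences) >= 1, all(coherences > 0))
  if (any(coherences > 1)) coherences <- coherences / 100
  stopifnot(all(coherences <= 1))
  structure(list(coherences = sort(coherences),
                 pulse_duration_s = pulse_duration_s, pay = pay),
            class = "task_config")
}

#' Read a task configuration from YAML
#'
#' Accepts keys \code{coherences}, \code{pulse_duration_s} and
#' \code{payoffs: {query, wrong_leaf, target}} plus optional
#' \code{cost_multipliers: {query, requery}}.
#'
#' @param path path to a YAML file
#' @return a [task_config()] object
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  pq <- y$payoffs$query %||% 1
  pw <- y$payoffs$wrong_leaf %||% 3
  pt <- y$payoffs$target %||% 10
  qs <- y$cost_multipliers$query %||% 1
  rs <- y$cost_multipliers$requery %||% qs
  task_config(coherences = y$coherences %||% c(0.032, 0.064, 0.128, 0.256, 0.512),
              pulse_duration_s = y$pulse_duration_s %||% 0.227,
              pay = payoffs(pq, pw, pt, query_scale = qs, requery_scale = rs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected cost of committing to a leaf from level 3
#'
#' With probability \code{p_correct} the implied leaf is the target (no
#' loss); otherwise the wrong-leaf cost is paid before the error is
#' corrected. The worked example behind the planner's reluctance to query
#' level-3 nodes: committing after a query with accuracy 0.8 costs
#' \eqn{(1 - 0.8)(-3) = -0.6} in expectation, committing blind at accuracy
#' 0.5 costs \eqn{-1.5}, and the difference (0.9) is less than the 1-point
#' query cost, so the query does not pay.
#'
#' @param p_correct probability that the implied leaf is the target
#' @param pay a [payoffs()] object
#' @return expected points lost (a non-positive number)
#' @export
expected_commit_cost <- function(p_correct, pay = payoffs()) {
  stopifnot(p_correct >= 0, p_correct <= 1)
  (1 - p_correct) * -pay$wrong_leaf
}

#' Sample a trial's latent state
#'
#' Draws the ground truth of one trial: per internal node, a coherence
#' uniformly from the task's list and a direction uniformly from
#' \{-1, +1\}, all independent and fixed within the trial. The target is
#' the unique leaf reached by following the true direction at each
#' bifurcation from the root. Simulation is in spatial coordinates; the
#' canonical (target-relative) relabeling, under which the target is node
#' 15, is attached for analysis.
#'
#' @param config a [task_config()] object
#' @return object of class \code{"trial_state"} with elements
#'   \code{coherence} (length 7), \code{direction} (length 7, ±1),
#'   \code{target} (spatial leaf id), \code{map} (see [canonical_map()])
#' @export
sample_trial <- function(config = task_config()) {
  coh <- sample(config$coherences, 7, replace = TRUE)
  dir <- sample(c(-1, 1), 7, replace = TRUE)
  map <- canonical_map(dir)
  structure(list(coherence = coh, direction = dir,
                 target = map$to_spatial[15], map = map),
            class = "trial_state")
}

#' Start a trial session
#'
#' Creates the mutable bookkeeping for playing out a trial with [trial_step()]:
#' visited wrong leaves, accumulated points, query/error counters and
#' termination flag.
#'
#' @param trial a [sample_trial()] state
#' @return a \code{"trial_session"} list
#' @export
start_session <- function(trial) {
  structure(list(trial = trial, visited = integer(0), points = 0,
                 n_queries = 0L, n_errors = 0L, done = FALSE,
                 last_action = NA_integer_),
            class = "trial_session")
}

#' Execute one action in a trial
#'
#' Querying an internal node returns an evidence pulse and costs the query
#' price (scaled by the re-query multiplier if the same internal node was
#' queried in the immediately preceding step). Choosing a wrong leaf gives
#' negative feedback, costs the wrong-leaf price and adds the leaf to the
#' visited set; choosing the target ends the trial with the reward.
#' Re-querying a leaf already known to be wrong is an error unless
#' \code{allow_leaf_requery} is set.
#'
#' @param session a [start_session()] object
#' @param action node id 1..15
#' @param ep an [evidence_params()] object (for the evidence pulse)
#' @param pay a [payoffs()] object
#' @param allow_leaf_requery permit re-choosing a visited wrong leaf
#' @return the updated session, with the step outcome in
#'   \code{$last}: a list \code{(observation, points_delta, feedback, done)};
#'   \code{feedback} is "none", "negative" or "target".
#' @export
trial_step <- function(session, action, ep, pay = payoffs(),
                       allow_leaf_requery = FALSE) {
  if (session$done) stop("trial already terminated")
  stopifnot(action %in% 1:15)
  tr <- session$trial
  if (action <= 7) {
    scale <- if (identical(session$last_action, as.integer(action)))
      pay$requery_scale else pay$query_scale
    e <- sample_evidence(tr$coherence[action], tr$direction[action], ep, n = 1)
    delta <- -pay$query * scale
    out <- list(observation = e, points_delta = delta, feedback = "none",
                done = FALSE)
    session$n_queries <- session$n_queries + 1L
  } else if (action == tr$target) {
    out <- list(observation = NA_real_, points_delta = pay$target,
                feedback = "target", done = TRUE)
    session$done <- TRUE
  } else {
    if (action %in% session$visited && !allow_leaf_requery)
      stop("leaf ", action, " already known to be wrong")
    out <- list(observation = NA_real_, points_delta = -pay$wrong_leaf,
                feedback = "negative", done = FALSE)
    session$visited <- union(session$visited, as.integer(action))
    session$n_errors <- session$n_errors + 1L
  }
  session$points <- session$points + out$points_delta
  session$last_action <- as.integer(action)
  session$last <- out
  session
}
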