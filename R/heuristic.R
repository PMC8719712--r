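#' Heuristic-agent parameters
#'
#' The heuristic agent queries internal nodes under the detection model's
#' rules and, after an error at a leaf, uses the confidence of the choices
#' along the error path to decide which node to blame and what to query
#' next. Its single free parameter is the confidence threshold
#' \code{omega}: choices with confidence below it count as low-confidence.
#'
#' @param det a [detection_params()] object (sensory parameters and
#'   criteria, typically from a detection-model fit)
#' @param omega confidence threshold in [0, 1]
#' @return object of class \code{"heuristic_params"}
#' @export
heuristic_params <- function(det, omega) {
  stopifnot(inherits(det, "detection_params"), omega >= 0, omega <= 1)
  structure(list(det = det, omega = omega), class = "heuristic_params")
}

#' Blame assignment after a leaf error
#'
#' Implements the post-error rule on the error path \eqn{P_T} of the
#' failed leaf, restricted to blame-\emph{eligible} nodes (a node loses
#' eligibility when blamed and regains it when new evidence is sampled
#' from it):
#' \itemize{
#' \item if at least two eligible path nodes were decided with confidence
#'   below \code{omega}, blame the highest-level one and re-query it
#'   (\emph{on-path});
#' \item otherwise, if any node is eligible, blame the least-confident
#'   eligible node and query its counterfactual child -- the child not on
#'   the error path (\emph{off-path});
#' \item if no node is eligible, no blame is assigned and the next action
#'   is a uniformly random unvisited leaf (\emph{fallback}).
#' }
#'
#' @param error_leaf spatial leaf id 8..15 where the error occurred
#' @param confidences numeric length 3: confidence that the choice
#'   \emph{toward the error leaf} was correct at the level-1, -2, -3
#'   ancestors
#' @param eligibility logical length 3, blame eligibility of the same nodes
#' @param omega confidence threshold
#' @param visited leaves already known wrong (for the fallback draw)
#' @param tree a [build_tree()] object
#' @return list with \code{blamed} (node id or NA), \code{next_query}
#'   (node id), \code{path_type} ("on", "off" or "fallback")
#' @export
assign_blame <- function(error_leaf, confidences, eligibility, omega,
                         visited = integer(0), tree = build_tree()) {
  stopifnot(length(confidences) == 3, length(eligibility) == 3)
  anc <- tree_ancestors(tree, error_leaf)
  low <- eligibility & (confidences < omega)
  if (!any(eligibility)) {
    cand <- setdiff(tree$leaves, union(visited, error_leaf))
    nxt <- if (length(cand) == 1) cand else sample(cand, 1)
    return(list(blamed = NA_integer_, next_query = nxt, path_type = "fallback"))
  }
  if (sum(low) >= 2) {
    lev <- which(low)[1]                     # highest level = closest to root
    return(list(blamed = anc[lev], next_query = anc[lev], path_type = "on"))
  }
  lev <- which(eligibility)[which.min(confidences[eligibility])]
  cf <- tree_counterfactual(tree, error_leaf)[lev]
  list(blamed = anc[lev], next_query = cf, path_type = "off")
}

#' Simulate heuristic-agent sessions
#'
#' Runs full task sessions of the heuristic agent (compiled simulator):
#' detection-model querying with the collapsing criterion, leaf
#' commitment from level 3, leaf memory (a visited wrong leaf is never
#' queried again; a level-3 choice pointing at one triggers the post-error
#' rules at zero cost), and confidence-based blame after every error.
#'
#' @param params a [heuristic_params()] object
#' @param n_trials number of trials
#' @param task a [task_config()]
#' @param full_log also return the per-query session log (memory-heavy for
#'   large \code{n_trials})
#' @param subject subject label attached to the returned log
#' @param max_steps per-trial safeguard
#' @return list with
#'   \item{trials}{per-trial data frame: \code{reward}, queries per level
#'     \code{q1..q3}, \code{errors}, \code{errors_synthetic} (remembered
#'     errors that charged no points)}
#'   \item{errors}{per-error data frame in canonical numbering: error-path
#'     coherences \code{coh1..3}, confidences, eligibilities, blamed node
#'     and level (0 = none), \code{path_type} (1 on / 2 off / 3 fallback),
#'     next queried node, synthetic flag}
#'   \item{log}{(if \code{full_log}) session log as in [run_bayes_agent()]}
#' @export
run_heuristic_agent <- function(params, n_trials, task = task_config(),
                                full_log = FALSE, subject = "heuristic",
                                max_steps = 400) {
  stopifnot(inherits(params, "heuristic_params"))
  d <- params$det
  out <- cpp_heuristic_sessions(as.integer(n_trials), task$coherences,
                                d$kappa, d$gamma, d$t, d$phi, d$lambda,
                                params$omega,
                                task$pay$query, task$pay$wrong_leaf,
                                task$pay$target, full_log,
                                as.integer(max_steps))
  if (full_log) {
    lg <- out$log
    fb <- c("none", "negative", "target")[lg$feedback + 1L]
    out$log <- data.frame(subject = subject, trial = as.integer(lg$trial),
                          step = as.integer(lg$step),
                          node = as.integer(lg$node),
                          node_canonical = as.integer(lg$node_canonical),
                          level = as.integer(lg$level), coh = lg$coh,
                          dir = lg$dir, e = lg$e, n_q = as.integer(lg$n_q),
                          q = as.integer(lg$q), feedback = fb,
                          points = lg$points)
  }
  out
}

#' Proportion of on-path post-error queries
#'
#' Number of on-path queries divided by the total number of leaf errors.
#'
#' @param sim a [run_heuristic_agent()] result (or its \code{errors} frame)
#' @return proportion in [0, 1]
#' @export
p_on_path <- function(sim) {
  err <- if (is.data.frame(sim)) sim else sim$errors
  if (nrow(err) == 0) return(NA_real_)
  mean(err$path_type == 1)
}

#' Fit the confidence threshold omega
#'
#' Grid search minimizing the absolute difference between the simulated
#' and observed proportions of on-path post-error queries, with common
#' random numbers across grid points (the RNG is re-seeded identically
#' before each evaluation) and one local grid refinement around the coarse
#' minimum.
#'
#' @param observed_p_on target on-path proportion in [0, 1]
#' @param det a [detection_params()] object
#' @param task a [task_config()]
#' @param n_trials simulated trials per evaluation (default 20000)
#' @param n_grid points per grid pass (default 41)
#' @param seed seed for the common random numbers
#' @return list with \code{omega}, \code{err} (objective at the optimum),
#'   \code{grid} (data frame of all evaluations)
#' @export
fit_omega <- function(observed_p_on, det, task = task_config(),
                      n_trials = 20000, n_grid = 41, seed = 1) {
  stopifnot(observed_p_on >= 0, observed_p_on <= 1)
  evals <- function(omegas) {
    vapply(omegas, function(w) {
      set.seed(seed)
      p_on_path(run_heuristic_agent(heuristic_params(det, w), n_trials, task))
    }, numeric(1))
  }
  g1 <- seq(0.02, 0.98, length.out = n_grid)
  p1 <- evals(g1)
  i <- which.min(abs(p1 - observed_p_on))
  lo <- g1[max(i - 1, 1)]; hi <- g1[min(i + 1, n_grid)]
  g2 <- seq(lo, hi, length.out = n_grid)
  p2 <- evals(g2)
  grid <- data.frame(omega = c(g1, g2), p_on = c(p1, p2),
                     err = abs(c(p1, p2) - observed_p_on))
  j <- which.min(grid$err)
  list(omega = grid$omega[j], err = grid$err[j], grid = grid)
}
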