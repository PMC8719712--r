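#' Rollout-planner configuration
#'
#' The approximately optimal agent scores each of the 15 candidate next
#' actions by Monte-Carlo rollouts: it samples a latent state from the
#' current posterior, imagines playing out a constrained random policy
#' (internal-node query with probability 7/15, uniform over the 7 nodes;
#' otherwise the unvisited leaf with the highest current target belief)
#' until the sampled target is found, and averages the incurred cost. The
#' executed action is the one with the lowest mean cost.
#'
#' @param n_rollouts rollouts per candidate action (default 2000; smaller
#'   values give a faster, noisier planner)
#' @param max_depth rollout depth safeguard; past it the worst-case
#'   remaining cost is charged (default 200)
#' @return object of class \code{"rollout_config"}
#' @export
rollout_config <- function(n_rollouts = 2000, max_depth = 200) {
  stopifnot(n_rollouts >= 1, max_depth >= 10)
  structure(list(n_rollouts = n_rollouts, max_depth = max_depth),
            class = "rollout_config")
}

#' Sample a latent state from the posterior
#'
#' Directions are drawn from the renormalized joint direction-combination
#' distribution (so the implied target is never a visited wrong leaf);
#' coherences are then drawn per node from P(c | d, E_i).
#'
#' @param belief a [init_beliefs()] state
#' @return list with \code{direction} (length 7, ±1), \code{coherence}
#'   (length 7) and \code{target} (spatial leaf id)
#' @export
sample_state <- function(belief) {
  pk <- combo_probs_norm(belief)
  tgt <- attr(pk, "target")
  k <- sample.int(128, 1, prob = pk)
  dirs <- .combos()$combos[k, ]
  coh <- numeric(7)
  for (i in 1:7) {
    idx <- if (dirs[i] > 0) 6:10 else 1:5
    w <- belief$tables[i, idx]
    coh[i] <- belief$coherences[sample.int(5, 1, prob = w)]
  }
  list(direction = dirs, coherence = coh, target = tgt[k])
}

#' Mean rollout cost of each candidate action
#'
#' @param belief a belief state
#' @param pay a [payoffs()] object; the \code{query_scale} /
#'   \code{requery_scale} multipliers implement the modified-payoff planner
#'   variants
#' @param config a [rollout_config()]
#' @return numeric vector of length 15 (mean points lost; negative values
#'   are expected gains)
#' @export
rollout_costs <- function(belief, pay = payoffs(), config = rollout_config()) {
  cpp_rollout_costs(belief$tables, belief$V, belief$coherences,
                    belief$ep$kappa, belief$ep$gamma, belief$ep$t,
                    pay$query * pay$query_scale,
                    pay$query * pay$requery_scale,
                    pay$wrong_leaf, pay$target,
                    config$n_rollouts, config$max_depth)
}

#' Select the next action by rollouts
#'
#' Argmin of [rollout_costs()]; ties broken uniformly at random.
#'
#' @inheritParams rollout_costs
#' @return node id 1..15
#' @export
select_action <- function(belief, pay = payoffs(), config = rollout_config()) {
  costs <- rollout_costs(belief, pay, config)
  cands <- which(costs <= min(costs) + 1e-12)
  if (length(cands) == 1) cands else sample(cands, 1)
}

#' Run the Bayesian rollout-planner agent
#'
#' Full task sessions: at every step the planner scores all 15 actions by
#' rollouts under the (possibly cost-scaled) planning payoffs, executes the
#' best one in the world, observes the outcome under the \emph{true}
#' payoffs, and updates its beliefs exactly. Payoff variants:
#' \code{"standard"}, \code{"cheap30"} (internal queries planned at 30\% of
#' their cost) and \code{"requery5"} (queries at 50\%, immediate re-queries
#' at 5\%).
#'
#' @param ep sensory parameters ([evidence_params()] or
#'   [detection_params()]), typically from a detection-model fit
#' @param n_trials number of trials
#' @param config a [rollout_config()]
#' @param task a [task_config()]
#' @param variant payoff variant for planning
#' @param subject subject label stored in the log
#' @param max_actions per-trial safeguard on executed actions
#' @return a session-log data frame (one row per executed action) with
#'   columns \code{subject, trial, step, node, node_canonical, level, coh,
#'   dir, e, n_q, q, feedback, points}
#' @export
run_bayes_agent <- function(ep, n_trials, config = rollout_config(),
                            task = task_config(),
                            variant = c("standard", "cheap30", "requery5"),
                            subject = "bayes", max_actions = 100) {
  variant <- match.arg(variant)
  plan_pay <- switch(variant,
    standard = task$pay,
    cheap30 = payoffs(task$pay$query, task$pay$wrong_leaf, task$pay$target,
                      query_scale = 0.3),
    requery5 = payoffs(task$pay$query, task$pay$wrong_leaf, task$pay$target,
                       query_scale = 0.5, requery_scale = 0.05))
  world_pay <- task$pay
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    trial <- sample_trial(task)
    sess <- start_session(trial)
    belief <- init_beliefs(ep, task$coherences)
    step <- 0L; n_q <- 0L
    rec <- list()
    while (!sess$done && step < max_actions) {
      step <- step + 1L
      a <- select_action(belief, plan_pay, config)
      n_q <- if (identical(sess$last_action, as.integer(a)) && a <= 7) n_q + 1L else 0L
      sess <- trial_step(sess, a, ep, world_pay,
                         allow_leaf_requery = TRUE)
      out <- sess$last
      if (a <= 7) {
        belief <- update_node_posterior(belief, a, out$observation)
        coh_a <- trial$coherence[a]; dir_a <- trial$direction[a]
      } else {
        if (out$feedback == "negative") belief <- mark_visited(belief, a)
        coh_a <- NA_real_; dir_a <- NA_real_
      }
      rec[[step]] <- data.frame(
        subject = subject, trial = tr, step = step, node = as.integer(a),
        node_canonical = trial$map$to_canonical[a],
        level = build_tree()$level[a], coh = coh_a, dir = dir_a,
        e = out$observation, n_q = n_q, q = step,
        feedback = out$feedback, points = out$points_delta)
    }
    rows[[tr]] <- do.call(rbind, rec)
  }
  do.call(rbind, rows)
}

# ---- reduced single-node task (oracle cross-check) -------------------------

#' Exact policy for the reduced single-node task
#'
#' A one-bifurcation task with a single internal node of \emph{known}
#' coherence and two leaves: the belief state is the scalar
#' \eqn{p = P(d = +1)}. After a wrong leaf the target is known, so
#' choosing the better leaf is worth \eqn{R - W(1 - \max(p, 1-p))} and the
#' query value follows from one-step lookahead; value iteration over a
#' belief grid with Gauss-like quadrature over the evidence gives the exact
#' optimal action for every p. Used as an independent oracle for the
#' rollout planner.
#'
#' @param p_grid belief grid in (0, 1)
#' @param coh the node's (known) coherence
#' @param ep sensory parameters
#' @param pay a [payoffs()] object
#' @param n_e evidence quadrature points
#' @param tol value-iteration convergence tolerance
#' @return data frame with \code{p}, \code{v_query}, \code{v_leaf},
#'   \code{action} ("query", "leaf_right", "leaf_left")
#' @export
reduced_task_dp <- function(p_grid, coh, ep, pay = payoffs(), n_e = 801,
                            tol = 1e-10) {
  mu <- evidence_mean(coh, 1, ep)
  sigma <- evidence_sd(coh, ep)
  eg <- seq(-mu - 8 * sigma, mu + 8 * sigma, length.out = n_e)
  h <- eg[2] - eg[1]
  fp <- stats::dnorm(eg, mu, sigma)
  fm <- stats::dnorm(eg, -mu, sigma)
  # dense internal grid for interpolating the value function
  pg <- seq(0, 1, length.out = 2001)
  v_leaf <- function(p) pay$target - pay$wrong_leaf * (1 - pmax(p, 1 - p))
  V <- v_leaf(pg)
  repeat {
    Vq <- vapply(pg, function(p) {
      dens <- p * fp + (1 - p) * fm
      pp <- p * fp / pmax(dens, 1e-300)
      -pay$query * pay$query_scale +
        h * sum(dens * stats::approx(pg, V, xout = pp, rule = 2)$y)
    }, numeric(1))
    Vnew <- pmax(v_leaf(pg), Vq)
    if (max(abs(Vnew - V)) < tol) { V <- Vnew; break }
    V <- Vnew
  }
  vq <- vapply(p_grid, function(p) {
    dens <- p * fp + (1 - p) * fm
    pp <- p * fp / pmax(dens, 1e-300)
    -pay$query * pay$query_scale +
      h * sum(dens * stats::approx(pg, V, xout = pp, rule = 2)$y)
  }, numeric(1))
  vl <- v_leaf(p_grid)
  data.frame(p = p_grid, v_query = vq, v_leaf = vl,
             action = ifelse(vq > vl, "query",
                             ifelse(p_grid >= 0.5, "leaf_right", "leaf_left")))
}

#' Rollout planner on the reduced single-node task
#'
#' Same machinery as the full planner (sample a state from the belief,
#' random playouts, argmin mean cost) on the reduced task, for comparison
#' with [reduced_task_dp()]. Playout policy: query with probability 1/3
#' (one internal node out of three actions), otherwise the
#' highest-belief unvisited leaf.
#'
#' @inheritParams reduced_task_dp
#' @param p current belief P(d = +1)
#' @param n_rollouts rollouts per action
#' @param max_depth depth safeguard
#' @return list with \code{action} ("query", "leaf_right", "leaf_left") and
#'   \code{costs} (mean rollout cost per action)
#' @export
reduced_task_rollout <- function(p, coh, ep, pay = payoffs(),
                                 n_rollouts = 2000, max_depth = 50) {
  mu <- evidence_mean(coh, 1, ep)
  sigma <- evidence_sd(coh, ep)
  qc <- pay$query * pay$query_scale
  one_rollout <- function(first) {
    d_true <- if (stats::runif(1) < p) 1 else -1
    target <- if (d_true > 0) "leaf_right" else "leaf_left"
    pb <- p; visited <- character(0); cost <- 0
    act <- first
    for (i in seq_len(max_depth)) {
      if (act == "query") {
        cost <- cost + qc
        e <- stats::rnorm(1, d_true * mu, sigma)
        lp <- stats::dnorm(e, mu, sigma); lm <- stats::dnorm(e, -mu, sigma)
        pb <- pb * lp / (pb * lp + (1 - pb) * lm)
      } else if (act == target) {
        return(cost - pay$target)
      } else {
        visited <- union(visited, act)
        cost <- cost + pay$wrong_leaf
        pb <- if (act == "leaf_right") 0 else 1   # error reveals the truth
      }
      if (stats::runif(1) < 1 / 3) act <- "query"
      else {
        unvis <- setdiff(c("leaf_right", "leaf_left"), visited)
        act <- if (length(unvis) == 1) unvis
        else if (pb > 0.5) "leaf_right" else if (pb < 0.5) "leaf_left"
        else sample(unvis, 1)
      }
    }
    cost + pay$wrong_leaf - pay$target
  }
  acts <- c("query", "leaf_right", "leaf_left")
  costs <- vapply(acts, function(a)
    mean(vapply(seq_len(n_rollouts), function(i) one_rollout(a), numeric(1))),
    numeric(1))
  best <- which(costs <= min(costs) + 1e-12)
  list(action = acts[if (length(best) == 1) best else sample(best, 1)],
       costs = costs)
}
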