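# Myopic active-sensing policies scored on the target-belief distribution
# B(T | E, V): probability gain (expected increase of the posterior peak),
# information gain (expected entropy reduction, bits) and impact (expected
# total absolute belief change). Norms never read the payoffs.

.leaf_indicator <- function() {
  # 8 x 128 matrix mapping combination probabilities to leaf beliefs
  cc <- .combos()
  A <- matrix(0, 8, 128)
  A[cbind(cc$combo_target - 7L, 1:128)] <- 1
  A
}

#' Observation likelihood of an action
#'
#' For an internal node, the predictive density of the next evidence pulse:
#' a 10-component Gaussian mixture weighted by P(c | d, E_i) times the
#' post-error conditional direction marginal P_i(d | E, V). For a leaf, the
#' two-outcome probabilities (target / not target) given by B(T | E, V).
#'
#' @param belief a [init_beliefs()] state
#' @param node node id 1..15
#' @param grid_n quadrature points for the internal-node density
#' @param span_sd half-width of the evidence grid in units of the largest
#'   mixture standard deviation beyond the largest |mean|
#' @return for an internal node, a list \code{(e, density)}; for a leaf, a
#'   named vector \code{c(target = B, nontarget = 1 - B)}
#' @export
observation_likelihood <- function(belief, node, grid_n = 401, span_sd = 8) {
  if (node >= 8) {
    B <- target_beliefs(belief)[as.character(node)]
    return(c(target = unname(B), nontarget = unname(1 - B)))
  }
  ep <- belief$ep; coh <- belief$coherences
  wd <- conditional_direction_marginal(belief, node)
  row <- belief$tables[node, ]
  pc_minus <- row[1:5] / max(sum(row[1:5]), 1e-300)
  pc_plus <- row[6:10] / max(sum(row[6:10]), 1e-300)
  w <- c(pc_minus * wd["-1"], pc_plus * wd["1"])
  mu <- c(evidence_mean(coh, -1, ep), evidence_mean(coh, 1, ep))
  sd <- rep(evidence_sd(coh, ep), 2)
  half <- max(abs(mu)) + span_sd * max(sd)
  e <- seq(-half, half, length.out = grid_n)
  dens <- colSums(w * t(outer(e, seq_along(mu),
                              function(x, j) stats::dnorm(x, mu[j], sd[j]))))
  list(e = e, density = dens)
}

.norm_functional <- function(norm, Bnew, B0) {
  # Bnew: 8 x n matrix of updated beliefs (columns), B0 current beliefs
  switch(norm,
    pg = apply(Bnew, 2, max) - max(B0),
    ig = {
      h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
      h(B0) - apply(Bnew, 2, h)
    },
    impact = colSums(abs(Bnew - B0)),
    stop("unknown norm: ", norm))
}

#' Myopic norm scores for all 15 actions
#'
#' Expectation, over the observation likelihood of each action, of the
#' norm's functional of the updated target beliefs. Internal-node
#' expectations use deterministic trapezoid quadrature on the evidence
#' grid; leaf expectations enumerate the two outcomes exactly.
#'
#' @param belief a belief state
#' @param norm one of \code{"pg"}, \code{"ig"}, \code{"impact"}
#' @param grid_n evidence quadrature points (default 401)
#' @return numeric vector of length 15 (one score per action)
#' @export
norm_scores <- function(belief, norm = c("pg", "ig", "impact"), grid_n = 401) {
  norm <- match.arg(norm)
  B0 <- target_beliefs(belief)
  cc <- .combos()
  A <- .leaf_indicator()
  scores <- numeric(15)

  # leaves: exact two-outcome computation
  for (Tl in 8:15) {
    b <- B0[as.character(Tl)]
    Bhit <- numeric(8); Bhit[Tl - 7] <- 1
    if (b >= 1 - 1e-12) {
      Bnew <- matrix(Bhit, 8, 1); wts <- 1
    } else {
      bmiss <- target_beliefs(mark_visited(belief, Tl))
      Bnew <- cbind(Bhit, bmiss); wts <- c(b, 1 - b)
    }
    scores[Tl] <- sum(wts * .norm_functional(norm, Bnew, B0))
  }

  # internal nodes: vectorized over the evidence grid; only node i's
  # direction marginal depends on the observation
  mp <- direction_marginal_plus(belief)
  vis_row <- if (length(belief$V)) cc$combo_target %in% belief$V else rep(FALSE, 128)
  ep <- belief$ep; coh <- belief$coherences
  mu <- c(evidence_mean(coh, -1, ep), evidence_mean(coh, 1, ep))
  sd <- rep(evidence_sd(coh, ep), 2)
  for (i in 1:7) {
    ol <- observation_likelihood(belief, i, grid_n)
    h <- ol$e[2] - ol$e[1]
    wts <- ol$density * h
    wts <- wts / sum(wts)
    # posterior direction marginal of node i after each possible pulse
    lik <- outer(seq_along(mu), ol$e, function(j, x) stats::dnorm(x, mu[j], sd[j]))
    post <- belief$tables[i, ] * lik          # 10 x G
    mplus_e <- colSums(post[6:10, , drop = FALSE]) / colSums(post)
    pk_other <- rep(1, 128)
    for (j in setdiff(1:7, i))
      pk_other <- pk_other * ifelse(cc$combo_plus[, j], mp[j], 1 - mp[j])
    fac <- matrix(0, 128, length(ol$e))
    fac[cc$combo_plus[, i], ] <- rep(mplus_e, each = sum(cc$combo_plus[, i]))
    fac[!cc$combo_plus[, i], ] <- rep(1 - mplus_e, each = sum(!cc$combo_plus[, i]))
    PK <- pk_other * fac
    PK[vis_row, ] <- 0
    PK <- sweep(PK, 2, pmax(colSums(PK), 1e-300), "/")
    Bnew <- A %*% PK
    scores[i] <- sum(wts * .norm_functional(norm, Bnew, B0))
  }
  scores
}

#' @rdname norm_scores
#' @param action node id 1..15
#' @export
norm_score <- function(belief, action, norm = c("pg", "ig", "impact"),
                       grid_n = 401) {
  norm_scores(belief, norm, grid_n)[action]
}

.log_row <- function(subject, tr, step, a, trial, out, n_q, tree) {
  data.frame(subject = subject, trial = tr, step = step, node = as.integer(a),
             node_canonical = trial$map$to_canonical[a],
             level = tree$level[a],
             coh = if (a <= 7) trial$coherence[a] else NA_real_,
             dir = if (a <= 7) trial$direction[a] else NA_real_,
             e = out$observation, n_q = n_q, q = step,
             feedback = out$feedback, points = out$points_delta)
}

#' Run a myopic norm agent
#'
#' At every step the agent executes the action with the highest norm score
#' (ties broken uniformly at random), never re-choosing a leaf already
#' known to be wrong. The scores never read the payoffs, so these policies
#' are payoff-insensitive by construction.
#'
#' @param norm \code{"pg"}, \code{"ig"} or \code{"impact"}
#' @param ep sensory parameters
#' @param n_trials number of trials
#' @param task a [task_config()]
#' @param subject subject label for the log
#' @param grid_n quadrature resolution
#' @param max_actions per-trial safeguard
#' @return a session-log data frame (schema as [run_bayes_agent()])
#' @export
run_norm_agent <- function(norm, ep, n_trials, task = task_config(),
                           subject = norm, grid_n = 401, max_actions = 60) {
  norm <- match.arg(norm, c("pg", "ig", "impact"))
  tree <- build_tree()
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    trial <- sample_trial(task)
    sess <- start_session(trial)
    belief <- init_beliefs(ep, task$coherences)
    step <- 0L; n_q <- 0L
    rec <- list()
    while (!sess$done && step < max_actions) {
      step <- step + 1L
      B <- target_beliefs(belief)
      if (max(B) >= 1 - 1e-9) {
        # target certain: no action can change beliefs and every score is
        # zero, so the endgame is forced -- cash in on the certain leaf
        a <- as.integer(names(B)[which.max(B)])
      } else {
        sc <- norm_scores(belief, norm, grid_n)
        sc[sess$visited] <- -Inf
        cands <- which(sc >= max(sc) - 1e-9)
        a <- if (length(cands) == 1) cands else sample(cands, 1)
      }
      n_q <- if (identical(sess$last_action, as.integer(a)) && a <= 7) n_q + 1L else 0L
      sess <- trial_step(sess, a, ep, task$pay)
      out <- sess$last
      if (a <= 7) belief <- update_node_posterior(belief, a, out$observation)
      else if (out$feedback == "negative") belief <- mark_visited(belief, a)
      rec[[step]] <- .log_row(subject, tr, step, a, trial, out, n_q, tree)
    }
    rows[[tr]] <- do.call(rbind, rec)
  }
  do.call(rbind, rows)
}

#' Run the uniform random-leaf policy
#'
#' Never queries internal nodes; chooses unvisited leaves uniformly at
#' random until the target is found. With the standard payoffs its expected
#' reward is \eqn{10 - 3 \cdot 7/2 = -0.5} points per trial.
#'
#' @inheritParams run_norm_agent
#' @return a session-log data frame
#' @export
run_random_leaf_agent <- function(n_trials, task = task_config(),
                                  subject = "random_leaf") {
  tree <- build_tree()
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    trial <- sample_trial(task)
    sess <- start_session(trial)
    step <- 0L
    rec <- list()
    while (!sess$done) {
      step <- step + 1L
      a <- if (length(sess$visited) == 7) setdiff(8:15, sess$visited)
      else sample(setdiff(8:15, sess$visited), 1)
      sess <- trial_step(sess, a, evidence_params(1), task$pay)
      rec[[step]] <- .log_row(subject, tr, step, a, trial, sess$last, 0L, tree)
    }
    rows[[tr]] <- do.call(rbind, rec)
  }
  do.call(rbind, rows)
}
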