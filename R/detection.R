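#' Detection-model parameters
#'
#' Parameters of the extrema-detection choice model for internal-node
#' queries: sensory signal-to-noise \code{kappa} and variance slope
#' \code{gamma} (see [evidence_params()]), a base criterion per tree level
#' \code{phi} (length 3, evidence units), and the criterion decay rate
#' \code{lambda} (per successive query). After each query the evidence
#' pulse is compared against the symmetric criteria at
#' \eqn{\pm\Phi_\ell(n_q)}; evidence beyond the criterion commits to the
#' corresponding child, evidence inside the dead zone is discarded and the
#' node is re-queried.
#'
#' @param kappa signal-to-noise, > 0
#' @param gamma variance slope, >= 0
#' @param phi base criteria for levels 1..3, each >= 0
#' @param lambda criterion decay rate, >= 0
#' @param t pulse duration in seconds
#' @return object of class \code{"detection_params"} (also usable wherever
#'   an [evidence_params()] object is expected)
#' @export
detection_params <- function(kappa, gamma, phi, lambda, t = 0.227) {
  stopifnot(kappa > 0, gamma >= 0, length(phi) == 3, all(phi >= 0), lambda >= 0)
  structure(list(kappa = kappa, gamma = gamma, phi = phi, lambda = lambda, t = t),
            class = c("detection_params", "evidence_params"))
}

#' Decision criterion
#'
#' The criterion applied to an evidence pulse at a level-\code{level} node
#' after \code{n_q} immediately preceding successive queries of that node
#' (\code{n_q = 0} for the first query of a streak):
#' \deqn{\Phi_\ell = \phi_\ell (1 + e^{-\lambda n_q}).}
#' The criterion starts at \eqn{2\phi_\ell} and collapses towards
#' \eqn{\phi_\ell} as queries accumulate.
#'
#' @param level tree level 1..3 (vectorized)
#' @param n_q streak counter >= 0 (vectorized)
#' @param params a [detection_params()] object
#' @return numeric vector of criterion values
#' @export
criterion <- function(level, n_q, params) {
  stopifnot(all(level %in% 1:3), all(n_q >= 0))
  params$phi[level] * (1 + exp(-params$lambda * n_q))
}

.gauss_trichotomy <- function(mu, sigma, Phi) {
  p_right <- stats::pnorm(Phi, mean = mu, sd = sigma, lower.tail = FALSE)
  p_left <- stats::pnorm(-Phi, mean = mu, sd = sigma)
  list(p_right = p_right, p_left = p_left,
       p_requery = pmax(1 - p_right - p_left, 0))
}

#' Trinomial choice probabilities of the detection model
#'
#' Probability that a single evidence pulse at a node with coherence
#' \code{c} and direction \code{d} exceeds the criteria at
#' \eqn{\pm\Phi_\ell(n_q)} (commit right / commit left) or falls inside
#' the dead zone (re-query). These are plain Gaussian tail probabilities of
#' the pulse distribution \eqn{N(\kappa d c t, t(1+c\gamma))}. Vectorized.
#'
#' @inheritParams criterion
#' @param c coherence (proportion)
#' @param d direction, -1 or +1
#' @return list with numeric vectors \code{p_right}, \code{p_left},
#'   \code{p_requery} (summing to 1)
#' @export
choice_probs <- function(c, d, level, n_q, params) {
  mu <- evidence_mean(c, d, params)
  sigma <- evidence_sd(c, params)
  .gauss_trichotomy(mu, sigma, criterion(level, n_q, params))
}

.check_query_table <- function(tbl) {
  need <- c("c", "d", "level", "n_q", "outcome")
  if (!all(need %in% names(tbl)))
    stop("query table must have columns ", paste(need, collapse = ", "))
  if (!all(tbl$outcome %in% c("right", "left", "requery")))
    stop("outcome must be one of 'right', 'left', 'requery'")
  invisible(tbl)
}

#' Log-likelihood of a query table under the detection model
#'
#' Each row of \code{tbl} is one internal-node query with columns \code{c},
#' \code{d}, \code{level}, \code{n_q} and \code{outcome} in
#' \{"right", "left", "requery"\}. The table is expected to contain the
#' fitting subset only: queries followed by a re-query or by a query at one
#' of the two child nodes (see [query_table_from_log()]).
#'
#' @param tbl query table (data frame)
#' @param params a [detection_params()] object
#' @return total log-likelihood (0 for an empty table)
#' @export
detection_loglik <- function(tbl, params) {
  .check_query_table(tbl)
  if (nrow(tbl) == 0) return(0)
  p <- choice_probs(tbl$c, tbl$d, tbl$level, tbl$n_q, params)
  pr <- ifelse(tbl$outcome == "right", p$p_right,
               ifelse(tbl$outcome == "left", p$p_left, p$p_requery))
  sum(log(pmax(pr, 1e-300)))
}

#' Conditional per-pulse outcome probabilities of the integration model
#'
#' In the integration variant the evidence from successive queries of a
#' node is accumulated: after pulse \eqn{k} the decision is based on
#' \eqn{e_1 + \dots + e_k}, compared against the (collapsing) criteria
#' \eqn{\pm\Phi_\ell(k-1)}. This function propagates the surviving density
#' of the cumulative sum on a discrete evidence grid (FFT convolution,
#' trapezoid weights) and returns, for each pulse, the probability of
#' exiting right / left / continuing, \emph{conditional on having survived
#' the previous pulses}.
#'
#' @inheritParams choice_probs
#' @param n_pulses number of pulses to propagate
#' @param grid_n grid resolution (default 2001 points)
#' @return \code{n_pulses} x 3 matrix with columns \code{right},
#'   \code{left}, \code{continue}; row 1 equals the single-pulse
#'   [choice_probs()].
#' @export
integration_pulse_probs <- function(c, d, level, params, n_pulses,
                                    grid_n = 2001) {
  stopifnot(length(c) == 1, n_pulses >= 1, grid_n >= 201)
  mu <- evidence_mean(c, d, params)
  sigma <- evidence_sd(c, params)
  Phi <- criterion(rep(level, n_pulses), seq_len(n_pulses) - 1, params)
  out <- matrix(NA_real_, n_pulses, 3,
                dimnames = list(NULL, c("right", "left", "continue")))
  p1 <- .gauss_trichotomy(mu, sigma, Phi[1])
  out[1, ] <- c(p1$p_right, p1$p_left, p1$p_requery)
  if (n_pulses == 1) return(out)

  half <- max(Phi) + 8 * sigma
  if (grid_n %% 2 == 0) grid_n <- grid_n + 1
  x <- seq(-half, half, length.out = grid_n)
  h <- x[2] - x[1]
  # conditional (renormalized) density of the surviving cumulative sum;
  # keeping it normalized avoids survival-probability underflow. The
  # pulse-to-pulse convolution runs through a zero-padded FFT with a
  # composite padded length (a prime length makes R's fft quadratic).
  g <- stats::dnorm(x, mu, sigma) * (abs(x) < Phi[1])
  mass <- h * sum(g)
  N <- stats::nextn(2 * grid_n - 1, c(2, 3, 5))
  fk <- stats::fft(c(stats::dnorm(x, mu, sigma) * h, numeric(N - grid_n)))
  mid <- ((grid_n + 1) / 2):((grid_n + 1) / 2 + grid_n - 1)
  for (k in 2:n_pulses) {
    if (mass <= 0) { out[k, ] <- c(0.5, 0.5, 0); next }
    g <- g / mass
    # exact Gaussian tails given the conditional surviving density
    out[k, "right"] <- h * sum(g * stats::pnorm(Phi[k] - x, mu, sigma,
                                                lower.tail = FALSE))
    out[k, "left"] <- h * sum(g * stats::pnorm(-Phi[k] - x, mu, sigma))
    out[k, "continue"] <- max(1 - out[k, "right"] - out[k, "left"], 0)
    if (k < n_pulses) {
      fg <- stats::fft(c(g, numeric(N - grid_n)))
      conv <- Re(stats::fft(fg * fk, inverse = TRUE))[mid] / N
      g <- pmax(conv, 0) * (abs(x) < Phi[k])
      mass <- h * sum(g)
    }
  }
  out
}

.streak_ids <- function(tbl) {
  if (!is.null(tbl$streak)) return(tbl$streak)
  cumsum(tbl$n_q == 0)
}

#' Log-likelihood of a query table under the integration model
#'
#' Rows within an uninterrupted streak at a node are not independent under
#' integration; the chain rule over conditional per-pulse probabilities
#' ([integration_pulse_probs()]) recovers the streak likelihood as a sum of
#' per-row log conditional probabilities. Streak membership is taken from a
#' \code{streak} column if present, else reconstructed from \code{n_q == 0}
#' boundaries.
#'
#' @inheritParams detection_loglik
#' @param grid_n grid resolution passed to [integration_pulse_probs()]
#' @return total log-likelihood
#' @export
integration_loglik <- function(tbl, params, grid_n = 2001) {
  .check_query_table(tbl)
  if (nrow(tbl) == 0) return(0)
  pulse <- tbl$n_q + 1L
  # d = -1 mirrors d = +1 with right/left outcomes swapped, so the density
  # propagation is only run once per (coherence, level) pair
  oc <- tbl$outcome
  oc[tbl$d < 0] <- c(right = "left", left = "right",
                     requery = "requery")[oc[tbl$d < 0]]
  key <- interaction(tbl$c, tbl$level, drop = TRUE)
  ll <- 0
  for (kk in levels(key)) {
    idx <- which(key == kk)
    np <- max(pulse[idx])
    cp <- integration_pulse_probs(tbl$c[idx[1]], 1, tbl$level[idx[1]],
                                  params, np, grid_n)
    col <- match(ifelse(oc[idx] == "requery", "continue", oc[idx]),
                 colnames(cp))
    ll <- ll + sum(log(pmax(cp[cbind(pulse[idx], col)], 1e-300)))
  }
  ll
}

# ---- fitting ---------------------------------------------------------------

.variants <- c("detection", "integration", "one_phi_three_kappa",
               "three_phi_three_kappa", "gamma0", "query_order")

.variant_pack <- function(variant) {
  # returns list(par names, lower, upper, start sampler, expand fn)
  switch(variant,
    detection = ,
    integration = list(
      names = c("kappa", "gamma", "phi1", "phi2", "phi3", "lambda"),
      lower = c(1e-3, 0, 0, 0, 0, 0), upper = c(500, 30, 15, 15, 15, 60),
      start = function() c(exp(stats::runif(1, log(2), log(60))),
                           stats::runif(1, 0, 3), stats::runif(3, 0.1, 2),
                           stats::runif(1, 0.1, 5)),
      make = function(p, t) detection_params(p[1], p[2], p[3:5], p[6], t)),
    gamma0 = list(
      names = c("kappa", "phi1", "phi2", "phi3", "lambda"),
      lower = c(1e-3, 0, 0, 0, 0), upper = c(500, 15, 15, 15, 60),
      start = function() c(exp(stats::runif(1, log(2), log(60))),
                           stats::runif(3, 0.1, 2), stats::runif(1, 0.1, 5)),
      make = function(p, t) detection_params(p[1], 0, p[2:4], p[5], t)),
    one_phi_three_kappa = list(
      names = c("kappa1", "kappa2", "kappa3", "gamma", "phi", "lambda"),
      lower = c(rep(1e-3, 3), 0, 0, 0), upper = c(rep(500, 3), 30, 15, 60),
      start = function() c(exp(stats::runif(3, log(2), log(60))),
                           stats::runif(1, 0, 3), stats::runif(1, 0.1, 2),
                           stats::runif(1, 0.1, 5)),
      make = NULL),
    three_phi_three_kappa = list(
      names = c("kappa1", "kappa2", "kappa3", "gamma",
                "phi1", "phi2", "phi3", "lambda"),
      lower = c(rep(1e-3, 3), 0, rep(0, 3), 0),
      upper = c(rep(500, 3), 30, rep(15, 3), 60),
      start = function() c(exp(stats::runif(3, log(2), log(60))),
                           stats::runif(1, 0, 3), stats::runif(3, 0.1, 2),
                           stats::runif(1, 0.1, 5)),
      make = NULL),
    query_order = list(
      names = c("kappa", "gamma", "phi0", "phi_inf", "eta", "lambda"),
      lower = c(1e-3, 0, 0, 0, -10, 0), upper = c(500, 30, 15, 15, 10, 60),
      start = function() c(exp(stats::runif(1, log(2), log(60))),
                           stats::runif(1, 0, 3), stats::runif(2, 0.1, 2),
                           stats::runif(1, -2, 0.5), stats::runif(1, 0.1, 5)),
      make = NULL),
    stop("unknown variant: ", variant))
}

.variant_loglik <- function(p, variant, tbl, t, grid_n) {
  if (variant %in% c("detection", "integration", "gamma0")) {
    pk <- .variant_pack(variant)
    prm <- pk$make(pmax(p, c(1e-3, rep(0, length(p) - 1))), t)
    if (variant == "integration") return(integration_loglik(tbl, prm, grid_n))
    return(detection_loglik(tbl, prm))
  }
  mu_sd_ll <- function(kappa_row, Phi) {
    mu <- kappa_row * tbl$d * tbl$c * t
    sigma <- sqrt(t * (1 + tbl$c * gamma))
    pp <- .gauss_trichotomy(mu, sigma, Phi)
    pr <- ifelse(tbl$outcome == "right", pp$p_right,
                 ifelse(tbl$outcome == "left", pp$p_left, pp$p_requery))
    sum(log(pmax(pr, 1e-300)))
  }
  if (variant == "one_phi_three_kappa") {
    kap <- p[1:3][tbl$level]; gamma <- p[4]
    Phi <- p[5] * (1 + exp(-p[6] * tbl$n_q))
    return(mu_sd_ll(kap, Phi))
  }
  if (variant == "three_phi_three_kappa") {
    kap <- p[1:3][tbl$level]; gamma <- p[4]
    Phi <- p[5:7][tbl$level] * (1 + exp(-p[8] * tbl$n_q))
    return(mu_sd_ll(kap, Phi))
  }
  if (variant == "query_order") {
    if (is.null(tbl$q)) stop("query_order variant requires a 'q' column ",
                             "(order of the query in the trial)")
    kap <- rep(p[1], nrow(tbl)); gamma <- p[2]
    base <- pmax(p[4] + (p[3] - p[4]) * exp(p[5] * (tbl$q - 1)), 0)
    Phi <- base * (1 + exp(-p[6] * tbl$n_q))
    return(mu_sd_ll(kap, Phi))
  }
  stop("unhandled variant")
}

#' Fit the detection model (or a variant) by maximum likelihood
#'
#' Maximizes the trinomial choice likelihood over the query table with a
#' multi-start bounded quasi-Newton scheme (L-BFGS-B from random starting
#' points, deterministic given \code{seed}). Variants are parameter-tying
#' options of the same likelihood: \code{"integration"} accumulates
#' evidence within streaks, \code{"gamma0"} fixes the variance slope at 0,
#' \code{"one_phi_three_kappa"} / \code{"three_phi_three_kappa"} let the
#' signal-to-noise vary by level, and \code{"query_order"} replaces the
#' level-dependent base criterion by an exponential function
#' \eqn{\phi_\infty + (\phi_0-\phi_\infty)e^{\eta(q-1)}} of the query's
#' order in the trial (requires a \code{q} column).
#'
#' @inheritParams detection_loglik
#' @param variant one of \code{"detection"}, \code{"integration"},
#'   \code{"one_phi_three_kappa"}, \code{"three_phi_three_kappa"},
#'   \code{"gamma0"}, \code{"query_order"}
#' @param n_starts number of optimizer starts (>= 8 recommended)
#' @param seed RNG seed for the starting points
#' @param grid_n integration-likelihood grid resolution
#' @param t pulse duration in seconds
#' @param init optional matrix (or vector) of additional starting points,
#'   one row per start, prepended to the random starts
#' @param maxit optimizer iteration cap per start
#' @param factr L-BFGS-B convergence factor (larger stops earlier); the
#'   slower integration likelihood tolerates a loose factor when only a
#'   BIC-scale comparison is needed
#' @return object of class \code{"detection_fit"}: list with \code{par}
#'   (named vector), \code{params} (a [detection_params()] object for the
#'   variants that map onto one, else NULL), \code{loglik}, \code{bic},
#'   \code{aic}, \code{n}, \code{k}, \code{variant}, \code{convergence}
#'   (per start), \code{seed}
#' @export
fit_detection <- function(tbl, variant = "detection", n_starts = 8, seed = 1,
                          grid_n = 2001, t = 0.227, init = NULL,
                          maxit = 500, factr = 1e7) {
  variant <- match.arg(variant, .variants)
  .check_query_table(tbl)
  pk <- .variant_pack(variant)
  negll <- function(p) -.variant_loglik(p, variant, tbl, t, grid_n)
  best <- NULL
  if (!is.null(init)) init <- matrix(init, ncol = length(pk$names))
  n_tot <- n_starts + NROW(init)
  conv <- integer(n_tot)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (s in seq_len(n_tot)) {
    p0 <- if (s <= NROW(init)) init[s, ] else pk$start()
    p0 <- pmin(pmax(p0, pk$lower), pk$upper)
    fit <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B",
                   lower = pk$lower, upper = pk$upper,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) { conv[s] <- NA_integer_; next }
    conv[s] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (is.null(best)) stop("all optimizer starts failed")
  if (all(is.na(conv) | conv != 0))
    warning("no optimizer start reported clean convergence")
  par <- stats::setNames(best$par, pk$names)
  n <- nrow(tbl); k <- length(par); ll <- -best$value
  prm <- if (!is.null(pk$make)) pk$make(par, t) else NULL
  structure(list(par = par, params = prm, loglik = ll,
                 bic = k * log(n) - 2 * ll, aic = 2 * k - 2 * ll,
                 n = n, k = k, variant = variant, convergence = conv,
                 seed = seed),
            class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat("Maximum-likelihood fit, variant:", x$variant, "\n")
  print(round(x$par, 4))
  cat(sprintf("logLik %.2f on n = %d queries; BIC %.1f; AIC %.1f\n",
              x$loglik, x$n, x$bic, x$aic))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit a [fit_detection()] result
#' @param path output path
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(variant = fit$variant, par = as.list(fit$par),
                            loglik = fit$loglik, bic = fit$bic, aic = fit$aic,
                            n = fit$n, seed = fit$seed),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Extract the fitting-subset query table from a session log
#'
#' Selects internal-node query rows whose immediately following action in
#' the same trial was either a re-query of the same node or a query of one
#' of its two children, and codes the outcome accordingly ("requery",
#' "right", "left"; spatial coordinates: right child = \code{2i + 1}). All
#' other rows are dropped; the number dropped is attached as attribute
#' \code{"n_dropped"}.
#'
#' @param log a session-log data frame (see [run_heuristic_agent()] and
#'   friends) with columns \code{subject}, \code{trial}, \code{step},
#'   \code{node}, \code{level}, \code{coh}, \code{dir}, \code{n_q}, \code{q}
#' @return a query table suitable for [fit_detection()]
#' @export
query_table_from_log <- function(log) {
  ord <- order(log$subject, log$trial, log$step)
  log <- log[ord, ]
  same_trial <- c(log$trial[-1] == log$trial[-nrow(log)] &
                    log$subject[-1] == log$subject[-nrow(log)], FALSE)
  nxt <- c(log$node[-1], NA_integer_)
  is_int <- log$node <= 7
  outcome <- rep(NA_character_, nrow(log))
  outcome[is_int & same_trial & nxt == log$node] <- "requery"
  outcome[is_int & same_trial & nxt == 2 * log$node] <- "left"
  outcome[is_int & same_trial & nxt == 2 * log$node + 1] <- "right"
  keep <- !is.na(outcome)
  out <- data.frame(c = log$coh[keep], d = log$dir[keep],
                    level = log$level[keep], n_q = log$n_q[keep],
                    q = if (!is.null(log$q)) log$q[keep] else NA_integer_,
                    outcome = outcome[keep])
  attr(out, "n_dropped") <- sum(is_int) - nrow(out)
  out
}
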