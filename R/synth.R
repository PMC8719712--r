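# Synthetic-data generation, session I/O and parameter-recovery harnesses.

#' Generate a synthetic query table from the detection model
#'
#' Draws i.i.d. (coherence, direction, level) conditions and simulates
#' query streaks under the detection model until a child choice, emitting
#' one row per query with the streak counter and outcome. Streaks are
#' whole: generation stops at the first streak boundary at or past
#' \code{n} rows.
#'
#' @param params a [detection_params()] object
#' @param n target number of query rows (>= 0)
#' @param coherences task coherence levels
#' @return query table with columns \code{c, d, level, n_q, outcome,
#'   streak} (suitable for [fit_detection()])
#' @export
generate_query_dataset <- function(params, n,
                                   coherences = c(0.032, 0.064, 0.128,
                                                  0.256, 0.512)) {
  if (n == 0)
    return(data.frame(c = numeric(0), d = numeric(0), level = integer(0),
                      n_q = integer(0), outcome = character(0),
                      e = numeric(0), streak = integer(0)))
  out <- list(); total <- 0; next_id <- 1L
  while (total < n) {
    m <- max(64L, ceiling((n - total) / 2))
    cc <- sample(coherences, m, replace = TRUE)
    dd <- sample(c(-1, 1), m, replace = TRUE)
    ll <- sample(1:3, m, replace = TRUE)
    id <- seq.int(next_id, length.out = m); next_id <- next_id + m
    active <- rep(TRUE, m); n_q <- 0L
    while (any(active)) {
      ai <- which(active)
      e <- sample_evidence(cc[ai], dd[ai], params)
      Phi <- criterion(ll[ai], n_q, params)
      oc <- ifelse(e > Phi, "right", ifelse(e < -Phi, "left", "requery"))
      out[[length(out) + 1]] <- data.frame(
        c = cc[ai], d = dd[ai], level = ll[ai], n_q = n_q, outcome = oc,
        e = e, streak = id[ai])
      active[ai[oc != "requery"]] <- FALSE
      n_q <- n_q + 1L
      if (n_q > 500) active[] <- FALSE   # pathological parameter safeguard
    }
    total <- sum(vapply(out, nrow, integer(1)))
  }
  tbl <- do.call(rbind, out)
  tbl <- tbl[order(tbl$streak, tbl$n_q), ]
  rownames(tbl) <- NULL
  tbl
}

#' Generate a query table from the integration model
#'
#' As [generate_query_dataset()] but the choice at each pulse is driven by
#' the cumulative evidence within the streak, compared against the same
#' collapsing criteria.
#'
#' @inheritParams generate_query_dataset
#' @export
generate_integration_dataset <- function(params, n,
                                         coherences = c(0.032, 0.064, 0.128,
                                                        0.256, 0.512)) {
  if (n == 0) return(generate_query_dataset(params, 0, coherences))
  out <- list(); total <- 0; next_id <- 1L
  while (total < n) {
    m <- max(64L, ceiling((n - total) / 2))
    cc <- sample(coherences, m, replace = TRUE)
    dd <- sample(c(-1, 1), m, replace = TRUE)
    ll <- sample(1:3, m, replace = TRUE)
    id <- seq.int(next_id, length.out = m); next_id <- next_id + m
    mu <- evidence_mean(cc, dd, params); sd <- evidence_sd(cc, params)
    active <- rep(TRUE, m); n_q <- 0L
    csum <- numeric(m)
    while (any(active)) {
      ai <- which(active)
      e <- stats::rnorm(length(ai), mu[ai], sd[ai])
      csum[ai] <- csum[ai] + e
      Phi <- criterion(ll[ai], n_q, params)
      oc <- ifelse(csum[ai] > Phi, "right",
                   ifelse(csum[ai] < -Phi, "left", "requery"))
      out[[length(out) + 1]] <- data.frame(
        c = cc[ai], d = dd[ai], level = ll[ai], n_q = n_q, outcome = oc,
        e = e, streak = id[ai])
      active[ai[oc != "requery"]] <- FALSE
      n_q <- n_q + 1L
      if (n_q > 500) active[] <- FALSE
    }
    total <- sum(vapply(out, nrow, integer(1)))
  }
  tbl <- do.call(rbind, out)
  tbl <- tbl[order(tbl$streak, tbl$n_q), ]
  rownames(tbl) <- NULL
  tbl
}

#' Write / read a session log (CSV with JSON sidecar)
#'
#' Standard schema: UTF-8 comma-separated with header, '.' decimal, one
#' row per executed action. A sidecar JSON (\code{<path>.json}) records
#' the seed, any configuration supplied and the CSV's MD5 checksum.
#'
#' @param log session-log data frame
#' @param path CSV path
#' @param seed seed used to generate the log (stored in the sidecar)
#' @param config optional configuration list stored in the sidecar
#' @export
write_session_log <- function(log, path, seed = NA, config = NULL) {
  utils::write.csv(log, path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, config = config,
         md5 = unname(tools::md5sum(path)), n_rows = nrow(log)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate multi-subject session logs
#'
#' Drives any of the package's agents with per-subject seeds derived from
#' a master seed; identical configuration and seed give identical logs.
#'
#' @param agent one of "heuristic", "bayes", "pg", "ig", "impact",
#'   "random_leaf"
#' @param params agent parameters: a [heuristic_params()] for "heuristic",
#'   an [evidence_params()]/[detection_params()] for the others (ignored
#'   for "random_leaf")
#' @param n_trials trials per subject
#' @param n_subjects number of subjects
#' @param seed master seed
#' @param task a [task_config()]
#' @param ... passed to the agent runner
#' @return a single session-log data frame with subjects "s1", "s2", ...
#' @export
generate_sessions <- function(agent, params, n_trials, n_subjects = 1,
                              seed = 1, task = task_config(), ...) {
  agent <- match.arg(agent, c("heuristic", "bayes", "pg", "ig", "impact",
                              "random_leaf"))
  logs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(seed + s)
    sid <- paste0("s", s)
    logs[[s]] <- switch(agent,
      heuristic = {
        r <- run_heuristic_agent(params, n_trials, task, full_log = TRUE,
                                 subject = sid, ...)
        r$log
      },
      bayes = run_bayes_agent(params, n_trials, task = task, subject = sid, ...),
      random_leaf = run_random_leaf_agent(n_trials, task, subject = sid),
      run_norm_agent(agent, params, n_trials, task, subject = sid, ...))
  }
  do.call(rbind, logs)
}

#' Synthetic participant parameters
#'
#' A fixture of four synthetic "participants" with detection-model and
#' heuristic parameters in the plausible range for extrema-detection fits
#' to random-dot-motion behavior. These are a labelled synthetic stand-in
#' (no human parameter values ship with the package) used by the
#' participant-conditioned simulation examples and the acceptance checks.
#'
#' @return list of [heuristic_params()] objects, named by participant id
#' @export
synthetic_participants <- function() {
  path <- system.file("extdata", "synthetic_participants.json",
                      package = "treequery", mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(x$participants)), function(i) {
    p <- x$participants[i, ]
    heuristic_params(
      detection_params(p$kappa, p$gamma, unlist(p$phi), p$lambda), p$omega)
  })
  names(out) <- x$participants$id
  out
}

#' Parameter-recovery harness
#'
#' Generates synthetic data under known parameters, refits the model and
#' reports per-parameter relative (or absolute, for omega) error against
#' a tolerance.
#'
#' @param model "detection" or "omega"
#' @param true_params generating parameters ([detection_params()] or a
#'   [heuristic_params()])
#' @param n queries (detection) or trials per evaluation (omega)
#' @param tol named tolerances; defaults: 10\% for kappa/phi, 25\% for
#'   gamma/lambda, 0.05 absolute for omega
#' @param seed RNG seed
#' @param ... passed to the fitter
#' @return data frame with \code{param, true, est, err, tol, pass}
#' @export
recovery_suite <- function(model = c("detection", "omega"), true_params, n,
                           tol = NULL, seed = 1, ...) {
  model <- match.arg(model)
  if (model == "detection") {
    set.seed(seed)
    tbl <- generate_query_dataset(true_params, n)
    fit <- fit_detection(tbl, "detection", seed = seed, ...)
    truth <- c(kappa = true_params$kappa, gamma = true_params$gamma,
               phi1 = true_params$phi[1], phi2 = true_params$phi[2],
               phi3 = true_params$phi[3], lambda = true_params$lambda)
    if (is.null(tol))
      tol <- c(kappa = 0.10, gamma = 0.25, phi1 = 0.10, phi2 = 0.10,
               phi3 = 0.10, lambda = 0.25)
    err <- abs(fit$par[names(truth)] - truth) / abs(truth)
    return(data.frame(param = names(truth), true = unname(truth),
                      est = unname(fit$par[names(truth)]), err = unname(err),
                      tol = unname(tol[names(truth)]),
                      pass = unname(err <= tol[names(truth)])))
  }
  # omega: simulate at the true omega, then refit from the observed p_on
  set.seed(seed)
  sim <- run_heuristic_agent(true_params, n)
  fit <- fit_omega(p_on_path(sim), true_params$det, n_trials = n,
                   seed = seed, ...)
  tol <- tol %||% 0.05
  err <- abs(fit$omega - true_params$omega)
  data.frame(param = "omega", true = true_params$omega, est = fit$omega,
             err = err, tol = tol, pass = err <= tol)
}
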