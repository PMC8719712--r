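# Descriptive and statistical analyses applied uniformly to session logs
# (simulated or human-format). All positional analyses use the canonical
# (target-relative) numbering in which the target is node 15 and the true
# direction of motion is rightward at every bifurcation.

.split_trials <- function(log) {
  split(log, interaction(log$subject, log$trial, drop = TRUE))
}

#' Transition statistics between queried nodes
#'
#' Per-subject raw transition counts \eqn{M_u(i, j)} between consecutive
#' queries within a trial (canonical numbering), their row-normalized
#' conditional probabilities \eqn{W_u(j | i)} and the cross-subject mean
#' \eqn{W(j | i)}; plus level-by-level transition frequencies
#' \eqn{N(\ell_i, \ell_j)}, normalized per subject by the total number of
#' queries minus one and averaged across subjects, split into transitions
#' before and after the first leaf error of the trial.
#'
#' @param log a session-log data frame with at least \code{subject},
#'   \code{trial}, \code{step}, \code{node_canonical}, \code{level},
#'   \code{feedback}
#' @return object of class \code{"transition_stats"}: list with \code{M}
#'   (per-subject 15 x 15 count matrices), \code{W} (per-subject
#'   conditional matrices), \code{W_mean}, \code{N_pre}, \code{N_post}
#'   (4 x 4 level matrices), and the customary display thresholds
#' @export
transition_stats <- function(log) {
  if (nrow(log) == 0) stop("empty log")
  subjects <- unique(log$subject)
  M <- W <- list()
  Npre <- Npost <- list()
  for (u in subjects) {
    lu <- log[log$subject == u, ]
    m <- matrix(0, 15, 15, dimnames = list(1:15, 1:15))
    npre <- npost <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
    for (tt in split(lu, lu$trial)) {
      tt <- tt[order(tt$step), ]
      n <- nrow(tt)
      if (n < 2) next
      i <- tt$node_canonical[-n]; j <- tt$node_canonical[-1]
      for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1
      err_so_far <- cumsum(tt$feedback == "negative") > 0
      li <- tt$level[-n]; lj <- tt$level[-1]; post <- err_so_far[-n]
      for (r in seq_along(li)) {
        if (post[r]) npost[li[r], lj[r]] <- npost[li[r], lj[r]] + 1
        else npre[li[r], lj[r]] <- npre[li[r], lj[r]] + 1
      }
    }
    w <- m / pmax(rowSums(m), 1)
    w[rowSums(m) == 0, ] <- NA
    M[[as.character(u)]] <- m
    W[[as.character(u)]] <- w
    tot <- nrow(lu) - 1
    Npre[[as.character(u)]] <- npre / max(tot, 1)
    Npost[[as.character(u)]] <- npost / max(tot, 1)
  }
  Wm <- Reduce(`+`, lapply(W, function(x) ifelse(is.na(x), 0, x))) /
    pmax(Reduce(`+`, lapply(W, function(x) !is.na(x))), 1)
  structure(list(M = M, W = W, W_mean = Wm,
                 N_pre = Reduce(`+`, Npre) / length(Npre),
                 N_post = Reduce(`+`, Npost) / length(Npost),
                 node_threshold = 0.075, level_threshold = 0.05),
            class = "transition_stats")
}

.canonical_on_off <- function(leaf) {
  # canonical error path and counterfactual children of a canonical leaf
  anc <- c(1L, leaf %/% 4L, leaf %/% 2L)
  list(on = anc, off = as.integer(bitwXor(c(anc[2], anc[3], leaf), 1L)))
}

#' Classify each action by what preceded it
#'
#' Actions following an \emph{error at a leaf} are sorted into on-path
#' queries (a node of the error path), off-path queries (a counterfactual
#' child of an error-path node) and "other". Actions following an
#' \emph{internal-node query} are sorted into: correct child (the child in
#' the true direction of motion), incorrect child, re-query, other node at
#' the same level, other lower-level node, higher-level node.
#'
#' @param log a session-log data frame (canonical numbering)
#' @return data frame with \code{subject}, \code{trial}, \code{prev_node},
#'   \code{next_node} (canonical), \code{context} ("internal" or "error")
#'   and \code{category}
#' @export
classify_actions <- function(log) {
  out <- list()
  for (tt in .split_trials(log)) {
    tt <- tt[order(tt$step), ]
    n <- nrow(tt)
    if (n < 2) next
    for (r in seq_len(n - 1)) {
      prev <- tt$node_canonical[r]; nxt <- tt$node_canonical[r + 1]
      if (tt$feedback[r] == "negative") {
        oo <- .canonical_on_off(prev)
        cat_ <- if (nxt %in% oo$on) "on_path"
        else if (nxt %in% oo$off) "off_path" else "other"
        ctx <- "error"
      } else if (prev <= 7) {
        lev_p <- tt$level[r]; lev_n <- tt$level[r + 1]
        cat_ <- if (nxt == prev) "requery"
        else if (nxt == 2 * prev + 1) "correct_child"
        else if (nxt == 2 * prev) "incorrect_child"
        else if (lev_n == lev_p) "other_same_level"
        else if (lev_n > lev_p) "other_lower_level"
        else "higher_level"
        ctx <- "internal"
      } else next   # after the target the trial ends; nothing follows
      out[[length(out) + 1]] <- data.frame(
        subject = tt$subject[1], trial = tt$trial[1], prev_node = prev,
        next_node = nxt, context = ctx, category = cat_)
    }
  }
  do.call(rbind, out)
}

#' Blame statistics conditional on coherence and level
#'
#' Three tables in the style of the model's blame predictions:
#' \itemize{
#' \item \code{by_coherence}: proportion of errors in which the blamed node
#'   had coherence c, among errors whose path contained a node with
#'   coherence c;
#' \item \code{on_path}: 3 x 5 matrix, proportion of errors followed by an
#'   on-path query at the level-\eqn{\ell} path node, given that node had
#'   coherence c;
#' \item \code{off_path}: same for off-path queries from the level-\eqn{\ell}
#'   node.
#' }
#'
#' For \code{mode = "model"}, \code{x} is the \code{errors} frame of
#' [run_heuristic_agent()] (explicit blame). For \code{mode = "data"},
#' \code{x} is a session log and blame is operationalized from the
#' observed next query: the on-path target node, or the parent of an
#' off-path query.
#'
#' @param x errors frame or session log
#' @param mode "model" or "data"
#' @param coherences the task's coherence levels
#' @return list of the three tables plus \code{n_errors}
#' @export
blame_stats <- function(x, mode = c("model", "data"),
                        coherences = c(0.032, 0.064, 0.128, 0.256, 0.512)) {
  mode <- match.arg(mode)
  err <- if (mode == "model") x else .errors_from_log(x)
  cohm <- as.matrix(err[, c("coh1", "coh2", "coh3")])
  blamed_coh <- ifelse(err$blamed_level > 0,
                       cohm[cbind(seq_len(nrow(err)),
                                  pmax(err$blamed_level, 1))], NA)
  by_coh <- vapply(coherences, function(cc) {
    # unknown coherences (never-queried nodes in data mode) count as
    # non-matching
    denom <- sum(rowSums(cohm == cc, na.rm = TRUE) > 0)
    if (denom == 0) return(NA_real_)
    sum(!is.na(blamed_coh) & blamed_coh == cc) / denom
  }, numeric(1))
  names(by_coh) <- coherences
  tab <- function(type) {
    m <- matrix(NA_real_, 3, 5, dimnames = list(level = 1:3, coh = coherences))
    for (l in 1:3) for (ci in 1:5) {
      match_l <- !is.na(cohm[, l]) & cohm[, l] == coherences[ci]
      denom <- sum(match_l)
      if (denom == 0) next
      m[l, ci] <- sum(err$path_type == type & err$blamed_level == l &
                        match_l) / denom
    }
    m
  }
  list(by_coherence = by_coh, on_path = tab(1), off_path = tab(2),
       n_errors = nrow(err))
}

.errors_from_log <- function(log) {
  # infer blame from the next query after each leaf error; path coherences
  # are recovered from the trial's internal-node query rows where available
  out <- list()
  for (tt in .split_trials(log)) {
    tt <- tt[order(tt$step), ]
    n <- nrow(tt)
    coh_of <- tapply(tt$coh, tt$node_canonical, function(z) z[1])
    for (r in seq_len(n - 1)) {
      if (tt$feedback[r] != "negative") next
      leaf <- tt$node_canonical[r]; nxt <- tt$node_canonical[r + 1]
      oo <- .canonical_on_off(leaf)
      if (nxt %in% oo$on) { type <- 1; bl <- match(nxt, oo$on) }
      else if (nxt %in% oo$off) { type <- 2; bl <- match(nxt, oo$off) }
      else { type <- 3; bl <- 0 }
      ch <- vapply(oo$on, function(nd) {
        v <- coh_of[as.character(nd)]
        if (is.null(v) || is.na(v)) NA_real_ else unname(v)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        trial = tt$trial[1], leaf = leaf, coh1 = ch[1], coh2 = ch[2],
        coh3 = ch[3], blamed_level = bl, path_type = type)
    }
  }
  do.call(rbind, out)
}

# ---- logistic regressions --------------------------------------------------

.lr_test <- function(full, reduced) {
  stat <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(reduced)))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Logistic-regression analyses of choices, re-queries and blame
#'
#' Maximum-likelihood logistic fits of the task's standard regression
#' analyses, with
#' subject indicator variables when more than one subject is present and
#' likelihood-ratio tests of the models' stated null hypotheses:
#' \describe{
#' \item{\code{"choice"}}{rightward choice on signed strength \code{s} and
#'   its interaction with tree level: \code{y ~ s + s:level}. LR test on
#'   the interaction.}
#' \item{\code{"requery"}}{re-query on unsigned coherence \code{c} and
#'   level: \code{y ~ c + level}. LR tests on each.}
#' \item{\code{"on_path"}}{on-path (vs off-path) post-error query on the
#'   blamed node's coherence \code{c_b} and the product of the two
#'   non-blamed coherences \code{c_prod}. LR test on \code{c_prod}.}
#' \item{\code{"pulse1"}}{rightward choice after exactly one query on
#'   signed strength, level and the pulse's evidence \code{m}. LR test on
#'   \code{m}.}
#' \item{\code{"pulse2"}}{choice after exactly two successive queries, with
#'   both pulses' evidence \code{m1}, \code{m2}. LR tests on each pulse.}
#' \item{\code{"blame"}}{three rows per classified error (one per path
#'   node); blamed indicator on coherence and level. LR tests on each.}
#' }
#'
#' @param tag model tag (see Details)
#' @param tbl data frame with the tag's columns (and \code{subject})
#' @return object of class \code{"tq_logit"}: list with \code{tag},
#'   \code{fit} (the \code{glm} object), \code{coef} (estimate/SE table),
#'   \code{loglik}, \code{bic}, \code{lr_p} (named LR p-values)
#' @export
fit_logistic <- function(tag = c("choice", "requery", "on_path", "pulse1",
                                 "pulse2", "blame"), tbl) {
  tag <- match.arg(tag)
  subj <- if (!is.null(tbl$subject) && length(unique(tbl$subject)) > 1)
    "+ subject" else ""
  tbl$subject <- factor(tbl$subject %||% "s1")
  spec <- switch(tag,
    choice = list(f = paste("y ~ s + s:level", subj), drops = c(interaction = "s:level")),
    requery = list(f = paste("y ~ c + level", subj),
                   drops = c(coherence = "c", level = "level")),
    on_path = list(f = paste("y ~ c_b + c_prod", subj), drops = c(product = "c_prod")),
    pulse1 = list(f = paste("y ~ s + level + m", subj), drops = c(pulse = "m")),
    pulse2 = list(f = paste("y ~ s + level + m1 + m2", subj),
                  drops = c(first_pulse = "m1", second_pulse = "m2")),
    blame = list(f = paste("y ~ c + level", subj),
                 drops = c(coherence = "c", level = "level")))
  full <- stats::glm(stats::as.formula(spec$f), family = stats::binomial(), data = tbl)
  if (!full$converged || any(abs(stats::coef(full)) > 50, na.rm = TRUE))
    warning("possible separation in logistic fit '", tag, "'")
  lr <- vapply(spec$drops, function(term) {
    red <- stats::update(full, stats::as.formula(paste(". ~ . -", term)))
    .lr_test(full, red)
  }, numeric(1))
  sm <- summary(full)$coefficients
  ll <- as.numeric(stats::logLik(full))
  structure(list(tag = tag, fit = full,
                 coef = sm, loglik = ll,
                 bic = attr(stats::logLik(full), "df") * log(nrow(tbl)) - 2 * ll,
                 lr_p = lr),
            class = "tq_logit")
}

#' @export
print.tq_logit <- function(x, ...) {
  cat("Logistic regression:", x$tag, "\n")
  print(round(x$coef, 4))
  cat("LR p-values:", paste(names(x$lr_p), signif(x$lr_p, 3), collapse = "; "), "\n")
  invisible(x)
}

#' Build regression tables from session logs
#'
#' Prepares the input of [fit_logistic()] from a session log (tags
#' "choice", "requery", "pulse1", "pulse2") or from a heuristic-agent
#' errors frame (tags "on_path", "blame"). Choices are coded in spatial
#' coordinates (y = 1 for a rightward commitment, \code{s = c * d} signed
#' strength); for model-simulated data the evidence samples stand in for
#' the stimulus motion energy.
#'
#' @param x session log or errors frame
#' @param tag regression tag
#' @return a data frame for [fit_logistic()]
#' @export
regression_table <- function(x, tag = c("choice", "requery", "pulse1",
                                        "pulse2", "on_path", "blame")) {
  tag <- match.arg(tag)
  if (tag %in% c("on_path", "blame")) {
    err <- x[x$path_type %in% c(1, 2), ]
    cohm <- as.matrix(err[, c("coh1", "coh2", "coh3")])
    if (tag == "on_path") {
      idx <- cbind(seq_len(nrow(err)), err$blamed_level)
      c_b <- cohm[idx]
      c_prod <- vapply(seq_len(nrow(err)), function(r)
        prod(cohm[r, -err$blamed_level[r]]), numeric(1))
      return(data.frame(y = as.integer(err$path_type == 1), c_b = c_b,
                        c_prod = c_prod, subject = "s1"))
    }
    rows <- lapply(seq_len(nrow(err)), function(r)
      data.frame(y = as.integer(1:3 == err$blamed_level[r]), c = cohm[r, ],
                 level = 1:3, subject = "s1"))
    return(do.call(rbind, rows))
  }
  if (!is.null(x$outcome)) {
    # already a query table (e.g. from the synthetic generators)
    qt <- x
    qt$subject <- qt$subject %||% "s1"
  } else {
    qt <- query_table_from_log(x)
    qt$subject <- .subject_for_qt(x, qt)
    qt$e <- .evidence_for_qt(x)
  }
  if (tag == "requery")
    return(data.frame(y = as.integer(qt$outcome == "requery"), c = qt$c,
                      level = qt$level, subject = qt$subject))
  # choices: need streak structure to separate 1- vs 2-pulse decisions
  qt$streak <- .streak_ids(qt)
  ch <- qt[qt$outcome != "requery", ]
  if (tag == "choice")
    return(data.frame(y = as.integer(ch$outcome == "right"), s = ch$c * ch$d,
                      level = ch$level, subject = ch$subject))
  len <- stats::ave(qt$streak, qt$streak, FUN = length)
  ended <- stats::ave(qt$outcome != "requery", qt$streak, FUN = any)
  if (tag == "pulse1") {
    k <- qt[len == 1 & ended, ]
    return(data.frame(y = as.integer(k$outcome == "right"), s = k$c * k$d,
                      level = k$level, m = k$e, subject = k$subject))
  }
  # pulse2: streaks of exactly two queries ending in a choice
  out <- list()
  for (sid in unique(qt$streak[len == 2 & ended])) {
    k <- qt[qt$streak == sid, ]
    out[[length(out) + 1]] <- data.frame(
      y = as.integer(k$outcome[2] == "right"), s = k$c[1] * k$d[1],
      level = k$level[1], m1 = k$e[1], m2 = k$e[2], subject = k$subject[1])
  }
  do.call(rbind, out)
}

.evidence_for_qt <- function(log) {
  ord <- order(log$subject, log$trial, log$step)
  log <- log[ord, ]
  qt_keep <- attr(query_table_from_log(log), "rows")
  # recompute the keep mask exactly as query_table_from_log does
  same_trial <- c(log$trial[-1] == log$trial[-nrow(log)] &
                    log$subject[-1] == log$subject[-nrow(log)], FALSE)
  nxt <- c(log$node[-1], NA_integer_)
  is_int <- log$node <= 7
  keep <- is_int & same_trial &
    (nxt == log$node | nxt == 2 * log$node | nxt == 2 * log$node + 1)
  keep[is.na(keep)] <- FALSE
  log$e[keep]
}

.subject_for_qt <- function(log, qt) {
  ord <- order(log$subject, log$trial, log$step)
  log <- log[ord, ]
  same_trial <- c(log$trial[-1] == log$trial[-nrow(log)] &
                    log$subject[-1] == log$subject[-nrow(log)], FALSE)
  nxt <- c(log$node[-1], NA_integer_)
  keep <- log$node <= 7 & same_trial &
    (nxt == log$node | nxt == 2 * log$node | nxt == 2 * log$node + 1)
  keep[is.na(keep)] <- FALSE
  log$subject[keep]
}

#' Reward and query summaries of a session log
#'
#' Mean reward per trial with its SEM over trials; queries per tree level
#' and leaf errors per trial, averaged first within and then across
#' subjects.
#'
#' @param log a session-log data frame
#' @return list with \code{reward} (mean, sem, n_trials) and
#'   \code{per_level} (data frame: level, queries per trial), plus
#'   \code{errors_per_trial}
#' @export
summarize_sessions <- function(log) {
  per_trial <- do.call(rbind, lapply(.split_trials(log), function(tt)
    data.frame(subject = tt$subject[1], reward = sum(tt$points),
               q1 = sum(tt$level == 1), q2 = sum(tt$level == 2),
               q3 = sum(tt$level == 3),
               errors = sum(tt$feedback == "negative"))))
  n <- nrow(per_trial)
  reward <- list(mean = mean(per_trial$reward),
                 sem = if (n > 1) stats::sd(per_trial$reward) / sqrt(n) else 0,
                 n_trials = n)
  by_subj <- do.call(rbind, lapply(split(per_trial, per_trial$subject),
                                   function(s) colMeans(s[, c("q1", "q2", "q3", "errors")])))
  means <- colMeans(by_subj)
  list(reward = reward,
       per_level = data.frame(level = 1:3, queries = unname(means[1:3])),
       errors_per_trial = unname(means["errors"]))
}
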