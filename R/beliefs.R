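# Exact discrete inference over the task's latent state.
#
# Each internal node i holds an independent 5 x 2 posterior table
# P_i(c, d | E_i) over coherence x direction. Leaf feedback turns the leaves
# into observed colliders: conditioning on "leaf T was not the target"
# couples the otherwise independent node posteriors. The engine handles this
# by enumerating the 2^7 = 128 joint direction assignments, zeroing those
# whose implied target is a visited wrong leaf, and renormalizing.

# cell layout of a posterior table row: columns 1..5 are d = -1 for the five
# coherences (ascending), columns 6..10 are d = +1.

.tq_cache <- new.env(parent = emptyenv())

.combos <- function() {
  if (is.null(.tq_cache$combos)) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), 7)))[, 7:1]
    dimnames(m) <- NULL
    tgt <- apply(m, 1, function(d) {
      i <- 1L
      for (s in 1:3) i <- 2L * i + (d[i] > 0)
      i
    })
    .tq_cache$combos <- m
    .tq_cache$combo_target <- as.integer(tgt)
    # per node, which combos have d = +1 at that node
    .tq_cache$combo_plus <- m > 0
  }
  .tq_cache
}

#' Initialize a belief state
#'
#' Uniform posteriors: 1/10 per (coherence, direction) cell at every
#' internal node, no visited leaves, hence 1/8 target belief per leaf.
#'
#' @param ep an [evidence_params()] (or [detection_params()]) object used
#'   for the evidence likelihood
#' @param coherences the task's coherence levels (proportions)
#' @return object of class \code{"belief_state"}: list with
#'   \code{tables} (7 x 10 matrix of per-node posteriors),
#'   \code{V} (visited wrong leaves), \code{ep}, \code{coherences}
#' @export
init_beliefs <- function(ep, coherences = c(0.032, 0.064, 0.128, 0.256, 0.512)) {
  stopifnot(length(coherences) == 5)
  structure(list(tables = matrix(1 / 10, 7, 10), V = integer(0),
                 ep = ep, coherences = coherences),
            class = "belief_state")
}

.cell_likelihood <- function(e, ep, coherences) {
  mu <- c(evidence_mean(coherences, -1, ep), evidence_mean(coherences, 1, ep))
  sd <- rep(evidence_sd(coherences, ep), 2)
  lik <- stats::dnorm(e, mu, sd)
  m <- max(lik)
  if (m > 0) lik / m else exp(-((e - mu) / sd)^2 / 2 - log(sd) + 700)
}

#' Update one node's posterior with an evidence pulse
#'
#' Bayes' rule on the node's 10-cell table with the Gaussian pulse
#' likelihood; other nodes are untouched (evidence is conditionally
#' independent across nodes given the latent state).
#'
#' @param belief a [init_beliefs()] state
#' @param node internal node id 1..7
#' @param e observed evidence value
#' @return the updated belief state
#' @export
update_node_posterior <- function(belief, node, e) {
  stopifnot(node %in% 1:7)
  post <- belief$tables[node, ] * .cell_likelihood(e, belief$ep, belief$coherences)
  belief$tables[node, ] <- post / sum(post)
  belief
}

#' Record a wrong-leaf error
#'
#' @param belief a belief state
#' @param leaf spatial leaf id 8..15 that received negative feedback
#' @return the updated belief state
#' @export
mark_visited <- function(belief, leaf) {
  stopifnot(leaf %in% 8:15)
  belief$V <- union(belief$V, as.integer(leaf))
  belief
}

#' Per-node direction marginal, ignoring leaf errors
#'
#' \eqn{P_i(d = +1 | E_i)} for each node, from the per-node tables alone.
#'
#' @param belief a belief state
#' @return numeric vector of length 7
#' @export
direction_marginal_plus <- function(belief) {
  rowSums(belief$tables[, 6:10, drop = FALSE])
}

#' Joint direction-combination probabilities
#'
#' \code{combo_probs} returns the product probabilities \eqn{P_k} of the
#' 128 joint direction assignments (errors ignored);
#' \code{combo_probs_norm} zeroes the assignments whose implied target is a
#' visited wrong leaf and renormalizes.
#'
#' @param belief a belief state
#' @return numeric vector of length 128; attribute \code{"target"} holds
#'   each combination's implied target leaf (spatial id)
#' @export
combo_probs <- function(belief) {
  cc <- .combos()
  mp <- direction_marginal_plus(belief)
  pk <- rep(1, 128)
  for (i in 1:7)
    pk <- pk * ifelse(cc$combo_plus[, i], mp[i], 1 - mp[i])
  attr(pk, "target") <- cc$combo_target
  pk
}

#' @rdname combo_probs
#' @export
combo_probs_norm <- function(belief) {
  pk <- combo_probs(belief)
  tgt <- attr(pk, "target")
  if (length(belief$V)) pk[tgt %in% belief$V] <- 0
  s <- sum(pk)
  if (s <= 0) stop("all direction combinations eliminated")
  out <- pk / s
  attr(out, "target") <- tgt
  out
}

#' Target beliefs B(T | E, V)
#'
#' Posterior probability that each leaf is the target, given all evidence
#' and the visited wrong leaves. With no errors this factorizes as the
#' product, over the leaf's three ancestors, of the direction marginal
#' toward the leaf; after errors it is computed from the renormalized
#' direction-combination probabilities (explaining away).
#'
#' @param belief a belief state
#' @return named numeric vector of length 8 (spatial leaves 8..15),
#'   summing to 1; zero on visited leaves
#' @export
target_beliefs <- function(belief) {
  pk <- combo_probs_norm(belief)
  tgt <- attr(pk, "target")
  b <- vapply(8:15, function(T) sum(pk[tgt == T]), numeric(1))
  names(b) <- 8:15
  b
}

#' Post-error conditional direction marginal at a node
#'
#' \eqn{P_i(d | E, V)}: the direction marginal conditioned on the visited
#' wrong leaves, computed from the renormalized combination enumeration.
#' Equals the plain per-node marginal when no errors occurred.
#'
#' @param belief a belief state
#' @param node internal node id 1..7
#' @return named numeric vector \code{c("-1" = ..., "1" = ...)}
#' @export
conditional_direction_marginal <- function(belief, node) {
  stopifnot(node %in% 1:7)
  pk <- combo_probs_norm(belief)
  plus <- sum(pk[.combos()$combo_plus[, node]])
  c("-1" = 1 - plus, "1" = plus)
}

#' Choice confidence from the last evidence sample
#'
#' Posterior probability that \code{chosen_direction} is the true direction
#' at a node, given only the last evidence sample \code{e} and (by default)
#' a uniform prior over the 10 (coherence, direction) cells, marginalizing
#' over coherence. \code{conf(+1) + conf(-1) = 1}.
#'
#' @param e last evidence sample at the node
#' @param ep an [evidence_params()] object
#' @param chosen_direction -1 or +1
#' @param coherences the task's coherence levels
#' @param prior optional length-10 prior over cells (layout as in
#'   [init_beliefs()]); default uniform
#' @return probability in (0, 1)
#' @export
confidence <- function(e, ep, chosen_direction,
                       coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                       prior = NULL) {
  stopifnot(chosen_direction %in% c(-1, 1), is.finite(e))
  if (is.null(prior)) prior <- rep(1 / 10, 10)
  lik <- .cell_likelihood(e, ep, coherences) * prior
  idx <- if (chosen_direction > 0) 6:10 else 1:5
  sum(lik[idx]) / sum(lik)
}

#' Serialize / restore a belief state (JSON)
#'
#' @param belief a belief state
#' @param path file path
#' @export
write_belief_json <- function(belief, path) {
  jsonlite::write_json(list(tables = belief$tables, V = belief$V,
                            kappa = belief$ep$kappa, gamma = belief$ep$gamma,
                            t = belief$ep$t, coherences = belief$coherences),
                       path, digits = NA, auto_unbox = TRUE)
}

#' @rdname write_belief_json
#' @export
read_belief_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- init_beliefs(evidence_params(x$kappa, x$gamma, x$t), x$coherences)
  b$tables <- matrix(unlist(x$tables), 7, 10)
  b$V <- as.integer(x$V)
  b
}
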