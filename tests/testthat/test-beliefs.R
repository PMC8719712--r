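test_that("initial beliefs are uniform with 3 bits of target uncertainty", {
  b <- init_beliefs(tq_ep())
  expect_equal(unname(target_beliefs(b)), rep(1 / 8, 8))
  expect_equal(as.vector(combo_probs(b)), rep(1 / 128, 128))
  B <- target_beliefs(b)
  expect_equal(-sum(B * log2(B)), 3)
  expect_true(all(abs(rowSums(b$tables) - 1) < 1e-12))
})

test_that("node updates follow Bayes rule against a 10-cell brute force", {
  ep <- tq_ep()
  set.seed(3)
  for (i in 1:20) {
    b <- tq_random_belief(sample(0:3, 1))
    node <- sample(7, 1)
    e <- stats::rnorm(1, 0, 1)
    b2 <- update_node_posterior(b, node, e)
    expect_equal(sum(b2$tables[node, ]), 1, tolerance = 1e-12)
    # brute force over all 10 (c, d) cells
    mu <- c(evidence_mean(b$coherences, -1, ep), evidence_mean(b$coherences, 1, ep))
    sd <- rep(evidence_sd(b$coherences, ep), 2)
    post <- b$tables[node, ] * stats::dnorm(e, mu, sd)
    expect_equal(unname(b2$tables[node, ]), unname(post / sum(post)),
                 tolerance = 1e-12)
    # symmetric likelihood at e = 0 on a uniform prior keeps d at 1/2
    b0 <- update_node_posterior(init_beliefs(ep), node, 0)
    expect_equal(unname(direction_marginal_plus(b0)[node]), 0.5)
  }
})

test_that("target beliefs factorize over ancestors when no errors occurred", {
  set.seed(5)
  tr <- build_tree()
  for (i in 1:10) {
    b <- tq_random_belief(4)
    B <- target_beliefs(b)
    mp <- direction_marginal_plus(b)
    for (leaf in 8:15) {
      anc <- tree_ancestors(tr, leaf)
      onc <- c(anc[2], anc[3], leaf)
      pr <- prod(ifelse(onc == 2 * anc + 1, mp[anc], 1 - mp[anc]))
      expect_equal(unname(B[as.character(leaf)]), pr, tolerance = 1e-12)
    }
  }
})

test_that("one error with no evidence spreads belief as 1/7", {
  b <- mark_visited(init_beliefs(tq_ep()), 12)
  B <- target_beliefs(b)
  expect_equal(unname(B["12"]), 0)
  expect_equal(unname(B[setdiff(names(B), "12")]), rep(1 / 7, 7))
})

test_that("explaining away: certain ancestors plus a sibling error imply the sibling leaf", {
  # make the level-1 and level-2 choices toward leaf 14/15 certain, then
  # observe that 14 is not the target: belief must concentrate on 15 and
  # the (never queried) level-3 node's direction becomes certain
  b <- init_beliefs(tq_ep())
  b$tables[1, ] <- 0; b$tables[1, 10] <- 1   # d = +1 certain at root
  b$tables[3, ] <- 0; b$tables[3, 10] <- 1   # d = +1 certain at node 3
  b <- mark_visited(b, 14)
  B <- target_beliefs(b)
  expect_equal(unname(B["15"]), 1, tolerance = 1e-12)
  m7 <- conditional_direction_marginal(b, 7)
  expect_equal(unname(m7["1"]), 1, tolerance = 1e-12)
  expect_error(target_beliefs(mark_visited(b, 15)), "eliminated")
})

test_that("collider property: errors couple otherwise independent nodes", {
  ep <- tq_ep()
  b <- init_beliefs(ep)
  m0 <- conditional_direction_marginal(b, 7)
  b1 <- update_node_posterior(b, 1, 1.5)     # evidence at the root only
  expect_equal(conditional_direction_marginal(b1, 7), m0, tolerance = 1e-12)
  # after an error the same root evidence moves node 7's marginal
  b2 <- mark_visited(b1, 14)
  expect_gt(abs(conditional_direction_marginal(b2, 7)["1"] - 0.5), 1e-3)
})

test_that("combination engine matches full-joint enumeration over all 10^7 states", {
  # independent oracle: enumerate every joint assignment of the 7 nodes'
  # 10 cells -- 128 direction patterns x 5^7 coherence patterns -- score
  # each by its product probability, and condition on the visited set
  ep <- tq_ep()
  set.seed(11)
  b <- init_beliefs(ep)
  for (i in 1:5) b <- update_node_posterior(b, sample(7, 1), stats::rnorm(1, 0.3, 1))
  for (leaf in c(9, 14)) b <- mark_visited(b, leaf)

  cidx <- as.matrix(expand.grid(rep(list(1:5), 7)))   # 78125 x 7
  dirs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 7)))
  Bor <- stats::setNames(numeric(8), 8:15)
  m7 <- c("-1" = 0, "1" = 0)
  for (k in seq_len(nrow(dirs))) {
    node <- 1L
    for (s in 1:3) node <- if (dirs[k, node] > 0) 2L * node + 1L else 2L * node
    if (node %in% b$V) next
    cols <- ifelse(dirs[k, ] > 0, 5, 0)
    w <- rep(1, nrow(cidx))
    for (j in 1:7) w <- w * b$tables[j, cols[j] + cidx[, j]]
    sk <- sum(w)
    Bor[as.character(node)] <- Bor[as.character(node)] + sk
    m7[as.character(dirs[k, 7])] <- m7[as.character(dirs[k, 7])] + sk
  }
  Bor <- Bor / sum(Bor)
  m7 <- m7 / sum(m7)
  expect_equal(target_beliefs(b), Bor, tolerance = 1e-10)
  expect_equal(conditional_direction_marginal(b, 7), m7, tolerance = 1e-10)
})

test_that("all distributions stay normalized through arbitrary histories", {
  set.seed(13)
  for (i in 1:10) {
    b <- tq_random_belief(sample(1:6, 1), sample(0:3, 1))
    expect_equal(sum(target_beliefs(b)), 1, tolerance = 1e-10)
    expect_equal(sum(combo_probs(b)), 1, tolerance = 1e-10)
    expect_equal(sum(combo_probs_norm(b)), 1, tolerance = 1e-10)
    expect_true(all(abs(rowSums(b$tables) - 1) < 1e-10))
    expect_true(all(target_beliefs(b)[as.character(b$V)] == 0))
    nd <- sample(7, 1)
    expect_equal(sum(conditional_direction_marginal(b, nd)), 1, tolerance = 1e-12)
  }
})

test_that("mirror symmetry: negating evidence and directions mirrors the beliefs", {
  ep <- tq_ep()
  set.seed(17)
  ev <- stats::rnorm(4, 0.5, 1)
  nodes <- c(1, 2, 3, 5)
  # the left-right reflection of the tree permutes node identities too
  sigma <- c(1L, 3L, 2L, 7L, 6L, 5L, 4L)
  b_pos <- init_beliefs(ep); b_neg <- init_beliefs(ep)
  for (i in seq_along(ev)) {
    b_pos <- update_node_posterior(b_pos, nodes[i], ev[i])
    b_neg <- update_node_posterior(b_neg, sigma[nodes[i]], -ev[i])
  }
  # reflected leaves: 8 + k maps to 15 - k
  Bp <- target_beliefs(b_pos); Bn <- target_beliefs(b_neg)
  expect_equal(unname(Bp), rev(unname(Bn)), tolerance = 1e-12)
})

test_that("confidence behaves as a posterior over the chosen direction", {
  ep <- tq_ep()
  expect_equal(confidence(0, ep, 1), 0.5)
  set.seed(19)
  for (i in 1:20) {
    e <- stats::rnorm(1, 0, 1.2)
    expect_equal(confidence(e, ep, 1) + confidence(e, ep, -1), 1,
                 tolerance = 1e-12)
  }
  es <- seq(0, 3, by = 0.1)
  conf <- vapply(es, confidence, numeric(1), ep = ep, chosen_direction = 1)
  expect_true(all(diff(conf) > 0))
  expect_true(all(conf > 0 & conf < 1))
})

test_that("belief states survive a JSON round trip", {
  set.seed(23)
  b <- tq_random_belief(3, 1)
  f <- tempfile(fileext = ".json")
  write_belief_json(b, f)
  b2 <- read_belief_json(f)
  expect_equal(b2$tables, b$tables, tolerance = 1e-12)
  expect_identical(b2$V, b$V)
  expect_equal(target_beliefs(b2), target_beliefs(b), tolerance = 1e-12)
})
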