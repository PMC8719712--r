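test_that("criterion has the right limits and collapse behavior", {
  p <- tq_det()
  expect_equal(criterion(1, 0, p), 2 * p$phi[1])
  expect_equal(criterion(2:3, 0, p), 2 * p$phi[2:3])
  big <- criterion(1, 1000, p)
  expect_equal(big, p$phi[1], tolerance = 1e-12)
  p0 <- detection_params(15, 1, c(0.5, 0.375, 0.25), 0)
  expect_equal(criterion(1, 0:5, p0), rep(2 * p0$phi[1], 6))
  # strictly decreasing in n_q when lambda > 0
  expect_true(all(diff(criterion(rep(2, 6), 0:5, p)) < 0))
})

test_that("choice probabilities are a valid trichotomy with the right symmetries", {
  p <- tq_det()
  set.seed(5)
  for (i in 1:50) {
    cc <- sample(tq_coherences, 1); dd <- sample(c(-1, 1), 1)
    ll <- sample(3, 1); nq <- sample(0:4, 1)
    pr <- choice_probs(cc, dd, ll, nq, p)
    expect_equal(pr$p_right + pr$p_left + pr$p_requery, 1, tolerance = 1e-12)
    expect_true(all(unlist(pr) >= 0 & unlist(pr) <= 1))
    mir <- choice_probs(cc, -dd, ll, nq, p)
    expect_equal(pr$p_right, mir$p_left)
  }
  # no dead zone when the criterion is zero
  pz <- detection_params(15, 1, c(0, 0, 0), 1)
  expect_equal(choice_probs(0.128, 1, 1, 0, pz)$p_requery, 0)
  # zero coherence: left/right symmetric
  ps <- choice_probs(0, 1, 2, 0, p)
  expect_equal(ps$p_right, ps$p_left)
})

test_that("choice probabilities match Monte-Carlo thresholding of the evidence", {
  p <- tq_det()
  set.seed(9)
  n <- 1e5
  for (cell in list(c(0.064, 1, 1, 0), c(0.256, -1, 2, 1), c(0.512, 1, 3, 0))) {
    e <- sample_evidence(rep(cell[1], n), rep(cell[2], n), p)
    Phi <- criterion(cell[3], cell[4], p)
    pr <- choice_probs(cell[1], cell[2], cell[3], cell[4], p)
    for (pair in list(c(pr$p_right, mean(e > Phi)),
                      c(pr$p_left, mean(e < -Phi)),
                      c(pr$p_requery, mean(abs(e) <= Phi)))) {
      se <- sqrt(max(pair[1] * (1 - pair[1]), 1e-6) / n)
      expect_lt(abs(pair[1] - pair[2]), 4 * se)
    }
  }
})

test_that("requery probability falls with coherence and with streak length", {
  p <- tq_det()
  prc <- choice_probs(tq_coherences, 1, 2, 0, p)$p_requery
  expect_true(all(diff(prc) <= 0))
  prq <- choice_probs(0.064, 1, 2, 0:5, p)$p_requery
  expect_true(all(diff(prq) <= 0))
})

test_that("accuracy rises with coherence and falls with depth when criteria decrease", {
  p <- tq_det()   # phi1 > phi2 > phi3
  acc <- function(cc, ll) {
    pr <- choice_probs(cc, 1, ll, 0, p)
    pr$p_right / (pr$p_right + pr$p_left)
  }
  for (ll in 1:3) expect_true(all(diff(sapply(tq_coherences, acc, ll = ll)) > 0))
  for (cc in tq_coherences[1:4]) expect_true(all(diff(sapply(1:3, acc, cc = cc)) < 0))
})

test_that("detection log-likelihood equals a naive row-by-row computation", {
  p <- tq_det()
  expect_equal(detection_loglik(data.frame(c = numeric(0), d = numeric(0),
                                           level = integer(0), n_q = integer(0),
                                           outcome = character(0)), p), 0)
  set.seed(13)
  tbl <- generate_query_dataset(p, 300)
  naive <- 0
  for (r in seq_len(nrow(tbl))) {
    pr <- choice_probs(tbl$c[r], tbl$d[r], tbl$level[r], tbl$n_q[r], p)
    naive <- naive + log(switch(tbl$outcome[r], right = pr$p_right,
                                left = pr$p_left, requery = pr$p_requery))
  }
  expect_equal(detection_loglik(tbl, p), naive, tolerance = 1e-10)
  expect_error(detection_loglik(transform(tbl, outcome = "up"), p), "outcome")
})

test_that("the generating parameters beat perturbed ones on average", {
  p <- tq_det()
  set.seed(17)
  wins <- 0
  for (i in 1:10) {
    tbl <- generate_query_dataset(p, 2000)
    pert <- detection_params(p$kappa * 1.3, p$gamma, p$phi * 0.8, p$lambda)
    if (detection_loglik(tbl, p) > detection_loglik(tbl, pert)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("fitting is deterministic, order-invariant and at least as good as truth", {
  p <- tq_det()
  set.seed(19)
  tbl <- generate_query_dataset(p, 1500)
  f1 <- fit_detection(tbl, n_starts = 3, seed = 4)
  f2 <- fit_detection(tbl[sample(nrow(tbl)), ], n_starts = 3, seed = 4)
  expect_equal(f1$par, f2$par, tolerance = 1e-6)
  expect_gte(f1$loglik, detection_loglik(tbl, p) - 1e-6)
  expect_equal(f1$bic, f1$k * log(f1$n) - 2 * f1$loglik)
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik)
})

test_that("variant likelihoods restrict or extend the detection family coherently", {
  p <- tq_det()
  set.seed(29)
  tbl <- generate_query_dataset(p, 800)
  tbl$q <- pmin(tbl$n_q + 1L, 10L)   # stand-in trial order for the query-order variant
  pars <- c(p$kappa, p$gamma, p$phi, p$lambda)
  # gamma0 at gamma = 0 equals detection with gamma = 0
  p0 <- detection_params(p$kappa, 0, p$phi, p$lambda)
  expect_equal(treequery:::.variant_loglik(c(p$kappa, p$phi, p$lambda), "gamma0",
                                           tbl, p$t, 2001),
               detection_loglik(tbl, p0), tolerance = 1e-10)
  # tied-kappa variants at equal kappas reproduce the detection likelihood
  expect_equal(treequery:::.variant_loglik(c(rep(p$kappa, 3), p$gamma,
                                             p$phi, p$lambda),
                                           "three_phi_three_kappa", tbl, p$t, 2001),
               detection_loglik(tbl, p), tolerance = 1e-10)
  # query-order variant with flat criterion (phi0 = phi_inf) is level-free
  flat <- detection_params(p$kappa, p$gamma, rep(0.4, 3), p$lambda)
  expect_equal(treequery:::.variant_loglik(c(p$kappa, p$gamma, 0.4, 0.4, 0,
                                             p$lambda),
                                           "query_order", tbl, p$t, 2001),
               detection_loglik(tbl, flat), tolerance = 1e-10)
})

test_that("one-pulse integration probabilities equal the detection trichotomy", {
  p <- tq_det()
  for (cc in c(0.064, 0.512)) {
    cp <- integration_pulse_probs(cc, 1, 2, p, 1)
    pr <- choice_probs(cc, 1, 2, 0, p)
    expect_equal(unname(cp[1, ]), c(pr$p_right, pr$p_left, pr$p_requery),
                 tolerance = 1e-12)
  }
})

test_that("integration exit probabilities match Monte-Carlo cumulative sums", {
  p <- tq_det()
  set.seed(31)
  n <- 1e5
  for (cc in c(0.064, 0.256)) {
    npulse <- 5
    cp <- integration_pulse_probs(cc, 1, 1, p, npulse)
    mu <- evidence_mean(cc, 1, p); sd <- evidence_sd(cc, p)
    cs <- matrix(stats::rnorm(npulse * n, mu, sd), n, npulse)
    cs <- t(apply(cs, 1, cumsum))
    alive <- rep(TRUE, n)
    for (k in seq_len(npulse)) {
      Phi <- criterion(1, k - 1, p)
      na <- sum(alive)
      if (na < 5000) break
      r <- alive & cs[, k] > Phi
      l <- alive & cs[, k] < -Phi
      emp <- c(sum(r), sum(l), na - sum(r) - sum(l)) / na
      for (j in 1:3) {
        se <- sqrt(max(cp[k, j] * (1 - cp[k, j]), 1e-6) / na)
        expect_lt(abs(cp[k, j] - emp[j]), 4 * se + 2e-3)
      }
      alive <- alive & !r & !l
    }
  }
})

test_that("a coarse integration grid is flagged by disagreement with a fine one", {
  p <- tq_det()
  fine <- integration_pulse_probs(0.128, 1, 1, p, 4, grid_n = 4001)
  std <- integration_pulse_probs(0.128, 1, 1, p, 4, grid_n = 2001)
  expect_equal(std, fine, tolerance = 2e-3)
})

test_that("integration log-likelihood chains conditional pulse probabilities", {
  p <- tq_det()
  set.seed(37)
  tbl <- generate_integration_dataset(p, 400)
  # brute force: per streak, product of conditional outcome probabilities
  naive <- 0
  for (sid in unique(tbl$streak)) {
    k <- tbl[tbl$streak == sid, ]
    cp <- integration_pulse_probs(k$c[1], k$d[1], k$level[1], p, nrow(k))
    for (r in seq_len(nrow(k))) {
      col <- switch(k$outcome[r], right = 1, left = 2, requery = 3)
      naive <- naive + log(unname(cp[r, col]))
    }
  }
  expect_equal(integration_loglik(tbl, p), naive, tolerance = 1e-8)
})

test_that("the fitting subset is extracted exactly from a session log", {
  lg <- tq_toy_log()
  qt <- query_table_from_log(lg)
  # rows: 1 (requery), 1 (right child 3), 3 (right child 7); row 4 (node 7)
  # is followed by a leaf, and leaves/terminal rows are dropped
  expect_identical(nrow(qt), 3L)
  expect_identical(qt$outcome, c("requery", "right", "right"))
  expect_identical(attr(qt, "n_dropped"), 2L)  # nodes 7 and 5 rows
  expect_identical(qt$n_q, c(0L, 1L, 0L))
})
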