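test_that("transition counts match a hand tabulation on a toy log", {
  st <- transition_stats(tq_toy_log())
  m <- st$M[["s1"]]
  expect_equal(sum(m), 6)                      # 7 queries -> 6 transitions
  expect_equal(m[1, 1], 1)                     # re-query of the root
  expect_equal(m[1, 3], 1)
  expect_equal(m[3, 7], 1)
  expect_equal(m[7, 11], 1)
  expect_equal(m[11, 5], 1)
  expect_equal(m[5, 15], 1)
  w <- st$W[["s1"]]
  expect_equal(w[1, 1], 0.5)
  rs <- rowSums(w, na.rm = TRUE)
  expect_true(all(abs(rs[rowSums(m) > 0] - 1) < 1e-12))
  # level transitions split at the first error: 4 transitions before
  # (1-1, 1-2, 2-3, 3-4), 2 after (4-3, 3-4), normalized by queries - 1
  expect_equal(sum(st$N_pre) * 6, 4)
  expect_equal(sum(st$N_post) * 6, 2)
  expect_equal(st$N_post[4, 3] * 6, 1)
  expect_error(transition_stats(tq_toy_log()[0, ]), "empty")
})

test_that("a root-requery-only log gives W(1|1) = 1", {
  lg <- tq_toy_log()[1:2, ]
  st <- transition_stats(lg)
  expect_equal(st$W_mean[1, 1], 1)
})

test_that("analyses are invariant to subject order and log concatenation", {
  pp <- synthetic_participants()
  set.seed(3)
  s1 <- run_heuristic_agent(pp$p1, 60, full_log = TRUE, subject = "a")$log
  s2 <- run_heuristic_agent(pp$p2, 60, full_log = TRUE, subject = "b")$log
  st12 <- transition_stats(rbind(s1, s2))
  st21 <- transition_stats(rbind(s2, s1))
  expect_equal(st12$W_mean, st21$W_mean)
  expect_equal(st12$N_pre, st21$N_pre)
  sm12 <- summarize_sessions(rbind(s1, s2))
  sm21 <- summarize_sessions(rbind(s2, s1))
  expect_equal(sm12$reward$mean, sm21$reward$mean)
  expect_equal(sm12$per_level, sm21$per_level)
})

test_that("post-error and post-internal actions are classified correctly", {
  cls <- classify_actions(tq_toy_log())
  expect_identical(cls$category[cls$context == "internal"],
                   c("requery", "correct_child", "correct_child",
                     "other_lower_level", "other_lower_level"))
  # after the error at 11, querying 5 is on-path
  expect_identical(cls$category[cls$context == "error"], "on_path")

  # off-path example: error at 11 followed by node 10
  lg <- tq_toy_log()
  lg$node_canonical[6] <- 10L; lg$node[6] <- 10L; lg$level[6] <- 4L
  lg$feedback[6] <- "negative"
  cls2 <- classify_actions(lg)
  expect_identical(cls2$category[cls2$context == "error"][1], "off_path")

  # categories are exhaustive and mutually exclusive by construction
  pp <- synthetic_participants()
  set.seed(5)
  lg3 <- run_heuristic_agent(pp$p2, 150, full_log = TRUE)$log
  cls3 <- classify_actions(lg3)
  expect_true(all(cls3$category[cls3$context == "error"] %in%
                    c("on_path", "off_path", "other")))
  expect_true(all(cls3$category[cls3$context == "internal"] %in%
                    c("requery", "correct_child", "incorrect_child",
                      "other_same_level", "other_lower_level", "higher_level")))
})

test_that("blame statistics agree with a brute-force recount", {
  pp <- synthetic_participants()
  set.seed(7)
  sim <- run_heuristic_agent(pp$p3, 2500)
  bs <- blame_stats(sim$errors)
  err <- sim$errors
  cohm <- as.matrix(err[, c("coh1", "coh2", "coh3")])
  cc <- 0.032
  denom <- sum(apply(cohm == cc, 1, any))
  num <- sum(err$blamed_level > 0 &
               cohm[cbind(seq_len(nrow(err)), pmax(err$blamed_level, 1))] == cc)
  expect_equal(unname(bs$by_coherence[1]), num / denom)
  # on-path table, level 2 at coherence 0.128
  denom2 <- sum(cohm[, 2] == 0.128)
  num2 <- sum(err$path_type == 1 & err$blamed_level == 2 & cohm[, 2] == 0.128)
  expect_equal(unname(bs$on_path[2, 3]), num2 / denom2)
})

test_that("data-mode blame statistics recover a hand-built single-error log", {
  lg <- tq_toy_log()   # error at 11 followed by on-path query at 5
  bs <- blame_stats(lg, mode = "data")
  expect_equal(bs$n_errors, 1)
  # path of 11 is (1, 2, 5); the on-path query went to node 5 (level 3),
  # whose coherence in the log is 0.128
  expect_equal(unname(bs$on_path["3", "0.128"]), 1)
})

test_that("logistic fits recover known coefficients within 2 SE", {
  set.seed(11)
  n <- 6000
  tbl <- data.frame(c = sample(tq_coherences, n, TRUE),
                    level = sample(1:3, n, TRUE), subject = "s1")
  eta <- 1.5 - 6 * tbl$c - 0.5 * tbl$level
  tbl$y <- stats::rbinom(n, 1, stats::plogis(eta))
  fit <- fit_logistic("requery", tbl)
  est <- fit$coef[c("c", "level"), "Estimate"]
  se <- fit$coef[c("c", "level"), "Std. Error"]
  expect_lt(abs(est["c"] - (-6)), 2 * se["c"])
  expect_lt(abs(est["level"] - (-0.5)), 2 * se["level"])
  expect_lt(fit$lr_p["coherence"], 0.01)
})

test_that("choice and requery regressions show the expected sign pattern", {
  set.seed(13)
  tbl <- generate_query_dataset(tq_det(), 6000)
  rc <- fit_logistic("choice", regression_table(tbl, "choice"))
  expect_gt(rc$coef["s", "Estimate"], 0)
  expect_lt(rc$coef["s:level", "Estimate"], 0)
  rq <- fit_logistic("requery", regression_table(tbl, "requery"))
  expect_lt(rq$coef["c", "Estimate"], 0)
  expect_lt(rq$coef["level", "Estimate"], 0)
  expect_lt(rq$lr_p["coherence"], 1e-8)
})

test_that("the product of non-blamed coherences predicts on-path queries negatively", {
  pp <- synthetic_participants()
  set.seed(17)
  sim <- run_heuristic_agent(heuristic_params(pp$p3$det, 0.85), 6000)
  tab <- regression_table(sim$errors, "on_path")
  fit <- fit_logistic("on_path", tab)
  expect_lt(fit$coef["c_prod", "Estimate"], 0)
  expect_lt(fit$lr_p["product"], 0.01)
  # blame regression: weaker motion and lower level attract blame
  bt <- regression_table(sim$errors, "blame")
  fb <- fit_logistic("blame", bt)
  expect_lt(fb$coef["c", "Estimate"], 0)
})

test_that("session summaries follow the stated conventions", {
  lg <- tq_toy_log()
  s <- summarize_sessions(lg)
  expect_equal(s$reward$mean, 2)     # 10 - 4 queries - 3
  expect_equal(s$reward$sem, 0)
  expect_equal(s$per_level$queries, c(2, 1, 2))
  expect_equal(s$errors_per_trial, 1)
  set.seed(19)
  lr <- run_random_leaf_agent(400)
  sr <- summarize_sessions(lr)
  expect_lt(abs(sr$reward$mean - (-0.5)), 4 * sr$reward$sem + 0.05)
})
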