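test_that("blame assignment follows the on-path / off-path / fallback rules", {
  tr <- build_tree()
  # error at 11 (path 1, 2, 5); confidences ordered by level
  r <- assign_blame(11, c(0.9, 0.4, 0.5), rep(TRUE, 3), omega = 0.6, tree = tr)
  expect_identical(r$blamed, 2L)          # >= 2 low-conf: highest level of {2, 5}
  expect_identical(r$next_query, 2L)
  expect_identical(r$path_type, "on")

  r <- assign_blame(11, c(0.9, 0.4, 0.95), rep(TRUE, 3), omega = 0.6, tree = tr)
  expect_identical(r$blamed, 2L)          # only node 2 low-conf
  expect_identical(r$next_query, 4L)      # its counterfactual child
  expect_identical(r$path_type, "off")

  # least-confident eligible node when none is low-confidence
  r <- assign_blame(11, c(0.9, 0.8, 0.7), rep(TRUE, 3), omega = 0.6, tree = tr)
  expect_identical(r$blamed, 5L)
  expect_identical(r$next_query, 10L)     # counterfactual child of 5 is leaf 10
  expect_identical(r$path_type, "off")

  # ineligible nodes are skipped before the rules apply
  r <- assign_blame(11, c(0.4, 0.3, 0.5), c(FALSE, TRUE, TRUE), omega = 0.6,
                    tree = tr)
  expect_identical(r$blamed, 2L)          # 1 is ineligible; {2, 5} low-conf
  expect_identical(r$path_type, "on")

  # nothing eligible: fallback to an unvisited leaf, no blame
  set.seed(3)
  r <- assign_blame(11, c(0.4, 0.3, 0.5), rep(FALSE, 3), omega = 0.6,
                    visited = c(9, 10), tree = tr)
  expect_true(is.na(r$blamed))
  expect_identical(r$path_type, "fallback")
  expect_true(r$next_query %in% setdiff(8:15, c(9, 10, 11)))
})

test_that("omega = 0 makes every blamed error off-path", {
  pp <- synthetic_participants()
  set.seed(5)
  sim <- run_heuristic_agent(heuristic_params(pp$p1$det, 0), 2000)
  expect_identical(sum(sim$errors$path_type == 1), 0L)
  expect_equal(p_on_path(sim), 0, tolerance = 1e-12)
})

test_that("simulated sessions respect leaf memory and the path-type geometry", {
  pp <- synthetic_participants()
  set.seed(7)
  sim <- run_heuristic_agent(pp$p2, 400, full_log = TRUE)
  lg <- sim$log
  # no leaf is ever queried twice within a trial
  for (tt in split(lg, lg$trial)) {
    leaves <- tt$node[tt$level == 4]
    expect_identical(anyDuplicated(leaves), 0L)
  }
  err <- sim$errors
  # canonical geometry: on-path next query lies on the error path,
  # off-path next query is a counterfactual child, fallback goes to leaves
  anc <- cbind(1L, err$leaf %/% 4L, err$leaf %/% 2L)
  cf <- cbind(bitwXor(anc[, 2], 1L), bitwXor(anc[, 3], 1L),
              bitwXor(err$leaf, 1L))
  on <- err$path_type == 1
  off <- err$path_type == 2
  fb <- err$path_type == 3
  expect_true(all(err$next_node[on] == anc[cbind(which(on), err$blamed_level[on])]))
  expect_true(all(err$next_node[off] == cf[cbind(which(off), err$blamed_level[off])]))
  expect_true(all(err$next_node[fb] >= 8))
  expect_true(all(err$blamed_level[fb] == 0))
  # blamed node is never blamed with eligibility off
  el <- as.matrix(err[, c("elig1", "elig2", "elig3")])
  blamed <- err$blamed_level > 0
  expect_true(all(el[cbind(which(blamed), err$blamed_level[blamed])] == 1))
})

test_that("the compiled blame decisions replay exactly through assign_blame", {
  pp <- synthetic_participants()
  set.seed(9)
  sim <- run_heuristic_agent(pp$p3, 300)
  err <- sim$errors
  tr <- build_tree()
  for (r in seq_len(min(nrow(err), 200))) {
    out <- assign_blame(err$leaf[r],
                        c(err$conf1[r], err$conf2[r], err$conf3[r]),
                        c(err$elig1[r], err$elig2[r], err$elig3[r]) == 1,
                        pp$p3$omega, tree = tr)
    type <- c(on = 1L, off = 2L, fallback = 3L)[out$path_type]
    expect_identical(unname(type), err$path_type[r])
    if (type < 3) {
      expect_identical(tr$level[out$blamed], err$blamed_level[r])
      expect_identical(out$next_query, err$next_node[r])
    }
  }
})

test_that("the on-path proportion is nondecreasing in omega", {
  pp <- synthetic_participants()
  po <- vapply(c(0.2, 0.5, 0.7, 0.85, 0.95), function(w) {
    set.seed(11)
    p_on_path(run_heuristic_agent(heuristic_params(pp$p3$det, w), 4000))
  }, numeric(1))
  expect_true(all(diff(po) >= -0.005))
  expect_lt(po[1], po[5])
})

test_that("on-path blame concentrates high and off-path blame low in the tree", {
  pp <- synthetic_participants()
  set.seed(13)
  sim <- run_heuristic_agent(heuristic_params(pp$p3$det, 0.85), 8000)
  err <- sim$errors
  on_lv <- table(factor(err$blamed_level[err$path_type == 1], levels = 1:3))
  off_lv <- table(factor(err$blamed_level[err$path_type == 2], levels = 1:3))
  expect_gt(on_lv["1"], on_lv["3"])
  expect_gt(off_lv["3"], off_lv["1"])
})

test_that("a reward-maximizing threshold pushes all post-error queries off-path", {
  # the reward surface is flat wherever the threshold produces (almost) no
  # on-path queries, so the informative comparison is between the
  # off-path-only regime and a strongly on-path one
  pp <- synthetic_participants()
  grid <- c(0.05, 0.5, 0.95)
  res <- t(vapply(grid, function(w) {
    set.seed(17)
    s <- run_heuristic_agent(heuristic_params(pp$p3$det, w), 10000)
    c(reward = mean(s$trials$reward), p_on = p_on_path(s))
  }, numeric(2)))
  expect_lt(res[1, "p_on"], 0.01)
  expect_gt(res[3, "p_on"], 0.3)
  # on-path re-querying costs points: reward is maximized off-path
  expect_gt(res[1, "reward"], res[3, "reward"])
  best <- which.max(res[, "reward"])
  expect_lt(res[best, "p_on"], 0.05)
})

test_that("omega recovery works in the identifiable threshold range", {
  pp <- synthetic_participants()
  rec <- recovery_suite("omega", heuristic_params(pp$p3$det, 0.85), 15000,
                        seed = 1)
  expect_true(rec$pass)
  expect_lt(rec$err, 0.05)
})

test_that("a zero target proportion drives the fit to the grid minimum", {
  pp <- synthetic_participants()
  f <- fit_omega(0, pp$p1$det, n_trials = 1500, n_grid = 9, seed = 1)
  expect_equal(f$omega, min(f$grid$omega))
  expect_lte(f$err, min(f$grid$err) + 1e-12)
})
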