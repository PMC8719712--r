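# Shared fixtures for the suite: mid-range sensory/criterion parameters and
# small builders used across files.

tq_coherences <- c(0.032, 0.064, 0.128, 0.256, 0.512)

tq_det <- function() detection_params(15, 1, c(0.5, 0.375, 0.25), 1.2)
tq_ep <- function() evidence_params(15, 1)

# a tiny hand-written session log (canonical coordinates already aligned:
# all true directions rightward, so node == node_canonical)
tq_toy_log <- function() {
  data.frame(
    subject = "s1", trial = 1, step = 1:7,
    node = c(1L, 1L, 3L, 7L, 11L, 5L, 15L),
    node_canonical = c(1L, 1L, 3L, 7L, 11L, 5L, 15L),
    level = c(1L, 1L, 2L, 3L, 4L, 3L, 4L),
    coh = c(0.064, 0.064, 0.256, 0.032, NA, 0.128, NA),
    dir = c(1, 1, 1, 1, NA, 1, NA),
    e = c(0.1, 0.9, 1.2, -0.3, NA, 0.5, NA),
    n_q = c(0L, 1L, 0L, 0L, 0L, 0L, 0L),
    q = 1:7,
    feedback = c("none", "none", "none", "none", "negative", "none", "target"),
    points = c(-1, -1, -1, -1, -3, -1, 10))
}

# random belief state: a few random evidence updates and optional errors
tq_random_belief <- function(n_updates = 3, n_errors = 0, ep = tq_ep()) {
  b <- init_beliefs(ep)
  for (i in seq_len(n_updates))
    b <- update_node_posterior(b, sample(7, 1), stats::rnorm(1, 0, 0.8))
  if (n_errors > 0)
    for (leaf in sample(8:15, n_errors)) b <- mark_visited(b, leaf)
  b
}
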