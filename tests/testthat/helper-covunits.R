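# Small-scale simulation used across module tests: 4 metrics, 2 planted
# replicable units over 3-metric subsets, desk-sized cohorts.
small_sim <- function(seed = 1, rho = 0.95, snr = 5, n_discover = 80,
                      n_confirm = 120, v = 400, replicable = TRUE) {
  simulate_cohorts(synthetic_config(
    n_discover = n_discover, n_confirm = n_confirm, v = v,
    metrics = c("vol", "area", "alff", "ec"),
    components_per_metric = 4L,
    n_units = 2L, unit_size = 3L, rho = rho, replicable = replicable,
    snr = snr, seed = seed))
}

# hand-built 3-metric x 2-component similarity toy used in the alignment
# tests; all block segments have two elements, so every zrow value is +/-1
toy_fsm <- function() {
  S <- diag(6)
  set_pair <- function(S, i, j, r) { S[i, j] <- r; S[j, i] <- r; S }
  # metrics A = rows 1:2, B = 3:4, C = 5:6
  S <- set_pair(S, 1, 3, 0.9); S <- set_pair(S, 1, 4, 0.1)
  S <- set_pair(S, 2, 3, 0.2); S <- set_pair(S, 2, 4, 0.8)
  S <- set_pair(S, 1, 5, 0.7); S <- set_pair(S, 1, 6, 0.3)
  S <- set_pair(S, 2, 5, 0.6); S <- set_pair(S, 2, 6, 0.4)
  S <- set_pair(S, 3, 5, 0.5); S <- set_pair(S, 3, 6, 0.2)
  S <- set_pair(S, 4, 5, 0.1); S <- set_pair(S, 4, 6, 0.6)
  S <- set_pair(S, 1, 2, 0.05); S <- set_pair(S, 3, 4, 0.05)
  S <- set_pair(S, 5, 6, 0.05)
  labels <- c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2")
  dimnames(S) <- list(labels, labels)
  structure(list(sims = S, block = rep(1:3, each = 2),
                 metric_levels = c("A", "B", "C"), scm_labels = labels,
                 k_per_metric = c(A = 2L, B = 2L, C = 2L)),
            class = "covunit_fsm")
}

# brute-force iterated Grubbs: remove the most extreme studentized value up
# to m times, testing each step against the gESD critical value
grubbs_iterated <- function(x, alpha, m) {
  n <- length(x)
  idx <- seq_len(n)
  removed <- integer(0)
  decisions <- logical(0)
  for (i in seq_len(m)) {
    xi <- x[idx]
    if (sd(xi) == 0) break
    dev <- abs(xi - mean(xi)) / sd(xi)
    j <- which.max(dev)
    ni <- length(xi)
    tq <- qt(1 - alpha / (2 * ni), df = ni - 2)
    crit <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
    decisions <- c(decisions, dev[j] > crit)
    removed <- c(removed, idx[j])
    idx <- idx[-j]
  }
  if (!any(decisions)) return(integer(0))
  sort(removed[seq_len(max(which(decisions)))])
}
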