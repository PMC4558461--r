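# shared helpers for the test suite: small scenarios, group summaries and
# the independent hand-written state-derivative oracle

# group-mean log-scaling trajectories from a posterior
group_trajectories <- function(post) {
  lam <- seizuredcm:::posterior_lambda(post)
  list(inhibitory = rowMeans(lam[, c("g3", "g4", "g9")]),
       excitatory = rowMeans(lam[, c("g5", "g6", "g8")]))
}

# a small, quick scenario (4 windows) for integration-style tests
tiny_scenario <- function(seed = 1, preset = "stationary", ...) {
  seizure_scenario(preset, duration_s = 8, n_seizures = 8, seed = seed, ...)
}

# hand-expanded CMC equations, written out term by term, independent of the
# package's wiring table: the oracle for state_derivative
oracle_state_derivative <- function(x, xd, u, p) {
  sig <- function(v) 1 / (1 + exp(-p[["gamma"]] * v)) - 0.5
  v <- x[1:4]; i <- x[5:8]; vd <- xd[1:4]
  g <- unname(p[5:14]); T <- unname(p[1:4])
  drive <- c(
    -g[1] * sig(v[1]) - g[2] * sig(vd[2]) - g[3] * sig(vd[3]) + u,  # ss
    +g[8] * sig(vd[1]) - g[7] * sig(v[2]),                          # sp
    +g[5] * sig(vd[1]) - g[4] * sig(v[3]) + g[6] * sig(vd[4]),      # ii
    -g[9] * sig(vd[3]) - g[10] * sig(v[4])                          # dp
  )
  c(i, T * drive - 2 * T * i - T^2 * v)
}
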