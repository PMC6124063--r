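# Shared fixtures, computed lazily and cached for the whole test run.
# Heavy experiment ensembles (the S = 200 repeat sets) are reused across
# test files so each is simulated exactly once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tp1_ensemble <- function() {
  fixture("tp1_S200",
          run_experiment(make_test_problem("tp1"), "hybrid", S = 200,
                         base_seed = 1))
}

tp2_ensemble <- function() {
  fixture("tp2_S200",
          run_experiment(make_test_problem("tp2"), "hybrid", S = 200,
                         base_seed = 1))
}

tp3_ensemble <- function() {
  fixture("tp3_S200",
          run_experiment(make_test_problem("tp3"), "hybrid", S = 200,
                         base_seed = 1))
}

tp3_oracle <- function() {
  fixture("tp3_oracle",
          meanfield_morphogen(t_out = seq(0, 100, by = 5), lambda = 400,
                              mu = 0.001, D = 0.0025, N = 500))
}

tp4_pair <- function() {
  fixture("tp4_pair", {
    cfg <- make_test_problem("tp4")
    list(hybrid = run_experiment(cfg, "hybrid", S = 100, base_seed = 1),
         micro = run_experiment(cfg, "microscopic", S = 100,
                                base_seed = 5001))
  })
}

# integrate a density function over h_a bins (fine midpoint rule)
bin_mass_of <- function(f, edges, t, k = 50L) {
  vapply(seq_len(length(edges) - 1L), function(b) {
    xs <- seq(edges[b], edges[b + 1], length.out = k + 1L)
    xm <- (xs[-1] + xs[-length(xs)]) / 2
    mean(f(xm, t)) * (edges[b + 1] - edges[b])
  }, numeric(1))
}

# mean binned mass profile of an experiment at a snapshot index
mean_bin_mass <- function(exp, j) {
  apply(exp$density[, j, , drop = FALSE], 3, mean) * exp$config$h_a
}
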