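# shared helpers for synthetic-data tests

# a standard added-ligand grid for competition titrations, as multiples of
# the fixed-ligand total
ratio_grid <- function(fixed_total, r_max = 30, n = 40) {
  fixed_total * exp(seq(log(0.025), log(r_max), length.out = n))
}

# noiseless titration from a fixture id, plus the matching replot call
replot_from_fixture <- function(id, r_max = 30) {
  fx <- get_fixture(id)
  p <- fx$params
  cv <- gen_titration(fx, ratio_grid(p$fixed_total, r_max), Bmax = 1,
                      noise = noise_spec(0))
  replot(cv, fixed_total = p$fixed_total, Bmax = 1,
         mode = if (p$style == "displacement") "displacement" else
           "association")
}

# recovered chase rates over `n_seeds` noisy replicates of a fixture
chase_replicates <- function(k_true, n_seeds, sigma_frac = 0.01,
                             n_averages = 5, seed_base = 0) {
  vapply(seq_len(n_seeds), function(j) {
    tr <- gen_trace_multiexp(list(c(1, k_true)),
                             noise = noise_spec(sigma_frac, n_averages,
                                                seed_base + j))
    chase_koff(tr)$k_off
  }, numeric(1))
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
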