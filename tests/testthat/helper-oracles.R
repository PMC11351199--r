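# Independent oracles and shared fixtures.

# Brute-force two-sided Fisher p for a 2x2 table (a, b / c, d): enumerate
# every table with the same margins via binomial coefficients and sum the
# probabilities of tables no more probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Step-up BH definition: q_(i) = min over j >= i of p_(j) * n / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(1, q_sorted)[order(o)]
}

# Exact hypergeometric upper-tail via enumeration.
oracle_hyper_tail <- function(overlap, size_a, size_b, universe) {
  support <- overlap:min(size_a, size_b)
  sum(vapply(support, function(x)
    choose(size_a, x) * choose(universe - size_a, size_b - x) /
      choose(universe, size_b), numeric(1)))
}

# Desk-scale simulation config used by unit tests (smaller than the
# default study conditions to keep the suite fast).
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_case = 40, n_control = 60, n_cytobands = 60,
             n_genes = 120, n_enriched_cytobands = 8, n_switch_genes = 12,
             ...)
}

# Near-noiseless variant: strong coupling, negligible expression and BF
# noise, so downstream selections equal the planted truth exactly.
noiseless_config <- function(seed = 1, ...) {
  sim_config(seed = seed, expr_effect = 4, expr_sd = 0.01,
             bf_noise_sd = 0.01, ...)
}

groups_of <- function(bundle) {
  grp <- classify_group(bundle$samples)
  stats::setNames(grp$group, grp$sample_id)
}
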