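# Shared fixture builders for the suite. Everything is generated in code;
# no data files.

tiny_grid <- function(n_bins = 100, bin_size = 1e5, n_chrom = 1) {
  build_genome(n_chrom, n_bins * bin_size, bin_size)
}

# A block-compartment contact matrix with pure power-law decay times a
# plaid boost, deterministic (expected values, no sampling).
plaid_matrix <- function(labels, depth = 50, decay = -1, plaid = 3) {
  n <- length(labels)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(labels, labels, "==")
  contact_matrix(depth * (1 + d)^decay * plaid^same)
}

# Noiseless nested-domain matrix: one parent [a, b) with two children
# split at m (bins are 1-based here), on an n-bin chromosome.
nested_domain_matrix <- function(n = 60, a = 21, b = 40, depth = 100,
                                 decay = -1, boost = 3) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- depth * (1 + d)^decay
  inp <- seq_len(n) >= a & seq_len(n) <= b
  m <- a + (b - a + 1) %/% 2
  in1 <- seq_len(n) >= a & seq_len(n) < m
  in2 <- seq_len(n) >= m & seq_len(n) <= b
  mu <- mu * boost^outer(inp, inp) * boost^outer(in1, in1) *
    boost^outer(in2, in2)
  contact_matrix(round(mu, 6))
}

# Independent full-enumeration oracle for the exact two-sided rank-sum
# p-value (no ties): enumerates every assignment of ranks to group x.
rank_sum_enum_p <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)])
  all_w <- utils::combn(N, n, FUN = sum)
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  min(1, p)
}

rt_profile_from <- function(grid, values, cell_type = "ref") {
  out <- tibble::as_tibble(grid)
  out$rt <- values
  out$cell_type <- cell_type
  out
}
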