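test_that("expected-by-distance equals the per-diagonal mean", {
  # constant diagonals
  n <- 10
  v <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    idx <- which(abs(outer(1:n, 1:n, "-")) == d)
    v[idx] <- 10 - d
  }
  m <- contact_matrix(v)
  ed <- expected_by_distance(m)
  expect_equal(ed$expected, 10 - ed$distance)

  # brute-force oracle on a random symmetric matrix with a mask
  set.seed(4)
  r <- matrix(rpois(15 * 15, 20), 15, 15)
  r <- r + t(r)
  mask <- rep(FALSE, 15); mask[c(3, 11)] <- TRUE
  mr <- contact_matrix(r, mask = mask)
  ed2 <- expected_by_distance(mr)
  for (d in 0:14) {
    vals <- c()
    for (i in 1:15) for (j in 1:15) {
      if (abs(i - j) == d && !mask[i] && !mask[j]) vals <- c(vals, r[i, j])
    }
    if (length(vals)) expect_equal(ed2$expected[d + 1], mean(vals))
  }

  expect_error(expected_by_distance(contact_matrix(matrix(1, 3, 3),
                                                   mask = rep(TRUE, 3))),
               "unmasked")
})

test_that("O/E diagonals average to one and expose plaid enrichment", {
  # pure decay: every diagonal mean is exactly 1
  n <- 40
  d <- abs(outer(1:n, 1:n, "-"))
  m <- contact_matrix(100 * (1 + d)^-1)
  oe <- oe_transform(m)
  for (dd in 0:(n - 2)) {
    vals <- oe$oe[cbind(1:(n - dd), (1 + dd):n)]
    expect_equal(mean(vals, na.rm = TRUE), 1, tolerance = 1e-6)
  }

  # plaid: same-compartment O/E above 1, cross below 1
  labs <- rep(c("A", "B"), each = 20)
  mp <- plaid_matrix(labs)
  oep <- oe_transform(mp)
  same <- outer(labs, labs, "==")
  off <- abs(outer(1:40, 1:40, "-")) > 0
  expect_gt(mean(oep$oe[same & off], na.rm = TRUE), 1)
  expect_lt(mean(oep$oe[!same], na.rm = TRUE), 1)
})

test_that("correlation matrix matches brute-force pairwise Pearson", {
  set.seed(9)
  n <- 10
  base <- matrix(rlnorm(n * n), n, n)
  base <- (base + t(base)) / 2
  m <- contact_matrix(base)
  oe <- oe_transform(m)
  cm <- correlation_matrix(oe)
  for (i in 1:n) for (j in 1:n) {
    expect_equal(cm[i, j], stats::cor(oe$oe[i, ], oe$oe[j, ]),
                 tolerance = 1e-10)
  }
  expect_equal(diag(cm), rep(1, n))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
})

test_that("the leading eigenvector separates anti-correlated blocks and recovers rank-one structure", {
  # exact two-block structure
  labs <- rep(c(1, -1), each = 10)
  cm <- outer(labs, labs)
  ev <- leading_eigenvector(cm)
  expect_equal(abs(ev), rep(1 / sqrt(20), 20))
  expect_true(all(sign(ev[1:10]) == -sign(ev[11:20])))

  # rank-one construction: c = v v^T recovers v up to sign and scale
  set.seed(12)
  v <- rnorm(30)
  ev2 <- leading_eigenvector(v %*% t(v))
  vn <- v / sqrt(sum(v^2))
  expect_lt(min(max(abs(ev2 - vn)), max(abs(ev2 + vn))), 1e-8)

  # invariance (up to global sign) under bin reordering
  perm <- sample(30)
  ev3 <- leading_eigenvector((v %*% t(v))[perm, perm])
  back <- ev3[order(perm)]
  expect_lt(min(max(abs(back - ev2)), max(abs(back + ev2))), 1e-8)
})

test_that("orientation follows the reference and flags degenerate cases", {
  set.seed(6)
  ev <- rnorm(50)
  ref <- ev + rnorm(50, 0, 0.1)          # positively correlated
  cp <- orient_compartments(ev, ref)
  expect_equal(cp$eigenvector, ev)
  expect_equal(cp$compartment[ev > 0][1], "A")
  expect_false(attr(cp, "orientation_flipped"))

  cpn <- orient_compartments(ev, -ref)   # anti-correlated: flip
  expect_equal(cpn$eigenvector, -ev)
  expect_true(attr(cpn, "orientation_flipped"))

  # orientation is idempotent
  cp2 <- orient_compartments(cp, ref)
  expect_equal(cp2$eigenvector, cp$eigenvector)

  expect_warning(orient_compartments(ev, rep(1, 50)), "uncertain")
  expect_error(orient_compartments(ev[1:5], ref[1:5]), ">= 10")
})

test_that("fine-resolution compartments align to the coarse profile by majority vote", {
  g <- tiny_grid(100)
  tr <- plant_truth(g, c(CE = 0.5, CL = 0.5, EtoL = 0, LtoE = 0, other = 0),
                    seed = 14)
  p <- sim_params(plaid_strength = 3, seed = 14)
  m_fine <- simulate_contacts(tr, p, "ref")
  m_coarse <- aggregate_contacts(m_fine, 5)
  ref_sig <- simulate_mark_signal(tr, p, "active", "ref")

  cp <- compartments_at_resolution(m_coarse, m_fine, ref_sig)
  expect_false(attr(cp, "coarse_flip"))
  expect_gt(attr(cp, "coarse_agreement"), 0.5)

  # force a disagreeing coarse orientation: the fine chromosome is flipped
  coarse_ref <- -as.numeric(tapply(ref_sig$value, (seq_len(100) - 1) %/% 5,
                                   mean))
  cp_flip <- compartments_at_resolution(m_coarse, m_fine, ref_sig,
                                        reference_coarse = coarse_ref)
  expect_true(attr(cp_flip, "coarse_flip"))
  expect_equal(cp_flip$eigenvector, -cp$eigenvector)

  expect_error(compartments_at_resolution(
    contact_matrix(matrix(0, 2, 2), resolution = 2.5e5), m_fine, ref_sig),
    "divide")
})

test_that("compartmentalization degree scores same/opposite contact balance", {
  # constructed bin with equal same and opposite sums -> exactly 0
  cnt <- matrix(0, 4, 4)
  cnt[1, 2] <- 50; cnt[1, 3] <- 30; cnt[1, 4] <- 20
  cnt <- cnt + t(cnt)
  m <- contact_matrix(cnt)
  labs <- c("A", "A", "B", "B")   # same = 50, opp = 50 for bin 1
  deg <- compartmentalization_degree(m, labs, pseudocount = 0)
  expect_identical(deg$degree[1], 0)
  expect_equal(deg$same[1], 50)

  # same 80, opp 20 -> log2(4) = 2
  cnt2 <- matrix(0, 3, 3)
  cnt2[1, 2] <- 80; cnt2[1, 3] <- 20
  cnt2 <- cnt2 + t(cnt2)
  deg2 <- compartmentalization_degree(contact_matrix(cnt2),
                                      c("A", "A", "B"), pseudocount = 0)
  expect_equal(deg2$degree[1], 2)

  # the statistic is label-symmetric: exchanging every A and B leaves the
  # same/opposite partition of each bin's partners, hence every score,
  # unchanged; negation happens when a single bin's own label flips
  set.seed(15)
  r <- matrix(rpois(100, 10), 10, 10); r <- r + t(r)
  labs10 <- sample(c("A", "B"), 10, replace = TRUE)
  flip <- ifelse(labs10 == "A", "B", "A")
  d1 <- compartmentalization_degree(contact_matrix(r), labs10, 0)
  d2 <- compartmentalization_degree(contact_matrix(r), flip, 0)
  expect_equal(d1$degree, d2$degree)
  one <- labs10
  one[4] <- setdiff(c("A", "B"), labs10[4])
  d_one <- compartmentalization_degree(contact_matrix(r), one, 0)
  expect_equal(d_one$degree[4], -d1$degree[4])

  # monotonicity in a same-compartment count
  r2 <- r; r2[1, 2] <- r2[1, 2] + 5; r2[2, 1] <- r2[1, 2]
  if (labs10[1] == labs10[2]) {
    d3 <- compartmentalization_degree(contact_matrix(r2), labs10, 0)
    expect_gte(d3$degree[1], d1$degree[1])
  }

  expect_error(compartmentalization_degree(m, rep("masked", 4)),
               "entirely masked")
  expect_error(compartmentalization_degree(m, labs, pseudocount = -1), ">= 0")
})
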