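test_that("planted truth is reproducible and validates its inputs", {
  g <- tiny_grid(100)
  t1 <- plant_truth(g, seed = 11)
  t2 <- plant_truth(g, seed = 11)
  expect_identical(t1$categories, t2$categories)
  expect_identical(t1$rt_state, t2$rt_state)
  expect_identical(t1$compartments, t2$compartments)

  expect_error(plant_truth(g, c(0.5, 0.5, 0.1, 0, 0)), "sum to 1")
  expect_error(plant_truth(g, n_cell_types = 1), "reference")
})

test_that("degenerate all-CE fractions give early states everywhere", {
  g <- tiny_grid(50)
  tr <- plant_truth(g, c(CE = 1, CL = 0, EtoL = 0, LtoE = 0, other = 0),
                    seed = 2)
  expect_true(all(tr$categories$category == "CE"))
  for (ct in tr$cell_types) expect_true(all(tr$rt_state[[ct]] == "early"))
  expect_true(all(tr$compartments$ref == "A"))
})

test_that("planted category proportions converge to the requested fractions", {
  g <- build_genome(1, 1e9, 1e5)  # 10,000 bins
  fr <- c(CE = 0.4, CL = 0.4, EtoL = 0.1, LtoE = 0.1, other = 0)
  tr <- plant_truth(g, fr, seed = 5)
  obs <- table(tr$categories$category) / nrow(g)
  for (k in names(fr)[fr > 0]) {
    expect_lt(abs(obs[[k]] - fr[[k]]), 0.02)
  }
})

test_that("category semantics bind RT states across cell types", {
  g <- tiny_grid(200)
  tr <- plant_truth(g, seed = 9, n_cell_types = 3)
  cat <- tr$categories$category
  expect_true(all(tr$rt_state$ref[cat == "EtoL"] == "early"))
  expect_true(all(tr$rt_state$diff1[cat == "EtoL"] == "late"))
  expect_true(all(tr$rt_state$diff2[cat == "LtoE"] == "early"))
  expect_true(all(tr$rt_state$ref[cat == "CL"] == "late"))
  # compartments follow RT state by default
  expect_true(all((tr$compartments$diff1 == "A") ==
                    (tr$rt_state$diff1 == "early")))
})

test_that("discordant planting puts reference EtoL in B and LtoE in A", {
  g <- tiny_grid(300)
  tr <- plant_truth(g, seed = 4, discordant = TRUE)
  cat <- tr$categories$category
  expect_true(all(tr$compartments$ref[cat == "EtoL"] == "B"))
  expect_true(all(tr$compartments$ref[cat == "LtoE"] == "A"))
  # differentiated types remain tied to their RT state
  expect_true(all(tr$compartments$diff1[cat == "EtoL"] == "B"))
  expect_true(all(tr$compartments$diff1[cat == "LtoE"] == "A"))
})

test_that("phase counts honour depth, dispersion and the planted balance", {
  g <- tiny_grid(500)
  tr <- plant_truth(g, seed = 21)
  p0 <- sim_params(depth = 0, seed = 21)
  pc0 <- simulate_phase_counts(tr, p0, "ref")
  expect_true(all(pc0$S1 == 0 & pc0$S4 == 0))

  # near-zero noise: the sign of the log ratio matches truth nearly always
  p <- sim_params(depth = 100, dispersion = 0, seed = 21)
  pc <- simulate_phase_counts(tr, p, "ref")
  rt <- log2((pc$S1 + pc$S2 + 1) / (pc$S3 + pc$S4 + 1))
  early <- tr$rt_state$ref == "early"
  expect_gte(mean(sign(rt) == ifelse(early, 1, -1)), 0.99)
  expect_gt(mean(pc$S1[early] + pc$S2[early]),
            mean(pc$S3[early] + pc$S4[early]))

  expect_identical(simulate_phase_counts(tr, p, "ref"), pc)
  expect_error(simulate_phase_counts(tr, p, "hepatocyte"), "unknown cell type")
})

test_that("simulated contact matrices are symmetric with planted structure", {
  g <- tiny_grid(60)
  tr <- plant_truth(g, seed = 3)
  p <- sim_params(plaid_strength = 3, tad_boost = 2, seed = 3)
  m <- simulate_contacts(tr, p, "ref")
  expect_identical(m$counts, t(m$counts))
  expect_true(all(m$counts >= 0))
  expect_identical(simulate_contacts(tr, p, "ref")$counts, m$counts)

  # neutral structure: O/E diagonal means are 1 by construction downstream
  pn <- sim_params(plaid_strength = 1, tad_boost = 1, seed = 3)
  oe <- oe_transform(mask_empty_bins(simulate_contacts(tr, pn, "ref")))
  for (d in c(1, 5, 10)) {
    diag_vals <- oe$oe[cbind(1:(60 - d), (1 + d):60)]
    expect_equal(mean(diag_vals, na.rm = TRUE), 1, tolerance = 1e-6)
  }
})

test_that("mark signals separate early and late bins only when an effect is planted", {
  g <- tiny_grid(400)
  tr <- plant_truth(g, seed = 8)
  early <- tr$rt_state$ref == "early"

  p <- sim_params(mark_effect = 2, seed = 8)
  act <- simulate_mark_signal(tr, p, "active", "ref")
  rep_ <- simulate_mark_signal(tr, p, "repressive", "ref")
  expect_gt(mean(act$value[early]), mean(act$value[!early]))
  expect_gt(mean(rep_$value[!early]), mean(rep_$value[early]))
  expect_true(all(act$value >= 0))
  expect_identical(simulate_mark_signal(tr, p, "active", "ref"), act)

  # null effect: rank-sum p-values approximately uniform over seeds
  pvals <- vapply(1:200, function(s) {
    p0 <- sim_params(mark_effect = 0, seed = s)
    sig <- simulate_mark_signal(tr, p0, "active", "ref")
    rank_sum_test(sig$value[early], sig$value[!early])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("with all structure at neutral values compartment detection is at chance", {
  g <- tiny_grid(100)
  agree <- vapply(1:20, function(s) {
    tr <- plant_truth(g, seed = s)
    pn <- sim_params(plaid_strength = 1, tad_boost = 1, seed = s)
    m <- simulate_contacts(tr, pn, "ref")
    ev <- leading_eigenvector(correlation_matrix(oe_transform(mask_empty_bins(m))))
    lab <- ifelse(ev > 0, "A", "B")
    ok <- !is.na(ev)
    acc <- mean(lab[ok] == tr$compartments$ref[ok])
    max(acc, 1 - acc)  # orientation-free agreement
  }, numeric(1))
  expect_lt(mean(agree), 0.75)  # far from the >= 0.95 recovered regime
})

test_that("planted domain trees satisfy the nesting invariants", {
  g <- tiny_grid(150)
  tr <- plant_truth(g, seed = 13)
  for (ct in tr$cell_types) {
    expect_silent(validate_tad_tree(tr$tads[[ct]]))
  }
})
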