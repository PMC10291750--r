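test_that("expected signal is linear in amounts and saturates at the ceiling", {
  g <- gene_signal_model("g", baseline = 50, cellline_rates = c(A = 2, B = 1),
                         wbc_rate = 10, saturation_ceiling = 1e5)
  # empty composition: only the baseline enters the linear predictor
  expect_equal(expected_signal(g, sample_composition(), saturation = "clip"), 50)
  expect_equal(expected_signal(g, sample_composition()), 50, tolerance = 1e-3)
  # linear predictor adds rate * amount per source
  comp <- sample_composition(c(A = 10, B = 5), ng_wbc = 2)
  expect_equal(expected_signal(g, comp, saturation = "clip"),
               50 + 2 * 10 + 1 * 5 + 10 * 2)
  # small-signal regime: within 1% of the linear predictor
  g2 <- gene_signal_model("g2", baseline = 1000, saturation_ceiling = 1e5)
  expect_equal(expected_signal(g2, sample_composition()), 1000,
               tolerance = 0.01)
  # deep saturation approaches the ceiling from below
  g3 <- gene_signal_model("g3", baseline = 10, cellline_rates = c(A = 1000),
                          saturation_ceiling = 500)
  big <- expected_signal(g3, sample_composition(c(A = 1e4)))
  expect_lte(big, 500)
  expect_equal(big, 500, tolerance = 1e-6)
  # monotone nondecreasing in every amount
  amounts <- seq(0, 200, by = 20)
  resp <- vapply(amounts, function(a)
    expected_signal(g, sample_composition(c(A = a))), numeric(1))
  expect_true(all(diff(resp) >= 0))
})

test_that("tumor-cell counts convert at 20 pg per cell and negatives are rejected", {
  comp <- sample_composition(n_tumor_cells = 3, cell_line_of_cells = "A")
  expect_equal(unname(comp$pg_by_cellline["A"]), 60)
  comp2 <- sample_composition(c(A = 10), n_tumor_cells = 1,
                              cell_line_of_cells = "A")
  expect_equal(unname(comp2$pg_by_cellline["A"]), 30)
  expect_error(sample_composition(c(A = -1)), "amounts")
  expect_error(sample_composition(ng_wbc = -0.5), "amounts")
})

test_that("spot simulation is lognormal, seed-reproducible and exact at zero noise", {
  g0 <- gene_signal_model("g", baseline = 100, noise_sigma = 0)
  expect_equal(simulate_spots(g0, sample_composition(), n_spots = 5, seed = 1),
               rep(expected_signal(g0, sample_composition()), 5))
  g <- gene_signal_model("g", baseline = 100, noise_sigma = 0.25)
  a <- simulate_spots(g, sample_composition(), n_spots = 3, seed = 42)
  b <- simulate_spots(g, sample_composition(), n_spots = 3, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_spots(g, sample_composition(),
                                           n_spots = 3, seed = 43)))
})

test_that("replicate two-fold agreement matches the closed-form lognormal probability", {
  # ratio of two independent lognormal spots: log-ratio ~ N(0, 2 sigma^2),
  # P(within 2-fold) = 2 Phi(ln 2 / (sqrt(2) sigma)) - 1
  sigma <- 0.25
  p_closed <- 2 * stats::pnorm(log(2) / (sqrt(2) * sigma)) - 1
  expect_equal(p_closed, 0.9500645237714558, tolerance = 1e-12)
  g <- gene_signal_model("g", baseline = 100, noise_sigma = sigma)
  n <- 2e4
  spots <- simulate_spots(g, sample_composition(), n_spots = 2 * n, seed = 7)
  ratio <- spots[seq_len(n) * 2 - 1] / spots[seq_len(n) * 2]
  p_hat <- mean(ratio < 2 & ratio > 0.5)
  expect_equal(p_hat, p_closed, tolerance = 4 * sqrt(p_closed * (1 - p_closed) / n))
})

test_that("titration designs have the published layout", {
  p <- tiny_panel()
  d <- simulate_titration(p, "A", seed = 1)
  # five amounts x three replicates plus nine no-template controls
  expect_equal(nrow(d$samples), 15 + 9)
  expect_equal(sum(d$samples$group == "ntc"), 9)
  # triplicate spots for every probe of every sample
  expect_equal(nrow(d$spots), 24 * length(panel_probes(p)) * 3)
  expect_error(simulate_titration(p, "NOPE"), "unknown cell line")
  # WBC background adds WBC-only replicates
  d2 <- simulate_titration(p, "A", wbc_ng = 1, seed = 1)
  expect_equal(sum(d2$samples$group == "wbc_only"), 3)
  # a 0 pg sample is distributed like an NTC (baseline only)
  p0 <- tiny_panel(noise_sigma = 0)
  d0 <- simulate_titration(p0, "A", amounts_pg = c(0, 20, 40), seed = 1)
  em0 <- summarize_spots(d0)
  zero_rows <- d0$samples$sample_id[d0$samples$pg == 0 &
                                      d0$samples$group == "titration"]
  ntc_rows <- d0$samples$sample_id[d0$samples$group == "ntc"]
  expect_equal(unname(em0$values[zero_rows[1], "HIGH"]),
               unname(em0$values[ntc_rows[1], "HIGH"]))
})

test_that("simulation is deterministic and stable under design subsetting", {
  p <- tiny_panel()
  d1 <- simulate_titration(p, "A", seed = 5)
  d2 <- simulate_titration(p, "A", seed = 5)
  expect_identical(d1$spots, d2$spots)
  # per-sample child streams: dropping replicates does not reshuffle others
  d3 <- simulate_titration(p, "A", n_replicates = 2, seed = 5)
  shared <- intersect(d1$samples$sample_id, d3$samples$sample_id)
  s1 <- d1$spots[d1$spots$sample_id %in% shared, ]
  s3 <- d3$spots[d3$spots$sample_id %in% shared, ]
  expect_equal(s1$intensity, s3$intensity)
})

test_that("cohort simulation honors its latent-structure contracts", {
  p <- cohort_panel(n_exclusive = 4, n_wbc = 6)
  # all-CTC-negative: MBC differs from HV only in WBC load
  spec0 <- cohort_spec(n_hv = 4, n_mbc = 4, p_ctc_negative_mbc = 1)
  sim0 <- simulate_cohort(p, spec0, seed = 2)
  expect_true(all(sim0$truth$n_ctc == 0))
  expect_true(all(!sim0$truth$expressed))
  # zero marker positivity: tumor cells express nothing
  spec1 <- cohort_spec(n_hv = 4, n_mbc = 4, p_ctc_negative_mbc = 0,
                       marker_positivity = 0)
  sim1 <- simulate_cohort(p, spec1, seed = 2)
  mbc_ids <- grep("^MBC", names(sim1$truth$n_ctc), value = TRUE)
  expect_true(all(sim1$truth$n_ctc[mbc_ids] > 0))
  expect_true(all(!sim1$truth$expressed))
  # determinism
  expect_identical(simulate_cohort(p, spec1, seed = 9)$spots,
                   simulate_cohort(p, spec1, seed = 9)$spots)
})

test_that("simulated PTPRC fold difference recovers the generative WBC-load factor", {
  p <- cohort_panel(n_exclusive = 2, n_wbc = 2)
  spec <- cohort_spec(n_hv = 10, n_mbc = 10)
  folds <- vapply(1:20, function(s) {
    sim <- simulate_cohort(p, spec, n_spots = 1, seed = s)
    em <- net_signal(summarize_spots(sim))
    grp <- em$samples$group
    mean(em$values[grp == "MBC", "PTPRC"]) /
      mean(em$values[grp == "HV", "PTPRC"])
  }, numeric(1))
  expect_equal(mean(folds), spec$wbc_fold_mbc, tolerance = 0.25)
})

test_that("mean spot intensity is linear in pg in the unsaturated regime", {
  g <- gene_signal_model("g", baseline = 0.001, cellline_rates = c(A = 5),
                         saturation_ceiling = 1e5, noise_sigma = 0.25)
  # lognormal correction: E[exp(eps)] = exp(sigma^2/2)
  amounts <- c(20, 40, 60, 80, 100)
  means <- vapply(amounts, function(a) {
    mean(simulate_spots(g, sample_composition(c(A = a)), n_spots = 3000,
                        seed = a))
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(means ~ amounts))[2])
  expect_equal(slope, 5 * exp(0.25^2 / 2), tolerance = 0.05)
})
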