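test_that("the WBC-background screen needs responsiveness and significance", {
  p <- tiny_panel()
  d <- simulate_titration(p, "A", wbc_ng = 1, seed = 12)
  em <- net_signal(summarize_spots(d))
  scr <- wbc_background_screen(em, genes = names(p$genes))
  scr <- scr[match(names(p$genes), scr$gene_id), ]
  # planted responsive gene (rate 5/pg, no WBC expression) is selected
  expect_true(scr$selected[scr$gene_id == "HIGH"])
  # a flat gene is excluded regardless of its t-test (conjunction)
  expect_false(scr$selected[scr$gene_id == "WBCY"])
  expect_false(scr$selected[scr$gene_id == "PTPRC"])
  # too few WBC-only replicates is an error
  em2 <- subset_matrix(em, samples = setdiff(
    em$samples$sample_id, c("WBC_only_r1", "WBC_only_r2")))
  expect_error(wbc_background_screen(em2, genes = names(p$genes)),
               "WBC-only")
})

test_that("null genes reach t-test significance at about the alpha rate", {
  # many independent background-only genes in one WBC-background design:
  # the significance component of the screen should fire at ~alpha
  ctl <- ctcpanel:::.default_control_scheme()
  genes <- lapply(sprintf("N%03d", 1:300), function(id)
    gene_signal_model(id, baseline = 20, cellline_rates = c(A = 0),
                      wbc_rate = 100, noise_sigma = 0.25))
  p <- panel_model(c(genes, list(gene_signal_model(
    "PTPRC", 20, c(A = 0), wbc_rate = 1000, noise_sigma = 0.25))),
    control_ids = ctl$ids, control_levels = ctl$levels)
  d <- simulate_titration(p, "A", amounts_pg = c(20, 40, 60), wbc_ng = 1,
                          seed = 77)
  em <- net_signal(summarize_spots(d))
  scr <- wbc_background_screen(em, genes = sprintf("N%03d", 1:300))
  rate <- mean(scr$significant)
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
  # and essentially none survive the conjunction with responsiveness
  expect_lte(sum(scr$selected), 3)
})

test_that("the spike screen applies the fold and p-value rules per group", {
  set.seed(4)
  un <- matrix(10 + rnorm(12, sd = 0.3), 4, 3,
               dimnames = list(paste0("u", 1:4), c("big", "small", "zero")))
  sp <- cbind(big = 30 + rnorm(4, sd = 0.3),
              small = 15 + rnorm(4, sd = 0.3),
              zero = 8 + rnorm(4, sd = 0.3))
  rownames(sp) <- paste0("s", 1:4)
  un[, "zero"] <- rnorm(4, 0, 0.2)     # unspiked mean ~0: floored ratio
  vals <- rbind(un, sp)
  em <- make_em(vals, rep(c("unspiked", "spiked_cells_X"), each = 4))
  scr <- spike_screen(em, genes = colnames(vals))
  expect_true(scr$selected[scr$gene_id == "big"])       # fold 3, tiny p
  expect_false(scr$selected[scr$gene_id == "small"])    # fold 1.5 < 2
  expect_true(scr$selected[scr$gene_id == "zero"])      # ratio vs floor 1
  expect_gt(scr$fold_change_best[scr$gene_id == "zero"], 2)
  expect_error(spike_screen(make_em(sp, rep("spiked_cells_X", 4)),
                            genes = "big"), "unspiked")
  # banded mode keeps only 0.05 < p <= 0.1
  scr_band <- spike_screen(em, genes = colnames(vals), p_band = TRUE)
  expect_false(scr_band$selected[scr_band$gene_id == "big"])
})

test_that("PTPRC regressions recover proportional genes and flag sparse ones", {
  set.seed(8)
  ptprc <- 10^runif(12, 2, 4)
  vals <- cbind(PTPRC = ptprc,
                prop = 0.5 * ptprc,              # exactly proportional
                sparse = c(rep(0, 10), 50, 60))  # 2 samples above threshold
  rownames(vals) <- paste0("s", 1:12)
  em <- make_em(vals, rep(c("HV", "MBC"), 6))
  reg <- ptprc_regression(em, "prop")
  expect_true(reg$defined)
  expect_equal(reg$slope, 1, tolerance = 1e-9)
  expect_equal(reg$r, 1, tolerance = 1e-9)
  expect_equal(reg$n_above, 12)
  sparse <- ptprc_regression(em, "sparse")
  expect_false(sparse$defined)
  expect_true(is.na(sparse$slope))
  expect_equal(sparse$n_above, 2)
  expect_equal(sum(unlist(sparse$n_above_by_group)), 2)
  expect_error(ptprc_regression(em, "prop", ptprc_id = "CD45"), "missing")
})

test_that("raising the threshold never increases above-threshold counts", {
  set.seed(21)
  vals <- matrix(rlnorm(60, 2, 1.5), 10, 6,
                 dimnames = list(paste0("s", 1:10), paste0("g", 1:6)))
  vals <- cbind(vals, PTPRC = rlnorm(10, 5, 1))
  em <- make_em(vals, rep(c("HV", "MBC"), 5))
  for (g in paste0("g", 1:6)) {
    counts <- vapply(c(1, 5, 10, 50, 200), function(thr)
      ptprc_regression(em, g, threshold_units = thr)$n_above, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("gene ranking is a deterministic total order with undefined first", {
  regs <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     slope = c(0.5, NA, -0.2, 1.1, NA),
                     r = c(0.9, NA, -0.3, 0.95, NA),
                     defined = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                     n_above = c(10, 2, 8, 12, 1),
                     stringsAsFactors = FALSE)
  rk <- rank_genes(regs)
  # undefined first (by n_above then id), then ascending slope
  expect_equal(rk$gene_id, c("e", "b", "c", "a", "d"))
  expect_equal(rk$rank, 1:5)
  # permuted input gives the identical order
  rk2 <- rank_genes(regs[c(4, 2, 5, 1, 3), ])
  expect_equal(rk2$gene_id, rk$gene_id)
  # undefined ties on n_above break by gene id
  regs$n_above[regs$gene_id == "e"] <- 2
  expect_equal(rank_genes(regs)$gene_id[1:2], c("b", "e"))
})

test_that("exclusive markers require silence in HV and signal in MBC", {
  vals <- matrix(0, 30, 3, dimnames = list(
    c(sprintf("HV_%02d", 1:15), sprintf("MBC_%02d", 1:15)),
    c("good", "leaky", "silent")))
  vals[c("MBC_01", "MBC_05", "MBC_09", "MBC_12"), "good"] <- c(50, 200, 15, 80)
  vals["HV_03", "leaky"] <- 12
  vals[c("MBC_02", "MBC_03"), "leaky"] <- c(40, 90)
  em <- make_em(vals, rep(c("HV", "MBC"), each = 15))
  ex <- exclusive_markers(em, colnames(vals))
  expect_equal(ex$selected, c(TRUE, FALSE, FALSE))
  expect_equal(ex$n_above_mbc, c(4, 2, 0))
  expect_equal(ex$n_above_hv, c(0, 1, 0))
  # one tolerated HV admits the leaky gene
  ex1 <- exclusive_markers(em, colnames(vals), hv_tolerance = 1)
  expect_true(ex1$selected[2])
  expect_error(exclusive_markers(make_em(vals, rep("HV", 30)),
                                 colnames(vals)), "both groups")
})

test_that("exclusive selection avoids purely WBC-driven genes on simulated cohorts", {
  p <- cohort_panel()
  truth <- attr(p, "truth")
  wbc_genes <- truth$gene_id[truth$source == "wbc"]
  markers <- truth$gene_id[truth$source == "tumor"]
  for (s in 1:5) {
    sim <- simulate_cohort(p, cohort_spec(), seed = 100 + s)
    em <- net_signal(summarize_spots(sim))
    ex <- exclusive_markers(em, c(markers, wbc_genes))
    false_hits <- sum(ex$selected & ex$gene_id %in% wbc_genes)
    expect_lte(false_hits, 1)
  }
})

test_that("the marker report merges tiers by gene id", {
  rep_df <- marker_report(
    c("a", "b"),
    clean = data.frame(gene_id = c("b", "a"), informative = c(TRUE, FALSE)),
    exclusive = data.frame(gene_id = "a", n_above_hv = 0, n_above_mbc = 3,
                           selected = TRUE))
  expect_equal(rep_df$informative_clean, c(FALSE, TRUE))
  expect_equal(rep_df$exclusive_marker, c(TRUE, NA))
  expect_equal(attr(rep_df, "correction"), "none")
})
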