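#' Expected probe intensity for a sample composition
#'
#' The linear predictor is
#' `mu = baseline + sum_c rate_c * pg_c + wbc_rate * ng_wbc`; detector
#' saturation is applied as the smooth map `S * (1 - exp(-mu / S))` with
#' `S = saturation_ceiling` (monotone, bounded by `S`, and within 1\% of
#' `mu` when `mu <= 0.01 * S`). A hard clip at `S` is available instead via
#' `saturation = "clip"`.
#'
#' @param gene A [gene_signal_model()].
#' @param comp A [sample_composition()].
#' @param saturation `"smooth"` (default) or `"clip"`.
#' @return Expected intensity in signal units.
#' @export
expected_signal <- function(gene, comp, saturation = c("smooth", "clip")) {
  saturation <- match.arg(saturation)
  stopifnot(inherits(gene, "gene_signal_model"),
            inherits(comp, "sample_composition"))
  .assert(all(comp$pg_by_cellline >= 0) && comp$ng_wbc >= 0,
          "negative amounts are not allowed")
  mu <- gene$baseline + gene$wbc_rate * comp$ng_wbc
  if (length(comp$pg_by_cellline)) {
    known <- names(comp$pg_by_cellline) %in% names(gene$cellline_rates)
    mu <- mu + sum(gene$cellline_rates[names(comp$pg_by_cellline)[known]] *
                     comp$pg_by_cellline[known])
  }
  s <- gene$saturation_ceiling
  if (saturation == "smooth") s * (1 - exp(-mu / s)) else min(mu, s)
}

#' Simulate replicate spot intensities for one probe in one sample
#'
#' Each spot is `expected_signal(gene, comp) * exp(eps)` with independent
#' `eps ~ Normal(0, noise_sigma^2)`; probes are printed in triplicate on the
#' array, hence the default `n_spots = 3`.
#'
#' @inheritParams expected_signal
#' @param n_spots Number of replicate spots (>= 1).
#' @param seed Optional seed; identical seeds yield identical spots. When
#'   `NULL` the current RNG stream is used.
#' @return Numeric vector of `n_spots` intensities.
#' @export
simulate_spots <- function(gene, comp, n_spots = 3, seed = NULL,
                           saturation = "smooth") {
  .assert(.is_count(n_spots), "n_spots must be >= 1")
  mu <- expected_signal(gene, comp, saturation)
  draw <- function() mu * exp(stats::rnorm(n_spots, 0, gene$noise_sigma))
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# Simulate all probes of a panel for one sample, returning a spot-level
# data.frame.  Control probes have fixed expected intensities.  Each sample
# gets its own child RNG stream derived from (seed, sample_id), so removing
# or reordering samples in a design does not reshuffle the others.
#' @noRd
.simulate_sample <- function(panel, sample_id, comp, n_spots, seed,
                             saturation = "smooth") {
  .with_seed(.hash32(sample_id, seed), {
    gene_ids <- names(panel$genes)
    mu <- vapply(panel$genes, expected_signal, numeric(1),
                 comp = comp, saturation = saturation)
    ctl_ids <- unlist(panel$control_ids, use.names = FALSE)
    mu <- c(mu, panel$control_levels[ctl_ids])
    probe_ids <- c(gene_ids, ctl_ids)
    sig <- c(vapply(panel$genes, function(g) g$noise_sigma, numeric(1)),
             rep(panel$noise_sigma, length(ctl_ids)))
    eps <- stats::rnorm(length(mu) * n_spots)
    data.frame(
      sample_id = sample_id,
      probe_id = rep(probe_ids, each = n_spots),
      spot_index = rep(seq_len(n_spots), times = length(mu)),
      intensity = rep(mu, each = n_spots) *
        exp(rep(sig, each = n_spots) * eps),
      evaluable = TRUE,
      stringsAsFactors = FALSE)
  })
}

#' @noRd
.bind_spot_dataset <- function(spots_list, samples, truth = NULL) {
  out <- list(spots = do.call(rbind, spots_list), samples = samples,
              truth = truth)
  rownames(out$spots) <- NULL
  class(out) <- "spot_dataset"
  out
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d samples, %d probes, %d spot records\n",
              nrow(x$samples), length(unique(x$spots$probe_id)),
              nrow(x$spots)))
  invisible(x)
}

#' Simulate a titration experiment
#'
#' One sample per RNA amount and replicate (triplicate spots per probe),
#' plus nine no-template-control (NTC) samples, optionally in a constant
#' background of WBC RNA. With `wbc_ng > 0`, `n_replicates` WBC-only samples
#' (background without tumor RNA) are added; NTC samples contain neither.
#'
#' @param panel A [panel_model()].
#' @param cellline Cell line whose rates drive the response; must be present
#'   in the panel's rate vectors.
#' @param amounts_pg RNA amounts in pg (nonempty). Amounts of 0 behave as
#'   NTCs (plus any WBC background).
#' @param n_replicates Replicates per amount.
#' @param wbc_ng WBC RNA background per titration sample (ng).
#' @param n_ntc Number of no-template-control samples.
#' @param n_spots Spots per probe.
#' @param seed Parent seed for the per-sample RNG streams.
#' @return A `spot_dataset`: `spots` (sample_id, probe_id, spot_index,
#'   intensity, evaluable), `samples` (sample sheet), `truth` (expected
#'   intensities and design parameters).
#' @export
simulate_titration <- function(panel, cellline,
                               amounts_pg = c(20, 40, 60, 80, 100),
                               n_replicates = 3, wbc_ng = 0, n_ntc = 9,
                               n_spots = 3, seed = 1) {
  stopifnot(inherits(panel, "panel_model"))
  .assert(length(amounts_pg) > 0, "amounts_pg must be nonempty")
  known <- unique(unlist(lapply(panel$genes,
                                function(g) names(g$cellline_rates))))
  .assert(cellline %in% known,
          sprintf("unknown cell line '%s'", cellline))
  sheet <- expand.grid(replicate = seq_len(n_replicates), pg = amounts_pg,
                       KEEP.OUT.ATTRS = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("T_%s_%03gpg_r%d", cellline, sheet$pg, sheet$replicate),
    group = "titration", cellline = cellline, pg = sheet$pg,
    ng_wbc = wbc_ng, replicate = sheet$replicate, stringsAsFactors = FALSE)
  if (wbc_ng > 0) {
    sheet <- rbind(sheet, data.frame(
      sample_id = sprintf("WBC_only_r%d", seq_len(n_replicates)),
      group = "wbc_only", cellline = NA_character_, pg = 0, ng_wbc = wbc_ng,
      replicate = seq_len(n_replicates), stringsAsFactors = FALSE))
  }
  sheet <- rbind(sheet, data.frame(
    sample_id = sprintf("NTC_%d", seq_len(n_ntc)),
    group = "ntc", cellline = NA_character_, pg = 0, ng_wbc = 0,
    replicate = seq_len(n_ntc), stringsAsFactors = FALSE))
  spots <- lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    comp <- sample_composition(
      pg_by_cellline = if (row$pg > 0)
        stats::setNames(row$pg, cellline) else numeric(0),
      ng_wbc = row$ng_wbc)
    .simulate_sample(panel, row$sample_id, comp, n_spots, seed)
  })
  truth <- list(design = "titration", cellline = cellline,
                amounts_pg = amounts_pg, wbc_ng = wbc_ng, seed = seed,
                rates = vapply(panel$genes, .rate_of, numeric(1),
                               cellline = cellline),
                ceilings = vapply(panel$genes, function(g)
                  g$saturation_ceiling, numeric(1)))
  .bind_spot_dataset(spots, sheet, truth)
}

#' Simulate spiked microfluidic-capture harvests
#'
#' Emulates harvests of healthy-donor blood from a size/deformability-based
#' capture device: every harvest carries a lognormally varying WBC RNA load;
#' harvests are either unspiked or spiked with a known number of cultured
#' tumor cells or a known mass of tumor cell-line RNA.
#'
#' @param panel A [panel_model()].
#' @param celllines Cell lines used for the spikes.
#' @param n_unspiked Number of unspiked harvests.
#' @param n_per_spike Harvests per (cell line x spike type).
#' @param cells_per_spike Tumor cells per cell-spiked harvest.
#' @param rna_pg_per_spike pg RNA per RNA-spiked harvest.
#' @param wbc_load_median Median WBC RNA load (ng).
#' @param wbc_sdlog Lognormal sdlog of the WBC load.
#' @param pg_per_cell RNA per tumor cell (pg).
#' @param n_ntc,n_spots,seed As in [simulate_titration()].
#' @return A `spot_dataset`; `samples$group` is `"unspiked"`,
#'   `"spiked_cells_<cellline>"`, `"spiked_rna_<cellline>"` or `"ntc"`.
#' @export
simulate_harvest <- function(panel, celllines, n_unspiked = 3,
                             n_per_spike = 3, cells_per_spike = 1,
                             rna_pg_per_spike = 50, wbc_load_median = 1,
                             wbc_sdlog = 0.6, pg_per_cell = 20,
                             n_ntc = 9, n_spots = 3, seed = 1) {
  stopifnot(inherits(panel, "panel_model"))
  rows <- list()
  add <- function(group, cellline, pg, n) {
    for (r in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sprintf("H_%s_r%d", group, r), group = group,
        cellline = cellline, pg = pg, ng_wbc = NA_real_, replicate = r,
        stringsAsFactors = FALSE)
    }
  }
  add("unspiked", NA_character_, 0, n_unspiked)
  for (cl in celllines) {
    add(paste0("spiked_cells_", cl), cl, cells_per_spike * pg_per_cell,
        n_per_spike)
    add(paste0("spiked_rna_", cl), cl, rna_pg_per_spike, n_per_spike)
  }
  sheet <- do.call(rbind, rows)
  # WBC loads drawn on dedicated child streams so each harvest is stable
  # under design subsetting.
  sheet$ng_wbc <- vapply(sheet$sample_id, function(id)
    .with_seed(.hash32(paste0("wbc:", id), seed),
               stats::rlnorm(1, log(wbc_load_median), wbc_sdlog)),
    numeric(1), USE.NAMES = FALSE)
  sheet <- rbind(sheet, data.frame(
    sample_id = sprintf("NTC_%d", seq_len(n_ntc)), group = "ntc",
    cellline = NA_character_, pg = 0, ng_wbc = 0,
    replicate = seq_len(n_ntc), stringsAsFactors = FALSE))
  spots <- lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    comp <- sample_composition(
      pg_by_cellline = if (!is.na(row$cellline) && row$pg > 0)
        stats::setNames(row$pg, row$cellline) else numeric(0),
      ng_wbc = row$ng_wbc)
    .simulate_sample(panel, row$sample_id, comp, n_spots, seed)
  })
  truth <- list(design = "harvest", celllines = celllines,
                wbc_load_median = wbc_load_median, wbc_sdlog = wbc_sdlog,
                seed = seed, wbc_loads = stats::setNames(sheet$ng_wbc,
                                                         sheet$sample_id))
  .bind_spot_dataset(spots, sheet, truth)
}

#' Simulate an HV/MBC cohort
#'
#' Healthy-volunteer (HV) harvests carry a lognormal WBC RNA load around
#' `wbc_load_median_hv` and no tumor RNA. MBC harvests have their WBC load
#' scaled by `wbc_fold_mbc`; with probability `1 - p_ctc_negative_mbc` an
#' MBC sample additionally contains CTCs (count drawn from the tumor-burden
#' distribution) whose RNA drives each marker gene independently with
#' probability `marker_positivity`, reproducing the heterogeneous marker
#' expression seen across patients.
#'
#' @param panel A [panel_model()] whose genes carry a rate for
#'   `spec$tumor_cellline` (see [cohort_panel()]).
#' @param spec A [cohort_spec()].
#' @param n_ntc,n_spots,seed As in [simulate_titration()].
#' @return A `spot_dataset`; `truth` records per-sample WBC load, CTC count
#'   and the expressed-marker indicator matrix.
#' @export
simulate_cohort <- function(panel, spec = cohort_spec(), n_ntc = 9,
                            n_spots = 3, seed = 1) {
  stopifnot(inherits(panel, "panel_model"), inherits(spec, "cohort_spec"))
  marker_genes <- names(panel$genes)[vapply(panel$genes, function(g)
    .rate_of(g, spec$tumor_cellline) > 0, logical(1))]
  pos <- spec$marker_positivity
  if (length(pos) == 1L && is.null(names(pos)))
    pos <- stats::setNames(rep(pos, length(marker_genes)), marker_genes)
  ids <- c(sprintf("HV_%02d", seq_len(spec$n_hv)),
           sprintf("MBC_%02d", seq_len(spec$n_mbc)))
  group <- rep(c("HV", "MBC"), c(spec$n_hv, spec$n_mbc))
  expressed <- matrix(FALSE, nrow = length(ids), ncol = length(marker_genes),
                      dimnames = list(ids, marker_genes))
  wbc_ng <- numeric(length(ids))
  n_ctc <- integer(length(ids))
  sheet_rows <- vector("list", length(ids))
  spots <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    lat <- .with_seed(.hash32(paste0("latent:", id), seed), {
      med <- spec$wbc_load_median_hv *
        if (group[i] == "MBC") spec$wbc_fold_mbc else 1
      w <- stats::rlnorm(1, log(med), spec$wbc_sdlog)
      n <- 0L
      expr <- rep(FALSE, length(marker_genes))
      if (group[i] == "MBC" &&
          stats::runif(1) >= spec$p_ctc_negative_mbc) {
        n <- spec$tumor_burden$min_cells +
          stats::rpois(1, spec$tumor_burden$lambda)
        expr <- stats::runif(length(marker_genes)) < pos[marker_genes]
      }
      list(w = w, n = n, expr = expr)
    })
    wbc_ng[i] <- lat$w
    n_ctc[i] <- lat$n
    expressed[i, ] <- lat$expr
    pg <- lat$n * spec$pg_per_cell
    # Markers the patient's CTCs do not express contribute nothing: the
    # composition carries tumor RNA only for the expressed markers, encoded
    # per gene below via a masked panel evaluation.
    comp <- sample_composition(
      pg_by_cellline = if (pg > 0)
        stats::setNames(pg, spec$tumor_cellline) else numeric(0),
      ng_wbc = lat$w)
    masked <- panel
    if (pg > 0) {
      off <- marker_genes[!lat$expr]
      for (g in off)
        masked$genes[[g]]$cellline_rates[spec$tumor_cellline] <- 0
    }
    spots[[i]] <- .simulate_sample(masked, id, comp, n_spots, seed)
    sheet_rows[[i]] <- data.frame(
      sample_id = id, group = group[i], cellline = NA_character_,
      pg = pg, ng_wbc = lat$w, replicate = 1L, stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheet_rows)
  sheet <- rbind(sheet, data.frame(
    sample_id = sprintf("NTC_%d", seq_len(n_ntc)), group = "ntc",
    cellline = NA_character_, pg = 0, ng_wbc = 0,
    replicate = seq_len(n_ntc), stringsAsFactors = FALSE))
  for (j in seq_len(n_ntc)) {
    id <- sprintf("NTC_%d", j)
    spots[[length(ids) + j]] <- .simulate_sample(
      panel, id, sample_composition(), n_spots, seed)
  }
  truth <- list(design = "cohort", seed = seed, spec = spec,
                marker_genes = marker_genes,
                wbc_ng = stats::setNames(wbc_ng, ids),
                n_ctc = stats::setNames(n_ctc, ids),
                expressed = expressed)
  .bind_spot_dataset(spots, sheet, truth)
}
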