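#' Per-gene signal model for the array simulator
#'
#' Describes how one probe responds to input RNA: a baseline intensity seen
#' with no template, a linear rate per pg of total RNA for each tumor cell
#' line, a linear rate per ng of white-blood-cell (WBC) total RNA, a detector
#' saturation ceiling, and the standard deviation of the multiplicative
#' (natural-log) replicate noise.
#'
#' @param gene_id Probe/gene identifier.
#' @param baseline Intensity observed with no template, in signal units.
#' @param cellline_rates Named numeric vector, signal units per pg of total
#'   RNA for each cell line.
#' @param wbc_rate Signal units per ng of WBC total RNA.
#' @param saturation_ceiling Detector ceiling in signal units; must exceed
#'   the baseline.
#' @param noise_sigma Standard deviation of the lognormal spot noise on the
#'   natural-log scale. The default 0.25 places about 95\% of replicate spot
#'   pairs within two-fold of each other.
#' @return An object of class `gene_signal_model`.
#' @export
gene_signal_model <- function(gene_id, baseline = 20,
                              cellline_rates = numeric(0), wbc_rate = 0,
                              saturation_ceiling = 1e5, noise_sigma = 0.25) {
  .assert(is.character(gene_id) && length(gene_id) == 1L, "gene_id must be a string")
  cellline_rates <- unlist(cellline_rates)
  if (length(cellline_rates))
    .assert(!is.null(names(cellline_rates)) && all(nzchar(names(cellline_rates))),
            "cellline_rates must be named by cell line")
  .assert(all(cellline_rates >= 0) && wbc_rate >= 0, "rates must be >= 0")
  .assert(baseline >= 0, "baseline must be >= 0")
  .assert(saturation_ceiling > baseline, "saturation_ceiling must exceed baseline")
  .assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  structure(list(gene_id = gene_id, baseline = baseline,
                 cellline_rates = cellline_rates, wbc_rate = wbc_rate,
                 saturation_ceiling = saturation_ceiling,
                 noise_sigma = noise_sigma),
            class = "gene_signal_model")
}

#' Assay panel model
#'
#' A collection of [gene_signal_model()] objects plus the identity of the
#' WBC-marker probe (PTPRC/CD45) and the hybridization/amplification control
#' probes with their fixed expected intensities. The PTPRC probe must respond
#' to WBC RNA and (essentially) not to tumor cell-line RNA.
#'
#' @param genes List of `gene_signal_model` objects (unique ids).
#' @param ptprc_id Identifier of the WBC-marker gene; must be present in
#'   `genes`.
#' @param control_ids List with character elements `synthetic` (amplification
#'   positive controls), `positive` (hybridization positive controls) and
#'   `negative`.
#' @param control_levels Named numeric vector of expected intensities for
#'   every control probe (negatives at the baseline level).
#' @param noise_sigma Spot noise applied to control probes.
#' @return An object of class `panel_model`.
#' @export
panel_model <- function(genes, ptprc_id = "PTPRC",
                        control_ids = list(synthetic = character(0),
                                           positive = character(0),
                                           negative = character(0)),
                        control_levels = numeric(0),
                        noise_sigma = 0.25) {
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  .assert(!anyDuplicated(ids), "gene ids must be unique")
  names(genes) <- ids
  .assert(ptprc_id %in% ids, "ptprc_id must be among the panel genes")
  ptprc <- genes[[ptprc_id]]
  .assert(ptprc$wbc_rate > 0, "the PTPRC probe must respond to WBC RNA")
  .assert(length(ptprc$cellline_rates) == 0 || all(ptprc$cellline_rates < 1e-6),
          "the PTPRC probe must not respond to tumor cell-line RNA")
  ctl <- unlist(control_ids, use.names = FALSE)
  .assert(!anyDuplicated(c(ids, ctl)), "control ids must not clash with gene ids")
  .assert(all(ctl %in% names(control_levels)),
          "every control probe needs an expected intensity in control_levels")
  structure(list(genes = genes, ptprc_id = ptprc_id,
                 control_ids = control_ids, control_levels = control_levels,
                 noise_sigma = noise_sigma),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d gene probes (WBC marker %s), %d controls\n",
              length(x$genes), x$ptprc_id,
              length(unlist(x$control_ids))))
  invisible(x)
}

#' All probe ids of a panel (genes then controls)
#' @param panel A [panel_model()].
#' @export
panel_probes <- function(panel) {
  c(names(panel$genes), unlist(panel$control_ids, use.names = FALSE))
}

#' Sample composition
#'
#' The RNA content of one assayed sample: pg of total RNA per tumor cell
#' line, ng of WBC total RNA, and optionally a tumor-cell count which is
#' converted at 20 pg of total RNA per cell (the approximate content of a
#' single cell).
#'
#' @param pg_by_cellline Named numeric vector of pg total RNA per cell line.
#' @param ng_wbc ng of WBC total RNA.
#' @param n_tumor_cells Optional cell count; each cell contributes
#'   `pg_per_cell` pg of the cell line named in `cell_line_of_cells`.
#' @param cell_line_of_cells Cell line the counted cells belong to.
#' @param pg_per_cell RNA content per cell (pg); default 20.
#' @return An object of class `sample_composition`.
#' @export
sample_composition <- function(pg_by_cellline = numeric(0), ng_wbc = 0,
                               n_tumor_cells = NULL, cell_line_of_cells = NULL,
                               pg_per_cell = 20) {
  pg_by_cellline <- unlist(pg_by_cellline)
  .assert(all(pg_by_cellline >= 0) && ng_wbc >= 0, "amounts must be >= 0")
  if (!is.null(n_tumor_cells)) {
    .assert(n_tumor_cells >= 0, "amounts must be >= 0")
    .assert(!is.null(cell_line_of_cells),
            "cell_line_of_cells required with n_tumor_cells")
    add <- n_tumor_cells * pg_per_cell
    if (cell_line_of_cells %in% names(pg_by_cellline)) {
      pg_by_cellline[[cell_line_of_cells]] <-
        pg_by_cellline[[cell_line_of_cells]] + add
    } else {
      pg_by_cellline <- c(pg_by_cellline, stats::setNames(add, cell_line_of_cells))
    }
  }
  structure(list(pg_by_cellline = pg_by_cellline, ng_wbc = ng_wbc,
                 n_tumor_cells = n_tumor_cells),
            class = "sample_composition")
}

#' Cohort specification for the clinical-style simulation
#'
#' Defaults encode the study conditions of a 15 healthy-volunteer (HV) vs 15
#' metastatic-breast-cancer (MBC) cohort: 35\% of MBC patients carry no
#' detectable CTCs, MBC harvests carry 2.3-fold more WBC RNA than HV
#' harvests, and each exclusive marker is expressed by a given patient's
#' CTCs with probability 0.25 (CTC marker expression is heterogeneous).
#'
#' @param n_hv,n_mbc Group sizes.
#' @param p_ctc_negative_mbc Probability an MBC patient has no CTCs.
#' @param marker_positivity Probability a CTC-positive patient's tumor cells
#'   express a given marker; scalar or named per marker gene.
#' @param wbc_load_median_hv Median WBC RNA load of HV harvests (ng).
#' @param wbc_fold_mbc Multiplicative WBC-load factor for MBC harvests.
#' @param wbc_sdlog Lognormal sdlog of the WBC load across harvests.
#' @param tumor_burden `list(min_cells=, lambda=)`: CTC count per positive
#'   patient is `min_cells + Poisson(lambda)`.
#' @param tumor_cellline Name of the cell-line rate entry used for patient
#'   tumor cells.
#' @param pg_per_cell RNA content per CTC (pg).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hv = 15, n_mbc = 15, p_ctc_negative_mbc = 0.35,
                        marker_positivity = 0.25, wbc_load_median_hv = 1,
                        wbc_fold_mbc = 2.3, wbc_sdlog = 0.6,
                        tumor_burden = list(min_cells = 1, lambda = 2),
                        tumor_cellline = "tumor", pg_per_cell = 20) {
  .assert(.is_count(n_hv) && .is_count(n_mbc), "group sizes must be counts > 0")
  .assert(all(marker_positivity >= 0 & marker_positivity <= 1) &&
            p_ctc_negative_mbc >= 0 && p_ctc_negative_mbc <= 1,
          "probabilities must be in [0, 1]")
  .assert(wbc_fold_mbc > 0, "wbc_fold_mbc must be > 0")
  structure(list(n_hv = n_hv, n_mbc = n_mbc,
                 p_ctc_negative_mbc = p_ctc_negative_mbc,
                 marker_positivity = marker_positivity,
                 wbc_load_median_hv = wbc_load_median_hv,
                 wbc_fold_mbc = wbc_fold_mbc, wbc_sdlog = wbc_sdlog,
                 tumor_burden = tumor_burden, tumor_cellline = tumor_cellline,
                 pg_per_cell = pg_per_cell),
            class = "cohort_spec")
}

.default_control_scheme <- function() {
  list(ids = list(synthetic = paste0("SYN", 1:5),
                  positive  = paste0("ATH", 1:6),
                  negative  = paste0("NEG", 1:3)),
       levels = c(stats::setNames(rep(5000, 5), paste0("SYN", 1:5)),
                  stats::setNames(rep(8000, 6), paste0("ATH", 1:6)),
                  stats::setNames(rep(20, 3),  paste0("NEG", 1:3))))
}

#' Default 72-probe titration panel
#'
#' Builds a panel with the structure of the breast-cancer assay used for the
#' titration experiments: 71 tumor-marker probes plus the WBC marker PTPRC,
#' five synthetic-mRNA amplification controls, six Arabidopsis hybridization
#' positive controls and three negative controls. Of the 72 gene probes, 53
#' are planted "informative" (per-pg response above 1 signal unit/pg for at
#' least one cell line) and 19 are not, mirroring the reported screen
#' structure. Rates are drawn reproducibly from `seed`, which is part of the
#' panel definition, not an analysis input.
#'
#' @param celllines Cell-line names carried by the rate vectors.
#' @param n_informative,n_uninformative Planted class sizes (including the
#'   non-informative PTPRC probe among `n_uninformative`).
#' @param noise_sigma Spot noise sd (natural log scale).
#' @param baseline Baseline (no-template) intensity, signal units.
#' @param saturation_ceiling Detector ceiling, signal units.
#' @param wbc_expressed_fraction Fraction of gene probes with appreciable
#'   expression in WBC RNA.
#' @param seed Seed fixing the drawn rates.
#' @return A [panel_model()] with a `truth` attribute recording the planted
#'   informative partition.
#' @export
default_panel <- function(celllines = c("BT474", "MDA-MB-231", "SK-BR-3",
                                        "MCF-7", "Caov-3"),
                          n_informative = 53, n_uninformative = 19,
                          noise_sigma = 0.25, baseline = 20,
                          saturation_ceiling = 1e5,
                          wbc_expressed_fraction = 0.5, seed = 101) {
  n_genes <- n_informative + n_uninformative
  ctl <- .default_control_scheme()
  .with_seed(.hash32("default_panel", seed), {
    genes <- vector("list", n_genes)
    informative <- rep(c(TRUE, FALSE), c(n_informative, n_uninformative - 1L))
    for (i in seq_len(n_genes - 1L)) {
      id <- sprintf("G%02d", i)
      if (informative[i]) {
        best <- stats::runif(1, 2, 30)
        rates <- stats::runif(length(celllines), 0, best)
        rates[sample.int(length(celllines), 1)] <- best
      } else {
        rates <- stats::runif(length(celllines), 0, 0.3)
      }
      wbc <- if (stats::runif(1) < wbc_expressed_fraction)
        stats::rlnorm(1, log(100), 1) else 0
      genes[[i]] <- gene_signal_model(
        id, baseline = baseline,
        cellline_rates = stats::setNames(rates, celllines),
        wbc_rate = wbc, saturation_ceiling = saturation_ceiling,
        noise_sigma = noise_sigma)
    }
    genes[[n_genes]] <- gene_signal_model(
      "PTPRC", baseline = baseline,
      cellline_rates = stats::setNames(rep(0, length(celllines)), celllines),
      wbc_rate = 1000, saturation_ceiling = saturation_ceiling,
      noise_sigma = noise_sigma)
    panel <- panel_model(genes, ptprc_id = "PTPRC", control_ids = ctl$ids,
                         control_levels = ctl$levels, noise_sigma = noise_sigma)
    attr(panel, "truth") <- data.frame(
      gene_id = names(panel$genes),
      informative = c(informative, FALSE),
      stringsAsFactors = FALSE)
    panel
  })
}

#' Default cohort panel
#'
#' Panel used by [simulate_cohort()]: `n_exclusive` tumor-exclusive marker
#' probes (respond to tumor-cell RNA, silent in WBC RNA), `n_wbc`
#' WBC-background probes (driven purely by WBC load), the PTPRC WBC marker,
#' and the standard control probes.
#'
#' @param n_exclusive,n_wbc Planted class sizes.
#' @param noise_sigma,baseline,saturation_ceiling As in [default_panel()].
#' @param seed Seed fixing the drawn rates.
#' @return A [panel_model()] with a `truth` attribute recording per-gene
#'   signal sources (`tumor`, `wbc`, `ptprc`).
#' @export
cohort_panel <- function(n_exclusive = 10, n_wbc = 60, noise_sigma = 0.25,
                         baseline = 20, saturation_ceiling = 1e5, seed = 202) {
  ctl <- .default_control_scheme()
  .with_seed(.hash32("cohort_panel", seed), {
    genes <- list()
    for (i in seq_len(n_exclusive)) {
      genes[[length(genes) + 1L]] <- gene_signal_model(
        sprintf("M%02d", i), baseline = baseline,
        cellline_rates = c(tumor = stats::runif(1, 3, 8)),
        wbc_rate = 0, saturation_ceiling = saturation_ceiling,
        noise_sigma = noise_sigma)
    }
    for (i in seq_len(n_wbc)) {
      genes[[length(genes) + 1L]] <- gene_signal_model(
        sprintf("W%02d", i), baseline = baseline,
        cellline_rates = c(tumor = 0),
        wbc_rate = stats::rlnorm(1, log(200), 1),
        saturation_ceiling = saturation_ceiling, noise_sigma = noise_sigma)
    }
    genes[[length(genes) + 1L]] <- gene_signal_model(
      "PTPRC", baseline = baseline, cellline_rates = c(tumor = 0),
      wbc_rate = 1000, saturation_ceiling = saturation_ceiling,
      noise_sigma = noise_sigma)
    panel <- panel_model(genes, ptprc_id = "PTPRC", control_ids = ctl$ids,
                         control_levels = ctl$levels, noise_sigma = noise_sigma)
    attr(panel, "truth") <- data.frame(
      gene_id = names(panel$genes),
      source = c(rep("tumor", n_exclusive), rep("wbc", n_wbc), "ptprc"),
      stringsAsFactors = FALSE)
    panel
  })
}

#' Write or read a panel model as YAML
#'
#' @param panel A [panel_model()].
#' @param path File path.
#' @return `read_panel_yaml` returns a [panel_model()]; `write_panel_yaml`
#'   returns `path` invisibly.
#' @export
write_panel_yaml <- function(panel, path) {
  lst <- list(
    ptprc_id = panel$ptprc_id,
    noise_sigma = panel$noise_sigma,
    control_ids = panel$control_ids,
    control_levels = as.list(panel$control_levels),
    genes = lapply(panel$genes, function(g) {
      list(gene_id = g$gene_id, baseline = g$baseline,
           cellline_rates = as.list(g$cellline_rates),
           wbc_rate = g$wbc_rate,
           saturation_ceiling = g$saturation_ceiling,
           noise_sigma = g$noise_sigma)
    }))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_panel_yaml
#' @export
read_panel_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  genes <- lapply(lst$genes, function(g) {
    gene_signal_model(g$gene_id, baseline = g$baseline,
                      cellline_rates = unlist(g$cellline_rates),
                      wbc_rate = g$wbc_rate,
                      saturation_ceiling = g$saturation_ceiling,
                      noise_sigma = g$noise_sigma)
  })
  panel_model(genes, ptprc_id = lst$ptprc_id,
              control_ids = lapply(lst$control_ids, as.character),
              control_levels = unlist(lst$control_levels),
              noise_sigma = lst$noise_sigma)
}
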