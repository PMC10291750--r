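#' WBC-background marker screen
#'
#' First selection tier: a gene survives the leukocyte-background challenge
#' when (a) its titration fit in the constant WBC background is still
#' responsive (slope above `slope_min` and limit of detection below
#' `lod_pg_max`) for at least one cell line, and (b) a two-sample Student
#' t-test between the WBC-only replicates and the replicates carrying
#' `spike_pg` of that cell line's RNA is significant at `alpha`.
#'
#' @param em A net [expression_matrix()] from a titration-with-background
#'   design including `group == "wbc_only"` samples.
#' @param genes Probe ids to screen.
#' @param th A [screen_thresholds()].
#' @param spike_pg RNA amount compared against the WBC-only group (pg);
#'   20 pg is roughly one cell.
#' @param k LOD detection multiple.
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   equal-variance Student test.
#' @return data.frame per gene: `responsive`, `best_slope`, `min_lod_pg`,
#'   `t_p` (smallest per-cell-line p), `significant`, `selected`.
#' @export
wbc_background_screen <- function(em, genes, th = screen_thresholds(),
                                  spike_pg = 20, k = 3, welch = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  s <- em$samples
  wbc_rows <- s$group == "wbc_only"
  .assert(sum(wbc_rows) >= 2, "need >= 2 WBC-only replicates")
  celllines <- unique(s$cellline[!is.na(s$cellline)])
  fits <- fit_all_titrations(em, genes = genes, celllines = celllines, k = k)
  rows <- lapply(genes, function(g) {
    fg <- fits[fits$gene_id == g, , drop = FALSE]
    responsive <- any(fg$slope > th$slope_min & fg$lod_pg < th$lod_pg_max)
    pvals <- vapply(celllines, function(cl) {
      grp <- !is.na(s$cellline) & s$cellline == cl & s$pg == spike_pg
      if (sum(grp) < 2) return(NA_real_)
      stats::t.test(em$values[grp, g], em$values[wbc_rows, g],
                    var.equal = !welch)$p.value
    }, numeric(1))
    data.frame(gene_id = g, responsive = responsive,
               best_slope = max(fg$slope), min_lod_pg = min(fg$lod_pg),
               t_p = suppressWarnings(min(pvals, na.rm = TRUE)),
               significant = any(pvals < th$alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$responsive & out$significant
  out
}

#' Spiked-harvest marker screen
#'
#' Second tier, on contrived harvests: a gene is selected when, for at
#' least one spiked group, its mean net signal is at least `fold_min` times
#' the unspiked mean (denominators below `floor` are floored at `floor`
#' signal units) and the Student t-test against the unspiked group has
#' p <= `p_max`. With `p_band = TRUE` the significance condition becomes
#' `alpha < p <= p_max`, the alternative reading of "p between 0.05 and
#' 0.1".
#'
#' @param em A net [expression_matrix()] whose sample `group`s include
#'   `"unspiked"` and one or more `"spiked_*"` groups.
#' @param genes Probe ids to screen.
#' @param th A [screen_thresholds()].
#' @param p_max Maximum t-test p-value.
#' @param floor Denominator floor for the fold ratio (signal units).
#' @param p_band Use the banded significance rule.
#' @param welch Use Welch's t-test.
#' @return data.frame per gene: `best_group`, `fold_change_best`, `t_p`,
#'   `selected`.
#' @export
spike_screen <- function(em, genes, th = screen_thresholds(), p_max = 0.1,
                         floor = 1, p_band = FALSE, welch = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  s <- em$samples
  un <- s$group == "unspiked"
  if (!any(un)) stop("no unspiked group in the sample sheet", call. = FALSE)
  .assert(sum(un) >= 2, "need >= 2 unspiked samples")
  spiked_groups <- setdiff(unique(s$group[startsWith(s$group, "spiked")]),
                           character(0))
  .assert(length(spiked_groups) > 0, "no spiked groups in the sample sheet")
  rows <- lapply(genes, function(g) {
    base_mean <- mean(em$values[un, g])
    res <- vapply(spiked_groups, function(grp) {
      sel <- s$group == grp
      if (sum(sel) < 2) return(c(NA_real_, NA_real_))
      fold <- mean(em$values[sel, g]) / max(base_mean, floor)
      p <- stats::t.test(em$values[sel, g], em$values[un, g],
                         var.equal = !welch)$p.value
      c(fold, p)
    }, numeric(2))
    fold <- res[1, ]; p <- res[2, ]
    sig <- if (p_band) p > th$alpha & p <= p_max else p <= p_max
    hit <- fold >= th$fold_min & sig
    best <- if (any(hit, na.rm = TRUE)) {
      which(hit & fold == max(fold[hit], na.rm = TRUE))[1]
    } else which.max(fold)
    data.frame(gene_id = g, best_group = spiked_groups[best],
               fold_change_best = fold[best], t_p = p[best],
               selected = any(hit, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-log regression of a gene on the WBC marker PTPRC
#'
#' Deconfounding tier: genes whose expression tracks PTPRC (CD45) reflect
#' the number of contaminating leukocytes rather than CTCs. The regression
#' of `log10(gene net)` on `log10(PTPRC net)` is fit only to samples whose
#' gene net signal exceeds `threshold_units`; with fewer than 3 such
#' samples the slope is undefined (flagged), but the above-threshold counts
#' per group are still reported.
#'
#' @param em A net [expression_matrix()] with group labels in the sheet
#'   (NTC rows are ignored).
#' @param gene Probe id.
#' @param threshold_units Net-signal threshold (units).
#' @param ptprc_id Id of the WBC-marker probe.
#' @param floor Floor applied inside the log10 transforms (signal units).
#' @return List of class `ptprc_regression`: `gene_id`, `slope`, `r`,
#'   `defined`, `n_above`, `n_above_by_group`.
#' @export
ptprc_regression <- function(em, gene, threshold_units = 10,
                             ptprc_id = "PTPRC", floor = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!ptprc_id %in% colnames(em$values))
    stop(sprintf("WBC marker probe '%s' missing from the matrix", ptprc_id),
         call. = FALSE)
  keep <- em$samples$group != "ntc"
  v <- em$values[keep, , drop = FALSE]
  grp <- em$samples$group[keep]
  above <- v[, gene] > threshold_units
  n_by_group <- tapply(above, grp, sum)
  if (sum(above) >= 3) {
    x <- log10(pmax(v[above, ptprc_id], floor))
    y <- log10(pmax(v[above, gene], floor))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      slope <- 0; r <- 0
    } else {
      slope <- unname(stats::coef(stats::lm(y ~ x))[2])
      r <- stats::cor(x, y)
    }
    defined <- TRUE
  } else {
    slope <- NA_real_; r <- NA_real_; defined <- FALSE
  }
  structure(list(gene_id = gene, slope = slope, r = r, defined = defined,
                 n_above = sum(above),
                 n_above_by_group = as.list(n_by_group),
                 threshold_units = threshold_units),
            class = "ptprc_regression")
}

#' Rank genes by their PTPRC slope
#'
#' Ascending PTPRC slope; genes at the top of the list are the least
#' leukocyte-driven. Genes with an undefined slope (too few samples above
#' the expression threshold -- precisely the exclusively-expressed
#' candidates) rank first, ordered by above-threshold count then gene id.
#' The order is a deterministic total order, invariant to input order.
#'
#' @param regs List of [ptprc_regression()] results (or a data.frame with
#'   columns `gene_id`, `slope`, `defined`, `n_above`).
#' @return data.frame ordered by rank with columns `rank`, `gene_id`,
#'   `slope`, `r`, `defined`, `n_above`.
#' @export
rank_genes <- function(regs) {
  if (!is.data.frame(regs)) {
    regs <- do.call(rbind, lapply(regs, function(x)
      data.frame(gene_id = x$gene_id, slope = x$slope, r = x$r,
                 defined = x$defined, n_above = x$n_above,
                 stringsAsFactors = FALSE)))
  }
  undef <- regs[!regs$defined, , drop = FALSE]
  undef <- undef[order(undef$n_above, undef$gene_id), , drop = FALSE]
  def <- regs[regs$defined, , drop = FALSE]
  def <- def[order(def$slope, def$gene_id), , drop = FALSE]
  out <- rbind(undef, def)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Exclusive-marker selection
#'
#' Final tier: a gene is an exclusive marker when it exceeds the
#' expression threshold in at most `hv_tolerance` reference (HV) samples
#' and in at least one case (MBC) sample. Such genes report CTC presence
#' independently of leukocyte contamination.
#'
#' @param em A net [expression_matrix()]; the sheet's `group` column must
#'   contain both `ref_group` and `case_group`.
#' @param genes Probe ids to consider.
#' @param threshold_units Net-signal threshold (units).
#' @param hv_tolerance Maximum reference samples allowed above threshold.
#' @param ref_group,case_group Group labels.
#' @return data.frame per gene: `n_above_hv`, `n_above_mbc`, `selected`.
#' @export
exclusive_markers <- function(em, genes = colnames(em$values),
                              threshold_units = 10, hv_tolerance = 0,
                              ref_group = "HV", case_group = "MBC") {
  stopifnot(inherits(em, "expression_matrix"))
  grp <- em$samples$group
  .assert(any(grp == ref_group) && any(grp == case_group),
          "both groups must be present")
  ref <- em$values[grp == ref_group, genes, drop = FALSE] > threshold_units
  cas <- em$values[grp == case_group, genes, drop = FALSE] > threshold_units
  out <- data.frame(gene_id = genes,
                    n_above_hv = colSums(ref), n_above_mbc = colSums(cas),
                    stringsAsFactors = FALSE)
  out$selected <- out$n_above_hv <= hv_tolerance & out$n_above_mbc >= 1
  rownames(out) <- NULL
  out
}

#' Combined per-gene marker report
#'
#' Merges whichever screening tiers were run into one table, one row per
#' gene: tier flags, fold change, t-test p, PTPRC slope/correlation,
#' above-threshold counts and final rank. No multiple-testing correction
#' is applied anywhere in the selection (recorded in the `correction`
#' attribute).
#'
#' @param genes Character vector of gene ids (the report's row set).
#' @param clean,wbc,harvest Optional outputs of [panel_screen()]'s
#'   `per_gene`, [wbc_background_screen()] and [spike_screen()].
#' @param ranking Optional output of [rank_genes()].
#' @param exclusive Optional output of [exclusive_markers()].
#' @return data.frame, one row per gene.
#' @export
marker_report <- function(genes, clean = NULL, wbc = NULL, harvest = NULL,
                          ranking = NULL, exclusive = NULL) {
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  take <- function(out, d, cols, names_to) {
    if (is.null(d)) return(out)
    idx <- match(out$gene_id, d$gene_id)
    for (i in seq_along(cols)) out[[names_to[i]]] <- d[[cols[i]]][idx]
    out
  }
  out <- take(out, clean, "informative", "informative_clean")
  out <- take(out, wbc, c("selected", "t_p"),
              c("informative_wbc_bg", "t_p"))
  out <- take(out, harvest, c("selected", "fold_change_best"),
              c("informative_harvest", "fold_change_best"))
  out <- take(out, ranking, c("slope", "r", "rank"),
              c("ptprc_slope", "ptprc_r", "rank"))
  out <- take(out, exclusive, c("n_above_hv", "n_above_mbc", "selected"),
              c("n_above_threshold_hv", "n_above_threshold_mbc",
                "exclusive_marker"))
  attr(out, "correction") <- "none"
  out
}
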