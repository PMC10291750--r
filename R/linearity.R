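#' Screening thresholds
#'
#' The decision thresholds used across the screening tiers: titration slope
#' above 1 signal unit/pg and correlation above 0.65 (both strict) define an
#' informative probe; fold changes of at least 2 and the 10-unit net-signal
#' expression threshold drive the later tiers; limits of detection above
#' 20 pg (about one cell's RNA) disqualify a probe from single-cell work.
#'
#' @param slope_min Minimum titration slope, signal units per pg.
#' @param r_min Minimum correlation coefficient.
#' @param alpha Significance level for t-tests and correlation p-values.
#' @param fold_min Minimum fold change for the spike screen.
#' @param threshold_units Net-signal expression threshold (units).
#' @param lod_pg_max Maximum acceptable limit of detection (pg).
#' @return An object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(slope_min = 1, r_min = 0.65, alpha = 0.05,
                              fold_min = 2, threshold_units = 10,
                              lod_pg_max = 20) {
  vals <- c(slope_min, r_min, alpha, fold_min, threshold_units, lod_pg_max)
  .assert(all(vals > 0), "thresholds must be positive")
  structure(list(slope_min = slope_min, r_min = r_min, alpha = alpha,
                 fold_min = fold_min, threshold_units = threshold_units,
                 lod_pg_max = lod_pg_max),
            class = "screen_thresholds")
}

#' Two-sided p-value of a correlation coefficient
#'
#' Student-t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2`
#' degrees of freedom; `r = 0` gives 1, `|r| = 1` gives 0 (the limit).
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return p-value in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  .assert(n >= 3, "n must be >= 3")
  .assert(abs(r) <= 1 + 1e-12, "|r| must be <= 1")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Fit a titration regression for one gene and cell line
#'
#' Ordinary least squares of the mean net signal (over replicates) on the
#' RNA amount in pg gives the slope and intercept; the correlation
#' coefficient and its p-value are computed on the replicate-level points
#' (so a five-amount, three-replicate design tests the correlation at
#' n = 15). Samples with 0 pg serve as no-template controls and are
#' excluded. A constant response is reported as slope 0, r 0, p 1.
#'
#' @param em A net [expression_matrix()] from a titration design; the
#'   sample sheet needs `cellline`, `pg` and `group` columns.
#' @param gene Probe id.
#' @param cellline Cell line to fit.
#' @param ceiling Optional saturation ceiling (signal units); when given,
#'   the fit is flagged `saturated` if any amount's mean exceeds 80\% of it.
#' @return An object of class `titration_fit` with fields `gene_id`,
#'   `cellline`, `slope`, `intercept`, `r`, `p_r`, `n_points` (distinct
#'   amounts), `n_obs` (replicate-level points) and `saturated`.
#' @export
fit_titration <- function(em, gene, cellline, ceiling = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  .assert(gene %in% colnames(em$values), sprintf("unknown probe '%s'", gene))
  s <- em$samples
  keep <- !is.na(s$cellline) & s$cellline == cellline & s$pg > 0
  y <- em$values[keep, gene]
  x <- s$pg[keep]
  ok <- is.finite(y)
  y <- y[ok]; x <- x[ok]
  amounts <- sort(unique(x))
  if (length(amounts) < 3)
    stop("need >= 3 distinct RNA amounts with data", call. = FALSE)
  means <- tapply(y, factor(x, levels = amounts), mean)
  fit <- stats::lm(means ~ amounts)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (stats::sd(y) == 0 || stats::sd(means) == 0) {
    slope <- 0; r <- 0; p <- 1
  } else {
    r <- stats::cor(x, y)
    p <- correlation_pvalue(r, length(y))
  }
  saturated <- if (is.null(ceiling)) NA else any(means > 0.8 * ceiling)
  structure(list(gene_id = gene, cellline = cellline, slope = slope,
                 intercept = intercept, r = r, p_r = p,
                 n_points = length(amounts), n_obs = length(y),
                 saturated = saturated),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("titration_fit %s / %s: slope %.3g, r %.3f (p %.3g), n %d\n",
              x$gene_id, x$cellline, x$slope, x$r, x$p_r, x$n_obs))
  invisible(x)
}

#' Is a titration fit informative?
#'
#' Strict thresholds: slope > `slope_min` and r > `r_min`. A gene is
#' panel-informative when at least one of its cell-line fits passes.
#'
#' @param fit A [fit_titration()] result.
#' @param th A [screen_thresholds()].
#' @return Logical flag.
#' @export
informative_probe <- function(fit, th = screen_thresholds()) {
  stopifnot(inherits(fit, "titration_fit"))
  fit$slope > th$slope_min && fit$r > th$r_min
}

#' Limit of detection from a titration fit
#'
#' `lod_pg = k * ntc_sd / slope` (the classic 3-sigma detection limit for
#' `k = 3`); non-positive slopes give `+Inf` (undetectable).
#'
#' @param fit A [fit_titration()] result.
#' @param ntc_sd Standard deviation of this probe over the NTC samples.
#' @param k Detection multiple (> 0).
#' @return An object of class `lod_estimate` with `lod_pg` and `ntc_sd`.
#' @export
lod <- function(fit, ntc_sd, k = 3) {
  stopifnot(inherits(fit, "titration_fit"))
  .assert(k > 0, "k must be > 0")
  .assert(ntc_sd >= 0, "ntc_sd must be >= 0")
  lod_pg <- if (fit$slope > 0) k * ntc_sd / fit$slope else Inf
  structure(list(gene_id = fit$gene_id, cellline = fit$cellline,
                 lod_pg = lod_pg, ntc_sd = ntc_sd, k = k),
            class = "lod_estimate")
}

#' Fit every gene x cell line titration of a dataset
#'
#' @param em A net [expression_matrix()].
#' @param genes Probe ids to fit (default: every column that is not an NTC
#'   control, i.e. all probes; pass the panel's gene ids to skip controls).
#' @param celllines Cell lines (default: those present in the sheet).
#' @param ceilings Optional named vector of saturation ceilings per gene.
#' @param k LOD detection multiple passed to [lod()].
#' @return data.frame with one row per (gene, cellline): slope, intercept,
#'   r, p_r, n_points, n_obs, saturated, lod_pg.
#' @export
fit_all_titrations <- function(em, genes = colnames(em$values),
                               celllines = NULL, ceilings = NULL, k = 3) {
  stopifnot(inherits(em, "expression_matrix"))
  celllines <- celllines %||%
    unique(em$samples$cellline[!is.na(em$samples$cellline)])
  sds <- ntc_sd(em)
  rows <- list()
  for (g in genes) for (cl in celllines) {
    f <- fit_titration(em, g, cl,
                       ceiling = if (!is.null(ceilings)) ceilings[[g]])
    l <- lod(f, sds[[g]], k = k)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, cellline = cl, slope = f$slope, intercept = f$intercept,
      r = f$r, p_r = f$p_r, n_points = f$n_points, n_obs = f$n_obs,
      saturated = f$saturated, ntc_sd = sds[[g]], lod_pg = l$lod_pg,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Panel-level screening summary
#'
#' Applies [informative_probe()] to every fit, aggregates to per-gene flags
#' (informative for at least one cell line), and summarizes the finite
#' limits of detection.
#'
#' @param fits data.frame from [fit_all_titrations()] (or equivalent rows).
#' @param th A [screen_thresholds()].
#' @return List with `summary` (n_genes, n_informative, fraction, LOD
#'   median/range over finite LODs), `per_gene` (gene_id, informative,
#'   best_cellline, best_slope, best_r, min_lod_pg) and the annotated
#'   per-fit table.
#' @export
panel_screen <- function(fits, th = screen_thresholds()) {
  .assert(is.data.frame(fits) && nrow(fits) > 0, "fits must be a nonempty data.frame")
  fits$informative <- fits$slope > th$slope_min & fits$r > th$r_min
  per_gene <- do.call(rbind, lapply(split(fits, fits$gene_id), function(d) {
    best <- which.max(d$slope)
    data.frame(gene_id = d$gene_id[1], informative = any(d$informative),
               best_cellline = d$cellline[best], best_slope = d$slope[best],
               best_r = d$r[best], min_lod_pg = min(d$lod_pg),
               stringsAsFactors = FALSE)
  }))
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL
  finite_lod <- fits$lod_pg[is.finite(fits$lod_pg)]
  summary <- list(
    n_genes = nrow(per_gene),
    n_informative = sum(per_gene$informative),
    fraction_informative = mean(per_gene$informative),
    lod_median_pg = if (length(finite_lod)) stats::median(finite_lod) else Inf,
    lod_range_pg = if (length(finite_lod)) range(finite_lod) else c(Inf, Inf))
  list(summary = summary, per_gene = per_gene, per_fit = fits)
}
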