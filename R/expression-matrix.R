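#' Expression matrix container
#'
#' Samples x probes intensity matrix with a sample annotation sheet and a
#' provenance flag distinguishing raw (spot-summarized) from net
#' (background-subtracted) values. Net matrices record the no-template
#' control (NTC) sample ids used for the subtraction.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns.
#' @param samples `data.frame` with at least a `sample_id` column matching
#'   the row order of `values`.
#' @param provenance `"raw"` or `"net"`.
#' @param ntc_ids NTC sample ids (required for net matrices).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, provenance = c("raw", "net"),
                              ntc_ids = NULL) {
  provenance <- match.arg(provenance)
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  .assert(is.data.frame(samples) && "sample_id" %in% names(samples),
          "samples must be a data.frame with a sample_id column")
  .assert(!anyDuplicated(samples$sample_id), "duplicated sample ids")
  .assert(!anyDuplicated(colnames(values)), "duplicated probe ids")
  .assert(identical(rownames(values), as.character(samples$sample_id)),
          "rownames(values) must equal samples$sample_id in order")
  if (provenance == "net")
    .assert(length(ntc_ids) >= 1, "net matrices must record the NTC set used")
  structure(list(values = values, samples = samples,
                 provenance = provenance, ntc_ids = ntc_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d samples x %d probes\n",
              x$provenance, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples and/or probes
#' @param x An `expression_matrix`.
#' @param samples,probes Character ids or logical/integer indices.
#' @export
subset_matrix <- function(x, samples = NULL, probes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  s <- x$samples
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(v)) else samples
    v <- v[idx, , drop = FALSE]
    s <- s[idx, , drop = FALSE]
  }
  if (!is.null(probes)) v <- v[, probes, drop = FALSE]
  # the recorded NTC set documents how the net values were obtained and is
  # kept even when the NTC rows themselves are subset away
  expression_matrix(v, s, x$provenance, ntc_ids = x$ntc_ids)
}

#' Summarize spot-level intensities to a raw probe-level matrix
#'
#' Each (sample, probe) cell is the median of its evaluable replicate spots,
#' the instrument's reported statistic. Pairs without any evaluable spot
#' become `NA` and are reported in the `missing` attribute.
#'
#' @param x A `spot_dataset` (from the simulators) or a spot-level
#'   `data.frame` with columns `sample_id`, `probe_id`, `spot_index`,
#'   `intensity` and optionally `evaluable`.
#' @param samples Optional sample sheet; defaults to the dataset's sheet or
#'   the distinct sample ids in order of first appearance.
#' @return A raw [expression_matrix()].
#' @export
summarize_spots <- function(x, samples = NULL) {
  if (inherits(x, "spot_dataset")) {
    samples <- samples %||% x$samples
    x <- x$spots
  }
  .assert(is.data.frame(x) && nrow(x) > 0, "empty spot table")
  .assert(all(c("sample_id", "probe_id", "intensity") %in% names(x)),
          "spot table needs sample_id, probe_id, intensity columns")
  .assert(all(is.finite(x$intensity)), "spot intensities must be finite")
  if (is.null(x$evaluable)) x$evaluable <- TRUE
  if (is.null(samples))
    samples <- data.frame(sample_id = unique(x$sample_id),
                          stringsAsFactors = FALSE)
  sample_ids <- as.character(samples$sample_id)
  probe_ids <- unique(x$probe_id)
  ev <- x[x$evaluable, , drop = FALSE]
  med <- tapply(ev$intensity,
                list(factor(ev$sample_id, levels = sample_ids),
                     factor(ev$probe_id, levels = probe_ids)),
                stats::median)
  values <- matrix(as.numeric(med), nrow = length(sample_ids),
                   dimnames = list(sample_ids, probe_ids))
  em <- expression_matrix(values, samples, "raw")
  miss <- which(is.na(values), arr.ind = TRUE)
  if (nrow(miss)) {
    missing <- data.frame(sample_id = sample_ids[miss[, 1]],
                          probe_id = probe_ids[miss[, 2]],
                          stringsAsFactors = FALSE)
    message(nrow(missing), " (sample, probe) pairs had no evaluable spots")
    attr(em, "missing") <- missing
  }
  em
}

#' QC thresholds for control probes
#'
#' Minimum acceptable intensities for positive controls and maximum
#' acceptable intensities for negative controls. The instrument vendor's
#' acceptance metrics are unpublished, so thresholds are configuration;
#' [default_qc_thresholds()] derives them from a panel's expected control
#' intensities (positive minimum = expected/5; negative maximum = 10x the
#' probe baseline).
#'
#' @param positive_min Named numeric vector (control probe -> minimum).
#' @param negative_max Named numeric vector (control probe -> maximum).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(positive_min = numeric(0),
                          negative_max = numeric(0)) {
  .assert(all(positive_min >= 0) && all(negative_max >= 0),
          "thresholds must be >= 0")
  structure(list(positive_min = positive_min, negative_max = negative_max),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param panel A [panel_model()].
#' @export
default_qc_thresholds <- function(panel) {
  pos <- c(panel$control_ids$synthetic, panel$control_ids$positive)
  neg <- panel$control_ids$negative
  base <- mean(vapply(panel$genes, function(g) g$baseline, numeric(1)))
  qc_thresholds(positive_min = panel$control_levels[pos] / 5,
                negative_max = stats::setNames(rep(10 * base, length(neg)), neg))
}

#' Control-probe QC for one sample or a whole matrix
#'
#' A sample passes iff every positive control is at or above its minimum and
#' every negative control at or below its maximum. Failing samples should be
#' excluded from downstream analysis (see `keep`).
#'
#' @param row Named numeric vector of raw intensities for one sample.
#' @param thresholds A [qc_thresholds()].
#' @return `qc_sample`: list with `pass` and a per-control `report`
#'   data.frame. `qc_samples`: data.frame with one row per sample (`pass`,
#'   comma-separated `failed_controls`).
#' @export
qc_sample <- function(row, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c(names(thresholds$positive_min), names(thresholds$negative_max))
  absent <- setdiff(need, names(row))
  if (length(absent))
    stop("missing control probe(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  rep_pos <- data.frame(
    control = names(thresholds$positive_min), type = "positive",
    intensity = as.numeric(row[names(thresholds$positive_min)]),
    limit = as.numeric(thresholds$positive_min),
    ok = as.numeric(row[names(thresholds$positive_min)]) >=
      as.numeric(thresholds$positive_min),
    stringsAsFactors = FALSE)
  rep_neg <- data.frame(
    control = names(thresholds$negative_max), type = "negative",
    intensity = as.numeric(row[names(thresholds$negative_max)]),
    limit = as.numeric(thresholds$negative_max),
    ok = as.numeric(row[names(thresholds$negative_max)]) <=
      as.numeric(thresholds$negative_max),
    stringsAsFactors = FALSE)
  report <- rbind(rep_pos, rep_neg)
  list(pass = all(report$ok), report = report)
}

#' @rdname qc_sample
#' @param em A raw [expression_matrix()].
#' @export
qc_samples <- function(em, thresholds) {
  stopifnot(inherits(em, "expression_matrix"))
  res <- lapply(seq_len(nrow(em$values)), function(i) {
    q <- qc_sample(em$values[i, ], thresholds)
    data.frame(sample_id = rownames(em$values)[i], pass = q$pass,
               failed_controls = paste(q$report$control[!q$report$ok],
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Background-subtract a raw matrix against its NTC samples
#'
#' Per probe, the median raw intensity over the no-template-control samples
#' is subtracted from every sample (net signal). Negative net values are
#' retained, not clipped; flooring happens only inside log transforms
#' downstream. Applying `net_signal` to an already-net matrix is refused.
#'
#' @param em A raw [expression_matrix()].
#' @param ntc_ids NTC sample ids; defaults to samples whose `group` is
#'   `"ntc"`.
#' @param expected_ntc Warn when fewer NTCs than this are available
#'   (the assay design uses nine).
#' @return A net [expression_matrix()] (NTC rows retained).
#' @export
net_signal <- function(em, ntc_ids = NULL, expected_ntc = 9) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$provenance == "net")
    stop("matrix is already net (background-subtracted); refusing to subtract twice",
         call. = FALSE)
  if (is.null(ntc_ids)) {
    .assert("group" %in% names(em$samples),
            "ntc_ids not given and sample sheet has no 'group' column")
    ntc_ids <- em$samples$sample_id[em$samples$group == "ntc"]
  }
  if (length(ntc_ids) == 0)
    stop("no NTC samples available for background subtraction", call. = FALSE)
  if (length(ntc_ids) < expected_ntc)
    warning(sprintf("only %d NTC samples (design calls for %d)",
                    length(ntc_ids), expected_ntc))
  .assert(all(ntc_ids %in% rownames(em$values)), "unknown NTC sample id")
  bg <- apply(em$values[ntc_ids, , drop = FALSE], 2, stats::median,
              na.rm = TRUE)
  values <- sweep(em$values, 2, bg, `-`)
  expression_matrix(values, em$samples, "net", ntc_ids = ntc_ids)
}

#' Per-probe standard deviation over the NTC samples
#'
#' Used as the background-noise estimate entering the limit-of-detection
#' formula `k * SD(NTC) / slope`.
#'
#' @param em An [expression_matrix()] whose rows include NTC samples
#'   (either provenance; the SD is translation-invariant).
#' @param ntc_ids NTC sample ids; defaults to the recorded set (net) or the
#'   `group == "ntc"` samples.
#' @return Named numeric vector, one SD per probe.
#' @export
ntc_sd <- function(em, ntc_ids = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  ntc_ids <- ntc_ids %||% em$ntc_ids %||%
    em$samples$sample_id[em$samples$group == "ntc"]
  .assert(length(ntc_ids) >= 2, "need >= 2 NTC samples to estimate noise")
  apply(em$values[ntc_ids, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
}
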