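#' Read a spot-level intensity table
#'
#' CSV or TSV (auto-detected from the header line) with required columns
#' `sample_id`, `probe_id`, `spot_index`, `intensity` and optional
#' `evaluable`. Rows with non-numeric intensity are rejected and reported
#' with their line numbers.
#'
#' @param path File path.
#' @return data.frame suitable for [summarize_spots()]; rejected rows (if
#'   any) are listed in the `rejected_lines` attribute.
#' @export
read_spot_table <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "probe_id", "spot_index", "intensity")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  inten <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(inten))
  if (length(bad)) {
    warning(sprintf("rejected %d row(s) with non-numeric intensity (lines %s)",
                    length(bad),
                    paste(utils::head(bad + 1L, 10), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
    inten <- inten[-bad]
  }
  out <- data.frame(sample_id = df$sample_id, probe_id = df$probe_id,
                    spot_index = as.integer(df$spot_index),
                    intensity = inten,
                    evaluable = if ("evaluable" %in% names(df))
                      as.logical(df$evaluable) else TRUE,
                    stringsAsFactors = FALSE)
  if (length(bad)) attr(out, "rejected_lines") <- bad + 1L
  out
}

#' Read a sample sheet
#'
#' CSV/TSV with at least a `sample_id` column; all other columns are kept
#' as annotations (`group`, `cellline`, `pg`, `ng_wbc`, `replicate`, ...).
#'
#' @param path File path.
#' @return data.frame of sample annotations.
#' @export
read_sample_sheet <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  .assert("sample_id" %in% names(df), "sample sheet needs a sample_id column")
  df
}

#' Write simulator outputs and matrices as CSV
#'
#' Numeric columns are serialized with 9 significant digits.
#'
#' @param x What to write (`spot_dataset` pieces or an
#'   [expression_matrix()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(x, path) {
  if (inherits(x, "spot_dataset")) x <- x$spots
  utils::write.csv(.format_numeric(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
write_sample_sheet <- function(x, path) {
  if (inherits(x, "spot_dataset")) x <- x$samples
  utils::write.csv(.format_numeric(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(sample_id = rownames(x$values),
                   signif(x$values, 9), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an expression matrix written by [write_expression_matrix()]
#'
#' @param values_path Matrix CSV (first column `sample_id`).
#' @param samples Sample sheet data.frame or path.
#' @param provenance `"raw"` or `"net"`.
#' @param ntc_ids NTC ids for net matrices (default: `group == "ntc"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(values_path, samples,
                                   provenance = c("raw", "net"),
                                   ntc_ids = NULL) {
  provenance <- match.arg(provenance)
  df <- utils::read.csv(values_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  .assert(names(df)[1] == "sample_id", "first column must be sample_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  samples <- samples[match(df$sample_id, samples$sample_id), , drop = FALSE]
  if (provenance == "net" && is.null(ntc_ids))
    ntc_ids <- samples$sample_id[samples$group == "ntc"]
  expression_matrix(values, samples, provenance, ntc_ids = ntc_ids)
}

#' @noRd
.format_numeric <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 9)
  df
}

#' Read panel transcripts from FASTA (+ optional exon BED)
#'
#' FASTA headers are `transcript_id` optionally followed by
#' `gene=<gene_id>`. The BED file (0-based half-open) holds exon blocks in
#' transcript coordinates: columns chrom(=transcript_id), start, end,
#' name, and an optional fifth `score` column where 0 marks a
#' non-universal (isoform-specific) exon.
#'
#' @param fasta_path Transcript FASTA.
#' @param bed_path Optional exon BED.
#' @return List of [transcript_record()]s.
#' @export
read_transcripts <- function(fasta_path, bed_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  tid <- sub("\\s.*$", "", headers)
  gid <- ifelse(grepl("gene=", headers),
                sub(".*gene=(\\S+).*", "\\1", headers), tid)
  exons <- NULL
  if (!is.null(bed_path)) {
    exons <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    .assert(ncol(exons) >= 3, "BED needs chrom, start, end columns")
  }
  lapply(seq_along(seqs), function(i) {
    lens <- NULL; univ <- NULL
    if (!is.null(exons)) {
      ex <- exons[exons[[1]] == tid[i], , drop = FALSE]
      if (nrow(ex)) {
        ex <- ex[order(ex[[2]]), , drop = FALSE]
        lens <- ex[[3]] - ex[[2]]
        univ <- if (ncol(ex) >= 5) ex[[5]] != 0 else NULL
      }
    }
    transcript_record(gid[i], tid[i], as.character(seqs[[i]]),
                      exon_lengths = lens, universal_exons = univ)
  })
}

#' Write designed amplicons as FASTA / the panel as CSV
#'
#' @param designs Output of [assemble_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_amplicons_fasta <- function(designs, path) {
  seqs <- character(0)
  for (g in names(designs)) {
    cands <- designs[[g]]$candidates
    for (i in seq_along(cands)) {
      nm <- sprintf("%s_amp%d %d-%d", g, i, cands[[i]]$amplicon$start,
                    cands[[i]]$amplicon$end)
      seqs[nm] <- cands[[i]]$amplicon$seq
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_amplicons_fasta
#' @export
write_panel_csv <- function(designs, path) {
  rows <- list()
  for (g in names(designs)) {
    cands <- designs[[g]]$candidates
    for (i in seq_along(cands)) {
      p <- cands[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, candidate = i,
        forward = p$forward$seq, reverse = p$reverse$seq,
        tailed_forward = p$tailed_forward, tailed_reverse = p$tailed_reverse,
        probe = p$probe$seq,
        amplicon_start = p$amplicon$start, amplicon_end = p$amplicon$end,
        amplicon_gc = p$amplicon$gc,
        tm_forward = p$forward$tm, tm_reverse = p$reverse$tm,
        tm_probe = p$probe$tm, three_prime_ok = p$three_prime_ok,
        universal = p$universal, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  utils::write.csv(.format_numeric(df), path, row.names = FALSE)
  invisible(path)
}

#' Run one of the four canonical experiments end to end
#'
#' Simulate -> spot summarization -> QC -> background subtraction ->
#' stage-specific analysis, optionally writing every artifact plus a JSON
#' manifest (seed, configuration hash, package version) to `out_dir`.
#'
#' * `titration`: per gene x cell line fits, panel screen, PCA on the
#'   informative probes (centered, unscaled), Kendall/Ward.D2 clustering
#'   of the 20 pg samples (log2, centered, scaled).
#' * `wbc_background`: the titration repeated in 1 ng of WBC RNA plus
#'   WBC-only replicates; WBC-background marker screen.
#' * `harvest_spike`: spiked capture-device harvests; fold-change/t-test
#'   spike screen with per-gene PTPRC correlation annotations.
#' * `cohort`: HV/MBC cohort; PTPRC fold difference, PTPRC slope ranking,
#'   exclusive-marker selection, Euclidean/Ward.D clustering of the
#'   selected markers cut at k = 2.
#'
#' @param which Experiment name.
#' @param config List of overrides: `panel`, `thresholds`
#'   ([screen_thresholds()]), `cohort` ([cohort_spec()]), `celllines`,
#'   `n_replicates`, `wbc_ng`, `n_top_markers`.
#' @param seed Seed for the simulation.
#' @param out_dir Optional output directory (created if needed).
#' @return List of stage results (invisible); see the vignette for a tour.
#' @export
run_experiment <- function(which = c("titration", "wbc_background",
                                     "harvest_spike", "cohort"),
                           config = list(), seed = 1, out_dir = NULL) {
  which <- match.arg(which)
  th <- config$thresholds %||% screen_thresholds()
  res <- list(which = which, seed = seed)
  if (which %in% c("titration", "wbc_background")) {
    panel <- config$panel %||% default_panel()
    celllines <- config$celllines %||%
      names(panel$genes[[1]]$cellline_rates)
    wbc_ng <- if (which == "wbc_background") config$wbc_ng %||% 1 else 0
    sim <- list()
    for (cl in celllines)
      sim[[cl]] <- simulate_titration(
        panel, cl, n_replicates = config$n_replicates %||% 3,
        wbc_ng = wbc_ng, seed = .hash32(cl, seed))
    # one matrix per cell line; NTC background from each run's own NTCs
    raws <- lapply(sim, summarize_spots)
    res$qc <- lapply(raws, qc_samples,
                     thresholds = default_qc_thresholds(panel))
    nets <- lapply(raws, net_signal)
    genes <- names(panel$genes)
    fits <- do.call(rbind, lapply(celllines, function(cl)
      fit_all_titrations(nets[[cl]], genes = genes, celllines = cl)))
    res$screen <- panel_screen(fits, th)
    if (which == "wbc_background") {
      wbc_res <- lapply(celllines, function(cl)
        wbc_background_screen(nets[[cl]], genes = genes, th = th))
      merged <- wbc_res[[1]]
      for (d in wbc_res[-1]) {
        merged$responsive <- merged$responsive | d$responsive
        merged$significant <- merged$significant | d$significant
        merged$t_p <- pmin(merged$t_p, d$t_p)
      }
      merged$selected <- merged$responsive & merged$significant
      res$wbc_screen <- merged
      keep <- merged$gene_id[merged$selected]
    } else {
      keep <- res$screen$per_gene$gene_id[res$screen$per_gene$informative]
    }
    res$selected_genes <- keep
    stacked <- .stack_titrations(nets, celllines)
    if (length(keep) >= 2) {
      res$pca <- pca_expression(stacked$values[, keep, drop = FALSE],
                                center = TRUE, scale = FALSE)
      low <- stacked$samples$pg == min(stacked$samples$pg)
      z <- transform_expression(
        stacked$values[low, keep, drop = FALSE], transform_spec())
      res$clustering <- hierarchical_cluster(
        kendall_distance(z, "samples"), "ward_d2")
    }
    res$net <- nets
  } else if (which == "harvest_spike") {
    panel <- config$panel %||% default_panel()
    celllines <- config$celllines %||%
      utils::head(names(panel$genes[[1]]$cellline_rates), 3)
    sim <- simulate_harvest(panel, celllines, seed = seed)
    raw <- summarize_spots(sim)
    res$qc <- qc_samples(raw, default_qc_thresholds(panel))
    em <- net_signal(raw)
    genes <- names(panel$genes)
    res$spike_screen <- spike_screen(em, genes = genes, th = th)
    keep <- res$spike_screen$gene_id[res$spike_screen$selected]
    res$selected_genes <- keep
    nonntc <- em$samples$group != "ntc"
    res$ptprc_cor <- vapply(setdiff(keep, panel$ptprc_id), function(g)
      stats::cor(log10(pmax(em$values[nonntc, g], 1)),
                 log10(pmax(em$values[nonntc, panel$ptprc_id], 1))),
      numeric(1))
    if (length(keep) >= 2) {
      z <- transform_expression(em$values[nonntc, keep, drop = FALSE],
                                transform_spec())
      res$clustering <- hierarchical_cluster(
        kendall_distance(z, "samples"), "ward_d2")
    }
    res$net <- em
  } else {
    panel <- config$panel %||% cohort_panel()
    spec <- config$cohort %||% cohort_spec()
    sim <- simulate_cohort(panel, spec, seed = seed)
    raw <- summarize_spots(sim)
    res$qc <- qc_samples(raw, default_qc_thresholds(panel))
    em <- net_signal(raw)
    grp <- em$samples$group
    hv <- grp == "HV"; mbc <- grp == "MBC"
    ptprc <- em$values[, panel$ptprc_id]
    res$ptprc_fold <- mean(ptprc[mbc]) / mean(ptprc[hv])
    res$ptprc_p <- stats::t.test(ptprc[mbc], ptprc[hv],
                                 var.equal = TRUE)$p.value
    genes <- setdiff(names(panel$genes), panel$ptprc_id)
    regs <- lapply(genes, function(g)
      ptprc_regression(em, g, th$threshold_units, panel$ptprc_id))
    res$ranking <- rank_genes(regs)
    res$exclusive <- exclusive_markers(em, genes, th$threshold_units)
    n_top <- config$n_top_markers %||% 10
    top <- utils::head(res$ranking$gene_id, n_top)
    res$top_genes <- top
    keep <- hv | mbc
    z <- transform_expression(em$values[keep, top, drop = FALSE],
                              transform_spec())
    res$clustering <- hierarchical_cluster(stats::dist(z), "ward_d")
    res$clusters <- cut_and_score(res$clustering, 2, grp[keep])
    res$report <- marker_report(genes, ranking = res$ranking,
                                exclusive = res$exclusive)
    res$net <- em
    res$truth <- sim$truth
  }
  if (!is.null(out_dir)) .write_experiment(res, out_dir, seed, which)
  invisible(res)
}

#' @noRd
.stack_titrations <- function(nets, celllines) {
  vals <- do.call(rbind, lapply(celllines, function(cl) {
    em <- nets[[cl]]
    keep <- em$samples$group == "titration"
    em$values[keep, , drop = FALSE]
  }))
  sheets <- do.call(rbind, lapply(celllines, function(cl) {
    em <- nets[[cl]]
    em$samples[em$samples$group == "titration", , drop = FALSE]
  }))
  list(values = vals, samples = sheets)
}

#' @noRd
.write_experiment <- function(res, out_dir, seed, which) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(res$net, "expression_matrix")) {
    write_expression_matrix(res$net, file.path(out_dir, "net_matrix.csv"))
    write_sample_sheet(res$net$samples, file.path(out_dir, "samples.csv"))
  }
  for (nm in c("ranking", "exclusive", "spike_screen", "wbc_screen",
               "report")) {
    if (!is.null(res[[nm]]))
      utils::write.csv(.format_numeric(res[[nm]]),
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(res$clustering))
    write_dendrogram_newick(res$clustering,
                            file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(res$clusters))
    utils::write.csv(data.frame(sample_id = names(res$clusters$assignments),
                                cluster = res$clusters$assignments),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
  manifest <- list(experiment = which, seed = seed,
                   package_version = as.character(utils::packageVersion("ctcpanel")),
                   config_hash = .hash32(paste(deparse(res$which), seed)),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
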