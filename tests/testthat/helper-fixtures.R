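# Shared fixtures, built in code at test time.

# Small panel for fast pipeline tests: a handful of genes with known rates.
tiny_panel <- function(noise_sigma = 0.25, baseline = 20) {
  ctl <- ctcpanel:::.default_control_scheme()
  genes <- list(
    gene_signal_model("HIGH", baseline, c(A = 5, B = 2), wbc_rate = 0,
                      noise_sigma = noise_sigma),
    gene_signal_model("LOW", baseline, c(A = 0.2, B = 0.1), wbc_rate = 0,
                      noise_sigma = noise_sigma),
    gene_signal_model("WBCY", baseline, c(A = 0, B = 0), wbc_rate = 300,
                      noise_sigma = noise_sigma),
    gene_signal_model("MIXED", baseline, c(A = 3, B = 0.5), wbc_rate = 50,
                      noise_sigma = noise_sigma),
    gene_signal_model("PTPRC", baseline, c(A = 0, B = 0), wbc_rate = 1000,
                      noise_sigma = noise_sigma))
  panel_model(genes, control_ids = ctl$ids, control_levels = ctl$levels,
              noise_sigma = noise_sigma)
}

# Expression matrix built directly from a value matrix + group labels.
make_em <- function(values, group, provenance = "net",
                    extra = NULL, ntc_ids = "none") {
  samples <- data.frame(sample_id = rownames(values), group = group,
                        stringsAsFactors = FALSE)
  if (!is.null(extra)) samples <- cbind(samples, extra)
  expression_matrix(values, samples, provenance,
                    ntc_ids = if (provenance == "net") ntc_ids else NULL)
}

# Random DNA of given GC content.
random_dna <- function(n, gc = 0.5, seed = 1) {
  withr::with_seed(seed, paste(sample(
    c("A", "T", "G", "C"), n, replace = TRUE,
    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)), collapse = ""))
}

# Three ~50% GC design regions separated by AT-only spacers: admits one
# valid amplicon per region and nothing across regions.
fixture_transcript <- function() {
  block <- function(seed) random_dna(155, 0.5, seed)
  spacer <- paste(rep("AT", 60), collapse = "")
  transcript_record("FIX1", "FIX1-201",
                    paste0(spacer, block(11), spacer, block(12),
                           spacer, block(13), spacer))
}

# Independent tau-b oracle: explicit concordant/discordant/tie counting.
tau_b_oracle <- function(a, b) {
  n <- length(a)
  C <- D <- Tx <- Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(a[j] - a[i]); dy <- sign(b[j] - b[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) { Tx <- Tx + 1; next }
    if (dy == 0) { Ty <- Ty + 1; next }
    if (dx == dy) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# Independent O(n^3) hairpin oracle: test every (outer pair, stem length)
# combination explicitly.
hairpin_oracle <- function(seq, loop_min = 3) {
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  n <- length(ch)
  worst <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    for (L in seq_len(n)) {
      if (i + L - 1 >= j - L + 1) break
      if ((j - L + 1) - (i + L - 1) - 1 < loop_min) break
      ok <- TRUE
      for (k in 0:(L - 1))
        if (ch[j - k] != comp[[ch[i + k]]]) { ok <- FALSE; break }
      if (ok) worst <- max(worst, L) else break
    }
  }
  worst
}

# Ward.D2 merge-sequence oracle on Euclidean data: exhaustive greedy
# agglomeration using the explicit error-sum-of-squares formulation
# (centroids and cluster sizes), independent of Lance-Williams updates.
ward2_merge_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      A <- x[clusters[[a]], , drop = FALSE]
      B <- x[clusters[[b]], , drop = FALSE]
      na <- nrow(A); nb <- nrow(B)
      cost <- (na * nb) / (na + nb) *
        sum((colMeans(A) - colMeans(B))^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Merge trace of an hclust object in the same (min-leaf pair) encoding.
merge_trace <- function(hc) {
  n <- length(hc$order)
  minleaf <- function(node) {
    if (node < 0) return(-node)
    min(minleaf(hc$merge[node, 1]), minleaf(hc$merge[node, 2]))
  }
  lapply(seq_len(n - 1), function(s)
    sort(c(minleaf(hc$merge[s, 1]), minleaf(hc$merge[s, 2]))))
}
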