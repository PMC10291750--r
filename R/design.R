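#' Universal primer tail sequences
#'
#' The constant 5' sequences appended to every gene-specific primer so a
#' single biotinylated forward / phosphorylated reverse primer pair drives
#' the bulk PCR, plus the blocker oligo that prevents the universal forward
#' primer from binding the array probes.
#'
#' @return Named character vector: `forward`, `reverse`, `blocker`.
#' @export
universal_tails <- function() {
  c(forward = "CGCTGCCAACTACCGCACATC",
    reverse = "GGAGCACGCTATCCCGTTAGAC",
    blocker = "GATGTGCGGTAGTTGGCAGCG")
}

#' Multiplex design constraints
#'
#' The assay's design rules: ~150 nt amplicons with ~50\% GC, gene-specific
#' primers of 22-38 nt with similar melting temperatures, at least one
#' primer crossing an exon junction on multi-exon transcripts (guards
#' against genomic DNA amplification), a restricted 3'-end alphabet on the
#' forward primer (at most two distinct nucleotides over the last few
#' bases, limiting primer-dimer formation), no stable hairpins in the
#' tailed primers, no exact k-mer homology with other panel amplicons, and
#' a probe of uniform melting temperature centered in the amplicon.
#'
#' @param amplicon_len_target,amplicon_len_tol Amplicon length target and
#'   half-width (nt).
#' @param gc_window Acceptable GC fraction range of the amplicon.
#' @param primer_len Gene-specific primer length range (nt).
#' @param tm_target Target primer melting temperature (degrees C).
#' @param tm_tolerance Maximum Tm difference between the two primers
#'   (degrees C).
#' @param junction_min_overhang Minimum bases on each side of a crossed
#'   exon junction (nt).
#' @param three_prime_window Length of the 3'-end window checked for the
#'   restricted alphabet (nt).
#' @param three_prime_max_alphabet Maximum distinct nucleotides allowed in
#'   that window.
#' @param require_three_prime Enforce the 3'-alphabet rule instead of
#'   using it as a preference (the rule holds only "when possible").
#' @param hairpin_stem_max Maximum tolerated self-complementary stem (bp).
#' @param hairpin_loop_min Minimum unpaired loop between stem arms (nt).
#' @param probe_len Probe length (nt).
#' @param probe_tm_tolerance Probe Tm tolerance around `tm_target`
#'   (degrees C).
#' @param cross_k Exact-match k-mer length for the cross-homology screen.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(amplicon_len_target = 150,
                               amplicon_len_tol = 10,
                               gc_window = c(0.45, 0.55),
                               primer_len = c(22, 38),
                               tm_target = 60, tm_tolerance = 3,
                               junction_min_overhang = 5,
                               three_prime_window = 5,
                               three_prime_max_alphabet = 2,
                               require_three_prime = FALSE,
                               hairpin_stem_max = 6, hairpin_loop_min = 3,
                               probe_len = 25, probe_tm_tolerance = 5,
                               cross_k = 15) {
  .assert(amplicon_len_target > 0 && amplicon_len_tol >= 0 &&
            gc_window[1] <= gc_window[2] && primer_len[1] <= primer_len[2],
          "invalid constraint ranges")
  structure(list(amplicon_len_target = amplicon_len_target,
                 amplicon_len_tol = amplicon_len_tol,
                 gc_window = gc_window, primer_len = primer_len,
                 tm_target = tm_target, tm_tolerance = tm_tolerance,
                 junction_min_overhang = junction_min_overhang,
                 three_prime_window = three_prime_window,
                 three_prime_max_alphabet = three_prime_max_alphabet,
                 require_three_prime = require_three_prime,
                 hairpin_stem_max = hairpin_stem_max,
                 hairpin_loop_min = hairpin_loop_min,
                 probe_len = probe_len,
                 probe_tm_tolerance = probe_tm_tolerance,
                 cross_k = cross_k),
            class = "design_constraints")
}

#' @noRd
.check_acgt <- function(seq) {
  .assert(is.character(seq) && length(seq) == 1L && nchar(seq) > 0,
          "sequence must be a single nonempty string")
  .assert(grepl("^[ACGT]+$", seq), "sequence must be over {A,C,G,T}")
}

#' @noRd
.revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' @noRd
.gc_frac <- function(seq) {
  vapply(strsplit(seq, ""), function(ch) mean(ch %in% c("G", "C")),
         numeric(1))
}

#' Transcript record for panel design
#'
#' A transcript sequence with its exon structure in transcript coordinates
#' (0-based, half-open): exon i spans `[sum(len[1:(i-1)]), sum(len[1:i]))`.
#' `universal_exons` flags exons shared by all known isoforms of the gene;
#' amplicons confined to universal exons amplify every isoform.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param sequence Nucleotide string over {A,C,G,T}.
#' @param exon_lengths Exon lengths in nt, summing to the sequence length;
#'   default a single exon.
#' @param universal_exons Logical flag per exon (default all `TRUE`).
#' @return An object of class `transcript_record` with derived internal
#'   `boundaries` (junction positions).
#' @export
transcript_record <- function(gene_id, transcript_id, sequence,
                              exon_lengths = NULL, universal_exons = NULL) {
  sequence <- toupper(sequence)
  .check_acgt(sequence)
  n <- nchar(sequence)
  exon_lengths <- exon_lengths %||% n
  .assert(all(exon_lengths > 0) && sum(exon_lengths) == n,
          "exon lengths must be positive and sum to the sequence length")
  universal_exons <- universal_exons %||% rep(TRUE, length(exon_lengths))
  .assert(length(universal_exons) == length(exon_lengths),
          "one universal flag per exon")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 sequence = sequence, exon_lengths = exon_lengths,
                 boundaries = utils::head(cumsum(exon_lengths), -1L),
                 universal_exons = universal_exons),
            class = "transcript_record")
}

#' Scan a transcript for candidate amplicon windows
#'
#' Every window whose length is within the tolerance of the target and
#' whose GC fraction falls in the GC window, annotated with isoform
#' universality (window fully inside exons shared by all isoforms) and
#' whether it spans an exon junction.
#'
#' @param transcript A [transcript_record()].
#' @param constraints A [design_constraints()].
#' @return data.frame: `start`, `end` (0-based half-open), `length`, `gc`,
#'   `universal`, `crosses_junction`.
#' @export
scan_amplicons <- function(transcript, constraints = design_constraints()) {
  stopifnot(inherits(transcript, "transcript_record"))
  seq <- transcript$sequence
  n <- nchar(seq)
  lmin <- constraints$amplicon_len_target - constraints$amplicon_len_tol
  lmax <- constraints$amplicon_len_target + constraints$amplicon_len_tol
  if (n < lmin)
    stop("sequence shorter than the minimum amplicon length", call. = FALSE)
  is_gc <- cumsum(c(0, strsplit(seq, "")[[1]] %in% c("G", "C")))
  exon_of <- findInterval(seq_len(n) - 1L, c(0, cumsum(transcript$exon_lengths)),
                          rightmost.closed = FALSE)
  rows <- list()
  for (len in seq(lmin, min(lmax, n))) {
    starts <- 0:(n - len)
    gc <- (is_gc[starts + len + 1L] - is_gc[starts + 1L]) / len
    ok <- gc >= constraints$gc_window[1] & gc <= constraints$gc_window[2]
    if (!any(ok)) next
    starts <- starts[ok]; gc <- gc[ok]
    universal <- vapply(starts, function(s) {
      ex <- unique(exon_of[(s + 1L):(s + len)])
      all(transcript$universal_exons[ex])
    }, logical(1))
    crosses <- vapply(starts, function(s)
      any(transcript$boundaries > s & transcript$boundaries < s + len),
      logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts, end = starts + len, length = len, gc = gc,
      universal = universal, crosses_junction = crosses)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc = numeric(0),
                      universal = logical(0), crosses_junction = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$length), , drop = FALSE]
}

# SantaLucia (1998) unified nearest-neighbor parameters; dH kcal/mol,
# dS cal/(mol K).  Antiparallel-complement stacks share entries.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor Tm with the SantaLucia (1998) unified
#' parameter set, terminal initiation corrections, an entropic salt
#' correction of `0.368 (N-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`. Default conditions:
#' 50 mM monovalent salt, 250 nM total oligo. Deterministic; vectorized
#' over sequences.
#'
#' @param seq Character vector of primer sequences (length >= 8 each).
#' @param na_mM Monovalent cation concentration (mM).
#' @param oligo_nM Total oligo concentration (nM).
#' @return Melting temperature(s) in degrees C.
#' @export
melting_temp <- function(seq, na_mM = 50, oligo_nM = 250) {
  vapply(seq, function(s) {
    s <- toupper(s)
    .check_acgt(s)
    n <- nchar(s)
    .assert(n >= 8, "sequence must be at least 8 nt for a stable duplex Tm")
    ch <- strsplit(s, "")[[1]]
    stacks <- paste0(ch[-n], ch[-1])
    dh <- sum(.NN_DH[stacks])
    ds <- sum(.NN_DS[stacks])
    for (term in ch[c(1, n)]) {
      if (term %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
      else                       { dh <- dh + 0.1; ds <- ds - 2.8 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
    1000 * dh / (ds + 1.987 * log(oligo_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Does a primer cross an exon junction?
#'
#' TRUE iff the primer interval `[start, end)` (0-based transcript
#' coordinates) spans at least one exon boundary with at least
#' `min_overhang` bases on each side of it.
#'
#' @param start,end Primer interval, 0-based half-open.
#' @param boundaries Internal exon boundary positions of the transcript
#'   (as in a [transcript_record()]'s `boundaries`).
#' @param min_overhang Minimum anchored bases per side (nt).
#' @return Logical flag.
#' @export
junction_check <- function(start, end, boundaries, min_overhang = 5) {
  .assert(end > start, "empty primer interval")
  any(boundaries >= start + min_overhang & boundaries <= end - min_overhang)
}

#' Restricted 3'-end alphabet check
#'
#' TRUE iff the last `window` bases of the primer use at most
#' `max_alphabet` distinct nucleotides (a two-letter 3' end limits
#' primer-dimer formation between pooled forward primers).
#'
#' @param primer Primer sequence.
#' @param window 3'-end window length (nt, at most the primer length).
#' @param max_alphabet Maximum distinct nucleotides.
#' @return Logical flag.
#' @export
three_prime_alphabet_check <- function(primer, window = 5,
                                       max_alphabet = 2) {
  .check_acgt(primer)
  .assert(window <= nchar(primer), "window exceeds primer length")
  tail_seq <- substring(primer, nchar(primer) - window + 1L, nchar(primer))
  length(unique(strsplit(tail_seq, "")[[1]])) <= max_alphabet
}

#' Hairpin screen on a (tailed) primer
#'
#' Finds the longest antiparallel self-complementary stem separated by at
#' least `loop_min` unpaired bases; primers whose worst stem exceeds
#' `stem_max` can fold into stable hairpins and are rejected. The search
#' is combinatorial (base-pair counting), not thermodynamic.
#'
#' @param seq Oligo sequence.
#' @param stem_max Maximum tolerated stem length (bp).
#' @param loop_min Minimum loop length (nt).
#' @return List: `worst_stem` (bp) and `pass`.
#' @export
hairpin_screen <- function(seq, stem_max = 6, loop_min = 3) {
  .check_acgt(seq)
  ch <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  n <- length(ch)
  worst <- 0L
  for (i in seq_len(n)) {
    j0 <- i + loop_min + 1L
    if (j0 > n) break
    for (j in j0:n) {
      if (ch[j] != comp[[ch[i]]]) next
      len <- 1L
      while (i + len <= n && j - len >= 1L &&
             (j - len) - (i + len) - 1L >= loop_min &&
             ch[j - len] == comp[[ch[i + len]]]) len <- len + 1L
      if (len > worst) worst <- len
    }
  }
  list(worst_stem = worst, pass = worst <= stem_max)
}

#' Cross-homology screen against the rest of the panel
#'
#' Reports exact k-mers (either strand) shared between an amplicon and any
#' non-target transcript of the panel; shared k-mers mark regions that
#' could cross-amplify or cross-hybridize.
#'
#' @param amplicon Amplicon sequence.
#' @param gene_id Gene the amplicon belongs to (its own transcripts are
#'   excluded).
#' @param transcripts List of [transcript_record()]s (the panel).
#' @param k Exact-match k-mer length.
#' @return data.frame: `other_gene`, `kmer`, `amplicon_pos` (0-based),
#'   `strand`; zero rows when the amplicon is panel-specific.
#' @export
cross_homology_screen <- function(amplicon, gene_id, transcripts, k = 15) {
  .check_acgt(amplicon)
  .assert(length(transcripts) > 0, "panel must be nonempty")
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  fwd <- kmers_of(amplicon)
  rev <- kmers_of(.revcomp(amplicon))
  hits <- list()
  for (tr in transcripts) {
    if (tr$gene_id == gene_id) next
    targ <- unique(kmers_of(tr$sequence))
    for (strand in c("+", "-")) {
      q <- if (strand == "+") fwd else rev
      m <- which(q %in% targ)
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          other_gene = tr$gene_id, kmer = q[m], amplicon_pos = m - 1L,
          strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(other_gene = character(0), kmer = character(0),
                      amplicon_pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Design a hybridization probe inside an amplicon
#'
#' Chooses the probe window whose center is nearest the amplicon center
#' among windows with melting temperature within `tolerance` of
#' `tm_target` (the detection probes hybridize near the center of the
#' amplicons and have uniform Tm).
#'
#' @param amplicon Amplicon sequence.
#' @param tm_target Target probe Tm (degrees C).
#' @param tolerance Tm tolerance (degrees C).
#' @param probe_len Probe length (nt).
#' @return List: `seq`, `start`, `end` (0-based within the amplicon),
#'   `tm`. Errors (reporting the best candidate) when no window meets the
#'   Tm requirement.
#' @export
design_probe <- function(amplicon, tm_target = 60, tolerance = 5,
                         probe_len = 25) {
  .check_acgt(amplicon)
  n <- nchar(amplicon)
  .assert(n >= probe_len, "amplicon shorter than the probe")
  starts <- 0:(n - probe_len)
  center_dist <- abs((starts + probe_len / 2) - n / 2)
  ord <- order(center_dist, starts)
  best <- NULL
  for (s in starts[ord]) {
    sq <- substring(amplicon, s + 1L, s + probe_len)
    tm <- melting_temp(sq)
    if (is.null(best) || abs(tm - tm_target) < abs(best$tm - tm_target))
      best <- list(seq = sq, start = s, end = s + probe_len, tm = tm)
    if (abs(tm - tm_target) <= tolerance)
      return(list(seq = sq, start = s, end = s + probe_len, tm = tm))
  }
  stop(sprintf(
    "no probe window within %.1f degrees C of %.1f; best candidate %s (Tm %.1f)",
    tolerance, tm_target, best$seq, best$tm), call. = FALSE)
}

#' @noRd
.best_primer <- function(candidates, tm_target) {
  tms <- melting_temp(candidates)
  i <- order(abs(tms - tm_target), nchar(candidates))[1]
  list(seq = candidates[i], tm = tms[i])
}

# Build and check one primer set on a given amplicon window.  Returns NULL
# with a reason attribute on failure.
#' @noRd
.build_primer_set <- function(transcript, w, constraints, transcripts) {
  seq <- transcript$sequence
  amp <- substring(seq, w$start + 1L, w$end)
  lens <- constraints$primer_len[1]:min(constraints$primer_len[2], nchar(amp))
  fwd <- .best_primer(substring(amp, 1L, lens), constraints$tm_target)
  rev <- .best_primer(.revcomp(substring(amp, nchar(amp) - lens + 1L,
                                         nchar(amp))),
                      constraints$tm_target)
  fail <- function(reason) structure(list(), failed = reason)
  checks <- c(amplicon_gc = TRUE, amplicon_length = TRUE)   # by construction
  if (abs(fwd$tm - rev$tm) > constraints$tm_tolerance)
    return(fail("tm_mismatch"))
  checks["tm_similar"] <- TRUE
  f_start <- w$start; f_end <- w$start + nchar(fwd$seq)
  r_start <- w$end - nchar(rev$seq); r_end <- w$end
  three_ok <- three_prime_alphabet_check(
    fwd$seq, constraints$three_prime_window,
    constraints$three_prime_max_alphabet)
  if (constraints$require_three_prime && !three_ok)
    return(fail("three_prime"))
  checks["three_prime"] <- three_ok || !constraints$require_three_prime
  if (length(transcript$boundaries)) {
    jc <- junction_check(f_start, f_end, transcript$boundaries,
                         constraints$junction_min_overhang) ||
      junction_check(r_start, r_end, transcript$boundaries,
                     constraints$junction_min_overhang)
    if (!jc) return(fail("junction"))
    checks["junction"] <- TRUE
  }
  tails <- universal_tails()
  tailed_f <- paste0(tails[["forward"]], fwd$seq)
  tailed_r <- paste0(tails[["reverse"]], rev$seq)
  hp_f <- hairpin_screen(tailed_f, constraints$hairpin_stem_max,
                         constraints$hairpin_loop_min)
  hp_r <- hairpin_screen(tailed_r, constraints$hairpin_stem_max,
                         constraints$hairpin_loop_min)
  if (!hp_f$pass || !hp_r$pass) return(fail("hairpin"))
  checks["hairpin"] <- TRUE
  if (length(transcripts) > 1) {
    hits <- cross_homology_screen(amp, transcript$gene_id, transcripts,
                                  constraints$cross_k)
    if (nrow(hits)) return(fail("cross_homology"))
    checks["cross_homology"] <- TRUE
  }
  probe <- tryCatch(
    design_probe(amp, constraints$tm_target,
                 constraints$probe_tm_tolerance, constraints$probe_len),
    error = function(e) NULL)
  if (is.null(probe)) return(fail("probe_tm"))
  checks["probe"] <- TRUE
  structure(list(
    gene_id = transcript$gene_id,
    forward = list(seq = fwd$seq, start = f_start, end = f_end, tm = fwd$tm),
    reverse = list(seq = rev$seq, start = r_start, end = r_end, tm = rev$tm),
    tailed_forward = tailed_f, tailed_reverse = tailed_r,
    probe = list(seq = probe$seq, start = w$start + probe$start,
                 end = w$start + probe$end, tm = probe$tm),
    amplicon = list(seq = amp, start = w$start, end = w$end,
                    length = nchar(amp), gc = .gc_frac(amp)),
    three_prime_ok = three_ok, universal = w$universal,
    checks = checks), class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set %s: amplicon [%d,%d) %dnt GC %.2f; Tm F/R/probe %.1f/%.1f/%.1f\n",
              x$gene_id, x$amplicon$start, x$amplicon$end,
              x$amplicon$length, x$amplicon$gc,
              x$forward$tm, x$reverse$tm, x$probe$tm))
  invisible(x)
}

#' Re-validate an emitted primer set against the constraints
#'
#' Recomputes every enabled constraint from the stored sequences and
#' coordinates; emitted sets must pass all of them (idempotence of the
#' design checks).
#'
#' @param ps A `primer_set`.
#' @param transcript The [transcript_record()] it was designed on.
#' @param constraints A [design_constraints()].
#' @param transcripts Optional panel for the cross-homology re-check.
#' @return Named logical vector of check results.
#' @export
validate_primer_set <- function(ps, transcript,
                                constraints = design_constraints(),
                                transcripts = NULL) {
  stopifnot(inherits(ps, "primer_set"))
  amp <- ps$amplicon
  tails <- universal_tails()
  res <- c(
    amplicon_length = abs(amp$length - constraints$amplicon_len_target) <=
      constraints$amplicon_len_tol,
    amplicon_gc = amp$gc >= constraints$gc_window[1] &&
      amp$gc <= constraints$gc_window[2],
    amplicon_matches_transcript = identical(
      amp$seq, substring(transcript$sequence, amp$start + 1L, amp$end)),
    primer_lengths = all(c(nchar(ps$forward$seq), nchar(ps$reverse$seq)) >=
                           constraints$primer_len[1]) &&
      all(c(nchar(ps$forward$seq), nchar(ps$reverse$seq)) <=
            constraints$primer_len[2]),
    primers_span_amplicon = ps$forward$start == amp$start &&
      ps$reverse$end == amp$end,
    probe_inside_amplicon = ps$probe$start >= amp$start &&
      ps$probe$end <= amp$end,
    tm_similar = abs(ps$forward$tm - ps$reverse$tm) <=
      constraints$tm_tolerance,
    probe_tm = abs(ps$probe$tm - constraints$tm_target) <=
      constraints$probe_tm_tolerance,
    tails_universal = startsWith(ps$tailed_forward, tails[["forward"]]) &&
      startsWith(ps$tailed_reverse, tails[["reverse"]]) &&
      endsWith(ps$tailed_forward, ps$forward$seq) &&
      endsWith(ps$tailed_reverse, ps$reverse$seq),
    hairpin = hairpin_screen(ps$tailed_forward, constraints$hairpin_stem_max,
                             constraints$hairpin_loop_min)$pass &&
      hairpin_screen(ps$tailed_reverse, constraints$hairpin_stem_max,
                     constraints$hairpin_loop_min)$pass)
  if (length(transcript$boundaries)) {
    res["junction"] <-
      junction_check(ps$forward$start, ps$forward$end,
                     transcript$boundaries,
                     constraints$junction_min_overhang) ||
      junction_check(ps$reverse$start, ps$reverse$end,
                     transcript$boundaries,
                     constraints$junction_min_overhang)
  }
  if (constraints$require_three_prime) {
    res["three_prime"] <- three_prime_alphabet_check(
      ps$forward$seq, constraints$three_prime_window,
      constraints$three_prime_max_alphabet)
  }
  if (!is.null(transcripts) && length(transcripts) > 1) {
    res["cross_homology"] <- nrow(cross_homology_screen(
      amp$seq, ps$gene_id, transcripts, constraints$cross_k)) == 0
  }
  res
}

#' Assemble primer/probe candidates for a panel of transcripts
#'
#' For each gene, scans the amplicon windows in preference order (isoform
#' universality, GC closeness to 50\%, position), builds a primer set per
#' window, and keeps up to `n_candidates` non-overlapping sets that pass
#' every enabled check, preferring candidates that satisfy the 3'-alphabet
#' rule. Per-gene failures are reported, not raised.
#'
#' @param transcripts List of [transcript_record()]s, one per gene.
#' @param constraints A [design_constraints()].
#' @param n_candidates Maximum candidate sets per gene.
#' @param max_windows Maximum windows evaluated per gene (search budget).
#' @return List per gene: `candidates` (list of `primer_set`s) and
#'   `failures` (named counts of rejection reasons).
#' @export
assemble_panel <- function(transcripts, constraints = design_constraints(),
                           n_candidates = 3, max_windows = 1000) {
  ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  .assert(!anyDuplicated(ids), "one transcript record per gene expected")
  out <- list()
  for (tr in transcripts) {
    windows <- tryCatch(scan_amplicons(tr, constraints),
                        error = function(e) NULL)
    if (is.null(windows) || !nrow(windows)) {
      out[[tr$gene_id]] <- list(candidates = list(),
                                failures = c(no_gc_window = 1L))
      next
    }
    ord <- order(!windows$universal, abs(windows$gc - 0.5), windows$start)
    windows <- windows[ord, , drop = FALSE]
    select_nonoverlap <- function(valid) {
      pref <- order(!vapply(valid, function(p) p$three_prime_ok, logical(1)),
                    abs(vapply(valid, function(p) p$amplicon$gc, numeric(1)) -
                          0.5))
      chosen <- list()
      for (p in valid[pref]) {
        overlap <- any(vapply(chosen, function(q)
          p$amplicon$start < q$amplicon$end &&
            q$amplicon$start < p$amplicon$end, logical(1)))
        if (!overlap) chosen[[length(chosen) + 1L]] <- p
        if (length(chosen) >= n_candidates) break
      }
      chosen
    }
    valid <- list()
    failures <- integer(0)
    n_eval <- 0L
    full_at <- NA_integer_
    chosen <- list()
    for (i in seq_len(nrow(windows))) {
      if (n_eval >= max_windows) break
      # once the selection is full, scan a bounded lookahead for windows
      # that would upgrade it to full 3'-compliance, then stop
      if (!is.na(full_at) && n_eval - full_at >= 200L) break
      n_eval <- n_eval + 1L
      ps <- .build_primer_set(tr, windows[i, ], constraints, transcripts)
      if (!is.null(attr(ps, "failed"))) {
        reason <- attr(ps, "failed")
        prev <- if (reason %in% names(failures)) failures[[reason]] else 0L
        failures[reason] <- prev + 1L
        next
      }
      valid[[length(valid) + 1L]] <- ps
      # stop once the non-overlapping selection is full with 3'-compliant
      # sets; otherwise keep scanning within the window budget
      chosen <- select_nonoverlap(valid)
      if (length(chosen) >= n_candidates) {
        if (all(vapply(chosen, function(p) p$three_prime_ok, logical(1))))
          break
        if (is.na(full_at)) full_at <- n_eval
      }
    }
    out[[tr$gene_id]] <- list(candidates = chosen, failures = failures)
  }
  out
}
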