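test_that("amplicon scanning filters on GC and annotates isoform coverage", {
  # 300 nt: alternating GC/AT halves
  seq <- paste0(paste(rep("GCAT", 50), collapse = ""),   # GC = 0.5
                paste(rep("AT", 50), collapse = ""))     # GC = 0
  tr <- transcript_record("g", "t", seq)
  w <- scan_amplicons(tr, design_constraints(amplicon_len_tol = 0))
  expect_true(all(w$length == 150))
  expect_true(all(w$gc >= 0.45 & w$gc <= 0.55))
  expect_true(any(w$start == 0))                 # pure GCAT window retained
  expect_false(any(w$start > 130))               # AT-rich windows rejected
  # isoform-specific exon marks overlapping windows as non-universal
  tr2 <- transcript_record("g", "t", seq, exon_lengths = c(100, 200),
                           universal_exons = c(TRUE, FALSE))
  w2 <- scan_amplicons(tr2, design_constraints(amplicon_len_tol = 0))
  expect_true(all(!w2$universal[w2$end > 100]))
  expect_true(all(w2$universal[w2$end <= 100]))
  expect_error(scan_amplicons(transcript_record("g", "t", "ACGTACGT")),
               "shorter")
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  # frozen oracle values from a second implementation of the SantaLucia
  # unified tables under identical conditions (50 mM Na+, 250 nM oligo)
  expect_equal(melting_temp("AGCTGACCTGAAGGCTCATTGCGTA"),
               62.0538272924432, tolerance = 0.5)
  expect_equal(melting_temp("ACGTACGTACGTACGTACGTACGT"),
               59.494468639462525, tolerance = 0.5)
  expect_equal(melting_temp("CGCTGCCAACTACCGCACATC"),
               60.825776162674174, tolerance = 0.5)
  # duplex symmetry: a sequence and its reverse complement share a Tm
  s <- "AGCTGACCTGAAGGCTCATTGCGTA"
  rc <- ctcpanel:::.revcomp(s)
  expect_equal(melting_temp(s), melting_temp(rc), tolerance = 1e-9)
  # appending GC-rich bases never lowers Tm on a fixture set
  base <- "ATGCATGCATGCATGCAT"
  grown <- vapply(0:6, function(k)
    melting_temp(paste0(base, strrep("GC", k))), numeric(1))
  expect_true(all(diff(grown) > 0))
  expect_error(melting_temp("ACGTN$"), "A,C,G,T")
  expect_error(melting_temp("ACGT"), "at least 8")
})

test_that("junction crossing requires the minimum overhang on both sides", {
  b <- 100
  expect_false(junction_check(10, 40, b, 5))              # inside one exon
  expect_true(junction_check(b - 5, b + 5, b, 5))         # exactly anchored
  expect_false(junction_check(b - 4, b + 5, b, 5))        # one side short
  expect_false(junction_check(b - 5, b + 4, b, 5))
  expect_true(junction_check(80, 130, c(50, 100, 200), 5))
  expect_false(junction_check(80, 130, numeric(0), 5))    # single exon
})

test_that("the 3'-alphabet rule counts distinct bases in the end window", {
  expect_true(three_prime_alphabet_check("GGGGGGCCATATA", 5))   # {A,T}
  expect_false(three_prime_alphabet_check("GGGGGGCCACGTA", 5))  # 4 letters
  expect_true(three_prime_alphabet_check("GGGGGGCCACGTA", 1))   # window 1
  expect_false(three_prime_alphabet_check("AAAAAAAACGT", 3, 2))
  expect_error(three_prime_alphabet_check("ACGTACGT", 9), "window")
})

test_that("the hairpin screen finds the longest self-complementary stem", {
  expect_equal(hairpin_screen(strrep("A", 30))$worst_stem, 0)
  expect_true(hairpin_screen(strrep("A", 30))$pass)
  # constructed hairpin: X + loop + revcomp(X) with |X| = stem_max + 1
  X <- "GCATCGA"
  hp <- paste0("AAAA", X, "TTTT", ctcpanel:::.revcomp(X), "AAAA")
  res <- hairpin_screen(hp, stem_max = 6)
  expect_gte(res$worst_stem, 7)
  expect_false(res$pass)
  # random 40-mers agree exactly with the exhaustive O(n^3) oracle
  for (i in 1:8) {
    s <- random_dna(40, 0.5, seed = 400 + i)
    expect_equal(hairpin_screen(s)$worst_stem, hairpin_oracle(s),
                 info = paste("seed", 400 + i))
  }
})

test_that("cross-homology reports shared k-mers on either strand, self excluded", {
  amp <- random_dna(150, 0.5, seed = 51)
  other <- random_dna(400, 0.5, seed = 52)
  panel <- list(transcript_record("ME", "t1", amp),
                transcript_record("OTHER", "t2", other))
  # an amplicon never hits its own gene
  expect_equal(nrow(cross_homology_screen(amp, "ME", panel)), 0)
  # a copied 20 nt block is found at its position
  block <- substr(amp, 61, 80)
  panel2 <- list(transcript_record("ME", "t1", amp),
                 transcript_record("OTHER", "t2",
                                   paste0(other, block, other)))
  hits <- cross_homology_screen(amp, "ME", panel2)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$other_gene == "OTHER"))
  expect_true(60 %in% hits$amplicon_pos)
  # reverse-complement homology is also caught
  panel3 <- list(transcript_record("ME", "t1", amp),
                 transcript_record("OTHER", "t2",
                                   paste0(other, ctcpanel:::.revcomp(block))))
  expect_true(any(cross_homology_screen(amp, "ME", panel3)$strand == "-"))
})

test_that("probes are centered subject to the Tm constraint", {
  amp <- paste(rep("GCAT", 40), collapse = "")   # uniform composition
  pr <- design_probe(amp, tm_target = melting_temp(substr(amp, 1, 25)),
                     tolerance = 3, probe_len = 25)
  expect_equal(pr$start, (160 - 25) %/% 2)       # exactly centered
  # unreachable Tm errors and names the best candidate
  expect_error(design_probe(amp, tm_target = 95, tolerance = 1), "best candidate")
  # chosen window matches a full-enumeration oracle
  amp2 <- random_dna(150, 0.5, seed = 61)
  tol <- 2; target <- 62
  pr2 <- design_probe(amp2, target, tol)
  starts <- 0:(150 - 25)
  tms <- melting_temp(substring(amp2, starts + 1, starts + 25))
  feas <- starts[abs(tms - target) <= tol]
  oracle <- feas[order(abs(feas + 12.5 - 75), feas)][1]
  expect_equal(pr2$start, oracle)
})

test_that("assembled panels pass every constraint and honor the tails", {
  tr <- fixture_transcript()
  des <- assemble_panel(list(tr))
  cands <- des$FIX1$candidates
  # the three-region fixture admits exactly three non-overlapping sets
  expect_length(cands, 3)
  tails <- universal_tails()
  for (ps in cands) {
    expect_s3_class(ps, "primer_set")
    expect_true(startsWith(ps$tailed_forward, tails[["forward"]]))
    expect_true(startsWith(ps$tailed_reverse, tails[["reverse"]]))
    # re-validation idempotence: every enabled check still passes
    expect_true(all(validate_primer_set(ps, tr, transcripts = list(tr))))
    # structural invariants
    expect_true(ps$probe$start >= ps$amplicon$start &&
                  ps$probe$end <= ps$amplicon$end)
    expect_true(nchar(ps$forward$seq) >= 22 && nchar(ps$forward$seq) <= 38)
    expect_true(nchar(ps$reverse$seq) >= 22 && nchar(ps$reverse$seq) <= 38)
    expect_true(abs(ps$amplicon$length - 150) <= 10)
  }
  # non-overlap
  starts <- sort(vapply(cands, function(p) p$amplicon$start, numeric(1)))
  ends <- sort(vapply(cands, function(p) p$amplicon$end, numeric(1)))
  expect_true(all(starts[-1] >= ends[-3]))
  # determinism
  des2 <- assemble_panel(list(tr))
  expect_identical(lapply(des$FIX1$candidates, unclass),
                   lapply(des2$FIX1$candidates, unclass))
  # an all-AT transcript yields no candidates with a GC failure reported
  at <- transcript_record("ATGENE", "t", strrep("AT", 100))
  res <- assemble_panel(list(at))
  expect_length(res$ATGENE$candidates, 0)
  expect_true("no_gc_window" %in% names(res$ATGENE$failures))
})

test_that("junction-spanning designs are enforced on multi-exon transcripts", {
  # two exons; force every valid amplicon to straddle the boundary
  core <- random_dna(180, 0.5, seed = 71)
  seq <- paste0(strrep("AT", 30), core, strrep("AT", 30))
  tr <- transcript_record("JX", "t", seq, exon_lengths = c(150, 150))
  des <- assemble_panel(list(tr), n_candidates = 1)
  if (length(des$JX$candidates)) {
    ps <- des$JX$candidates[[1]]
    crossed <- junction_check(ps$forward$start, ps$forward$end, 150, 5) ||
      junction_check(ps$reverse$start, ps$reverse$end, 150, 5)
    expect_true(crossed)
  } else {
    expect_true("junction" %in% names(des$JX$failures))
  }
})

test_that("transcripts round-trip through FASTA and exon BED", {
  tr <- fixture_transcript()
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  writeLines(c(sprintf(">%s gene=%s", tr$transcript_id, tr$gene_id),
               tr$sequence), fa)
  writeLines(sprintf("%s\t%d\t%d\texon%d\t%d", tr$transcript_id,
                     c(0, 500), c(500, nchar(tr$sequence)), 1:2, c(1, 0)),
             bed)
  back <- read_transcripts(fa, bed)
  expect_length(back, 1)
  expect_equal(back[[1]]$gene_id, "FIX1")
  expect_equal(back[[1]]$sequence, tr$sequence)
  expect_equal(back[[1]]$exon_lengths, c(500, nchar(tr$sequence) - 500))
  expect_equal(back[[1]]$universal_exons, c(TRUE, FALSE))
  expect_equal(back[[1]]$boundaries, 500)
})
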