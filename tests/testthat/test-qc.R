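test_that("theoretical coverage is count x mean length over genome size", {
  expect_equal(theoretical_coverage(1, 3e9, 3e9), 1)
  expect_equal(round(theoretical_coverage(309879, 285000, 3.0e9), 1), 29.4)
  expect_error(theoretical_coverage(100, 285000, 0), "genome_size")
})

test_that("yield counts whole lengths of uniquely aligned molecules", {
  rows <- list(
    aln_row("m:1", matched = 10, missed = 2, mol_length = 300000,
            unique = TRUE),
    aln_row("m:2", matched = 10, missed = 2, mol_length = 100000,
            unique = TRUE),
    aln_row("m:3", mol_length = 400000, unique = FALSE))
  aln <- make_alignments(rows)
  # half the total molecule length (400k of 800k) is aligned
  expect_equal(yield_coverage(aln, 4e6), 0.1)
  none <- make_alignments(list(aln_row("m:1", mol_length = 1e5,
                                       unique = FALSE)))
  expect_equal(yield_coverage(none, 4e6), 0)
})

test_that("digestion-rate estimator arithmetic (raw and corrected)", {
  one <- make_alignments(list(aln_row("m:1", matched = 6, missed = 4,
                                      mol_length = 2e5)))
  expect_equal(estimate_digestion_rate(one, exclude_delimiters = FALSE), 0.6)
  expect_equal(estimate_digestion_rate(one), 0.5)  # (6-2)/(10-2)
  # pooled, not averaged: two molecules pool their counts
  two <- make_alignments(list(
    aln_row("m:1", matched = 6, missed = 4, mol_length = 2e5),
    aln_row("m:2", matched = 9, missed = 1, mol_length = 2e5)))
  expect_equal(estimate_digestion_rate(two, exclude_delimiters = FALSE),
               15 / 20)
  unaligned <- make_alignments(list(aln_row("m:1", unique = FALSE)))
  expect_error(estimate_digestion_rate(unaligned), "no unique")
})

test_that("extra-cut estimator is false cuts per 100 kb of aligned length", {
  one <- make_alignments(list(aln_row("m:1", matched = 8, false = 3,
                                      mol_length = 300000)))
  expect_equal(estimate_extra_cut_rate(one), 1.0)
  clean <- make_alignments(list(aln_row("m:1", matched = 8, false = 0,
                                        mol_length = 300000)))
  expect_equal(estimate_extra_cut_rate(clean), 0)
})

test_that("small-missing ratio counts unmatched flanks of small fragments", {
  # contig with 8 fragments; fragments 2..5 (0-based) are <= 2 kb
  frags <- c(10000, 9000, 1500, 1800, 1200, 1900, 9500, 10000)
  rm_ <- refmap(builtin_enzymes("KpnI"),
                list(c1 = list(length = sum(frags),
                               cuts = cumsum(frags)[-length(frags)])))
  # span covers fragments 1..6 inclusive -> delimiting cuts 2 and 6;
  # interior small fragments 2,3,4,5 flanked by cuts (2,3),(3,4),(4,5),(5,6);
  # leaving cut 4 unmatched makes fragments 3 and 4 missing
  row <- aln_row("m:1", matched = 4, missed = 1, mol_length = 4e4,
                 span = c(1L, 7L))
  aln <- make_alignments(list(row), list(c(2L, 3L, 5L, 6L)))
  expect_equal(small_missing_ratio(aln, rm_), 2 / 4)
  # all interior cuts matched -> nothing missing
  aln2 <- make_alignments(list(aln_row("m:1", matched = 5, missed = 0,
                                       mol_length = 4e4, span = c(1L, 7L))),
                          list(2:6))
  expect_equal(small_missing_ratio(aln2, rm_), 0)
  # no small fragments inside any span -> NA, not zero
  aln3 <- make_alignments(list(aln_row("m:1", matched = 1, missed = 0,
                                       mol_length = 2e4, span = c(0L, 2L))),
                          list(1L))
  expect_true(is.na(small_missing_ratio(aln3, rm_)))
})

test_that("loss of small fragments raises the small-missing ratio", {
  rm_ <- synthetic_refmap(1e7, mean_frag = 6000, seed = 61)
  base_model <- error_model(p_small_loss = 0)
  loss_model <- error_model(p_small_loss = 0.5)
  r0 <- apply_filter(sample_molecules(rm_, base_model, 250, seed = 62))$rmaps
  r1 <- apply_filter(sample_molecules(rm_, loss_model, 250, seed = 62))$rmaps
  a0 <- align_all(r0, rm_)
  a1 <- align_all(r1, rm_)
  s0 <- small_missing_ratio(a0, rm_)
  s1 <- small_missing_ratio(a1, rm_)
  expect_gt(s1, s0)   # loss channel adds to the digestion-only baseline
  expect_lt(s1, 1)
})

test_that("qc_summarize groups by id prefix with an additive Total row", {
  rm_ <- synthetic_refmap(5e6, seed = 63)
  model <- error_model(p_small_loss = 0)
  g1 <- sample_molecules(rm_, model, 30, seed = 64, id_prefix = "cardA")
  g2 <- sample_molecules(rm_, model, 20, seed = 65, id_prefix = "cardB")
  rmaps <- c(g1, g2)
  aln <- align_all(rmaps, rm_)
  qc <- qc_summarize(rmaps, aln, rm_ = rm_, genome_size = 5e6)
  expect_equal(qc$group, c("cardA", "cardB", "Total"))
  expect_equal(qc$n_maps[3], sum(qc$n_maps[1:2]))
  expect_true(all(qc$yield_coverage <= qc$theoretical_coverage + 1e-12))
  # average fragment size is length-total over fragment-total
  expect_equal(qc$avg_fragment_kb[3],
               sum(vapply(rmaps, `[[`, numeric(1), "length")) /
                 sum(vapply(rmaps, function(r) length(r$fragments),
                            integer(1))) / 1000)
})

test_that("an unaligned-only dataset reports rate 0 and absent estimators", {
  rmaps <- list(make_rmap(rep(20000, 12), id = "solo:1"))
  aln <- make_alignments(list(aln_row("solo:1", mol_length = 240000,
                                      unique = FALSE)))
  qc <- qc_summarize(rmaps, aln, genome_size = 3e9)
  expect_equal(qc$alignment_rate, 0)
  expect_true(is.na(qc$digestion_rate))
  expect_true(is.na(qc$extra_cut_rate_per_100kb))
})

test_that("stricter filter (s) selects longer molecules than filter (r)", {
  rm_ <- synthetic_refmap(2e7, seed = 67)
  rmaps <- sample_molecules(rm_, error_model(), 400, seed = 68)
  r_set <- apply_filter(rmaps, filter_spec(10, 150000))$rmaps
  s_set <- apply_filter(rmaps, filter_spec(12, 250000))$rmaps
  mean_len <- function(x) mean(vapply(x, `[[`, numeric(1), "length"))
  expect_gt(mean_len(s_set), mean_len(r_set))
})

test_that("digestion estimator stays near truth as molecule count grows", {
  rm_ <- synthetic_refmap(1e7, seed = 71)
  model <- error_model(p_small_loss = 0)
  for (n in c(250, 1000)) {
    rmaps <- apply_filter(sample_molecules(rm_, model, n, seed = 72))$rmaps
    aln <- align_all(rmaps, rm_)
    expect_lt(abs(estimate_digestion_rate(aln) - 0.66), 0.04)
  }
})

test_that("QC writers emit rounded TSV and full-precision JSON", {
  rm_ <- synthetic_refmap(5e6, seed = 63)
  rmaps <- sample_molecules(rm_, error_model(p_small_loss = 0), 40, seed = 64)
  aln <- align_all(rmaps, rm_)
  qc <- qc_summarize(rmaps, aln, rm_ = rm_, genome_size = 5e6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_qc(qc, f)
  lines <- readLines(f)
  expect_match(lines[1], "^group\t")
  expect_equal(length(lines), nrow(qc) + 1L)
  fj <- withr::local_tempfile(fileext = ".json")
  write_qc(qc, fj, format = "json")
  back <- jsonlite::fromJSON(fj)
  expect_equal(back$digestion_rate, qc$digestion_rate, tolerance = 1e-12)
})
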