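noise_free <- function() error_model(p_digest = 1, lambda_false = 0,
                                     sizing_cv = 0, p_small_loss = 0)

test_that("with error channels off, fragments reproduce the reference", {
  rm_ <- synthetic_refmap(3e6, seed = 5)
  rmaps <- sample_molecules(rm_, noise_free(), n = 40, seed = 9)
  ct <- rm_$contigs[[1]]
  for (r in rmaps) {
    t <- r$truth
    frags <- if (t$orientation == "-") rev(r$fragments) else r$fragments
    expect_equal(sum(frags), t$end - t$start)
    cuts_in <- ct$cuts[ct$cuts > t$start & ct$cuts < t$end]
    if (length(cuts_in) >= 2) {
      interior <- frags[2:(length(frags) - 1)]
      expect_equal(interior, as.integer(diff(cuts_in)))
    }
  }
})

test_that("zero digestion yields single-fragment molecules", {
  rm_ <- synthetic_refmap(3e6, seed = 5)
  model <- error_model(p_digest = 0, lambda_false = 0, sizing_cv = 0,
                       p_small_loss = 0)
  rmaps <- sample_molecules(rm_, model, n = 20, seed = 3)
  expect_true(all(vapply(rmaps, function(r) length(r$fragments), integer(1)) == 1L))
  for (r in rmaps) expect_equal(r$length, r$truth$end - r$truth$start)
})

test_that("false-cut counts follow the configured Poisson rate", {
  rm_ <- synthetic_refmap(2e7, seed = 5)
  model <- error_model(p_digest = 1, lambda_false = 0.751, sizing_cv = 0,
                       p_small_loss = 0)
  rmaps <- sample_molecules(rm_, model, n = 2000, seed = 13)
  n_false <- sum(vapply(rmaps, function(r) length(r$truth$false_pos), integer(1)))
  total_len <- sum(vapply(rmaps, function(r)
    as.numeric(r$truth$end - r$truth$start), numeric(1)))
  rate <- n_false / total_len * 1e5
  se <- sqrt(0.751 * total_len / 1e5) / total_len * 1e5
  expect_lt(abs(rate - 0.751), 3 * se)
})

test_that("retained-cut fraction converges to p_digest", {
  rm_ <- synthetic_refmap(2e7, seed = 5)
  model <- error_model(p_digest = 0.66, lambda_false = 0, sizing_cv = 0,
                       p_small_loss = 0)
  rmaps <- sample_molecules(rm_, model, n = 1000, seed = 29)
  n_sites <- sum(vapply(rmaps, function(r) r$truth$n_sites, integer(1)))
  n_kept <- sum(vapply(rmaps, function(r) length(r$truth$true_cut_idx),
                       integer(1)))
  se <- sqrt(0.66 * 0.34 / n_sites)
  expect_lt(abs(n_kept / n_sites - 0.66), 3 * se)
})

test_that("small-fragment loss removes mass and is truth-tracked", {
  rm_ <- synthetic_refmap(1e7, mean_frag = 3000, seed = 5)
  model <- error_model(p_digest = 1, lambda_false = 0, sizing_cv = 0,
                       p_small_loss = 1)
  rmaps <- sample_molecules(rm_, model, n = 50, seed = 31)
  any_lost <- FALSE
  for (r in rmaps) {
    window <- r$truth$end - r$truth$start
    if (length(r$fragments) > 1L)
      expect_true(all(r$fragments > 2000))   # every retained small one is gone
    # deleted mass, not merged: total shrinks by what was lost
    expect_lte(r$length, window)
    if (r$truth$n_lost_small > 0L) {
      any_lost <- TRUE
      expect_lt(r$length, window)
    }
  }
  expect_true(any_lost)
})

test_that("the retention filter applies inclusive thresholds idempotently", {
  mk <- function(n_frag, total) make_rmap(rep(total / n_frag, n_frag))
  flt <- filter_spec(10, 150000)
  expect_equal(apply_filter(list(mk(9, 200000)), flt)$n_retained, 0L)
  expect_equal(apply_filter(list(mk(10, 150000)), flt)$n_retained, 1L)
  expect_equal(apply_filter(list(mk(10, 149999)), flt)$n_retained, 0L)
  out <- apply_filter(list(), flt)
  expect_equal(out$n_input, 0L)
  expect_equal(out$n_retained, 0L)

  rm_ <- synthetic_refmap(5e6, seed = 5)
  rmaps <- sample_molecules(rm_, error_model(), n = 100, seed = 11)
  once <- apply_filter(rmaps, flt)
  twice <- apply_filter(once$rmaps, flt)
  expect_identical(twice$rmaps, once$rmaps)
  expect_equal(twice$n_discarded, 0L)
})

test_that("Rmap TSV round-trips exactly, truth included", {
  rm_ <- synthetic_refmap(5e6, seed = 5)
  rmaps <- sample_molecules(rm_, error_model(), n = 3, seed = 17)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rmaps(rmaps, f, enzyme_name = "KpnI")
  back <- read_rmaps(f)
  expect_length(back, 3L)
  for (k in 1:3) {
    expect_identical(back[[k]]$fragments, rmaps[[k]]$fragments)
    expect_identical(back[[k]]$id, rmaps[[k]]$id)
    expect_equal(back[[k]]$truth[names(rmaps[[k]]$truth)], rmaps[[k]]$truth)
  }
  f2 <- withr::local_tempfile()
  write_rmaps(back, f2, enzyme_name = "KpnI")
  expect_identical(readLines(f2), readLines(f))
})

test_that("malformed Rmap files are rejected with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("#rmaps v1 enzyme=KpnI", "m:1\t2\t100\t0,100"), f)
  expect_error(read_rmaps(f), "line 2.*> 0")
  writeLines(c("#rmaps v1 enzyme=KpnI", "m:1\t3\t200\t100,100"), f)
  expect_error(read_rmaps(f), "line 2.*n_fragments")
  writeLines(c("#rmaps v1 enzyme=KpnI", "m:1\t2\t999\t100,100"), f)
  expect_error(read_rmaps(f), "line 2.*total_len")
  writeLines("not a header", f)
  expect_error(read_rmaps(f), "header")
  # truth-less rows read back with NULL truth
  writeLines(c("#rmaps v1 enzyme=KpnI", "m:1\t2\t200\t100,100"), f)
  back <- read_rmaps(f)
  expect_null(back[[1]]$truth)
})

test_that("simulation is reproducible by seed and varies across seeds", {
  rm_ <- synthetic_refmap(5e6, seed = 5)
  a <- sample_molecules(rm_, error_model(), n = 25, seed = 99)
  b <- sample_molecules(rm_, error_model(), n = 25, seed = 99)
  expect_identical(a, b)
  c_ <- sample_molecules(rm_, error_model(), n = 25, seed = 100)
  expect_false(identical(a, c_))
  # byte-identical files under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_rmaps(a, f1, "KpnI"); write_rmaps(b, f2, "KpnI")
  expect_identical(readLines(f1), readLines(f2))
})
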