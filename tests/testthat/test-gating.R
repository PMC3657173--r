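# Negative-control gate derivation and percent-positive counting.

test_that("a constant-background control puts the threshold at the constant", {
  nc <- pe_table(rep(5, 200))
  g <- derive_positive_gate(nc, 0.99)
  expect_identical(g$fluor_threshold, 5)
  # strict '>' means the control itself reads 0% positive
  expect_identical(apply_gate(nc, g)$pct_positive, 0)
})

test_that("gate threshold equals the full-sort quantile oracle", {
  set.seed(41)
  for (q in c(0.95, 0.99, 0.995)) {
    x <- 10^rnorm(10000, 1, 0.35)
    nc <- pe_table(x)
    g <- derive_positive_gate(nc, q)
    # inverted-CDF (type 1) quantile: the ceiling(n*q)-th order statistic
    expect_identical(g$fluor_threshold, sort(x)[ceiling(length(x) * q)])
  }
})

test_that("the gate applied back to its own negative control passes <= 1% of events", {
  nc <- generate_negative_control(15000, seed = 51)
  g <- derive_positive_gate(nc, 0.99)
  res <- apply_gate(nc, g)
  expect_lte(res$pct_positive, 1)
  n <- n_events(nc)
  expect_lte(res$n_positive, ceiling((1 - 0.99) * n) + 1)
})

test_that("counting is exact on constructed tables", {
  g <- derive_positive_gate(pe_table(rep(10, 200)), 0.99)
  expect_identical(apply_gate(pe_table(c(1, 2, 9, 10)), g)$pct_positive, 0)
  res <- apply_gate(pe_table(c(1, 2, 100, 200)), g)   # exactly half above
  expect_identical(res$pct_positive, 50)
  expect_identical(res$n_positive, 2L)
  # threshold ties go negative
  expect_identical(apply_gate(pe_table(c(10, 10, 11)), g)$n_positive, 1L)
})

test_that("estimated percent positive tracks truth plus the background false-positive rate", {
  q <- 0.99
  nc <- generate_negative_control(15000, seed = 61)
  g <- derive_positive_gate(nc, q)
  et <- quick_sample(0.653, n = 15000, seed = 62)
  res <- apply_gate(et, g)
  expected <- 100 * (0.653 + (1 - q) * (1 - 0.653))
  expect_lt(abs(res$pct_positive - expected), 1.5)
  # per-event label tally oracle: every true positive is above threshold
  labels <- attr(et, "population")
  recount <- sum(et$PE > g$fluor_threshold)
  expect_identical(res$n_positive, recount)
  expect_gte(recount, sum(labels) - sum(labels) * 1e-2)
})

test_that("counts match an exhaustive per-event re-check on small tables", {
  g <- derive_positive_gate(generate_negative_control(2000, seed = 71), 0.99)
  for (seed in 1:5) {
    et <- quick_sample(runif(1, 0, 1), n = 1000, seed = seed)
    res <- apply_gate(et, g)
    manual <- 0L
    for (i in seq_len(nrow(et))) {
      if (et$PE[i] > g$fluor_threshold) manual <- manual + 1L
    }
    expect_identical(res$n_positive, manual)
    expect_identical(res$pct_positive, 100 * manual / nrow(et))
  }
})

test_that("raising the threshold never increases percent positive", {
  et <- quick_sample(0.5, n = 2000, seed = 81)
  thresholds <- quantile(et$PE, seq(0.1, 0.9, by = 0.1))
  base <- derive_positive_gate(pe_table(rep(1, 200)), 0.99)
  pcts <- vapply(thresholds, function(th) {
    g <- base; g$fluor_threshold <- th
    apply_gate(et, g)$pct_positive
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("quantiles commute with the log transform", {
  set.seed(91)
  x <- 10^rnorm(5000, 2, 0.35)  # log10 values stay positive, valid as a table
  g_lin <- derive_positive_gate(pe_table(x), 0.99)
  g_log <- derive_positive_gate(pe_table(log10(x)), 0.99)
  expect_equal(10^g_log$fluor_threshold, g_lin$fluor_threshold, tolerance = 1e-12)
})

test_that("parameter recovery holds across the dynamic range at 15,000 events", {
  q <- 0.99
  g <- derive_positive_gate(generate_negative_control(15000, seed = 101), q)
  for (p in c(0.1, 0.4, 0.65, 0.95)) {
    et <- quick_sample(p, n = 15000, seed = round(1000 * p))
    est <- apply_gate(et, g)$pct_positive
    p_eff <- p + (1 - q) * (1 - p)
    tol <- 3 * sqrt(p_eff * (1 - p_eff) / 15000) * 100
    expect_lt(abs(est - 100 * p_eff), tol)
  }
})

test_that("SSC windowing restricts both derivation and counting", {
  nc <- event_table(cbind(SSC = c(rep(100, 100), rep(900, 100)),
                          PE = c(rep(5, 100), rep(50, 100))))
  g <- derive_positive_gate(nc, 0.99, ssc_window = c(0, 500))
  expect_identical(g$fluor_threshold, 5)  # high-SSC events excluded
  res <- apply_gate(nc, g)
  expect_identical(res$n_events_gated, 100L)
  expect_identical(res$pct_positive, 0)
})

test_that("gate inputs are validated", {
  nc <- pe_table(10^rnorm(500, 1, 0.35))
  expect_error(derive_positive_gate(nc, 0.5), "between 0.5 and 1")
  expect_error(derive_positive_gate(nc, 1), "between 0.5 and 1")
  expect_warning(derive_positive_gate(pe_table(1:50), 0.99), "only 50 events")
  g <- derive_positive_gate(nc, 0.99)
  no_pe <- event_table(cbind(SSC = 1:10, FITC = 1:10))
  expect_error(apply_gate(no_pe, g), "channel 'PE'")
})

test_that("gate_batch applies one shared gate, survives bad files, ignores order", {
  g <- derive_positive_gate(generate_negative_control(2000, seed = 111), 0.99)
  et <- quick_sample(0.4, n = 1000, seed = 112)
  perm <- et[sample.int(nrow(et)), , drop = FALSE]
  class(perm) <- class(et)
  good <- withr::local_tempfile(fileext = ".csv")
  write_csv_events(et, good)
  res <- suppressWarnings(  # the unreadable file also emits a connection warning
    gate_batch(list(a = et, a_copy = et, shuffled = perm,
                    from_file = good, broken = "/nonexistent/x.csv"), g))
  expect_identical(res$pct_positive[res$sample_id == "a"],
                   res$pct_positive[res$sample_id == "a_copy"])
  expect_identical(res$pct_positive[res$sample_id == "a"],
                   res$pct_positive[res$sample_id == "shuffled"])
  expect_identical(res$pct_positive[res$sample_id == "a"],
                   res$pct_positive[res$sample_id == "from_file"])
  expect_false(res$ok[res$sample_id == "broken"])
  expect_identical(attr(res, "n_failed"), 1L)
  expect_identical(sum(res$ok), 4L)
})

test_that("gates serialise to JSON and back", {
  g <- derive_positive_gate(generate_negative_control(1000, seed = 121), 0.975,
                            ssc_window = c(100, 800), control_id = "NC1")
  path <- withr::local_tempfile(fileext = ".json")
  write_gate(g, path)
  g2 <- read_gate(path)
  # JSON carries ~15 significant digits
  expect_equal(g2$fluor_threshold, g$fluor_threshold, tolerance = 1e-12)
  expect_identical(g2$quantile_used, g$quantile_used)
  expect_equal(as.numeric(g2$ssc_window), g$ssc_window)
  expect_identical(g2$derived_from, "NC1")
  et <- quick_sample(0.3, 500, 122)
  expect_identical(apply_gate(et, g2), apply_gate(et, g))
})
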