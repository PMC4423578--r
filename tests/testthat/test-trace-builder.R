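test_that("ppm linking joins and separates neutroids as specified", {
  # 3.4 ppm <= 7: one trace of two
  nd <- rbind(neutroid_df(0, 500.0000), neutroid_df(1, 500.0017))
  tr <- build_neutromer_traces(nd)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$neutroids), 2)

  # 8.0 ppm > 7: two singleton traces
  nd <- rbind(neutroid_df(0, 500.0000), neutroid_df(1, 500.0040))
  tr <- build_neutromer_traces(nd)
  expect_length(tr, 2)

  # penultimate-scan rule bridges one missing scan
  nd <- rbind(neutroid_df(0, 500.0000), neutroid_df(2, 500.0010))
  tr <- build_neutromer_traces(nd)
  expect_length(tr, 1)

  # but never two missing scans
  nd <- rbind(neutroid_df(0, 500.0000), neutroid_df(3, 500.0010))
  tr <- build_neutromer_traces(nd)
  expect_length(tr, 2)

  # closest-in-ppm wins among competing open traces
  nd <- rbind(neutroid_df(0, c(500.0000, 500.0020)), neutroid_df(1, 500.0005))
  tr <- build_neutromer_traces(nd)
  expect_length(tr, 2)
  lens <- vapply(tr, function(t) nrow(t$neutroids), integer(1))
  expect_equal(sort(lens), c(1L, 2L))
  joined <- tr[[which(lens == 2)]]
  expect_equal(joined$neutroids$mz, c(500.0000, 500.0005))

  expect_error(build_neutromer_traces(rbind(neutroid_df(0, 500),
                                            neutroid_df(0, 500))),
               "duplicate")
})

test_that("culling removes exactly the too-short traces", {
  mk <- function(len, mz) trace_from(seq_len(len) - 1, seq_len(len),
                                     rep(mz, len), rep(1, len))
  traces <- list(mk(1, 500), mk(2, 600), mk(5, 700))
  out <- cull_short_traces(traces)
  expect_equal(vapply(out, function(t) nrow(t$neutroids), integer(1)),
               c(2L, 5L))
  expect_length(cull_short_traces(list(mk(1, 500), mk(1, 600))), 0)
  out <- cull_short_traces(traces, trace_builder_config(min_trace_length = 1))
  expect_length(out, 3)
})

test_that("splitting triggers at the exact 1/1.3 boundary and not above", {
  mk <- function(y) trace_from(seq_along(y) - 1, seq_along(y),
                               rep(500, length(y)), y)
  # 13.0 / 1.3 == 10.0 exactly: minimum 10.0 triggers (<=)
  out <- split_traces(list(mk(c(5, 13.1, 10.0, 13.0, 6))))
  expect_length(out, 2)
  expect_equal(out[[1]]$neutroids$intensity, c(5, 13.1))
  expect_equal(out[[2]]$neutroids$intensity, c(10.0, 13.0, 6))

  # epsilon above the boundary: no split
  out <- split_traces(list(mk(c(5, 13.1, 10.1, 13.0, 6))))
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$neutroids), 5)

  # monotone trace: no interior minimum, unchanged
  out <- split_traces(list(mk(c(1, 2, 3, 4))))
  expect_length(out, 1)

  # iterative splitting with re-culling: two deep valleys
  y <- c(1, 30, 2, 28, 2, 26, 1)
  out <- split_traces(list(mk(y)))
  expect_length(out, 3)
  expect_equal(unlist(lapply(out, function(t) t$neutroids$intensity)),
               c(1, 30, 2, 28, 2, 26, 1))

  # a split yielding a singleton segment loses it to culling
  out <- split_traces(list(mk(c(30, 2, 28, 26))))
  expect_length(out, 1)
  expect_equal(out[[1]]$neutroids$intensity, c(2, 28, 26))
})

test_that("build+split partition neutroids and respect the gap law", {
  set.seed(21)
  for (i in 1:20) {
    nscan <- sample(5:15, 1)
    rows <- list()
    for (s in seq_len(nscan) - 1) {
      k <- sample(0:4, 1)
      if (k > 0)
        rows[[length(rows) + 1]] <-
          neutroid_df(s, sort(500 + runif(k, 0, 0.05)),
                      intensity = runif(k, 1, 100))
    }
    nd <- do.call(rbind, rows)
    if (is.null(nd)) next
    traces <- build_neutromer_traces(nd)
    traces <- split_traces(traces, trace_builder_config(min_trace_length = 1))
    got <- do.call(rbind, lapply(traces, `[[`, "neutroids"))
    # partition: every output neutroid is an input, used at most once
    key_in <- paste(nd$scan_index, nd$mz)
    key_out <- paste(got$scan_index, got$mz)
    expect_true(all(key_out %in% key_in))
    expect_false(anyDuplicated(key_out) > 0)
    # gap law: consecutive members at most max_gap_scans + 1 apart
    for (t in traces)
      if (nrow(t$neutroids) > 1)
        expect_true(all(diff(t$neutroids$scan_index) <= 2))
  }
})

test_that("trace building is deterministic under within-scan permutation", {
  set.seed(5)
  nd <- rbind(neutroid_df(0, c(500.000, 500.002, 500.004)),
              neutroid_df(1, c(500.0005, 500.0025)),
              neutroid_df(2, c(500.0008, 500.0042)))
  nd$intensity <- runif(nrow(nd), 1, 10)
  ref <- build_neutromer_traces(nd)
  for (i in 1:5) {
    perm <- nd[sample(nrow(nd)), , drop = FALSE]
    got <- build_neutromer_traces(perm)
    expect_equal(lapply(got, function(t) t$neutroids$mz),
                 lapply(ref, function(t) t$neutroids$mz))
  }
})

test_that("extract_hulls recovers the source hulls behind each trace", {
  y <- c(0, 2, 5, 3, 0)
  run <- raw_run(list(scan_from_intensities(y, 0L, 10),
                      scan_from_intensities(y, 1L, 11),
                      scan_from_intensities(y, 2L, 12)), mode = "profile")
  cr <- centroid_run(run)
  traces <- build_neutromer_traces(cr)
  expect_length(traces, 1)
  hulls <- extract_hulls(traces, cr)
  expect_length(hulls, 1)
  expect_length(hulls[[1]]$instantaneous_hulls, 3)
  expect_equal(unname(vapply(hulls[[1]]$instantaneous_hulls, `[[`, integer(1),
                             "scan_index")), 0:2)

  # centroid-mode input: single-point hulls
  crun <- raw_run(list(ms_scan(0L, 10, 500, 7), ms_scan(1L, 11, 500.0001, 8)),
                  mode = "centroid")
  cc <- centroid_run(crun)
  tr <- build_neutromer_traces(cc)
  hh <- extract_hulls(tr, cc)
  expect_true(all(vapply(hh[[1]]$instantaneous_hulls, function(h)
    length(h$mz), integer(1)) == 1))

  # unknown hull ids are an error
  bad <- list(trace_from(0:1, c(1, 2), c(500, 500), c(1, 1)))
  expect_error(extract_hulls(bad, cr), "no recorded source hull")

  expect_length(extract_hulls(list(), cr), 0)
})
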