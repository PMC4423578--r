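co_trace <- function(mz, intensity = 1000, len = 5, id = "T") {
  shape <- exp(-((seq_len(len) - (len + 1) / 2)^2) / 4)
  trace_from(0:(len - 1), 10 * (0:(len - 1)), rep(mz, len), intensity * shape,
             id = id)
}

test_that("chargite grouping assembles envelopes by isotope spacing", {
  # spacing 1.003355/2: one chargite at z = 2
  tr <- list(co_trace(500.0000, 1000, id = "a"),
             co_trace(500.0000 + 1.003355 / 2, 500, id = "b"),
             co_trace(500.0000 + 1.003355, 200, id = "c"))
  ch <- group_chargites(tr)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$z, 2L)
  expect_length(ch[[1]]$traces, 3)
  expect_equal(ch[[1]]$monoisotopic_mz, 500.0)

  # 8.9 ppm offset from the z = 3 prediction: inside the 10 ppm default,
  # outside a 7 ppm tolerance
  tr <- list(co_trace(500.000, 1000, id = "a"),
             co_trace(500.330, 500, id = "b"))
  ch <- group_chargites(tr)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$z, 3L)
  ch <- group_chargites(tr, envelope_config(grouping_ppm_tol = 7))
  expect_length(ch, 2)
  expect_true(all(vapply(ch, `[[`, integer(1), "z") == 0L))

  # unit spacing at z = 1
  tr <- list(co_trace(600.0, 1000, id = "a"),
             co_trace(601.003355, 400, id = "b"))
  ch <- group_chargites(tr)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$z, 1L)

  # disjoint RT spans do not co-elute
  a <- co_trace(600.0, 1000, id = "a")
  b <- trace_from(10:14, 10 * (10:14), rep(601.003355, 5), rep(100, 5),
                  id = "b")
  ch <- group_chargites(list(a, b))
  expect_length(ch, 2)
})

test_that("chargite grouping is deterministic under input permutation", {
  tr <- list(co_trace(500.0000, 1000, id = "a"),
             co_trace(500.0000 + 1.003355 / 2, 500, id = "b"),
             co_trace(500.0000 + 1.003355, 200, id = "c"),
             co_trace(800.0, 900, id = "d"),
             co_trace(801.003355, 450, id = "e"))
  ref <- group_chargites(tr)
  sig <- function(chs) lapply(chs, function(c)
    list(c$z, vapply(c$traces, trace_mz, numeric(1))))
  for (i in 1:5) {
    got <- group_chargites(tr[sample(length(tr))])
    expect_equal(sig(got), sig(ref))
  }
})

test_that("member trace m/z fit the predicted isotope ladder", {
  tr <- list(co_trace(500.0000, 1000, id = "a"),
             co_trace(500.0000 + 1.003355 / 2, 500, id = "b"),
             co_trace(500.0000 + 1.003355, 200, id = "c"))
  cfg <- envelope_config()
  ch <- group_chargites(tr, cfg)[[1]]
  for (k in seq_along(ch$traces)) {
    pred <- ch$monoisotopic_mz + (k - 1) * cfg$isotope_spacing / ch$z
    off <- abs(trace_mz(ch$traces[[k]]) - pred) / pred * 1e6
    expect_true(off <= cfg$grouping_ppm_tol)
  }
})

test_that("deisotoping sums isotope intensities at the monoisotopic anchor", {
  ch <- make_chargite(500.0, z = 2, rel_ab = c(0.6, 0.3, 0.1), len = 1,
                      height = 100)
  d <- deisotope(ch)
  expect_equal(nrow(d), 1)
  expect_equal(d$mz, 500.0)
  expect_equal(d$intensity, 100 * (0.6 + 0.3 + 0.1) * exp(0))
  expect_equal(d$provenance, "deisotoped")

  # single-isotope chargite: identity on intensities
  ch1 <- make_chargite(500.0, z = 1, rel_ab = 1, len = 4)
  d1 <- deisotope(ch1)
  expect_equal(d1$intensity, ch1$traces[[1]]$neutroids$intensity)

  # deisotoped-then-integrated equals per-trace-integrated-then-summed
  ch <- make_chargite(700.0, z = 2, len = 6)
  di <- deisotope(ch, rt_mode = "integrated")
  per_trace <- sum(vapply(ch$traces, trace_intensity, numeric(1)))
  expect_equal(di$intensity, per_trace, tolerance = 1e-12)
  expect_equal(di$provenance, "deisotoped+integrated")
  expect_equal(nrow(di), 1)
})

test_that("molecule grouping merges chargites by implied neutral mass", {
  proton <- 1.007276466812
  a <- make_chargite(1001.007276466812, z = 1, id = "a")
  b <- make_chargite(501.007276466812, z = 2, id = "b")
  mols <- group_molecules(list(a, b))
  expect_length(mols, 1)
  expect_equal(mols[[1]]$neutral_mass, 1000.0, tolerance = 1e-9)

  # disjoint RT spans: two molecules
  b2 <- b
  for (k in seq_along(b2$traces))
    b2$traces[[k]]$neutroids$rt <- b2$traces[[k]]$neutroids$rt + 1000
  expect_length(group_molecules(list(a, b2)), 2)

  # 50 ppm mass disagreement: two molecules
  c50 <- make_chargite(501.007276466812 + 500 * 50e-6, z = 2, id = "c")
  expect_length(group_molecules(list(a, c50)), 2)

  # undetermined-charge chargites are skipped
  z0 <- chargite_trace(0L, list(co_trace(333.3)), 333.3, "z0")
  expect_length(group_molecules(list(z0)), 0)
})

test_that("charge reduction re-coordinates to the lowest common charge", {
  proton <- 1.007276466812
  # closed form: z=2 monoisotopic 500.50 reduces at z*=1 to 999.992724
  ch2 <- make_chargite(500.50, z = 2, id = "z2")
  M <- 2 * (500.50 - proton)
  mol <- molecular_distribution_trace(list(ch2), M)
  red <- reduce_molecule(mol, z_target = 1)
  expect_equal(unique(red$mz), 999.992724, tolerance = 1e-6)
  expect_equal(red$provenance[1], "deisotoped+reduced")

  # single-chargite molecule at its own z: m/z and intensities unchanged
  ch1 <- make_chargite(600.0, z = 1, id = "z1")
  mol1 <- molecular_distribution_trace(list(ch1), 600.0 - proton)
  red1 <- reduce_molecule(mol1)
  expect_equal(unique(red1$mz), 600.0, tolerance = 1e-9)
  expect_equal(red1$intensity, deisotope(ch1)$intensity)

  # intensities sum across chargites per shared scan
  a <- make_chargite(1001.007276466812, z = 1, rel_ab = 1, len = 1,
                     height = 70, id = "a")
  b <- make_chargite(501.007276466812, z = 2, rel_ab = 1, len = 1,
                     height = 30, id = "b")
  mol <- group_molecules(list(a, b))[[1]]
  red <- reduce_molecule(mol)
  expect_equal(sum(red$intensity), 100)

  z0 <- chargite_trace(0L, list(co_trace(333.3)), 333.3, "z0")
  expect_error(reduce_molecule(molecular_distribution_trace(list(z0), 300)),
               "undetermined")
})

test_that("deisotoping and reduction conserve total intensity", {
  set.seed(33)
  for (i in 1:30) {
    z <- sample(1:3, 1)
    nk <- sample(1:4, 1)
    ab <- sort(runif(nk, 0.05, 1), decreasing = TRUE)
    ab <- ab / max(ab)
    ch <- make_chargite(runif(1, 300, 900), z = z, rel_ab = ab,
                        len = sample(2:8, 1), height = runif(1, 10, 1e5))
    tot <- sum(vapply(ch$traces, trace_intensity, numeric(1)))
    expect_equal(sum(deisotope(ch)$intensity), tot, tolerance = 1e-9)
    mol <- molecular_distribution_trace(
      list(ch), ch$z * (ch$monoisotopic_mz - 1.007276466812))
    expect_equal(sum(reduce_molecule(mol)$intensity), tot, tolerance = 1e-9)
  }
})
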