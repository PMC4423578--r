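# Shared fixtures and independent oracles.

# Brute-force hull segmenter: classifies every point directly from the
# definitions (zero point; interior local-minimum plateau point; ordinary),
# then reads off contiguous runs of ordinary points as hulls. Written
# point-by-point, independently of the run-scanning implementation.
oracle_segments <- function(y, floor = 0) {
  n <- length(y)
  is_zero <- y <= floor
  is_sep <- logical(n)
  for (i in seq_len(n)) {
    if (is_zero[i]) next
    l <- i
    while (l > 1 && !is_zero[l - 1] && y[l - 1] == y[i]) l <- l - 1
    r <- i
    while (r < n && !is_zero[r + 1] && y[r + 1] == y[i]) r <- r + 1
    if (l > 1 && !is_zero[l - 1] && y[l - 1] > y[i] &&
        r < n && !is_zero[r + 1] && y[r + 1] > y[i])
      is_sep[i] <- TRUE
  }
  ok <- !(is_zero | is_sep)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && ok[j + 1L]) j <- j + 1L
    segs[[length(segs) + 1L]] <- i:j
    i <- j + 1L
  }
  segs
}

# a scan with the given intensity vector on a unit-ish m/z ladder
scan_from_intensities <- function(y, scan_index = 0L, rt = 0,
                                  mz_start = 100) {
  ms_scan(scan_index, rt, mz_start + seq_along(y) * 0.01, y)
}

# a trace directly from vectors
trace_from <- function(scan_index, rt, mz, intensity, id = "T") {
  neutromer_trace(data.frame(scan_index = as.integer(scan_index), rt = rt,
                             mz = mz, intensity = intensity), trace_id = id)
}

# random profile-like intensity vector with zeros and plateaus
random_intensities <- function(n) {
  y <- sample(0:9, n, replace = TRUE)
  as.numeric(y)
}

# neutroid data.frame builder for trace-builder tests: one row per (scan, mz)
neutroid_df <- function(scan_index, mz, intensity = 100) {
  data.frame(scan_index = as.integer(scan_index),
             rt = as.numeric(scan_index), mz = mz,
             intensity = rep_len(intensity, length(mz)),
             hull_id = NA_character_)
}

# small co-eluting chargite for envelope tests: k isotopes at charge z,
# sharing scans 0..(len-1)
make_chargite <- function(mono_mz, z, rel_ab = c(1, 0.5, 0.2), len = 5,
                          spacing = 1.003355, height = 1000, id = "C1") {
  traces <- lapply(seq_along(rel_ab), function(k) {
    shape <- exp(-((seq_len(len) - (len + 1) / 2)^2) / 4)
    trace_from(0:(len - 1), 10 * (0:(len - 1)),
               rep(mono_mz + (k - 1) * spacing / z, len),
               height * rel_ab[k] * shape, id = sprintf("%s_k%d", id, k - 1))
  })
  chargite_trace(z = z, traces = traces, monoisotopic_mz = mono_mz,
                 chargite_id = id)
}
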