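# mzML reading/writing (via mzR) and nomenclature-validated feature tables.

#' Read MS1 spectra from an mzML file
#'
#' Only MS-level-1 spectra are kept; scans are sorted by retention time and
#' re-indexed from 0. Retention times are normalized to seconds (mzR reports
#' seconds regardless of the file's declared unit). Mode is inferred from
#' the file's spectrum-type declaration: centroid if every MS1 spectrum is
#' declared centroided, else profile.
#'
#' @param path Path to an mzML file.
#' @return A [raw_run()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1)
  if (length(ms1) == 0) stop("no MS-level-1 spectra in ", path)
  ms1 <- ms1[order(hdr$retentionTime[ms1])]
  scans <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    pk <- mzR::peaks(handle, ms1[i])
    scans[[i]] <- ms_scan(i - 1L, hdr$retentionTime[ms1[i]],
                          pk[, 1], pk[, 2])
  }
  centroided <- hdr$centroided[ms1]
  mode <- if (length(centroided) > 0 && all(!is.na(centroided)) &&
              all(centroided)) "centroid" else "profile"
  raw_run(scans, mode = mode, metadata = list(source = path))
}

#' Write a run to mzML
#'
#' MS-level-1 spectra with 64-bit m/z and intensity arrays, so that a
#' write/read round trip preserves the data exactly.
#'
#' @param run A [raw_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$scans)
  if (n == 0) stop("cannot write an empty run")
  pk <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(run$scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(run$scans, function(s) s$rt, numeric(1)),
    basePeakMZ = vapply(run$scans, function(s)
      if (length(s$mz) > 0) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$scans, function(s)
      if (length(s$intensity) > 0) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s)
      if (length(s$mz) > 0) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$scans, function(s)
      if (length(s$mz) > 0) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = run$mode == "centroid",
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

# ---- feature tables --------------------------------------------------------

.feature_cols <- c("entity_kind", "provenance", "id", "z", "isotope_index",
                   "scan_index", "mz", "rt", "intensity")

.empty_feature_table <- function() {
  data.frame(entity_kind = character(0), provenance = character(0),
             id = character(0), z = integer(0), isotope_index = integer(0),
             scan_index = integer(0), mz = numeric(0), rt = numeric(0),
             intensity = numeric(0))
}

#' Convert pipeline entities to feature-table rows
#'
#' One row per neutroid (for RT-extended entities) or per projected tuple.
#' The `provenance` column carries the full nomenclature term for the row
#' (e.g. `"neutromer trace"`, `"integrated chargite distribution trace"`),
#' validated against the lexicon.
#'
#' @param x A `neutromer_trace`, `chargite_trace`,
#'   `molecular_distribution_trace`, `projected_entities` data frame, or a
#'   list of these.
#' @param ... Unused.
#' @return A `data.frame` with columns `entity_kind`, `provenance`, `id`,
#'   `z`, `isotope_index`, `scan_index`, `mz`, `rt`, `intensity`.
#' @export
as_feature_table <- function(x, ...) UseMethod("as_feature_table")

#' @export
as_feature_table.list <- function(x, ...) {
  if (length(x) == 0) return(.empty_feature_table())
  do.call(rbind, lapply(x, as_feature_table))
}

#' @export
as_feature_table.neutromer_trace <- function(x, ...) {
  nd <- x$neutroids
  data.frame(entity_kind = "neutromer_trace",
             provenance = provenance_label("neutromer_trace"),
             id = x$trace_id, z = NA_integer_, isotope_index = NA_integer_,
             scan_index = nd$scan_index, mz = nd$mz, rt = nd$rt,
             intensity = nd$intensity)
}

#' @export
as_feature_table.chargite_trace <- function(x, ...) {
  rows <- lapply(seq_along(x$traces), function(k) {
    nd <- x$traces[[k]]$neutroids
    data.frame(entity_kind = "chargite_trace",
               provenance = provenance_label("chargite_trace"),
               id = x$chargite_id, z = x$z, isotope_index = k - 1L,
               scan_index = nd$scan_index, mz = nd$mz, rt = nd$rt,
               intensity = nd$intensity)
  })
  do.call(rbind, rows)
}

#' @export
as_feature_table.molecular_distribution_trace <- function(x, ...) {
  rows <- lapply(x$chargites, function(ch) {
    df <- as_feature_table(ch)
    df$entity_kind <- "molecular_distribution_trace"
    df$provenance <- provenance_label("molecular_distribution_trace")
    df$id <- x$molecule_id
    df
  })
  do.call(rbind, rows)
}

#' @export
as_feature_table.projected_entities <- function(x, ...) {
  kind <- unique(x$entity_kind)
  data.frame(entity_kind = x$entity_kind,
             provenance = vapply(seq_len(nrow(x)), function(i)
               provenance_label(x$entity_kind[i], split_tags(x$provenance[i])),
               character(1)),
             id = x$source_id, z = NA_integer_,
             isotope_index = x$isotope_index,
             scan_index = x$scan_index, mz = x$mz, rt = x$rt,
             intensity = x$intensity)
}

#' Write a feature table to TSV or JSON
#'
#' Rows are ordered deterministically by (entity_kind, mz, rt); every
#' provenance term is validated against the nomenclature lexicon before
#' writing.
#'
#' @param entities Anything accepted by [as_feature_table()], or a
#'   feature-table `data.frame`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(entities, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(entities) &&
            all(.feature_cols %in% names(entities))) entities
        else as_feature_table(entities)
  for (i in seq_len(nrow(df))) {
    parsed <- parse_provenance(df$provenance[i])  # errors on unlicensed terms
    if (parsed$entity_kind != df$entity_kind[i])
      stop("provenance term '", df$provenance[i],
           "' does not match entity kind '", df$entity_kind[i], "'")
  }
  df <- df[order(df$entity_kind, df$mz, df$rt), .feature_cols, drop = FALSE]
  rownames(df) <- NULL
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to a TSV or JSON feature table.
#' @param format `"tsv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return A feature-table `data.frame`.
#' @export
read_feature_table <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  missing <- setdiff(.feature_cols, names(df))
  if (length(missing) > 0)
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  df
}

# ---- full pipeline ---------------------------------------------------------

#' Run the full MS1 feature-extraction pipeline
#'
#' Centroiding, neutromer-trace construction, culling, splitting, chargite
#' grouping and molecule grouping, in order.
#'
#' @param run A [raw_run()].
#' @param centroider A [centroider_config()].
#' @param builder A [trace_builder_config()].
#' @param envelope An [envelope_config()].
#' @return List with `centroided`, `traces` (culled and split), `chargites`,
#'   `molecules`.
#' @export
detect_features <- function(run, centroider = centroider_config(),
                            builder = trace_builder_config(),
                            envelope = envelope_config()) {
  centroided <- centroid_run(run, centroider)
  traces <- build_neutromer_traces(centroided, builder)
  traces <- cull_short_traces(traces, builder)
  traces <- split_traces(traces, builder)
  chargites <- group_chargites(traces, envelope)
  molecules <- group_molecules(chargites, envelope)
  list(centroided = centroided, traces = traces, chargites = chargites,
       molecules = molecules)
}
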