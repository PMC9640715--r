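# Acquisition I/O: mzML scan streams (via mzR), DESI stage logs, plate
# maps, and deterministic result tables.

#' Construct a single mass spectrum
#'
#' @param start_time_s Acquisition start time in seconds.
#' @param mz,intensity Equal-length numeric vectors; m/z need not arrive
#'   sorted (it is sorted here, duplicate m/z summed), intensities must be
#'   non-negative.
#' @param mode `"full_scan"` (MS1) or `"msms"` (MS2).
#' @param precursor_window For MS/MS scans, numeric `c(center_mz, width_mz)`
#'   of the isolation window; the paired 2HG/Glu method uses `c(146.5, 3)`.
#' @return A `scan` object.
#' @export
scan <- function(start_time_s, mz, intensity, mode = c("full_scan", "msms"),
                 precursor_window = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            is.numeric(start_time_s), length(start_time_s) == 1L)
  if (mode == "msms") {
    stopifnot(length(precursor_window) == 2L, precursor_window[2] > 0)
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(rowsum(intensity, group = mz))
    mz <- sort(unique(mz))
  }
  structure(list(start_time_s = start_time_s, mode = mode,
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor_window = precursor_window),
            class = "scan")
}

#' Construct a time-ordered scan stream
#'
#' @param run_id Run identifier.
#' @param scans List of [scan()] objects; sorted by start time here.
#' @return A `scan_stream`.
#' @export
scan_stream <- function(run_id, scans) {
  stopifnot(is.list(scans), all(vapply(scans, inherits, TRUE, "scan")))
  times <- vapply(scans, `[[`, numeric(1), "start_time_s")
  structure(list(run_id = run_id, scans = scans[order(times)]),
            class = "scan_stream")
}

#' @export
print.scan_stream <- function(x, ...) {
  cat(sprintf("scan_stream '%s': %d scan(s)\n", x$run_id, length(x$scans)))
  invisible(x)
}

.mzr_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  list(header = h, peaks = pk)
}

#' Read a full-scan (MS1) raster run
#'
#' Reads an mzML/mzXML file and returns its MS1 scans in acquisition-time
#' order with ascending m/z arrays (scans stored out of order on disk are
#' re-sorted). MS2 scans present in the file are ignored by this reader.
#'
#' @param path mzML or mzXML file.
#' @return A `scan_stream` of `full_scan` scans.
#' @export
read_fullscan_run <- function(path) {
  d <- .mzr_read(path)
  keep <- which(d$header$msLevel == 1L)
  if (!length(keep)) stop("run '", path, "' contains no MS1 scans", call. = FALSE)
  scans <- lapply(keep, function(i) {
    scan(d$header$retentionTime[i], d$peaks[[i]][, 1], d$peaks[[i]][, 2],
         mode = "full_scan")
  })
  scan_stream(tools::file_path_sans_ext(basename(path)), scans)
}

#' Read one per-spot MS/MS run
#'
#' @param path mzML/mzXML file of MS2 scans.
#' @return A `scan_stream` of `msms` scans with their precursor isolation
#'   windows.
#' @export
read_msms_run <- function(path) {
  d <- .mzr_read(path)
  keep <- which(d$header$msLevel == 2L)
  if (!length(keep)) stop("run '", path, "' contains no MS2 scans", call. = FALSE)
  scans <- lapply(keep, function(i) {
    ctr <- d$header$isolationWindowTargetMZ[i]
    lo <- d$header$isolationWindowLowerOffset[i]
    hi <- d$header$isolationWindowUpperOffset[i]
    win <- if (!is.na(ctr)) c(ctr, sum(c(lo, hi), na.rm = TRUE))
           else c(d$header$precursorMZ[i], 3)
    scan(d$header$retentionTime[i], d$peaks[[i]][, 1], d$peaks[[i]][, 2],
         mode = "msms", precursor_window = win)
  })
  scan_stream(tools::file_path_sans_ext(basename(path)), scans)
}

#' Read a directory of per-spot MS/MS runs
#'
#' The spot index is recorded in each file name; the default pattern
#' matches the simulator's `spot_0007.mzML` convention. Files whose names
#' do not match are skipped with a warning; a duplicate spot index is an
#' error.
#'
#' @param directory Directory containing one mzML per analysed spot.
#' @param pattern Regex with one capture group yielding the integer spot
#'   index.
#' @return Named list of `scan_stream`s keyed by spot index.
#' @export
read_msms_runs <- function(directory,
                           pattern = "^spot_([0-9]+)\\.(mzML|mzXML)$") {
  stopifnot(dir.exists(directory))
  files <- list.files(directory, full.names = FALSE)
  files <- files[grepl("\\.(mzML|mzXML)$", files)]
  hit <- grepl(pattern, files)
  if (any(!hit)) {
    warning("skipping file(s) not matching spot pattern: ",
            paste(files[!hit], collapse = ", "), call. = FALSE)
  }
  files <- files[hit]
  if (!length(files)) return(stats::setNames(list(), character()))
  idx <- as.integer(sub(pattern, "\\1", files))
  if (anyDuplicated(idx)) {
    stop("duplicate spot index in MS/MS file names", call. = FALSE)
  }
  o <- order(idx)
  out <- lapply(file.path(directory, files[o]), read_msms_run)
  names(out) <- idx[o]
  out
}

#' Read and validate a DESI stage log
#'
#' A stage log records the dwell window of the stage on each spot as a
#' 3-column CSV `spot_index,t_arrive_s,t_leave_s`. Windows must be
#' well-formed (`t_arrive < t_leave`) and mutually non-overlapping; rows
#' are returned ordered by arrival time.
#'
#' @param path CSV path, or a data frame with the same columns.
#' @return A `stage_log` data frame.
#' @export
read_stage_log <- function(path) {
  log <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_index", "t_arrive_s", "t_leave_s")
  if (!all(need %in% names(log))) {
    stop("stage log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- log$t_arrive_s >= log$t_leave_s
  if (any(bad)) {
    stop("stage log entries with t_arrive >= t_leave for spot(s) ",
         paste(log$spot_index[bad], collapse = ", "), call. = FALSE)
  }
  log <- log[order(log$t_arrive_s), , drop = FALSE]
  if (nrow(log) > 1L &&
      any(log$t_arrive_s[-1L] < log$t_leave_s[-nrow(log)])) {
    stop("stage log contains overlapping dwell windows", call. = FALSE)
  }
  rownames(log) <- NULL
  class(log) <- c("stage_log", "data.frame")
  log
}

#' Write a stage log CSV
#' @param log A `stage_log` (or compatible data frame).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_stage_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a plate map
#'
#' The plate map records which biopsy sits in each source-plate well,
#' plus optional per-biopsy metadata (tissue class, tumor cell
#' percentage, IDH genotype). Accepted dialects: CSV with columns
#' `biopsy_id,plate_id,well` (plus optional `tissue_class,tcp,idh`), or a
#' YAML file with a `biopsies:` list of the same fields.
#'
#' @param path CSV/YAML path, or an equivalent data frame.
#' @return A `plate_map` data frame, one row per biopsy.
#' @export
read_plate_map <- function(path) {
  if (is.data.frame(path)) {
    pm <- path
  } else if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rows <- lapply(y$biopsies, function(b) {
      data.frame(biopsy_id = b$biopsy_id, plate_id = b$plate_id,
                 well = b$well,
                 tissue_class = b$tissue_class %||% NA_character_,
                 tcp = b$tcp %||% NA_real_,
                 idh = b$idh %||% NA_character_,
                 stringsAsFactors = FALSE)
    })
    pm <- do.call(rbind, rows)
  } else {
    pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("biopsy_id", "plate_id", "well")
  if (is.null(pm) || !all(need %in% names(pm))) {
    stop("plate map must provide ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tissue_class", "idh")) if (is.null(pm[[col]])) pm[[col]] <- NA_character_
  if (is.null(pm$tcp)) pm$tcp <- NA_real_
  if (anyDuplicated(pm$biopsy_id)) {
    stop("duplicate biopsy_id in plate map", call. = FALSE)
  }
  if (anyDuplicated(pm[, c("plate_id", "well")])) {
    stop("duplicate (plate_id, well) assignment in plate map", call. = FALSE)
  }
  rownames(pm) <- NULL
  class(pm) <- c("plate_map", "data.frame")
  pm
}

#' Write a plate map
#'
#' @param pm A `plate_map`.
#' @param path Output path; `.yaml`/`.yml` writes the YAML dialect,
#'   anything else CSV.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(pm, path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_len(nrow(pm)), function(i) {
      r <- as.list(pm[i, , drop = FALSE])
      r <- lapply(r, function(v) if (is.na(v)) NULL else unname(v))
      Filter(Negate(is.null), r)
    })
    yaml::write_yaml(list(biopsies = rows), path)
  } else {
    utils::write.csv(as.data.frame(pm), path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table deterministically
#'
#' Writes records as CSV with a header, numeric columns at full (17
#' significant digits) precision so values round-trip bit-identically
#' through [utils::read.csv()], and a deterministic row order (by
#' `biopsy_id`, then `spot_index`, when those columns exist).
#'
#' @param records Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  ord <- intersect(c("biopsy_id", "spot_index"), names(records))
  if (length(ord) && nrow(records)) {
    records <- records[do.call(order, records[ord]), , drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  status <- try(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
                silent = TRUE)
  if (inherits(status, "try-error")) {
    stop("cannot write table to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write a scan stream as mzML
#'
#' Serializes a `scan_stream` to an mzML file (used by the acquisition
#' simulator; files read back with [read_fullscan_run()] /
#' [read_msms_run()] reproduce the arrays to float-encoding precision).
#'
#' @param stream A `scan_stream`.
#' @param path Output `.mzML` path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(stream, path) {
  n <- length(stream$scans)
  stopifnot(n >= 1L)
  pk <- lapply(stream$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  lv <- vapply(stream$scans, function(s) if (s$mode == "msms") 2L else 1L, 0L)
  win <- lapply(stream$scans, `[[`, "precursor_window")
  nap <- function(i, k) if (lv[i] == 2L) win[[i]][k] else NA_real_
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = 0L,
    peaksCount = vapply(pk, nrow, 0L),
    totIonCurrent = vapply(stream$scans, function(s) sum(s$intensity), 0),
    retentionTime = vapply(stream$scans, `[[`, 0, "start_time_s"),
    basePeakMZ = vapply(stream$scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(stream$scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = ifelse(lv == 2L, 20, NA_real_),
    ionisationEnergy = 0,
    lowMZ = vapply(stream$scans, function(s)
      if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(stream$scans, function(s)
      if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = 0L,
    precursorMZ = vapply(seq_len(n), nap, 0, k = 1),
    precursorCharge = ifelse(lv == 2L, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(seq_len(n), nap, 0, k = 1),
    isolationWindowLowerOffset = vapply(seq_len(n), function(i)
      if (lv[i] == 2L) win[[i]][2] / 2 else NA_real_, 0),
    isolationWindowUpperOffset = vapply(seq_len(n), function(i)
      if (lv[i] == 2L) win[[i]][2] / 2 else NA_real_, 0),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
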