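# Per-spot spectral processing: partition raster scans among spots,
# resample onto a common m/z grid, average, normalize, QC, and aggregate
# to per-biopsy profiles.

#' Equally spaced m/z grid
#'
#' @param mz_min,mz_max Grid range in m/z units.
#' @param step Grid spacing; the default 0.01 suits centroided QTOF data
#'   over the lipid range.
#' @return An `mz_grid` object.
#' @export
mz_grid <- function(mz_min = 100, mz_max = 1000, step = 0.01) {
  stopifnot(mz_min < mz_max, step > 0)
  structure(list(mz_min = mz_min, mz_max = mz_max, step = step),
            class = "mz_grid")
}

#' Grid points of an [mz_grid()]
#' @param grid An `mz_grid`.
#' @return Numeric vector of equally spaced m/z values.
#' @export
grid_points <- function(grid) {
  n <- floor((grid$mz_max - grid$mz_min) / grid$step + 1e-9)
  grid$mz_min + grid$step * (0:n)
}

#' Assign raster scans to array spots by stage-log dwell windows
#'
#' A scan with start time t belongs to the unique stage-log entry with
#' t in `[t_arrive, t_leave)`. Scans acquired while the stage was in
#' motion (falling in no window) are discarded and counted, so assigned
#' plus discarded scans always partition the stream.
#'
#' @param log A `stage_log` from [read_stage_log()].
#' @param stream A `scan_stream`.
#' @return List with `spots` (named list, spot index -> list of scans;
#'   only spots that received scans appear) and `n_discarded`.
#' @export
assign_scans <- function(log, stream) {
  stopifnot(inherits(stream, "scan_stream"))
  log <- read_stage_log(log)  # revalidate / order
  times <- vapply(stream$scans, `[[`, numeric(1), "start_time_s")
  if (!nrow(log) || !length(times)) {
    return(list(spots = stats::setNames(list(), character()),
                n_discarded = length(times)))
  }
  # windows are disjoint and ordered: locate each time in the arrival
  # sequence, then check it falls before that entry's departure
  pos <- findInterval(times, log$t_arrive_s)
  ok <- pos >= 1L & ifelse(pos >= 1L, times < log$t_leave_s[pmax(pos, 1L)], FALSE)
  spots <- list()
  for (i in which(ok)) {
    key <- as.character(log$spot_index[pos[i]])
    spots[[key]] <- c(spots[[key]], list(stream$scans[[i]]))
  }
  list(spots = spots, n_discarded = sum(!ok))
}

#' Resample one scan onto an m/z grid
#'
#' Linearly interpolates the scan's (m/z, intensity) profile at the grid
#' points (`method = "linear"`, the default). Grid points outside the
#' scan's m/z range are 0. `method = "nearest"` instead bins each
#' centroid's intensity onto its nearest grid point (area-preserving for
#' stick spectra).
#'
#' @param scan A [scan()].
#' @param grid An [mz_grid()].
#' @param method `"linear"` or `"nearest"`.
#' @return Non-negative intensity vector on the grid. A scan with fewer
#'   than 2 points yields a zero vector with a warning.
#' @export
resample_scan <- function(scan, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  gp <- grid_points(grid)
  if (length(scan$mz) < 2L && method == "linear") {
    warning("scan with < 2 points resampled to zero vector", call. = FALSE)
    return(numeric(length(gp)))
  }
  if (method == "linear") {
    out <- stats::approx(scan$mz, scan$intensity, xout = gp,
                         method = "linear", yleft = 0, yright = 0,
                         ties = "ordered")$y
  } else {
    out <- numeric(length(gp))
    keep <- scan$mz >= grid$mz_min - grid$step / 2 &
            scan$mz <= grid$mz_max + grid$step / 2
    if (any(keep)) {
      idx <- pmin(pmax(round((scan$mz[keep] - grid$mz_min) / grid$step), 0),
                  length(gp) - 1L) + 1L
      acc <- rowsum(scan$intensity[keep], group = idx)
      out[as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  pmax(out, 0)
}

#' Average the scans of one spot
#'
#' Resamples every scan onto the grid and takes the arithmetic mean,
#' recording the pre-normalization total ion current for QC. A spot with
#' no scans (or all-zero signal) is flagged `empty`.
#'
#' @param scans List of [scan()]s assigned to the spot.
#' @param grid An [mz_grid()].
#' @param spot_index Integer spot index carried into the result.
#' @param method Resampling method, see [resample_scan()].
#' @return A `spot_spectrum` with fields `spot_index`, `grid`,
#'   `intensity`, `n_scans`, `tic`, `qc_flag`.
#' @export
average_spot <- function(scans, grid, spot_index = NA_integer_,
                         method = "linear") {
  gp_len <- length(grid_points(grid))
  if (!length(scans)) {
    inten <- numeric(gp_len)
  } else {
    acc <- numeric(gp_len)
    for (s in scans) acc <- acc + resample_scan(s, grid, method)
    inten <- acc / length(scans)
  }
  structure(list(spot_index = spot_index, grid = grid, intensity = inten,
                 n_scans = length(scans), tic = sum(inten),
                 qc_flag = if (sum(inten) > 0) "ok" else "empty"),
            class = "spot_spectrum")
}

#' Base-peak normalize a spot spectrum
#'
#' Divides the spectrum by its maximum intensity so the base peak is 1;
#' an all-zero spectrum is left at zero and flagged `empty`. Idempotent.
#'
#' @param s A `spot_spectrum`.
#' @return The normalized `spot_spectrum`.
#' @export
base_peak_normalize <- function(s) {
  m <- max(s$intensity)
  if (m > 0) {
    s$intensity <- s$intensity / m
  } else {
    s$qc_flag <- "empty"
  }
  s
}

#' Flag low-signal spots
#'
#' Spots whose pre-normalization TIC falls below `min_tic_fraction` times
#' the median TIC over all spots are flagged `low_signal` (incomplete
#' pin-tool transfers); flagged spots are excluded from biopsy averaging.
#'
#' @param spots List of `spot_spectrum`s.
#' @param min_tic_fraction Fraction of the median TIC below which a spot
#'   is flagged (default 0.1).
#' @return The list with updated `qc_flag`s.
#' @export
qc_flag_spots <- function(spots, min_tic_fraction = 0.1) {
  stopifnot(length(spots) >= 1L)
  tics <- vapply(spots, `[[`, numeric(1), "tic")
  med <- stats::median(tics)
  for (i in seq_along(spots)) {
    if (spots[[i]]$qc_flag == "ok" && tics[i] < min_tic_fraction * med) {
      spots[[i]]$qc_flag <- "low_signal"
    }
  }
  spots
}

#' Average normalized spot spectra per biopsy
#'
#' Resolves each spot to its biopsy through the layout (spot -> plate/well)
#' and plate map (plate/well -> biopsy), then averages the base-peak
#' normalized spectra of the `ok`-flagged spots of each biopsy. Spots in
#' wells with no biopsy assignment are skipped with a message. Biopsies
#' with no usable spot are reported with `n_spots_used = 0` and a zero
#' profile.
#'
#' @param spots List of (normalized) `spot_spectrum`s.
#' @param layout A `tma_layout`.
#' @param plate_map A `plate_map`.
#' @return List of `biopsy_profile` objects (fields `biopsy_id`, `grid`,
#'   `intensity`, `n_spots_used`), ordered by biopsy id.
#' @export
average_biopsy <- function(spots, layout, plate_map) {
  plate_map <- read_plate_map(plate_map)
  key <- paste(layout$spots$plate_id, layout$spots$well, sep = "\r")
  map_key <- paste(plate_map$plate_id, plate_map$well, sep = "\r")
  spot_biopsy <- plate_map$biopsy_id[match(key, map_key)]
  names(spot_biopsy) <- as.character(layout$spots$index)

  grid <- NULL
  groups <- list()
  for (s in spots) {
    if (is.null(grid)) grid <- s$grid
    b <- spot_biopsy[[as.character(s$spot_index)]]
    if (is.null(b) || is.na(b)) {
      message("spot ", s$spot_index, " has no biopsy assignment; skipped")
      next
    }
    if (s$qc_flag != "ok") next
    groups[[b]] <- c(groups[[b]], list(s$intensity))
  }
  ids <- sort(unique(plate_map$biopsy_id))
  lapply(ids, function(b) {
    vs <- groups[[b]]
    inten <- if (length(vs)) Reduce(`+`, vs) / length(vs)
             else numeric(length(grid_points(grid %||% mz_grid())))
    structure(list(biopsy_id = b, grid = grid, intensity = inten,
                   n_spots_used = length(vs)),
              class = "biopsy_profile")
  })
}

#' Stack biopsy profiles into a sample-by-m/z matrix
#'
#' @param profiles List of `biopsy_profile`s (from [average_biopsy()]).
#' @param drop_empty Drop biopsies with `n_spots_used == 0` (default TRUE).
#' @return Numeric matrix, rows named by biopsy id, columns by grid m/z.
#' @export
profile_matrix <- function(profiles, drop_empty = TRUE) {
  if (drop_empty) {
    profiles <- Filter(function(p) p$n_spots_used > 0, profiles)
  }
  stopifnot(length(profiles) >= 1L)
  gp <- grid_points(profiles[[1]]$grid)
  m <- do.call(rbind, lapply(profiles, `[[`, "intensity"))
  rownames(m) <- vapply(profiles, `[[`, "", "biopsy_id")
  colnames(m) <- format(gp, trim = TRUE, scientific = FALSE)
  m
}

#' Full-scan processing pipeline
#'
#' Convenience wrapper running assignment, per-spot averaging, base-peak
#' normalization, QC flagging and per-biopsy aggregation in the canonical
#' order.
#'
#' @param stream `scan_stream` of MS1 scans.
#' @param log `stage_log`.
#' @param layout `tma_layout`.
#' @param plate_map `plate_map`.
#' @param grid [mz_grid()].
#' @param min_tic_fraction QC threshold, see [qc_flag_spots()].
#' @param method Resampling method.
#' @return List with `spots` (normalized, QC-flagged `spot_spectrum`s),
#'   `profiles` (list of `biopsy_profile`), `qc` (per-spot QC data frame)
#'   and `n_discarded` scans.
#' @export
process_fullscan <- function(stream, log, layout, plate_map,
                             grid = mz_grid(), min_tic_fraction = 0.1,
                             method = "linear") {
  asg <- assign_scans(log, stream)
  idx <- as.integer(names(asg$spots))
  spots <- mapply(function(scans, i) average_spot(scans, grid, i, method),
                  asg$spots, idx, SIMPLIFY = FALSE)
  spots <- qc_flag_spots(spots, min_tic_fraction)
  spots <- lapply(spots, base_peak_normalize)
  profiles <- average_biopsy(spots, layout, plate_map)
  qc <- data.frame(
    spot_index = vapply(spots, `[[`, 0L, "spot_index"),
    n_scans = vapply(spots, `[[`, 0L, "n_scans"),
    tic = vapply(spots, `[[`, 0, "tic"),
    qc_flag = vapply(spots, `[[`, "", "qc_flag"),
    stringsAsFactors = FALSE
  )
  rownames(qc) <- NULL
  list(spots = spots, profiles = profiles, qc = qc,
       n_discarded = asg$n_discarded)
}
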