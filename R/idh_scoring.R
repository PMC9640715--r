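# Targeted MS/MS IDH genotyping: paired isolation of 2HG (m/z 147) and
# Glu (m/z 146), fragment-bin extraction, and the isotope-corrected
# 2HG:Glu ion-ratio score.

#' Paired 2HG/Glu MS/MS method description
#'
#' Both precursors (m/z 146 and 147) are co-isolated in a 3-unit window
#' centered at m/z 146.5 and fragmented together; the water-loss product
#' ions are read out in 1-unit bins centered at m/z 128 (Glu) and m/z 129
#' (2HG plus the 13C-Glu isotope contribution).
#'
#' @param precursor_center_mz Isolation window center (146.5).
#' @param window_width_mz Isolation window width (3).
#' @param glu_bin_mz,twohg_bin_mz Product bin centers (128, 129).
#' @param bin_width_mz Product bin width (1).
#' @return An `msms_method` object.
#' @export
msms_method <- function(precursor_center_mz = 146.5, window_width_mz = 3,
                        glu_bin_mz = 128, twohg_bin_mz = 129,
                        bin_width_mz = 1) {
  lo <- precursor_center_mz - window_width_mz / 2
  hi <- precursor_center_mz + window_width_mz / 2
  stopifnot(lo <= 146, hi >= 147,
            abs(twohg_bin_mz - glu_bin_mz) == bin_width_mz)
  structure(list(precursor_center_mz = precursor_center_mz,
                 window_width_mz = window_width_mz,
                 glu_bin_mz = glu_bin_mz, twohg_bin_mz = twohg_bin_mz,
                 bin_width_mz = bin_width_mz),
            class = "msms_method")
}

#' Scoring parameters
#'
#' @param isotope_correction Fractional 13C-Glu contribution subtracted
#'   from the m/z 129 bin (default 0.061, i.e. 6.1%).
#' @param call_threshold Score above which a biopsy is called IDH-mutant
#'   (default 0.1; mutant and wildtype scores separate widely, so the
#'   call is insensitive to the exact value).
#' @return A `score_params` object.
#' @export
score_params <- function(isotope_correction = 0.061, call_threshold = 0.1) {
  stopifnot(isotope_correction >= 0, isotope_correction < 1)
  structure(list(isotope_correction = isotope_correction,
                 call_threshold = call_threshold),
            class = "score_params")
}

#' Average the MS/MS scans of one spot
#'
#' Resamples every product-ion scan onto a shared fine grid by
#' nearest-grid-point binning (area-preserving for centroided stick
#' spectra) and takes the point-wise mean.
#'
#' @param stream `scan_stream` of MS/MS scans.
#' @param grid Shared product-ion grid; the default covers m/z 100-160 at
#'   0.001 spacing.
#' @return A single averaged [scan()].
#' @export
average_msms <- function(stream, grid = mz_grid(100, 160, 0.001)) {
  stopifnot(inherits(stream, "scan_stream"))
  if (!length(stream$scans)) stop("empty MS/MS stream", call. = FALSE)
  gp <- grid_points(grid)
  acc <- numeric(length(gp))
  for (s in stream$scans) acc <- acc + resample_scan(s, grid, "nearest")
  avg <- acc / length(stream$scans)
  keep <- avg > 0
  win <- stream$scans[[1]]$precursor_window
  scan(start_time_s = stream$scans[[1]]$start_time_s,
       mz = gp[keep], intensity = avg[keep], mode = "msms",
       precursor_window = win %||% c(146.5, 3))
}

#' Extract the Glu / 2HG fragment-bin intensities
#'
#' Sums intensity in 1-m/z-unit bins centered on the product ions:
#' I128 over `[127.5, 128.5)` and I129 over `[128.5, 129.5)` by default.
#' Bins are half-open (shared edge counts upward) so they partition the
#' axis; an empty bin gives 0.
#'
#' @param avg Averaged MS/MS [scan()] from [average_msms()].
#' @param method An [msms_method()].
#' @param statistic Bin statistic: `"sum"` (default) totals all intensity
#'   in the bin, `"max"` takes the most intense point instead.
#' @return A `fragment_intensities` object with fields `I128` and `I129`.
#' @export
extract_fragment_intensities <- function(avg, method = msms_method(),
                                         statistic = c("sum", "max")) {
  statistic <- match.arg(statistic)
  half <- method$bin_width_mz / 2
  in_bin <- function(center) {
    sel <- avg$mz >= center - half & avg$mz < center + half
    if (!any(sel)) return(0)
    if (statistic == "sum") sum(avg$intensity[sel])
    else max(avg$intensity[sel])
  }
  structure(list(I128 = in_bin(method$glu_bin_mz),
                 I129 = in_bin(method$twohg_bin_mz)),
            class = "fragment_intensities")
}

#' Compute the IDH mutation score
#'
#' The score is the 2HG:Glu product-ion ratio corrected for the 13C-Glu
#' isotope contribution to the m/z 129 bin:
#' `score = (I129 - I128 * isotope_correction) / I128`.
#' Ratios of co-acquired channels cancel temporal signal drift, so the
#' score is invariant to common intensity scaling. It can be negative
#' when the m/z 129 bin holds less than the isotopic expectation.
#'
#' @param fi A `fragment_intensities` (or list with `I128`, `I129`).
#' @param params A [score_params()].
#' @return Numeric score.
#' @export
compute_idh_score <- function(fi, params = score_params()) {
  if (!(fi$I128 > 0)) {
    stop("IDH score undefined: Glu fragment intensity I128 = ", fi$I128,
         " (I129 = ", fi$I129, "); no usable Glu signal in the m/z 128 bin",
         call. = FALSE)
  }
  (fi$I129 - fi$I128 * params$isotope_correction) / fi$I128
}

#' Call IDH genotype from a score
#'
#' @param score Finite numeric score.
#' @param params A [score_params()]; the call is `IDH_mutant` iff
#'   `score > call_threshold` (strict, so a score exactly at threshold is
#'   wildtype).
#' @return `"IDH_mutant"` or `"IDH_wildtype"`.
#' @export
call_genotype <- function(score, params = score_params()) {
  stopifnot(is.finite(score))
  if (score > params$call_threshold) "IDH_mutant" else "IDH_wildtype"
}

#' Score a whole TMA of per-spot MS/MS runs
#'
#' Resolves each spot's run to its biopsy through the layout and plate
#' map, averages the scans, extracts fragment bins and computes the score
#' and genotype call. Spots that cannot be resolved to a biopsy are
#' logged and excluded. One result row per resolvable biopsy, ordered by
#' biopsy id.
#'
#' @param msms_runs Named list of `scan_stream`s keyed by spot index
#'   (from [read_msms_runs()] or the simulator).
#' @param layout A `tma_layout`.
#' @param plate_map A `plate_map`.
#' @param params A [score_params()].
#' @param method An [msms_method()].
#' @return Data frame with columns `biopsy_id`, `spot_index`, `I128`,
#'   `I129`, `score`, `call`, `threshold`, `n_scans`.
#' @export
score_tma <- function(msms_runs, layout, plate_map,
                      params = score_params(), method = msms_method()) {
  plate_map <- read_plate_map(plate_map)
  key <- paste(layout$spots$plate_id, layout$spots$well, sep = "\r")
  map_key <- paste(plate_map$plate_id, plate_map$well, sep = "\r")
  spot_biopsy <- stats::setNames(plate_map$biopsy_id[match(key, map_key)],
                                 as.character(layout$spots$index))
  rows <- list()
  for (k in names(msms_runs)) {
    b <- spot_biopsy[[k]]
    if (is.null(b) || is.na(b)) {
      message("MS/MS spot ", k, " does not resolve to a biopsy; excluded")
      next
    }
    avg <- average_msms(msms_runs[[k]])
    fi <- extract_fragment_intensities(avg, method)
    sc <- compute_idh_score(fi, params)
    rows[[length(rows) + 1L]] <- data.frame(
      biopsy_id = b, spot_index = as.integer(k),
      I128 = fi$I128, I129 = fi$I129, score = sc,
      call = call_genotype(sc, params),
      threshold = params$call_threshold,
      n_scans = length(msms_runs[[k]]$scans),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else data.frame(biopsy_id = character(), spot_index = integer(),
                         I128 = numeric(), I129 = numeric(),
                         score = numeric(), call = character(),
                         threshold = numeric(), n_scans = integer(),
                         stringsAsFactors = FALSE)
  res <- res[order(res$biopsy_id, res$spot_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}
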