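# Synthetic DESI acquisition simulator: class-dependent lipid templates,
# TCP mixing, full-scan raster runs with stage logs, per-spot MS/MS runs
# with the 2HG/Glu channels, and complete ground-truth manifests.

.GLU_FRAG_MZ <- 128.0353    # Glu [M-H-H2O]-
.TWOHG_FRAG_MZ <- 129.0193  # 2HG [M-H-H2O]-
.C13_GLU_FRAG_MZ <- 129.0386  # 13C-Glu [M-H-H2O]-

#' Acquisition noise model
#'
#' Statistical model of spot-to-spot and scan-to-scan variability:
#' multiplicative log-normal per-peak noise, a per-spot transfer scale
#' (differences in transfer efficiency and blood content), small m/z
#' jitter, and an optional chemical baseline of random low-intensity
#' peaks.
#'
#' @param peak_cv Coefficient of variation of the per-peak log-normal
#'   intensity noise (default 0.2).
#' @param baseline_level Mean intensity of baseline peaks (default 0 =
#'   no baseline).
#' @param mz_jitter_ppm Standard deviation of m/z jitter in ppm
#'   (default 2).
#' @param spot_scale_cv CV of the per-spot log-normal intensity scale
#'   (default 0.3).
#' @param seed Integer seed; identical seeds give byte-identical
#'   simulations.
#' @return A `noise_model` object.
#' @export
noise_model <- function(peak_cv = 0.2, baseline_level = 0,
                        mz_jitter_ppm = 2, spot_scale_cv = 0.3, seed = 1L) {
  stopifnot(peak_cv >= 0, baseline_level >= 0, mz_jitter_ppm >= 0,
            spot_scale_cv >= 0)
  structure(list(peak_cv = peak_cv, baseline_level = baseline_level,
                 mz_jitter_ppm = mz_jitter_ppm,
                 spot_scale_cv = spot_scale_cv, seed = as.integer(seed)),
            class = "noise_model")
}

.lnorm_sdlog <- function(cv) if (cv > 0) sqrt(log(1 + cv^2)) else 0

.rln <- function(n, cv) {
  if (cv <= 0) rep(1, n) else stats::rlnorm(n, meanlog = 0,
                                            sdlog = .lnorm_sdlog(cv))
}

#' Build a ground-truth sample sheet
#'
#' One row per biopsy with tissue class, tumor cell percentage (glioma
#' only), IDH genotype and true 2HG:Glu fragment ratio, plus the
#' simulator nuisance parameters. Biopsies are assigned to source-plate
#' wells in row-major order. Invariants enforced: mutants have ratio > 0,
#' wildtypes ratio 0.
#'
#' @param tissue_class Character vector in
#'   `c("NCB", "glioma", "meningioma", "pituitary")`.
#' @param tcp Tumor cell percentage in `[0, 1]`; `NA` outside glioma.
#' @param idh `"mutant"`, `"wildtype"` or `NA` per biopsy.
#' @param true_2hg_glu_ratio True 2HG:Glu fragment ratio (>= 0).
#' @param transfer_efficiency Per-biopsy mean transfer scale (> 0).
#' @param failed_spot_probability Probability that a given spot of the
#'   biopsy is an incomplete transfer.
#' @param biopsy_id Ids; default `B001`, `B002`, ...
#' @param plate_id Source plate id (default `"SP1"`).
#' @return A `sample_sheet` data frame including `plate_id` and `well`.
#' @export
sample_sheet <- function(tissue_class, tcp = NA_real_, idh = NA_character_,
                         true_2hg_glu_ratio = 0, transfer_efficiency = 1,
                         failed_spot_probability = 0, biopsy_id = NULL,
                         plate_id = "SP1") {
  n <- length(tissue_class)
  stopifnot(n >= 1L, n <= 384L,
            all(tissue_class %in% c("NCB", "glioma", "meningioma",
                                    "pituitary")))
  sheet <- data.frame(
    biopsy_id = biopsy_id %||% sprintf("B%03d", seq_len(n)),
    tissue_class = tissue_class,
    tcp = rep_len(as.numeric(tcp), n),
    idh = rep_len(as.character(idh), n),
    true_2hg_glu_ratio = rep_len(as.numeric(true_2hg_glu_ratio), n),
    transfer_efficiency = rep_len(as.numeric(transfer_efficiency), n),
    failed_spot_probability = rep_len(as.numeric(failed_spot_probability), n),
    plate_id = plate_id,
    well = well_labels()[seq_len(n)],
    stringsAsFactors = FALSE
  )
  bad <- (!is.na(sheet$idh) & sheet$idh == "mutant" &
            sheet$true_2hg_glu_ratio <= 0) |
         (!is.na(sheet$idh) & sheet$idh == "wildtype" &
            sheet$true_2hg_glu_ratio != 0)
  if (any(bad)) {
    stop("sample sheet invariant violated (mutant => ratio > 0, ",
         "wildtype => ratio = 0) for: ",
         paste(sheet$biopsy_id[bad], collapse = ", "), call. = FALSE)
  }
  stopifnot(all(sheet$transfer_efficiency > 0),
            all(sheet$failed_spot_probability >= 0 &
                  sheet$failed_spot_probability <= 1))
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Plate map of a sample sheet
#' @param sheet A [sample_sheet()].
#' @return The corresponding `plate_map` (biopsy -> plate/well + metadata).
#' @export
sheet_plate_map <- function(sheet) {
  pm <- data.frame(biopsy_id = sheet$biopsy_id, plate_id = sheet$plate_id,
                   well = sheet$well, tissue_class = sheet$tissue_class,
                   tcp = sheet$tcp, idh = sheet$idh,
                   stringsAsFactors = FALSE)
  read_plate_map(pm)
}

#' Source plate(s) of a sample sheet
#' @param sheet A [sample_sheet()].
#' @return List of `well_plate` objects, one per distinct plate id.
#' @export
sheet_plates <- function(sheet) {
  lapply(split(sheet, sheet$plate_id), function(s) {
    well_plate(s$plate_id[1], stats::setNames(s$biopsy_id, s$well))
  })
}

#' IDH genotyping study cohort
#'
#' A 40-biopsy glioma cohort for targeted MS/MS validation: half
#' IDH-mutant with true 2HG:Glu fragment ratios drawn uniformly from
#' `ratio_range`, half wildtype with ratio 0.
#'
#' @param n_mutant,n_wildtype Cohort composition (default 20 + 20).
#' @param ratio_range Range of mutant ratios (default `c(0.5, 3)`).
#' @param seed Seed for the ratio draw.
#' @return A [sample_sheet()].
#' @export
idh_cohort_sheet <- function(n_mutant = 20L, n_wildtype = 20L,
                             ratio_range = c(0.5, 3), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ratios <- stats::runif(n_mutant, ratio_range[1], ratio_range[2])
  sample_sheet(
    tissue_class = rep("glioma", n_mutant + n_wildtype),
    tcp = 0.8,
    idh = c(rep("mutant", n_mutant), rep("wildtype", n_wildtype)),
    true_2hg_glu_ratio = c(ratios, rep(0, n_wildtype))
  )
}

#' Brain-tissue screening cohort
#'
#' A 36-biopsy sheet emulating a banked brain-tissue collection: 14
#' non-cancerous brain parenchyma (NCB), 13 glioma (TCP spread evenly
#' over 0.2-0.95; 6 IDH-mutant, 7 wildtype), 5 meningioma and 4
#' pituitary samples.
#'
#' @param seed Seed for the mutant ratio draw.
#' @param failed_spot_probability Per-spot failed-transfer probability
#'   (default 0).
#' @return A [sample_sheet()].
#' @export
brain_cohort_sheet <- function(seed = 1L, failed_spot_probability = 0) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- c(rep("NCB", 14), rep("glioma", 13), rep("meningioma", 5),
           rep("pituitary", 4))
  tcp <- c(rep(NA, 14), seq(0.2, 0.95, length.out = 13), rep(NA, 9))
  idh <- c(rep(NA, 14), rep("mutant", 6), rep("wildtype", 7), rep(NA, 9))
  ratio <- ifelse(!is.na(idh) & idh == "mutant",
                  stats::runif(length(cls), 0.5, 3), 0)
  sample_sheet(cls, tcp = tcp, idh = idh, true_2hg_glu_ratio = ratio,
               failed_spot_probability = failed_spot_probability)
}

# invented templates for tumor types the marker panel does not cover;
# peak positions are synthetic, not literature species
.MENINGIOMA_PEAKS <- data.frame(
  mz = c(715.4500, 745.4800, 788.5447, 794.5467, 834.5291, 885.5499),
  intensity = c(1.0, 0.8, 0.35, 0.3, 0.45, 0.25)
)
.PITUITARY_PEAKS <- data.frame(
  mz = c(815.5500, 842.5800, 766.5392, 700.5287, 888.6240, 598.4966),
  intensity = c(1.0, 0.7, 0.4, 0.3, 0.2, 0.35)
)

.norm_template <- function(df) {
  df <- stats::aggregate(intensity ~ mz, df, sum)
  df <- df[order(df$mz), , drop = FALSE]
  df$intensity <- df$intensity / max(df$intensity)
  rownames(df) <- NULL
  df
}

.panel_template <- function(association) {
  tab <- builtin_marker_table()
  tab <- tab[tab$association == association, , drop = FALSE]
  # fixed relative abundances, decreasing within the panel order
  w <- c(1.0, 0.9, 0.8, 0.6, 0.5, 0.45, 0.4, 0.35, 0.3, 0.28,
         0.26, 0.24, 0.22, 0.2)[seq_len(nrow(tab))]
  data.frame(mz = tab$theoretical_mz, intensity = w)
}

#' Class-dependent spectral template
#'
#' Returns the noise-free centroid template (m/z, relative intensity,
#' base peak 1) for one tissue class. Glioma and NCB templates are the
#' linear TCP mix `tcp * tumor + (1 - tcp) * normal` of the two
#' marker-panel templates (higher-TCP species vs lower-TCP species);
#' NCB uses tcp = 0. Meningioma and pituitary carry distinct fixed
#' synthetic templates.
#'
#' @param tissue_class One of `"NCB"`, `"glioma"`, `"meningioma"`,
#'   `"pituitary"`.
#' @param tcp Tumor cell percentage in `[0, 1]` (glioma; ignored
#'   elsewhere).
#' @return Data frame with columns `mz`, `intensity` (max 1), sorted by
#'   m/z.
#' @export
class_template <- function(tissue_class, tcp = NA_real_) {
  tissue_class <- match.arg(tissue_class,
                            c("NCB", "glioma", "meningioma", "pituitary"))
  if (tissue_class == "meningioma") return(.norm_template(.MENINGIOMA_PEAKS))
  if (tissue_class == "pituitary") return(.norm_template(.PITUITARY_PEAKS))
  if (tissue_class == "NCB") tcp <- 0
  if (is.na(tcp)) stop("glioma template requires tcp", call. = FALSE)
  stopifnot(tcp >= 0, tcp <= 1)
  normal <- .panel_template("lower_TCP")
  tumor <- .panel_template("higher_TCP")
  normal$intensity <- (1 - tcp) * normal$intensity
  tumor$intensity <- tcp * tumor$intensity
  .norm_template(rbind(normal, tumor))
}

# snap m/z to the grid's reporting resolution and add zero-intensity
# flanking points one step either side of each stick
.emit_centroids <- function(mz, intensity, grid) {
  snapped <- grid$mz_min + round((mz - grid$mz_min) / grid$step) * grid$step
  flank <- c(snapped - grid$step, snapped + grid$step)
  all_mz <- c(snapped, flank)
  all_in <- c(intensity, numeric(length(flank)))
  keep <- all_mz >= grid$mz_min & all_mz <= grid$mz_max
  list(mz = all_mz[keep], intensity = all_in[keep])
}

.noisy_peaks <- function(template, scale, noise, grid) {
  inten <- template$intensity * scale * .rln(nrow(template), noise$peak_cv)
  mz <- template$mz *
    (1 + noise$mz_jitter_ppm * stats::rnorm(nrow(template)) / 1e6)
  if (noise$baseline_level > 0) {
    nb <- 20L
    mz <- c(mz, stats::runif(nb, grid$mz_min, grid$mz_max))
    inten <- c(inten, stats::rexp(nb, rate = 1 / noise$baseline_level))
  }
  .emit_centroids(mz, inten, grid)
}

#' Simulate a full-scan raster acquisition of a TMA
#'
#' For every spot of the layout, draws a per-spot transfer scale
#' (log-normal, CV `spot_scale_cv`, times the biopsy's transfer
#' efficiency; failed transfers scaled by `failure_scale`), then emits
#' `scans_per_spot` centroid scans of the biopsy's class template with
#' per-peak log-normal noise, m/z jitter and optional baseline, placed on
#' consecutive dwell windows in raster order. Deterministic given the
#' noise model's seed.
#'
#' @param layout A `tma_layout` whose wells resolve through the sheet.
#' @param sheet A [sample_sheet()].
#' @param noise A [noise_model()].
#' @param grid Analysis [mz_grid()]; emitted centroid m/z are reported at
#'   the grid's resolution.
#' @param scans_per_spot Scans per dwell window (default 5, i.e. 500 ms
#'   at 100 ms per scan).
#' @param scan_time_s Scan time (default 0.1).
#' @param travel_s Stage travel time between spots (default 0.1); scans
#'   are never emitted in travel windows.
#' @param failure_scale Intensity scale of failed transfers (default
#'   0.01).
#' @param out_dir If non-NULL, writes `run.mzML`, `stage_log.csv`,
#'   `plate_map.csv`, `layout.csv` and `manifest.json` there.
#' @return List with `stream` (`scan_stream`), `stage_log`, `plate_map`,
#'   `manifest` (ground truth: spot -> biopsy, applied scales, failed
#'   spots, per-biopsy truth, seed) and `paths` (when written).
#' @export
simulate_fullscan_run <- function(layout, sheet, noise = noise_model(),
                                  grid = mz_grid(), scans_per_spot = 5L,
                                  scan_time_s = 0.1, travel_s = 0.1,
                                  failure_scale = 0.01, out_dir = NULL) {
  stopifnot(inherits(layout, "tma_layout"), inherits(sheet, "sample_sheet"))
  pm <- sheet_plate_map(sheet)
  key <- paste(layout$spots$plate_id, layout$spots$well, sep = "\r")
  row_of <- match(key, paste(sheet$plate_id, sheet$well, sep = "\r"))
  if (anyNA(row_of)) {
    stop("layout contains wells absent from the sample sheet", call. = FALSE)
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)

  templates <- lapply(seq_len(nrow(sheet)), function(i)
    class_template(sheet$tissue_class[i], sheet$tcp[i]))

  dwell <- scans_per_spot * scan_time_s
  n_spots <- nrow(layout$spots)
  scans <- vector("list", n_spots * scans_per_spot)
  log <- data.frame(spot_index = layout$spots$index,
                    t_arrive_s = NA_real_, t_leave_s = NA_real_)
  scale_applied <- numeric(n_spots)
  failed <- logical(n_spots)
  si <- 0L
  for (j in seq_len(n_spots)) {
    b <- row_of[j]
    t0 <- (j - 1L) * (dwell + travel_s)
    log$t_arrive_s[j] <- t0
    log$t_leave_s[j] <- t0 + dwell
    sc <- sheet$transfer_efficiency[b] * .rln(1, noise$spot_scale_cv)
    failed[j] <- stats::runif(1) < sheet$failed_spot_probability[b]
    if (failed[j]) sc <- sc * failure_scale
    scale_applied[j] <- sc
    for (k in seq_len(scans_per_spot)) {
      pk <- .noisy_peaks(templates[[b]], sc, noise, grid)
      si <- si + 1L
      scans[[si]] <- scan(t0 + (k - 1L) * scan_time_s, pk$mz, pk$intensity,
                          mode = "full_scan")
    }
  }
  stream <- scan_stream("simulated_fullscan", scans)
  stage_log <- read_stage_log(log)
  manifest <- list(
    kind = "fullscan", seed = noise$seed, grid = unclass(grid),
    scans_per_spot = scans_per_spot,
    spots = data.frame(spot_index = layout$spots$index,
                       biopsy_id = sheet$biopsy_id[row_of],
                       scale = scale_applied, failed = failed,
                       stringsAsFactors = FALSE),
    biopsies = as.data.frame(sheet)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(run = file.path(out_dir, "run.mzML"),
                  stage_log = file.path(out_dir, "stage_log.csv"),
                  plate_map = file.path(out_dir, "plate_map.csv"),
                  layout = file.path(out_dir, "layout.csv"),
                  manifest = file.path(out_dir, "manifest.json"))
    write_mzml(stream, paths$run)
    write_stage_log(stage_log, paths$stage_log)
    write_plate_map(pm, paths$plate_map)
    write_layout(layout, paths$layout)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  list(stream = stream, stage_log = stage_log, plate_map = pm,
       manifest = manifest, paths = paths)
}

#' Simulate per-spot MS/MS acquisitions for IDH genotyping
#'
#' For each biopsy (one array spot each, spot index = row order), emits
#' `n_scans` product-ion scans of the paired 2HG/Glu method: a Glu
#' water-loss fragment stick at m/z 128.0353 of area G (reduced by
#' `glu_mutant_factor` in mutants, whose Glu is typically depleted), a
#' 13C-Glu isotope stick at m/z 129.0386 of area
#' `G * isotope_correction` (fully correlated with the Glu channel), and
#' a 2HG stick at m/z 129.0193 of area `glu_level * true_ratio` with
#' independent per-scan noise. Deterministic given the noise seed.
#'
#' @param sheet A [sample_sheet()]; biopsies without an `idh` annotation
#'   (non-glioma tissue) are simulated with normal Glu and no 2HG.
#' @param noise A [noise_model()].
#' @param params A [score_params()] supplying the isotope crosstalk
#'   fraction planted in the data.
#' @param n_scans Scans per spot (default 25; about 6 s of acquisition).
#' @param glu_area Mean Glu fragment area in wildtype tissue.
#' @param glu_mutant_factor Glu reduction factor in mutants (default
#'   0.5).
#' @param out_dir If non-NULL, writes one `spot_%04d.mzML` per biopsy
#'   plus `plate_map.csv` and `manifest.json`.
#' @return List with `runs` (named list of `scan_stream` keyed by spot
#'   index), `layout` (single-replicate `tma_layout`), `plate_map`,
#'   `manifest` and `dir`.
#' @export
simulate_msms_run <- function(sheet, noise = noise_model(),
                              params = score_params(), n_scans = 25L,
                              glu_area = 1000, glu_mutant_factor = 0.5,
                              out_dir = NULL) {
  stopifnot(inherits(sheet, "sample_sheet"),
            all(sheet$true_2hg_glu_ratio >= 0),
            all(sheet$true_2hg_glu_ratio[is.na(sheet$idh)] == 0))
  layout <- build_tma_layout(sheet_plates(sheet), replicates = 1L)
  pm <- sheet_plate_map(sheet)
  key <- paste(layout$spots$plate_id, layout$spots$well, sep = "\r")
  spot_of <- layout$spots$index[match(paste(sheet$plate_id, sheet$well,
                                            sep = "\r"), key)]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)

  runs <- list()
  for (i in seq_len(nrow(sheet))) {
    is_mut <- !is.na(sheet$idh[i]) && sheet$idh[i] == "mutant"
    glu_level <- glu_area * (if (is_mut) glu_mutant_factor else 1)
    hg_level <- glu_level * sheet$true_2hg_glu_ratio[i]
    scans <- vector("list", n_scans)
    for (k in seq_len(n_scans)) {
      eps_glu <- .rln(1, noise$peak_cv)
      eps_hg <- .rln(1, noise$peak_cv)
      mzv <- c(.GLU_FRAG_MZ, .C13_GLU_FRAG_MZ, .TWOHG_FRAG_MZ) *
        (1 + noise$mz_jitter_ppm * stats::rnorm(3) / 1e6)
      inten <- c(glu_level * eps_glu,
                 glu_level * eps_glu * params$isotope_correction,
                 hg_level * eps_hg)
      keep <- inten > 0
      scans[[k]] <- scan((k - 1L) * 0.24, mzv[keep], inten[keep],
                         mode = "msms", precursor_window = c(146.5, 3))
    }
    runs[[as.character(spot_of[i])]] <-
      scan_stream(sprintf("spot_%04d", spot_of[i]), scans)
  }
  manifest <- list(kind = "msms", seed = noise$seed, n_scans = n_scans,
                   glu_area = glu_area, glu_mutant_factor = glu_mutant_factor,
                   isotope_correction = params$isotope_correction,
                   spots = data.frame(spot_index = spot_of,
                                      biopsy_id = sheet$biopsy_id,
                                      stringsAsFactors = FALSE),
                   biopsies = as.data.frame(sheet))
  dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(runs)) {
      write_mzml(runs[[k]],
                 file.path(out_dir, sprintf("spot_%04d.mzML", as.integer(k))))
    }
    write_plate_map(pm, file.path(out_dir, "plate_map.csv"))
    write_layout(layout, file.path(out_dir, "layout.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    dir <- out_dir
  }
  list(runs = runs, layout = layout, plate_map = pm, manifest = manifest,
       dir = dir)
}
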