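# Shared fixture builders: everything is generated in code at test time.

# a noise model with every stochastic term switched off
quiet_noise <- function(seed = 1L) {
  noise_model(peak_cv = 0, baseline_level = 0, mz_jitter_ppm = 0,
              spot_scale_cv = 0, seed = seed)
}

# small partially occupied plate: n biopsies in the first n wells
tiny_plate <- function(plate_id = "P1", n = 4, prefix = "B") {
  labs <- well_labels()[seq_len(n)]
  well_plate(plate_id, stats::setNames(paste0(prefix, seq_len(n)), labs))
}

# sheet of n glioma biopsies with explicit genotypes/ratios
tiny_idh_sheet <- function(idh, ratio) {
  sample_sheet(tissue_class = rep("glioma", length(idh)), tcp = 0.8,
               idh = idh, true_2hg_glu_ratio = ratio)
}

# a centroid stick scan
stick_scan <- function(mz, intensity, t = 0, mode = "full_scan",
                       win = if (mode == "msms") c(146.5, 3) else NULL) {
  scan(t, mz, intensity, mode = mode, precursor_window = win)
}

# independent piecewise-linear interpolation oracle (explicit formula,
# no shared code with resample_scan)
oracle_interp <- function(mz, inten, points) {
  vapply(points, function(g) {
    if (g < mz[1] || g > mz[length(mz)]) return(0)
    j <- max(which(mz <= g))
    if (j == length(mz)) return(inten[j])
    w <- (g - mz[j]) / (mz[j + 1] - mz[j])
    max((1 - w) * inten[j] + w * inten[j + 1], 0)
  }, numeric(1))
}

# brute-force O(n*m) scan-to-interval assignment oracle
oracle_assign <- function(times, log) {
  vapply(times, function(t) {
    hit <- which(t >= log$t_arrive_s & t < log$t_leave_s)
    if (length(hit) == 1L) log$spot_index[hit] else NA_integer_
  }, numeric(1))
}

# run the full MS/MS genotyping pipeline in memory for one seed and
# return per-biopsy calls joined to the ground truth
run_idh_cohort <- function(seed, n_scans = 25L, peak_cv = 0.2) {
  sheet <- idh_cohort_sheet(seed = seed)
  sim <- simulate_msms_run(sheet, noise_model(peak_cv = peak_cv, seed = seed),
                           n_scans = n_scans)
  res <- score_tma(sim$runs, sim$layout, sim$plate_map)
  truth <- ifelse(sheet$idh == "mutant", "IDH_mutant", "IDH_wildtype")
  data.frame(biopsy_id = sheet$biopsy_id, truth = truth,
             call = res$call[match(sheet$biopsy_id, res$biopsy_id)],
             score = res$score[match(sheet$biopsy_id, res$biopsy_id)],
             true_ratio = sheet$true_2hg_glu_ratio,
             stringsAsFactors = FALSE)
}
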