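# Exact-mass computation and ppm-tolerance lipid annotation.

# Monoisotopic masses of the most abundant isotope of each supported element,
# IUPAC/CODATA values to >= 6 decimals.
.element_masses <- c(
  C  = 12.0000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271
)

# Adduct mass shifts (Da): proton 1.007276, chloride 34.968853, water 18.010565.
.adduct_shifts <- c(
  "[M-H]-"     = -1.007276,
  "[M+Cl]-"    = +34.968853,
  "[M-H-H2O]-" = -1.007276 - 18.010565
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic (most-abundant-isotope) mass of a neutral
#' molecule from a Hill-style formula string such as `"C42H80NO10P"`.
#' Supported elements are C, H, N, O, P, S and Cl.
#'
#' @param formula Character vector of molecular formulas. An element symbol
#'   without a count means count 1 (`"NO10P"` = one N, ten O, one P).
#' @return Numeric vector of masses in Da. The empty formula `""` gives 0.
#' @examples
#' monoisotopic_mass("H2O")          # 18.010565
#' monoisotopic_mass("C42H80NO10P")  # PS 36:1 neutral mass
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(0)
    tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (sum(nchar(tokens)) != nchar(f)) {
      stop("malformed formula: '", f, "'", call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      el <- gsub("[0-9]", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.element_masses)) {
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      total <- total + .element_masses[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of a negative-mode adduct
#'
#' Converts a neutral monoisotopic mass to the m/z of a deprotonated,
#' chlorinated or water-loss ion, the three species observed in
#' negative-mode DESI of brain lipids and metabolites.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"[M-H]-"`, `"[M+Cl]-"`, `"[M-H-H2O]-"`.
#' @return m/z of the ion (singly charged).
#' @examples
#' adduct_mz(monoisotopic_mass("C42H80NO10P"), "[M-H]-")  # 788.5447
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  adduct <- match.arg(adduct, names(.adduct_shifts))
  neutral_mass + .adduct_shifts[[adduct]]
}

#' Built-in brain-tissue lipid marker panel
#'
#' Returns the panel of lipid species reported as DESI-MS markers of
#' tumor-cell-percentage (TCP) contrast in glioma biopsies: PS 36:1 and
#' sulfatides associated with lower-TCP (gray/white matter) samples, and
#' PE/PC/PI/PS species, plasmenyl-PEs and chloride-adducted ceramides
#' associated with higher-TCP samples. Formulas are sum-composition level:
#' glycerophospholipids carry total acyl carbons:double-bonds,
#' sphingolipids assume a d18:1 backbone.
#'
#' @return A data frame with columns `name`, `class_tag`, `formula`,
#'   `adduct`, `association` (`lower_TCP`/`higher_TCP`), `printed_mz`
#'   (literature 1-dp value), `theoretical_mz` (computed here) and
#'   `flagged` (`TRUE` where the computed adduct m/z does not round to the
#'   literature value; PI 38:4 and plasmenyl-PE 40:6).
#' @export
builtin_marker_table <- function() {
  path <- system.file("extdata", "marker_panel.csv", package = "desitma",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(tab$name))
  tab$theoretical_mz <- mapply(
    function(f, a) adduct_mz(monoisotopic_mass(f), a),
    tab$formula, tab$adduct, USE.NAMES = FALSE
  )
  tab
}

#' Annotate observed peaks against a lipid panel
#'
#' Matches observed m/z values to the theoretical adduct masses of a
#' species table within a relative mass tolerance, reporting every
#' (peak, species) pair inside the tolerance. Ties (one peak matching
#' several species, or vice versa) are reported, not resolved.
#'
#' @param peaks Numeric vector of observed m/z values.
#' @param table Species table as returned by [builtin_marker_table()]
#'   (needs columns `name`, `formula`, `adduct`; `theoretical_mz` is
#'   computed when absent).
#' @param tolerance_ppm Maximum absolute mass error in parts per million
#'   (default 5, the usual QTOF exact-mass criterion).
#' @return Data frame with columns `observed_mz`, `name`, `adduct`,
#'   `theoretical_mz`, `ppm_error` where
#'   `ppm_error = 1e6 * (observed - theoretical) / theoretical`.
#' @export
annotate_peaks <- function(peaks, table = builtin_marker_table(),
                           tolerance_ppm = 5) {
  stopifnot(is.numeric(peaks), tolerance_ppm > 0)
  if (is.null(table$theoretical_mz)) {
    table$theoretical_mz <- mapply(
      function(f, a) adduct_mz(monoisotopic_mass(f), a),
      table$formula, table$adduct, USE.NAMES = FALSE
    )
  }
  out <- list()
  for (i in seq_along(peaks)) {
    ppm <- 1e6 * (peaks[i] - table$theoretical_mz) / table$theoretical_mz
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        observed_mz = peaks[i],
        name = table$name[hit],
        adduct = table$adduct[hit],
        theoretical_mz = table$theoretical_mz[hit],
        ppm_error = ppm[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(observed_mz = numeric(), name = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
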