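# TMA geometry: 384-well source plates, high-density spot grids, and
# stage-coordinate calibration.

.PLATE_ROWS <- 16L  # A..P
.PLATE_COLS <- 24L  # 1..24
.MAX_SPOTS <- 6144L

#' Labels of a 384-well plate
#'
#' @return Character vector of the 384 well labels in row-major order
#'   ("A1".."A24", "B1", ..., "P24").
#' @export
well_labels <- function() {
  as.vector(t(outer(LETTERS[seq_len(.PLATE_ROWS)], seq_len(.PLATE_COLS), paste0)))
}

#' 384-well source plate
#'
#' A source plate holds up to 384 biopsies, one per well. Wells not listed
#' in `assignments` are empty and produce no spots when the plate is
#' arrayed.
#'
#' @param plate_id Plate identifier string.
#' @param assignments Named character vector mapping well labels (e.g.
#'   `"A1"`) to biopsy ids. Unnamed empty vector gives an empty plate.
#' @return A `well_plate` object.
#' @export
well_plate <- function(plate_id, assignments = character()) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L)
  assignments <- as.character(assignments) |>
    stats::setNames(names(assignments))
  if (length(assignments)) {
    labs <- names(assignments)
    if (is.null(labs) || any(!nzchar(labs))) {
      stop("well assignments must be named by well label", call. = FALSE)
    }
    bad <- setdiff(labs, well_labels())
    if (length(bad)) {
      stop("invalid well label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(labs)) {
      stop("duplicate well labels in plate '", plate_id, "'", call. = FALSE)
    }
  }
  structure(list(plate_id = plate_id, assignments = assignments),
            class = "well_plate")
}

#' Fully occupied plate (convenience)
#'
#' @param plate_id Plate identifier.
#' @param biopsy_prefix Prefix for auto-generated biopsy ids; default
#'   derives one biopsy per well named `<plate_id>_<well>`.
#' @return A `well_plate` with all 384 wells occupied.
#' @export
full_plate <- function(plate_id, biopsy_prefix = plate_id) {
  labs <- well_labels()
  well_plate(plate_id, stats::setNames(paste0(biopsy_prefix, "_", labs), labs))
}

#' Spot geometry of a DESI array
#'
#' @param pitch_mm Center-to-center spot distance in mm (1.1 at the
#'   highest density).
#' @param spot_diameter_um Spot diameter in micrometres (ca. 800 for
#'   pin-tool transfers).
#' @param origin_mm Numeric length-2, (x, y) of the row-0/col-0 spot centre.
#' @return A `spot_geometry` object.
#' @export
spot_geometry <- function(pitch_mm = 1.1, spot_diameter_um = 800,
                          origin_mm = c(0, 0)) {
  stopifnot(length(origin_mm) == 2L, is.numeric(pitch_mm),
            is.numeric(spot_diameter_um))
  if (!(pitch_mm > spot_diameter_um / 1000 && spot_diameter_um > 0)) {
    stop("require pitch_mm > spot_diameter_um/1000 > 0", call. = FALSE)
  }
  structure(list(pitch_mm = pitch_mm, spot_diameter_um = spot_diameter_um,
                 origin_mm = as.numeric(origin_mm)),
            class = "spot_geometry")
}

#' Build a high-density TMA layout
#'
#' Enumerates every occupied well of every source plate, replicated
#' `replicates` times, onto a single spot grid. Each source plate occupies
#' a contiguous block of 16 rows by `24 * replicates` columns, with the
#' replicate spots of one well at adjacent columns; plate blocks tile the
#' slide left-to-right, wrapping at 96 grid columns. Spot indices are a
#' contiguous 0-based sequence in raster (row-major) order over the final
#' grid, so replicates of a well occupy consecutive indices.
#'
#' @param plates A `well_plate` or list of up to 16 `well_plate` objects.
#' @param replicates Spots per occupied well (>= 1); four replicates of a
#'   full plate give the 1536-position grid used for brain-biopsy TMAs.
#' @param geometry A [spot_geometry()]; spot (row, col) maps to
#'   `origin + c(col, row) * pitch`.
#' @return A `tma_layout` with a `spots` data frame (`index`, `row`,
#'   `col`, `x_mm`, `y_mm`, `plate_id`, `well`, `replicate`), the geometry,
#'   `n_source_plates` and `replicates`. At most 6144 spots.
#' @examples
#' nrow(build_tma_layout(full_plate("P1"), replicates = 4)$spots)  # 1536
#' @export
build_tma_layout <- function(plates, replicates = 1L,
                             geometry = spot_geometry()) {
  if (inherits(plates, "well_plate")) plates <- list(plates)
  stopifnot(length(plates) >= 1L, all(vapply(plates, inherits, TRUE, "well_plate")))
  if (length(plates) > 16L) {
    stop("at most 16 source plates fit one DESI slide", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  ids <- vapply(plates, `[[`, "", "plate_id")
  if (anyDuplicated(ids)) stop("duplicate plate_id", call. = FALSE)

  n_occupied <- vapply(plates, function(p) length(p$assignments), integer(1))
  total <- sum(n_occupied) * replicates
  if (total > .MAX_SPOTS) {
    stop("layout capacity exceeded: ", total, " spots > ", .MAX_SPOTS,
         call. = FALSE)
  }

  block_cols <- .PLATE_COLS * replicates
  plates_per_row <- max(1L, 96L %/% block_cols)
  recs <- vector("list", length(plates))
  all_labs <- well_labels()
  for (i in seq_along(plates)) {
    p <- plates[[i]]
    if (!length(p$assignments)) next
    occ <- all_labs[all_labs %in% names(p$assignments)]  # row-major order
    wr <- match(substr(occ, 1, 1), LETTERS) - 1L
    wc <- as.integer(substring(occ, 2)) - 1L
    brow <- ((i - 1L) %/% plates_per_row) * .PLATE_ROWS
    bcol <- ((i - 1L) %% plates_per_row) * block_cols
    k <- rep(seq_len(replicates) - 1L, times = length(occ))
    recs[[i]] <- data.frame(
      row = brow + rep(wr, each = replicates),
      col = bcol + rep(wc, each = replicates) * replicates + k,
      plate_id = p$plate_id,
      well = rep(occ, each = replicates),
      replicate = k,
      stringsAsFactors = FALSE
    )
  }
  spots <- do.call(rbind, recs)
  if (is.null(spots)) {
    spots <- data.frame(row = integer(), col = integer(),
                        plate_id = character(), well = character(),
                        replicate = integer(), stringsAsFactors = FALSE)
  }
  spots <- spots[order(spots$row, spots$col), , drop = FALSE]
  spots$index <- seq_len(nrow(spots)) - 1L
  spots$x_mm <- geometry$origin_mm[1] + spots$col * geometry$pitch_mm
  spots$y_mm <- geometry$origin_mm[2] + spots$row * geometry$pitch_mm
  spots <- spots[, c("index", "row", "col", "x_mm", "y_mm",
                     "plate_id", "well", "replicate")]
  rownames(spots) <- NULL
  stopifnot(!anyDuplicated(spots[, c("row", "col")]))
  structure(list(spots = spots, geometry = geometry,
                 n_source_plates = length(plates), replicates = replicates),
            class = "tma_layout")
}

#' @export
print.tma_layout <- function(x, ...) {
  cat(sprintf("TMA layout: %d spots (%d plate(s) x %d replicate(s)), pitch %.2f mm\n",
              nrow(x$spots), x$n_source_plates, x$replicates,
              x$geometry$pitch_mm))
  invisible(x)
}

#' Fit a three-point affine stage calibration
#'
#' Solves for the affine map (2x2 linear part plus offset) that sends each
#' of three nominal plate coordinates exactly onto its measured stage
#' counterpart, as obtained from reference dye-marks near the plate
#' corners.
#'
#' @param nominal,measured 3x2 numeric matrices of (x, y) points in mm.
#' @return An `affine_transform` with fields `A` (2x2) and `b` (length 2).
#' @export
fit_calibration <- function(nominal, measured) {
  nominal <- as.matrix(nominal); measured <- as.matrix(measured)
  stopifnot(all(dim(nominal) == c(3, 2)), all(dim(measured) == c(3, 2)))
  M <- cbind(nominal, 1)
  if (abs(det(M)) < 1e-9) {
    stop("calibration points are collinear; affine fit is degenerate",
         call. = FALSE)
  }
  # solve [x y 1] %*% rbind(t(A), t(b)) = measured
  coef <- solve(M, measured)
  tf <- structure(list(A = t(coef[1:2, , drop = FALSE]),
                       b = as.numeric(coef[3, ])),
                  class = "affine_transform")
  if (abs(det(tf$A)) < 1e-12) {
    stop("fitted linear part is singular", call. = FALSE)
  }
  tf
}

#' Invert an affine transform
#'
#' @param t An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_transform <- function(t) {
  Ainv <- solve(t$A)
  structure(list(A = Ainv, b = as.numeric(-Ainv %*% t$b)),
            class = "affine_transform")
}

#' Apply a stage calibration to a layout
#'
#' Maps every spot's (x_mm, y_mm) through the transform; indices, grid
#' rows/columns and plate/well provenance are unchanged.
#'
#' @param t An `affine_transform` from [fit_calibration()].
#' @param layout A `tma_layout`.
#' @return The layout with transformed coordinates.
#' @export
apply_calibration <- function(t, layout) {
  stopifnot(inherits(t, "affine_transform"), inherits(layout, "tma_layout"))
  xy <- cbind(layout$spots$x_mm, layout$spots$y_mm) %*% t(t$A)
  layout$spots$x_mm <- xy[, 1] + t$b[1]
  layout$spots$y_mm <- xy[, 2] + t$b[2]
  layout
}

#' Write / read a layout as CSV
#'
#' The on-disk form is one row per spot with columns
#' `index,row,col,x_mm,y_mm,plate_id,well,replicate`; the spot geometry
#' travels alongside as JSON.
#'
#' @param layout A `tma_layout`.
#' @param path CSV path; the geometry is written to `<path>.geometry.json`.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout$spots, path, row.names = FALSE)
  jsonlite::write_json(
    c(layout$geometry[c("pitch_mm", "spot_diameter_um", "origin_mm")],
      list(n_source_plates = layout$n_source_plates,
           replicates = layout$replicates)),
    paste0(path, ".geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  spots <- utils::read.csv(path, stringsAsFactors = FALSE)
  gpath <- paste0(path, ".geometry.json")
  if (file.exists(gpath)) {
    g <- jsonlite::read_json(gpath, simplifyVector = TRUE)
    geometry <- spot_geometry(g$pitch_mm, g$spot_diameter_um, g$origin_mm)
    n_plates <- g$n_source_plates
    replicates <- g$replicates
  } else {
    geometry <- spot_geometry()
    n_plates <- length(unique(spots$plate_id))
    replicates <- max(spots$replicate) + 1L
  }
  structure(list(spots = spots, geometry = geometry,
                 n_source_plates = n_plates, replicates = replicates),
            class = "tma_layout")
}
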