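#' Superimpose a quadrate grid over the scale region
#'
#' Tiles the roi bounding box with congruent square cells whose side is
#' chosen so that approximately `target_cells` cells fit inside the roi:
#' `side = round(sqrt(roi_area_px / target_cells))`. The tiling is anchored
#' at the top-left corner of the roi bounding box and only cells lying
#' entirely inside the roi are kept, so the summed cell area is unambiguous.
#'
#' @param scene a [scale_scene()].
#' @param target_cells requested number of cells (default 100).
#' @return a `quadrate_grid`: list with `cell_side_px` and `cells`, a
#'   data frame of half-open pixel rectangles (`r0`, `c0` inclusive 1-based
#'   starts; the cell spans `side` rows and columns), in raster (row-major)
#'   order, plus empty `selected_ids`.
#' @export
build_grid <- function(scene, target_cells = 100) {
  stopifnot(inherits(scene, "scale_scene"))
  roi <- scene$roi
  area <- sum(roi)
  if (area == 0L) stopf("roi mask is empty")
  if (target_cells < 1) stopf("`target_cells` must be >= 1")
  side <- max(1L, as.integer(round(sqrt(area / target_cells))))
  w <- which(roi, arr.ind = TRUE)
  rmin <- min(w[, 1L]); rmax <- max(w[, 1L])
  cmin <- min(w[, 2L]); cmax <- max(w[, 2L])
  sat <- summed_area(roi)
  r_starts <- seq.int(rmin, rmax - side + 1L, by = side)
  c_starts <- seq.int(cmin, cmax - side + 1L, by = side)
  if (rmax - rmin + 1L < side || cmax - cmin + 1L < side)
    stopf("roi too small for cell side %d px", side)
  cells <- expand.grid(c0 = c_starts, r0 = r_starts,
                       KEEP.OUT.ATTRS = FALSE)[, c("r0", "c0")]
  full <- mapply(function(r0, c0)
    sat_sum(sat, r0, r0 + side, c0, c0 + side) == side * side,
    cells$r0, cells$c0)
  cells <- cells[full, , drop = FALSE]
  if (nrow(cells) == 0L)
    stopf("no grid cell of side %d px fits entirely inside the roi", side)
  rownames(cells) <- NULL
  structure(list(cell_side_px = side, cells = cells,
                 selected_ids = integer(0), seed = NA_integer_),
            class = "quadrate_grid")
}

#' @export
print.quadrate_grid <- function(x, ...) {
  cat(sprintf("quadrate_grid: %d cells of %d px side, %d selected\n",
              nrow(x$cells), x$cell_side_px, length(x$selected_ids)))
  invisible(x)
}

#' Systematically random selection of grid cells
#'
#' Selects `k` of the grid's cells by systematic sampling in raster order:
#' with `n` cells and stride `floor(n / k)`, a start offset is drawn
#' uniformly from `[0, stride)` and every stride-th cell from there is
#' taken. The seed is recorded in the returned grid so a run can be
#' reproduced exactly.
#'
#' @param grid a `quadrate_grid` from [build_grid()].
#' @param k number of cells to sample (default 10).
#' @param seed integer RNG seed (mandatory; selections must be replayable).
#' @return the grid with `selected_ids` (1-based, strictly increasing) and
#'   `seed` filled in.
#' @export
select_cells <- function(grid, k = 10, seed) {
  stopifnot(inherits(grid, "quadrate_grid"))
  if (missing(seed)) stopf("`seed` is required for cell selection")
  n <- nrow(grid$cells)
  if (k <= 0) stopf("`k` must be positive")
  if (k > n) stopf("cannot select k = %d cells from a grid of %d", k, n)
  stride <- n %/% k
  start <- with_seed(seed, sample.int(stride, 1L) - 1L)
  grid$selected_ids <- as.integer(start + stride * (seq_len(k) - 1L) + 1L)
  grid$seed <- as.integer(seed)
  grid
}

#' Count sensilla in one cell under the unbiased counting-frame rule
#'
#' An object is included if it has at least one pixel inside the cell and
#' does not cross the cell's top or right edge (the two forbidden edges of
#' the counting frame). In discretized form the rule is: the object belongs
#' to the cell whose row band contains its topmost pixel and whose column
#' range contains its rightmost pixel within that band. Any object that
#' crosses a cell's top edge has pixels above the band, and any object
#' crossing the right edge has band pixels beyond the cell's last column,
#' so both forbidden-edge exclusions follow; unlike a literal pixel-pair
#' edge test, the band-owner form stays exact when an object slips
#' diagonally across a cell corner, so each object is attributed to
#' exactly one cell of a full tiling.
#'
#' @param scene a [scale_scene()].
#' @param cell one row of a grid's `cells` (list or data frame row with
#'   `r0`, `c0`), or a numeric `c(r0, c0)`.
#' @param side cell side in px (taken from `cell$side` if present).
#' @return integer vector of included sensillum label ids (possibly empty).
#' @export
count_cell <- function(scene, cell, side = NULL) {
  stopifnot(inherits(scene, "scale_scene"))
  if (is.numeric(cell) && is.null(names(cell)))
    cell <- list(r0 = cell[[1L]], c0 = cell[[2L]])
  side <- side %||% cell$side
  if (is.null(side)) stopf("cell side not given")
  lab <- scene$labels
  nr <- nrow(lab); nc <- ncol(lab)
  r0 <- as.integer(cell$r0); c0 <- as.integer(cell$c0)
  r1 <- r0 + as.integer(side); c1 <- c0 + as.integer(side)  # exclusive
  if (r0 < 1L || c0 < 1L || r1 > nr + 1L || c1 > nc + 1L)
    stopf("cell exceeds raster bounds")
  block <- lab[r0:(r1 - 1L), c0:(c1 - 1L), drop = FALSE]
  present <- unique(block[block > 0L])
  present <- present[present != scene$bar_label]
  if (!length(present)) return(integer(0))
  idx <- which(matrix(lab %in% present, nr, nc))
  vals <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  keep <- vapply(present, function(id) {
    sel <- vals == id
    rmin <- min(rows[sel])                 # topmost pixel fixes the band
    if (rmin < r0 || rmin >= r1) return(FALSE)
    in_band <- sel & rows >= r0 & rows < r1
    cmax <- max(cols[in_band])             # rightmost pixel within the band
    cmax >= c0 && cmax < c1
  }, logical(1))
  sort(as.integer(present[keep]))
}

#' Quantify sensilla from the selected quadrate cells
#'
#' Applies [count_cell()] to every selected cell and derives the raw sample
#' totals and the three standard estimators:
#' \describe{
#'   \item{`N_s`}{number of distinct sensilla included over the selected
#'     cells (an object spanning two selected cells counts once).}
#'   \item{`A_s`}{summed full pixel area of the included sensilla, in mm^2
#'     (objects are not clipped to cells).}
#'   \item{`A_c`}{summed area of the selected cells, in mm^2.}
#'   \item{`density`}{numerical density `N_s / A_c` (mm^-2).}
#'   \item{`mean_size`}{mean individual sensillum area `A_s / N_s`, in
#'     um^2 (`NA` when `N_s` is 0).}
#'   \item{`coverage`}{percentage of scale area covered,
#'     `100 * A_s / A_c`.}
#' }
#' The unit identity `coverage = density * mean_size * 1e-4` holds exactly.
#'
#' @param scene a [scale_scene()].
#' @param grid a `quadrate_grid` with `selected_ids` set (see
#'   [select_cells()]).
#' @return list with elements `sample` (`N_s`, `A_s`, `A_c`, plus the
#'   included label ids) and `stats` (`density`, `mean_size`, `coverage`).
#' @export
quantify_scene <- function(scene, grid) {
  stopifnot(inherits(scene, "scale_scene"), inherits(grid, "quadrate_grid"))
  if (!length(grid$selected_ids))
    stopf("grid has no selected cells; call select_cells() first")
  side <- grid$cell_side_px
  ids <- integer(0)
  for (i in grid$selected_ids) {
    cell <- grid$cells[i, ]
    ids <- union(ids, count_cell(scene, cell, side = side))
  }
  ids <- sort(as.integer(ids))
  areas_px <- scene_object_areas_px(scene)
  px_area_mm2 <- scene$mm_per_px^2
  N_s <- length(ids)
  A_s <- if (N_s) sum(areas_px[ids]) * px_area_mm2 else 0
  A_c <- length(grid$selected_ids) * (side * scene$mm_per_px)^2
  density <- N_s / A_c
  mean_size <- if (N_s > 0) (A_s / N_s) * 1e6 else NA_real_
  coverage <- 100 * A_s / A_c
  list(sample = list(N_s = N_s, A_s = A_s, A_c = A_c, ids = ids),
       stats = list(density = density, mean_size = mean_size,
                    coverage = coverage))
}

#' Full-census counting-frame sweep
#'
#' Runs [count_cell()] over every cell of the tiling (not just the selected
#' ones) and returns the multiset of included ids per cell. Used to check
#' the tiling-conservation property: each object intersecting the tiling is
#' counted exactly once provided it does not leave the tiling through its
#' global top row or rightmost column.
#'
#' @inheritParams quantify_scene
#' @return integer vector of included ids, concatenated over all cells
#'   (duplicates would indicate double counting).
#' @export
census_counts <- function(scene, grid) {
  side <- grid$cell_side_px
  unlist(lapply(seq_len(nrow(grid$cells)), function(i)
    count_cell(scene, grid$cells[i, ], side = side)))
}

#' Head-volume proxy
#'
#' The product of head length, width and height (mm), used as the
#' allometric size covariate. Commutative in its arguments.
#'
#' @param length_mm,width_mm,height_mm head linear measurements in mm (> 0).
#' @return head volume proxy in mm^3.
#' @export
head_volume <- function(length_mm, width_mm, height_mm) {
  if (any(c(length_mm, width_mm, height_mm) <= 0, na.rm = FALSE) ||
      any(!is.finite(c(length_mm, width_mm, height_mm))))
    stopf("all head dimensions must be positive and finite")
  length_mm * width_mm * height_mm
}

#' Species means and standard errors from per-specimen data
#'
#' Aggregates per-specimen trait values to species level: arithmetic mean
#' and standard error of the mean (sample sd with `n - 1` denominator over
#' `sqrt(n)`). With a single specimen the sem is undefined and reported as
#' `NA`, never 0.
#'
#' @param specimens data frame with a `species` column and numeric trait
#'   columns.
#' @param traits character vector of trait column names to aggregate;
#'   defaults to every numeric column except `species`.
#' @return data frame with one row per species: `species`, `n`, and for
#'   each trait `<trait>_mean` and `<trait>_sem`.
#' @export
aggregate_species <- function(specimens, traits = NULL) {
  if (!is.data.frame(specimens) || nrow(specimens) == 0L)
    stopf("`specimens` must be a non-empty data frame")
  if (!"species" %in% names(specimens))
    stopf("`specimens` needs a `species` column")
  if (is.null(traits))
    traits <- names(specimens)[vapply(specimens, is.numeric, logical(1))]
  traits <- setdiff(traits, "species")
  sp <- sort(unique(specimens$species))
  out <- data.frame(species = sp,
                    n = as.integer(table(specimens$species)[sp]),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    vals <- split(specimens[[tr]], specimens$species)[sp]
    out[[paste0(tr, "_mean")]] <- vapply(vals, function(v)
      mean(v, na.rm = TRUE), numeric(1))
    out[[paste0(tr, "_sem")]] <- vapply(vals, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}
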