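#' Labelled scale-scene container
#'
#' A `scale_scene` holds one specimen's labelled postocular-scale image: an
#' integer label raster (0 = background, positive integers = individual
#' sensilla, one reserved value for the scale bar), a logical region-of-
#' interest mask of the same dimensions, the physical pixel calibration and
#' the specimen metadata used downstream (species, ecology, head
#' dimensions).
#'
#' @param labels integer matrix; 0 is background, each sensillum is one
#'   connected blob of a distinct positive label, `bar_label` is reserved
#'   for the scale bar.
#' @param roi logical matrix with the same dimensions as `labels`; `TRUE`
#'   marks pixels inside the postocular scale region.
#' @param mm_per_px physical side length of one pixel in mm (> 0).
#' @param specimen_id character scalar identifying the specimen.
#' @param meta named list of specimen metadata (`species`, `ecology`,
#'   `head_l_mm`, `head_w_mm`, `head_h_mm`); may be empty for purely
#'   geometric work.
#' @param bar_label reserved integer label of the rendered scale bar
#'   (default 65535, the 16-bit maximum).
#' @param roi_spec optional analytic description of the roi (as stored in a
#'   sidecar); kept so that writing a scene round-trips.
#' @param check_labels if `TRUE`, verify that every sensillum label forms a
#'   single 8-connected component (slow on large rasters, off by default).
#' @return an object of class `scale_scene`.
#' @seealso [read_scene()], [write_scene()], [quantify_scene()]
#' @export
scale_scene <- function(labels, roi, mm_per_px, specimen_id = "specimen",
                        meta = list(), bar_label = 65535L,
                        roi_spec = NULL, check_labels = FALSE) {
  if (!is.matrix(labels)) stopf("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (!is.matrix(roi) || !identical(dim(roi), dim(labels)))
    stopf("`roi` must be a logical matrix with the dimensions of `labels`")
  storage.mode(roi) <- "logical"
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0)
    stopf("`mm_per_px` must be a single positive number")
  if (any(labels < 0L, na.rm = TRUE)) stopf("labels must be non-negative")
  obj <- structure(
    list(labels = labels, roi = roi, mm_per_px = as.numeric(mm_per_px),
         specimen_id = as.character(specimen_id), meta = meta,
         bar_label = as.integer(bar_label), roi_spec = roi_spec),
    class = "scale_scene")
  if (check_labels) check_scene_labels(obj)
  obj
}

#' @export
print.scale_scene <- function(x, ...) {
  ids <- scene_object_ids(x)
  cat(sprintf(
    "scale_scene '%s': %d x %d px (%.4g mm/px), %d sensilla, roi %d px\n",
    x$specimen_id, nrow(x$labels), ncol(x$labels), x$mm_per_px,
    length(ids), sum(x$roi)))
  invisible(x)
}

# Positive sensillum labels present in the raster (scale bar excluded).
scene_object_ids <- function(scene) {
  ids <- sort(unique(as.vector(scene$labels)))
  ids[ids > 0L & ids != scene$bar_label]
}

# Pixel area of every object, indexed by label value.
scene_object_areas_px <- function(scene) {
  tab <- tabulate(scene$labels[scene$labels > 0L &
                                 scene$labels != scene$bar_label])
  tab
}

# Verify each sensillum label is one 8-connected component (flood fill over
# the label's bounding box; sensilla are small so this is cheap).
check_scene_labels <- function(scene) {
  lab <- scene$labels
  for (id in scene_object_ids(scene)) {
    w <- which(lab == id, arr.ind = TRUE)
    r0 <- min(w[, 1L]); r1 <- max(w[, 1L])
    c0 <- min(w[, 2L]); c1 <- max(w[, 2L])
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == id
    if (flood_count(sub) != sum(sub))
      stopf("label %d is not a single 8-connected component", id)
  }
  invisible(TRUE)
}

# Number of TRUE pixels reachable (8-neighbourhood) from the first TRUE pixel.
flood_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  start <- which(mask)[1L]
  seen <- matrix(FALSE, nr, nc)
  queue <- start
  seen[start] <- TRUE
  n <- 0L
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    n <- n + 1L
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    for (dr in -1L:1L) for (dc in -1L:1L) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc) {
        q <- (ccc - 1L) * nr + rr
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  n
}

#' Calibrate pixel size from a rendered scale bar
#'
#' Detects the scale bar by its reserved label value and converts its known
#' physical length into a pixel calibration. The bar length in pixels is the
#' longest horizontal run of bar-labelled pixels, which is robust to bars
#' rendered several rows thick.
#'
#' @param scene a [scale_scene()] (or a bare integer label matrix).
#' @param bar_label integer label of the scale bar; defaults to the scene's
#'   reserved label.
#' @param bar_length_mm physical bar length in mm (> 0; default 1, the
#'   conventional 1 mm bar).
#' @return `mm_per_px`, a positive scalar.
#' @export
calibrate_scale_bar <- function(scene, bar_label = NULL, bar_length_mm = 1) {
  lab <- if (inherits(scene, "scale_scene")) scene$labels else scene
  if (is.null(bar_label)) {
    if (!inherits(scene, "scale_scene"))
      stopf("`bar_label` must be given when `scene` is a bare matrix")
    bar_label <- scene$bar_label
  }
  if (!is.numeric(bar_length_mm) || bar_length_mm <= 0)
    stopf("`bar_length_mm` must be positive")
  hit <- lab == bar_label
  if (!any(hit)) stopf("scale-bar label %d not found in raster", bar_label)
  runs <- apply(hit, 1L, function(row) {
    r <- rle(row)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  len <- max(runs)
  if (len < 10L)
    stopf("scale bar run of %d px is too short for reliable calibration", len)
  bar_length_mm / len
}

# ---- roi rasterization --------------------------------------------------

# Rasterize a sidecar roi spec onto an nr x nc pixel grid. Pixel centres sit
# at integer coordinates (row 1 = image top). Specs:
#   list(type = "rect",    r0=, r1=, c0=, c1=)          inclusive pixel bounds
#   list(type = "ellipse", centre_r=, centre_c=, semi_r=, semi_c=)
#   list(type = "polygon", r = c(...), c = c(...))      vertex coordinates
rasterize_roi <- function(spec, nr, nc) {
  type <- spec$type %||% stopf("roi spec lacks a `type`")
  m <- matrix(FALSE, nr, nc)
  if (type == "rect") {
    r0 <- max(1L, as.integer(spec$r0)); r1 <- min(nr, as.integer(spec$r1))
    c0 <- max(1L, as.integer(spec$c0)); c1 <- min(nc, as.integer(spec$c1))
    if (r1 >= r0 && c1 >= c0) m[r0:r1, c0:c1] <- TRUE
  } else if (type == "ellipse") {
    r <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    m <- ((r - spec$centre_r) / spec$semi_r)^2 +
      ((cc - spec$centre_c) / spec$semi_c)^2 <= 1
  } else if (type == "polygon") {
    m <- rasterize_polygon(as.numeric(spec$r), as.numeric(spec$c), nr, nc)
  } else stopf("unknown roi type '%s'", type)
  m
}

# Even-odd scanline fill of a simple polygon given vertex (row, col) coords.
rasterize_polygon <- function(vr, vc, nr, nc) {
  stopifnot(length(vr) == length(vc), length(vr) >= 3L)
  n <- length(vr)
  nxt <- c(2:n, 1L)
  m <- matrix(FALSE, nr, nc)
  for (row in seq_len(nr)) {
    y <- row
    crossings <- numeric(0)
    for (e in seq_len(n)) {
      y1 <- vr[e]; y2 <- vr[nxt[e]]
      if ((y1 <= y) != (y2 <= y)) {   # edge straddles scanline
        x1 <- vc[e]; x2 <- vc[nxt[e]]
        crossings <- c(crossings, x1 + (y - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    if (length(crossings) >= 2L) {
      crossings <- sort(crossings)
      for (i in seq(1L, length(crossings) - 1L, by = 2L)) {
        c0 <- ceiling(crossings[i]); c1 <- floor(crossings[i + 1L])
        c0 <- max(1L, c0); c1 <- min(nc, c1)
        if (c1 >= c0) m[row, c0:c1] <- TRUE
      }
    }
  }
  m
}

# ---- scene I/O ----------------------------------------------------------

#' Write a labelled scene to disk
#'
#' Writes the label raster as a 16-bit greyscale image (PNG or TIFF by file
#' extension) and the metadata — specimen fields, calibration, scale-bar
#' spec and roi description — to a JSON sidecar next to it
#' (`<stem>.json`).
#'
#' @param scene a [scale_scene()]; must carry a `roi_spec` (scenes from
#'   [sim_scene()] and [read_scene()] always do).
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scale_scene"))
  if (is.null(scene$roi_spec))
    stopf("scene has no `roi_spec`; cannot serialize the roi")
  if (max(scene$labels) > 65535L)
    stopf("labels exceed the 16-bit range")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # writePNG emits 8-bit greyscale; fine only when labels fit in a byte
    if (max(scene$labels) > 255L)
      stopf("labels exceed 255; write a 16-bit TIFF instead of PNG")
    png::writePNG(scene$labels / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scene$labels / 65535, where = path,
                    bits.per.sample = 16, compression = "none")
  } else stopf("unsupported image extension '%s'", ext)
  sidecar <- c(
    list(specimen_id = scene$specimen_id),
    scene$meta,
    list(mm_per_px = scene$mm_per_px,
         bar_label = scene$bar_label,
         depth = if (ext == "png") 8L else 16L,
         roi = scene$roi_spec))
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path)
  file.path(dirname(path),
            paste0(tools::file_path_sans_ext(basename(path)), ".json"))

#' Read a labelled scene and its JSON sidecar
#'
#' Reads a 16-bit labelled mask (PNG or TIFF) together with the JSON sidecar
#' written by [write_scene()] (or assembled by hand). Calibration comes from
#' an explicit `mm_per_px` in the sidecar, or else from the rendered scale
#' bar via [calibrate_scale_bar()]; the roi mask is rasterized from the
#' sidecar's `roi` description, or taken from a second image channel when
#' `roi` is `"mask-channel"`.
#'
#' @param path image path; the sidecar is expected at `<stem>.json`.
#' @param check_labels passed to [scale_scene()].
#' @return a [scale_scene()].
#' @export
read_scene <- function(path, check_labels = FALSE) {
  if (!file.exists(path)) stopf("image '%s' not found", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stopf("sidecar '%s' not found", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stopf("unsupported image extension '%s'", ext)
  mask_channel <- NULL
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 2L) mask_channel <- img[, , 2L] > 0.5
    img <- img[, , 1L]
  }
  scale <- 2^(side$depth %||% 16L) - 1
  labels <- matrix(as.integer(round(img * scale)), nrow(img), ncol(img))
  bar_label <- as.integer(side$bar_label %||% 65535L)

  roi_spec <- side$roi
  if (identical(roi_spec, "mask-channel")) {
    if (is.null(mask_channel))
      stopf("sidecar requests roi from a mask channel, but '%s' has one channel",
            path)
    roi <- mask_channel
  } else if (is.null(roi_spec)) {
    stopf("sidecar '%s' lacks a `roi` entry", sc)
  } else {
    roi <- rasterize_roi(as.list(roi_spec), nrow(labels), ncol(labels))
  }

  mm_per_px <- side[["mm_per_px"]]
  if (is.null(mm_per_px)) {
    bar_info <- if (is.list(side[["bar"]])) side[["bar"]] else side
    if (is.null(bar_info[["bar_length_mm"]]))
      stopf("sidecar '%s' has neither `mm_per_px` nor scale-bar info", sc)
    bl <- bar_info[["bar_length_mm"]]
    mm_per_px <- calibrate_scale_bar(labels, bar_label = bar_label,
                                     bar_length_mm = as.numeric(bl))
  }

  meta_fields <- c("species", "ecology", "head_l_mm", "head_w_mm",
                   "head_h_mm", "bar_length_mm")
  meta <- side[intersect(meta_fields, names(side))]
  scale_scene(labels, roi, mm_per_px,
              specimen_id = side$specimen_id %||%
                tools::file_path_sans_ext(basename(path)),
              meta = meta, bar_label = bar_label,
              roi_spec = if (is.character(roi_spec)) roi_spec
                         else as.list(roi_spec),
              check_labels = check_labels)
}
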