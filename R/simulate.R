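#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Standard forward construction: starting from two lineages at the root,
#' the waiting time to the next speciation with `k` extant lineages is
#' exponential with rate `k * birth_rate`, and the splitting lineage is
#' chosen uniformly. After the (n-1)-th split a final exponential waiting
#' time with rate `n * birth_rate` is appended so pendant branches are
#' positive. Tips are labelled `t1 ... tn`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), per unit time.
#' @param seed integer RNG seed; the simulator is a pure function of
#'   `(n_tips, birth_rate, seed)`.
#' @return an ultrametric [ape::phylo] tree.
#' @export
sim_yule <- function(n_tips, birth_rate = 1, seed) {
  if (n_tips < 2L) stopf("`n_tips` must be >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stopf("`birth_rate` must be positive")
  with_seed(seed, {
    n <- as.integer(n_tips)
    # lineages: start node and birth time; root split happens at t = 0
    max_lin <- 2L * n - 2L
    start_node <- integer(max_lin); birth <- numeric(max_lin)
    alive <- logical(max_lin)
    root <- n + 1L
    start_node[1:2] <- root; birth[1:2] <- 0; alive[1:2] <- TRUE
    n_lin <- 2L
    next_node <- root + 1L
    edges <- matrix(0L, 2L * n - 2L, 2L)
    elen <- numeric(2L * n - 2L)
    n_edge <- 0L
    t <- 0
    k <- 2L
    while (k < n) {
      t <- t + stats::rexp(1L, rate = k * birth_rate)
      ai <- which(alive)
      i <- ai[sample.int(length(ai), 1L)]
      node <- next_node; next_node <- next_node + 1L
      n_edge <- n_edge + 1L
      edges[n_edge, ] <- c(start_node[i], node)
      elen[n_edge] <- t - birth[i]
      alive[i] <- FALSE
      for (j in 1:2) {
        n_lin <- n_lin + 1L
        start_node[n_lin] <- node; birth[n_lin] <- t; alive[n_lin] <- TRUE
      }
      k <- k + 1L
    }
    t <- t + stats::rexp(1L, rate = n * birth_rate)
    tip_id <- 0L
    for (i in which(alive)) {
      tip_id <- tip_id + 1L
      n_edge <- n_edge + 1L
      edges[n_edge, ] <- c(start_node[i], tip_id)
      elen[n_edge] <- t - birth[i]
    }
    storage.mode(edges) <- "integer"
    phy <- structure(list(edge = edges, edge.length = elen,
                          tip.label = paste0("t", seq_len(n)),
                          Nnode = n - 1L),
                     class = "phylo")
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Forward simulation of the Brownian model: the root takes `root_state`
#' and each child's value is its parent's plus a normal increment with
#' variance `sigma2 * branch length`. True internal-node states are
#' retained so estimator-recovery tests have ground truth.
#'
#' @param phy rooted [ape::phylo] tree with non-negative branch lengths.
#' @param sigma2 Brownian rate (variance per unit time, >= 0).
#' @param root_state trait value at the root.
#' @param seed integer RNG seed.
#' @return list with `tips` (named vector in tip-label order) and `nodes`
#'   (vector of all node states indexed by ape node number).
#' @export
sim_bm <- function(phy, sigma2, root_state = 0, seed) {
  if (!inherits(phy, "phylo")) stopf("`phy` must be a phylo tree")
  if (sigma2 < 0) stopf("`sigma2` must be >= 0")
  if (any(phy$edge.length < 0)) stopf("negative branch length")
  with_seed(seed, {
    n <- length(phy$tip.label)
    phy_cw <- ape::reorder.phylo(phy, "cladewise")  # parents before children
    nn <- n + phy_cw$Nnode
    states <- numeric(nn)
    states[n + 1L] <- root_state
    inc <- stats::rnorm(nrow(phy_cw$edge), mean = 0,
                        sd = sqrt(sigma2 * phy_cw$edge.length))
    for (i in seq_len(nrow(phy_cw$edge)))
      states[phy_cw$edge[i, 2L]] <- states[phy_cw$edge[i, 1L]] + inc[i]
    tips <- states[seq_len(n)]
    names(tips) <- phy$tip.label
    list(tips = tips, nodes = states)
  })
}

#' Simulate a bivariate allometric trait pair on a tree
#'
#' Generates log10-scale traits with a known allometric structure: the
#' predictor `x` evolves by Brownian motion at rate `sigma2_x`, and
#' `y = elevation + slope * x + e` where the residual `e` is an independent
#' Brownian trait at rate `sigma2_e`. PIC regression of `y` on `x` then has
#' true exponent `slope`, which recovery tests exploit.
#'
#' @param phy rooted [ape::phylo] tree.
#' @param slope true allometric exponent `b`.
#' @param elevation true intercept on the log10 scale (`log10(a)`).
#' @param sigma2_x,sigma2_e Brownian rates of the predictor and of the
#'   residual trait (>= 0).
#' @param root_x predictor value at the root.
#' @param seed integer RNG seed.
#' @return list with named vectors `x` and `y` (log10 scale).
#' @export
sim_allometric_traits <- function(phy, slope, elevation = 0,
                                  sigma2_x = 1, sigma2_e = 0.1,
                                  root_x = 0, seed) {
  if (sigma2_x < 0 || sigma2_e < 0) stopf("rates must be >= 0")
  x <- sim_bm(phy, sigma2_x, root_state = root_x, seed = seed)$tips
  e <- sim_bm(phy, sigma2_e, root_state = 0, seed = seed + 1L)$tips
  list(x = x, y = elevation + slope * x + e)
}

#' Simulate a labelled sensilla scene with known ground truth
#'
#' Renders a synthetic postocular-scale image: non-overlapping (hard-core)
#' discs placed by sequential-inhibition dart throwing at a requested
#' intensity inside a rectangular or elliptic roi, plus a rendered scale
#' bar carrying the reserved label. Disc centres are drawn uniformly in the
#' roi (discs near the boundary may overhang it, keeping the point process
#' uniform inside the roi). A pixel belongs to a disc when its centre lies
#' within the radius — no anti-aliasing — and the returned census truth is
#' measured on the rendered raster, so estimator checks are free of
#' discretization bias.
#'
#' @param roi_mm roi physical size `c(height, width)` in mm.
#' @param shape `"rect"` or `"ellipse"` (ellipse inscribed in the roi box).
#' @param mm_per_px pixel size in mm (default 0.005, i.e. 5 um pixels).
#' @param lambda target intensity in sensilla per mm^2 (>= 0); the placed
#'   count is `round(lambda * roi_area_mm2)`.
#' @param radius_um disc radius in um: a single number for fixed radii, or
#'   `c(meanlog, sdlog)` of a lognormal in um.
#' @param bar_length_mm rendered scale-bar length (default 1).
#' @param specimen_id,meta passed to [scale_scene()].
#' @param seed integer RNG seed.
#' @param max_reject abort placement after this many consecutive rejected
#'   darts (default 1e5).
#' @return list with `scene` (a [scale_scene()]) and `truth`: data frame
#'   `objects` (centre, radius per disc) and census `count`,
#'   `density` (mm^-2), `total_area_mm2`, `mean_size_um2`, `coverage_pct`
#'   — all measured on the rendered raster over the analytic roi area.
#' @export
sim_scene <- function(roi_mm = c(2, 5), shape = c("rect", "ellipse"),
                      mm_per_px = 0.005, lambda = 20, radius_um = 30,
                      bar_length_mm = 1, specimen_id = "sim",
                      meta = list(), seed, max_reject = 1e5) {
  shape <- match.arg(shape)
  if (lambda < 0) stopf("`lambda` must be >= 0")
  if (any(radius_um <= 0)) stopf("disc radii must be positive")
  h_mm <- roi_mm[1L]; w_mm <- roi_mm[2L]
  if (h_mm <= 0 || w_mm <= 0) stopf("roi dimensions must be positive")
  roi_area_mm2 <- if (shape == "rect") h_mm * w_mm else pi * h_mm * w_mm / 4
  mean_r_mm <- if (length(radius_um) == 1L) radius_um / 1000
               else exp(radius_um[1L] + radius_um[2L]^2 / 2) / 1000
  mean_r2_mm2 <- if (length(radius_um) == 1L) (radius_um / 1000)^2
                 else exp(2 * radius_um[1L] + 2 * radius_um[2L]^2) / 1e6
  if (lambda * pi * mean_r2_mm2 >= 0.4)
    stopf("requested packing fraction %.2f exceeds the 0.4 hard-core cap",
          lambda * pi * mean_r2_mm2)
  target <- round(lambda * roi_area_mm2)

  with_seed(seed, {
    # raster layout: margin around the roi, bar strip underneath
    margin_px <- max(4L, ceiling(4 * mean_r_mm / mm_per_px))
    h_px <- ceiling(h_mm / mm_per_px); w_px <- ceiling(w_mm / mm_per_px)
    bar_px <- ceiling(bar_length_mm / mm_per_px)
    bar_strip <- 8L
    nr <- h_px + 2L * margin_px + bar_strip
    nc <- max(w_px + 2L * margin_px, bar_px + 2L * margin_px)
    r_off <- margin_px; c_off <- margin_px   # roi starts at (r_off+1, c_off+1)

    in_roi <- function(y_mm, x_mm) {
      if (shape == "rect") y_mm >= 0 & y_mm <= h_mm & x_mm >= 0 & x_mm <= w_mm
      else ((y_mm - h_mm / 2) / (h_mm / 2))^2 +
        ((x_mm - w_mm / 2) / (w_mm / 2))^2 <= 1
    }
    draw_radius <- function()
      if (length(radius_um) == 1L) radius_um / 1000
      else stats::rlnorm(1L, radius_um[1L], radius_um[2L]) / 1000

    cy <- numeric(target); cx <- numeric(target); rad <- numeric(target)
    placed <- 0L; rejects <- 0L
    while (placed < target) {
      y <- stats::runif(1L, 0, h_mm); x <- stats::runif(1L, 0, w_mm)
      r <- draw_radius()
      ok <- in_roi(y, x)
      if (ok && placed > 0L) {
        d2 <- (cy[seq_len(placed)] - y)^2 + (cx[seq_len(placed)] - x)^2
        ok <- all(d2 >= (rad[seq_len(placed)] + r)^2)
      }
      if (ok) {
        placed <- placed + 1L
        cy[placed] <- y; cx[placed] <- x; rad[placed] <- r
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
        if (rejects >= max_reject)
          stopf("dart throwing stalled after %d consecutive rejections",
                max_reject)
      }
    }

    labels <- matrix(0L, nr, nc)
    # render discs: pixel centre at ((i - 0.5) mm_per_px) relative to roi top
    for (i in seq_len(target)) {
      pr <- r_off + cy[i] / mm_per_px + 0.5    # centre in pixel coords
      pc <- c_off + cx[i] / mm_per_px + 0.5
      rpx <- rad[i] / mm_per_px
      rr <- max(1L, floor(pr - rpx)):min(nr, ceiling(pr + rpx))
      cc <- max(1L, floor(pc - rpx)):min(nc, ceiling(pc + rpx))
      dy <- outer(rr - pr, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - pc)
      hit <- dy * dy + dx * dx <= rpx * rpx
      block <- labels[rr, cc, drop = FALSE]
      block[hit & block == 0L] <- i
      labels[rr, cc] <- block
    }
    # scale bar in the bottom strip, 3 px thick
    bar_label <- 65535L
    bar_r <- nr - 5L
    labels[bar_r:(bar_r + 2L), (c_off + 1L):(c_off + bar_px)] <- bar_label

    roi_spec <- if (shape == "rect")
      list(type = "rect", r0 = r_off + 1L, r1 = r_off + h_px,
           c0 = c_off + 1L, c1 = c_off + w_px)
    else
      list(type = "ellipse", centre_r = r_off + (h_px + 1) / 2,
           centre_c = c_off + (w_px + 1) / 2,
           semi_r = h_px / 2, semi_c = w_px / 2)
    roi <- rasterize_roi(roi_spec, nr, nc)
    meta <- utils::modifyList(list(bar_length_mm = bar_length_mm), meta)
    scene <- scale_scene(labels, roi, mm_per_px,
                         specimen_id = specimen_id, meta = meta,
                         bar_label = bar_label, roi_spec = roi_spec)

    areas_px <- scene_object_areas_px(scene)
    total_area_mm2 <- sum(areas_px) * mm_per_px^2
    truth <- list(
      objects = data.frame(y_mm = cy, x_mm = cx, radius_um = rad * 1000),
      count = target,
      density = target / roi_area_mm2,
      total_area_mm2 = total_area_mm2,
      mean_size_um2 = if (target > 0) total_area_mm2 / target * 1e6
                      else NA_real_,
      coverage_pct = 100 * total_area_mm2 / roi_area_mm2,
      roi_area_mm2 = roi_area_mm2, seed = as.integer(seed))
    list(scene = scene, truth = truth)
  })
}
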