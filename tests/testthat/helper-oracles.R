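# Shared fixtures and independent oracles used across test files.

# Scene with a full-raster rectangular roi from a bare label matrix.
make_scene <- function(labels, mm_per_px = 1, roi = NULL, ...) {
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(labels), ncol(labels))
  scale_scene(labels, roi, mm_per_px,
              roi_spec = list(type = "rect", r0 = 1, r1 = nrow(labels),
                              c0 = 1, c1 = ncol(labels)), ...)
}

# Stamp an id block into a label matrix.
place_block <- function(m, r, c, h, w, id) {
  m[r:(r + h - 1L), c:(c + w - 1L)] <- id
  m
}

# Full-census scene for the worked coverage examples: `n` rectangular
# sensilla of `h_px x w_px` pixels laid out on a 500 x 1000 px raster at
# 0.002 mm/px, so a 2-cell grid covers exactly 2 mm^2.
make_census_scene <- function(n, h_px, w_px, mm_per_px = 0.002) {
  labels <- matrix(0L, 500L, 1000L)
  per_row <- 15L
  pitch_c <- (1000L - 10L) %/% per_row
  pitch_r <- (500L - 10L) %/% ceiling(n / per_row)
  for (i in seq_len(n)) {
    r <- 6L + ((i - 1L) %/% per_row) * pitch_r
    c <- 6L + ((i - 1L) %% per_row) * pitch_c
    labels <- place_block(labels, r, c, h_px, w_px, i)
  }
  make_scene(labels, mm_per_px = mm_per_px)
}

# GLS phylogenetic mean and its variance factor from the full BM tip
# covariance matrix (C_ij = shared root-to-tip path length).
gls_root_oracle <- function(phy, x) {
  V <- ape::vcv(phy)
  iv <- solve(V)
  one <- rep(1, nrow(V))
  xx <- x[rownames(V)]
  denom <- as.numeric(one %*% iv %*% one)
  c(est = as.numeric(one %*% iv %*% xx) / denom, var = 1 / denom)
}

# Same quantity for the tree re-rooted at every internal node, built from
# node-to-node path lengths: the covariance of tips about node k is
# (d(k,i) + d(k,j) - d(i,j)) / 2.
gls_node_oracle <- function(phy, x) {
  n <- length(phy$tip.label)
  D <- ape::dist.nodes(phy)
  xx <- x[phy$tip.label]
  t(vapply((n + 1L):(n + phy$Nnode), function(k) {
    Vk <- outer(seq_len(n), seq_len(n), function(i, j)
      (D[k, i] + D[k, j] - D[cbind(i, j)]) / 2)
    diag(Vk) <- D[k, seq_len(n)]
    iv <- solve(Vk)
    one <- rep(1, n)
    denom <- as.numeric(one %*% iv %*% one)
    c(est = as.numeric(one %*% iv %*% xx) / denom, var = 1 / denom)
  }, c(est = 0, var = 0)))
}

# Brute-force expectation for the tiling-conservation property: ids of
# objects intersecting the grid's tiling that stay within its global top
# row and rightmost column (they may extend below or to the left). The
# counting frame must count each of these exactly once over a full tiling.
interior_tiling_ids <- function(scene, grid) {
  side <- grid$cell_side_px
  rt <- min(grid$cells$r0); ct <- min(grid$cells$c0)
  rb <- max(grid$cells$r0) + side - 1L
  cr <- max(grid$cells$c0) + side - 1L
  lab <- scene$labels
  ids <- sort(unique(lab[lab > 0L & lab != scene$bar_label]))
  keep <- vapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    all(w[, 1L] >= rt) && all(w[, 2L] <= cr) &&
      any(w[, 1L] <= rb & w[, 2L] >= ct)
  }, logical(1))
  ids[keep]
}
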