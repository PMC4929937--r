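#' Read a rooted time-calibrated tree from newick
#'
#' Thin wrapper around [ape::read.tree()] that validates what the
#' comparative machinery needs: branch lengths present and finite, tip
#' labels unique. Polytomies are permitted at this stage but flagged (the
#' contrast operations reject them).
#'
#' @param text newick string, or `NULL` when reading from `file`.
#' @param file path to a newick file.
#' @return an [ape::phylo] tree with an added logical attribute
#'   `"polytomies"`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stopf("give `text` or `file`")
  phy <- if (!is.null(text)) ape::read.tree(text = text)
         else {
           if (!file.exists(file)) stopf("tree file '%s' not found", file)
           ape::read.tree(file)
         }
  if (is.null(phy)) stopf("malformed newick string")
  if (is.null(phy$edge.length)) stopf("tree has no branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stopf("branch lengths must be finite and non-negative")
  if (anyDuplicated(phy$tip.label)) stopf("duplicate tip labels")
  attr(phy, "polytomies") <- has_polytomy(phy)
  phy
}

# ape::is.binary() tolerates a root trifurcation (unrooted convention);
# contrasts need every node, root included, to have exactly two daughters.
has_polytomy <- function(phy) any(tabulate(phy$edge[, 1L]) > 2L)

#' Log10-transform a raw trait map
#'
#' @param x named numeric vector (names are species); all values must be
#'   strictly positive.
#' @param trait optional trait name carried along as an attribute.
#' @return named vector of `log10(x)` with attributes `trait` and
#'   `transform = "log10"`.
#' @export
log10_transform <- function(x, trait = NULL) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stopf("trait vector must be named by species")
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("all trait values must be positive and finite for log10")
  out <- log10(x)
  attr(out, "trait") <- trait
  attr(out, "transform") <- "log10"
  out
}

# Match a named trait vector against tree tips, with a helpful error.
match_traits <- function(phy, x) {
  if (is.null(names(x))) stopf("trait vector must be named by species")
  miss_tree <- setdiff(phy$tip.label, names(x))
  miss_data <- setdiff(names(x), phy$tip.label)
  if (length(miss_tree) || length(miss_data))
    stopf(paste0(
      "species/tip mismatch.",
      if (length(miss_tree))
        paste0(" In tree but not data: ",
               paste(miss_tree, collapse = ", "), "."),
      if (length(miss_data))
        paste0(" In data but not tree: ",
               paste(miss_data, collapse = ", "), ".")))
  x[phy$tip.label]
}

#' Phylogenetic independent contrasts by post-order pruning
#'
#' Computes standardized independent contrasts on a strictly bifurcating
#' tree. At each internal node with daughter values `x_i, x_j` carrying
#' (branch-adjusted) variances `v_i, v_j`:
#' raw contrast `x_i - x_j`; expected variance `v_i + v_j`; nodal value the
#' inverse-variance weighted mean `(x_i/v_i + x_j/v_j)/(1/v_i + 1/v_j)`;
#' and the node's own branch is lengthened by `v_i v_j / (v_i + v_j)`.
#' The returned set also carries the phylogenetic (GLS) root value and the
#' root's adjusted variance, which downstream allometry uses for the
#' elevation and ancestral-state machinery.
#'
#' @param phy bifurcating rooted [ape::phylo] tree with branch lengths.
#' @param x named numeric trait vector covering exactly the tree's tips.
#' @param resolve if `TRUE`, resolve polytomies arbitrarily with
#'   zero-length branches before pruning (the GLS quantities are invariant
#'   to how a polytomy is resolved); by default polytomies are an error.
#' @return object of class `contrast_set`: data frame `contrasts` (node id,
#'   `raw`, `var`, `contrast`), vectors `node_values` and `node_adj_var`
#'   indexed by ape node number, `root_value`, `root_var`, `n_tips`.
#' @export
pic_contrasts <- function(phy, x, resolve = FALSE) {
  if (!inherits(phy, "phylo")) stopf("`phy` must be a phylo tree")
  if (has_polytomy(phy)) {
    if (!resolve)
      stopf("tree contains polytomies; resolve it before computing contrasts")
    phy <- ape::multi2di(phy, random = FALSE)
  }
  x <- match_traits(phy, x)
  if (any(!is.finite(x))) stopf("trait values must be finite")
  n <- length(phy$tip.label)
  phy <- ape::reorder.phylo(phy, "postorder")
  nn <- n + phy$Nnode
  val <- numeric(nn); adj <- numeric(nn)
  val[seq_len(n)] <- as.numeric(x)
  e1 <- phy$edge[, 1L]; e2 <- phy$edge[, 2L]; bl <- phy$edge.length
  node <- integer(phy$Nnode); raw <- numeric(phy$Nnode)
  vv <- numeric(phy$Nnode)
  k <- 0L
  # postorder edges come in consecutive sibling pairs for a binary tree
  for (i in seq(1L, length(e1), by = 2L)) {
    parent <- e1[i]
    if (e1[i + 1L] != parent) stopf("tree is not strictly bifurcating")
    ci <- e2[i]; cj <- e2[i + 1L]
    vi <- bl[i] + adj[ci]; vj <- bl[i + 1L] + adj[cj]
    if (vi + vj <= 0)
      stopf("zero pooled branch variance at node %d", parent)
    k <- k + 1L
    node[k] <- parent
    raw[k] <- val[ci] - val[cj]
    vv[k] <- vi + vj
    val[parent] <- (val[ci] / vi + val[cj] / vj) / (1 / vi + 1 / vj)
    adj[parent] <- vi * vj / (vi + vj)
  }
  res <- data.frame(node = node, raw = raw, var = vv,
                    contrast = raw / sqrt(vv))
  structure(list(contrasts = res,
                 node_values = val, node_adj_var = adj,
                 root_value = val[n + 1L], root_var = adj[n + 1L],
                 n_tips = n, trait = attr(x, "trait")),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("contrast_set: %d contrasts from %d tips, root value %.4g\n",
              nrow(x$contrasts), x$n_tips, x$root_value))
  invisible(x)
}

#' Upper-tail p value of an F statistic
#'
#' @param F observed F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return `P(F(df1, df2) >= F)`.
#' @export
f_test_p <- function(F, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stopf("degrees of freedom must be >= 1")
  if (any(F < 0)) stopf("F must be non-negative")
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Allometric regression on standardized contrasts
#'
#' Least-squares regression of y contrasts on x contrasts, the contrast-
#' space analogue of the power law `y = a X^b` on the original scale (both
#' traits log10-transformed before contrasts, so `b` is the exponent).
#' The default is the through-origin fit that contrast theory prescribes
#' (residual d.f. `m - 1`); `intercept_mode = TRUE` fits an intercept
#' (residual d.f. `m - 2`) after positivising the contrasts on x, matching
#' analyses that report d.f. `1, n - 3`. The elevation `a` is
#' back-transformed from the two traits' phylogenetic root values:
#' `a = 10^(root_y - b * root_x)` (only available when `contrast_set`
#' objects are supplied).
#'
#' @param y,x `contrast_set` objects (or bare numeric vectors of
#'   standardized contrasts, in which case `a` is `NA`).
#' @param intercept_mode logical; fit an intercept on the contrasts.
#' @return object of class `allometric_fit`: list with `a`, `b`, `ci95`
#'   (half-width on `b`), `r2`, `df1`, `df2`, `F`, `p`, `intercept_mode`,
#'   `m` (number of contrasts) and the underlying `lm` fit.
#' @export
regress_contrasts <- function(y, x, intercept_mode = FALSE) {
  root_y <- root_x <- NA_real_
  if (inherits(y, "contrast_set")) { root_y <- y$root_value; y <- y$contrasts$contrast }
  if (inherits(x, "contrast_set")) { root_x <- x$root_value; x <- x$contrasts$contrast }
  if (length(y) != length(x)) stopf("contrast vectors differ in length")
  m <- length(y)
  if (m < 3L) stopf("need at least 3 contrasts, got %d", m)
  if (all(x == 0)) stopf("x contrasts have zero variance")
  if (intercept_mode) {
    flip <- sign(x)
    flip[flip == 0] <- 1
    x <- x * flip; y <- y * flip            # positivise on x
    fit <- stats::lm(y ~ x)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_reg <- sum((stats::fitted(fit) - mean(y))^2)
    df2 <- m - 2L
    sxx <- sum((x - mean(x))^2)
  } else {
    fit <- stats::lm(y ~ x + 0)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_reg <- sum(stats::fitted(fit)^2)
    df2 <- m - 1L
    sxx <- sum(x^2)
  }
  b <- unname(stats::coef(fit)[["x"]])
  if (all(y == 0)) {
    Fstat <- 0; p <- 1; r2 <- 0; ci <- 0
  } else {
    Fstat <- (ss_reg / 1) / (ss_res / df2)
    p <- f_test_p(Fstat, 1, df2)
    r2 <- ss_reg / (ss_reg + ss_res)
    se <- sqrt((ss_res / df2) / sxx)
    ci <- stats::qt(0.975, df2) * se
  }
  a <- if (is.finite(root_y) && is.finite(root_x))
    10^(root_y - b * root_x) else NA_real_
  structure(list(a = a, b = b, ci95 = ci, r2 = r2, df1 = 1L, df2 = df2,
                 F = Fstat, p = p, intercept_mode = intercept_mode,
                 m = m, fit = fit),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "allometric fit (%s): y = %.4g * X^%.4g  (b +/- %.3g, r2 = %.3g, F[%d,%d] = %.4g, p = %.4g)\n",
    if (x$intercept_mode) "intercept on contrasts" else "through origin",
    x$a, x$b, x$ci95, x$r2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Drop a taxon and its trait value
#'
#' Prunes one tip from the tree (its sister's branch absorbs the removed
#' internal branch, as in [ape::drop.tip()]) and filters the trait vector,
#' for outlier-exclusion reruns of the contrast regressions.
#'
#' @param phy rooted [ape::phylo] tree.
#' @param x named trait vector (or a data frame with a `species` column).
#' @param species tip label to remove.
#' @return list with elements `phy` and `x`.
#' @export
exclude_taxon <- function(phy, x, species) {
  if (!species %in% phy$tip.label)
    stopf("species '%s' is not a tip of the tree", species)
  if (length(phy$tip.label) - 1L < 2L)
    stopf("pruning '%s' would not leave a proper tree", species)
  phy2 <- ape::drop.tip(phy, species)
  if (is.data.frame(x)) x2 <- x[x$species != species, , drop = FALSE]
  else x2 <- x[setdiff(names(x), species)]
  list(phy = phy2, x = x2)
}
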