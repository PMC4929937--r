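# Inverse-variance combination of independent estimates, tolerating
# zero-variance (exact) components.
combine_est <- function(vals, vars) {
  zero <- vars <= 0
  if (any(zero)) return(c(vals[zero][1L], 0))
  w <- 1 / vars
  c(sum(vals * w) / sum(w), 1 / sum(w))
}

#' Brownian-motion ancestral state reconstruction
#'
#' Estimates ancestral states for a continuous trait under Brownian motion
#' on a fixed, strictly bifurcating time tree. The Brownian rate `sigma2`
#' is the REML estimate from the standardized independent contrasts (mean
#' squared contrast, denominator `n_tips - 1`). Each internal node's state
#' is the GLS phylogenetic mean of the tree re-rooted at that node,
#' computed in linear time by an upward pruning pass ([pic_contrasts()])
#' followed by a downward message pass; its variance is `sigma2` times the
#' adjusted root variance of the re-rooted tree. The root estimate equals
#' the global phylogenetic mean, and tip states are the observations with
#' zero variance.
#'
#' @param phy bifurcating rooted [ape::phylo] tree with branch lengths.
#' @param x named trait vector covering exactly the tree's tips (typically
#'   log10-transformed coverage).
#' @param trait optional trait name stored in the result.
#' @param resolve resolve polytomies with zero-length branches first (the
#'   estimates are then reported on the resolved tree's nodes).
#' @return object of class `asr_estimate`: data frame `nodes` (ape node
#'   id, `type` tip/internal/root, `label`, `estimate`, `variance`), plus
#'   `sigma2` and `trait`.
#' @export
asr_bm <- function(phy, x, trait = NULL, resolve = FALSE) {
  if (has_polytomy(phy) && resolve) phy <- ape::multi2di(phy, random = FALSE)
  cs <- pic_contrasts(phy, x)       # validates tree + traits
  x <- match_traits(phy, x)
  n <- cs$n_tips
  sigma2 <- mean(cs$contrasts$contrast^2)
  phy_po <- ape::reorder.phylo(phy, "postorder")
  e1 <- phy_po$edge[, 1L]; e2 <- phy_po$edge[, 2L]; bl <- phy_po$edge.length
  nn <- n + phy_po$Nnode
  up_val <- cs$node_values; up_var <- cs$node_adj_var
  root <- n + 1L
  # downward messages: estimate of the trait at each node from the tree
  # OUTSIDE its own subtree, with its variance
  down_val <- rep(NA_real_, nn); down_var <- rep(NA_real_, nn)
  # iterate edges in reverse postorder so parents are processed first
  for (i in rev(seq(1L, length(e1), by = 2L))) {
    p <- e1[i]
    ch <- c(e2[i], e2[i + 1L]); brl <- c(bl[i], bl[i + 1L])
    for (j in 1:2) {
      k <- ch[j]; sib <- ch[3L - j]
      sib_msg <- c(up_val[sib], up_var[sib] + brl[3L - j])
      if (p == root) comb <- sib_msg
      else comb <- combine_est(c(down_val[p], sib_msg[1L]),
                               c(down_var[p], sib_msg[2L]))
      down_val[k] <- comb[1L]
      down_var[k] <- comb[2L] + brl[j]
    }
  }
  est <- numeric(nn); vr <- numeric(nn)
  est[seq_len(n)] <- as.numeric(x); vr[seq_len(n)] <- 0
  est[root] <- up_val[root]; vr[root] <- sigma2 * up_var[root]
  internals <- setdiff((n + 1L):nn, root)
  for (k in internals) {
    comb <- combine_est(c(up_val[k], down_val[k]),
                        c(up_var[k], down_var[k]))
    est[k] <- comb[1L]
    vr[k] <- sigma2 * comb[2L]
  }
  labels <- c(phy$tip.label,
              phy$node.label %||% paste0("node", (n + 1L):nn))
  type <- c(rep("tip", n),
            ifelse((n + 1L):nn == root, "root", "internal"))
  structure(list(
    nodes = data.frame(node = seq_len(nn), type = type, label = labels,
                       estimate = est, variance = vr,
                       stringsAsFactors = FALSE),
    sigma2 = sigma2, trait = trait, n_tips = n),
    class = "asr_estimate")
}

#' @export
print.asr_estimate <- function(x, ...) {
  rt <- x$nodes[x$nodes$type == "root", ]
  cat(sprintf(
    "asr_estimate%s: %d tips, sigma2 (REML) = %.4g, root = %.4g (var %.4g)\n",
    if (!is.null(x$trait)) paste0(" [", x$trait, "]") else "",
    x$n_tips, x$sigma2, rt$estimate, rt$variance))
  invisible(x)
}

#' Write a NEXUS tree annotated with ancestral states
#'
#' Serializes the tree with per-node metadata comments in the style used by
#' Bayesian phylogenetics tools (`[&mean=...,var=...]` after each node), so
#' reconstructed states can be inspected in standard tree viewers.
#'
#' @param phy the tree the estimates were computed on.
#' @param asr an `asr_estimate` from [asr_bm()].
#' @param file output path.
#' @param back_transform if `TRUE`, also write `mean10 = 10^mean` per node,
#'   the point back-transform for log10-scale traits.
#' @return `file`, invisibly.
#' @export
write_annotated_nexus <- function(phy, asr, file, back_transform = TRUE) {
  stopifnot(inherits(asr, "asr_estimate"))
  n <- length(phy$tip.label)
  nd <- asr$nodes
  note <- function(k) {
    s <- sprintf("[&mean=%.10g,var=%.10g", nd$estimate[k], nd$variance[k])
    if (back_transform) s <- paste0(s, sprintf(",mean10=%.10g",
                                               10^nd$estimate[k]))
    paste0(s, "]")
  }
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  blen <- numeric(n + phy$Nnode)
  blen[phy$edge[, 2L]] <- phy$edge.length
  build <- function(k) {
    if (k <= n)
      return(sprintf("%s%s:%.10g", phy$tip.label[k], note(k), blen[k]))
    inner <- paste(vapply(children[[as.character(k)]], build, character(1)),
                   collapse = ",")
    root <- n + 1L
    if (k == root) sprintf("(%s)%s;", inner, note(k))
    else sprintf("(%s)%s:%.10g", inner, note(k), blen[k])
  }
  lines <- c(
    "#NEXUS",
    "Begin taxa;",
    sprintf("\tDimensions ntax=%d;", n),
    "\tTaxlabels",
    paste0("\t\t", phy$tip.label),
    "\t\t;",
    "End;",
    "Begin trees;",
    paste0("tree ASR = [&R] ", build(n + 1L)),
    "End;")
  writeLines(lines, file)
  invisible(file)
}
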