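test_that("newick reading validates and flags what contrasts need", {
  phy <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  expect_equal(unname(ape::node.depth.edgelength(phy)[1:3]), c(2, 2, 2))
  expect_false(attr(phy, "polytomies"))
  expect_true(attr(read_newick("(A:1,B:1,C:1);"), "polytomies"))
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")

  tf <- file.path(withr::local_tempdir(), "t.nwk")
  ape::write.tree(phy, tf)
  phy2 <- read_newick(file = tf)
  expect_equal(phy2$edge.length, phy$edge.length)
  expect_identical(phy2$tip.label, phy$tip.label)
})

test_that("log10 transform requires positive values and keeps names", {
  expect_equal(as.numeric(log10_transform(c(a = 100, b = 1))), c(2, 0))
  expect_error(log10_transform(c(a = 0, b = 1)), "positive")
  expect_error(log10_transform(c(1, 2)), "named")
})

test_that("contrasts match the closed-form pruning recursion", {
  # cherry: one contrast (3 - 1)/sqrt(2), root value 2
  cs <- pic_contrasts(read_newick("(A:1,B:1);"), c(A = 3, B = 1))
  expect_equal(cs$contrasts$contrast, 2 / sqrt(2))
  expect_equal(cs$root_value, 2)

  # three tips, hand application of the recursion
  phy <- read_newick("((A:1,B:1):1,C:2);")
  cs3 <- pic_contrasts(phy, c(A = 3, B = 1, C = 2))
  expect_equal(sort(abs(cs3$contrasts$contrast)), c(0, sqrt(2)),
               tolerance = 1e-12)
  inner <- cs3$contrasts$node[cs3$contrasts$var == 2]
  expect_equal(cs3$node_values[inner], 2)       # weighted daughter mean
  expect_equal(cs3$node_adj_var[inner], 0.5)    # branch lengthened by 1/2
  expect_equal(cs3$root_value, 2)

  # constant trait: all contrasts zero, root the constant
  csc <- pic_contrasts(phy, c(A = 7, B = 7, C = 7))
  expect_true(all(csc$contrasts$contrast == 0))
  expect_equal(csc$root_value, 7)

  expect_error(pic_contrasts(read_newick("(A:1,B:1,C:1);"),
                             c(A = 1, B = 2, C = 3)), "polytomies")
  expect_error(pic_contrasts(phy, c(A = 1, B = 2, D = 3)), "C")
})

test_that("contrasts and root agree with ape::pic and the GLS oracle", {
  for (seed in 1:10) {
    phy <- sim_yule(sample(4:8, 1), 1, seed = seed)
    x <- sim_bm(phy, 1, seed = 100 + seed)$tips
    cs <- pic_contrasts(phy, x)
    ref <- ape::pic(x[phy$tip.label], phy)
    expect_equal(abs(cs$contrasts$contrast[order(cs$contrasts$node)]),
                 abs(ref[order(as.integer(names(ref)))]),
                 ignore_attr = TRUE, tolerance = 1e-10)
    gls <- gls_root_oracle(phy, x)
    expect_equal(cs$root_value, unname(gls["est"]), tolerance = 1e-10)
    expect_equal(cs$root_var, unname(gls["var"]), tolerance = 1e-10)
  }
})

test_that("BM-simulated contrasts are standard normal at the stated rate", {
  # mean squared standardized contrast estimates sigma2
  sig2 <- 0.7
  msq <- numeric(400)
  shapiro_p <- numeric(20)
  k <- 0
  for (seed in 1:400) {
    phy <- sim_yule(26, 1, seed = 5000 + seed)
    x <- sim_bm(phy, sig2, seed = 6000 + seed)$tips
    cs <- pic_contrasts(phy, x)
    msq[seed] <- mean(cs$contrasts$contrast^2)
    if (seed %% 20 == 0) {
      k <- k + 1
      shapiro_p[k] <- stats::shapiro.test(cs$contrasts$contrast)$p.value
    }
  }
  expect_lt(abs(mean(msq) - sig2) / sig2, 0.05)
  expect_gte(mean(shapiro_p > 0.01), 0.95)
})

test_that("contrast regression matches hand values and the matrix solve", {
  f <- regress_contrasts(c(2, 4, -2), c(1, 2, -1))
  expect_equal(f$b, 2)
  expect_equal(f$r2, 1)
  expect_equal(f$df2, 2L)

  fz <- regress_contrasts(c(0, 0, 0, 0), c(1, 2, -1, 3))
  expect_equal(fz$b, 0)
  expect_equal(fz$F, 0)
  expect_equal(fz$p, 1)

  set.seed(8)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20, sd = 0.3)
  f2 <- regress_contrasts(y, x)
  expect_equal(f2$b, sum(x * y) / sum(x * x), tolerance = 1e-10)
  expect_equal(f2$df2, 19L)
  fi <- regress_contrasts(y, x, intercept_mode = TRUE)
  expect_equal(fi$df2, 18L)
  # intercept-mode slope equals the normal-equation solve on positivised data
  s <- sign(x); s[s == 0] <- 1
  X <- cbind(1, x * s)
  beta <- solve(t(X) %*% X, t(X) %*% (y * s))
  expect_equal(fi$b, beta[2, 1], tolerance = 1e-10)

  expect_error(regress_contrasts(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regress_contrasts(c(1, 2, 3), c(0, 0, 0)), "zero variance")
})

test_that("regression through origin is invariant to contrast signs", {
  set.seed(3)
  x <- rnorm(15); y <- -1.2 * x + rnorm(15, sd = 0.2)
  flip <- sample(c(-1, 1), 15, replace = TRUE)
  f1 <- regress_contrasts(y, x)
  f2 <- regress_contrasts(y * flip, x * flip)
  expect_equal(f2$b, f1$b)
  expect_equal(f2$F, f1$F)
})

test_that("elevation back-transforms from the two GLS roots", {
  phy <- sim_yule(10, 1, seed = 4)
  tr <- sim_allometric_traits(phy, slope = -1, elevation = 2,
                              sigma2_x = 1, sigma2_e = 0, seed = 9)
  f <- regress_contrasts(pic_contrasts(phy, tr$y), pic_contrasts(phy, tr$x))
  expect_equal(f$b, -1, tolerance = 1e-10)
  expect_equal(f$a, 100, tolerance = 1e-8)   # 10^elevation, noise-free
})

test_that("F-test p values reproduce the printed regression statistics", {
  expect_equal(round(f_test_p(13.4, 1, 16), 3), 0.002)
  expect_equal(round(f_test_p(0.0002, 1, 16), 2), 0.99)
  expect_equal(f_test_p(0, 1, 16), 1)
  expect_error(f_test_p(1, 0, 16), "freedom")
  expect_error(f_test_p(-1, 1, 16), "non-negative")
})

test_that("taxon exclusion prunes tree and traits coherently", {
  phy <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 2, C = 3)
  ex <- exclude_taxon(phy, x, "C")
  expect_setequal(ex$phy$tip.label, c("A", "B"))
  expect_equal(sort(ex$phy$edge.length), c(1, 1))  # proper 2-tip tree
  expect_identical(names(ex$x), c("A", "B"))

  # pruning a cherry member: sibling absorbs the parent branch
  ex2 <- exclude_taxon(phy, x, "A")
  expect_equal(ex2$phy$edge.length[ex2$phy$edge[, 2] ==
                 which(ex2$phy$tip.label == "B")], 2)  # 1 + 1

  phy4 <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  cs4 <- pic_contrasts(phy4, c(A = 1, B = 2, C = 3, D = 4))
  ex4 <- exclude_taxon(phy4, c(A = 1, B = 2, C = 3, D = 4), "D")
  expect_equal(nrow(pic_contrasts(ex4$phy, ex4$x)$contrasts),
               nrow(cs4$contrasts) - 1L)

  expect_error(exclude_taxon(phy, x, "Z"), "not a tip")
  expect_error(exclude_taxon(read_newick("(A:1,B:1);"), x[1:2], "A"),
               "proper tree")
})
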