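# PCoA, environmental fitting and distance-based redundancy analysis,
# cross-checked against independent implementations (classical MDS,
# vegan) where those exist.

test_that("PCoA reproduces Euclidean geometry and spectral identities", {
  # planar points: PCoA coordinates must reproduce pairwise distances
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), 4, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$points[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)
  expect_false(ord$negative_eigenvalues)
  # eigenvalue sum equals trace of the Gower matrix
  G <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  expect_equal(sum(ord$eigenvalues), sum(diag(G)), tolerance = 1e-10)
  # centered coordinates
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-12)

  # degenerate all-zero distances
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ordz <- pcoa(z)
  expect_equal(ordz$eigenvalues, rep(0, 3))
  expect_equal(ncol(ordz$points), 0)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA agrees with classical MDS on a Bray-Curtis matrix", {
  tab <- random_otu_table(n_samples = 12, n_otus = 30, seed = 5)
  d <- bray_curtis(relative_abundance(tab))
  ord <- pcoa(d)
  cm <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  # eigenvalues identical; coordinates identical up to axis sign
  expect_equal(ord$eigenvalues[1:2], cm$eig[1:2], tolerance = 1e-10)
  expect_equal(abs(unname(ord$points[, 1:2])), abs(unname(cm$points)),
               tolerance = 1e-8)
  # sign convention: the largest-|loading| entry of each axis is positive
  for (j in 1:2) expect_gt(ord$points[which.max(abs(ord$points[, j])), j], 0)
})

test_that("envfit vector recovers exact linear structure and its p floor", {
  tab <- random_otu_table(n_samples = 15, n_otus = 40, seed = 7)
  ord <- pcoa(bray_curtis(relative_abundance(tab)))
  env <- 2 * ord$points[, 1] - ord$points[, 2] + 3
  ef <- envfit_vector(ord, env, n_perm = 999, seed = 1)
  expect_equal(ef$r2, 1, tolerance = 1e-10)
  expect_equal(ef$p, 1 / 1000)          # +1-corrected permutation floor
  expect_equal(sqrt(ef$arrow_x^2 + ef$arrow_y^2), sqrt(ef$r2),
               tolerance = 1e-8)
  # constant env is flagged not-computable
  expect_true(is.na(envfit_vector(ord, rep(1, 15))$r2))
})

test_that("envfit matches the vegan implementation on r2", {
  skip_if_not_installed("vegan")
  tab <- random_otu_table(n_samples = 18, n_otus = 30, seed = 9)
  ord <- pcoa(bray_curtis(relative_abundance(tab)))
  set.seed(4)
  env <- ord$points[, 1] + rnorm(18, 0, 0.1)
  grp <- factor(rep(c("a", "b", "c"), each = 6))
  ef <- envfit_vector(ord, env, n_perm = 99, seed = 1)
  vf <- vegan::envfit(ord$points[, 1:2], data.frame(env = env),
                      permutations = 99)
  expect_equal(ef$r2, unname(vf$vectors$r), tolerance = 1e-10)
  ff <- envfit_factor(ord, grp, n_perm = 99, seed = 1)
  vff <- vegan::envfit(ord$points[, 1:2], data.frame(grp = grp),
                       permutations = 99)
  expect_equal(ff$r2, unname(vff$factors$r), tolerance = 1e-10)
})

test_that("envfit factor r2 spans its 0-1 extremes", {
  coords <- rbind(matrix(c(-1, 0), 4, 2, byrow = TRUE),
                  matrix(c(1, 0), 4, 2, byrow = TRUE))
  coords <- coords + 0  # two coincident clusters along axis 1
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord <- pcoa(d)
  groups <- rep(c("a", "b"), each = 4)
  ff <- envfit_factor(ord, groups, n_perm = 99, seed = 1)
  expect_equal(ff$r2, 1, tolerance = 1e-10)
  # a single group explains nothing
  tab <- random_otu_table(n_samples = 10, seed = 2)
  ord2 <- pcoa(bray_curtis(relative_abundance(tab)))
  f1 <- envfit_factor(ord2, rep("a", 10), n_perm = 99, seed = 1)
  expect_equal(f1$r2, 0, tolerance = 1e-12)
})

test_that("dbrda matches capscale, self-projection and nestedness", {
  set.seed(2)
  X <- matrix(rnorm(20 * 4), 20, 4)
  d <- as.matrix(dist(X))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  pr <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))

  db <- mycocarbon::dbrda(d, pr)
  skip_if_not_installed("vegan")
  cs <- vegan::capscale(stats::as.dist(d) ~ scale(a) + scale(b) + scale(c),
                        data = pr)
  expect_equal(db$proportion, cs$CCA$tot.chi / cs$tot.chi, tolerance = 1e-8)

  # predictors = the PCoA axes themselves explain everything
  ord <- pcoa(d)
  db_self <- mycocarbon::dbrda(d, as.data.frame(ord$points))
  expect_equal(db_self$proportion, 1, tolerance = 1e-8)

  # adding a predictor never decreases constrained inertia
  db2 <- mycocarbon::dbrda(d, pr[, 1:2])
  expect_gte(db$constrained_inertia, db2$constrained_inertia - 1e-12)

  # affine rescaling of a standardized numeric predictor changes nothing
  pr_resc <- transform(pr, a = 100 * a - 7)
  expect_equal(mycocarbon::dbrda(d, pr_resc)$proportion, db$proportion,
               tolerance = 1e-10)

  # aliased columns are dropped with a warning
  pr_alias <- transform(pr, d = a)
  expect_warning(db_al <- mycocarbon::dbrda(d, pr_alias), "aliased")
  expect_equal(db_al$proportion, db$proportion, tolerance = 1e-10)
})

test_that("dbrda on pure-noise predictors matches the null R2 expectation", {
  # E[R^2] under the null is p/(n-1) per response dimension
  set.seed(3)
  props <- replicate(40, {
    X <- matrix(rnorm(30 * 3), 30, 3)
    d <- as.matrix(dist(X))
    dimnames(d) <- list(paste0("s", 1:30), paste0("s", 1:30))
    pr <- data.frame(a = rnorm(30), b = rnorm(30))
    mycocarbon::dbrda(d, pr)$proportion
  })
  expect_lt(abs(mean(props) - 2 / 29), 0.015)
})
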