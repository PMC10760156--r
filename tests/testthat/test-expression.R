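test_that("log1p normalization matches hand arithmetic", {
  m <- matrix(c(10, 10, 0), ncol = 1, dimnames = list(paste0("g", 1:3), "n1"))
  out <- normalizeLog1p(m, target_sum = 100)
  expect_equal(as.numeric(out), c(log(51), log(51), 0))
  ## zero count stays zero after the transform
  expect_equal(out[3, 1], 0)
  ## proportional nuclei normalize identically
  m2 <- cbind(n1 = c(2, 4, 6), n2 = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  out2 <- normalizeLog1p(m2)
  expect_equal(out2[, 1], out2[, 2], ignore_attr = TRUE)
  expect_error(normalizeLog1p(cbind(c(0, 0))), "zero total")
})

test_that("variable-gene selection keeps the engineered high-dispersion band", {
  set.seed(4)
  n <- 300
  base <- matrix(rpois(100 * n, 5), 100, n,
                 dimnames = list(paste0("g", 1:100), paste0("n", 1:n)))
  ## 10 engineered genes: same mean, far larger dispersion
  for (g in 1:10)
    base[g, ] <- rpois(n, 5) * rbinom(n, 1, 0.25) * 4
  ## a constant gene and a too-high-mean gene
  base[99, ] <- 7
  base[100, ] <- rpois(n, 500)
  ln <- log1p(base)   # already on a common scale for this toy
  keep <- selectHVG(ln, min_mean = 0.5, max_mean = 50, min_disp = 1)
  expect_setequal(names(which(keep)), paste0("g", 1:10))
  expect_false(keep["g99"])   # constant: no dispersion
  ## mean band excludes regardless of dispersion
  keep3 <- selectHVG(ln, min_mean = 0.5, max_mean = 6, min_disp = -10)
  expect_false(keep3["g100"])
})

test_that("regress-out matches the normal-equations oracle", {
  set.seed(9)
  y <- matrix(rnorm(5 * 40), 5, 40, dimnames = list(paste0("g", 1:5), NULL))
  cov <- cbind(rnorm(40), rnorm(40))
  out <- regressAndScale(y, cov, clip = Inf)
  X <- cbind(1, cov)
  for (g in 1:5) {
    r <- y[g, ] - X %*% solve(t(X) %*% X, t(X) %*% y[g, ])
    expect_equal(unname(out[g, ]), as.numeric(r / sd(r)), tolerance = 1e-10)
  }
  ## a gene exactly linear in the covariate has ~zero residual
  y2 <- rbind(lin = 2 + 3 * cov[, 1], noise = rnorm(40))
  out2 <- regressAndScale(y2, cov[, 1, drop = FALSE])
  expect_equal(unname(out2["lin", ]), rep(0, 40), tolerance = 1e-8)
  ## orthogonal covariate: residual is the centered input
  x <- rep(c(-1, 1), 20)
  y3 <- matrix(rnorm(40) + 5, 1, 40)
  y3 <- y3 - (sum(y3 * x) / sum(x * x)) * rbind(x)   # orthogonalize
  out3 <- regressAndScale(y3, cbind(x), clip = Inf)
  cen <- y3[1, ] - mean(y3[1, ])
  expect_equal(unname(out3[1, ]), as.numeric(cen / sd(cen)), tolerance = 1e-8)
})

test_that("two separated blobs give exactly two clusters", {
  set.seed(2)
  blob <- rbind(matrix(rnorm(100 * 40), 100), matrix(rnorm(100 * 40, 10), 100))
  res <- embedAndCluster(t(blob), n_pcs = 10, k = 10, resolution = 0.8,
                         seed = 3L)
  expect_equal(nlevels(res$clusters), 2L)
  expect_equal(length(unique(res$clusters[1:100])), 1L)
  ## graph has no isolated nuclei and one label per nucleus
  expect_true(all(igraph::degree(res$graph) >= 1))
  expect_equal(length(res$clusters), 200L)
})

test_that("single-batch correction is the identity", {
  set.seed(5)
  m <- matrix(rnorm(30 * 80), 30, 80)
  a <- embedAndCluster(m, n_pcs = 5, k = 5, seed = 1L)
  b <- embedAndCluster(m, n_pcs = 5, k = 5, batch = rep("w1", 80), seed = 1L)
  expect_equal(a$pcs, b$pcs, tolerance = 1e-8)
  expect_identical(a$clusters, b$clusters)
})

test_that("n_pcs beyond the rank is clipped with a warning", {
  m <- matrix(rnorm(10 * 30), 10, 30)
  expect_warning(res <- embedAndCluster(m, n_pcs = 40, k = 5, seed = 1L),
                 "clipped")
  expect_lte(ncol(res$pcs), 9L)
})

test_that("clustering recovers the generated cell types", {
  skip_if_not_installed("mclust")
  ie <- removeDoublets(filterGenes(filterNuclei(small_cohort())$x))
  ln <- normalizeLog1p(assay(ie, "counts"))
  hv <- selectHVG(ln, min_mean = 0.05, max_mean = 50, min_disp = 0.3)
  sc <- regressAndScale(ln[hv, ], covariates = Matrix::colSums(assay(ie, "counts")))
  res <- embedAndCluster(sc, n_pcs = 40, k = 10, resolution = 0.8,
                         batch = ie$batch_id, seed = 5L)
  expect_gte(mclust::adjustedRandIndex(res$clusters, ie$true_celltype), 0.90)
  ## stability across community-detection seeds
  res2 <- embedAndCluster(sc, n_pcs = 40, k = 10, resolution = 0.8,
                          batch = ie$batch_id, seed = 6L)
  expect_gte(mclust::adjustedRandIndex(res$clusters, res2$clusters), 0.95)
})

test_that("second-pass subclustering separates disease programs in the endothelium", {
  ie <- removeDoublets(filterGenes(filterNuclei(small_cohort())$x))
  ln <- normalizeLog1p(assay(ie, "counts"))
  ec <- ie$true_celltype == "EC"
  sub <- twoPassSubcluster(ln, ec, batch = ie$batch_id,
                           hvg = list(min_mean = 0.05, max_mean = 50,
                                      min_disp = 0.3), seed = 5L)
  dis <- !is_ctrl_state(ie$disease_state[ec])
  frac <- tapply(dis, sub$clusters, mean)
  tab <- table(sub$clusters %in% names(which(frac > 0.5)), dis)
  expect_lt(fisher.test(tab)$p.value, 0.01)
  ## identical settings reproduce identical labels
  sub2 <- twoPassSubcluster(ln, ec, batch = ie$batch_id,
                            hvg = list(min_mean = 0.05, max_mean = 50,
                                       min_disp = 0.3), seed = 5L)
  expect_identical(sub$clusters, sub2$clusters)
  expect_error(twoPassSubcluster(ln, 1:10), "fewer than 50")
})

test_that("a homogeneous subset yields no donor- or group-structured clusters", {
  ie <- removeDoublets(filterGenes(filterNuclei(small_cohort())$x))
  ln <- normalizeLog1p(assay(ie, "counts"))
  ## control-donor endothelium carries no disease or DAM program; community
  ## detection on a homogeneous kNN graph may still carve balanced noise
  ## communities, but none of them may align with donor, group or age
  hom <- ie$true_celltype == "EC" & is_ctrl_state(ie$disease_state)
  sub <- twoPassSubcluster(ln, hom, batch = ie$batch_id,
                           hvg = list(min_mean = 0.05, max_mean = 50,
                                      min_disp = 0.3), seed = 5L)
  expect_gt(suppressWarnings(
    chisq.test(table(sub$clusters, ie$donor_id[hom]))$p.value), 0.01)
  expect_gt(suppressWarnings(
    chisq.test(table(sub$clusters,
                     droplevels(ie$disease_state[hom])))$p.value), 0.01)
})

test_that("differential expression matches Welch's formula and is antisymmetric", {
  set.seed(14)
  m <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(paste0("g", 1:20), NULL))
  de <- differentialExpression(m, 1:5, 6:12)
  for (g in c(1, 7, 20)) {
    tt <- t.test(m[g, 1:5], m[g, 6:12])
    expect_equal(de$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[g], tt$p.value, tolerance = 1e-10)
  }
  rev <- differentialExpression(m, 6:12, 1:5)
  expect_equal(rev$t, -de$t, tolerance = 1e-12)
  expect_equal(rev$lfc, -de$lfc, tolerance = 1e-12)
  same <- differentialExpression(cbind(m[, 1:4], m[, 1:4]), 1:4, 5:8)
  expect_true(all(same$t == 0) && all(same$lfc == 0) && all(same$p == 1))
  expect_true(all(de$padj >= de$p))
})

test_that("cluster proportions sum to one and correlate as expected", {
  donor <- rep(c("d1", "d2", "d3", "d4", "d5", "d6"), each = 10)
  cl <- c(rep(1, 10),                      # d1 entirely in cluster 1
          rep(c(1, 2), c(3, 7)), rep(c(1, 2), c(5, 5)),
          rep(c(1, 2), c(6, 4)), rep(c(1, 2), c(8, 2)), rep(c(1, 2), c(9, 1)))
  prop <- clusterProportions(donor, cl)
  expect_equal(unname(rowSums(prop)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(prop["d1", ]), c(1, 0))
  ## monotone proportion vs age gives rho 1; hand-ranked oracle agrees
  age <- c(20, 30, 40, 50, 60, 70)
  res <- correlateProportion(prop, age)
  p2 <- prop[, "2"]
  oracle <- cor(rank(p2), rank(age))
  expect_equal(res$rho[res$cluster == "2"], oracle, tolerance = 1e-12)
  mono <- prop; mono[, 2] <- seq(0.1, 0.6, 0.1); mono[, 1] <- 1 - mono[, 2]
  expect_equal(correlateProportion(mono, age)$rho[2], 1)
  expect_error(correlateProportion(prop[1:2, ], age[1:2]), "3 donors")
})
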