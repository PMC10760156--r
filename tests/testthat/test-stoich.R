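test_that("the stoichiometry curve reproduces simple relations", {
  set.seed(12)
  x <- rnorm(2000)
  g <- rep(c("a", "b"), 1000)
  ## y = x exactly: per-bin mean equals the bin's mean x
  sc <- stoichCurve(x, x, g, n_bins = 10)
  expect_lt(max(abs(sc$mean - sc$x_center)), 1e-12)
  ## constant y: flat curve
  sc2 <- stoichCurve(x, rep(2, 2000), g, n_bins = 10)
  expect_true(all(sc2$mean == 2))
  expect_true(all(sc2$se == 0))
  ## bin occupancy sums to the population
  expect_equal(sum(sc$n), 2000L)
  expect_error(stoichCurve(x, x, g, which_groups = "zz"), "absent")
})

test_that("the control curve recovers the generative coupling slope", {
  ie <- cached_cohort("slope5k", cohortConfig(seed = 77L))
  nclr <- clrTransform(normalizeToH3(ie))
  cd <- colData(ie)[colnames(nclr), ]
  ec <- cd$true_celltype == "EC"
  grp <- ifelse(is_ctrl_state(cd$disease_state[ec]), "ctrl", "disease")
  sc <- stoichCurve(nclr["NFkB", ec], nclr["TDP43", ec], grp,
                    n_bins = 20, which_groups = "ctrl")
  slope <- coef(lm(mean ~ x_center, data = sc))[2]
  expect_lt(abs(slope - 0.8), 0.1)
})

test_that("one-way ANOVA and Tukey match closed-form oracles", {
  ## fixed 3-group, 5-per-group table
  y <- c(1.1, 2.0, 1.5, 1.8, 1.2,
         2.4, 2.9, 3.1, 2.2, 2.6,
         0.9, 1.4, 0.8, 1.3, 1.1)
  g <- rep(c("A", "B", "C"), each = 5)
  res <- stratifiedComparison(y, rep("top", 15), g)$top
  ## textbook F from sums of squares
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 12)
  expect_equal(unname(res$anova["F"]), Fo, tolerance = 1e-8)
  expect_equal(unname(res$anova["p"]), pf(Fo, 2, 12, lower.tail = FALSE),
               tolerance = 1e-8)
  ## Tukey from the studentized range distribution
  mse <- ssw / 12
  dAB <- mean(y[g == "B"]) - mean(y[g == "A"])
  pAB <- ptukey(abs(dAB) / sqrt(mse / 5), nmeans = 3, df = 12,
                lower.tail = FALSE)
  row <- res$tukey[res$tukey$comparison == "B-A", ]
  expect_equal(row$diff, dAB, tolerance = 1e-8)
  expect_equal(row$p_adj, pAB, tolerance = 1e-8)
})

test_that("stratified comparison has calibrated nulls and expected power", {
  set.seed(13)
  fp <- 0L
  for (i in 1:100) {
    y <- rnorm(150)
    g <- rep(c("a", "b", "c"), 50)
    p <- stratifiedComparison(y, rep("s", 150), g)$s$anova["p"]
    if (p < 0.01) fp <- fp + 1L
  }
  expect_lte(fp, 4L)  # ~1 expected at alpha 0.01; generous upper bound
  ## two groups a unit apart with sd 0.5, n = 200: decisive
  y <- c(rnorm(200, 0, 0.5), rnorm(200, 1, 0.5))
  g <- rep(c("ctl", "dis"), each = 200)
  res <- stratifiedComparison(y, rep("top", 400), g)$top
  expect_lt(res$tukey$p_adj[1], 0.001)
  expect_identical(res$tukey$stars[1], "***")
})

test_that("small groups are excluded from a stratum with a warning", {
  y <- rnorm(41)
  g <- c(rep("a", 20), rep("b", 20), "tiny")
  expect_warning(res <- stratifiedComparison(y, rep("s", 41), g), "tiny")
  expect_setequal(res$s$means$group, c("a", "b"))
})

test_that("the decoupling statistic is null on controls and recovers delta", {
  ie <- cached_cohort("rec05", recovery_config(-0.5, 321L,
                                               nuclei_per_donor = 150L))
  nclr <- clrTransform(normalizeToH3(ie))
  cd <- colData(ie)[colnames(nclr), ]
  ec <- cd$true_celltype == "EC"
  d <- decouplingStatistic(nclr["NFkB", ec], nclr["TDP43", ec],
                           as.character(cd$disease_state[ec]),
                           n_boot = 200, boot = "donor",
                           donor = cd$donor_id[ec], stratum_by = "donor",
                           top_pct = 80, seed = 4L)
  dd <- d$delta
  dis <- dd$group %in% c("AD", "ALS", "FTD")
  expect_lt(abs(mean(dd$delta[dis]) - (-0.5)), 0.15)
  ctrl <- dd[dd$group %in% c("young_ctrl", "old_ctrl"), ]
  expect_true(all(ctrl$lo <= 0 & ctrl$hi >= 0))
  expect_true(all(dd$lo <= dd$delta & dd$delta <= dd$hi))
  ## ANOVA separates groups; Tukey rows compare against controls
  expect_lt(d$anova["p"], 0.01)
  expect_true(all(grepl("ctrl", d$tukey$comparison)))
})

test_that("bootstrap confidence intervals are stable in n_boot", {
  ie <- cached_cohort("rec05", recovery_config(-0.5, 321L,
                                               nuclei_per_donor = 150L))
  nclr <- clrTransform(normalizeToH3(ie))
  cd <- colData(ie)[colnames(nclr), ]
  ec <- cd$true_celltype == "EC"
  args <- list(nclr["NFkB", ec], nclr["TDP43", ec],
               as.character(cd$disease_state[ec]), boot = "flat", seed = 9L)
  d1 <- do.call(decouplingStatistic, c(args, n_boot = 300))
  d2 <- do.call(decouplingStatistic, c(args, n_boot = 600))
  expect_lt(max(abs(d1$delta$lo - d2$delta$lo),
                abs(d1$delta$hi - d2$delta$hi)), 0.05)
})

test_that("degenerate NF-kB variance is an error", {
  expect_error(decouplingStatistic(rep(1, 200), rnorm(200),
                                   rep(c("young_ctrl", "AD"), 100),
                                   n_boot = 0),
               "degenerate")
})

test_that("high-vs-low NF-kB contrasts find the target program where TDP-43 is low", {
  ie <- removeDoublets(filterGenes(filterNuclei(small_cohort())$x))
  ln <- normalizeLog1p(assay(ie, "counts"))
  nclr <- clrTransform(normalizeToH3(ie))
  keep <- colnames(nclr)
  lnk <- ln[, keep]
  cdk <- colData(ie)[keep, ]
  ec <- cdk$true_celltype == "EC"
  cl <- ifelse(is_ctrl_state(cdk$disease_state), "healthy", "disease")
  cl[!ec] <- "other"
  nf <- rep(NA_real_, length(cl)); nf[ec] <- nclr["NFkB", ec]
  de_dis <- nfkbHighDEContrast(lnk, nf, cl, "disease")
  de_hea <- nfkbHighDEContrast(lnk, nf, cl, "healthy")
  targets <- geneMarkers(ie)$nfkb_targets
  sig_dis <- de_dis$gene[de_dis$padj < 0.05 & de_dis$lfc > 0]
  tab <- table(de_dis$gene %in% targets, de_dis$gene %in% sig_dis)
  expect_lt(fisher.test(tab, alternative = "greater")$p.value, 0.01)
  ## the healthy cluster carries no NF-kB target program
  sig_hea <- de_hea$gene[de_hea$padj < 0.05 & de_hea$lfc > 0]
  expect_lte(sum(sig_hea %in% targets), length(targets) * 0.1)
})
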