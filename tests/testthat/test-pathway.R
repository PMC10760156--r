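make_weights <- function(genes, n_path = 3, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, length(genes), n_path,
                dimnames = list(genes, paste0("P", seq_len(n_path))))
    for (j in seq_len(n_path))
      w[sample(length(genes), 8), j] <- rnorm(8, sd = 2)
    w
  })
}

test_that("mlm activity matches a per-nucleus lm oracle", {
  set.seed(11)
  genes <- paste0("g", 1:20)
  w <- make_weights(genes)
  expr <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(genes, paste0("n", 1:6)))
  act <- mlmActivity(expr, w)
  for (j in 1:6) {
    fit <- summary(lm(expr[, j] ~ w))$coefficients
    expect_equal(unname(act[, j]), unname(fit[-1, "t value"]),
                 tolerance = 1e-8)
  }
})

test_that("mlm activity flags exactly the matching pathway", {
  genes <- paste0("g", 1:30)
  w <- matrix(0, 30, 3, dimnames = list(genes, c("A", "B", "C")))
  w[1:10, "A"] <- 1:10
  w[11:20, "B"] <- 1:10
  w[21:30, "C"] <- 1:10
  expr <- cbind(n1 = w[, "B"], n0 = rep(0, 30))
  rownames(expr) <- genes
  act <- mlmActivity(expr, w)
  expect_gt(act["B", "n1"], 0)       # exact fit: unbounded t
  expect_lt(max(abs(act[c("A", "C"), "n1"])), 1e-8)
  expect_equal(unname(act[, "n0"]), rep(0, 3))
})

test_that("weight/logFC concordance classes match hand enumeration", {
  de <- data.frame(gene = paste0("g", 1:7),
                   lfc = c(1, -1, 1, -1, 0, 2, -3))
  w <- matrix(c(2, 2, -2, -2, 3, 0, -1), ncol = 1,
              dimnames = list(paste0("g", 1:7), "NFkB"))
  out <- weightLfcConcordance(de, w, "NFkB")
  expect_identical(out$class,
                   c("consistent_up", "discordant", "discordant",
                     "consistent_down", "neutral", "neutral",
                     "consistent_down"))
  ## genes missing from the weight table are omitted
  de2 <- rbind(de, data.frame(gene = "gX", lfc = 5))
  expect_equal(nrow(weightLfcConcordance(de2, w, "NFkB")), 7L)
  expect_error(weightLfcConcordance(de, w, "nope"), "unknown pathway")
})

test_that("GSEA enrichment score equals brute-force enumeration", {
  ## top-block set, unweighted: running sum peaks at 1 after the block
  scores <- setNames(seq(20, 1), paste0("g", 1:20))
  set5 <- paste0("g", 1:5)
  r <- gseaPreranked(scores, set5, weight_exponent = 0, n_perm = 50, seed = 1)
  expect_equal(r$es, brute_es(scores, set5, p = 0))
  expect_equal(r$es, 1)
  ## evenly spread set has a small |ES|
  scoresN <- setNames(seq(100, 1), paste0("g", 1:100))
  even <- paste0("g", seq(2, 100, 2))
  expect_lt(abs(gseaPreranked(scoresN, even, 0, n_perm = 10, seed = 1)$es), 0.2)
  ## reversing the ranking flips the signed extremum (unweighted)
  set.seed(3)
  sc <- setNames(rnorm(30), paste0("g", 1:30))
  gs <- paste0("g", sample(30, 6))
  up <- gseaPreranked(sc, gs, 0, n_perm = 10, seed = 1)$es
  dn <- gseaPreranked(-sc, gs, 0, n_perm = 10, seed = 1)$es
  expect_equal(dn, -up, tolerance = 1e-12)
  expect_error(gseaPreranked(sc, character(0), n_perm = 10), "empty")
  expect_error(gseaPreranked(sc, names(sc), n_perm = 10), "whole ranking")
})

test_that("GSEA matches brute force on random weighted cases", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:50, 1)
    sc <- setNames(rnorm(n), paste0("g", seq_len(n)))
    gs <- paste0("g", sample(n, sample(2:(n - 2), 1)))
    p <- sample(c(0, 1), 1)
    expect_equal(gseaPreranked(sc, gs, p, n_perm = 5, seed = i)$es,
                 brute_es(sc, gs, p), tolerance = 1e-12)
  }
})

test_that("NES and permutation p behave sensibly for a strong signal", {
  scores <- setNames(seq(50, 1) + rnorm(50, sd = 0.01), paste0("g", 1:50))
  r <- gseaPreranked(scores, paste0("g", 1:8), n_perm = 500, seed = 2)
  expect_gt(r$nes, 1)
  expect_lt(r$p, 0.02)
  expect_true(abs(r$es) <= 1)
})

test_that("the NES heatmap filter keeps pathways significant in >= 2 contrasts", {
  r1 <- data.frame(pathway = c("a", "b", "c"), es = 1, nes = c(2, 1, -2),
                   p = 0.001, q = c(0.001, 0.5, 0.001), n_set = 10)
  r2 <- data.frame(pathway = c("a", "b", "c"), es = 1, nes = c(1.5, 2, -1),
                   p = 0.001, q = c(0.005, 0.001, 0.2), n_set = 10)
  tab <- nesHeatmapTable(list(c1 = r1, c2 = r2), fdr_threshold = 0.01,
                         min_contrasts = 2)
  expect_identical(rownames(tab), "a")   # b and c significant once only
  tab2 <- nesHeatmapTable(list(c1 = r1, c2 = r1), fdr_threshold = 1,
                          min_contrasts = 2)
  expect_equal(nrow(tab2), 3L)
  expect_error(nesHeatmapTable(list(r1)), "2 contrasts")
})

test_that("the pathway overlap network uses Jaccard edges and communities", {
  sets <- list(A = as.character(1:10), B = as.character(6:15),
               C = as.character(100:110))
  net <- pathwayOverlapNetwork(sets, edge_threshold = 0.01)
  e <- net$edges
  expect_equal(nrow(e), 1L)
  expect_equal(e$jaccard, 5 / 15, tolerance = 1e-12)
  expect_equal(net$communities[["A"]], net$communities[["B"]])
  expect_false(net$communities[["A"]] == net$communities[["C"]])
  ## identical sets overlap completely; disjoint sets give an edgeless graph
  net2 <- pathwayOverlapNetwork(list(X = sets$A, Y = sets$A))
  expect_equal(net2$edges$jaccard, 1)
  net3 <- pathwayOverlapNetwork(list(X = sets$A, Y = sets$C))
  expect_equal(nrow(net3$edges), 0L)
  expect_equal(length(unique(net3$communities)), 2L)
})

test_that("footprint truncation keeps the n largest weights per pathway", {
  w <- matrix(c(5, -4, 3, 0.5, 0.1,
                1, 2, -3, 4, -5), 5, 2,
              dimnames = list(paste0("g", 1:5), c("A", "B")))
  out <- topFootprint(w, n = 2)
  expect_equal(sum(out[, "A"] != 0), 2L)
  expect_setequal(names(which(out[, "A"] != 0)), c("g1", "g2"))
  expect_setequal(names(which(out[, "B"] != 0)), c("g4", "g5"))
  expect_identical(topFootprint(w, n = 10), w)
})

test_that("the shipped synthetic weight and gene-set fixtures load", {
  wpath <- system.file("extdata", "synthetic_pathway_weights.tsv",
                       package = "incitekit")
  w <- read.delim(wpath, row.names = 1, check.names = FALSE)
  expect_identical(colnames(w), c("NFkB", "Wnt", "TGFb"))
  expect_true(all(colSums(w != 0) == 30))
  gmt <- readGMT(system.file("extdata", "synthetic_gene_sets.gmt",
                             package = "incitekit"))
  expect_length(gmt, 3L)
  expect_setequal(gmt$synthetic_nfkb_targets, rownames(w)[w$NFkB != 0])
})
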