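#' Total-count normalization and log transform
#'
#' Scales each nucleus to a common target sum, then applies the elementwise
#' natural-log transform \code{ln(x + 1)}.
#'
#' @param x genes x nuclei count matrix, or an \linkS4class{InciteExperiment}
#'   (the \code{"lognorm"} assay is added).
#' @param target_sum common per-nucleus total after scaling (default 10,000; a
#'   convention that cancels in fold-change comparisons).
#' @return Same shape as the input.
#' @examples
#' m <- matrix(c(10, 10, 0), ncol = 1, dimnames = list(paste0("g", 1:3), "n1"))
#' normalizeLog1p(m, target_sum = 100)  # ln(51), ln(51), 0
#' @export
setGeneric("normalizeLog1p", function(x, target_sum = 1e4)
  standardGeneric("normalizeLog1p"))

#' @rdname normalizeLog1p
#' @export
setMethod("normalizeLog1p", "ANY", function(x, target_sum = 1e4) {
  totals <- Matrix::colSums(x)
  if (any(totals == 0))
    stop("nucleus with zero total counts (apply QC filtering first)")
  sf <- target_sum / totals
  out <- x %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(x)
  log1p(out)
})

#' @rdname normalizeLog1p
#' @export
setMethod("normalizeLog1p", "InciteExperiment", function(x, target_sum = 1e4) {
  SummarizedExperiment::assay(x, "lognorm") <-
    normalizeLog1p(assay(x, "counts"), target_sum)
  x
})

#' Select highly variable genes
#'
#' Mean/dispersion selection on the normalized-count scale (the log-normalized
#' values are exponentiated back with \code{expm1}): a gene is kept iff its
#' mean lies strictly inside \code{(min_mean, max_mean)} and its normalized
#' dispersion (variance/mean, z-scored within \code{n_bins} mean-bins; bins
#' with fewer than 2 genes are merged with their lower neighbor) exceeds
#' \code{min_disp}.
#'
#' @param lognorm genes x nuclei log-normalized matrix.
#' @param min_mean,max_mean open mean band.
#' @param min_disp minimum normalized dispersion.
#' @param n_bins number of mean bins for dispersion normalization.
#' @return Named logical gene mask.
#' @export
selectHVG <- function(lognorm, min_mean = 0.0015, max_mean = 0.18,
                      min_disp = 0.30, n_bins = 20) {
  xm <- expm1(as.matrix(lognorm))
  mu <- rowMeans(xm)
  v <- apply(xm, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  bin <- cut(mu, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  ## merge sparse bins downward so every bin has >= 2 genes
  tab <- table(factor(bin, levels = seq_len(n_bins)))
  remap <- seq_len(n_bins)
  for (b in seq_len(n_bins)) {
    if (tab[b] > 0 && tab[b] < 2) {
      target <- if (b > 1) remap[b - 1] else which(tab >= 2)[1]
      if (!is.na(target)) remap[b] <- target
    }
  }
  bin <- remap[bin]
  z <- disp
  for (b in unique(bin[!is.na(bin)])) {
    i <- which(bin == b & !is.na(disp))
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  keep <- !is.na(disp) & mu > min_mean & mu < max_mean & !is.na(z) & z > min_disp
  stats::setNames(keep, rownames(lognorm))
}

#' Regress out covariates and scale
#'
#' Per gene, replaces the expression vector by its ordinary-least-squares
#' residual against the covariates (plus intercept), then z-scores to unit
#' variance with clipping.
#'
#' @param lognorm genes x nuclei matrix.
#' @param covariates nuclei x p numeric matrix (e.g. per-nucleus total UMI);
#'   \code{NULL} for centering/scaling only.
#' @param clip absolute clipping value after scaling.
#' @return genes x nuclei residual matrix, unit variance, clipped.
#' @export
regressAndScale <- function(lognorm, covariates = NULL, clip = 10) {
  y <- as.matrix(lognorm)
  X <- if (is.null(covariates)) matrix(1, ncol(y), 1L) else
    cbind(1, as.matrix(covariates))
  ## residuals for all genes in one solve
  bt <- solve(crossprod(X), crossprod(X, t(y)))
  res <- y - t(X %*% bt)
  s <- apply(res, 1L, stats::sd)
  ## a residual sd at numerical zero (relative to the gene's scale) means the
  ## gene is exactly explained by the covariates: leave it at 0
  zero <- s <= 1e-10 * pmax(apply(y, 1L, stats::sd), 1e-300)
  res <- res / ifelse(!zero, s, 1)
  res[zero, ] <- 0
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  res
}

.knn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  sq <- rowSums(pcs^2)
  edges <- matrix(0L, nrow = n * k, ncol = 2L)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(pcs[s:e, , drop = FALSE], pcs)
    for (i in seq_len(e - s + 1L)) {
      row <- d2[i, ]
      row[s + i - 1L] <- Inf
      nb <- order(row)[seq_len(k)]
      edges[((s + i - 2L) * k) + seq_len(k), ] <- cbind(s + i - 1L, nb)
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Embed and cluster nuclei
#'
#' Truncated PCA of the scaled matrix, optional per-batch mean-centering in PC
#' space (a simple default batch correction; heavier integration methods are a
#' pluggable external concern), a k-nearest-neighbor graph, Leiden community
#' detection (modularity objective), and a 2-D embedding for visualization
#' (first two PCs unless \code{embed_fun} is supplied).
#'
#' @param scaled genes x nuclei matrix from \code{\link{regressAndScale}}.
#' @param n_pcs number of principal components (clipped with a warning if it
#'   exceeds the matrix rank).
#' @param k neighbors for the kNN graph.
#' @param resolution Leiden resolution.
#' @param batch optional per-nucleus batch labels for PC-space centering.
#' @param seed integer seed (PCA initialization, Leiden refinement).
#' @param embed_fun optional \code{function(pcs)} returning an n x 2 matrix.
#' @return List of class \code{"EmbeddingResult"}: \code{pcs} (nuclei x
#'   n_pcs), \code{graph} (igraph), \code{clusters} (factor), \code{embedding}
#'   (nuclei x 2).
#' @export
embedAndCluster <- function(scaled, n_pcs = 40, k = 10, resolution = 0.8,
                            batch = NULL, seed = 1L, embed_fun = NULL) {
  y <- t(as.matrix(scaled))  # nuclei x genes
  max_pcs <- min(dim(y)) - 1L
  if (n_pcs > max_pcs) {
    warning("n_pcs clipped to ", max_pcs)
    n_pcs <- max_pcs
  }
  withr::with_seed(as.integer(seed), {
    ## truncated Lanczos for the usual case; exact SVD when asking for a
    ## large share of the spectrum (where irlba is unreliable)
    pcs <- if (n_pcs <= 0.5 * min(dim(y))) {
      irlba::prcomp_irlba(y, n = n_pcs, center = TRUE, scale. = FALSE)$x
    } else {
      stats::prcomp(y, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
    }
    rownames(pcs) <- colnames(scaled)
    if (!is.null(batch)) {
      for (b in unique(batch)) {
        i <- which(batch == b)
        pcs[i, ] <- sweep(pcs[i, , drop = FALSE], 2L,
                          colMeans(pcs[i, , drop = FALSE]))
      }
    }
    g <- .knn_graph(pcs, k)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
    clusters <- factor(igraph::membership(cl))
    emb <- if (is.null(embed_fun)) pcs[, 1:2, drop = FALSE] else embed_fun(pcs)
    colnames(emb) <- c("dim1", "dim2")
    structure(list(pcs = pcs, graph = g, clusters = clusters, embedding = emb),
              class = "EmbeddingResult")
  })
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat("EmbeddingResult:", nrow(x$pcs), "nuclei,", ncol(x$pcs), "PCs,",
      nlevels(x$clusters), "clusters\n")
  print(table(x$clusters))
  invisible(x)
}

#' Second-pass subclustering of one cell type
#'
#' Isolates a subset of nuclei in silico and re-embeds and re-clusters them
#' with batch-only correction, so donor and disease structure is retained (the
#' two-pass strategy: cell types are defined with full correction, disease
#' states within a cell type with batch correction only).
#'
#' @param lognorm genes x nuclei log-normalized matrix (full data).
#' @param cells indices or logical mask of the subset (e.g. one cell type).
#' @param batch optional batch labels for the subset (full-length vectors are
#'   subset automatically).
#' @param hvg named list of arguments for \code{\link{selectHVG}} on the
#'   subset; \code{NULL} skips re-selection and uses all genes.
#' @param clip scaling clip value.
#' @inheritParams embedAndCluster
#' @return An \code{"EmbeddingResult"} for the subset.
#' @export
twoPassSubcluster <- function(lognorm, cells, batch = NULL, hvg = NULL,
                              n_pcs = 40, k = 10, resolution = 0.8,
                              clip = 10, seed = 1L) {
  sub <- lognorm[, cells, drop = FALSE]
  if (ncol(sub) < 50L)
    stop("subcluster subset has fewer than 50 nuclei")
  if (!is.null(batch) && length(batch) > ncol(sub))
    batch <- batch[cells]
  if (!is.null(hvg)) {
    mask <- do.call(selectHVG, c(list(sub), hvg))
    if (sum(mask) >= 2L) sub <- sub[mask, , drop = FALSE]
  }
  scaled <- regressAndScale(sub, covariates = NULL, clip = clip)
  embedAndCluster(scaled, n_pcs = n_pcs, k = k, resolution = resolution,
                  batch = batch, seed = seed)
}

#' Differential expression by Welch's t-test
#'
#' Per-gene Welch two-sample t-test on log-normalized expression; the log fold
#' change is the difference of group means on the log scale; p-values are
#' Benjamini-Hochberg adjusted (configurable).
#'
#' @param lognorm genes x nuclei matrix.
#' @param groupA,groupB column indices or logical masks (each >= 2 nuclei).
#' @param adjust multiple-testing method for \code{\link[stats]{p.adjust}}.
#' @return \code{data.frame} with \code{gene}, \code{lfc}, \code{t}, \code{p},
#'   \code{padj}, one row per gene.
#' @export
differentialExpression <- function(lognorm, groupA, groupB, adjust = "BH") {
  a <- as.matrix(lognorm[, groupA, drop = FALSE])
  b <- as.matrix(lognorm[, groupB, drop = FALSE])
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("both groups need >= 2 nuclei")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  t <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L)), 1)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  p[se2 == 0 & lfc == 0] <- 1
  data.frame(gene = rownames(lognorm), lfc = lfc, t = t, p = p,
             padj = stats::p.adjust(p, method = adjust), row.names = NULL)
}

#' Per-donor cluster proportions
#'
#' @param donor per-nucleus donor labels.
#' @param clusters per-nucleus cluster labels.
#' @return donor x cluster matrix of within-donor proportions (rows sum to 1);
#'   donors with zero nuclei are excluded with a warning.
#' @export
clusterProportions <- function(donor, clusters) {
  tab <- table(donor, clusters)
  n <- rowSums(tab)
  if (any(n == 0)) {
    warning("excluding donors with zero nuclei: ",
            paste(rownames(tab)[n == 0], collapse = ", "))
    tab <- tab[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  sweep(unclass(tab), 1L, n, "/")
}

#' Correlate cluster proportions with a donor covariate
#'
#' Spearman rank correlation of each cluster's per-donor proportion against a
#' donor-level covariate (e.g. age or a disease coding). Ties are handled by
#' average ranks; the p-value is exact for fewer than 10 donors without ties,
#' asymptotic otherwise (the \code{\link[stats]{cor.test}} defaults).
#'
#' @param proportions donor x cluster matrix from
#'   \code{\link{clusterProportions}}.
#' @param covariate numeric vector aligned with its rows.
#' @return \code{data.frame} with \code{cluster}, \code{rho}, \code{p}.
#' @export
correlateProportion <- function(proportions, covariate) {
  if (nrow(proportions) < 3L) stop("need at least 3 donors")
  res <- lapply(colnames(proportions), function(cl) {
    ct <- suppressWarnings(
      stats::cor.test(proportions[, cl], covariate, method = "spearman"))
    data.frame(cluster = cl, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
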