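#' Per-nucleus pathway activity by a weighted multivariate linear model
#'
#' Regresses each nucleus's expression profile jointly on all pathway weight
#' columns (plus an intercept) by ordinary least squares; the activity of a
#' pathway in a nucleus is the t-value of its coefficient. If the weight
#' columns are collinear a small ridge penalty is added with a message.
#'
#' @param expr genes x nuclei expression matrix (log-normalized or scaled);
#'   genes are matched to the weight table by name.
#' @param weights genes x pathways numeric matrix of signed weights (footprint
#'   genes; zero elsewhere).
#' @return pathways x nuclei matrix of activity t-values.
#' @export
mlmActivity <- function(expr, weights) {
  weights <- as.matrix(weights)
  common <- intersect(rownames(expr), rownames(weights))
  if (length(common) < ncol(weights) + 2L)
    stop("too few genes shared between expression and the weight table")
  Y <- as.matrix(expr[common, , drop = FALSE])
  W <- weights[common, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, W)
  XtX <- crossprod(X)
  Kinv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(Kinv) || rcond(XtX) < 1e-12) {
    lambda <- 1e-6 * mean(diag(XtX))
    message("collinear weight columns; ridge fallback with lambda = ",
            signif(lambda, 3))
    XtX <- XtX + diag(lambda, ncol(X))
    Kinv <- solve(XtX)
  }
  B <- Kinv %*% crossprod(X, Y)                    # (p+1) x nuclei
  R <- Y - X %*% B
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / dfree
  ## an exact fit (residual variance at numerical zero relative to the
  ## response scale) has coefficients at numerical zero -> activity 0, and
  ## genuinely nonzero coefficients -> unbounded activity
  exact <- sigma2 <= 1e-16 * (colMeans(Y^2) + 1e-300)
  se <- sqrt(outer(diag(Kinv), sigma2))
  tval <- B / se
  if (any(exact)) {
    scl <- sqrt(colMeans(Y^2))[exact]
    Bx <- B[, exact, drop = FALSE]
    tx <- ifelse(abs(Bx) <= 1e-8 * pmax(rep(scl, each = nrow(Bx)), 1e-300),
                 0, sign(Bx) * Inf)
    tval[, exact] <- tx
  }
  out <- tval[-1L, , drop = FALSE]
  dimnames(out) <- list(colnames(W), colnames(expr))
  out
}

#' Classify genes by weight / log-fold-change concordance
#'
#' For one pathway, pairs each gene's signed weight with its measured log fold
#' change: \code{consistent_up} when both are positive, \code{consistent_down}
#' when both are negative (both patterns read as pathway activation),
#' \code{discordant} when the signs oppose, and \code{neutral} when either is
#' zero. Genes missing from the weight table are omitted.
#'
#' @param de a \code{\link{differentialExpression}} result.
#' @param weights genes x pathways weight matrix.
#' @param pathway pathway (column) name.
#' @return \code{data.frame} with \code{gene}, \code{weight}, \code{lfc},
#'   \code{class} — the scatter table behind weight-vs-logFC plots.
#' @export
weightLfcConcordance <- function(de, weights, pathway) {
  weights <- as.matrix(weights)
  if (!pathway %in% colnames(weights)) stop("unknown pathway: ", pathway)
  w <- weights[, pathway]
  common <- intersect(de$gene, rownames(weights))
  d <- de[match(common, de$gene), ]
  wv <- w[common]
  cls <- ifelse(wv == 0 | d$lfc == 0, "neutral",
         ifelse(wv > 0 & d$lfc > 0, "consistent_up",
         ifelse(wv < 0 & d$lfc < 0, "consistent_down", "discordant")))
  data.frame(gene = common, weight = unname(wv), lfc = d$lfc, class = cls,
             row.names = NULL)
}

## Weighted Kolmogorov-Smirnov running sum for a ranked score vector (sorted
## decreasing) and hit indicator; returns the signed extremum.
.es_running <- function(scores_sorted, hit, p = 1) {
  nr <- sum(abs(scores_sorted[hit])^p)
  n_miss <- length(hit) - sum(hit)
  inc <- ifelse(hit,
                if (nr > 0) abs(scores_sorted)^p / nr else 0,
                -1 / n_miss)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov statistic on a ranked gene list: walking
#' down the ranking, hits increment the running sum by
#' \code{|score|^weight_exponent} (normalized by the set total) and misses
#' decrement it by \code{1/(N - n_set)}; the enrichment score ES is the signed
#' extremum. Significance uses gene-label permutation (the ranking comes from
#' an exported differential-expression table, so sample permutation is not
#' available): NES is ES divided by the mean |ES| of same-sign permutations,
#' and the p-value is the same-sign permutation tail with the +1 correction.
#'
#' @param scores named numeric ranking statistic (e.g. DE t-statistics); sorted
#'   decreasing internally.
#' @param gene_set character vector of member genes (non-empty after
#'   intersection with the ranking, and not the whole ranking).
#' @param weight_exponent exponent on |score| for hit increments (1 = classic
#'   weighted; 0 = unweighted KS).
#' @param n_perm number of gene-label permutations.
#' @param seed integer seed for the permutations.
#' @return List with \code{es}, \code{nes}, \code{p}, \code{n_set},
#'   \code{perm_es} (the permutation null, reused for pooled FDR).
#' @export
gseaPreranked <- function(scores, gene_set, weight_exponent = 1,
                          n_perm = 1000, seed = 1L) {
  if (!all(is.finite(scores))) stop("ranking scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  hit <- genes %in% gene_set
  n_set <- sum(hit)
  if (n_set == 0L) stop("gene set is empty after intersection with the ranking")
  if (n_set == length(genes)) stop("gene set equals the whole ranking")
  es <- .es_running(s, hit, weight_exponent)
  perm_es <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(genes))
      ph[sample(length(genes), n_set)] <- TRUE
      .es_running(s, ph, weight_exponent)
    }, numeric(1))
  })
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else sign(es) * Inf
  p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
  list(es = es, nes = nes, p = p, n_set = n_set, perm_es = perm_es)
}

#' GSEA over a collection of gene sets with pooled permutation FDR
#'
#' Runs \code{\link{gseaPreranked}} for each set and computes FDR q-values by
#' the permutation-pool procedure: permutation ES values are normalized per
#' set into a pooled NES null, and q(NES*) compares the sign-matched tail
#' fraction of the pooled null with the tail fraction of the observed NES
#' values. \code{fdr_method = "BH"} instead applies Benjamini-Hochberg to the
#' permutation p-values.
#'
#' @inheritParams gseaPreranked
#' @param gene_sets named list of gene sets.
#' @param fdr_method \code{"pool"} (permutation-pool NES FDR) or \code{"BH"}.
#' @return \code{data.frame} with \code{pathway}, \code{es}, \code{nes},
#'   \code{p}, \code{q}, \code{n_set}.
#' @export
gseaCollection <- function(scores, gene_sets, weight_exponent = 1,
                           n_perm = 1000, seed = 1L,
                           fdr_method = c("pool", "BH")) {
  fdr_method <- match.arg(fdr_method)
  res <- lapply(seq_along(gene_sets), function(i)
    gseaPreranked(scores, gene_sets[[i]], weight_exponent, n_perm,
                  seed = seed + i - 1L))
  nes <- vapply(res, `[[`, numeric(1), "nes")
  p <- vapply(res, `[[`, numeric(1), "p")
  if (fdr_method == "BH") {
    q <- stats::p.adjust(p, "BH")
  } else {
    pool <- unlist(lapply(res, function(r) {
      pos <- mean(r$perm_es[r$perm_es >= 0])
      neg <- mean(abs(r$perm_es[r$perm_es < 0]))
      ifelse(r$perm_es >= 0,
             r$perm_es / ifelse(is.finite(pos) && pos > 0, pos, 1),
             r$perm_es / ifelse(is.finite(neg) && neg > 0, neg, 1))
    }))
    q <- vapply(nes, function(v) {
      if (v >= 0) {
        num <- sum(pool >= v) / max(sum(pool >= 0), 1L)
        den <- sum(nes >= v) / max(sum(nes >= 0), 1L)
      } else {
        num <- sum(pool <= v) / max(sum(pool < 0), 1L)
        den <- sum(nes <= v) / max(sum(nes < 0), 1L)
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
  }
  data.frame(pathway = names(gene_sets), es = vapply(res, `[[`, numeric(1), "es"),
             nes = nes, p = p, q = q,
             n_set = vapply(res, `[[`, numeric(1), "n_set"), row.names = NULL)
}

#' Filter a NES table across contrasts
#'
#' Builds the pathway x contrast NES matrix, retaining only pathways whose FDR
#' q-value passes the threshold in at least \code{min_contrasts} contrasts.
#'
#' @param results named list of \code{\link{gseaCollection}} results, one per
#'   contrast.
#' @param fdr_threshold FDR cutoff.
#' @param min_contrasts minimum number of contrasts passing the cutoff.
#' @return pathway x contrast NES matrix.
#' @export
nesHeatmapTable <- function(results, fdr_threshold = 0.01, min_contrasts = 2) {
  if (length(results) < 2L) stop("need at least 2 contrasts")
  paths <- unique(unlist(lapply(results, `[[`, "pathway")))
  nes <- sapply(results, function(r) r$nes[match(paths, r$pathway)])
  qs <- sapply(results, function(r) r$q[match(paths, r$pathway)])
  rownames(nes) <- rownames(qs) <- paths
  keep <- rowSums(qs < fdr_threshold, na.rm = TRUE) >= min_contrasts
  nes[keep, , drop = FALSE]
}

#' Pathway overlap network
#'
#' Nodes are gene sets; edges are weighted by the Jaccard overlap of member
#' genes, thresholded; communities by greedy modularity.
#'
#' @param gene_sets named list of gene sets (>= 2).
#' @param edge_threshold minimum Jaccard overlap to keep an edge.
#' @return List with \code{graph} (igraph, weighted), \code{edges}
#'   (\code{data.frame} of retained pairs) and \code{communities} (named
#'   membership vector).
#' @export
pathwayOverlapNetwork <- function(gene_sets, edge_threshold = 0.01) {
  if (length(gene_sets) < 2L) stop("need at least 2 gene sets")
  nm <- names(gene_sets)
  pairs <- utils::combn(length(gene_sets), 2L)
  jac <- apply(pairs, 2L, function(ij) {
    a <- gene_sets[[ij[1]]]; b <- gene_sets[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  keep <- jac >= edge_threshold & jac > 0
  edges <- data.frame(from = nm[pairs[1L, keep]], to = nm[pairs[2L, keep]],
                      jaccard = jac[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nm))
  if (nrow(edges)) igraph::E(g)$weight <- edges$jaccard
  comm <- if (igraph::ecount(g) > 0) {
    igraph::membership(igraph::cluster_fast_greedy(g))
  } else stats::setNames(seq_along(nm), nm)
  list(graph = g, edges = edges,
       communities = stats::setNames(as.integer(comm), nm))
}

#' Restrict a weight table to each pathway's top footprint genes
#'
#' Keeps the \code{n} largest-|weight| genes per pathway and zeroes the rest,
#' mirroring the practice of exporting the top footprint genes from a
#' pathway-weight database.
#'
#' @param weights genes x pathways signed weight matrix.
#' @param n footprint size per pathway.
#' @return Weight matrix of the same shape with at most \code{n} nonzero
#'   entries per column.
#' @export
topFootprint <- function(weights, n = 1000) {
  w <- as.matrix(weights)
  for (j in seq_len(ncol(w))) {
    keep <- rank(-abs(w[, j]), ties.method = "first") <= n
    w[!keep, j] <- 0
  }
  w
}
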