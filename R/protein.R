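#' Normalize target antibody counts to histone H3
#'
#' Divides each target antibody's counts by the same nucleus's histone-H3
#' counts, controlling for antibody access to the nuclear compartment. Nuclei
#' with zero H3 counts cannot be normalized: they are dropped from the
#' returned matrix (with a message and an attribute recording them) but are
#' deliberately left untouched in the RNA data.
#'
#' @param x an \linkS4class{InciteExperiment}, or an antibodies x nuclei count
#'   matrix containing the normalizer row.
#' @param normalizer normalizer antibody name (matrix input only).
#' @return targets x nuclei matrix of H3 ratios (H3-zero nuclei removed), with
#'   attribute \code{"dropped"} naming them.
#' @examples
#' m <- rbind(NFkB = c(10, 0), TDP43 = c(5, 25), HistoneH3 = c(10, 50))
#' normalizeToH3(m, normalizer = "HistoneH3")
#' @export
setGeneric("normalizeToH3", function(x, normalizer = "HistoneH3")
  standardGeneric("normalizeToH3"))

#' @rdname normalizeToH3
#' @export
setMethod("normalizeToH3", "InciteExperiment", function(x, normalizer) {
  .h3_ratio(targetCounts(x), normalizerCounts(x))
})

#' @rdname normalizeToH3
#' @export
setMethod("normalizeToH3", "ANY", function(x, normalizer = "HistoneH3") {
  x <- as.matrix(x)
  if (!normalizer %in% rownames(x))
    stop("normalizer antibody '", normalizer, "' missing")
  .h3_ratio(x[setdiff(rownames(x), normalizer), , drop = FALSE],
            x[normalizer, ])
})

.h3_ratio <- function(targets, h3) {
  ok <- h3 > 0
  if (any(!ok))
    message(sum(!ok), " nuclei with zero H3 counts excluded from protein ",
            "analyses (retained for RNA)")
  out <- sweep(as.matrix(targets[, ok, drop = FALSE]), 2L, h3[ok], "/")
  attr(out, "dropped") <- colnames(targets)[!ok]
  out
}

#' Centered log-ratio transform of H3-normalized antibody levels
#'
#' The nCLR value of target j in nucleus i is the natural log of the
#' (pseudocounted) H3 ratio divided by the geometric mean across the target
#' panel of that nucleus:
#' \deqn{nCLR_{ij} = \ln\frac{x_{ij} + \epsilon}{(\prod_j (x_{ij} +
#'   \epsilon))^{1/n}}.}
#' The geometric mean runs over target antibodies only (the H3 normalizer and
#' hashtags are not measurements of nuclear signaling and are excluded).
#' By construction the nCLR values of each nucleus sum to zero, and the
#' transform is invariant to scaling a nucleus's whole antibody vector
#' (capture depth).
#'
#' @param h3_ratio targets x nuclei matrix from \code{\link{normalizeToH3}}.
#' @param pseudocount epsilon added before the log; the default 1e-6 guards
#'   zeros on the H3-ratio scale; 0 is permitted when all values are positive.
#' @return targets x nuclei nCLR matrix.
#' @examples
#' clrTransform(matrix(c(1, 2, 4), ncol = 1), pseudocount = 0)  # -ln2, 0, ln2
#' @export
clrTransform <- function(h3_ratio, pseudocount = 1e-6) {
  x <- as.matrix(h3_ratio)
  if (nrow(x) < 2L)
    stop("CLR is undefined for a single-target panel")
  lx <- log(x + pseudocount)
  if (any(!is.finite(lx)))
    stop("zero or negative values with pseudocount 0; use a positive pseudocount")
  sweep(lx, 2L, colMeans(lx))
}

#' Percentile ranks (0, 100]
#'
#' Average-rank percentiles over a population; the reference for all
#' stratification functions.
#'
#' @param v numeric vector.
#' @return percentiles in (0, 100].
#' @export
percentileRanks <- function(v) 100 * rank(v, ties.method = "average") / length(v)

#' Stratify nuclei by a protein's nCLR percentile
#'
#' Assigns named percentile bins over one protein's nCLR values, computed on
#' the supplied analysis population (typically all nuclei of one cell type,
#' pooled across donors). The default scheme follows the highest/high/low
#' reading: \code{top10} = (90, 100], \code{mid10_25} = (75, 90],
#' \code{bottom25} = [0, 25]; nuclei outside all bins are labeled
#' \code{"unassigned"}. Ties use average ranks; if a tie group straddles a bin
#' boundary it is resolved by stable ordinal assignment with a warning.
#'
#' @param nclr targets x nuclei nCLR matrix (or a numeric vector of one
#'   protein's values).
#' @param protein target name (ignored for vector input).
#' @param scheme named list of \code{c(lo, hi)} percentile bins, disjoint;
#'   bins are (lo, hi] except that lo = 0 is inclusive.
#' @return factor of bin labels per nucleus.
#' @export
stratifyByProtein <- function(nclr, protein = NULL,
                              scheme = list(top10 = c(90, 100),
                                            mid10_25 = c(75, 90),
                                            bottom25 = c(0, 25))) {
  v <- if (is.matrix(nclr)) {
    if (is.null(protein) || !protein %in% rownames(nclr))
      stop("protein not found in the nCLR panel")
    nclr[protein, ]
  } else as.numeric(nclr)
  if (length(v) == 0L) stop("empty analysis population")
  pct <- percentileRanks(v)
  if (anyDuplicated(v)) {
    pct_ord <- 100 * rank(v, ties.method = "first") / length(v)
    boundary <- setdiff(sort(unique(unlist(scheme))), c(0, 100))
    straddle <- vapply(split(seq_along(v), v), function(i)
      length(i) > 1L && any(vapply(boundary, function(b)
        min(pct_ord[i]) <= b && max(pct_ord[i]) > b, logical(1))), logical(1))
    if (any(straddle)) {
      warning("ties straddle a bin boundary; resolved by stable ordinal ranks")
      pct <- pct_ord
    }
  }
  lab <- rep("unassigned", length(v))
  for (nm in names(scheme)) {
    b <- scheme[[nm]]
    inbin <- pct <= b[2] & (pct > b[1] | b[1] == 0)
    lab[inbin] <- nm
  }
  factor(lab, levels = c(names(scheme), "unassigned"))
}

#' Quintile labels of a protein's nCLR values
#'
#' Five equal-frequency bins (1 = lowest, 5 = highest), invariant to monotone
#' transforms of the values; ties are broken by stable ordinal ranks.
#'
#' @inheritParams stratifyByProtein
#' @return integer quintile (1-5) per nucleus.
#' @export
quintileLabels <- function(nclr, protein = NULL) {
  v <- if (is.matrix(nclr)) {
    if (is.null(protein) || !protein %in% rownames(nclr))
      stop("protein not found in the nCLR panel")
    nclr[protein, ]
  } else as.numeric(nclr)
  if (length(v) == 0L) stop("empty analysis population")
  as.integer(ceiling(5 * rank(v, ties.method = "first") / length(v)))
}

#' Embedding density of a stratum
#'
#' Gaussian kernel density of the stratum's members evaluated at every nucleus
#' of the 2-D embedding, normalized to [0, 1] by its maximum
#' (\code{mode = "max"}) or first divided by the all-nuclei density and then
#' max-normalized (\code{mode = "relative"}).
#'
#' @param embedding nuclei x 2 coordinate matrix.
#' @param stratum logical mask or indices of the stratum members.
#' @param bandwidth kernel bandwidth; default is Scott's rule on the stratum
#'   (\code{n^(-1/6)} times the mean per-dimension sd), a fixed value may be
#'   supplied for reproducibility.
#' @param mode \code{"max"} or \code{"relative"}.
#' @return numeric density score in [0, 1] per nucleus.
#' @export
embeddingDensity <- function(embedding, stratum, bandwidth = NULL,
                             mode = c("max", "relative")) {
  mode <- match.arg(mode)
  emb <- as.matrix(embedding)
  idx <- if (is.logical(stratum)) which(stratum) else as.integer(stratum)
  if (length(idx) == 0L) stop("stratum of size 0")
  if (length(idx) == 1L)
    warning("stratum of size 1: density is a delta-like peak")
  if (is.null(bandwidth)) {
    s <- mean(apply(emb[idx, , drop = FALSE], 2L, stats::sd))
    if (!is.finite(s) || s == 0) s <- mean(apply(emb, 2L, stats::sd))
    bandwidth <- max(length(idx)^(-1 / 6) * s, .Machine$double.eps)
  }
  dens <- .kernel_sum(emb, emb[idx, , drop = FALSE], bandwidth)
  if (mode == "relative") {
    overall <- .kernel_sum(emb, emb, bandwidth)
    dens <- dens / overall
  }
  dens / max(dens)
}

.kernel_sum <- function(points, members, h) {
  sqp <- rowSums(points^2)
  sqm <- rowSums(members^2)
  d2 <- outer(sqp, sqm, "+") - 2 * tcrossprod(points, members)
  d2[d2 < 0] <- 0
  rowSums(exp(-d2 / (2 * h^2)))
}
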