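#' Demultiplex hashed nuclei by hashtag dominance
#'
#' A deliberately simple ratio demultiplexer (a documented stand-in for model
#' based demultiplexers such as DemuxEM): each nucleus is assigned its top
#' hashtag when the top count reaches \code{min_top_counts} and the
#' top/second-best ratio reaches \code{min_ratio}; otherwise it is labeled
#' \code{"ambiguous"} (ratio too low) or \code{"negative"} (top count too
#' low). Synthetic cohorts retain \code{true_hash} ground truth so its
#' accuracy can be measured.
#'
#' @param x an \linkS4class{InciteExperiment}, or a hashtags x nuclei count
#'   matrix.
#' @param min_top_counts minimum counts of the winning hashtag.
#' @param min_ratio minimum top/second-best count ratio.
#' @return Character vector (one label per nucleus): a hashtag name,
#'   \code{"ambiguous"} or \code{"negative"}.
#' @export
demultiplexHashes <- function(x, min_top_counts = 20, min_ratio = 3) {
  h <- if (is(x, "InciteExperiment")) hashtagCounts(x) else x
  if (nrow(h) < 2L)
    stop("demultiplexing requires at least 2 hashtag antibodies")
  top_i <- apply(h, 2L, which.max)
  top <- h[cbind(top_i, seq_len(ncol(h)))]
  second <- vapply(seq_len(ncol(h)), function(j) max(h[-top_i[j], j]),
                   numeric(1))
  ratio <- top / pmax(second, 1)
  lab <- rownames(h)[top_i]
  lab[!(ratio >= min_ratio) | top == second] <- "ambiguous"
  lab[top < min_top_counts] <- "negative"
  stats::setNames(lab, colnames(h))
}

#' Filter nuclei by quality-control rules
#'
#' A nucleus is kept iff it detects at least
#' \code{min_genes_per_nucleus} genes AND its mitochondrial count fraction is
#' at most \code{max_mito_fraction} (strictly more is excluded) AND its summed
#' hashtag counts do not exceed \code{max_hashtag_counts} AND its raw
#' anti-TDP-43 counts do not exceed \code{max_tdp43_counts}. Removal counts
#' are reported per rule; a nucleus may count toward several. If the TDP-43
#' antibody is absent that rule is skipped with a warning. Filtering is
#' idempotent.
#'
#' @param x an \linkS4class{InciteExperiment}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return List with \code{x} (the filtered experiment), \code{kept} (logical
#'   over input nuclei) and \code{removed} (named per-rule removal counts).
#' @export
filterNuclei <- function(x, thresholds = qcThresholds()) {
  counts <- assay(x, "counts")
  genes_detected <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thresholds@mito_prefix)
  total <- Matrix::colSums(counts)
  mito_frac <- ifelse(total > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1), 0)
  hash_sum <- Matrix::colSums(hashtagCounts(x))

  fail_genes <- genes_detected < thresholds@min_genes_per_nucleus
  fail_mito <- mito_frac > thresholds@max_mito_fraction
  fail_hash <- hash_sum > thresholds@max_hashtag_counts
  adt <- adtCounts(x)
  if (thresholds@tdp43_antibody %in% rownames(adt)) {
    fail_tdp <- adt[thresholds@tdp43_antibody, ] > thresholds@max_tdp43_counts
  } else {
    warning("TDP-43 antibody '", thresholds@tdp43_antibody,
            "' not in panel; ceiling rule skipped")
    fail_tdp <- rep(FALSE, ncol(x))
  }
  kept <- !(fail_genes | fail_mito | fail_hash | fail_tdp)
  removed <- c(min_genes = sum(fail_genes), mito_fraction = sum(fail_mito),
               hashtag_counts = sum(fail_hash), tdp43_counts = sum(fail_tdp))
  list(x = x[, kept], kept = unname(kept), removed = removed)
}

#' Filter genes by detection frequency
#'
#' Keeps genes detected (count > 0) in at least
#' \code{min_nuclei_per_gene} nuclei. Apply after nucleus filtering.
#'
#' @inheritParams filterNuclei
#' @return The filtered \linkS4class{InciteExperiment}.
#' @export
filterGenes <- function(x, thresholds = qcThresholds()) {
  keep <- Matrix::rowSums(assay(x, "counts") > 0) >= thresholds@min_nuclei_per_gene
  x[keep, ]
}

#' Remove doublets
#'
#' By default honors the synthetic ground-truth flag (\code{true_doublet} in
#' \code{colData}). \code{method = "heuristic"} instead removes nuclei whose
#' hashtag assignment is ambiguous AND whose total RNA counts exceed the 99th
#' percentile — explicit plumbing, not equivalent to a dedicated doublet
#' caller.
#'
#' @param x an \linkS4class{InciteExperiment}.
#' @param method \code{"truth"} or \code{"heuristic"}.
#' @param demux demultiplexing labels (from \code{\link{demultiplexHashes}});
#'   computed if missing and needed.
#' @return The experiment with doublets removed.
#' @export
removeDoublets <- function(x, method = c("truth", "heuristic"), demux = NULL) {
  method <- match.arg(method)
  if (method == "truth") {
    if (is.null(x$true_doublet))
      stop("no true_doublet ground truth; use method='heuristic'")
    return(x[, !x$true_doublet])
  }
  if (is.null(demux)) demux <- demultiplexHashes(x)
  total <- Matrix::colSums(assay(x, "counts"))
  sus <- demux == "ambiguous" & total > stats::quantile(total, 0.99)
  x[, !sus]
}
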