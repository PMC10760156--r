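#' Write a cohort to a 10x-style directory
#'
#' Emits \code{matrix.mtx} (Matrix Market triplet, 1-based indices, RNA and
#' antibody-capture rows stacked), \code{features.tsv} (id, name,
#' feature_type \code{"Gene Expression"}/\code{"Antibody Capture"}, antibody
#' role), \code{barcodes.tsv}, \code{metadata.csv} (per-nucleus colData) and,
#' for synthetic cohorts, \code{ground_truth.json} with the gene programs.
#'
#' @param x an \linkS4class{InciteExperiment}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- methods::as(assay(x, "counts"), "CsparseMatrix")
  adt <- methods::as(Matrix::Matrix(adtCounts(x), sparse = TRUE),
                     "CsparseMatrix")
  full <- rbind(counts, adt)
  Matrix::writeMM(full, file.path(dir, "matrix.mtx"))
  roles <- antibodyRoles(x)
  feats <- data.frame(
    id = rownames(full),
    name = rownames(full),
    feature_type = c(rep("Gene Expression", nrow(counts)),
                     rep("Antibody Capture", nrow(adt))),
    role = c(rep("", nrow(counts)), unname(roles[rownames(adt)])))
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  barcodes <- if (is.null(colnames(full))) character(0) else colnames(full)
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(colData(x))
  if (ncol(cd) > 0)
    utils::write.csv(cd, file.path(dir, "metadata.csv"), row.names = FALSE)
  gp <- metadata(x)$gene_programs
  if (!is.null(gp))
    jsonlite::write_json(gp, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a cohort from a 10x-style directory
#'
#' Inverse of \code{\link{writeCohort}}: a lossless round trip of the integer
#' counts, feature and barcode names, antibody roles and per-nucleus metadata.
#'
#' @param dir directory written by \code{\link{writeCohort}} (or following the
#'   same dialect).
#' @return An \linkS4class{InciteExperiment}.
#' @export
readCohort <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, quote = "",
                             colClasses = "character",
                             col.names = c("id", "name", "feature_type",
                                           "role")[1:4])
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop("dimension mismatch between matrix.mtx and features/barcodes tables")
  dimnames(m) <- list(feats$id, barcodes)
  is_gex <- feats$feature_type == "Gene Expression"
  counts <- m[is_gex, , drop = FALSE]
  adt <- as.matrix(m[!is_gex, , drop = FALSE])
  roles <- stats::setNames(feats$role[!is_gex], feats$id[!is_gex])
  cd <- NULL
  meta_path <- file.path(dir, "metadata.csv")
  if (file.exists(meta_path) && length(barcodes)) {
    df <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if ("disease_state" %in% names(df))
      df$disease_state <- factor(df$disease_state, levels = DISEASE_GROUPS)
    cd <- DataFrame(df, row.names = barcodes)
  }
  meta <- list()
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    meta$gene_programs <- lapply(jsonlite::read_json(gt_path),
                                 function(g) unlist(g, use.names = FALSE))
  InciteExperiment(counts, adt, roles, colData = cd, metadata = meta)
}

#' Read and write GMT gene-set collections
#'
#' Standard tab-separated GMT: one set per line, \code{name<TAB>description}
#' followed by member genes.
#'
#' @param path file path.
#' @return \code{readGMT} returns a named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- mapply(function(nm, genes, d)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}
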