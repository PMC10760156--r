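#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays rowData colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment altExp altExp<- altExpNames
#'   reducedDim reducedDim<- reducedDimNames
NULL

DISEASE_GROUPS <- c("young_ctrl", "old_ctrl", "AD", "ALS", "FTD")
CONTROL_GROUPS <- c("young_ctrl", "old_ctrl")

#' Configuration of a synthetic multiplexed inCITE-seq cohort
#'
#' Holds every knob of the cohort generator: cohort design (donors per disease
#' group, nuclei per donor, 10x well batching), cell-type composition, RNA
#' count model, antibody panel, and the latent nuclear-protein model including
#' the NF-kB/TDP-43 coupling and its disease-specific decoupling.
#'
#' The latent protein model works on the natural-log scale. Nuclear NF-kB is
#' drawn per cell type, TDP-43 follows
#' \code{intercept + coupling_slope * NFkB + noise}, and beta-Catenin closes
#' the three-target log-ratio composition (see the methods vignette). In
#' nuclei from disease donors whose NF-kB exceeds the
#' \code{decoupling_percentile} of that donor's (cell-type matched)
#' distribution, TDP-43 is shifted by \code{decoupling_delta} (in nCLR units;
#' always <= 0).
#'
#' @slot n_donors_per_group named integer, donors per disease group.
#' @slot nuclei_per_donor integer, nuclei generated per donor (pre-doublets).
#' @slot celltype_fractions named numeric summing to 1.
#' @slot n_genes integer number of genes.
#' @slot mito_gene_fraction fraction of genes flagged mitochondrial.
#' @slot mito_expr_fraction generative mitochondrial share of counts.
#' @slot doublet_rate fraction of barcodes that are doublets, in [0, 0.5).
#' @slot hash_signal_to_noise dominant-hashtag counts relative to ambient.
#' @slot hash_ambient mean ambient hashtag counts.
#' @slot protein_panel character, target antibody names (NF-kB first by
#'   convention, then TDP-43, then beta-Catenin).
#' @slot normalizer name of the normalizer antibody (histone H3).
#' @slot coupling_slope healthy TDP-43 per unit NF-kB on the log scale.
#' @slot coupling_noise_sd residual sd of TDP-43 about the coupling line.
#' @slot nfkb_sd sd of the latent NF-kB level within a cell type.
#' @slot closure_noise_sd sd of the compositional closure residual.
#' @slot decoupling_delta TDP-43 nCLR shift in decoupled disease nuclei (<= 0).
#' @slot decoupling_percentile NF-kB percentile above which disease nuclei
#'   decouple, in (0, 100).
#' @slot disease_protein_shift named numeric over the target panel, summing to
#'   0: composition shift applied to all disease-donor endothelial nuclei.
#' @slot target_program_effect log-fold effect on NF-kB target genes in
#'   decoupled (TDP-43-low) nuclei.
#' @slot wnt_program_effect log-fold effect on Wnt target genes in
#'   disease-donor endothelial nuclei.
#' @slot dam_program_effect log-fold effect on DAM markers (and minus it on
#'   homeostatic markers) in DAM-state microglia.
#' @slot dispersion negative-binomial dispersion of RNA counts (size = 1/disp).
#' @slot mean_counts_per_nucleus expected RNA library size.
#' @slot adt_base expected antibody counts at latent level 0.
#' @slot seed integer seed; fixed seed gives byte-identical cohorts.
#' @export
setClass("CohortConfig", representation(
  n_donors_per_group = "integer",
  nuclei_per_donor = "integer",
  celltype_fractions = "numeric",
  n_genes = "integer",
  mito_gene_fraction = "numeric",
  mito_expr_fraction = "numeric",
  doublet_rate = "numeric",
  hash_signal_to_noise = "numeric",
  hash_ambient = "numeric",
  protein_panel = "character",
  normalizer = "character",
  coupling_slope = "numeric",
  coupling_noise_sd = "numeric",
  nfkb_sd = "numeric",
  closure_noise_sd = "numeric",
  decoupling_delta = "numeric",
  decoupling_percentile = "numeric",
  disease_protein_shift = "numeric",
  target_program_effect = "numeric",
  wnt_program_effect = "numeric",
  dam_program_effect = "numeric",
  dispersion = "numeric",
  mean_counts_per_nucleus = "numeric",
  adt_base = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!identical(sort(names(object@n_donors_per_group)), sort(DISEASE_GROUPS)))
    msg <- c(msg, "n_donors_per_group must be named by the five disease groups")
  if (any(object@n_donors_per_group < 1L) || object@nuclei_per_donor < 1L ||
      object@n_genes < 10L)
    msg <- c(msg, "all count parameters must be positive")
  if (abs(sum(object@celltype_fractions) - 1) > 1e-9)
    msg <- c(msg, "celltype_fractions must sum to 1 (tolerance 1e-9)")
  if (any(object@celltype_fractions < 0))
    msg <- c(msg, "celltype_fractions must be nonnegative")
  if (object@doublet_rate < 0 || object@doublet_rate >= 0.5)
    msg <- c(msg, "doublet_rate must be in [0, 0.5)")
  if (object@decoupling_delta > 0)
    msg <- c(msg, "decoupling_delta must be <= 0")
  if (object@decoupling_percentile <= 0 || object@decoupling_percentile >= 100)
    msg <- c(msg, "decoupling_percentile must be in (0, 100)")
  if (object@hash_signal_to_noise <= 0)
    msg <- c(msg, "hash_signal_to_noise must be positive")
  if (length(object@protein_panel) < 2L)
    msg <- c(msg, "protein_panel needs >= 2 target antibodies")
  if (!identical(sort(names(object@disease_protein_shift)),
                 sort(object@protein_panel)))
    msg <- c(msg, "disease_protein_shift must be named by the target panel")
  if (abs(sum(object@disease_protein_shift)) > 1e-9)
    msg <- c(msg, "disease_protein_shift must sum to 0 (a composition shift)")
  if (length(msg)) msg else TRUE
})

#' Create a cohort configuration
#'
#' Defaults emulate the study conditions of the analysed cohort: five donor
#' groups (young/old controls, AD, ALS, FTD), 10x wells pooling two controls
#' and two disease donors, ~50% endothelial and ~25% microglial nuclei after
#' sorting, a three-target nuclear antibody panel (p65/NF-kB, TDP-43,
#' beta-Catenin) plus a histone-H3 normalizer and per-donor hashtags, and a
#' healthy NF-kB/TDP-43 coupling (slope 0.8 on the log scale) that decouples
#' (delta = -0.5 nCLR units) in disease nuclei above the 75th NF-kB
#' percentile.
#'
#' @param n_donors_per_group integer, donors per group (scalar or named by
#'   group).
#' @param nuclei_per_donor nuclei per donor before doublet injection.
#' @param celltype_fractions named fractions summing to 1.
#' @param n_genes number of genes.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial ("MT-").
#' @param mito_expr_fraction generative mitochondrial count share per nucleus.
#' @param doublet_rate doublet fraction in [0, 0.5).
#' @param hash_signal_to_noise dominant hashtag counts / ambient mean.
#' @param hash_ambient ambient hashtag count mean.
#' @param protein_panel target antibody names.
#' @param normalizer normalizer antibody name.
#' @param coupling_slope,coupling_noise_sd,nfkb_sd,closure_noise_sd latent
#'   protein model parameters (natural-log scale).
#' @param decoupling_delta TDP-43 nCLR shift in decoupled nuclei (<= 0).
#' @param decoupling_percentile NF-kB percentile for decoupling, in (0, 100).
#' @param disease_protein_shift named sum-zero composition shift for disease
#'   endothelial nuclei; set to zeros to isolate the decoupling knob.
#' @param target_program_effect,wnt_program_effect,dam_program_effect log-fold
#'   gene-program effects.
#' @param dispersion RNA negative-binomial dispersion.
#' @param mean_counts_per_nucleus expected RNA library size.
#' @param adt_base expected antibody counts at latent 0.
#' @param seed integer seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(n_donors_per_group = 2, nuclei_per_donor = 50)
#' @export
cohortConfig <- function(n_donors_per_group = 4L,
                         nuclei_per_donor = 250L,
                         celltype_fractions = c(EC = 0.50, microglia = 0.25,
                                                neuron = 0.15, other = 0.10),
                         n_genes = 1000L,
                         mito_gene_fraction = 0.03,
                         mito_expr_fraction = 0.03,
                         doublet_rate = 0.05,
                         hash_signal_to_noise = 20,
                         hash_ambient = 10,
                         protein_panel = c("NFkB", "TDP43", "bCatenin"),
                         normalizer = "HistoneH3",
                         coupling_slope = 0.8,
                         coupling_noise_sd = 0.25,
                         nfkb_sd = 0.9,
                         closure_noise_sd = 0.15,
                         decoupling_delta = -0.5,
                         decoupling_percentile = 75,
                         disease_protein_shift = c(NFkB = 0.55, TDP43 = -0.20,
                                                   bCatenin = -0.35),
                         target_program_effect = 1.0,
                         wnt_program_effect = -0.8,
                         dam_program_effect = 1.0,
                         dispersion = 0.5,
                         mean_counts_per_nucleus = 2500,
                         adt_base = 500,
                         seed = 1L) {
  if (length(n_donors_per_group) == 1L && is.null(names(n_donors_per_group)))
    n_donors_per_group <- stats::setNames(rep(as.integer(n_donors_per_group),
                                              5L), DISEASE_GROUPS)
  storage.mode(n_donors_per_group) <- "integer"  # keep names
  new("CohortConfig",
      n_donors_per_group = n_donors_per_group,
      nuclei_per_donor = as.integer(nuclei_per_donor),
      celltype_fractions = celltype_fractions,
      n_genes = as.integer(n_genes),
      mito_gene_fraction = mito_gene_fraction,
      mito_expr_fraction = mito_expr_fraction,
      doublet_rate = doublet_rate,
      hash_signal_to_noise = hash_signal_to_noise,
      hash_ambient = hash_ambient,
      protein_panel = protein_panel,
      normalizer = normalizer,
      coupling_slope = coupling_slope,
      coupling_noise_sd = coupling_noise_sd,
      nfkb_sd = nfkb_sd,
      closure_noise_sd = closure_noise_sd,
      decoupling_delta = decoupling_delta,
      decoupling_percentile = decoupling_percentile,
      disease_protein_shift = disease_protein_shift,
      target_program_effect = target_program_effect,
      wnt_program_effect = wnt_program_effect,
      dam_program_effect = dam_program_effect,
      dispersion = dispersion,
      mean_counts_per_nucleus = mean_counts_per_nucleus,
      adt_base = adt_base,
      seed = as.integer(seed))
}

#' Quality-control thresholds for nuclei and genes
#'
#' Defaults are the filters applied to the cohort: nuclei must express at
#' least 50 genes; nuclei with more than 5% mitochondrial counts, summed
#' hashtag counts exceeding 4000, or anti-TDP-43 antibody counts above 3000
#' are excluded; genes must be detected in at least 5 nuclei. Boundary
#' semantics are read literally: "at least 50" is inclusive, the other three
#' are strict exceedances.
#'
#' @slot min_genes_per_nucleus inclusive lower bound on detected genes.
#' @slot min_nuclei_per_gene inclusive lower bound on nuclei detecting a gene.
#' @slot max_mito_fraction nuclei strictly above this fraction are removed.
#' @slot max_hashtag_counts nuclei with summed hashtag counts strictly above
#'   this are removed.
#' @slot max_tdp43_counts nuclei with anti-TDP-43 counts strictly above this
#'   are removed.
#' @slot mito_prefix gene-name prefix identifying mitochondrial genes.
#' @slot tdp43_antibody name of the TDP-43 antibody in the panel.
#' @export
setClass("QCThresholds", representation(
  min_genes_per_nucleus = "numeric",
  min_nuclei_per_gene = "numeric",
  max_mito_fraction = "numeric",
  max_hashtag_counts = "numeric",
  max_tdp43_counts = "numeric",
  mito_prefix = "character",
  tdp43_antibody = "character"
))

setValidity("QCThresholds", function(object) {
  msg <- character()
  vals <- c(object@min_genes_per_nucleus, object@min_nuclei_per_gene,
            object@max_hashtag_counts, object@max_tdp43_counts)
  if (any(vals < 0)) msg <- c(msg, "all thresholds must be >= 0")
  if (object@max_mito_fraction < 0 || object@max_mito_fraction > 1)
    msg <- c(msg, "max_mito_fraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param min_genes_per_nucleus,min_nuclei_per_gene,max_mito_fraction,max_hashtag_counts,max_tdp43_counts
#'   thresholds (see slots).
#' @param mito_prefix,tdp43_antibody feature-name conventions.
#' @return A validated \linkS4class{QCThresholds}.
#' @rdname QCThresholds-class
#' @examples
#' qcThresholds()
#' @export
qcThresholds <- function(min_genes_per_nucleus = 50,
                         min_nuclei_per_gene = 5,
                         max_mito_fraction = 0.05,
                         max_hashtag_counts = 4000,
                         max_tdp43_counts = 3000,
                         mito_prefix = "MT-",
                         tdp43_antibody = "TDP43") {
  new("QCThresholds",
      min_genes_per_nucleus = min_genes_per_nucleus,
      min_nuclei_per_gene = min_nuclei_per_gene,
      max_mito_fraction = max_mito_fraction,
      max_hashtag_counts = max_hashtag_counts,
      max_tdp43_counts = max_tdp43_counts,
      mito_prefix = mito_prefix,
      tdp43_antibody = tdp43_antibody)
}

#' Container for joint RNA and nuclear antibody-capture data
#'
#' An \code{InciteExperiment} is a \linkS4class{SingleCellExperiment} whose
#' main assay holds nuclei x gene RNA counts (stored genes x nuclei, the
#' Bioconductor convention) and whose \code{"AntibodyCapture"} alternative
#' experiment holds the antibody panel, with a \code{role} column in its
#' \code{rowData} classifying each antibody as \code{"target"},
#' \code{"normalizer"} (histone H3) or \code{"hashtag"}.
#'
#' @export
setClass("InciteExperiment", contains = "SingleCellExperiment")

setValidity("InciteExperiment", function(object) {
  msg <- character()
  ## reach through the internal colData rather than altExp(): the public
  ## accessor triggers updateObject -> validObject on a partially built
  ## object, which would recurse back into this validity method
  alts <- object@int_colData[["altExps"]]
  if (is.null(alts) || !"AntibodyCapture" %in% names(alts))
    return("missing 'AntibodyCapture' alternative experiment")
  roles <- rowData(methods::slot(alts[["AntibodyCapture"]], "se"))$role
  if (is.null(roles))
    return("antibody rowData must carry a 'role' column")
  if (sum(roles == "normalizer") != 1L)
    msg <- c(msg, "exactly one normalizer antibody is required")
  if (sum(roles == "target") < 1L)
    msg <- c(msg, "at least one target antibody is required")
  if (sum(roles == "hashtag") < 1L)
    msg <- c(msg, "at least one hashtag antibody is required")
  if (!all(roles %in% c("target", "normalizer", "hashtag")))
    msg <- c(msg, "roles must be target/normalizer/hashtag")
  if (length(msg)) msg else TRUE
})

#' Construct an InciteExperiment
#'
#' @param counts genes x nuclei integer matrix (sparse or dense) of RNA counts.
#' @param adt antibodies x nuclei integer matrix of antibody-capture counts.
#' @param roles named character vector mapping each antibody to
#'   \code{"target"}, \code{"normalizer"} or \code{"hashtag"}; names must match
#'   \code{rownames(adt)}.
#' @param colData per-nucleus metadata (coerced to \code{DataFrame}).
#' @param metadata list of cohort-level metadata (e.g. ground-truth gene
#'   programs).
#' @return An \linkS4class{InciteExperiment}.
#' @examples
#' counts <- matrix(rpois(60, 2), nrow = 6,
#'                  dimnames = list(paste0("G", 1:6), paste0("N", 1:10)))
#' adt <- matrix(rpois(40, 20), nrow = 4,
#'               dimnames = list(c("NFkB", "TDP43", "HistoneH3", "Hash1"),
#'                               paste0("N", 1:10)))
#' roles <- c(NFkB = "target", TDP43 = "target",
#'            HistoneH3 = "normalizer", Hash1 = "hashtag")
#' ie <- InciteExperiment(counts, adt, roles)
#' @export
InciteExperiment <- function(counts, adt, roles, colData = NULL,
                             metadata = list()) {
  if (ncol(counts) != ncol(adt))
    stop("RNA and antibody matrices must share nuclei (columns)")
  if (is.null(rownames(adt)) || !all(rownames(adt) %in% names(roles)))
    stop("every antibody needs a role")
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(counts))
  adt_se <- SingleCellExperiment(
    assays = list(counts = adt),
    rowData = DataFrame(role = unname(roles[rownames(adt)]),
                        row.names = rownames(adt)))
  sce <- SingleCellExperiment(assays = list(counts = counts),
                              colData = colData, metadata = metadata)
  altExp(sce, "AntibodyCapture") <- adt_se
  new("InciteExperiment", sce)
}

setMethod("show", "InciteExperiment", function(object) {
  cat("InciteExperiment:", nrow(object), "genes x", ncol(object), "nuclei\n")
  r <- antibodyRoles(object)
  cat("  antibody panel:", sum(r == "target"), "targets,",
      "normalizer", sQuote(normalizerName(object)), ",",
      sum(r == "hashtag"), "hashtags\n")
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
  if (length(reducedDimNames(object)))
    cat("  reducedDims:", paste(reducedDimNames(object), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CohortConfig", function(object) {
  n_nuc <- sum(object@n_donors_per_group) * object@nuclei_per_donor
  cat("CohortConfig:", sum(object@n_donors_per_group), "donors,",
      n_nuc, "nuclei,", object@n_genes, "genes\n")
  cat("  panel:", paste(object@protein_panel, collapse = ", "),
      "| normalizer:", object@normalizer, "\n")
  cat("  coupling slope:", object@coupling_slope,
      "| decoupling delta:", object@decoupling_delta,
      "above the", object@decoupling_percentile, "th percentile\n")
  invisible(NULL)
})
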