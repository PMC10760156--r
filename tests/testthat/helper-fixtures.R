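suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
  library(Matrix)
})

## Hand-written 10-nucleus QC fixture. Three nuclei each violate exactly one
## rule (N2: 49 detected genes; N5: mito fraction 4/60 > 5%; N7: TDP-43 counts
## 3001 > 3000); N3/N4/N6/N8 sit exactly on the inclusive side of a boundary.
## Expected survivors: N1, N3, N4, N6, N8, N9, N10 (7 nuclei).
qc_fixture <- function() {
  genes <- c(paste0("G", 1:58), "MT-1", "MT-2")
  nuclei <- paste0("N", 1:10)
  counts <- matrix(0, 60, 10, dimnames = list(genes, nuclei))
  counts[1:50, ] <- 1                       # baseline: 50 detected genes
  counts["MT-1", "N1"] <- 2                 # mito 2/52
  counts[1:49, "N2"] <- 1; counts[50, "N2"] <- 0   # 49 genes -> fails
  counts[51:57, "N4"] <- 1; counts["MT-1", "N4"] <- 3  # mito 3/60 = 0.05 kept
  counts[51:56, "N5"] <- 1
  counts["MT-1", "N5"] <- 2; counts["MT-2", "N5"] <- 2 # mito 4/60 > 0.05
  adt <- rbind(
    NFkB = rep(10, 10),
    TDP43 = c(5, 5, 5, 5, 5, 5, 3001, 3000, 5, 5),
    HistoneH3 = rep(10, 10),
    Hash1 = c(rep(30, 5), 3000, rep(30, 4)),
    Hash2 = c(rep(2, 5), 1000, rep(2, 4)))
  colnames(adt) <- nuclei
  roles <- c(NFkB = "target", TDP43 = "target", HistoneH3 = "normalizer",
             Hash1 = "hashtag", Hash2 = "hashtag")
  InciteExperiment(counts, adt, roles)
}

qc_fixture_survivors <- paste0("N", c(1, 3, 4, 6, 8, 9, 10))

## small cached cohorts so multiple test files can share one generation
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(name, config) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, generateCohort(config), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

small_cohort <- function() cached_cohort("small", cohortConfig(
  nuclei_per_donor = 100L, seed = 11L))          # 2,000 nuclei

recovery_config <- function(delta, seed, nuclei_per_donor = 250L)
  cohortConfig(nuclei_per_donor = nuclei_per_donor, decoupling_delta = delta,
               doublet_rate = 0,
               disease_protein_shift = c(NFkB = 0, TDP43 = 0, bCatenin = 0),
               seed = seed)

## independent brute-force GSEA running sum (plain loop, kept separate from
## the package implementation)
brute_es <- function(scores, gene_set, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  nr <- sum(abs(s[hit])^p)
  n_miss <- sum(!hit)
  best <- 0; run <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) {
      if (nr > 0) abs(s[i])^p / nr else 0
    } else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

is_ctrl_state <- function(x) x %in% c("young_ctrl", "old_ctrl")
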