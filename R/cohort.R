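#' Generate a synthetic multiplexed inCITE-seq cohort
#'
#' Draws a full multiplexed cohort with the statistical structure the analysis
#' pipeline assumes: donors in five disease groups pooled into 10x wells and
#' tagged by nuclear-pore hashtags; cell types at the sorted composition
#' (~50\% endothelial, ~25\% microglial); negative-binomial RNA counts with
#' cell-type marker programs, mitochondrial genes, Wnt-target, NF-kB-target,
#' DAM and homeostatic programs; and Poisson antibody-capture counts around a
#' latent nuclear-protein model in which TDP-43 is coupled to NF-kB in health
#' and decouples (drops by \code{decoupling_delta}) in disease nuclei above
#' the configured NF-kB percentile.
#'
#' The three target-antibody latents are drawn as a zero-sum log-ratio
#' composition (NF-kB per cell type, TDP-43 on the coupling line,
#' beta-Catenin closing the composition), so the nCLR transform downstream
#' recovers them directly; common-mode nuclear abundance is carried by the
#' per-nucleus capture depth and removed by H3 normalization. See the methods
#' vignette for the rationale.
#'
#' Ground truth is stored in \code{colData} (\code{true_celltype},
#' \code{true_hash}, \code{true_doublet}, \code{true_decoupled},
#' \code{true_nfkb_level}, \code{true_tdp43_level}, \code{true_bcat_level},
#' \code{true_disease_program}) and the gene programs in
#' \code{metadata(x)$gene_programs}.
#'
#' @param config a \code{\link{cohortConfig}}; the same config and seed give
#'   byte-identical cohorts.
#' @return An \linkS4class{InciteExperiment} (doublets already injected at
#'   \code{config@doublet_rate} and flagged, not removed).
#' @examples
#' ie <- generateCohort(cohortConfig(n_donors_per_group = 1,
#'                                   nuclei_per_donor = 40, n_genes = 400))
#' table(ie$true_celltype)
#' @export
generateCohort <- function(config) {
  validObject(config)
  if (length(config@protein_panel) != 3L)
    stop("the generator models a three-target panel (NF-kB, TDP-43, ",
         "beta-Catenin roles, in that order)")
  if (config@n_genes < 400L)
    stop("n_genes must be >= 400 to host the ground-truth gene programs")
  withr::with_seed(config@seed, {
    out <- .generate_singlets(config)
    if (config@doublet_rate > 0)
      out <- .inject_doublets_impl(out, config@doublet_rate)
    out
  })
}

.generate_singlets <- function(config) {
  groups <- DISEASE_GROUPS
  n_don <- config@n_donors_per_group[groups]
  donor_group <- rep(groups, n_don)
  donor_id <- paste0("D", sprintf("%02d", seq_along(donor_group)), "_",
                     donor_group)
  donor_age <- ifelse(donor_group == "young_ctrl",
                      sample(15:29, length(donor_group), replace = TRUE),
                      sample(67:95, length(donor_group), replace = TRUE))

  ## pool donors into 10x wells of up to 5, interleaving groups so each well
  ## mixes controls and disease states; hashtag index = slot within the well
  ord <- order(ave(seq_along(donor_group), donor_group, FUN = seq_along),
               match(donor_group, groups))
  batch_of <- integer(length(donor_group))
  hash_of <- integer(length(donor_group))
  batch_of[ord] <- (seq_along(ord) - 1L) %/% 5L + 1L
  hash_of[ord] <- (seq_along(ord) - 1L) %% 5L + 1L
  n_hash <- max(hash_of)

  n_per <- config@nuclei_per_donor
  di <- rep(seq_along(donor_id), each = n_per)
  n <- length(di)
  celltypes <- names(config@celltype_fractions)
  ct <- sample(celltypes, n, replace = TRUE, prob = config@celltype_fractions)
  disease <- !(donor_group[di] %in% CONTROL_GROUPS)

  ## ---- gene universe and ground-truth programs ----
  n_mito <- max(1L, round(config@mito_gene_fraction * config@n_genes))
  mito_genes <- paste0("MT-G", sprintf("%03d", seq_len(n_mito)))
  n_rest <- config@n_genes - n_mito
  rest <- paste0("G", sprintf("%04d", seq_len(n_rest)))
  sizes <- c(EC_markers = 40L, microglia_markers = 40L, neuron_markers = 40L,
             other_markers = 40L, nfkb_targets = 50L, wnt_targets = 50L,
             dam_markers = 30L, homeostatic_markers = 30L)
  idx <- utils::relist(seq_len(sum(sizes)), lapply(sizes, seq_len))
  programs <- lapply(idx, function(i) rest[i])
  gene_names <- c(mito_genes, rest)

  base <- stats::rlnorm(config@n_genes, meanlog = 0, sdlog = 1)
  names(base) <- gene_names
  ## fix the generative mitochondrial share of counts
  base[mito_genes] <- base[mito_genes] *
    (config@mito_expr_fraction / sum(base[mito_genes])) *
    (sum(base[rest]) / (1 - config@mito_expr_fraction))
  ## baseline cell-type context: Wnt targets are an endothelial program,
  ## homeostatic markers a microglial one (elevated below via fold layers)

  ## ---- latent nuclear protein composition ----
  ct_nfkb <- c(EC = 0, microglia = 0, neuron = -0.3, other = -0.3)
  ct_nfkb <- ct_nfkb[celltypes]
  ct_nfkb[is.na(ct_nfkb)] <- 0
  names(ct_nfkb) <- celltypes

  dam_prob <- ifelse(donor_group[di] == "young_ctrl", 0.15,
                     ifelse(donor_group[di] == "old_ctrl", 0.35, 0.70))
  dam <- ct == "microglia" & stats::runif(n) < dam_prob

  f <- ct_nfkb[ct] + stats::rnorm(n, 0, config@nfkb_sd)
  f[dam] <- f[dam] + 0.4  # DAM microglia carry more nuclear NF-kB (on-line)
  t_lat <- config@coupling_slope * f + stats::rnorm(n, 0, config@coupling_noise_sd)
  b <- -(f + t_lat) + stats::rnorm(n, 0, config@closure_noise_sd)

  ## disease nuclei above the donor x cell-type NF-kB percentile decouple:
  ## TDP-43 drops by delta in nCLR units (sum-zero shift against beta-Catenin)
  dec <- rep(FALSE, n)
  q <- config@decoupling_percentile / 100
  for (grp in split(seq_len(n), list(di, ct), drop = TRUE)) {
    cut <- stats::quantile(f[grp], q, names = FALSE)
    dec[grp] <- f[grp] > cut
  }
  dec <- dec & disease
  t_lat[dec] <- t_lat[dec] + config@decoupling_delta
  b[dec] <- b[dec] - config@decoupling_delta

  ## disease-associated endothelial composition shift (sum-zero)
  dis_ec <- disease & ct == "EC"
  sh <- config@disease_protein_shift[config@protein_panel]
  f[dis_ec] <- f[dis_ec] + sh[1L]
  t_lat[dis_ec] <- t_lat[dis_ec] + sh[2L]
  b[dis_ec] <- b[dis_ec] + sh[3L]

  ## ---- RNA counts ----
  ## expression state = cell type x (disease EC program) x (DAM) x (decoupled)
  state <- paste(ct, dis_ec, dam, dec, sep = ".")
  ustate <- unique(state)
  marker_of <- c(EC = "EC_markers", microglia = "microglia_markers",
                 neuron = "neuron_markers", other = "other_markers")
  share <- vapply(ustate, function(s) {
    p <- strsplit(s, ".", fixed = TRUE)[[1]]
    ab <- base
    if (p[1] %in% names(marker_of))
      ab[programs[[marker_of[p[1]]]]] <- ab[programs[[marker_of[p[1]]]]] * exp(2)
    if (p[1] == "EC") {
      wf <- 3
      if (p[2] == "TRUE") wf <- wf * exp(config@wnt_program_effect)
      ab[programs$wnt_targets] <- ab[programs$wnt_targets] * wf
    }
    if (p[1] == "microglia") {
      hf <- 3; df <- 1
      if (p[3] == "TRUE") {
        hf <- hf * exp(-config@dam_program_effect)
        df <- exp(config@dam_program_effect)
      }
      ab[programs$homeostatic_markers] <- ab[programs$homeostatic_markers] * hf
      ab[programs$dam_markers] <- ab[programs$dam_markers] * df
    }
    if (p[4] == "TRUE")  # NF-kB target program fires when TDP-43 is low
      ab[programs$nfkb_targets] <- ab[programs$nfkb_targets] *
        exp(config@target_program_effect)
    ## pin the mitochondrial count share at its configured generative value
    mito_i <- seq_len(n_mito)
    ab[mito_i] <- ab[mito_i] * config@mito_expr_fraction / sum(ab[mito_i])
    ab[-mito_i] <- ab[-mito_i] * (1 - config@mito_expr_fraction) /
      sum(ab[-mito_i])
    ab
  }, numeric(config@n_genes))

  depth <- stats::rlnorm(n, log(config@mean_counts_per_nucleus) - 0.35^2 / 2,
                         0.35)
  mu <- share[, match(state, ustate), drop = FALSE] *
    rep(depth, each = config@n_genes)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / config@dispersion),
                   nrow = config@n_genes)
  nucleus_id <- paste0("N", sprintf("%06d", seq_len(n)))
  dimnames(counts) <- list(gene_names, nucleus_id)
  counts <- methods::as(counts, "CsparseMatrix")

  ## ---- antibody capture counts ----
  adt_depth <- stats::rlnorm(n, 0, 0.3)
  lat <- rbind(f, t_lat, b)
  adt_t <- matrix(stats::rpois(3L * n, config@adt_base * exp(lat) *
                                 rep(adt_depth, each = 3L)),
                  nrow = 3L, dimnames = list(config@protein_panel, nucleus_id))
  h3 <- stats::rpois(n, config@adt_base * adt_depth)
  hash_names <- paste0("Hash", seq_len(n_hash))
  hash <- matrix(stats::rpois(n_hash * n, config@hash_ambient),
                 nrow = n_hash, dimnames = list(hash_names, nucleus_id))
  true_hash <- hash_names[hash_of[di]]
  sig <- stats::rpois(n, config@hash_signal_to_noise * config@hash_ambient)
  hash[cbind(hash_of[di], seq_len(n))] <- hash[cbind(hash_of[di], seq_len(n))] + sig

  adt <- rbind(adt_t, HistoneH3 = h3, hash)
  rownames(adt)[4L] <- config@normalizer
  roles <- stats::setNames(
    c(rep("target", 3L), "normalizer", rep("hashtag", n_hash)), rownames(adt))

  cd <- DataFrame(
    nucleus_id = nucleus_id,
    donor_id = donor_id[di],
    disease_state = factor(donor_group[di], levels = groups),
    donor_age = donor_age[di],
    batch_id = paste0("well", batch_of[di]),
    true_celltype = ct,
    true_doublet = FALSE,
    true_hash = true_hash,
    true_nfkb_level = unname(f),
    true_tdp43_level = unname(t_lat),
    true_bcat_level = unname(b),
    true_decoupled = dec,
    true_disease_program = dis_ec,
    true_dam = dam,
    row.names = nucleus_id)

  InciteExperiment(counts, adt, roles, colData = cd,
                   metadata = list(gene_programs = programs, config = config))
}

#' Inject synthetic doublets
#'
#' Sums \code{floor(rate * ncol(x))} pairs of nuclei (RNA and antibody
#' counts) into single barcodes, so cross-donor doublets carry two strong
#' hashtags. The surviving barcode keeps the first partner's metadata with
#' \code{true_doublet = TRUE}.
#'
#' @param x an \linkS4class{InciteExperiment} of singlets.
#' @param rate doublet fraction of the input barcodes, in [0, 0.5).
#' @param seed integer seed (the operation is deterministic given it).
#' @return An \code{InciteExperiment} with \code{ncol(x) - floor(rate*ncol(x))}
#'   barcodes.
#' @export
injectDoublets <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5) stop("doublet rate must be in [0, 0.5)")
  if (rate == 0) return(x)
  withr::with_seed(as.integer(seed), .inject_doublets_impl(x, rate))
}

.inject_doublets_impl <- function(x, rate) {
  n <- ncol(x)
  m <- floor(rate * n)
  if (m == 0L) return(x)
  picked <- sample(n, 2L * m)
  a <- picked[seq_len(m)]
  bdx <- picked[m + seq_len(m)]
  keep <- setdiff(seq_len(n), bdx)
  ## column-summing selector: kept barcode j <- its own column, plus its
  ## doublet partner's column where j was picked as a doublet host
  S <- Matrix::sparseMatrix(i = c(keep, bdx),
                            j = c(seq_along(keep), match(a, keep)),
                            x = 1, dims = c(n, length(keep)))
  counts <- assay(x, "counts") %*% S
  dimnames(counts) <- list(rownames(x), colnames(x)[keep])
  adt <- as.matrix(adtCounts(x) %*% S)
  dimnames(adt) <- list(rownames(adtCounts(x)), colnames(x)[keep])
  cd <- colData(x)
  cd$true_doublet[a] <- TRUE
  InciteExperiment(methods::as(counts, "CsparseMatrix"), adt,
                   antibodyRoles(x), colData = cd[keep, , drop = FALSE],
                   metadata = metadata(x))
}
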