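#' Binned NF-kB to TDP-43 stoichiometry curve
#'
#' Equal-frequency bins of the x protein's nCLR values are computed on the
#' pooled population (so bins are comparable across disease groups); within
#' each group and bin the mean and standard error of the y protein's nCLR are
#' reported. Binned means are used instead of a smoother for determinism.
#'
#' @param x,y numeric nCLR values of the x protein (NF-kB) and y protein
#'   (TDP-43), one per nucleus.
#' @param groups per-nucleus group labels.
#' @param n_bins number of equal-frequency bins.
#' @param which_groups groups to report (default all); a requested group
#'   absent from \code{groups} is an error.
#' @return \code{data.frame} with \code{group}, \code{bin}, \code{x_center}
#'   (mean x of the group's nuclei in the bin), \code{mean}, \code{se},
#'   \code{n}.
#' @export
stoichCurve <- function(x, y, groups, n_bins = 20, which_groups = NULL) {
  groups <- as.character(groups)
  if (is.null(which_groups)) which_groups <- unique(groups)
  missing_g <- setdiff(which_groups, groups)
  if (length(missing_g))
    stop("group absent from labels: ", paste(missing_g, collapse = ", "))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  small <- names(which(table(groups)[which_groups] < 5 * n_bins))
  if (length(small))
    warning("fewer than 5 nuclei per bin recommended for: ",
            paste(small, collapse = ", "))
  out <- do.call(rbind, lapply(which_groups, function(g) {
    gi <- groups == g
    do.call(rbind, lapply(sort(unique(bin[gi])), function(b) {
      i <- gi & bin == b
      data.frame(group = g, bin = b, x_center = mean(x[i]),
                 mean = mean(y[i]),
                 se = stats::sd(y[i]) / sqrt(sum(i)), n = sum(i))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Stratified group comparison with ANOVA and Tukey HSD
#'
#' Within each percentile stratum of one protein, compares another protein's
#' nCLR levels across disease groups by one-way ANOVA with post-hoc Tukey HSD.
#' Significance stars follow the ***P<0.001, **P<0.01, *P<0.05 convention.
#' Groups with fewer than 2 nuclei in a stratum are excluded with a warning.
#'
#' @param y numeric values compared across groups (e.g. TDP-43 nCLR).
#' @param strata per-nucleus stratum labels (from
#'   \code{\link{stratifyByProtein}}); \code{"unassigned"} nuclei are ignored.
#' @param groups per-nucleus group labels.
#' @return Named list (one element per stratum) with \code{means}
#'   (\code{data.frame} of group mean/sd/n), \code{anova}
#'   (\code{F}, \code{p}), and \code{tukey} (\code{data.frame} of pairwise
#'   comparisons with adjusted p and stars).
#' @export
stratifiedComparison <- function(y, strata, groups) {
  strata <- as.character(strata)
  keepstr <- setdiff(unique(strata), "unassigned")
  out <- lapply(keepstr, function(s) {
    i <- strata == s
    g <- factor(as.character(groups[i]))
    v <- y[i]
    small <- names(which(table(g) < 2))
    if (length(small)) {
      warning("excluding groups with <2 nuclei in stratum ", s, ": ",
              paste(small, collapse = ", "))
      keep <- !(g %in% small)
      g <- droplevels(g[keep]); v <- v[keep]
    }
    means <- data.frame(group = levels(g),
                        mean = as.numeric(tapply(v, g, mean)),
                        sd = as.numeric(tapply(v, g, stats::sd)),
                        n = as.integer(table(g)))
    fit <- stats::aov(v ~ g)
    a <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lo = tk[, "lwr"], hi = tk[, "upr"],
                        p_adj = tk[, "p adj"],
                        stars = .stars(tk[, "p adj"]), row.names = NULL)
    list(means = means,
         anova = c(F = a$`F value`[1], p = a$`Pr(>F)`[1]),
         tukey = tukey)
  })
  names(out) <- keepstr
  out
}

.stars <- function(p) ifelse(p < 0.001, "***",
                      ifelse(p < 0.01, "**",
                      ifelse(p < 0.05, "*", "")))

#' Decoupling statistic of TDP-43 from NF-kB
#'
#' Formalizes the breakdown of the NF-kB/TDP-43 stoichiometry at the highest
#' NF-kB levels: an ordinary-least-squares line of the y protein's nCLR on the
#' x protein's nCLR is fitted over pooled control nuclei below the pooled 75th
#' x percentile, and for each group g the statistic
#' \deqn{\Delta_g = \mathrm{mean}_{i \in g,\; x_i \ge P_{75}}\,(y_i -
#'   \hat y(x_i))}
#' is the mean observed-minus-predicted y in the top-25\% x stratum. Negative
#' values mean the group's TDP-43 fails to rise with NF-kB as controls do.
#' Confidence intervals are percentile bootstrap over nuclei, by default
#' resampling donors within group and then nuclei within donor to respect
#' donor structure (\code{boot = "flat"} resamples nuclei directly). A one-way
#' ANOVA with Tukey HSD compares the top-stratum residuals across groups.
#'
#' @param x,y per-nucleus nCLR values (x = NF-kB, y = TDP-43).
#' @param groups per-nucleus group labels.
#' @param control_groups labels pooled as the control reference.
#' @param top_pct percentile defining the top stratum (default 75, i.e. top
#'   25\%).
#' @param n_boot bootstrap replicates; 0 skips the CI.
#' @param seed integer seed for the bootstrap.
#' @param boot \code{"donor"} (hierarchical) or \code{"flat"}.
#' @param donor per-nucleus donor ids (required for \code{boot = "donor"} and
#'   \code{stratum_by = "donor"}).
#' @param stratum_by \code{"pooled"} (default: one percentile cutoff over the
#'   whole analysis population) or \code{"donor"} (each donor's own cutoff;
#'   appropriate when the top stratum is a within-donor notion, e.g. for
#'   parameter recovery against the generator).
#' @param conf confidence level.
#' @return List of class \code{"DecouplingResult"}: \code{delta}
#'   (\code{data.frame} with \code{group}, \code{delta}, \code{lo}, \code{hi},
#'   \code{n}), \code{fit} (control line coefficients), \code{anova},
#'   \code{tukey} (pairs involving a control group).
#' @export
decouplingStatistic <- function(x, y, groups, control_groups = CONTROL_GROUPS,
                                top_pct = 75, n_boot = 500, seed = 1L,
                                boot = c("donor", "flat"), donor = NULL,
                                stratum_by = c("pooled", "donor"),
                                conf = 0.95) {
  boot <- match.arg(boot)
  stratum_by <- match.arg(stratum_by)
  groups <- as.character(groups)
  if (is.null(donor)) {
    if (stratum_by == "donor") stop("stratum_by='donor' needs donor ids")
    boot <- "flat"
  }
  is_ctrl <- groups %in% control_groups
  if (sum(is_ctrl) < 10L) stop("too few pooled control nuclei")
  if (sum(is_ctrl) < 100L)
    warning("fewer than 100 pooled control nuclei; the control fit is noisy")
  strat_donor <- if (stratum_by == "donor") donor else NULL
  point <- .delta_point(x, y, groups, is_ctrl, top_pct, strat_donor)
  glev <- point$delta$group

  ci <- NULL
  if (n_boot > 0) {
    ci <- withr::with_seed(as.integer(seed), {
      reps <- replicate(n_boot, {
        idx <- if (boot == "flat") {
          unlist(lapply(split(seq_along(groups), groups), function(i)
            sample(i, length(i), replace = TRUE)), use.names = FALSE)
        } else {
          unlist(lapply(split(seq_along(groups), groups), function(i) {
            dn <- split(i, donor[i])
            picked <- sample(length(dn), length(dn), replace = TRUE)
            unlist(lapply(dn[picked], function(j)
              sample(j, length(j), replace = TRUE)), use.names = FALSE)
          }), use.names = FALSE)
        }
        p <- .delta_point(x[idx], y[idx], groups[idx],
                          groups[idx] %in% control_groups, top_pct,
                          if (is.null(strat_donor)) NULL else donor[idx])
        p$delta$delta[match(glev, p$delta$group)]
      })
      if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L)
      alpha <- (1 - conf) / 2
      t(apply(reps, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE))
    })
  }
  delta <- point$delta
  delta$lo <- if (is.null(ci)) NA_real_ else ci[, 1L]
  delta$hi <- if (is.null(ci)) NA_real_ else ci[, 2L]

  ## ANOVA / Tukey on top-stratum residuals across groups
  top <- point$top
  res <- y[top] - (point$fit[1] + point$fit[2] * x[top])
  g <- factor(groups[top])
  anova <- tukey <- NULL
  if (nlevels(g) >= 2L && all(table(g) >= 2L)) {
    fit <- stats::aov(res ~ g)
    a <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    ctrl_pair <- grepl(paste(control_groups, collapse = "|"), rownames(tk))
    tukey <- data.frame(comparison = rownames(tk)[ctrl_pair],
                        diff = tk[ctrl_pair, "diff"],
                        p_adj = tk[ctrl_pair, "p adj"],
                        stars = .stars(tk[ctrl_pair, "p adj"]),
                        row.names = NULL)
    anova <- c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }
  structure(list(delta = delta, fit = point$fit, anova = anova, tukey = tukey,
                 top_pct = top_pct, control_groups = control_groups),
            class = "DecouplingResult")
}

.delta_point <- function(x, y, groups, is_ctrl, top_pct, strat_donor = NULL) {
  if (is.null(strat_donor)) {
    cutoff <- stats::quantile(x, top_pct / 100, names = FALSE)
    top <- x > cutoff
  } else {
    top <- logical(length(x))
    for (i in split(seq_along(x), strat_donor))
      top[i] <- x[i] > stats::quantile(x[i], top_pct / 100, names = FALSE)
  }
  fit_idx <- is_ctrl & !top
  if (stats::var(x[fit_idx]) == 0)
    stop("degenerate control fit: zero NF-kB variance")
  cf <- stats::coef(stats::lm.fit(cbind(1, x[fit_idx]),
                                  y[fit_idx]))
  glev <- sort(unique(groups))
  delta <- vapply(glev, function(g) {
    i <- top & groups == g
    if (!any(i)) return(NA_real_)
    mean(y[i] - (cf[1] + cf[2] * x[i]))
  }, numeric(1))
  n <- vapply(glev, function(g) sum(top & groups == g), numeric(1))
  list(delta = data.frame(group = glev, delta = unname(delta), n = unname(n)),
       fit = unname(cf), top = top)
}

#' @export
print.DecouplingResult <- function(x, ...) {
  cat("Decoupling of y from x in the top", 100 - x$top_pct,
      "% x stratum (controls:", paste(x$control_groups, collapse = ", "), ")\n")
  cat("control line: y =", signif(x$fit[1], 3), "+", signif(x$fit[2], 3), "x\n")
  print(x$delta, row.names = FALSE)
  if (!is.null(x$anova))
    cat("ANOVA F =", signif(x$anova["F"], 4), ", p =",
        signif(x$anova["p"], 3), "\n")
  invisible(x)
}

#' Differential expression between high- and low-NF-kB strata of a cluster
#'
#' Within one cluster, contrasts nuclei in the top 10th percentile of the
#' protein's nCLR against the bottom 25th percentile (percentiles computed
#' within the cluster) with \code{\link{differentialExpression}}.
#'
#' @param lognorm genes x nuclei log-normalized matrix.
#' @param protein_values per-nucleus nCLR values of the stratifying protein.
#' @param clusters per-nucleus cluster labels.
#' @param cluster the cluster to analyse.
#' @param top_pct,bottom_pct stratum percentiles (top = above
#'   \code{100 - top_pct} from the top; defaults 10 and 25).
#' @return A \code{\link{differentialExpression}} table (top vs bottom, so
#'   positive lfc means higher with high NF-kB).
#' @export
nfkbHighDEContrast <- function(lognorm, protein_values, clusters, cluster,
                               top_pct = 10, bottom_pct = 25) {
  i <- which(as.character(clusters) == as.character(cluster))
  if (!length(i)) stop("cluster not found")
  pct <- percentileRanks(protein_values[i])
  top <- i[pct > 100 - top_pct]
  bottom <- i[pct <= bottom_pct]
  if (!length(top) || !length(bottom))
    stop("empty stratum within the cluster")
  differentialExpression(lognorm, top, bottom)
}
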