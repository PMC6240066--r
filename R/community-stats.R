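# Descriptive and comparative community statistics across regimes.
# Ordination and dispersion operate on the fourth-root (uncentred,
# unstandardized) matrix because Bray-Curtis requires non-negative input.

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(u, v) = sum|u - v| / sum(u + v)} over paired non-negative
#' abundance vectors; symmetric with a zero diagonal and values in [0, 1].
#'
#' @param x Non-negative matrix or data.frame (sites x variables).
#' @return A \code{dist} object.
#' @examples
#' bray_curtis(rbind(c(1, 2, 3), c(2, 1, 3)))
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0))
    stop("negative entries: Bray-Curtis needs untransformed-scale ",
         "(non-negative) input")
  vegan::vegdist(x, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimization with monotone regression, restarted from
#' \code{n_starts} random configurations to avoid local optima; the best
#' solution is returned with its stress. Coordinates are centred.
#'
#' @param distances A \code{dist} object (e.g. from
#'   \code{\link{bray_curtis}}).
#' @param dims Embedding dimension.
#' @param n_starts Maximum random starts.
#' @param seed Seed for the start stream.
#' @return \code{ordination_result}: \code{points} (n x dims), \code{stress}
#'   (stress-1, in [0, 1]), \code{n_starts}, \code{seed}.
#' @export
nmds_ordination <- function(distances, dims = 2, n_starts = 50, seed = 1) {
  distances <- as.dist(distances)
  if (attr(distances, "Size") < 3) stop("need at least 3 points for nMDS")
  set.seed(seed)
  fit <- vegan::metaMDS(distances, k = dims, trymax = n_starts,
                        autotransform = FALSE, wascores = FALSE,
                        trace = 0)
  pts <- scale(fit$points, scale = FALSE)
  out <- list(points = pts, stress = fit$stress, n_starts = n_starts,
              seed = seed)
  class(out) <- "ordination_result"
  out
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("nMDS ordination:", nrow(x$points), "points,",
      ncol(x$points), "dimensions, stress =",
      format(round(x$stress, 3)), "\n")
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates, measures each
#' point's distance to its group centroid, and tests equality of mean
#' dispersion across groups with an F statistic whose p-value comes from
#' permuting group labels: \code{p = (1 + #[perm >= obs]) / (n_perm + 1)}.
#'
#' @param distances A \code{dist} object.
#' @param groups Group labels (one per point; >= 2 groups of >= 2).
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutation stream.
#' @return \code{dispersion_result}: per-group mean distance-to-centroid,
#'   F, p, n_perm, and the per-point distances.
#' @export
dispersion_test <- function(distances, groups, n_perm = 999, seed = 1) {
  distances <- as.dist(distances)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 members each")
  set.seed(seed)
  bd <- vegan::betadisper(distances, groups, type = "centroid")
  pt <- vegan::permutest(bd, permutations = n_perm)
  tab <- pt$tab
  out <- list(
    group_means = tapply(bd$distances, bd$group, mean),
    f_statistic = tab$F[1],
    p_value = tab[1, "Pr(>F)"],
    n_perm = n_perm,
    distances_to_centroid = bd$distances,
    groups = groups, seed = seed)
  class(out) <- "dispersion_result"
  out
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion test: F =", format(round(x$f_statistic, 3)),
      ", p =", format(x$p_value), "(", x$n_perm, "permutations )\n")
  print(round(x$group_means, 3))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD contrasts
#'
#' Overall F test of a response across regimes plus all pairwise differences
#' with family-wise 95\% intervals.
#'
#' @param response Numeric response (e.g. depth, complexity, coral
#'   richness).
#' @param groups Regime labels.
#' @param conf_level Family-wise confidence level.
#' @return \code{contrast_result}: f_statistic, df (pair), p_value,
#'   \code{contrasts} data.frame (pair, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(response, groups, conf_level = 0.95) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 observations each")
  if (sd(response) < .Machine$double.eps)
    stop("constant response: F statistic undefined")
  fit <- aov(response ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf_level)$groups
  out <- list(
    f_statistic = an$`F value`[1],
    df = c(an$Df[1], an$Df[2]),
    p_value = an$`Pr(>F)`[1],
    contrasts = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                           lwr = tk[, "lwr"], upr = tk[, "upr"],
                           p_adj = tk[, "p adj"], row.names = NULL,
                           stringsAsFactors = FALSE),
    conf_level = conf_level)
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ",", x$df[2], ") =",
      format(round(x$f_statistic, 2)), ", p =", format(x$p_value), "\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}

#' Ecological and spatial summaries of regimes
#'
#' Summarizes the spatial footprint and ecology of assigned regimes:
#' \itemize{
#'   \item island x regime percentages (share of each island's sites in each
#'     regime; columns sum to 100 per island);
#'   \item shore-direction composition per regime (rows sum to 100);
#'   \item depth and habitat-complexity contrasts across regimes
#'     (\code{\link{anova_tukey}});
#'   \item per-regime proportional cover of the four most abundant coral
#'     species and trait-class shares, when species-level coral cover is
#'     supplied.
#' }
#'
#' @param assignments data.frame with site_id and regime (e.g. from
#'   \code{\link{assign_regimes}} joined to site ids).
#' @param metadata Site metadata (site_id, island, shore_direction, depth_m,
#'   complexity).
#' @param coral_cover Optional data.frame site_id, species, percent_cover.
#' @param trait_lu Coral trait lookup (default packaged).
#' @return List of summary data.frames; unjoined site ids in
#'   \code{$unjoined}.
#' @export
regime_summaries <- function(assignments, metadata, coral_cover = NULL,
                             trait_lu = coral_trait_lookup()) {
  m <- merge(assignments, metadata, by = "site_id")
  unjoined <- setdiff(assignments$site_id, metadata$site_id)
  if (length(unjoined))
    message("regime_summaries: ", length(unjoined), " site(s) unjoined: ",
            paste(head(unjoined, 5), collapse = ", "))
  out <- list(unjoined = unjoined)

  if ("island" %in% names(m)) {
    tab <- table(m$regime, m$island)
    out$island_regime_pct <- as.data.frame.matrix(
      100 * prop.table(tab, margin = 2))
  }
  if ("shore_direction" %in% names(m)) {
    tab <- table(m$regime, m$shore_direction)
    out$shore_regime_pct <- as.data.frame.matrix(
      100 * prop.table(tab, margin = 1))
  }
  for (v in c("depth_m", "complexity")) {
    if (v %in% names(m) && length(unique(m$regime)) >= 2)
      out[[paste0(v, "_contrasts")]] <-
        tryCatch(anova_tukey(m[[v]], m$regime), error = function(e) NULL)
  }

  if (!is.null(coral_cover)) {
    cc <- merge(coral_cover, assignments, by = "site_id")
    tot <- tapply(cc$percent_cover, cc$species, sum)
    top4 <- names(sort(tot, decreasing = TRUE))[seq_len(min(4, length(tot)))]
    sub <- cc[cc$species %in% top4, ]
    by_rs <- tapply(sub$percent_cover, list(sub$regime, sub$species), sum)
    by_rs[is.na(by_rs)] <- 0
    out$top_coral_prop <- as.data.frame.matrix(
      by_rs / rowSums(by_rs))
    cc$trait <- trait_lu$trait_class[match(cc$species, trait_lu$species)]
    known <- !is.na(cc$trait)
    if (any(known)) {
      tt <- tapply(cc$percent_cover[known],
                   list(cc$regime[known], cc$trait[known]), sum)
      tt[is.na(tt)] <- 0
      out$trait_shares <- as.data.frame.matrix(tt / rowSums(tt))
    }
  }
  out
}
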