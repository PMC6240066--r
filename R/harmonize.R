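# Harmonization: heterogeneous raw survey records -> analysis-ready
# site x 10 functional-group matrix.

#' Length-weight biomass of fish observations
#'
#' Applies the allometric conversion \code{W = a * TL^b} (W in g, TL total
#' length in cm) per observation and multiplies by the count; density is
#' mass per survey area.
#'
#' @param observations data.frame with columns species, count, length_cm,
#'   area_m2.
#' @param params Length-weight lookup with columns species, a, b (default:
#'   packaged \code{\link{species_lookup}}).
#' @return The observations with columns \code{weight_g} (a TL^b count) and
#'   \code{density_g_m2} appended.
#' @examples
#' obs <- data.frame(species = "Scarus psittacus", count = 1,
#'                   length_cm = 10, area_m2 = 100)
#' compute_biomass(obs, data.frame(species = "Scarus psittacus",
#'                                 a = 0.01, b = 3))
#' @export
compute_biomass <- function(observations, params = species_lookup()) {
  stopifnot(all(c("species", "count", "length_cm", "area_m2") %in%
                  names(observations)))
  if (any(params$a <= 0) || any(params$b <= 0))
    stop("length-weight parameters a and b must be positive")
  idx <- match(observations$species, params$species)
  if (anyNA(idx))
    stop("no length-weight parameters for species: ",
         paste(unique(observations$species[is.na(idx)]), collapse = ", "))
  a <- params$a[idx]
  b <- params$b[idx]
  observations$weight_g <- a * observations$length_cm^b * observations$count
  observations$density_g_m2 <- observations$weight_g / observations$area_m2
  observations
}

#' Remove species excluded from biomass calculations
#'
#' Drops observations of species whose life history makes visual counts
#' unreliable (cryptic, nocturnal, pelagic schooling, manta rays).
#'
#' @param observations data.frame with a species column.
#' @param exclusions data.frame with a species column (default packaged
#'   \code{\link{exclusion_list}}).
#' @param quiet Suppress the removal-count message.
#' @return Filtered observations; number removed in attribute
#'   \code{"n_removed"}.
#' @export
filter_exclusions <- function(observations, exclusions = exclusion_list(),
                              quiet = FALSE) {
  drop <- observations$species %in% exclusions$species
  if (!quiet && any(drop))
    message("filter_exclusions: removed ", sum(drop), " observation(s) of ",
            length(unique(observations$species[drop])), " excluded species")
  out <- observations[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Cap extreme schooling counts
#'
#' Two-step screen for extreme observations: (1) flag observations whose
#' count exceeds the global 99.9\% quantile of all counts; (2) for each
#' species with at least one flagged observation, replace counts above that
#' species' 99.0\% count quantile (computed on the pre-capping distribution)
#' with that quantile. Quantiles are linear-interpolation (type 7)
#' empirical quantiles. Passing a stored threshold table re-applies the same
#' caps, making the operation idempotent.
#'
#' @param observations data.frame with species and count columns.
#' @param global_q,species_q Quantile levels for the two steps.
#' @param thresholds Optional threshold table from a previous call.
#' @return List: \code{observations} (capped), \code{report} (species,
#'   threshold, n_adjusted), \code{thresholds} (for re-application).
#' @export
cap_outliers <- function(observations, global_q = 0.999, species_q = 0.99,
                         thresholds = NULL) {
  stopifnot(nrow(observations) >= 1)
  if (is.null(thresholds)) {
    g_thr <- quantile(observations$count, global_q, type = 7, names = FALSE)
    flagged_sp <- unique(observations$species[observations$count > g_thr])
    thresholds <- data.frame(
      species = flagged_sp,
      threshold = vapply(flagged_sp, function(s)
        quantile(observations$count[observations$species == s], species_q,
                 type = 7, names = FALSE), numeric(1)),
      stringsAsFactors = FALSE)
    attr(thresholds, "global_threshold") <- g_thr
  }
  n_adj <- integer(nrow(thresholds))
  for (i in seq_len(nrow(thresholds))) {
    hit <- observations$species == thresholds$species[i] &
      observations$count > thresholds$threshold[i]
    observations$count[hit] <- thresholds$threshold[i]
    n_adj[i] <- sum(hit)
  }
  report <- cbind(thresholds, n_adjusted = n_adj)
  list(observations = observations, report = report, thresholds = thresholds)
}

# Fit one multiplicative calibration factor from paired densities under the
# decision cascade: through-origin linear fit; delta model if zero-dominated;
# log-linear refit if residuals non-normal. Returns NULL if the pair set
# fails every admissible form.
.fit_pair_factor <- function(src, tgt, alpha = 0.05, zero_dominance = 0.5) {
  zero_pair <- src == 0 | tgt == 0
  if (mean(zero_pair) > zero_dominance) {
    # delta model: occurrence and positive abundance calibrated separately
    if (mean(src > 0) == 0) return(NULL)
    occ <- mean(tgt > 0) / mean(src > 0)
    both <- src > 0 & tgt > 0
    pos <- if (any(both)) mean(tgt[both]) / mean(src[both]) else 1
    f <- occ * pos
    if (!is.finite(f) || f <= 0) return(NULL)
    return(list(factor = f, form = "delta"))
  }
  fit <- lm(tgt ~ src + 0)
  f <- unname(coefficients(fit)[1])
  if (!is.finite(f) || f <= 0) return(NULL)
  r <- resid(fit)
  if (.resid_normal(r, alpha))
    return(list(factor = f, form = "linear"))
  both <- src > 0 & tgt > 0
  if (sum(both) < 3) return(NULL)
  lfit <- lm(log(tgt[both]) ~ 1, offset = log(src[both]))
  if (!.resid_normal(resid(lfit), alpha)) return(NULL)
  list(factor = exp(unname(coefficients(lfit)[1])), form = "log-linear")
}

.resid_normal <- function(r, alpha) {
  if (sd(r) < 1e-12) return(TRUE)      # perfect fit: nothing to test
  if (length(r) > 5000) r <- r[seq(1, length(r), length.out = 5000)]
  if (length(r) < 3) return(TRUE)
  shapiro.test(r)$p.value >= alpha
}

#' Derive method calibration factors from paired surveys
#'
#' Fits multiplicative factors converting source-method densities onto the
#' target-method scale, by species where the decision rules allow, else by
#' family-by-trophic pool, else a single global method factor (always
#' emitted). Rules per species: (1) at least \code{min_pairs} paired
#' observations (evaluated within an island when an island column is
#' present, otherwise pooled with a message); (2) if pairs are dominated by
#' zeros a delta model separates occurrence from positive abundance; (3) if
#' residuals of the through-origin linear fit fail a Shapiro-Wilk test at
#' \code{alpha}, the model is refit log-linearly and rechecked.
#'
#' @param pairs data.frame with columns species, family, trophic,
#'   density_source, density_target, optionally island.
#' @param min_pairs Minimum paired observations for a species-level factor.
#' @param zero_dominance Zero-pair fraction above which the delta model is
#'   used.
#' @param alpha Shapiro-Wilk significance level.
#' @return Calibration table: scope (species / family_trophic / global),
#'   key, factor, model_form, n_pairs.
#' @export
derive_calibration <- function(pairs, min_pairs = 10, zero_dominance = 0.5,
                               alpha = 0.05) {
  need <- c("species", "family", "trophic", "density_source",
            "density_target")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  if (nrow(pairs) == 0) stop("no paired observations supplied")
  has_island <- "island" %in% names(pairs)
  if (!has_island)
    message("derive_calibration: no island column; pairing pooled across islands")
  rows <- list()
  done_sp <- character(0)
  for (s in unique(pairs$species)) {
    p <- pairs[pairs$species == s, ]
    enough <- if (has_island) any(table(p$island) >= min_pairs)
              else nrow(p) >= min_pairs
    if (!enough) next
    f <- .fit_pair_factor(p$density_source, p$density_target,
                          alpha, zero_dominance)
    if (is.null(f)) next
    rows[[length(rows) + 1]] <- data.frame(
      scope = "species", key = s, factor = f$factor, model_form = f$form,
      n_pairs = nrow(p), stringsAsFactors = FALSE)
    done_sp <- c(done_sp, s)
  }
  # family x trophic pools are fitted on every pair in the combination, but
  # only emitted for combinations that still contain uncovered species
  rest <- pairs[!pairs$species %in% done_sp, ]
  if (nrow(rest) > 0) {
    ft_all <- paste(pairs$family, pairs$trophic, sep = ":")
    for (k in unique(paste(rest$family, rest$trophic, sep = ":"))) {
      p <- pairs[ft_all == k, ]
      if (nrow(p) < min_pairs) next
      f <- .fit_pair_factor(p$density_source, p$density_target,
                            alpha, zero_dominance)
      if (is.null(f)) next
      rows[[length(rows) + 1]] <- data.frame(
        scope = "family_trophic", key = k, factor = f$factor,
        model_form = f$form, n_pairs = nrow(p), stringsAsFactors = FALSE)
    }
  }
  gfit <- lm(density_target ~ density_source + 0, data = pairs)
  gf <- unname(coefficients(gfit)[1])
  if (!is.finite(gf) || gf <= 0) gf <- 1
  rows[[length(rows) + 1]] <- data.frame(
    scope = "global", key = "global", factor = gf, model_form = "linear",
    n_pairs = nrow(pairs), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Apply calibration factors to fish observations
#'
#' Multiplies each observation's count and derived density columns by the
#' most specific applicable factor: species, else family-by-trophic, else
#' global. Benthic records are never calibrated and must not be passed here.
#'
#' @param observations Fish observations with species, family, trophic
#'   columns.
#' @param factors Calibration table from \code{\link{derive_calibration}}.
#' @return Calibrated observations with a \code{calibration_scope} column.
#' @export
apply_calibration <- function(observations, factors) {
  if (is.null(factors) || nrow(factors) == 0)
    stop("empty calibration factor table")
  sp_f <- factors[factors$scope == "species", ]
  ft_f <- factors[factors$scope == "family_trophic", ]
  gl_f <- factors[factors$scope == "global", ]
  ftk <- paste(observations$family, observations$trophic, sep = ":")
  f <- sp_f$factor[match(observations$species, sp_f$key)]
  scope <- ifelse(is.na(f), NA_character_, "species")
  miss <- is.na(f)
  f[miss] <- ft_f$factor[match(ftk[miss], ft_f$key)]
  scope[miss & !is.na(f)] <- "family_trophic"
  miss <- is.na(f)
  if (any(miss)) {
    if (nrow(gl_f) == 0)
      stop("observations match no calibration factor at any scope: ",
           paste(unique(observations$species[miss]), collapse = ", "))
    f[miss] <- gl_f$factor[1]
    scope[miss] <- "global"
  }
  for (col in intersect(c("count", "weight_g", "density_g_m2"),
                        names(observations)))
    observations[[col]] <- observations[[col]] * f
  observations$calibration_scope <- scope
  observations
}

#' Aggregate nearby sites by single-linkage distance clustering
#'
#' Groups sites whose great-circle (haversine) distance chains below
#' \code{radius_m} via single-linkage agglomeration, then averages every
#' numeric variable across member surveys (and years); group coordinates are
#' member centroids. Single linkage merges chains: sites A and C 500 m apart
#' still merge if B sits within 300 m of both.
#'
#' @param site_table data.frame with lat, lon (decimal degrees) and numeric
#'   survey variables.
#' @param radius_m Linkage cut height in meters.
#' @return Aggregated data.frame: group_id, n_members, lat, lon, numeric
#'   means; member site ids in attribute \code{"members"}.
#' @export
aggregate_spatial <- function(site_table, radius_m = 300) {
  stopifnot(all(c("lat", "lon") %in% names(site_table)))
  if (anyNA(site_table$lat) || anyNA(site_table$lon))
    stop("missing coordinates")
  n <- nrow(site_table)
  if (n == 1) {
    grp <- 1L
  } else {
    dm <- geosphere::distm(cbind(site_table$lon, site_table$lat),
                           fun = geosphere::distHaversine)
    grp <- cutree(hclust(as.dist(dm), method = "single"), h = radius_m)
  }
  num_cols <- setdiff(names(site_table)[vapply(site_table, is.numeric,
                                               logical(1))], c("lat", "lon"))
  ord <- sort(unique(grp))
  out <- do.call(rbind, lapply(ord, function(g) {
    m <- site_table[grp == g, , drop = FALSE]
    row <- data.frame(group_id = sprintf("G%04d", g), n_members = nrow(m),
                      lat = mean(m$lat), lon = mean(m$lon),
                      stringsAsFactors = FALSE)
    for (cc in num_cols) row[[cc]] <- mean(m[[cc]])
    row
  }))
  members <- if ("site_id" %in% names(site_table))
    split(site_table$site_id, grp) else split(seq_len(n), grp)
  attr(out, "members") <- members
  out
}

#' Build the site x 10 functional-profile matrix
#'
#' Maps each fish species to one of the five fish functional groups and each
#' benthic category to one of the five cover groups, sums densities/covers
#' within a survey, and averages across surveys of the same site. Unmapped
#' taxa or categories are an error listing the offenders.
#'
#' @param fish Calibrated fish observations with \code{density_g_m2}.
#' @param benthic Benthic records with category and percent_cover.
#' @param species_lu,benthic_lu Lookup tables (packaged defaults).
#' @return data.frame: site_id + the 10 columns of
#'   \code{\link{functional_groups}}.
#' @export
build_profile_matrix <- function(fish, benthic,
                                 species_lu = species_lookup(),
                                 benthic_lu = benthic_lookup()) {
  g <- functional_groups()
  fgrp <- species_lu$functional_group[match(fish$species,
                                            species_lu$species)]
  if (anyNA(fgrp))
    stop("unmapped fish species: ",
         paste(unique(fish$species[is.na(fgrp)]), collapse = ", "))
  bgrp <- benthic_lu$functional_group[match(benthic$category,
                                            benthic_lu$category)]
  if (anyNA(bgrp))
    stop("unmapped benthic categories: ",
         paste(unique(benthic$category[is.na(bgrp)]), collapse = ", "))

  survey_key <- function(df) {
    ks <- intersect(c("method", "date", "year"), names(df))
    if (length(ks) == 0) return(rep("all", nrow(df)))
    do.call(paste, c(df[ks], sep = "|"))
  }

  # fish: sum density per group within survey, then mean across surveys;
  # dividing the across-survey sum by the survey count per site lets surveys
  # that miss a group contribute an implicit zero to the mean
  fk <- survey_key(fish)
  fsum <- aggregate(list(v = fish$density_g_m2),
                    by = list(site_id = fish$site_id, survey = fk,
                              group = fgrp), FUN = sum)
  nsurv <- tapply(fk, fish$site_id, function(x) length(unique(x)))
  fmean <- aggregate(list(v = fsum$v),
                     by = list(site_id = fsum$site_id, group = fsum$group),
                     FUN = sum)
  fmean$v <- fmean$v / as.numeric(nsurv[fmean$site_id])

  bk <- survey_key(benthic)
  bsum <- aggregate(list(v = benthic$percent_cover),
                    by = list(site_id = benthic$site_id, survey = bk,
                              group = bgrp), FUN = sum)
  nbs <- tapply(bk, benthic$site_id, function(x) length(unique(x)))
  bmean <- aggregate(list(v = bsum$v),
                     by = list(site_id = bsum$site_id, group = bsum$group),
                     FUN = sum)
  bmean$v <- bmean$v / as.numeric(nbs[bmean$site_id])

  sites <- sort(unique(c(fish$site_id, benthic$site_id)))
  out <- matrix(0, length(sites), 10, dimnames = list(sites, g))
  long <- rbind(fmean, bmean)
  out[cbind(match(long$site_id, sites), match(long$group, g))] <- long$v
  cbind(data.frame(site_id = sites, stringsAsFactors = FALSE),
        as.data.frame(out, row.names = FALSE))
}

#' Fourth-root transform with centring and unit scaling
#'
#' \code{y = x^(1/4)} per cell, then per-column centring and scaling to unit
#' standard deviation. Columns that are constant after the root transform
#' keep scale 1. The fitted centre/scale state is returned for exact
#' inversion and for transforming new data at prediction time.
#'
#' @param x Non-negative matrix or data.frame (numeric columns only).
#' @return List: \code{scores} (transformed matrix), \code{state}
#'   (list(center, scale)).
#' @seealso \code{\link{profile_inverse_transform}}
#' @export
profile_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative values: transform requires raw-scale input")
  y <- x^(1 / 4)
  ctr <- colMeans(y)
  scl <- apply(y, 2, sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  z <- sweep(sweep(y, 2, ctr), 2, scl, "/")
  list(scores = z, state = list(center = ctr, scale = scl))
}

#' Invert the fourth-root transform
#'
#' @param z Transformed matrix (or component means) on the centred/scaled
#'   fourth-root scale.
#' @param state Transform state from \code{\link{profile_transform}}.
#' @return Raw-scale matrix; values whose de-scaled fourth root is negative
#'   are truncated at 0.
#' @export
profile_inverse_transform <- function(z, state) {
  if (is.null(state)) stop("missing transform state")
  z <- as.matrix(z)
  y <- sweep(sweep(z, 2, state$scale, "*"), 2, state$center, "+")
  pmax(y, 0)^4
}

#' Harmonize raw survey tables into functional profiles
#'
#' Composes the full harmonization chain: optional depth-window filter,
#' species exclusions, outlier capping, length-weight biomass, method
#' calibration derived from paired same-site surveys (when at least two
#' method labels are present), profile assembly, and optional spatial
#' aggregation of sites within \code{radius_m}.
#'
#' @param fish Fish observations (site_id, method, species, count,
#'   length_cm, area_m2).
#' @param benthic Benthic records (site_id, category, percent_cover).
#' @param metadata Optional site metadata (site_id, lat, lon, depth_m, ...).
#' @param target_method Method whose scale others are calibrated onto
#'   (default: the most frequent method label).
#' @param depth_window Length-2 numeric depth filter in meters (requires
#'   metadata depth_m), default c(0, 30).
#' @param cap Apply \code{\link{cap_outliers}}.
#' @param calibrate Derive and apply method calibration.
#' @param radius_m Aggregation radius; NULL skips spatial aggregation.
#' @param species_lu,benthic_lu,exclusions Lookup tables.
#' @return List: \code{profiles} (site x 10), \code{capping_report},
#'   \code{calibration}, \code{aggregated} (if radius_m given),
#'   \code{metadata} (filtered).
#' @export
harmonize_surveys <- function(fish, benthic, metadata = NULL,
                              target_method = NULL,
                              depth_window = c(0, 30),
                              cap = TRUE, calibrate = TRUE,
                              radius_m = NULL,
                              species_lu = species_lookup(),
                              benthic_lu = benthic_lookup(),
                              exclusions = exclusion_list()) {
  if (!is.null(metadata) && "depth_m" %in% names(metadata) &&
      !is.null(depth_window)) {
    keep <- metadata$site_id[metadata$depth_m >= depth_window[1] &
                               metadata$depth_m <= depth_window[2]]
    fish <- fish[fish$site_id %in% keep, , drop = FALSE]
    benthic <- benthic[benthic$site_id %in% keep, , drop = FALSE]
    metadata <- metadata[metadata$site_id %in% keep, , drop = FALSE]
  }
  fish <- filter_exclusions(fish, exclusions, quiet = TRUE)
  capping_report <- NULL
  if (cap && nrow(fish) > 0) {
    capped <- cap_outliers(fish)
    fish <- capped$observations
    capping_report <- capped$report
  }
  fish$family <- species_lu$family[match(fish$species, species_lu$species)]
  fish$trophic <- species_lu$trophic[match(fish$species, species_lu$species)]
  fish <- compute_biomass(fish, species_lu)

  calibration <- NULL
  methods <- unique(fish$method)
  if (calibrate && length(methods) >= 2) {
    if (is.null(target_method))
      target_method <- names(sort(table(fish$method), decreasing = TRUE))[1]
    pairs <- .extract_pairs(fish, target_method)
    if (nrow(pairs) > 0) {
      calibration <- derive_calibration(pairs)
      src <- fish$method != target_method
      fish_cal <- apply_calibration(fish[src, , drop = FALSE], calibration)
      fish_cal$calibration_scope <- NULL
      fish <- rbind(fish[!src, , drop = FALSE], fish_cal)
    }
  }

  profiles <- build_profile_matrix(fish, benthic, species_lu, benthic_lu)

  aggregated <- NULL
  if (!is.null(radius_m)) {
    if (is.null(metadata) || !all(c("lat", "lon") %in% names(metadata)))
      stop("spatial aggregation requires metadata with lat/lon")
    joined <- merge(profiles, metadata[, c("site_id", "lat", "lon")],
                    by = "site_id")
    aggregated <- aggregate_spatial(joined, radius_m = radius_m)
  }

  list(profiles = profiles, capping_report = capping_report,
       calibration = calibration, aggregated = aggregated,
       metadata = metadata)
}

# Paired same-site per-species densities under two methods.
.extract_pairs <- function(fish, target_method) {
  agg <- aggregate(list(density = fish$density_g_m2),
                   by = list(site_id = fish$site_id, method = fish$method,
                             species = fish$species, family = fish$family,
                             trophic = fish$trophic), FUN = sum)
  tgt <- agg[agg$method == target_method, ]
  src <- agg[agg$method != target_method, ]
  if (nrow(src) == 0) return(data.frame())
  m <- merge(src, tgt, by = c("site_id", "species", "family", "trophic"),
             suffixes = c("_src", "_tgt"))
  data.frame(species = m$species, family = m$family, trophic = m$trophic,
             density_source = m$density_src, density_target = m$density_tgt,
             stringsAsFactors = FALSE)
}
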