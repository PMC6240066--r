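# Synthetic reef survey generators. Every generator draws sites on the
# fourth-root scale (where regimes are multivariate normal with diagonal
# covariance), clamps negative draws at zero, and raises to the fourth power
# to return raw-scale profiles. Clamping rather than rejection keeps draws
# seed-reproducible and fast.

.draw_component_rows <- function(labels, tc) {
  n <- length(labels)
  d <- ncol(tc$mu)
  yt <- matrix(rnorm(n * d), n, d) * tc$sd[labels, , drop = FALSE] +
    tc$mu[labels, , drop = FALSE]
  yt[yt < 0] <- 0
  raw <- yt^4
  dimnames(raw) <- list(NULL, colnames(tc$mu))
  raw
}

.island_centers <- function() {
  data.frame(
    island = c("Hawaii", "Maui", "Kahoolawe", "Lanai", "Molokai", "Oahu",
               "Kauai", "Niihau"),
    lat = c(19.6, 20.8, 20.55, 20.83, 21.13, 21.48, 22.05, 21.9),
    lon = c(-155.5, -156.3, -156.6, -156.92, -157.0, -157.97, -159.5, -160.15)
  )
}

# Site metadata: island + jittered coordinates, shore direction, depth and
# habitat complexity. When the config is the packaged five-regime
# parameterization-compatible (K == 5), shore/depth/complexity are drawn from
# the per-regime reference summaries; otherwise generic ranges are used.
.draw_metadata <- function(site_id, labels, config) {
  n <- length(site_id)
  ic <- .island_centers()
  island_idx <- sample.int(nrow(ic), n, replace = TRUE)
  lat <- ic$lat[island_idx] + runif(n, -0.15, 0.15)
  lon <- ic$lon[island_idx] + runif(n, -0.15, 0.15)
  if (config$K == 5L) {
    ref <- .reference_regimes()
    shore <- vapply(labels, function(k)
      sample(rownames(ref$shore), 1L, prob = ref$shore[, k]), character(1))
    nref <- ref$n_sites[labels]
    depth <- rnorm(n, ref$depth["mean", labels],
                   ref$depth["se", labels] * sqrt(nref))
    cmplx <- rnorm(n, ref$complexity["mean", labels],
                   ref$complexity["se", labels] * sqrt(nref))
  } else {
    shore <- sample(c("N", "E", "S", "W"), n, replace = TRUE)
    depth <- runif(n, 3, 25)
    cmplx <- runif(n, 2, 18)
  }
  data.frame(
    site_id = site_id,
    island = ic$island[island_idx],
    lat = lat, lon = lon,
    shore_direction = shore,
    depth_m = pmin(pmax(depth, 1), 30),
    complexity = pmax(cmplx, 0.5),
    pop_density = runif(n),
    dhw = runif(n),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic functional profiles with known regime labels
#'
#' Draws \code{config$n_sites} sites from the K-component mixture implied by
#' the configuration: labels from the mixing weights, then the ten
#' functional-group values from that regime's diagonal-normal component on
#' the fourth-root scale (negative draws clamped at zero), returned on the
#' raw scale (percent cover / g m^-2). Ground truth (regime label and the
#' two scaled driver values per site) is returned separately and is never
#' consumed by analysis stages.
#'
#' @param config A \code{\link{generator_config}}.
#' @return List with elements \code{profiles} (site_id + 10 functional-group
#'   columns), \code{truth} (site_id, regime, pop_density, dhw), and
#'   \code{metadata} (island, coordinates, shore direction, depth,
#'   complexity, drivers).
#' @examples
#' sim <- generate_profiles(default_generator_config(n_sites = 50, seed = 3))
#' table(sim$truth$regime)
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_sites
  g <- functional_groups()
  if (n == 0L) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), 10), g))
    empty <- cbind(data.frame(site_id = character(0)), empty)
    return(list(profiles = empty,
                truth = data.frame(site_id = character(0),
                                   regime = integer(0),
                                   pop_density = numeric(0),
                                   dhw = numeric(0)),
                metadata = data.frame(site_id = character(0))))
  }
  set.seed(config$seed)
  labels <- sample.int(config$K, n, replace = TRUE,
                       prob = config$regime_weights)
  tc <- .transformed_components(config)
  raw <- .draw_component_rows(labels, tc)
  site_id <- sprintf("S%05d", seq_len(n))
  metadata <- .draw_metadata(site_id, labels, config)
  list(
    profiles = cbind(data.frame(site_id = site_id, stringsAsFactors = FALSE),
                     as.data.frame(raw)),
    truth = data.frame(site_id = site_id, regime = labels,
                       pop_density = metadata$pop_density,
                       dhw = metadata$dhw, stringsAsFactors = FALSE),
    metadata = metadata
  )
}

# Decompose one group biomass (g m^-2) into itemized observations for the
# species of that group so that sum(a * TL^b * count) / area reproduces the
# biomass exactly: integer counts at a drawn length plus one closing
# individual whose length absorbs the remainder.
.decompose_group <- function(site_id, biomass, area, sp) {
  if (biomass <= 0) return(NULL)
  mass <- biomass * area
  n_sp <- nrow(sp)
  shares <- runif(n_sp, 0.5, 1.5)
  shares <- shares / sum(shares)
  out <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    m_i <- mass * shares[i]
    tl <- sp$typical_tl_cm[i] * exp(rnorm(1, 0, 0.15))
    w1 <- sp$a[i] * tl^sp$b[i]
    cnt <- floor(m_i / w1)
    rows <- list()
    if (cnt > 0)
      rows[[1]] <- data.frame(site_id = site_id, species = sp$species[i],
                              count = cnt, length_cm = tl)
    rem <- m_i - cnt * w1
    if (rem > 1e-9) {
      tl_rem <- (rem / sp$a[i])^(1 / sp$b[i])
      rows[[length(rows) + 1]] <-
        data.frame(site_id = site_id, species = sp$species[i],
                   count = 1, length_cm = tl_rem)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Decompose synthetic profiles into itemized survey records
#'
#' Expands each functional profile into the raw records a field program would
#' produce: per-species fish observations (species, count, total length,
#' survey area) whose summed length-weight biomass reproduces the profile's
#' group biomasses, and per-category benthic cover lines. All primary
#' surveys carry the target method label; a random subset of sites is
#' re-surveyed under a second method with counts multiplied by a known bias
#' factor, providing a paired-method calibration subset. Optionally a
#' fraction of sites receives a planted extreme schooling count (flagged in
#' the output, ignored by analysis) to exercise outlier capping.
#'
#' @param profiles Profile data.frame from \code{\link{generate_profiles}}.
#' @param config The \code{\link{generator_config}} used (supplies the seed).
#' @param area_m2 Survey area per site.
#' @param calibration_fraction Fraction of sites surveyed under both methods.
#' @param calibration_bias Multiplicative count bias of the second method.
#' @param outlier_fraction Fraction of sites receiving a planted extreme
#'   schooling count.
#' @param target_method,alt_method Method labels.
#' @return List with \code{fish} (site_id, method, species, count, length_cm,
#'   area_m2, planted_outlier) and \code{benthic} (site_id, method, category,
#'   percent_cover).
#' @export
generate_surveys <- function(profiles, config,
                             area_m2 = 100,
                             calibration_fraction = 0.15,
                             calibration_bias = 2,
                             outlier_fraction = 0,
                             target_method = "belt-transect",
                             alt_method = "stationary-count") {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  g <- functional_groups()
  if (any(as.matrix(profiles[, g]) < 0))
    stop("profiles contain negative entries")
  set.seed(config$seed + 1L)
  sp_all <- species_lookup()
  excl <- exclusion_list()$species
  sp_all <- sp_all[!sp_all$species %in% excl, ]
  fish <- vector("list", nrow(profiles))
  for (r in seq_len(nrow(profiles))) {
    sid <- profiles$site_id[r]
    rows <- lapply(.fish_groups(), function(grp)
      .decompose_group(sid, profiles[r, grp], area_m2,
                       sp_all[sp_all$functional_group == grp, ]))
    fish[[r]] <- do.call(rbind, rows)
  }
  fish <- do.call(rbind, fish)
  fish$method <- target_method
  fish$area_m2 <- area_m2
  fish$planted_outlier <- FALSE

  if (outlier_fraction > 0) {
    school <- sp_all$species[sp_all$schooling]
    hit <- which(runif(nrow(profiles)) < outlier_fraction)
    if (length(hit)) {
      extra <- data.frame(
        site_id = profiles$site_id[hit],
        species = sample(school, length(hit), replace = TRUE),
        count = round(runif(length(hit), 2000, 10000)),
        length_cm = 8, method = target_method, area_m2 = area_m2,
        planted_outlier = TRUE, stringsAsFactors = FALSE)
      fish <- rbind(fish, extra)
    }
  }

  n_cal <- floor(calibration_fraction * nrow(profiles))
  if (n_cal > 0) {
    cal_sites <- sample(profiles$site_id, n_cal)
    cal <- fish[fish$site_id %in% cal_sites & !fish$planted_outlier, ]
    cal$method <- alt_method
    cal$count <- cal$count * calibration_bias
    fish <- rbind(fish, cal)
  }
  rownames(fish) <- NULL

  benthic <- data.frame(
    site_id = rep(profiles$site_id, each = 5),
    method = "photoquadrat",
    category = rep(c("hard_coral", "macroalgae", "other", "turf_algae",
                     "cca"), nrow(profiles)),
    percent_cover = as.numeric(t(as.matrix(
      profiles[, c("coral", "macroalgae", "other_cover", "turf", "cca")]))),
    stringsAsFactors = FALSE)

  list(fish = fish[, c("site_id", "method", "species", "count", "length_cm",
                       "area_m2", "planted_outlier")],
       benthic = benthic)
}

#' Generate a longitudinal regime time series with driver-dependent dynamics
#'
#' Per site, a regime sequence follows a first-order Markov chain: at each
#' step the baseline kernel row (log scale) is shifted by
#' \code{driver_slopes[[d]][i, j] * driver_d} for each driver and
#' renormalized, so positive slopes make the i-to-j transition more likely at
#' high driver values. A functional profile is drawn from the occupied
#' regime's component for every site-year.
#'
#' @param config A \code{\link{generator_config}} with \code{n_years >= 2}.
#' @return List with \code{profiles} (site_id, year, 10 group columns) and
#'   \code{truth} (site_id, year, regime, pop_density, dhw).
#' @export
generate_time_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_years < 2L) stop("n_years must be >= 2 for a time series")
  set.seed(config$seed + 2L)
  n <- config$n_sites
  K <- config$K
  yrs <- seq_len(config$n_years)
  site_id <- sprintf("S%05d", seq_len(n))
  drivers <- data.frame(pop_density = runif(n), dhw = runif(n))
  used <- intersect(names(config$driver_slopes), names(drivers))

  states <- matrix(0L, n, config$n_years)
  states[, 1] <- sample.int(K, n, replace = TRUE,
                            prob = config$regime_weights)
  for (t in seq_len(config$n_years - 1L)) {
    for (s in seq_len(n)) {
      i <- states[s, t]
      logp <- log(config$transition_kernel[i, ])
      for (d in used)
        logp <- logp + config$driver_slopes[[d]][i, ] * drivers[[d]][s]
      p <- exp(logp - max(logp[is.finite(logp)]))
      p[!is.finite(p)] <- 0
      states[s, t + 1L] <- sample.int(K, 1L, prob = p / sum(p))
    }
  }

  labels <- as.integer(t(states))
  tc <- .transformed_components(config)
  raw <- .draw_component_rows(labels, tc)
  profiles <- cbind(
    data.frame(site_id = rep(site_id, each = config$n_years),
               year = rep(yrs, n), stringsAsFactors = FALSE),
    as.data.frame(raw))
  truth <- data.frame(
    site_id = profiles$site_id, year = profiles$year, regime = labels,
    pop_density = rep(drivers$pop_density, each = config$n_years),
    dhw = rep(drivers$dhw, each = config$n_years),
    stringsAsFactors = FALSE)
  list(profiles = profiles, truth = truth)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes survey and profile tables as comma-separated UTF-8 text with a
#' header row, the generator configuration as YAML, and the ground truth as
#' a separate CSV that analysis stages never read.
#'
#' @param sim Output of \code{\link{generate_profiles}} (optionally with
#'   \code{surveys} from \code{\link{generate_surveys}} attached).
#' @param config The \code{\link{generator_config}} used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    p
  }
  paths <- c(paths, wr(sim$profiles, "profiles.csv"))
  if (!is.null(sim$metadata)) paths <- c(paths, wr(sim$metadata, "metadata.csv"))
  if (!is.null(sim$truth)) paths <- c(paths, wr(sim$truth, "ground_truth.csv"))
  if (!is.null(sim$surveys)) {
    paths <- c(paths, wr(sim$surveys$fish, "fish.csv"),
               wr(sim$surveys$benthic, "benthic.csv"))
  }
  cfg <- config
  cfg$regime_means <- as.data.frame(cfg$regime_means)
  cfg$regime_sds <- as.data.frame(cfg$regime_sds)
  cfg$transition_kernel <- as.data.frame(cfg$transition_kernel)
  cfg$driver_slopes <- lapply(cfg$driver_slopes, as.data.frame)
  yaml_path <- file.path(dir, "generator_config.yaml")
  yaml::write_yaml(unclass(cfg), yaml_path)
  invisible(c(paths, yaml_path))
}
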