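#' Names of the ten functional-group variables
#'
#' Order is fixed throughout the package: five benthic cover groups (percent)
#' followed by five fish biomass groups (g m^-2).
#'
#' @return Character vector of length 10.
#' @export
functional_groups <- function() {
  c("coral", "macroalgae", "other_cover", "turf", "cca",
    "browsers", "grazers", "scrapers", "predators", "secondary")
}

.benthic_groups <- function() functional_groups()[1:5]
.fish_groups    <- function() functional_groups()[6:10]

# Reference five-regime parameterization for Hawaiian forereef communities:
# per-regime means and standard errors of the ten functional groups, regime
# site counts, plus seascape covariates (depth, habitat complexity, shore
# direction composition) used to decorate synthetic site metadata.
.reference_regimes <- function() {
  g <- functional_groups()
  means <- rbind(
    c(5.8, 10.3, 13.0, 65.6, 3.5, 1.0, 5.1, 1.1, 0.0, 7.5),
    c(9.8, 10.4, 5.4, 64.7, 7.2, 20.5, 25.4, 15.1, 9.7, 27.0),
    c(26.0, 0.0, 5.5, 60.3, 6.5, 5.2, 16.5, 11.8, 8.7, 23.4),
    c(23.5, 13.0, 22.6, 31.9, 5.0, 3.1, 12.2, 12.6, 8.3, 28.9),
    c(31.1, 6.2, 9.6, 43.0, 8.1, 3.9, 11.7, 10.6, 4.1, 19.3))
  ses <- rbind(
    c(0.5, 0.9, 1.0, 1.4, 0.4, 0.2, 0.7, 0.2, 0.0, 0.5),
    c(0.5, 0.6, 0.4, 0.9, 0.4, 3.4, 2.1, 1.5, 1.5, 1.8),
    c(1.4, 0.0, 0.7, 1.6, 0.5, 1.0, 1.9, 1.4, 1.5, 1.5),
    c(1.6, 1.5, 1.8, 1.9, 0.7, 0.7, 1.6, 1.7, 1.1, 3.8),
    c(1.0, 0.4, 0.6, 1.0, 0.4, 0.3, 0.7, 0.7, 0.3, 0.7))
  dimnames(means) <- dimnames(ses) <- list(paste0("regime", 1:5), g)
  n_sites <- c(205L, 250L, 158L, 200L, 214L)
  depth <- rbind(mean = c(8.8, 11.4, 8.3, 10.2, 9.6),
                 se   = c(0.5, 0.4, 0.4, 0.5, 0.3))
  complexity <- rbind(mean = c(6.5, 12.1, 10.7, 10.3, 13.5),
                      se   = c(0.4, 0.4, 0.5, 0.5, 0.5))
  shore <- rbind(N = c(13.7, 41.6, 4.4, 13.0, 6.1),
                 E = c(23.9, 22.0, 3.8, 21.5, 21.0),
                 S = c(37.6, 12.8, 22.2, 37.0, 11.7),
                 W = c(24.9, 23.6, 69.6, 28.5, 61.2))
  list(means = means, ses = ses, n_sites = n_sites,
       depth = depth, complexity = complexity, shore = shore)
}

#' Create a synthetic-data generator configuration
#'
#' Bundles and validates everything the generators need: per-regime raw-scale
#' means and standard deviations of the ten functional groups, mixing
#' weights, and (for longitudinal designs) a transition kernel with optional
#' per-transition driver effects on the log-odds scale.
#'
#' Sites are drawn on the fourth-root scale, where each regime is a
#' multivariate normal with diagonal covariance; raw-scale standard
#' deviations are mapped to that scale by the delta method
#' (\code{sd_t = sd_raw * m^(-3/4) / 4}) with a floor of \code{sd_floor} so
#' regimes with a zero mean (e.g. total macroalgae absence) remain proper
#' components.
#'
#' @param n_sites Number of sites to generate.
#' @param regime_means K x 10 matrix of raw-scale regime means (percent cover
#'   for the five benthic columns, g m^-2 for the five fish columns).
#' @param regime_sds K x 10 matrix of raw-scale standard deviations.
#' @param regime_weights K-vector of mixing proportions (sums to 1).
#' @param n_years Number of survey years for longitudinal designs.
#' @param transition_kernel K x K row-stochastic baseline transition matrix.
#'   Default: sticky kernel with 0.8 self-transition probability.
#' @param driver_slopes Named list of K x K matrices of log-odds slopes, one
#'   per driver (default two all-zero drivers, \code{pop_density} and
#'   \code{dhw}). Entry (i, j) shifts the log-probability of the i to j
#'   transition by \code{slope * driver} before row renormalization.
#' @param sd_floor Minimum fourth-root-scale standard deviation.
#' @param seed Integer seed recorded in the config; generators reset the RNG
#'   from it.
#' @return A \code{generator_config} list.
#' @seealso \code{\link{default_generator_config}} for the packaged
#'   five-regime Hawaiian parameterization.
#' @export
generator_config <- function(n_sites,
                             regime_means,
                             regime_sds,
                             regime_weights,
                             n_years = 1L,
                             transition_kernel = NULL,
                             driver_slopes = NULL,
                             sd_floor = 0.05,
                             seed = 1L) {
  regime_means <- as.matrix(regime_means)
  regime_sds <- as.matrix(regime_sds)
  K <- nrow(regime_means)
  if (ncol(regime_means) != 10L)
    stop("regime_means: expected 10 functional-group columns, got ",
         ncol(regime_means))
  if (!identical(dim(regime_sds), dim(regime_means)))
    stop("regime_sds: dimensions must match regime_means")
  if (any(regime_means < 0)) stop("regime_means: all means must be >= 0")
  if (any(regime_sds < 0)) stop("regime_sds: all SDs must be >= 0")
  if (length(regime_weights) != K)
    stop("regime_weights: length must equal nrow(regime_means)")
  if (any(regime_weights < 0) || abs(sum(regime_weights) - 1) > 1e-9)
    stop("regime_weights: must be non-negative and sum to 1 (got sum = ",
         format(sum(regime_weights)), ")")
  if (is.null(transition_kernel)) {
    transition_kernel <- matrix((1 - 0.8) / max(K - 1, 1), K, K)
    diag(transition_kernel) <- if (K == 1) 1 else 0.8
  }
  transition_kernel <- as.matrix(transition_kernel)
  if (!identical(dim(transition_kernel), c(K, K)))
    stop("transition_kernel: must be ", K, " x ", K)
  if (any(transition_kernel < 0) ||
      any(abs(rowSums(transition_kernel) - 1) > 1e-9))
    stop("transition_kernel: rows must be non-negative and sum to 1")
  if (is.null(driver_slopes))
    driver_slopes <- list(pop_density = matrix(0, K, K),
                          dhw = matrix(0, K, K))
  if (!is.list(driver_slopes) || is.null(names(driver_slopes)))
    stop("driver_slopes: must be a named list of K x K matrices")
  for (nm in names(driver_slopes)) {
    driver_slopes[[nm]] <- as.matrix(driver_slopes[[nm]])
    if (!identical(dim(driver_slopes[[nm]]), c(K, K)))
      stop("driver_slopes[['", nm, "']]: must be ", K, " x ", K)
  }
  colnames(regime_means) <- colnames(regime_sds) <- functional_groups()
  structure(list(
    n_sites = as.integer(n_sites),
    K = K,
    regime_means = regime_means,
    regime_sds = regime_sds,
    regime_weights = as.numeric(regime_weights),
    n_years = as.integer(n_years),
    transition_kernel = transition_kernel,
    driver_slopes = driver_slopes,
    sd_floor = sd_floor,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' The packaged five-regime generator configuration
#'
#' Parameterizes the generator from the reference summary of Hawaiian
#' forereef regimes: per-regime means and standard errors of the ten
#' functional groups and per-regime site counts (205, 250, 158, 200, 214;
#' 1,027 sites in total). Raw-scale SDs are reconstructed from the standard
#' errors as \code{se * sqrt(n_regime)}; mixing weights are the site counts
#' normalized to proportions.
#'
#' @param n_sites Total number of sites (default 1027).
#' @param n_years Number of years for longitudinal designs.
#' @param seed Integer seed.
#' @param ... Passed on to \code{\link{generator_config}} (e.g.
#'   \code{transition_kernel}, \code{driver_slopes}).
#' @return A \code{generator_config}.
#' @examples
#' cfg <- default_generator_config(n_sites = 100, seed = 7)
#' sim <- generate_profiles(cfg)
#' head(sim$profiles)
#' @export
default_generator_config <- function(n_sites = 1027L, n_years = 1L,
                                     seed = 1L, ...) {
  ref <- .reference_regimes()
  sds <- ref$ses * sqrt(ref$n_sites)[row(ref$ses)]
  generator_config(
    n_sites = n_sites,
    regime_means = ref$means,
    regime_sds = sds,
    regime_weights = ref$n_sites / sum(ref$n_sites),
    n_years = n_years,
    seed = seed,
    ...
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic reef-survey generator configuration\n")
  cat("  regimes (K):", x$K, " sites:", x$n_sites,
      " years:", x$n_years, " seed:", x$seed, "\n")
  cat("  mixing weights:", paste(signif(x$regime_weights, 3),
                                 collapse = ", "), "\n")
  invisible(x)
}

# Fourth-root-scale component parameters implied by a config (delta method
# with SD floor). Returns list(mu, sd): K x 10 each.
.transformed_components <- function(config) {
  m <- config$regime_means
  s <- config$regime_sds
  sd_t <- s * ifelse(m > 0, m^(-3 / 4), 0) / 4
  sd_t[m == 0] <- config$sd_floor
  sd_t <- pmax(sd_t, config$sd_floor)
  list(mu = m^(1 / 4), sd = sd_t)
}
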