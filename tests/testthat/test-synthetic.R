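test_that("generator config validation names the offending field", {
  m <- matrix(5, 2, 10)
  s <- matrix(1, 2, 10)
  expect_error(generator_config(10, m, s, c(0.6, 0.6)), "regime_weights")
  expect_error(generator_config(10, m, s, c(0.5, 0.5),
                                transition_kernel = matrix(1, 2, 2)),
               "transition_kernel")
  expect_error(generator_config(10, -m, s, c(0.5, 0.5)), "regime_means")
  expect_error(generator_config(10, m[, 1:4], s[, 1:4], c(0.5, 0.5)),
               "10 functional-group")
})

test_that("empty designs yield empty tables", {
  cfg <- default_generator_config(n_sites = 0)
  sim <- generate_profiles(cfg)
  expect_equal(nrow(sim$profiles), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_named(sim$profiles, c("site_id", fg))
})

test_that("a degenerate one-component mixture with zero spread is a point mass", {
  m <- matrix(c(16, 1, 4, 25, 9, 1, 16, 4, 9, 1), 1, 10)
  cfg <- generator_config(12, m, matrix(0, 1, 10), 1, sd_floor = 0)
  sim <- generate_profiles(cfg)
  expect_equal(nrow(unique(sim$profiles[, fg])), 1)
  expect_equal(unname(as.numeric(sim$profiles[1, fg])), as.numeric(m),
               tolerance = 1e-12)
})

test_that("default parameterization reproduces the reference structure", {
  cfg <- default_generator_config(seed = 1)
  sim <- generate_profiles(cfg)
  expect_equal(nrow(sim$profiles), 1027)
  # component means on the fourth-root scale sit within 3 transformed-scale
  # SEs of their targets (the generator's sampling contract)
  tc <- reefregimes:::.transformed_components(cfg)
  for (k in 1:5) {
    rows <- sim$truth$regime == k
    emp <- colMeans(as.matrix(sim$profiles[rows, fg])^(1 / 4))
    se_t <- tc$sd[k, ] / sqrt(sum(rows))
    # clamping at zero shifts high-variance cells up slightly; allow its
    # analytic magnitude on top of 3 SEs
    clamp_shift <- tc$sd[k, ] * dnorm(tc$mu[k, ] / tc$sd[k, ]) +
      tc$mu[k, ] * (pnorm(tc$mu[k, ] / tc$sd[k, ]) - 1)
    expect_true(all(abs(emp - tc$mu[k, ]) <= 3 * se_t + clamp_shift + 1e-9),
                info = paste("component", k))
  }
  # the low-variance showcase cell: raw-scale coral mean of component 5
  emp5 <- mean(sim$profiles$coral[sim$truth$regime == 5])
  expect_lt(abs(emp5 - 31.1), 3 * 1)
  # raw-scale outputs are never negative
  expect_true(all(as.matrix(sim$profiles[, fg]) >= 0))
})

test_that("mixing proportions converge to the configured weights", {
  cfg <- default_generator_config(n_sites = 10000, seed = 8)
  sim <- generate_profiles(cfg)
  w <- cfg$regime_weights
  emp <- tabulate(sim$truth$regime, 5) / 10000
  for (k in 1:5) {
    ci <- wilson_ci(sum(sim$truth$regime == k), 10000, level = 0.999)
    expect_true(w[k] >= ci$lower && w[k] <= ci$upper,
                info = paste("weight", k))
  }
  expect_equal(emp, w, tolerance = 0.05)
})

test_that("a fixed seed reproduces tables bit-identically", {
  cfg <- default_generator_config(n_sites = 50, seed = 77)
  a <- generate_profiles(cfg)
  b <- generate_profiles(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)
  sa <- generate_surveys(a$profiles, cfg)
  sb <- generate_surveys(b$profiles, cfg)
  expect_identical(sa$fish, sb$fish)
  ta <- generate_time_series(default_generator_config(n_sites = 20,
                                                      n_years = 4, seed = 7))
  tb <- generate_time_series(default_generator_config(n_sites = 20,
                                                      n_years = 4, seed = 7))
  expect_identical(ta$profiles, tb$profiles)
})

test_that("survey decomposition reproduces profile biomasses and plants a known method bias", {
  cfg <- default_generator_config(n_sites = 30, seed = 21)
  sim <- generate_profiles(cfg)
  sv <- generate_surveys(sim$profiles, cfg, calibration_bias = 2)
  expect_error(generate_surveys(transform(sim$profiles, coral = -1), cfg),
               "negative")
  # no planted outliers by default
  expect_false(any(sv$fish$planted_outlier))
  # per-site, per-group biomass from the length-weight law matches the
  # profile cell (target method only)
  lu <- species_lookup()
  tgt <- sv$fish[sv$fish$method == "belt-transect", ]
  tgt <- compute_biomass(tgt, lu)
  tgt$group <- lu$functional_group[match(tgt$species, lu$species)]
  agg <- aggregate(density_g_m2 ~ site_id + group, data = tgt, FUN = sum)
  for (i in seq_len(nrow(agg))) {
    want <- sim$profiles[sim$profiles$site_id == agg$site_id[i],
                         agg$group[i]]
    expect_equal(agg$density_g_m2[i], want, tolerance = 1e-6)
  }
  # paired subset carries the planted 2x density ratio exactly
  alt <- sv$fish[sv$fish$method == "stationary-count", ]
  expect_gt(nrow(alt), 0)
  key <- function(d) paste(d$site_id, d$species, d$length_cm)
  m <- match(key(alt), key(tgt))
  expect_true(all(abs(alt$count / tgt$count[m] - 2) < 1e-12))
})

test_that("planted extreme schooling counts are flagged and extreme", {
  cfg <- default_generator_config(n_sites = 60, seed = 31)
  sim <- generate_profiles(cfg)
  sv <- generate_surveys(sim$profiles, cfg, outlier_fraction = 0.2)
  fl <- sv$fish$planted_outlier
  expect_gt(sum(fl), 0)
  q999 <- quantile(sv$fish$count[!fl], 0.999, type = 7)
  expect_true(all(sv$fish$count[fl] > q999))
})

test_that("time series follow the configured Markov kernel", {
  # identity kernel: absorbing states, constant sequences
  cfg <- generator_config(25, matrix(10, 3, 10), matrix(1, 3, 10),
                          rep(1 / 3, 3), n_years = 5,
                          transition_kernel = diag(3), seed = 3)
  ts <- generate_time_series(cfg)
  per_site <- tapply(ts$truth$regime, ts$truth$site_id,
                     function(r) length(unique(r)))
  expect_true(all(per_site == 1))
  expect_error(generate_time_series(
    generator_config(5, matrix(10, 3, 10), matrix(1, 3, 10), rep(1 / 3, 3),
                     n_years = 1)), "n_years")

  # uniform kernel: empirical transition frequencies near 1/K
  K <- 3
  cfg2 <- generator_config(400, matrix(10, K, 10), matrix(1, K, 10),
                           rep(1 / K, K), n_years = 6,
                           transition_kernel = matrix(1 / K, K, K),
                           seed = 12)
  ts2 <- generate_time_series(cfg2)
  tr <- ts2$truth[order(ts2$truth$site_id, ts2$truth$year), ]
  from <- tr$regime[-nrow(tr)][diff(as.integer(factor(tr$site_id))) == 0]
  to <- tr$regime[-1][diff(as.integer(factor(tr$site_id))) == 0]
  for (i in seq_len(K)) for (j in seq_len(K)) {
    n_i <- sum(from == i)
    ci <- wilson_ci(sum(from == i & to == j), n_i, level = 0.999)
    expect_true(1 / K >= ci$lower && 1 / K <= ci$upper,
                info = paste(i, "->", j))
  }
})

test_that("driver slopes shift transition odds in the planted direction", {
  K <- 2
  slopes <- list(pop_density = matrix(c(0, 2, 0, 0), K, K, byrow = TRUE),
                 dhw = matrix(0, K, K))
  cfg <- generator_config(600, matrix(10, K, 10), matrix(1, K, 10),
                          c(1, 0), n_years = 6,
                          transition_kernel = matrix(0.5, K, K),
                          driver_slopes = slopes, seed = 9)
  ts <- generate_time_series(cfg)
  tr <- ts$truth[order(ts$truth$site_id, ts$truth$year), ]
  same_site <- diff(as.integer(factor(tr$site_id))) == 0
  from <- tr$regime[-nrow(tr)][same_site]
  to <- tr$regime[-1][same_site]
  drv <- tr$pop_density[-nrow(tr)][same_site]
  hi <- drv > 0.5 & from == 1
  lo <- drv <= 0.5 & from == 1
  # logistic oracle: slope +2 on 1->2 makes the 1->2 rate strictly higher in
  # the high-driver half
  expect_gt(mean(to[hi] == 2), mean(to[lo] == 2))
})

test_that("synthetic datasets round-trip through delimited text", {
  cfg <- default_generator_config(n_sites = 12, seed = 5)
  sim <- generate_profiles(cfg)
  sim$surveys <- generate_surveys(sim$profiles, cfg)
  dir <- tempfile("synthdata")
  paths <- write_synthetic_dataset(sim, cfg, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "profiles.csv"))
  expect_equal(back[, fg], sim$profiles[, fg], tolerance = 1e-12)
  cfg_back <- yaml::read_yaml(file.path(dir, "generator_config.yaml"))
  expect_equal(cfg_back$seed, cfg$seed)
})
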