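test_that("length-weight biomass follows W = a TL^b", {
  params <- data.frame(species = c("sp1", "sp2"),
                       a = c(0.01, 0.02), b = c(3, 2.9))
  obs <- data.frame(species = c("sp1", "sp1", "sp2"),
                    count = c(1, 5, 3),
                    length_cm = c(10, 0, 23.5),
                    area_m2 = 100)
  out <- compute_biomass(obs, params)
  expect_equal(out$weight_g[1], 10)          # 0.01 * 10^3
  expect_equal(out$weight_g[2], 0)           # zero length, zero mass
  expect_equal(out$weight_g[3], 567.868855907248, tolerance = 1e-12)
  expect_equal(out$density_g_m2, out$weight_g / 100)
  expect_error(compute_biomass(
    data.frame(species = "ghost", count = 1, length_cm = 5, area_m2 = 1),
    params), "ghost")
  # strictly increasing in TL for b > 0
  tls <- seq(1, 60, by = 1)
  w <- compute_biomass(
    data.frame(species = "sp1", count = 1, length_cm = tls, area_m2 = 1),
    params)$weight_g
  expect_true(all(diff(w) > 0))
})

test_that("exclusion filtering removes exactly the planted biomass", {
  lu <- species_lookup()
  obs <- data.frame(
    species = c("Naso unicornis", "Manta birostris", "Scarus psittacus"),
    count = c(2, 1, 4), length_cm = c(30, 250, 20), area_m2 = 100)
  none <- filter_exclusions(obs, data.frame(species = character(0)))
  expect_equal(none$species, obs$species)
  expect_equal(attr(none, "n_removed"), 0L)
  out <- filter_exclusions(obs, quiet = TRUE)
  expect_false("Manta birostris" %in% out$species)
  expect_equal(attr(out, "n_removed"), 1L)
  full <- sum(compute_biomass(obs, lu)$weight_g)
  kept <- sum(compute_biomass(out, lu)$weight_g)
  manta <- compute_biomass(obs[2, ], lu)$weight_g
  expect_equal(full - kept, manta)
})

test_that("outlier capping follows the two-step quantile rule and is idempotent", {
  # all counts equal: nothing flagged, nothing changed
  eq <- data.frame(species = rep(c("a", "b"), each = 10), count = 5)
  expect_equal(cap_outliers(eq)$observations$count, rep(5, 20))

  # planted extreme among benign counts: adjusted to the species' 99.0%
  # quantile of the pre-capping distribution (type-7 oracle)
  set.seed(4)
  counts_a <- sample(1:50, 400, replace = TRUE)
  obs <- data.frame(species = c(rep("a", 400), rep("b", 300)),
                    count = c(counts_a, sample(1:30, 300, replace = TRUE)))
  obs$count[1] <- 10000
  capped <- cap_outliers(obs)
  expect_equal(capped$observations$count[1], unname(
    quantile(obs$count[obs$species == "a"], 0.99, type = 7)))
  # capping never increases counts, never touches unflagged species
  expect_true(all(capped$observations$count <= obs$count))
  expect_equal(capped$observations$count[obs$species == "b"],
               obs$count[obs$species == "b"])
  # re-applying the stored thresholds is a fixed point
  again <- cap_outliers(capped$observations, thresholds = capped$thresholds)
  expect_identical(again$observations$count, capped$observations$count)
  expect_true(all(capped$report$n_adjusted >= 1))
})

test_that("calibration decision cascade: species, pooled, delta and global scopes", {
  mk <- function(n, sp, fam = "F1", tro = "T1", bias = 1, noise = 0,
                 zeros = 0, seed = 1) {
    set.seed(seed)
    src <- runif(n, 1, 10)
    src[seq_len(floor(zeros * n))] <- 0
    tgt <- bias * src + rnorm(n, 0, noise)
    data.frame(species = rep(sp, n), family = rep(fam, n),
               trophic = rep(tro, n),
               density_source = src, density_target = pmax(tgt, 0))
  }
  expect_error(derive_calibration(mk(0, "s")), "paired")

  # identical densities, n = 12: species factor ~ 1
  p1 <- mk(12, "s1")
  f1 <- suppressMessages(derive_calibration(p1))
  expect_equal(f1$factor[f1$scope == "species" & f1$key == "s1"], 1,
               tolerance = 1e-9)

  # planted 2x bias with noise, n = 20: factor ~ 2 (least-squares oracle)
  p2 <- mk(20, "s2", bias = 2, noise = 0.1, seed = 2)
  f2 <- suppressMessages(derive_calibration(p2))
  got <- f2$factor[f2$scope == "species" & f2$key == "s2"]
  want <- unname(coefficients(lm(density_target ~ density_source + 0,
                                 data = p2))[1])
  expect_equal(got, want, tolerance = 1e-10)
  expect_lt(abs(got - 2), 0.05)

  # n = 9 pairs: species-level factor absent, family x trophic emitted
  p3 <- rbind(mk(9, "s3", noise = 0.05, seed = 3),
              mk(11, "s4", noise = 0.05, seed = 4))
  f3 <- suppressMessages(derive_calibration(p3))
  expect_false("s3" %in% f3$key[f3$scope == "species"])
  expect_true("F1:T1" %in% f3$key[f3$scope == "family_trophic"])
  expect_true("global" %in% f3$key)

  # zero-dominated pairs trigger the delta model
  p4 <- mk(40, "s5", zeros = 0.7, noise = 0.05, seed = 5)
  f4 <- suppressMessages(derive_calibration(p4))
  expect_equal(f4$model_form[f4$scope == "species" & f4$key == "s5"],
               "delta")
})

test_that("calibration precedence is total and specific-first", {
  factors <- data.frame(
    scope = c("species", "family_trophic", "global"),
    key = c("spA", "F1:T1", "global"),
    factor = c(2, 5, 3), model_form = "linear", n_pairs = 10)
  obs <- data.frame(
    species = c("spA", "spB", "spC"),
    family = c("F1", "F1", "F9"), trophic = c("T1", "T1", "T9"),
    count = c(10, 10, 10))
  out <- apply_calibration(obs, factors)
  expect_equal(out$count, c(20, 50, 30))     # per-row multiplication oracle
  expect_equal(out$calibration_scope,
               c("species", "family_trophic", "global"))
  # identity factors leave observations unchanged
  id <- factors; id$factor <- 1
  expect_equal(apply_calibration(obs, id)$count, obs$count)
  # with no global row, an unmatched observation is an error
  expect_error(apply_calibration(obs, factors[1, , drop = FALSE]), "spB")
})

test_that("spatial aggregation merges by single-linkage chains at 300 m", {
  base <- data.frame(site_id = c("a", "b"), lat = c(21, lat_offset_m(21, 150)),
                     lon = -157.9, coral = c(10, 20))
  one <- aggregate_spatial(base, 300)
  expect_equal(nrow(one), 1)
  expect_equal(one$coral, 15)                # mean of two
  expect_equal(one$n_members, 2)

  apart <- base
  apart$lat[2] <- lat_offset_m(21, 400)
  expect_equal(nrow(aggregate_spatial(apart, 300)), 2)

  # chain A-B 250 m, B-C 250 m (A-C 500 m): single linkage merges all three
  chain <- data.frame(site_id = c("a", "b", "c"),
                      lat = c(21, lat_offset_m(21, 250),
                              lat_offset_m(21, 500)),
                      lon = -157.9, coral = c(1, 2, 3))
  merged <- aggregate_spatial(chain, 300)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$coral, 2)

  # permutation invariance of the grouping
  perm <- chain[c(3, 1, 2), ]
  merged2 <- aggregate_spatial(perm, 300)
  expect_equal(merged2$coral, merged$coral)
  expect_error(aggregate_spatial(data.frame(site_id = "x", lat = NA,
                                            lon = 1, v = 1)),
               "coordinates")
})

test_that("profile assembly maps taxa to the ten groups and flags strangers", {
  lu <- species_lookup()
  fish <- data.frame(site_id = "s1", method = "belt-transect",
                     species = "Ctenochaetus strigosus", count = 2,
                     length_cm = 14, area_m2 = 100)
  fish <- compute_biomass(fish, lu)
  benthic <- data.frame(site_id = "s1", method = "pq",
                        category = c("hard_coral", "macroalgae", "other",
                                     "turf_algae", "cca"),
                        percent_cover = c(20, 20, 20, 20, 20))
  prof <- build_profile_matrix(fish, benthic)
  expect_equal(prof$grazers, fish$density_g_m2)
  expect_equal(unname(as.numeric(prof[1, fg[1:5]])), rep(20, 5))
  expect_equal(prof$browsers + prof$scrapers + prof$predators +
                 prof$secondary, 0)
  bad <- fish; bad$species <- "Unknownus fishus"
  expect_error(build_profile_matrix(bad, benthic), "Unknownus")
  badb <- benthic; badb$category[1] <- "mystery_goo"
  expect_error(build_profile_matrix(fish, badb), "mystery_goo")
})

test_that("fourth-root transform centres, scales and inverts exactly", {
  tr1 <- profile_transform(matrix(c(16, 81), 2, 1))
  expect_equal(as.numeric(tr1$scores * tr1$state$scale + tr1$state$center),
               c(2, 3))                       # 16^(1/4), 81^(1/4)
  set.seed(6)
  X <- matrix(rexp(200), 20, 10)
  tr <- profile_transform(X)
  expect_equal(unname(apply(tr$scores, 2, sd)), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(tr$scores)), rep(0, 10), tolerance = 1e-12)
  back <- profile_inverse_transform(tr$scores, tr$state)
  expect_equal(back, X, tolerance = 1e-10)
  expect_error(profile_transform(matrix(-1, 2, 2)), "negative")
  # constant columns keep scale 1
  Xc <- cbind(X, 7)
  trc <- profile_transform(Xc)
  expect_equal(unname(trc$state$scale[11]), 1)
  expect_true(all(is.finite(trc$scores)))
  expect_error(profile_inverse_transform(tr$scores, NULL), "state")
})

test_that("generated surveys harmonize back to the generator's profiles", {
  cfg <- default_generator_config(n_sites = 35, seed = 14)
  sim <- generate_profiles(cfg)
  sv <- generate_surveys(sim$profiles, cfg)
  h <- suppressMessages(harmonize_surveys(sv$fish, sv$benthic, cap = FALSE))
  p0 <- sim$profiles[order(sim$profiles$site_id), fg]
  p1 <- h$profiles[order(h$profiles$site_id), fg]
  denom <- pmax(as.matrix(p0), 1e-6)
  expect_lt(max(abs(as.matrix(p1) - as.matrix(p0)) / denom), 0.01)
})
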