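# Shared fixtures and independent oracles. Everything is built in code at
# test time; seeds are fixed so assertions are deterministic.

fg <- functional_groups()

# Brute-force posterior responsibilities for a mixture with diagonal or full
# covariances, computed directly from normal densities (independent of the
# package's log-sum-exp E-step).
brute_responsibilities <- function(X, weights, means, covs, structure) {
  n <- nrow(X); K <- length(weights)
  dens <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (grepl("diagonal|spherical", structure)) {
      v <- covs[[k]]
      if (length(v) == 1) v <- rep(v, ncol(X))
      dens[, k] <- apply(X, 1, function(x)
        prod(dnorm(x, means[k, ], sqrt(v))))
    } else {
      S <- covs[[k]]
      Si <- solve(S)
      cst <- 1 / sqrt((2 * pi)^ncol(X) * det(S))
      dens[, k] <- apply(X, 1, function(x) {
        xc <- x - means[k, ]
        cst * exp(-0.5 * drop(t(xc) %*% Si %*% xc))
      })
    }
  }
  w <- sweep(dens, 2, weights, "*")
  w / rowSums(w)
}

# Independent Wilson interval: prop.test without continuity correction (its
# small-count chi-squared warning is irrelevant to the interval itself).
wilson_oracle <- function(k, n, level = 0.95) {
  ci <- suppressWarnings(
    stats::prop.test(k, n, correct = FALSE, conf.level = level))$conf.int
  c(lower = ci[1], upper = ci[2])
}

# Two well-separated Gaussian blobs in 2-D with labels.
two_blobs <- function(n_per = 40, sep = 8, seed = 99) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  list(X = X, labels = rep(1:2, each = n_per))
}

# Minimal site-year prediction table for the transition stage.
prediction_table <- function(site_id, years, regimes, prob = 1) {
  data.frame(site_id = site_id, year = years, regime = regimes,
             probability = prob, stringsAsFactors = FALSE)
}

# Coordinates offset north by a given number of meters (1 deg lat is about
# 111.32 km), for constructing spatial-aggregation fixtures.
lat_offset_m <- function(lat0, meters) lat0 + meters / 111320

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table); avoids depending on clustering packages in most tests.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
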