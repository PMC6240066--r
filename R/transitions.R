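# Regime time series per site, transition frequencies with binomial
# uncertainty, and covariate-dependent transition-probability models.

#' Filter site-year regime predictions for the transition analysis
#'
#' Retains site-years whose most likely regime has membership probability of
#' at least \code{min_prob}, then keeps only sites with at least
#' \code{min_years} retained years.
#'
#' @param predictions data.frame with site_id, year, regime and either a
#'   \code{probability} column (max membership probability) or an
#'   \code{uncertainty} column (1 - probability).
#' @param min_prob Minimum membership probability (default 0.95).
#' @param min_years Minimum retained years per site (default 3).
#' @param quiet Suppress the drop-count message.
#' @return Filtered data.frame; counts dropped at each step in attributes
#'   \code{"n_dropped_prob"} and \code{"n_dropped_years"}.
#' @export
filter_predictions <- function(predictions, min_prob = 0.95, min_years = 3,
                               quiet = FALSE) {
  stopifnot(all(c("site_id", "year", "regime") %in% names(predictions)))
  prob <- if ("probability" %in% names(predictions)) predictions$probability
          else if ("uncertainty" %in% names(predictions))
            1 - predictions$uncertainty
          else stop("predictions need a probability or uncertainty column")
  keep <- prob >= min_prob
  n_prob <- sum(!keep)
  out <- predictions[keep, , drop = FALSE]
  yrs <- table(out$site_id)
  good_sites <- names(yrs)[yrs >= min_years]
  n_years <- sum(!out$site_id %in% good_sites)
  out <- out[out$site_id %in% good_sites, , drop = FALSE]
  if (!quiet)
    message("filter_predictions: dropped ", n_prob,
            " site-year(s) below p = ", min_prob, "; dropped ", n_years,
            " site-year(s) at sites with < ", min_years, " retained years")
  attr(out, "n_dropped_prob") <- n_prob
  attr(out, "n_dropped_years") <- n_years
  out
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval: with \code{p = k/n} and
#' \code{z = qnorm(1 - (1 - level)/2)}, the interval is
#' \code{(p + z^2/2n +/- z sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)},
#' always inside [0, 1] and always containing \code{k/n}. Vectorized over
#' \code{k} and \code{n}.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param level Confidence level.
#' @return data.frame: k, n, estimate, lower, upper.
#' @examples
#' wilson_ci(5, 10)
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("require 0 <= k <= n and n >= 1")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # guard rounding at the boundaries: the interval always contains k/n
  data.frame(k = k, n = n, estimate = p,
             lower = pmin(pmax(0, centre - half), p),
             upper = pmax(pmin(1, centre + half), p))
}

#' Build a regime transition matrix from retained site-year sequences
#'
#' Forms one transition record per pair of successive retained years within
#' each site (by default also across gap years; \code{consecutive_only}
#' restricts to strictly adjacent years), and tabulates K x K counts,
#' row-conditional proportions, overall proportions of the total, and a
#' Wilson 95\% interval per cell on the overall proportion.
#'
#' @param retained Filtered site-year regimes from
#'   \code{\link{filter_predictions}}; optional driver columns
#'   (\code{pop_density}, \code{dhw}) are carried onto the records.
#' @param K Number of regimes (default: maximum observed label).
#' @param consecutive_only Count only year pairs with \code{year_t+1 ==
#'   year_t + 1}.
#' @param level Confidence level for the Wilson intervals.
#' @return \code{transition_matrix}: \code{records} (site_id, year_t,
#'   year_t1, regime_t, regime_t1, drivers), \code{counts},
#'   \code{row_proportions}, \code{overall_proportions}, \code{wilson}
#'   (long-format intervals), \code{n_transitions}.
#' @export
build_transition_matrix <- function(retained, K = NULL,
                                    consecutive_only = FALSE,
                                    level = 0.95) {
  stopifnot(all(c("site_id", "year", "regime") %in% names(retained)))
  drivers <- intersect(c("pop_density", "dhw"), names(retained))
  recs <- lapply(split(retained, retained$site_id), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    if (nrow(s) < 2) return(NULL)
    i <- seq_len(nrow(s) - 1)
    r <- data.frame(site_id = s$site_id[i], year_t = s$year[i],
                    year_t1 = s$year[i + 1], regime_t = s$regime[i],
                    regime_t1 = s$regime[i + 1], stringsAsFactors = FALSE)
    for (d in drivers) r[[d]] <- s[[d]][i]
    if (consecutive_only) r <- r[r$year_t1 == r$year_t + 1, , drop = FALSE]
    r
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (is.null(records) || nrow(records) == 0)
    stop("no transitions: need >= 1 site with >= 2 retained years")
  if (is.null(K)) K <- max(records$regime_t, records$regime_t1)
  counts <- matrix(0L, K, K,
                   dimnames = list(paste0("from_", seq_len(K)),
                                   paste0("to_", seq_len(K))))
  tb <- table(factor(records$regime_t, levels = seq_len(K)),
              factor(records$regime_t1, levels = seq_len(K)))
  counts[] <- as.integer(tb)
  n_tr <- sum(counts)
  rs <- rowSums(counts)
  row_prop <- counts / ifelse(rs > 0, rs, 1)
  row_prop[rs == 0, ] <- NA_real_
  overall <- counts / n_tr
  wil <- wilson_ci(as.vector(counts), n_tr, level = level)
  wil <- cbind(expand.grid(from = seq_len(K), to = seq_len(K)), wil)
  out <- list(records = records, counts = counts,
              row_proportions = row_prop, overall_proportions = overall,
              wilson = wil, n_transitions = n_tr, K = K, level = level)
  class(out) <- "transition_matrix"
  out
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Regime transitions:", x$n_transitions, "transitions among",
      x$K, "regimes\n")
  print(x$counts)
  invisible(x)
}

#' Bayesian binomial model of a transition probability against a driver
#'
#' For records leaving regime \code{from}, models the probability of
#' arriving in regime \code{to} as a Bernoulli outcome with
#' \code{logit p = alpha + beta * driver}, the driver pre-scaled to [0, 1].
#' Priors are weakly informative Normal(0, 2.5^2) on both coefficients; the
#' posterior is sampled by MCMC (JAGS), half of each chain discarded as
#' warm-up. Transitions observed fewer than \code{min_occurrences} times
#' return a skip status rather than a fit.
#'
#' @param records Transition records (from
#'   \code{\link{build_transition_matrix}$records}).
#' @param from,to Regime indices of the transition modelled.
#' @param driver Name of the driver column (values in [0, 1]).
#' @param min_occurrences Minimum number of observed from-to transitions.
#' @param n_chains,n_iter Chains and total draws per chain (half warm-up).
#' @param prior_sd Prior standard deviation for alpha and beta.
#' @param seed RNG seed (each chain is seeded deterministically from it).
#' @return \code{driver_model_result}: status ("ok" or "skipped"), posterior
#'   \code{draws} (alpha, beta), \code{beta_ci} (95\% credible interval),
#'   \code{curve} (fitted probability over the driver range with credible
#'   band), \code{rhat}, counts.
#' @export
fit_driver_model <- function(records, from, to, driver = "pop_density",
                             min_occurrences = 4, n_chains = 4,
                             n_iter = 2000, prior_sd = 2.5, seed = 1) {
  stopifnot(driver %in% names(records))
  sub <- records[records$regime_t == from, , drop = FALSE]
  y <- as.integer(sub$regime_t1 == to)
  x <- sub[[driver]]
  ok <- is.finite(x)
  y <- y[ok]; x <- x[ok]
  res <- list(transition = c(from = from, to = to), driver = driver,
              n = length(y), n_occurrences = sum(y))
  if (sum(y) < min_occurrences) {
    res$status <- "skipped"
    res$reason <- paste0("only ", sum(y), " occurrence(s) of ", from,
                         " -> ", to, "; need >= ", min_occurrences)
    class(res) <- "driver_model_result"
    return(res)
  }
  model_str <- "model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- alpha + beta * x[i]
    }
    alpha ~ dnorm(0, tau)
    beta ~ dnorm(0, tau)
  }"
  inits <- lapply(seq_len(n_chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + i) %% 2147483647L))
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, x = x, N = length(y), tau = 1 / prior_sd^2),
    n.chains = n_chains, inits = inits, quiet = TRUE)
  n_warm <- floor(n_iter / 2)
  update(jm, n_warm, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "beta"), n_iter - n_warm,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  rhat <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE)$psrf[, 1],
    error = function(e) c(alpha = NA_real_, beta = NA_real_))
  grid <- seq(0, 1, length.out = 101)
  curves <- plogis(outer(draws[, "alpha"], rep(1, 101)) +
                     outer(draws[, "beta"], grid))
  res$status <- "ok"
  res$draws <- draws
  res$alpha_mean <- mean(draws[, "alpha"])
  res$beta_mean <- mean(draws[, "beta"])
  res$beta_ci <- unname(quantile(draws[, "beta"], c(0.025, 0.975)))
  res$curve <- data.frame(
    driver = grid,
    p = colMeans(curves),
    lower = apply(curves, 2, quantile, 0.025),
    upper = apply(curves, 2, quantile, 0.975))
  res$rhat <- rhat
  class(res) <- "driver_model_result"
  res
}

#' @export
print.driver_model_result <- function(x, ...) {
  cat("Transition driver model:", x$transition["from"], "->",
      x$transition["to"], "vs", x$driver, "\n")
  if (x$status == "skipped") {
    cat("  skipped:", x$reason, "\n")
  } else {
    cat("  n =", x$n, " occurrences =", x$n_occurrences, "\n")
    cat("  beta =", format(round(x$beta_mean, 3)), " 95% CrI [",
        format(round(x$beta_ci[1], 3)), ",",
        format(round(x$beta_ci[2], 3)), "]\n")
  }
  invisible(x)
}
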