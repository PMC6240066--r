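# Model-based clustering core: multivariate Gaussian mixtures fitted by EM
# with deterministic hierarchical initialization and BIC model selection.
# Six covariance parameterizations span the spherical/diagonal/full x
# equal/varying axes.

#' The six covariance structures available for regime models
#'
#' @return Character vector: spherical-equal, spherical-varying,
#'   diagonal-equal, diagonal-varying, full-equal, full-varying.
#' @export
regime_structures <- function() {
  c("spherical-equal", "spherical-varying", "diagonal-equal",
    "diagonal-varying", "full-equal", "full-varying")
}

.cov_df <- function(structure, K, d) {
  switch(structure,
         "spherical-equal" = 1,
         "spherical-varying" = K,
         "diagonal-equal" = d,
         "diagonal-varying" = K * d,
         "full-equal" = d * (d + 1) / 2,
         "full-varying" = K * d * (d + 1) / 2,
         stop("unknown covariance structure: ", structure))
}

# n x K matrix of per-component log densities.
.log_dens_matrix <- function(X, means, covs, structure) {
  n <- nrow(X); d <- ncol(X); K <- nrow(means)
  out <- matrix(0, n, K)
  c2pi <- d * log(2 * pi)
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2, means[k, ])
    if (grepl("^spherical", structure)) {
      v <- covs[[k]]
      out[, k] <- -0.5 * (c2pi + d * log(v) + rowSums(Xc^2) / v)
    } else if (grepl("^diagonal", structure)) {
      v <- covs[[k]]
      out[, k] <- -0.5 * (c2pi + sum(log(v)) +
                            rowSums(sweep(Xc^2, 2, v, "/")))
    } else {
      L <- chol(covs[[k]])
      q <- backsolve(L, t(Xc), transpose = TRUE)
      out[, k] <- -0.5 * (c2pi + 2 * sum(log(diag(L))) + colSums(q^2))
    }
  }
  out
}

# M-step. Returns list(weights, means, covs, regularized, degenerate) or
# NULL on a collapsed component. A component whose variance in any direction
# falls below 1e-4 of the average column variance is degenerate: the mixture
# likelihood is unbounded along such point-mass solutions, so the fit is
# rejected rather than rescued by the ridge (which only smooths mild
# near-singularity).
.mstep <- function(X, z, structure, ridge_scale) {
  n <- nrow(X); d <- ncol(X); K <- ncol(z)
  rk <- colSums(z)
  if (any(rk < 1e-8)) return(NULL)
  w <- rk / n
  means <- crossprod(z, X) / rk
  ridge <- 1e-6 * ridge_scale
  degen_floor <- 1e-4 * ridge_scale
  degen <- FALSE
  reg <- FALSE
  if (structure %in% c("spherical-equal", "spherical-varying",
                       "diagonal-equal", "diagonal-varying")) {
    vk <- matrix(0, K, d)            # per-component diagonal second moments
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ])
      vk[k, ] <- colSums(z[, k] * Xc^2)
    }
    covs <- switch(structure,
      "diagonal-varying" = lapply(seq_len(K), function(k) vk[k, ] / rk[k]),
      "diagonal-equal" = rep(list(colSums(vk) / n), K),
      "spherical-varying" = lapply(seq_len(K),
                                   function(k) sum(vk[k, ]) / (d * rk[k])),
      "spherical-equal" = rep(list(sum(vk) / (n * d)), K))
    covs <- lapply(covs, function(v) {
      if (any(v < degen_floor)) degen <<- TRUE
      if (any(v < ridge)) { reg <<- TRUE; v <- pmax(v, ridge) }
      v
    })
  } else {
    Wk <- lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2, means[k, ])
      crossprod(sqrt(z[, k]) * Xc)
    })
    covs <- if (structure == "full-equal")
      rep(list(Reduce(`+`, Wk) / n), K)
    else lapply(seq_len(K), function(k) Wk[[k]] / rk[k])
    covs <- lapply(covs, function(S) {
      L <- NULL
      for (try in 0:4) {
        L <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(L)) break
        reg <<- TRUE
        S <- S + diag(ridge * 10^try, d)
      }
      if (is.null(L) || min(diag(L))^2 < degen_floor) degen <<- TRUE
      S
    })
  }
  list(weights = w, means = means, covs = covs, regularized = reg,
       degenerate = degen)
}

#' Hierarchical initialization partition
#'
#' Deterministic agglomerative partition used to start EM: Ward linkage on
#' Euclidean distances, cut at K groups.
#'
#' @param X Numeric matrix (observations x variables).
#' @param K Number of groups; requires \code{nrow(X) >= K}.
#' @return Integer vector of group labels in 1..K.
#' @export
hierarchical_init <- function(X, K) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < K) stop("need at least K = ", K, " observations, got ", n)
  if (K == 1) return(rep(1L, n))
  if (K == n) return(seq_len(n))
  cutree(hclust(dist(X), method = "ward.D2"), k = K)
}

#' Fit a Gaussian mixture with a fixed K and covariance structure
#'
#' EM from a hard-partition initialization (default:
#' \code{\link{hierarchical_init}}). The log-likelihood is non-decreasing
#' across iterations; near-singular covariances receive a diagonal ridge of
#' \code{1e-6 * trace/d} (recorded in \code{$regularized}). Non-convergence
#' within \code{max_iter} flags the model rather than raising.
#'
#' BIC uses the larger-is-better convention
#' \code{BIC = 2 logL - df log(n)}.
#'
#' @param X Numeric matrix of observations (rows) on the transformed scale.
#' @param K Number of components (>= 1).
#' @param structure One of \code{\link{regime_structures}}.
#' @param init Optional integer partition of length \code{nrow(X)}.
#' @param tol Relative log-likelihood change convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A \code{regime_model}: weights, means (K x d), covariances,
#'   loglik, bic, df, convergence metadata and the log-likelihood trace.
#' @export
fit_gmm <- function(X, K, structure = "diagonal-varying", init = NULL,
                    tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  structure <- match.arg(structure, regime_structures())
  n <- nrow(X); d <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (is.null(init)) init <- hierarchical_init(X, K)
  z <- matrix(0, n, K)
  z[cbind(seq_len(n), init)] <- 1
  ridge_scale <- mean(apply(X, 2, var))
  if (!is.finite(ridge_scale) || ridge_scale <= 0) ridge_scale <- 1

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  regularized <- FALSE
  params <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- .mstep(X, z, structure, ridge_scale)
    if (is.null(p) || p$degenerate) {          # collapsed or point-mass
      params <- NULL
      break
    }
    params <- p
    regularized <- regularized || p$regularized
    ld <- .log_dens_matrix(X, p$means, p$covs, structure)
    lr <- sweep(ld, 2, log(p$weights), "+")
    m <- apply(lr, 1, max)
    lse <- m + log(rowSums(exp(lr - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    z <- exp(lr - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (is.null(params)) {
    out <- list(K = K, structure = structure, converged = FALSE,
                loglik = NA_real_, bic = NA_real_, df = NA_real_,
                n_obs = n, d = d, iterations = iter,
                regularized = regularized, loglik_trace = trace,
                failed = TRUE)
    class(out) <- "regime_model"
    return(out)
  }
  ll <- trace[length(trace)]
  df <- (K - 1) + K * d + .cov_df(structure, K, d)
  rownames(params$means) <- paste0("regime", seq_len(K))
  colnames(params$means) <- colnames(X)
  out <- list(
    K = K, structure = structure,
    weights = as.numeric(params$weights),
    means = params$means,
    covariances = params$covs,
    loglik = ll, df = df,
    bic = 2 * ll - df * log(n),
    n_obs = n, d = d, var_names = colnames(X),
    iterations = iter, tol = tol,
    converged = converged, regularized = regularized,
    loglik_trace = trace, failed = FALSE,
    transform_state = NULL)
  class(out) <- "regime_model"
  out
}

#' @export
print.regime_model <- function(x, ...) {
  cat("Gaussian-mixture regime model\n")
  cat("  K =", x$K, " structure =", x$structure,
      " n =", x$n_obs, " d =", x$d, "\n")
  cat("  logL =", format(x$loglik), " df =", x$df,
      " BIC =", format(x$bic), "\n")
  cat("  converged:", x$converged, " iterations:", x$iterations,
      if (isTRUE(x$regularized)) " (covariance ridge applied)" else "", "\n")
  invisible(x)
}

#' Select a regime model by BIC over K and covariance structure
#'
#' Fits every combination of component count and covariance structure and
#' returns the converged fit with the highest BIC (larger-is-better
#' convention) together with the full BIC table.
#'
#' @param X Transformed profile matrix.
#' @param K_range Candidate component counts (default 1..9).
#' @param structures Candidate covariance structures (default all six).
#' @param tol,max_iter Passed to \code{\link{fit_gmm}}.
#' @param transform_state Optional transform state to attach to the selected
#'   model so \code{\link{predict_regime}} can consume raw-scale input.
#' @return List of class \code{regime_selection}: \code{model} (best
#'   \code{regime_model}), \code{bic_table} (K, structure, loglik, df, bic,
#'   converged).
#' @examples
#' sim <- generate_profiles(default_generator_config(n_sites = 120, seed = 2))
#' tr <- profile_transform(sim$profiles[, functional_groups()])
#' sel <- select_regime_model(tr$scores, K_range = 1:3,
#'                            structures = "diagonal-varying")
#' sel$model$K
#' @export
select_regime_model <- function(X, K_range = 1:9,
                                structures = regime_structures(),
                                tol = 1e-6, max_iter = 500L,
                                transform_state = NULL) {
  X <- as.matrix(X)
  fits <- list()
  rows <- list()
  for (K in K_range) {
    init <- if (nrow(X) >= K) hierarchical_init(X, K) else NULL
    for (s in structures) {
      fit <- tryCatch(
        fit_gmm(X, K, s, init = init, tol = tol, max_iter = max_iter),
        error = function(e) NULL)
      ok <- !is.null(fit) && !isTRUE(fit$failed)
      rows[[length(rows) + 1]] <- data.frame(
        K = K, structure = s,
        loglik = if (ok) fit$loglik else NA_real_,
        df = if (ok) fit$df else NA_real_,
        bic = if (ok) fit$bic else NA_real_,
        converged = ok && isTRUE(fit$converged),
        stringsAsFactors = FALSE)
      if (ok) fits[[paste(K, s)]] <- fit
    }
  }
  tbl <- do.call(rbind, rows)
  cand <- tbl$converged & is.finite(tbl$bic)
  if (!any(cand)) stop("no converged mixture fit for any (K, structure)")
  best_row <- which(cand)[which.max(tbl$bic[cand])]
  best <- fits[[paste(tbl$K[best_row], tbl$structure[best_row])]]
  best$transform_state <- transform_state
  structure(list(model = best, bic_table = tbl), class = "regime_selection")
}

#' @export
print.regime_selection <- function(x, ...) {
  cat("Regime model selection over", nrow(x$bic_table), "fits\n")
  cat("Selected: K =", x$model$K, " structure =", x$model$structure,
      " BIC =", format(x$model$bic), "\n")
  invisible(x)
}

#' Posterior regime membership for observations
#'
#' E-step responsibilities under a fitted model: membership probabilities
#' per component, the hard label (argmax; ties resolve to the lowest
#' component index), and the assignment uncertainty (one minus the largest
#' membership probability).
#'
#' @param model A fitted \code{regime_model}.
#' @param X Matrix on the same (transformed) scale and width as training.
#' @return data.frame: id, regime, uncertainty, prob_1..prob_K.
#' @export
assign_regimes <- function(model, X) {
  stopifnot(inherits(model, "regime_model"), !isTRUE(model$failed))
  X <- as.matrix(X)
  if (nrow(X) == 0) {
    out <- data.frame(id = character(0), regime = integer(0),
                      uncertainty = numeric(0))
    for (k in seq_len(model$K)) out[[paste0("prob_", k)]] <- numeric(0)
    return(out)
  }
  if (ncol(X) != model$d)
    stop("X has ", ncol(X), " columns; model was trained on ", model$d)
  ld <- .log_dens_matrix(X, model$means, model$covariances, model$structure)
  lr <- sweep(ld, 2, log(model$weights), "+")
  m <- apply(lr, 1, max)
  z <- exp(lr - (m + log(rowSums(exp(lr - m)))))
  lab <- max.col(z, ties.method = "first")
  pmax_ <- z[cbind(seq_len(nrow(z)), lab)]
  out <- data.frame(
    id = if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X))),
    regime = lab, uncertainty = 1 - pmax_, stringsAsFactors = FALSE)
  for (k in seq_len(model$K)) out[[paste0("prob_", k)]] <- z[, k]
  out
}

#' Predict regimes for new raw-scale observations
#'
#' Applies the stored fourth-root/centre/scale transform to raw-scale
#' profiles and computes posterior memberships under the fitted model; the
#' model is never refit.
#'
#' @param model A fitted \code{regime_model}.
#' @param X_new Raw-scale profile matrix (10 functional-group columns).
#' @param transform_state Transform state from training (defaults to the
#'   state attached by \code{\link{select_regime_model}}).
#' @return As \code{\link{assign_regimes}}.
#' @export
predict_regime <- function(model, X_new, transform_state = NULL) {
  if (is.null(transform_state)) transform_state <- model$transform_state
  if (is.null(transform_state))
    stop("missing transform state: pass the state fitted on training data")
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0) return(assign_regimes(model, X_new))
  y <- X_new^(1 / 4)
  z <- sweep(sweep(y, 2, transform_state$center), 2,
             transform_state$scale, "/")
  assign_regimes(model, z)
}
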