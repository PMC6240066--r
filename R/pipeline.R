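# One-command orchestration: synthesize (or load) -> harmonize -> cluster ->
# assign -> stats -> transitions, with a manifest for provenance. All
# randomness flows from one master seed via fixed named offsets.

.stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000000L
  c(synthesize = base, harmonize = base + 11L, cluster = base + 23L,
    assign = base + 37L, stats = base + 41L, transitions = base + 53L)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_sites,n_years Synthetic design size (ignored when input paths
#'   are given).
#' @param fish_csv,benthic_csv,meta_csv Optional paths to user survey data;
#'   when NULL the synthetic generator supplies the data.
#' @param depth_window Depth filter in meters.
#' @param radius_m Spatial aggregation radius (NULL to skip).
#' @param K_range Candidate component counts.
#' @param structures Candidate covariance structures.
#' @param min_prob,min_years Retention thresholds for the transition stage.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(out_dir = tempfile("reefrun"), seed = 1,
                       n_sites = 300, n_years = 6,
                       fish_csv = NULL, benthic_csv = NULL, meta_csv = NULL,
                       depth_window = c(0, 30), radius_m = NULL,
                       K_range = 1:9, structures = regime_structures(),
                       min_prob = 0.95, min_years = 3) {
  stopifnot(min_prob > 0, min_prob <= 1, min_years >= 2,
            length(depth_window) == 2, depth_window[1] <= depth_window[2])
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_sites = n_sites, n_years = n_years,
              fish_csv = fish_csv, benthic_csv = benthic_csv,
              meta_csv = meta_csv, depth_window = depth_window,
              radius_m = radius_m, K_range = K_range,
              structures = structures, min_prob = min_prob,
              min_years = min_years)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full regime analysis pipeline
#'
#' Executes six stages in order — synthesize (or load user CSVs),
#' harmonize, cluster (BIC model selection), assign, stats (ordination,
#' dispersion, regime summaries), transitions — writing each stage's outputs
#' as CSV under \code{config$out_dir} and recording a manifest (seeds,
#' per-stage status, row counts, file checksums). A stage failure is caught:
#' completed outputs remain on disk, the manifest records the failing stage,
#' and a \code{RESUME} marker names it.
#'
#' @param config A \code{\link{run_config}}.
#' @return The manifest (list), invisibly written as YAML alongside the
#'   outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  manifest <- list(seed = config$seed, seeds = as.list(seeds),
                   stages = list(), files = list())
  state <- new.env(parent = emptyenv())

  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write.csv(df, p, row.names = FALSE)
    manifest$files[[name]] <<- unname(tools::md5sum(p))
    p
  }

  stages <- list(
    synthesize = function() {
      set.seed(seeds[["synthesize"]])
      if (is.null(config$fish_csv)) {
        gcfg <- default_generator_config(
          n_sites = config$n_sites, n_years = config$n_years,
          seed = seeds[["synthesize"]])
        ts <- generate_time_series(gcfg)
        prof1 <- ts$profiles[ts$profiles$year == 1, , drop = FALSE]
        state$surveys <- generate_surveys(
          prof1[, c("site_id", functional_groups())], gcfg)
        tr1 <- ts$truth[ts$truth$year == 1, , drop = FALSE]
        ic <- .island_centers()
        ii <- sample.int(nrow(ic), nrow(tr1), replace = TRUE)
        state$metadata <- data.frame(
          site_id = tr1$site_id, island = ic$island[ii],
          lat = ic$lat[ii] + runif(nrow(tr1), -0.15, 0.15),
          lon = ic$lon[ii] + runif(nrow(tr1), -0.15, 0.15),
          shore_direction = sample(c("N", "E", "S", "W"), nrow(tr1),
                                   replace = TRUE),
          depth_m = runif(nrow(tr1), 5, 25),
          complexity = runif(nrow(tr1), 2, 18),
          pop_density = tr1$pop_density, dhw = tr1$dhw,
          stringsAsFactors = FALSE)
        state$ts_profiles <- ts$profiles
        save_csv(state$surveys$fish, "fish.csv")
        save_csv(state$surveys$benthic, "benthic.csv")
        save_csv(state$metadata, "metadata.csv")
        save_csv(ts$truth, "ground_truth.csv")
        nrow(ts$profiles)
      } else {
        state$surveys <- list(fish = read.csv(config$fish_csv),
                              benthic = read.csv(config$benthic_csv))
        need <- c("site_id", "method", "species", "count", "length_cm",
                  "area_m2")
        if (!all(need %in% names(state$surveys$fish)))
          stop("fish CSV missing columns: ",
               paste(setdiff(need, names(state$surveys$fish)),
                     collapse = ", "))
        state$metadata <- if (!is.null(config$meta_csv))
          read.csv(config$meta_csv) else NULL
        state$ts_profiles <- NULL
        nrow(state$surveys$fish)
      }
    },
    harmonize = function() {
      h <- harmonize_surveys(state$surveys$fish, state$surveys$benthic,
                             metadata = state$metadata,
                             depth_window = config$depth_window,
                             radius_m = config$radius_m)
      state$profiles <- h$profiles
      save_csv(h$profiles, "profiles.csv")
      nrow(h$profiles)
    },
    cluster = function() {
      set.seed(seeds[["cluster"]])
      X <- as.matrix(state$profiles[, functional_groups()])
      rownames(X) <- state$profiles$site_id
      tr <- profile_transform(X)
      state$transform <- tr$state
      sel <- select_regime_model(tr$scores, K_range = config$K_range,
                                 structures = config$structures,
                                 transform_state = tr$state)
      state$selection <- sel
      save_csv(sel$bic_table, "bic_table.csv")
      nrow(sel$bic_table)
    },
    assign = function() {
      X <- as.matrix(state$profiles[, functional_groups()])
      rownames(X) <- state$profiles$site_id
      tr_scores <- sweep(sweep(X^(1 / 4), 2, state$transform$center), 2,
                         state$transform$scale, "/")
      asg <- assign_regimes(state$selection$model, tr_scores)
      names(asg)[names(asg) == "id"] <- "site_id"
      state$assignments <- asg
      save_csv(asg, "assignments.csv")
      nrow(asg)
    },
    stats = function() {
      set.seed(seeds[["stats"]])
      X <- as.matrix(state$profiles[, functional_groups()])
      d <- bray_curtis(X^(1 / 4))
      ord <- nmds_ordination(d, seed = seeds[["stats"]])
      save_csv(data.frame(site_id = state$profiles$site_id, ord$points),
               "nmds_coordinates.csv")
      disp <- dispersion_test(d, state$assignments$regime,
                              seed = seeds[["stats"]])
      save_csv(data.frame(regime = names(disp$group_means),
                          mean_dispersion = as.numeric(disp$group_means),
                          f = disp$f_statistic, p = disp$p_value),
               "dispersion.csv")
      if (!is.null(state$metadata)) {
        sm <- regime_summaries(state$assignments, state$metadata)
        if (!is.null(sm$shore_regime_pct))
          save_csv(sm$shore_regime_pct, "shore_direction_pct.csv")
        if (!is.null(sm$island_regime_pct))
          save_csv(sm$island_regime_pct, "island_regime_pct.csv")
      }
      state$ordination <- ord
      nrow(ord$points)
    },
    transitions = function() {
      if (is.null(state$ts_profiles)) return(0L)  # no longitudinal data
      X <- as.matrix(state$ts_profiles[, functional_groups()])
      pred <- predict_regime(state$selection$model, X)
      pred$site_id <- state$ts_profiles$site_id
      pred$year <- state$ts_profiles$year
      pred$probability <- 1 - pred$uncertainty
      kept <- filter_predictions(pred, min_prob = config$min_prob,
                                 min_years = config$min_years, quiet = TRUE)
      tm <- build_transition_matrix(kept, K = state$selection$model$K)
      state$transitions <- tm
      save_csv(tm$records, "transition_records.csv")
      save_csv(tm$wilson, "transition_wilson.csv")
      tm$n_transitions
    })

  for (nm in names(stages)) {
    res <- tryCatch(list(ok = TRUE, n = stages[[nm]]()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[nm]] <- list(
      status = if (res$ok) "complete" else "failed",
      rows = if (res$ok) res$n else NA,
      error = if (res$ok) NULL else res$error)
    if (!res$ok) {
      writeLines(nm, file.path(config$out_dir, "RESUME"))
      break
    }
  }
  manifest$config <- unclass(config)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
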