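#' Run a packaged simulation experiment end-to-end
#'
#' Orchestrates the package's standard experiments on synthetic data and
#' writes a deterministic bundle of CSV/JSON outputs plus a manifest
#' (config, seeds, package version) from which the run can be reproduced
#' exactly. Numerical outputs are the contract; plotting is left to the
#' user.
#'
#' Available experiments:
#' \describe{
#'   \item{`peth_order`}{wave simulation, condition averaging, peak
#'     ordering, per-(neuron, condition) peak scatter, pairwise
#'     correlations.}
#'   \item{`subpop3d`}{early/intermediate/late subpopulation split and
#'     per-condition 3-d subpopulation-average trajectories, for the
#'     original and condition-shuffled data.}
#'   \item{`pca_traj`}{standardization and 3-component PCA trajectories.}
#'   \item{`jpca_variants`}{jPCA on a single-group wave (ill-conditioned),
#'     on the shuffled wave, and on the shuffled wave after the 100-ms
#'     half-of-conditions forward shift.}
#'   \item{`wave_groups`}{jPCA (mean subtraction on) for two- and
#'     three-onset-group waves.}
#'   \item{`synchronous`}{jPCA on a synchronous three-group population.}
#'   \item{`mean_subtraction_off`}{jPCA without mean subtraction on the
#'     wave, the shuffled wave, and the synchronous population.}
#'   \item{`lissajous`}{circle and figure-eight regressions with even/odd
#'     train/test splits, on original and shuffled data.}
#' }
#'
#' @param experiment one of the ids above.
#' @param out_dir output directory (created if needed).
#' @param config optional list overriding [wave_config()] arguments.
#' @param seed integer master seed (simulator and shuffles derive from it).
#' @return (Invisibly) the list of files written.
#' @export
run_experiment <- function(experiment, out_dir, config = list(), seed = 1L) {
  ids <- c("peth_order", "subpop3d", "pca_traj", "jpca_variants",
           "wave_groups", "synchronous", "mean_subtraction_off", "lissajous")
  if (!experiment %in% ids)
    stop("unknown experiment '", experiment, "'; valid ids: ",
         paste(ids, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  cfg_args <- utils::modifyList(list(seed = seed), config)
  make_cfg <- function(...) do.call(wave_config,
                                    utils::modifyList(cfg_args, list(...)))
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
  }
  jpca_summary_list <- function(fit) {
    s <- summary(fit)
    list(r2_skew = s$r2_skew, r2_best = s$r2_best,
         omegas = s$omegas, consistency = s$consistency,
         degenerate = s$degenerate,
         residual_fraction = if (!is.null(s$conditioning))
           s$conditioning$residual_fraction else NA,
         rank1_residual_fraction = if (!is.null(s$conditioning))
           s$conditioning$rank1_residual_fraction else NA)
  }

  if (experiment == "peth_order") {
    pop <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = c(50, 200)))
    avg <- average_across_conditions(pop)
    pk <- order_by_peak(avg)
    emit_csv(as.data.frame(pk), "peak_table.csv")
    emit_csv(peak_times(pop), "peak_scatter.csv")
    cc <- pairwise_correlation(pop)
    emit_csv(as.data.frame(cc), "pairwise_correlation.csv")
  }

  if (experiment == "subpop3d") {
    pop <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = c(50, 200)))
    pk <- order_by_peak(average_across_conditions(pop))
    split3 <- split_subpopulations(pk, 3)
    for (tag in c("original", "shuffled")) {
      p <- if (tag == "original") pop else shuffle_conditions(pop, seed)
      sa <- subpopulation_averages(p, split3)
      d <- dim(sa)
      emit_csv(data.frame(
        condition = rep(seq_len(d[2]), each = d[3]),
        time_ms = rep(pop$grid$times, times = d[2]),
        early = as.vector(t(sa[1, , ])),
        intermediate = as.vector(t(sa[2, , ])),
        late = as.vector(t(sa[3, , ]))
      ), paste0("subpop_traj_", tag, ".csv"))
    }
  }

  if (experiment == "pca_traj") {
    pop <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = c(50, 200)))
    traj <- pca_reduce(standardize(pop), k = 3)
    emit_csv(trajectories_long(traj), "pca_trajectories.csv")
    emit_json(list(var_explained = traj$var_explained), "pca_summary.json")
  }

  if (experiment == "jpca_variants") {
    pop1 <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = 50))
    sh <- shuffle_conditions(pop1, seed)
    shifted <- shift_half(sh, 100)
    fits <- list(
      single_group = suppressWarnings(jpca(pop1)),
      shuffled = suppressWarnings(jpca(sh)),
      shuffled_shifted = suppressWarnings(jpca(shifted))
    )
    emit_json(lapply(fits, jpca_summary_list), "jpca_variants.json")
  }

  if (experiment == "wave_groups") {
    fits <- list(
      two_groups = jpca(simulate_wave(make_cfg(lag_ms = 1,
                                               onsets_ms = c(50, 200)))),
      three_groups = jpca(simulate_wave(make_cfg(lag_ms = 1,
                                                 onsets_ms = c(50, 150, 200))))
    )
    emit_json(lapply(fits, jpca_summary_list), "wave_groups.json")
    emit_csv(projections_long(fits$three_groups), "three_group_projections.csv")
  }

  if (experiment == "synchronous") {
    pop <- simulate_synchronous(make_cfg(onsets_ms = c(50, 150, 200)))
    fit <- suppressWarnings(jpca(pop))
    emit_json(jpca_summary_list(fit), "synchronous.json")
  }

  if (experiment == "mean_subtraction_off") {
    wave <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = c(50, 200)))
    fits <- list(
      wave = jpca(wave, subtract_mean = FALSE),
      shuffled = jpca(shuffle_conditions(wave, seed), subtract_mean = FALSE),
      synchronous = jpca(simulate_synchronous(
        make_cfg(onsets_ms = c(50, 150, 200))), subtract_mean = FALSE)
    )
    emit_json(lapply(fits, jpca_summary_list), "mean_subtraction_off.json")
  }

  if (experiment == "lissajous") {
    # readout experiments use a wave whose sequence tiles the whole window,
    # so the regression has basis functions wherever the target lives
    n_n <- if (is.null(cfg_args$n_neurons)) 218L else cfg_args$n_neurons
    span <- 600
    tile <- simulate_wave(make_cfg(onsets_ms = -50, lag_ms = span / n_n))
    sp <- condition_split(dim(tile)[2])
    res <- list()
    for (shape in c("circle", "infinity")) {
      tg <- lissajous_target(tile$grid, shape)
      full <- lissajous_fit(tile, tg)
      half <- lissajous_fit(tile, tg, train_conditions = sp$train)
      pr <- predict(half, tile, sp$test)
      res[[shape]] <- list(r2_fit_all = full$r2_train,
                           r2_train_half = half$r2_train,
                           r2_test_half = pr$r2_test)
    }
    # shuffle contrast on the two-onset-group wave: per-neuron condition
    # shuffling degrades generalization of the shape-specific y output
    pop <- simulate_wave(make_cfg(lag_ms = 1, onsets_ms = c(50, 200)))
    tgi <- lissajous_target(pop$grid, "infinity")
    for (tag in c("original", "shuffled")) {
      p <- if (tag == "original") pop else shuffle_conditions(pop, seed)
      half <- lissajous_fit(p, tgi, train_conditions = sp$train)
      pr <- predict(half, p, sp$test)
      res[[paste0("infinity_twogroup_", tag)]] <-
        list(r2_train_half = half$r2_train, r2_test_half = pr$r2_test)
    }
    emit_json(res, "lissajous.json")
  }

  manifest <- list(
    experiment = experiment, seed = seed,
    config = cfg_args[setdiff(names(cfg_args), "grid")],
    package = "rotdyn",
    version = as.character(utils::packageVersion("rotdyn"))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, path)
  invisible(files)
}

# long-format per-condition state trajectories
trajectories_long <- function(traj) {
  ks <- seq_len(traj$k)
  do.call(rbind, lapply(seq_along(traj$scores), function(ci) {
    S <- traj$scores[[ci]]
    df <- data.frame(condition = ci, time_ms = traj$times)
    for (j in ks) df[[paste0("pc", j)]] <- S[, j]
    df
  }))
}

projections_long <- function(fit) {
  proj <- fit$top_summary$projections
  times <- fit$trajectories$times
  do.call(rbind, lapply(seq_along(proj), function(ci) {
    data.frame(condition = ci, time_ms = times,
               plane1 = proj[[ci]][, 1], plane2 = proj[[ci]][, 2])
  }))
}
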