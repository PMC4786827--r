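#' Baseline configuration
#'
#' The baseline condition: 20 groups of 20 members, conflict probability
#' 0.20, migration 0.15, mutation 0.01, strong selection (`w0 = 0`),
#' `r = 2`, 5000 generations, random initial strategies.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
baseline_config <- function(...) {
  args <- list(...)
  defaults <- list(n = 20L, g = 20L, k = 0.2, m = 0.15, mu = 0.01,
                   w0 = 0, r = 2, generations = 5000L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

#' Run independent replicates of one configuration
#'
#' Replicate `i` uses seed `seed + i`, so an experiment is reproducible
#' from its base seed alone.
#'
#' @param config A [sim_config()]; its own `seed` field is overridden.
#' @param runs Number of replicates.
#' @param seed Base seed.
#' @return List of `run_record`s.
#' @export
run_replicates <- function(config, runs = 5L, seed = 42L) {
  lapply(seq_len(runs), function(i) {
    config$seed <- as.integer(seed + i)
    run_simulation(config)
  })
}

#' Baseline dynamics experiment
#'
#' Replicated baseline runs with random initial strategies, aggregated
#' into the replicate-mean trajectory, cooperative-epoch statistics and
#' the final strategy frequency distribution.
#'
#' @param runs Number of replicate runs (the reference condition averages
#'   50; 5 is the desk-scale default).
#' @param seed Base seed.
#' @param ... Configuration overrides (e.g. `generations`).
#' @return List with `records`, `aggregate` (see [aggregate_runs()]),
#'   `epochs` (on the replicate-mean series), `final_freq` (27 strategy
#'   frequencies averaged over the stabilized window and runs) and
#'   `config`.
#' @export
baseline_experiment <- function(runs = 5L, seed = 42L, ...) {
  config <- baseline_config(...)
  records <- run_replicates(config, runs, seed)
  agg <- aggregate_runs(records, config$epoch_threshold)
  list(records = records,
       aggregate = agg,
       epochs = cooperative_epochs(agg$mean_record$mean_contribution,
                                   config$epoch_threshold),
       final_freq = stabilized_freq(agg$mean_record),
       config = config)
}

#' Stabilized strategy frequency distribution
#'
#' Averages the 27 strategy frequencies of a run record (or replicate-mean
#' record) over the final `frac` of generations.
#'
#' @param record A `run_record` or the `mean_record` of [aggregate_runs()].
#' @param frac Final fraction of generations to average over.
#' @return Named numeric vector `freq_0` ... `freq_26` summing to 1.
#' @export
stabilized_freq <- function(record, frac = 0.2) {
  T <- nrow(record)
  idx <- seq.int(max(1L, floor(T * (1 - frac)) + 1L), T)
  f <- colMeans(record[idx, paste0("freq_", 0:26), drop = FALSE])
  names(f) <- paste0("freq_", 0:26)
  f
}

#' Initial-condition robustness experiment
#'
#' Baseline runs started from a homogeneous population of one strategy
#' (e.g. all free riders, Type 0, or all perfectly conditional
#' cooperators, Type 5) instead of random strategies.
#'
#' @param init_label Strategy label filling every slot initially.
#' @inheritParams baseline_experiment
#' @return As [baseline_experiment()].
#' @export
initial_condition_experiment <- function(init_label, runs = 5L, seed = 42L,
                                         ...) {
  baseline_experiment(runs = runs, seed = seed, init = init_label, ...)
}

#' Unconditional-strategy control experiment
#'
#' Baseline runs with the strategy space restricted to the three constant
#' strategies \{0, 13, 26\}. Without conditional responses, free riding
#' dominates within groups and cooperation cannot be established at
#' strong selection.
#'
#' @inheritParams baseline_experiment
#' @return As [baseline_experiment()].
#' @export
unconditional_control <- function(runs = 5L, seed = 42L, ...) {
  baseline_experiment(runs = runs, seed = seed,
                      strategy_space = "unconditional", ...)
}

#' Parameter sweep experiment
#'
#' Replicated runs at each value of one swept parameter (`k`, `n`, `m` or
#' `w0`), summarised per value by mean cooperation (whole-run and
#' stabilized), mean cooperative-epoch length, 95% CIs, and the modal
#' strategy of the stabilized strategy distribution. When sweeping group
#' size `n`, total population size is held near 400 by setting
#' `g = round(400 / n)`.
#'
#' @param param One of `"k"`, `"n"`, `"m"`, `"w0"`.
#' @param values Numeric sweep values (reference ranges: k 0.05-0.30,
#'   n 5-30, m 0.05-0.25, w0 0-5).
#' @param runs Replicates per sweep value.
#' @param seed Base seed; cell `v` uses seeds
#'   `seed + 1000 * v + (1..runs)`.
#' @param ... Configuration overrides applied to every cell.
#' @return A `sweep_result` data frame, one row per value, with attribute
#'   `trend` (OLS of mean cooperation on the parameter) and
#'   `final_freqs` (per-cell stabilized strategy distributions).
#' @export
sweep_experiment <- function(param = c("k", "n", "m", "w0"), values,
                             runs = 5L, seed = 42L, ...) {
  param <- match.arg(param)
  if (length(values) < 1L) stop("need at least one sweep value", call. = FALSE)
  cells <- lapply(seq_along(values), function(v) {
    over <- list(...)
    over[[param]] <- values[v]
    if (param == "n") over$g <- max(2L, as.integer(round(400 / values[v])))
    config <- do.call(baseline_config, over)
    records <- run_replicates(config, runs, seed + 1000L * v)
    agg <- aggregate_runs(records, config$epoch_threshold)
    f <- stabilized_freq(agg$mean_record)
    list(summary = data.frame(
           value = values[v],
           mean_cooperation = agg$summary$mean_contribution[["mean"]],
           coop_lo = agg$summary$mean_contribution[["lo"]],
           coop_hi = agg$summary$mean_contribution[["hi"]],
           stabilized_mean = agg$summary$stabilized_mean[["mean"]],
           mean_epoch_length = agg$summary$mean_epoch_length[["mean"]],
           epoch_lo = agg$summary$mean_epoch_length[["lo"]],
           epoch_hi = agg$summary$mean_epoch_length[["hi"]],
           modal_strategy = as.integer(which.max(f) - 1L),
           freq_type2 = f[["freq_2"]]),
         freq = f)
  })
  out <- do.call(rbind, lapply(cells, `[[`, "summary"))
  rownames(out) <- NULL
  attr(out, "param") <- param
  attr(out, "trend") <- sweep_trend(out$value, out$mean_cooperation)
  attr(out, "final_freqs") <- lapply(cells, `[[`, "freq")
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Deterministic small population fixture
#'
#' Builds a tiny `population_state` for unit tests and examples, either
#' from explicit per-group label vectors or as `g` groups of `n` copies of
#' one label.
#'
#' @param groups Either a list of equal-length integer label vectors (one
#'   per group), or `NULL` to use `g` groups of `n` times `label`.
#' @param g,n,label Used when `groups` is `NULL`.
#' @param seed Optional seed (only relevant if callers draw from the
#'   fixture afterwards; the fixture itself is deterministic).
#' @return A `population_state` with at most 100 individuals.
#' @export
#' @examples
#' make_fixture(list(c(0, 5, 5, 5)))          # the exploitation fixture
#' make_fixture(g = 2, n = 4, label = 0)      # 8 free riders
make_fixture <- function(groups = NULL, g = 2L, n = 4L, label = 0L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) {
    groups <- rep(list(rep(as.integer(label), n)), g)
  }
  sizes <- lengths(groups)
  if (length(unique(sizes)) != 1L) stop("groups must have equal size",
                                        call. = FALSE)
  labels <- vapply(groups, as_labels, integer(sizes[1]))
  if (length(labels) > 100L) stop("fixture populations are capped at 100",
                                  call. = FALSE)
  structure(list(labels = matrix(labels, nrow = sizes[1]), generation = 0L),
            class = "population_state")
}

#' Write experiment outputs to disk
#'
#' Per-run CSV time series (`run_<i>.csv`) plus a `summary.json` with the
#' configuration, seeds and aggregate statistics, mirroring the
#' command-line interface's output layout.
#'
#' @param experiment Result of [baseline_experiment()] and friends.
#' @param dir Output directory (created if missing).
#' @param seed Base seed used, recorded for exact reruns.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, seed = NA_integer_) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing summary.json requires the jsonlite package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(experiment$records)) {
    write.csv(as.data.frame(experiment$records[[i]]),
              file.path(dir, sprintf("run_%d.csv", i)), row.names = FALSE)
  }
  cfg <- unclass(experiment$config)
  s <- experiment$aggregate$summary
  jsonlite::write_json(
    list(params = cfg, base_seed = seed,
         run_seeds = if (is.na(seed)) vapply(
           experiment$records,
           function(r) attr(r, "config")$seed, integer(1)
         ) else seed + seq_along(experiment$records),
         runs = length(experiment$records),
         mean_contribution_overall = s$mean_contribution[["mean"]],
         mean_contribution_stabilized = s$stabilized_mean[["mean"]],
         mean_epoch_length = s$mean_epoch_length[["mean"]],
         ci95 = list(mean_contribution = s$mean_contribution,
                     stabilized = s$stabilized_mean,
                     epoch_length = s$mean_epoch_length),
         strategy_frequency_final = as.list(experiment$final_freq)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
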