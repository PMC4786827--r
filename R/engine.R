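#' Simulation configuration
#'
#' Bundles every model parameter of the multilevel-selection public goods
#' simulation. Defaults are the baseline condition: 20 groups of 20, a 20%
#' per-group conflict probability, 15% migration, 1% mutation, strong
#' selection (`w0 = 0`), total return on cooperation `r = 2` (marginal
#' per-capita return `r/n = 0.1`), and 5000 generations.
#'
#' @param n Group size (members per group), >= 2.
#' @param g Number of groups, >= 2.
#' @param k Per-group per-generation probability of entering a conflict.
#' @param m Per-individual migration probability.
#' @param mu Per-individual mutation probability.
#' @param w0 Baseline payoff added to everyone; large `w0` weakens
#'   within-group selection on payoff differences.
#' @param r Total return to cooperation, `1 < r < n`; contributions are
#'   multiplied by `r` and shared equally among the `n` members.
#' @param generations Number of generations to simulate.
#' @param strategy_space `"full"` (27 strategies) or `"unconditional"`
#'   (\{0, 13, 26\} only).
#' @param init `"random"` (each individual draws a uniform strategy from the
#'   space) or a single strategy label for a homogeneous start.
#' @param seed Integer RNG seed; a run is bit-reproducible given its seed.
#' @param initial_belief,max_iter,tol,window Equilibrium controls, see
#'   [group_equilibrium()].
#' @param epoch_threshold Mean-contribution cutoff defining cooperative
#'   epochs, in (0, 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 20L, g = 20L, k = 0.2, m = 0.15, mu = 0.01,
                       w0 = 0, r = 2, generations = 5000L,
                       strategy_space = c("full", "unconditional"),
                       init = "random", seed = 1L,
                       initial_belief = 1, max_iter = 200L, tol = 1e-9,
                       window = 50L, epoch_threshold = 0.6) {
  strategy_space <- match.arg(strategy_space)
  n <- as.integer(n); g <- as.integer(g); generations <- as.integer(generations)
  if (n < 2L) stop("group size n must be >= 2", call. = FALSE)
  if (g < 2L) stop("number of groups g must be >= 2", call. = FALSE)
  if (!(r > 1 && r < n)) {
    stop("total return r must satisfy 1 < r < n", call. = FALSE)
  }
  for (p in c(k = k, m = m, mu = mu)) {
    if (p < 0 || p > 1) stop("k, m and mu must lie in [0, 1]", call. = FALSE)
  }
  if (w0 < 0) stop("w0 must be >= 0", call. = FALSE)
  if (generations < 0L) stop("generations must be >= 0", call. = FALSE)
  if (epoch_threshold <= 0 || epoch_threshold >= 1) {
    stop("epoch_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (!identical(init, "random")) {
    init <- as.integer(init)
    if (!(init %in% strategy_space(strategy_space))) {
      stop("homogeneous init label outside the configured strategy space",
           call. = FALSE)
    }
  }
  structure(
    list(n = n, g = g, k = k, m = m, mu = mu, w0 = w0, r = r,
         generations = generations, strategy_space = strategy_space,
         init = init, seed = as.integer(seed),
         initial_belief = initial_belief, max_iter = as.integer(max_iter),
         tol = tol, window = as.integer(window),
         epoch_threshold = epoch_threshold),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d groups x %d members, k=%g, m=%g, mu=%g, w0=%g, r=%g, T=%d\n",
    x$g, x$n, x$k, x$m, x$mu, x$w0, x$r, x$generations))
  cat(sprintf("  strategy space: %s; init: %s; seed: %d\n", x$strategy_space,
              if (identical(x$init, "random")) "random"
              else sprintf("homogeneous(%d)", x$init), x$seed))
  invisible(x)
}

#' Public goods payoffs within one group
#'
#' Everyone keeps the uncontributed share of a unit endowment; the pooled
#' contributions are multiplied by `r` and split equally among all `n`
#' members (self included):
#' `w_i = w0 + 1 - c_i + (r/n) * sum(c)`.
#'
#' @param contributions Numeric vector of contribution levels in \[0, 1\].
#' @param w0 Baseline payoff.
#' @param r Total return to cooperation, `1 < r < n`.
#' @param n Group size; defaults to `length(contributions)`.
#' @return Numeric vector of payoffs (all `> w0` for `r > 1`).
#' @export
#' @examples
#' payoffs(c(0, rep(1, 19)), w0 = 0, r = 2)  # free rider earns 2.9 vs 1.9
payoffs <- function(contributions, w0 = 0, r = 2, n = length(contributions)) {
  if (any(contributions < 0 | contributions > 1)) {
    stop("contributions must lie in [0, 1]", call. = FALSE)
  }
  if (!(r > 1 && r < n)) {
    stop("total return r must satisfy 1 < r < n", call. = FALSE)
  }
  w0 + 1 - contributions + (r / n) * sum(contributions)
}

#' Initialise a population
#'
#' @param config A [sim_config()].
#' @return A `population_state`: list with `labels` (an `n x g` integer
#'   matrix, column `j` = group `j`) and `generation = 0`.
#' @export
init_population <- function(config) {
  space <- strategy_space(config$strategy_space)
  labels <- if (identical(config$init, "random")) {
    matrix(sample(space, config$n * config$g, replace = TRUE),
           nrow = config$n, ncol = config$g)
  } else {
    matrix(config$init, nrow = config$n, ncol = config$g)
  }
  structure(list(labels = labels, generation = 0L),
            class = "population_state")
}

#' Public goods provision across the whole population
#'
#' Runs the within-group equilibrium for every group and computes payoffs.
#'
#' @param state A `population_state`.
#' @param config A [sim_config()].
#' @return List with matrices `contributions` and `payoffs` (`n x g`),
#'   `group_means` (length `g`), and per-group `converged`/`cycle_length`.
#' @export
provision <- function(state, config) {
  eq <- equilibrium_matrix(state$labels, config$initial_belief,
                           config$max_iter, config$tol, config$window)
  cm <- eq$contributions
  S <- colSums(cm)
  pay <- config$w0 + 1 - cm +
    rep(config$r / config$n * S, each = config$n)
  list(contributions = cm, payoffs = pay, group_means = S / config$n,
       converged = eq$converged, cycle_length = eq$cycle_length)
}

#' Probability that a group wins a conflict
#'
#' A contest between groups with mean contributions `ci` and `cj` is won by
#' the first with probability `0.5 + 5 * (ci - cj)`, clamped to \[0, 1\]:
#' a contribution advantage above 0.1 guarantees victory.
#'
#' @param ci,cj Mean contributions of the two groups, in \[0, 1\].
#' @return Win probability for the first group.
#' @export
#' @examples
#' conflict_win_prob(0.55, 0.5)  # 0.75
conflict_win_prob <- function(ci, cj) {
  if (any(ci < 0 | ci > 1) || any(cj < 0 | cj > 1)) {
    stop("group mean contributions must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(0.5 + 5 * (ci - cj), 0), 1)
}

#' Draw this generation's group conflicts
#'
#' Each group independently enters the conflict pool with probability `k`;
#' pool members are randomly paired (an odd leftover sits out) and each
#' pair is resolved by a single Bernoulli draw with [conflict_win_prob()].
#' The winner will repopulate the loser's site during reproduction.
#'
#' @param group_means Mean contribution of each group.
#' @param k Per-group conflict probability.
#' @return Integer vector `source` of length `g`: `source[j]` is the group
#'   whose members repopulate site `j` (equal to `j` unless `j` lost a
#'   conflict). Attribute `n_conflicts` counts the pairs fought.
#' @export
group_conflicts <- function(group_means, k) {
  g <- length(group_means)
  source <- seq_len(g)
  pool <- which(runif(g) < k)
  n_pairs <- length(pool) %/% 2L
  if (n_pairs > 0L) {
    pool <- sample(pool)   # random pairing; odd leftover sits out
    for (p in seq_len(n_pairs)) {
      i <- pool[2L * p - 1L]; j <- pool[2L * p]
      p_i <- conflict_win_prob(group_means[i], group_means[j])
      if (runif(1) < p_i) source[j] <- i else source[i] <- j
    }
  }
  attr(source, "n_conflicts") <- n_pairs
  source
}

#' Payoff-proportional reproduction
#'
#' Every site is refilled by `n` independent draws with replacement from
#' its source group (itself, or the conflict winner for a lost site), each
#' member drawn with probability equal to its share of the source group's
#' total payoff. A winning group's own site is refilled by an independent
#' set of draws from the same weighted pool.
#'
#' @param labels `n x g` label matrix of the current generation.
#' @param pay `n x g` payoff matrix from [provision()].
#' @param source Site-source mapping from [group_conflicts()].
#' @return New `n x g` label matrix.
#' @export
reproduce_groups <- function(labels, pay, source = seq_len(ncol(labels))) {
  n <- nrow(labels)
  out <- labels
  for (j in seq_len(ncol(labels))) {
    s <- source[j]
    w <- pay[, s]
    if (any(w < 0) || sum(w) <= 0) {
      warning("degenerate payoff weights in group ", s,
              "; falling back to uniform draws")
      w <- rep(1, n)
    }
    out[, j] <- labels[sample.int(n, n, replace = TRUE, prob = w), s]
  }
  out
}

#' Strategy mutation
#'
#' Each individual independently, with probability `mu`, replaces its
#' strategy by a uniform draw over the strategy space (which may return the
#' current label).
#'
#' @param labels `n x g` label matrix.
#' @param mu Mutation probability.
#' @param space Integer vector of admissible labels
#'   (see [strategy_space()]).
#' @return Mutated label matrix.
#' @export
mutate_strategies <- function(labels, mu, space = 0:26) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (mu == 0) return(labels)
  hit <- runif(length(labels)) < mu
  labels[hit] <- sample(space, sum(hit), replace = TRUE)
  labels
}

#' Migration between groups
#'
#' Each individual is independently marked a migrant with probability `m`;
#' migrants are reassigned by a uniform random permutation of the vacated
#' slots across all groups (a migrant may land back where it started).
#' Group sizes are exactly preserved and the population-wide multiset of
#' strategies is unchanged.
#'
#' @param labels `n x g` label matrix.
#' @param m Migration probability.
#' @return Label matrix after migration.
#' @export
migrate_strategies <- function(labels, m) {
  if (m < 0 || m > 1) stop("m must lie in [0, 1]", call. = FALSE)
  if (m == 0) return(labels)
  mig <- which(runif(length(labels)) < m)
  if (length(mig) > 1L) labels[mig] <- labels[mig][sample(length(mig))]
  labels
}

#' Advance the simulation by one generation
#'
#' Applies the five-step generation loop exactly once: public goods
#' provision, group conflict, payoff-proportional reproduction (with
#' winner repopulation), mutation, migration. The returned statistics row
#' describes the provision step — the contributions actually played this
#' generation, before reproduction reshuffles membership.
#'
#' @param state A `population_state`.
#' @param config A [sim_config()].
#' @return List with `state` (next generation) and `stats` (named numeric:
#'   `mean_contribution`, `var_between`, `mean_var_within`, `n_conflicts`,
#'   and the 27 strategy frequencies `freq_0` ... `freq_26`).
#' @export
step_generation <- function(state, config) {
  prov <- provision(state, config)
  stats <- generation_stats(state$labels, prov)
  source <- group_conflicts(prov$group_means, config$k)
  stats["n_conflicts"] <- attr(source, "n_conflicts")
  labels <- reproduce_groups(state$labels, prov$payoffs, source)
  labels <- mutate_strategies(labels, config$mu,
                              strategy_space(config$strategy_space))
  labels <- migrate_strategies(labels, config$m)
  stopifnot(length(labels) == config$n * config$g)
  state$labels <- labels
  state$generation <- state$generation + 1L
  list(state = state, stats = stats)
}

# Per-generation observables from the provision outcomes.
generation_stats <- function(labels, prov) {
  cm <- prov$contributions
  n <- nrow(cm); g <- ncol(cm)
  gm <- prov$group_means
  within <- colMeans((cm - rep(gm, each = n))^2)   # per-group population variance
  freq <- tabulate(labels + 1L, nbins = 27L) / (n * g)
  c(mean_contribution = mean(gm),
    var_between = mean((gm - mean(gm))^2),
    mean_var_within = mean(within),
    n_conflicts = NA_real_,
    structure(freq, names = paste0("freq_", 0:26)))
}

#' Run a full simulation
#'
#' Initialises the population per `config$init`, seeds the RNG with
#' `config$seed`, and iterates [step_generation()] for
#' `config$generations` generations. Row `t` of the returned record holds
#' the provision statistics of generation `t - 1` (column `generation`
#' counts from 0), so the first row describes the initial population.
#'
#' @param config A [sim_config()].
#' @return A `run_record` data frame with columns `generation`,
#'   `mean_contribution`, `var_between`, `mean_var_within`, `n_conflicts`
#'   and `freq_0` ... `freq_26`; the configuration is attached as
#'   attribute `config` and the final label matrix as `final_labels`.
#' @export
#' @examples
#' rec <- run_simulation(sim_config(n = 5, g = 4, generations = 50, seed = 7))
#' head(rec$mean_contribution)
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_population(config)
  T <- config$generations
  rows <- matrix(NA_real_, nrow = T, ncol = 31L)
  for (t in seq_len(T)) {
    stepped <- step_generation(state, config)
    rows[t, ] <- stepped$stats
    state <- stepped$state
  }
  rec <- as.data.frame(rows)
  names(rec) <- c("mean_contribution", "var_between", "mean_var_within",
                  "n_conflicts", paste0("freq_", 0:26))
  rec <- cbind(generation = seq_len(T) - 1L, rec)
  attr(rec, "config") <- config
  attr(rec, "final_labels") <- state$labels
  class(rec) <- c("run_record", "data.frame")
  rec
}
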