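test_that("public goods payoffs follow the shared-return formula", {
  expect_equal(payoffs(rep(0, 20), w0 = 0, r = 2), rep(1, 20))
  expect_equal(payoffs(rep(1, 20), w0 = 0, r = 2), rep(2, 20))

  pay <- payoffs(c(0, rep(1, 19)), w0 = 0, r = 2)
  expect_equal(pay[1], 2.9)                # free rider
  expect_equal(pay[2], 1.9)                # full contributor
  expect_true(all(pay > 0))

  expect_equal(payoffs(rep(0.5, 4), w0 = 3, r = 2), rep(3 + 0.5 + 1, 4))
  expect_error(payoffs(rep(0.5, 4), r = 5), "1 < r < n")
  expect_error(payoffs(c(-0.1, 0.5), r = 1.5), "\\[0, 1\\]")
})

test_that("conflict odds are linear in the contribution gap and clamped", {
  expect_equal(conflict_win_prob(0.7, 0.7), 0.5)
  expect_equal(conflict_win_prob(0.6, 0.5), 1)      # gap 0.1: certain win
  expect_equal(conflict_win_prob(0.55, 0.5), 0.75)
  expect_equal(conflict_win_prob(0.2, 0.9), 0)
  # symmetry: p(i beats j) + p(j beats i) == 1 on a grid
  ci <- runif(20); cj <- runif(20)
  expect_equal(conflict_win_prob(ci, cj) + conflict_win_prob(cj, ci),
               rep(1, 20))
})

test_that("conflict drawing respects the pool semantics", {
  set.seed(1)
  expect_identical(as.integer(group_conflicts(runif(10), k = 0)), 1:10)

  # k = 1 with an even pool: every group fights, g/2 pairs
  set.seed(2)
  src <- group_conflicts(rep(0.5, 20), k = 1)
  expect_equal(attr(src, "n_conflicts"), 10L)

  # a 0.2 contribution advantage wins for sure
  set.seed(3)
  for (i in 1:10) {
    src <- group_conflicts(c(0.9, 0.7), k = 1)
    expect_identical(as.integer(src), c(1L, 1L))
  }
})

test_that("reproduction is payoff-proportional with winner repopulation", {
  # homogeneous group: offspring identical regardless of payoffs
  lab <- matrix(7L, nrow = 4, ncol = 2)
  out <- reproduce_groups(lab, matrix(runif(8, 1, 2), 4, 2))
  expect_identical(out, lab)

  # member with payoff 2 vs 1 is drawn with probability 2/3 per slot:
  # Monte Carlo over many independent copies of the same 2-member group
  set.seed(42)
  g <- 5000L
  lab <- matrix(c(1L, 2L), nrow = 2, ncol = g)
  pay <- matrix(c(2, 1), nrow = 2, ncol = g)
  out <- reproduce_groups(lab, pay)
  share <- mean(out == 1L)
  se <- sqrt(2 / 9 / (2 * g))
  expect_lt(abs(share - 2 / 3), 4 * se)

  # the winner's members fill a lost site
  lab <- cbind(rep(2L, 4), rep(0L, 4))
  out <- reproduce_groups(lab, matrix(1, 4, 2), source = c(1L, 1L))
  expect_true(all(out == 2L))
})

test_that("mutation is per-individual and uniform over the strategy space", {
  lab <- matrix(sample(0:26, 200, TRUE), 20, 10)
  expect_identical(mutate_strategies(lab, 0), lab)

  set.seed(5)
  mut <- mutate_strategies(matrix(5L, 250, 400), 1, strategy_space("full"))
  counts <- tabulate(mut + 1L, 27)
  # uniformity over 27 labels on 1e5 slots (chi-squared goodness of fit)
  chi <- sum((counts - length(mut) / 27)^2 / (length(mut) / 27))
  expect_lt(chi, qchisq(1 - 1e-4, df = 26))

  set.seed(6)
  mutu <- mutate_strategies(matrix(0L, 50, 20), 1, strategy_space("unconditional"))
  expect_true(all(mutu %in% c(0L, 13L, 26L)))
})

test_that("migration permutes migrants and conserves the strategy multiset", {
  lab <- matrix(sample(0:26, 400, TRUE), 20, 20)
  expect_identical(migrate_strategies(lab, 0), lab)
  for (m in c(0.15, 0.5, 1)) {
    set.seed(100 + m * 100)
    out <- migrate_strategies(lab, m)
    expect_identical(dim(out), dim(lab))
    expect_identical(tabulate(out + 1L, 27), tabulate(lab + 1L, 27))
  }
})

test_that("homogeneous unconditional populations are absorbing states", {
  cfg0 <- sim_config(n = 5, g = 4, k = 0, m = 0, mu = 0, generations = 3,
                     init = 0L, seed = 1)
  st <- init_population(cfg0)
  stepped <- step_generation(st, cfg0)
  expect_identical(stepped$state$labels, st$labels)
  expect_equal(unname(stepped$stats["mean_contribution"]), 0)

  cfg26 <- sim_config(n = 5, g = 4, k = 0, m = 0, mu = 0, generations = 3,
                      init = 26L, seed = 1)
  st <- init_population(cfg26)
  stepped <- step_generation(st, cfg26)
  expect_identical(stepped$state$labels, st$labels)
  expect_equal(unname(stepped$stats["mean_contribution"]), 1)
})

test_that("runs are deterministic given the seed", {
  cfg <- sim_config(n = 6, g = 6, generations = 40, seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("population size and frequency bookkeeping are conserved", {
  cfg <- sim_config(n = 5, g = 6, generations = 60, seed = 3)
  rec <- run_simulation(cfg)
  expect_equal(nrow(rec), 60L)
  freqs <- as.matrix(rec[, paste0("freq_", 0:26)])
  expect_equal(unname(rowSums(freqs)), rep(1, 60))
  expect_true(all(rec$mean_contribution >= 0 & rec$mean_contribution <= 1))
  expect_true(all(rec$var_between >= 0 & rec$mean_var_within >= 0))
  expect_identical(dim(attr(rec, "final_labels")), c(5L, 6L))
})

test_that("without group conflict cooperation decays from a random start", {
  cfg <- sim_config(n = 10, g = 10, k = 0, w0 = 0, generations = 300,
                    seed = 8)
  rec <- run_simulation(cfg)
  expect_gt(rec$mean_contribution[1], 0.3)   # random start near 0.5
  expect_lt(mean(rec$mean_contribution[251:300]), 0.05)
})

test_that("a zero-length run returns the empty time series", {
  cfg <- sim_config(n = 4, g = 2, generations = 0, seed = 1)
  rec <- run_simulation(cfg)
  expect_equal(nrow(rec), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n = 1), "n must be")
  expect_error(sim_config(r = 25), "1 < r < n")
  expect_error(sim_config(k = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(epoch_threshold = 1), "epoch_threshold")
  expect_error(sim_config(init = 14L, strategy_space = "unconditional"),
               "outside the configured strategy space")
})
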