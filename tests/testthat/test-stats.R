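test_that("variance proxies use population variances over groups and members", {
  p <- variance_proxies(matrix(0.7, 5, 4))
  expect_equal(p$var_between, 0)
  expect_equal(p$mean_var_within, 0)

  p <- variance_proxies(cbind(c(0, 1), c(1, 1)))
  expect_equal(p$var_between, 0.0625)
  expect_equal(p$mean_var_within, 0.125)

  expect_equal(variance_proxies(matrix(c(0.2, 0.8), 2, 1))$var_between, 0)
  expect_error(variance_proxies(matrix(numeric(0), 0, 0)), "empty")
  expect_error(variance_proxies(list(c(0, 1), c(1, 1, 1))), "equal size")
})

test_that("the two proxies decompose the total contribution variance", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(2:8, 1); g <- sample(2:8, 1)
    cm <- matrix(runif(n * g), n, g)
    p <- variance_proxies(cm)
    total <- mean((cm - mean(cm))^2)
    expect_equal(p$var_between + p$mean_var_within, total, tolerance = 1e-12)
  }
})

test_that("cooperative epochs are maximal strict-threshold runs", {
  ep <- cooperative_epochs(c(0.7, 0.7, 0.5, 0.8), threshold = 0.6)
  expect_equal(ep$epochs$start, c(1L, 4L))
  expect_equal(ep$epochs$length, c(2L, 1L))
  expect_equal(ep$mean_length, 1.5)
  expect_equal(ep$count, 2L)

  none <- cooperative_epochs(rep(0.5, 10))
  expect_equal(none$count, 0L)
  expect_false(none$defined)
  expect_equal(none$mean_length, 0)

  all_up <- cooperative_epochs(rep(0.9, 17))
  expect_equal(all_up$epochs$length, 17L)

  # a generation exactly at the threshold ends an epoch
  ep <- cooperative_epochs(c(0.7, 0.6, 0.7), threshold = 0.6)
  expect_equal(ep$count, 2L)
  expect_error(cooperative_epochs(0.5, threshold = 0), "threshold")
})

test_that("Price decomposition matches the closed-form worked cases", {
  # all-cooperator group vs all-defector group (n = 4, r = 2, w0 = 0)
  tr <- list(rep(1, 4), rep(0, 4))
  pay <- lapply(tr, payoffs, w0 = 0, r = 2, n = 4)
  d <- price_decomposition(tr, pay)
  expect_equal(d$between_term, 0.25)
  expect_equal(d$within_term, 0)
  expect_equal(d$mean_payoff, 1.5)
  expect_equal(d$predicted_delta_p, 1 / 6)

  # one mixed group: within-group selection against the costly trait
  tr <- list(c(1, 1, 0, 0))
  pay <- lapply(tr, payoffs, w0 = 0, r = 2, n = 4)
  d <- price_decomposition(tr, pay)
  expect_equal(d$between_term, 0)
  expect_equal(d$within_term, -0.25)
  expect_equal(d$predicted_delta_p, -1 / 6)

  # both levels at once: within-group loss outweighs the between-group gain
  tr <- list(rep(1, 4), c(1, 1, 0, 0))
  pay <- lapply(tr, payoffs, w0 = 0, r = 2, n = 4)
  d <- price_decomposition(tr, pay)
  expect_equal(d$between_term, 0.0625)
  expect_equal(d$within_term, -0.125)
  expect_equal(d$mean_payoff, 1.75)
  expect_equal(d$predicted_delta_p, -1 / 28)

  # identity by construction
  expect_equal(d$predicted_delta_p * d$mean_payoff,
               d$between_term + d$within_term)
})

test_that("decomposition agrees with the brute-force oracle", {
  tr <- list(rep(1, 4), c(1, 1, 0, 0))
  pay <- lapply(tr, payoffs, w0 = 0, r = 2, n = 4)
  expect_equal(price_oracle(tr, pay), -1 / 28)

  # homogeneous trait: no variance, no change
  tr <- list(rep(1, 3), rep(1, 3))
  pay <- lapply(tr, payoffs, w0 = 0, r = 2, n = 3)
  expect_equal(price_oracle(tr, pay), 0)
  expect_equal(price_decomposition(tr, pay)$predicted_delta_p, 0)
})

test_that("weak selection washes out the frequency change", {
  tr <- list(rep(1, 4), c(1, 0, 0, 0))
  d0 <- abs(price_decomposition(
    tr, lapply(tr, payoffs, w0 = 0, r = 2, n = 4))$predicted_delta_p)
  d100 <- abs(price_decomposition(
    tr, lapply(tr, payoffs, w0 = 100, r = 2, n = 4))$predicted_delta_p)
  expect_lt(d100, d0 / 10)
})

test_that("closed forms hold for public-goods payoffs", {
  set.seed(31)
  for (rep in 1:100) {
    inst <- random_price_instance()
    d <- price_decomposition(inst$trait, inst$payoff)
    p_j <- vapply(inst$trait, mean, numeric(1))
    var_within <- mean(vapply(inst$trait,
                              function(p) mean((p - mean(p))^2), numeric(1)))
    expect_equal(d$within_term, -var_within, tolerance = 1e-12)
    expect_equal(d$between_term, (inst$r - 1) * mean((p_j - mean(p_j))^2),
                 tolerance = 1e-12)
  }
})

test_that("viability condition reflects the sign of the Price numerator", {
  expect_true(viability_condition(0.25, 0, r = 2, n = 4))
  expect_false(viability_condition(0.0625, 0.125, r = 2, n = 4))
  expect_false(viability_condition(0, 0.2, r = 2, n = 4))
  expect_error(viability_condition(-0.1, 0, r = 2, n = 4), "nonnegative")
})

test_that("replicate aggregation averages trajectories and reports CIs", {
  fake_rec <- function(mc) {
    data.frame(generation = seq_along(mc) - 1L, mean_contribution = mc)
  }
  recs <- list(fake_rec(rep(0.6, 10)), fake_rec(rep(0.8, 10)))
  agg <- aggregate_runs(recs)
  expect_equal(agg$mean_record$mean_contribution, rep(0.7, 10))
  expect_equal(agg$summary$mean_contribution[["mean"]], 0.7)
  expect_true(agg$summary$ci_defined)

  same <- aggregate_runs(list(fake_rec(rep(0.5, 6)), fake_rec(rep(0.5, 6))))
  expect_equal(same$summary$mean_contribution[["lo"]],
               same$summary$mean_contribution[["hi"]])

  single <- aggregate_runs(list(fake_rec(rep(0.4, 6))))
  expect_false(single$summary$ci_defined)
  expect_equal(single$summary$mean_contribution[["lo"]], 0.4)

  expect_error(aggregate_runs(list(fake_rec(rep(0.4, 6)),
                                   fake_rec(rep(0.4, 5)))), "equal length")
})

test_that("sweep trends recover a linear relationship", {
  x <- c(1, 2, 3, 4)
  tr <- sweep_trend(x, 0.1 + 0.2 * x)
  expect_equal(unname(tr["slope"]), 0.2)
  expect_equal(unname(tr["intercept"]), 0.1)
})
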