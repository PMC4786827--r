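# Population (divide-by-N) variance and covariance: the convention used
# throughout, matching the Price-equation algebra. Sample (n-1) variants
# would break the exact decomposition identities.
pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)

#' Selection-strength proxies from a contribution matrix
#'
#' With many strategies in play, per-strategy frequency variances are
#' uninformative; the variance structure of contributions serves instead.
#' `Var(c_j)` — the population variance across groups of group-mean
#' contributions — proxies the strength of between-group selection, while
#' `E[Var(c_ij)]` — the unweighted mean across groups of the within-group
#' population variance — proxies within-group selection.
#'
#' @param contributions `n x g` matrix (column `j` = group `j`), or a list
#'   of equal-length numeric vectors.
#' @return List with `var_between` and `mean_var_within`. For equal group
#'   sizes the two terms add up to the population variance of all
#'   contributions (law of total variance).
#' @export
#' @examples
#' variance_proxies(cbind(c(0, 1), c(1, 1)))  # 0.0625 between, 0.125 within
variance_proxies <- function(contributions) {
  if (is.list(contributions)) {
    sizes <- lengths(contributions)
    if (length(unique(sizes)) != 1L) stop("groups must have equal size",
                                          call. = FALSE)
    contributions <- do.call(cbind, contributions)
  }
  if (length(contributions) == 0L) stop("empty input", call. = FALSE)
  contributions <- as.matrix(contributions)
  gm <- colMeans(contributions)
  dev <- contributions - rep(gm, each = nrow(contributions))
  list(var_between = pop_var(gm),
       mean_var_within = mean(colMeans(dev^2)))
}

#' Cooperative epochs of a contribution time series
#'
#' A cooperative epoch is a maximal run of consecutive generations in which
#' the population mean contribution is strictly above `threshold` (default
#' 60%). Their mean length L measures the stability of cooperation.
#'
#' @param mean_series Numeric vector of per-generation population mean
#'   contributions.
#' @param threshold Contribution cutoff in (0, 1). A generation exactly at
#'   the threshold ends an epoch.
#' @return An `epoch_summary`: list with `epochs` (data frame of 1-based
#'   `start` and `length`), `count`, `mean_length` (0 with `defined =
#'   FALSE` when there are no epochs) and `defined`.
#' @export
#' @examples
#' cooperative_epochs(c(0.7, 0.7, 0.5, 0.8))  # two epochs, L = 1.5
cooperative_epochs <- function(mean_series, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  above <- mean_series > threshold
  r <- rle(above)
  len <- r$lengths[r$values]
  start <- (cumsum(c(1L, r$lengths))[seq_along(r$lengths)])[r$values]
  structure(
    list(epochs = data.frame(start = start, length = len),
         count = length(len),
         mean_length = if (length(len)) mean(len) else 0,
         defined = length(len) > 0L),
    class = "epoch_summary"
  )
}

#' @export
print.epoch_summary <- function(x, ...) {
  cat(sprintf("%d cooperative epoch(s), mean length %s\n", x$count,
              if (x$defined) format(x$mean_length) else "undefined"))
  invisible(x)
}

#' Price-equation decomposition of trait-frequency change
#'
#' Partitions the expected one-generation change of a trait's population
#' frequency into a between-group and a within-group selection term:
#' `delta_p * w = Cov_q(w_j, p_j) + E_q[Cov_j(w_ij, p_ij)]`,
#' where `w_j`, `p_j` are group means, `q_j` group weights, `w` the
#' population mean payoff, and the inner covariance is the within-group
#' population covariance. The between term captures selective migration
#' (groups grow in proportion to relative payoff); the within term captures
#' payoff-proportional reproduction inside groups and is never positive for
#' a costly trait.
#'
#' @param trait List of per-group numeric vectors of trait values `p_ij`
#'   (e.g. 1 = unconditional cooperator, 0 = defector).
#' @param payoff List of per-group numeric vectors of payoffs `w_ij`,
#'   congruent with `trait`.
#' @param q Group weights summing to 1; default equal weights.
#' @return A `price_decomposition`: list with `between_term`,
#'   `within_term`, `mean_payoff` and `predicted_delta_p`
#'   (`= (between + within) / mean_payoff`).
#' @seealso [price_oracle()] for the brute-force next-generation frequency.
#' @export
#' @examples
#' # all-cooperator group vs all-defector group, n = 4, r = 2:
#' tr <- list(rep(1, 4), rep(0, 4))
#' pay <- lapply(tr, payoffs, w0 = 0, r = 2)
#' price_decomposition(tr, pay)  # delta_p = 1/6: altruists gain
price_decomposition <- function(trait, payoff, q = NULL) {
  check_price_input(trait, payoff, q)
  g <- length(trait)
  if (is.null(q)) q <- rep(1 / g, g)
  p_j <- vapply(trait, mean, numeric(1))
  w_j <- vapply(payoff, mean, numeric(1))
  w <- sum(q * w_j)
  if (w <= 0) stop("mean payoff must be positive", call. = FALSE)
  between <- sum(q * w_j * p_j) - w * sum(q * p_j)
  within <- sum(q * mapply(pop_cov, payoff, trait))
  structure(
    list(between_term = between, within_term = within, mean_payoff = w,
         predicted_delta_p = (between + within) / w),
    class = "price_decomposition"
  )
}

#' @export
print.price_decomposition <- function(x, ...) {
  cat(sprintf("Price decomposition: between %+.6g, within %+.6g, mean payoff %.6g\n",
              x$between_term, x$within_term, x$mean_payoff))
  cat(sprintf("  predicted delta p = %+.6g\n", x$predicted_delta_p))
  invisible(x)
}

#' Brute-force next-generation trait frequency
#'
#' Independent oracle for [price_decomposition()]: computes the expected
#' next-generation population frequency directly. Within each group
#' reproduction is payoff-proportional (`p'_j = sum(w_ij p_ij) / sum(w_ij)`);
#' between groups, selective migration rescales group weights by relative
#' payoff (`q'_j = q_j w_j / w`). Returns `p' - p`.
#'
#' @inheritParams price_decomposition
#' @return The exact expected change in population trait frequency.
#' @export
price_oracle <- function(trait, payoff, q = NULL) {
  check_price_input(trait, payoff, q)
  g <- length(trait)
  if (is.null(q)) q <- rep(1 / g, g)
  w_j <- vapply(payoff, mean, numeric(1))
  w <- sum(q * w_j)
  if (w <= 0) stop("mean payoff must be positive", call. = FALSE)
  p_next_j <- mapply(function(wi, pi) sum(wi * pi) / sum(wi), payoff, trait)
  q_next <- q * w_j / w
  sum(q_next * p_next_j) - sum(q * vapply(trait, mean, numeric(1)))
}

check_price_input <- function(trait, payoff, q) {
  if (!is.list(trait) || !is.list(payoff) ||
      length(trait) != length(payoff) || length(trait) < 1L) {
    stop("trait and payoff must be congruent non-empty lists of group vectors",
         call. = FALSE)
  }
  if (!all(lengths(trait) == lengths(payoff))) {
    stop("trait and payoff group vectors must have matching lengths",
         call. = FALSE)
  }
  if (!is.null(q) && abs(sum(q) - 1) > 1e-8) {
    stop("group weights must sum to 1", call. = FALSE)
  }
}

#' Viability condition for a costly trait under multilevel selection
#'
#' For the public goods payoff, the Price numerator reduces to
#' `(r - 1) * Var_q(p_j) - E_q[Var_j(p_ij)]`: the trait spreads iff
#' between-group variance, amplified by the net return `r - 1`, outweighs
#' the mean within-group variance.
#'
#' @param var_between_p Between-group population variance of group trait
#'   frequencies.
#' @param mean_var_within_p Mean within-group population variance.
#' @param r Total return to cooperation.
#' @param n Group size (bounds `r`).
#' @return `TRUE` iff the trait is expected to increase in frequency.
#' @export
viability_condition <- function(var_between_p, mean_var_within_p, r, n) {
  if (var_between_p < 0 || mean_var_within_p < 0) {
    stop("variances must be nonnegative", call. = FALSE)
  }
  if (!(r > 1 && r < n)) {
    stop("total return r must satisfy 1 < r < n", call. = FALSE)
  }
  (r - 1) * var_between_p > mean_var_within_p
}

#' Aggregate replicate runs
#'
#' Averages the per-generation columns of several [run_simulation()]
#' records (the replicate-mean trajectory), and summarises each run by its
#' whole-run and stabilized mean contribution and its mean cooperative
#' epoch length, with normal-approximation 95% confidence intervals across
#' runs.
#'
#' @param records List of `run_record` data frames of equal length.
#' @param epoch_threshold Threshold for [cooperative_epochs()].
#' @param stabilized_frac Final fraction of generations regarded as
#'   stabilized (default 0.2: the last 1000 of 5000).
#' @return List with `mean_record` (generation-wise mean of every column),
#'   `run_summaries` (one row per run), and `summary` (across-run means and
#'   95% CIs; CI bounds equal the point estimate, flagged
#'   `ci_defined = FALSE`, for a single run).
#' @export
aggregate_runs <- function(records, epoch_threshold = 0.6,
                           stabilized_frac = 0.2) {
  if (length(records) < 1L) stop("need at least one run", call. = FALSE)
  T <- nrow(records[[1]])
  if (!all(vapply(records, nrow, integer(1)) == T)) {
    stop("runs must have equal length", call. = FALSE)
  }
  arr <- vapply(records, function(r) as.matrix(as.data.frame(r)),
                matrix(0, T, ncol(records[[1]])))
  mean_record <- as.data.frame(apply(arr, c(1, 2), mean))
  names(mean_record) <- names(records[[1]])

  tail_idx <- seq.int(max(1L, floor(T * (1 - stabilized_frac)) + 1L), T)
  run_summaries <- do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    ep <- cooperative_epochs(r$mean_contribution, epoch_threshold)
    data.frame(run = i,
               mean_contribution = mean(r$mean_contribution),
               stabilized_mean = mean(r$mean_contribution[tail_idx]),
               mean_epoch_length = ep$mean_length,
               n_epochs = ep$count)
  }))

  ci <- function(x) {
    m <- mean(x)
    if (length(x) < 2L) return(c(mean = m, lo = m, hi = m))
    half <- qnorm(0.975) * stats::sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }
  summary <- list(
    runs = length(records),
    mean_contribution = ci(run_summaries$mean_contribution),
    stabilized_mean = ci(run_summaries$stabilized_mean),
    mean_epoch_length = ci(run_summaries$mean_epoch_length),
    ci_defined = length(records) >= 2L
  )
  list(mean_record = mean_record, run_summaries = run_summaries,
       summary = summary)
}

#' Least-squares trend of a sweep summary
#'
#' Ordinary least-squares fit of a response (e.g. mean cooperation, or the
#' log mean epoch length) against the swept parameter, as shown alongside
#' sweep curves.
#'
#' @param x Sweep parameter values.
#' @param y Response values.
#' @return Named vector with `intercept` and `slope`.
#' @export
sweep_trend <- function(x, y) {
  fit <- lm(y ~ x)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}
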