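#' Within-group equilibrium contributions
#'
#' Computes the contribution profile a group settles on when the public
#' goods interaction is repeated indefinitely. Members hold a belief about
#' the others' mean contribution, starting from an optimistic prior
#' (`initial_belief = 1`: everyone expects full contribution), contribute
#' according to their response function, and all update beliefs
#' simultaneously to the realised mean contribution of the *other* members.
#'
#' The iteration stops at a fixed point (every member best-responds to the
#' others' realised mean), or on an exact recurrence of the contribution
#' vector (a limit cycle: since anchors sit on a 0.5-grid and interpolation
#' is linear, many orbits live on a finite rational set). For a cycle the
#' per-member average over one full period is returned — the long-run
#' average contribution of infinitely repeated play. If neither occurs
#' within `max_iter` rounds, the average over the trailing `window` rounds
#' is returned and `converged` is `FALSE`.
#'
#' @param strategies Integer vector of strategy labels (0..26), or a list of
#'   `strategy_spec` objects; one entry per group member.
#' @param initial_belief Common initial belief about others' mean
#'   contribution, in \[0, 1\]. Default 1 (optimistic).
#' @param max_iter Maximum number of synchronous rounds (>= 2).
#' @param tol Fixed-point tolerance on the max contribution change.
#' @param window Trailing-window length for the non-convergent fallback.
#' @return An `equilibrium_result`: list with `contributions` (one value per
#'   member), `converged` (logical), `cycle_length` (1 for a fixed point,
#'   the period for a cycle, `NA` if not converged) and `iterations`.
#' @export
#' @examples
#' group_equilibrium(rep(5, 4))             # all-conditional: stays at 1
#' group_equilibrium(c(0, rep(5, 19)))      # one free rider collapses it
#' group_equilibrium(rep(18, 4))            # 2-cycle, long-run average 0.5
group_equilibrium <- function(strategies, initial_belief = 1,
                              max_iter = 200L, tol = 1e-9, window = 50L) {
  labels <- as_labels(strategies)
  if (length(labels) == 0L) stop("empty group", call. = FALSE)
  if (max_iter < 2) stop("max_iter must be >= 2", call. = FALSE)
  if (initial_belief < 0 || initial_belief > 1) {
    stop("initial_belief must lie in [0, 1]", call. = FALSE)
  }
  res <- eq_groups_cpp(matrix(labels, ncol = 1L), .anchor_matrix,
                       initial_belief, as.integer(max_iter), tol,
                       as.integer(window))
  structure(
    list(contributions = as.numeric(res$contributions),
         converged = res$converged[1],
         cycle_length = res$cycle_length[1],
         iterations = res$iterations[1]),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Group equilibrium (%s, cycle length %s, %d rounds)\n",
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$cycle_length, x$iterations))
  print(x$contributions)
  invisible(x)
}

# Coerce labels / strategy_spec list to an integer label vector.
as_labels <- function(strategies) {
  if (inherits(strategies, "strategy_spec")) return(strategies$label)
  if (is.list(strategies)) {
    return(vapply(strategies,
                  function(s) if (inherits(s, "strategy_spec")) s$label
                              else as.integer(s),
                  integer(1)))
  }
  if (anyNA(strategies) || any(strategies < 0 | strategies > 26) ||
      any(strategies != as.integer(strategies))) {
    stop("invalid strategy label", call. = FALSE)
  }
  as.integer(strategies)
}

# All-groups equilibrium on an n x g label matrix; internal engine service.
equilibrium_matrix <- function(labels, initial_belief = 1, max_iter = 200L,
                               tol = 1e-9, window = 50L) {
  eq_groups_cpp(labels, .anchor_matrix, initial_belief,
                as.integer(max_iter), tol, as.integer(window))
}
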