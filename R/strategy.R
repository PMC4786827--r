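#' @useDynLib mlspgg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif var cov qnorm lm coef
#' @importFrom utils write.csv
NULL

# 27 x 3 anchor lookup, row l+1 = anchors of label l. Built once at load.
.anchor_matrix <- local({
  l <- 0:26
  m <- cbind(l %/% 9L, (l %/% 3L) %% 3L, l %% 3L) / 2
  dimnames(m) <- list(sprintf("%02d", l), c("x0", "x0.5", "x1"))
  m
})

#' Anchor contribution levels for all 27 conditional strategies
#'
#' Each strategy is a piecewise linear response function fixed by its
#' contribution level at three values of the others' mean contribution
#' (0, 0.5 and 1). Anchors take values in \{0, 0.5, 1\}, so the strategy
#' space is the 27 ternary strings of length 3.
#'
#' @return A 27 x 3 numeric matrix; row `l + 1` holds the anchors of
#'   strategy label `l` at mean-others contributions 0, 0.5 and 1.
#' @export
#' @examples
#' anchor_matrix()[2 + 1, ]  # Type 2 (ternary 002)
anchor_matrix <- function() .anchor_matrix

#' Decode a strategy label into its ternary digits and anchors
#'
#' Labels 0-26 are the base-3 interpretation (most significant digit first)
#' of the ternary string whose digits give the contribution level
#' (0 -> 0, 1 -> 0.5, 2 -> 1) at mean-others contribution 0, 0.5 and 1.
#' Type 0 (000) is a free rider, Type 5 (012) a perfectly conditional
#' cooperator, Type 26 (222) an unconditional cooperator.
#'
#' @param label Integer in 0..26.
#' @return A `strategy_spec`: list with `label`, `digits` (ternary triple),
#'   `anchors` (`digits / 2`) and `string` (3-character ternary string).
#' @seealso [encode_strategy()], [respond()]
#' @export
#' @examples
#' decode_strategy(5)   # 012: the perfectly conditional cooperator
#' decode_strategy(2)   # 002: unexploitable but capable of full cooperation
decode_strategy <- function(label) {
  if (length(label) != 1L || is.na(label) || label != as.integer(label) ||
      label < 0 || label > 26) {
    stop("invalid strategy label: must be a single integer in 0..26",
         call. = FALSE)
  }
  label <- as.integer(label)
  digits <- c(label %/% 9L, (label %/% 3L) %% 3L, label %% 3L)
  structure(
    list(label = label, digits = digits, anchors = digits / 2,
         string = paste(digits, collapse = "")),
    class = "strategy_spec"
  )
}

#' Encode anchor contribution levels as a strategy
#'
#' Inverse of [decode_strategy()]: maps a triple of contribution levels in
#' \{0, 0.5, 1\} (at mean-others contribution 0, 0.5, 1) to its ternary
#' string and decimal label. The points (0, 0.5), (0.5, 0), (1, 1) give
#' the string "102".
#'
#' @param anchors Numeric triple, each in \{0, 0.5, 1\}.
#' @return A `strategy_spec`.
#' @export
#' @examples
#' encode_strategy(c(0, 0.5, 1))$label    # 5
#' encode_strategy(c(0.5, 0, 1))$string   # "102"
encode_strategy <- function(anchors) {
  if (length(anchors) != 3L || anyNA(anchors) ||
      !all(anchors %in% c(0, 0.5, 1))) {
    stop("invalid anchors: need three values, each one of 0, 0.5 or 1",
         call. = FALSE)
  }
  digits <- as.integer(anchors * 2)
  decode_strategy(9L * digits[1] + 3L * digits[2] + digits[3])
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("Type %d (%s): anchors c(%s) at xbar = 0, 0.5, 1\n",
              x$label, x$string, paste(x$anchors, collapse = ", ")))
  invisible(x)
}

#' @export
format.strategy_spec <- function(x, ...) sprintf("Type %d (%s)", x$label, x$string)

#' Evaluate a conditional strategy's response function
#'
#' The response is the piecewise linear interpolation of the three anchors:
#' linear on \[0, 0.5\] and on \[0.5, 1\] with the only breakpoint at 0.5.
#' The result is clamped to \[0, 1\] (vacuous for the anchor grid, asserted
#' for safety).
#'
#' @param strategy A `strategy_spec` or a strategy label in 0..26.
#' @param xbar Mean contribution of the other group members, in \[0, 1\].
#'   Vectorised.
#' @return Contribution level(s) in \[0, 1\].
#' @export
#' @examples
#' respond(5, 0.37)   # perfectly conditional: mirrors xbar
#' respond(2, 0.75)   # halfway up the rising segment of Type 2
respond <- function(strategy, xbar) {
  if (!inherits(strategy, "strategy_spec")) strategy <- decode_strategy(strategy)
  if (anyNA(xbar) || any(xbar < 0 | xbar > 1)) {
    stop("xbar must lie in [0, 1]", call. = FALSE)
  }
  a <- strategy$anchors
  lo <- a[1] + (a[2] - a[1]) * (2 * xbar)       # xbar in [0, 0.5]
  hi <- a[2] + (a[3] - a[2]) * (2 * xbar - 1)   # xbar in (0.5, 1]
  pmin(pmax(ifelse(xbar <= 0.5, lo, hi), 0), 1)
}

#' Strategy labels of a strategy space
#'
#' "full" is all 27 conditional strategies; "unconditional" restricts to the
#' three constant response functions \{0 (000), 13 (111), 26 (222)\}, the
#' control under which cooperation cannot be established at baseline
#' selection strength.
#'
#' @param space `"full"` or `"unconditional"`.
#' @return Integer vector of admissible labels.
#' @export
strategy_space <- function(space = c("full", "unconditional")) {
  space <- match.arg(space)
  if (space == "full") 0:26 else c(0L, 13L, 26L)
}

#' Ternary string of a strategy label
#'
#' @param label Integer vector of labels in 0..26.
#' @return Character vector of 3-digit ternary strings.
#' @export
ternary_string <- function(label) {
  if (anyNA(label) || any(label < 0 | label > 26)) {
    stop("invalid strategy label", call. = FALSE)
  }
  label <- as.integer(label)
  paste0(label %/% 9L, (label %/% 3L) %% 3L, label %% 3L)
}
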