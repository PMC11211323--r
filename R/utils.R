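# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif rbinom rbeta plogis qlogis sd quantile pnorm
#'   predict cor median var binomial glm coef lm cov
#' @importFrom utils head tail
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package funnel through this so that seeds are local and composable.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a master seed and a stage label, staying below
# 2^31 - 1.  Deterministic and stable across platforms.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 7919 + h * 104729) %% 2147483629L)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "deeprisk_parameter_error")
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# z-score with a degenerate-sd guard: constant vectors map to zeros.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

lead_names_12 <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}
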