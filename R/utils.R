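# Small numerical helpers shared across modules.

#' Logit and inverse-logit
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] used for all
#' probability-scale transformations in the package.
#'
#' @param p proportion in (0, 1).
#' @param x real number.
#' @return `logit()` returns a real number; `invlogit()` a proportion.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

# Clamp a proportion away from {0, 1} with the 1/(2n) continuity correction.
# n is the effective sample size; the survey literature default when the
# denominator is unknown is used upstream.
correct_boundary <- function(p, n = 1000) {
  eps <- 1 / (2 * n)
  pmin(pmax(p, eps), 1 - eps)
}

# Half-normal log-density (support x >= 0), scale parameter `scale`.
dhalfnorm_log <- function(x, scale) {
  out <- log(2) + stats::dnorm(x, mean = 0, sd = scale, log = TRUE)
  out[x < 0] <- -Inf
  out
}

# Deterministic child seed: fold a label into a base seed, staying well
# inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted draw-level convex combination sanity check helper
stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(TRUE)
}
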