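# Internal numeric and RNG helpers.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' @noRd
odds <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("odds undefined: probability of 0 or 1 encountered", call. = FALSE)
  }
  p / (1 - p)
}

# Deterministic per-variable substream seed. Each generated variable draws
# under its own seed derived from (master seed, variable name), so adding a
# new variable to the generator leaves all existing variables untouched.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L + 1)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Truncated normal via inverse-CDF; vectorised over the mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(abs(x) * s + 0.5) / s * sign(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
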