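# Internal helpers: seeded evaluation, sub-stream seeds, small validators.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed so that plant / schedule / training randomness
# are independently reproducible from one session seed. Kept below 2^31.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# First-order low-pass recursion y[i] = y[i-1] + alpha * (x[i] - y[i-1]),
# vectorised via stats::filter (recursive AR(1)).
first_order_relax <- function(target, alpha, init = target[1L]) {
  if (length(target) == 0L) return(numeric(0))
  alpha <- min(max(alpha, 0), 1)
  # y[1] = alpha * x[1] + (1 - alpha) * init, i.e. init plays the role of y[0]
  y <- stats::filter(alpha * target, filter = 1 - alpha,
                     method = "recursive", init = init)
  as.numeric(y)
}
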