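#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All validation errors are thrown
# with a class so callers (and tests) can distinguish bad input from bugs.

gm_stop <- function(msg, class = "genometab_error", ...) {
  stop(structure(class = c(class, "genometab_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

gm_assert <- function(ok, msg, class = "genometab_validation_error") {
  if (!isTRUE(ok)) gm_stop(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x)

# Truncated-normal sampler via inverse CDF; deterministic given the RNG
# stream. lo/hi may be -Inf/Inf.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Cumulative trapezoidal integral of y over x, returned as a function of
# position (linear interpolation between grid points => exact for piecewise
# linear signals).
cumtrapz_fun <- function(x, y) {
  cz <- c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  stats::approxfun(x, cz, rule = 2)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Seed scoping: run expr under a fixed seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, expr) {
  gm_assert(is_count(seed), "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive stage-specific child seeds from one master seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}
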