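#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Stop with a message naming the offending field/argument.
cb_stop <- function(...) stop(sprintf(...), call. = FALSE)

cb_check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min ||
      x != round(x)) {
    cb_stop("'%s' must be a single integer >= %d (got %s)",
            field, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

cb_check_number <- function(x, field, lower = -Inf, upper = Inf,
                            lower_open = FALSE, upper_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) cb_stop("'%s' must be a number in %s%g, %g%s (got %s)",
                   field, if (lower_open) "(" else "[", lower, upper,
                   if (upper_open) ")" else "]", paste(format(x), collapse = ","))
  as.numeric(x)
}

# Derive a stream-specific 32-bit seed from a master seed by skipping ahead
# in the master-seeded generator: position (stream, index) maps to a distinct
# draw, and the resulting seeds are well-scrambled 31-bit integers. Linear
# combinations of the master seed must not be used here: set.seed() initialized
# with closely related values yields subtly correlated streams, which couples
# quantities that must be independent (e.g. scores and signal noise).
cb_derive_seed <- function(seed, stream, index = 0L) {
  pos <- stream * 1000L + (index %% 1000L) + 1L
  with_local_seed(as.integer(abs(seed) %% 2147483629), {
    u <- stats::runif(pos)
    as.integer(floor(u[pos] * 2147483629))
  })
}

# Evaluate `expr` with a local RNG state seeded at `seed`; the caller's RNG
# state is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Inverse-CDF sampler for a truncated normal: uses exactly `n` uniform draws,
# which keeps downstream RNG streams aligned regardless of the bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

# Population standard deviation of a truncated normal.
truncnorm_sd <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  vf <- 1 + (a * da - b * db) / z - ((da - db) / z)^2
  sd * sqrt(vf)
}

#' Scan duration in minutes
#'
#' Converts a volume count and repetition time into an acquisition duration,
#' e.g. 200 volumes at TR = 2 s last 6.7 minutes.
#'
#' @param n_volumes Number of volumes.
#' @param tr_seconds Repetition time in seconds.
#' @return Duration in minutes.
#' @export
scan_duration_minutes <- function(n_volumes, tr_seconds) {
  n_volumes <- cb_check_count(n_volumes, "n_volumes", min = 0L)
  tr_seconds <- cb_check_number(tr_seconds, "tr_seconds", lower = 0,
                                lower_open = TRUE)
  n_volumes * tr_seconds / 60
}
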