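# Shared helpers: link functions, time conversions, seeded evaluation.

# Days per month used for all date <-> month conversions.
DAYS_PER_MONTH <- 30.44

expit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a number of days to months
#'
#' Uses the fixed convention of 30.44 days per month for every conversion in
#' the package, so date arithmetic and simulated event times are directly
#' comparable.
#'
#' @param days numeric vector of day counts (or a difftime).
#' @return numeric vector of months.
#' @export
days_to_months <- function(days) as.numeric(days) / DAYS_PER_MONTH

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Syntactic ATC code check: levels 1/2/3/4/5 have 1/3/4/5/7 characters.
is_valid_atc <- function(x) {
  grepl("^[A-Z]$|^[A-Z][0-9]{2}$|^[A-Z][0-9]{2}[A-Z]$|^[A-Z][0-9]{2}[A-Z]{2}$|^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$",
        x)
}

stop_pharmscreen <- function(...) stop(..., call. = FALSE)
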