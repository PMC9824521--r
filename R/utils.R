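# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All stochastic steps in the package (SMOTE, undersampling, forest fits,
#' fold splitting, cohort simulation) run under explicit seeds through this
#' helper so repeated calls are reproducible and the caller's RNG stream is
#' never consumed.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Timestamps are timezone-naive local clock time; internally they are POSIXct
# pinned to UTC so arithmetic is pure seconds with no DST surprises.
#' @noRd
as_instant <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(as.numeric(x) * 86400, origin = "1970-01-01", tz = "UTC"))
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    if (anyNA(out) && !all(is.na(x)))
      stopf("unparseable timestamp(s): %s",
            paste(utils::head(x[is.na(out)], 3L), collapse = ", "))
    return(out)
  }
  stopf("cannot interpret object of class '%s' as a timestamp", class(x)[1L])
}

#' @noRd
as_day <- function(x) as.Date(as_instant(x), tz = "UTC")

#' @noRd
fmt_instant <- function(x) format(as_instant(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Population (divisor n) moments; the Lorenz/Poincare statistics use these.
#' @noRd
pop_var <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

#' @noRd
pop_sd <- function(x) sqrt(pop_var(x))
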