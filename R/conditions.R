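#' @keywords internal
"_PACKAGE"

# Structured conditions: every contract violation raises a classed error so
# callers (and tests) can dispatch on the failure kind rather than on message
# text. All classes inherit from "wq_error".

wq_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "wq_error", "error")))
}

wq_format_error <- function(fmt, ...) wq_stop("wq_format_error", fmt, ...)
wq_validation_error <- function(fmt, ...) wq_stop("wq_validation_error", fmt, ...)
wq_reference_error <- function(fmt, ...) wq_stop("wq_reference_error", fmt, ...)
wq_range_error <- function(fmt, ...) wq_stop("wq_range_error", fmt, ...)
wq_argument_error <- function(fmt, ...) wq_stop("wq_argument_error", fmt, ...)
wq_order_error <- function(fmt, ...) wq_stop("wq_order_error", fmt, ...)
wq_io_error <- function(fmt, ...) wq_stop("wq_io_error", fmt, ...)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed-width numeric formatting used for all report files so reruns are
# byte-identical regardless of options(digits)/scipen.
fmt_num <- function(x, digits = 4) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out
}
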