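#' @importFrom stats cor var sd rnorm runif rnbinom phyper dhyper setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a number at full double precision for text serialisation
#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Assert a scalar value lies in a closed range
#' @noRd
check_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("%s must be a single number in [%s, %s]", what, lo, hi)
  invisible(x)
}

PHENOTYPES <- c("LA", "HA")
PLATFORMS <- c("count", "intensity")
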