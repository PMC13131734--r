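#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm pchisq qnorm rnorm runif rbinom median mad sd
#'   ecdf setNames phyper p.adjust complete.cases quantile optimize cor
#' @importFrom utils head tail
NULL

# timestamped log line; all package logging funnels through here so the
# pipeline can redirect it to a file
pl_log <- function(..., verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  msg <- paste0("[", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), "] ", ...)
  message(msg)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
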