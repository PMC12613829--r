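`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

#' @noRd
check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

#' @noRd
check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a finite number")
  as.numeric(x)
}

#' @noRd
check_positive <- function(x, field) {
  x <- check_number(x, field)
  if (x <= 0) config_error(field, "must be > 0")
  x
}

# standardize a column; constants may be supplied to hold scaling fixed
standardize <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x)
  scale <- scale %||% stats::sd(x)
  if (!is.finite(scale) || scale <= 0)
    stop("cannot standardize a constant column", call. = FALSE)
  list(z = (x - center) / scale, center = center, scale = scale)
}

# stable hash of an R object, used for run provenance
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
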