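#' Regional time series
#'
#' Container for one subject x one region signal: a numeric sample vector
#' plus sampling rate and identifying labels. This is the unit of input to
#' all PAC computations; cohorts are tibbles holding one `regional_ts` per
#' row in a list-column.
#'
#' @param samples numeric vector of signal values. Must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id,group,region optional character labels.
#' @return an object of class `regional_ts`.
#' @export
#' @examples
#' x <- regional_ts(sin(2 * pi * 6 * seq_len(1200) / 120), fs = 120)
#' x
regional_ts <- function(samples, fs, subject_id = NA_character_,
                        group = NA_character_, region = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2) {
    abort("`samples` must be a numeric vector with at least 2 values")
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1]
    abort(sprintf("`samples` contains a non-finite value at position %d", bad))
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(
      samples = as.numeric(samples),
      fs = as.numeric(fs),
      subject_id = as.character(subject_id),
      group = as.character(group),
      region = as.character(region)
    ),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf(
    "<regional_ts> %d samples @ %g Hz (%.1f s)  subject=%s group=%s region=%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    x$subject_id, x$group, x$region
  ))
  invisible(x)
}

#' @export
length.regional_ts <- function(x) length(x$samples)

#' Duration of a regional time series in seconds
#' @param x a `regional_ts`.
#' @return duration in seconds.
#' @export
ts_duration <- function(x) {
  stopifnot(inherits(x, "regional_ts"))
  length(x$samples) / x$fs
}
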