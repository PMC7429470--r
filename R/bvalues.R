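#' Default multi-b-value acquisition scheme
#'
#' The 11-b-value diffusion-weighting scheme used throughout the package:
#' b = 0, 10, 20, 40, 80, 150, 200, 400, 800, 1000, 1200 s/mm^2. The dense
#' low-b sampling (b <= 200) resolves the perfusion compartment of the
#' bi-exponential model; the four high-b points anchor pure diffusion.
#'
#' @return Numeric vector of b-values in s/mm^2.
#' @export
#' @examples
#' default_bvalues()
default_bvalues <- function() {
  c(0, 10, 20, 40, 80, 150, 200, 400, 800, 1000, 1200)
}

#' Validate a b-value scheme
#'
#' A valid scheme is a strictly increasing numeric vector starting at b = 0.
#'
#' @param b_values numeric vector of diffusion weightings, s/mm^2.
#' @return The validated vector, invisibly classed as `bvalue_scheme`.
#' @export
bvalue_scheme <- function(b_values = default_bvalues()) {
  if (!is.numeric(b_values) || length(b_values) < 2) {
    stop("a b-value scheme needs at least two numeric b-values", call. = FALSE)
  }
  if (b_values[1] != 0) {
    stop("the first b-value must be 0 (the unweighted reference)", call. = FALSE)
  }
  if (any(diff(b_values) <= 0)) {
    stop("b-values must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(b_values), class = "bvalue_scheme")
}

#' Construct a signal-decay curve
#'
#' Pairs one signal intensity with each b-value of a scheme. The intensity at
#' b = 0 (S0) must be strictly positive; intensities at b > 0 may reach zero
#' (noise floor) but not below.
#'
#' @param intensities non-negative signal intensities, arbitrary units, one
#'   per b-value.
#' @param b_values b-value scheme (defaults to [default_bvalues()]).
#' @return A `signal_decay` object: list with elements `b_values` and
#'   `intensities`.
#' @export
#' @examples
#' sd0 <- signal_decay(mono_signal(default_bvalues(), adc = 1e-3, s0 = 100))
signal_decay <- function(intensities, b_values = default_bvalues()) {
  b_values <- unclass(bvalue_scheme(b_values))
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(b_values)) {
    stop(sprintf("length mismatch: %d intensities for %d b-values",
                 length(intensities), length(b_values)), call. = FALSE)
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  if (intensities[1] <= 0) {
    stop("the b = 0 intensity (S0) must be strictly positive", call. = FALSE)
  }
  structure(list(b_values = b_values, intensities = intensities),
            class = "signal_decay")
}

#' @export
print.signal_decay <- function(x, ...) {
  cat("signal decay over", length(x$b_values), "b-values (",
      min(x$b_values), "-", max(x$b_values), "s/mm^2 ), S0 =",
      format(x$intensities[1]), "\n")
  invisible(x)
}

#' Read a per-ROI decay table
#'
#' Reads a CSV with columns `b_value` and `intensity` into a [signal_decay()].
#'
#' @param path CSV file path.
#' @return A `signal_decay` object.
#' @export
read_decay_csv <- function(path) {
  tab <- read.csv(path)
  if (!all(c("b_value", "intensity") %in% names(tab))) {
    stop("decay CSV must have columns 'b_value' and 'intensity'", call. = FALSE)
  }
  tab <- tab[order(tab$b_value), , drop = FALSE]
  signal_decay(tab$intensity, tab$b_value)
}

#' Write a per-ROI decay table
#'
#' @param decay a [signal_decay()] object.
#' @param path output CSV path.
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "signal_decay"))
  write.csv(data.frame(b_value = decay$b_values,
                       intensity = decay$intensities),
            path, row.names = FALSE)
  invisible(path)
}
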