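#' Forward diffusion signal models
#'
#' Noise-free signal predicted at diffusion weighting `b` by each of the three
#' decay models:
#'
#' * mono-exponential: \eqn{S(b) = S_0 \exp(-b \cdot ADC)}
#' * bi-exponential (intravoxel incoherent motion, IVIM):
#'   \eqn{S(b) = S_0 [(1 - f_p)\exp(-b D_{slow}) + f_p \exp(-b D_{fast})]}
#' * stretched-exponential: \eqn{S(b) = S_0 \exp(-(b \cdot DDC)^\alpha)}
#'
#' All diffusivities (`adc`, `d_slow`, `d_fast`, `ddc`) are in mm^2/s; `b` is
#' in s/mm^2; `f_p` (perfusion fraction) and `alpha` (intravoxel heterogeneity
#' index) are dimensionless. Every model returns exactly `s0` at b = 0 and is
#' strictly decreasing in b for valid parameters.
#'
#' @param b diffusion weighting(s), s/mm^2, non-negative. Vectorized.
#' @param adc apparent diffusion coefficient, mm^2/s, > 0.
#' @param d_slow pure (tissue) diffusion coefficient, mm^2/s, > 0.
#' @param d_fast perfusion-related pseudo-diffusion coefficient, mm^2/s,
#'   must exceed `d_slow` (it is typically an order of magnitude larger).
#' @param f_p perfusion fraction in \[0, 1\].
#' @param ddc distributed diffusion coefficient, mm^2/s, > 0.
#' @param alpha heterogeneity index in (0, 1\]; `alpha = 1` collapses to the
#'   mono-exponential model.
#' @param s0 signal at b = 0, > 0.
#' @return Numeric vector of predicted signal intensities, same length as `b`.
#' @name forward_models
NULL

check_b <- function(b) {
  if (anyNA(b) || any(b < 0)) stop("b-values must be non-negative", call. = FALSE)
  as.numeric(b)
}

check_s0 <- function(s0) {
  if (length(s0) != 1 || is.na(s0) || s0 <= 0) {
    stop("s0 must be a single positive signal intensity", call. = FALSE)
  }
  as.numeric(s0)
}

#' @rdname forward_models
#' @export
#' @examples
#' mono_signal(c(0, 800), adc = 0.94e-3, s0 = 1)
mono_signal <- function(b, adc, s0 = 1) {
  b <- check_b(b); s0 <- check_s0(s0)
  if (is.na(adc) || adc <= 0) stop("adc must be > 0", call. = FALSE)
  s0 * exp(-b * adc)
}

#' @rdname forward_models
#' @export
biexp_signal <- function(b, d_slow, d_fast, f_p, s0 = 1) {
  b <- check_b(b); s0 <- check_s0(s0)
  if (is.na(d_slow) || d_slow <= 0) stop("d_slow must be > 0", call. = FALSE)
  if (is.na(d_fast) || d_fast <= d_slow) {
    stop("d_fast must exceed d_slow", call. = FALSE)
  }
  if (is.na(f_p) || f_p < 0 || f_p > 1) {
    stop("f_p must lie in [0, 1]", call. = FALSE)
  }
  s0 * ((1 - f_p) * exp(-b * d_slow) + f_p * exp(-b * d_fast))
}

#' @rdname forward_models
#' @export
stretched_signal <- function(b, ddc, alpha, s0 = 1) {
  b <- check_b(b); s0 <- check_s0(s0)
  if (is.na(ddc) || ddc <= 0) stop("ddc must be > 0", call. = FALSE)
  if (is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  s0 * exp(-(b * ddc)^alpha)
}

# Evaluate a forward model from a named parameter list; used by the phantom
# generator and voxelwise fitting so models stay addressable by name.
model_signal <- function(model, b, params, s0 = 1) {
  switch(model,
    mono = mono_signal(b, adc = params$adc, s0 = s0),
    biexp = biexp_signal(b, d_slow = params$d_slow, d_fast = params$d_fast,
                         f_p = params$f_p, s0 = s0),
    stretched = stretched_signal(b, ddc = params$ddc, alpha = params$alpha,
                                 s0 = s0),
    stop("unknown model: ", model, call. = FALSE)
  )
}

model_param_names <- function(model) {
  switch(model,
    mono = "adc",
    biexp = c("d_slow", "d_fast", "f_p"),
    stretched = c("ddc", "alpha"),
    stop("unknown model: ", model, call. = FALSE)
  )
}
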