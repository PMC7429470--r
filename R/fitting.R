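#' @title Model fitting for multi-b-value decay curves
#'
#' @description
#' Inverse estimation of the three forward models from a measured
#' [signal_decay()]. All final estimates come from bounded nonlinear least
#' squares on the linear signal scale (Levenberg-Marquardt via
#' \pkg{minpack.lm}); log-linear ordinary least squares serves only as the
#' initializer, because regressing on log-signal distorts the noise weighting
#' at high b where the signal approaches the noise floor.
#'
#' Fitting bounds (diffusivities in mm^2/s) bracket the physiological range
#' of pelvic tumors: `d_slow`, `adc`, `ddc` in \[1e-5, 5e-3\] (adc lower
#' bound 0 to admit the degenerate zero-decay curve), `d_fast` in
#' \[`d_slow`, 0.5\], `f_p` in \[0, 1\], `alpha` in \[0.01, 1\].
#'
#' @name fitting
NULL

.DIFF_LOWER <- 1e-5
.DIFF_UPPER <- 5e-3
.DFAST_UPPER <- 0.5
.ALPHA_LOWER <- 0.01

new_dwi_fit <- function(model, params, s0, residual_sse, converged,
                        n_points_used, n_clipped = 0L, diagnostics = list()) {
  structure(list(model = model, params = params, s0 = s0,
                 residual_sse = residual_sse, converged = converged,
                 n_points_used = n_points_used, n_clipped = n_clipped,
                 diagnostics = diagnostics),
            class = "dwi_fit")
}

#' @export
print.dwi_fit <- function(x, ...) {
  pv <- unlist(x$params)
  # report diffusivities in the conventional x1e-3 mm^2/s table units
  shown <- ifelse(grepl("^(adc|d_slow|d_fast|ddc)$", names(pv)), pv * 1e3, pv)
  unit <- ifelse(grepl("^(adc|d_slow|d_fast|ddc)$", names(pv)),
                 " x1e-3 mm^2/s", "")
  cat(sprintf("%s fit (%s)\n", x$model,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  for (i in seq_along(pv)) {
    cat(sprintf("  %-7s %8.4f%s\n", names(pv)[i], shown[i], unit[i]))
  }
  cat(sprintf("  SSE %.4g over %d points\n", x$residual_sse, x$n_points_used))
  invisible(x)
}

# Clip non-positive intensities at b > 0 to a small positive floor so the
# log-linear initializer is defined; the count is surfaced as a diagnostic.
clip_noise_floor <- function(b, s) {
  floor_val <- 1e-6 * s[1]
  bad <- b > 0 & s <= 0
  s[bad] <- floor_val
  list(s = s, n_clipped = sum(bad))
}

# Log-linear OLS of log(S) on b: returns c(amplitude, decay rate).
loglin_start <- function(b, s) {
  fit <- lm(log(s) ~ b)
  c(A = exp(unname(coef(fit)[1])), D = -unname(coef(fit)[2]))
}

# Bounded Levenberg-Marquardt on a residual function; returns par + status.
lm_fit <- function(resid_fn, start, lower, upper) {
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  # info 1-3: ftol/ptol convergence; 4: gradient orthogonality (gtol)
  list(par = out$par, sse = sum(out$fvec^2), converged = out$info %in% 1:4)
}

#' Fit the mono-exponential (ADC) model
#'
#' Estimates the apparent diffusion coefficient over all b-values of the
#' scheme. A log-linear OLS fit initializes a bounded nonlinear
#' least-squares refinement of both the amplitude and ADC on the linear
#' signal scale.
#'
#' A perfectly flat curve (no decay) is an exact ADC = 0 solution: it is
#' returned converged with `diagnostics$zero_decay = TRUE`. If no b > 0
#' point carries positive signal the fit is flagged `converged = FALSE`.
#'
#' @param decay a [signal_decay()].
#' @return A `dwi_fit` with `params$adc` (mm^2/s), fitted amplitude `s0`,
#'   residual sum of squares, convergence flag and point counts.
#' @export
#' @examples
#' d <- signal_decay(mono_signal(default_bvalues(), adc = 1.08e-3, s0 = 100))
#' fit_mono(d)$params$adc
fit_mono <- function(decay) {
  stopifnot(inherits(decay, "signal_decay"))
  b <- decay$b_values; s <- decay$intensities
  if (length(b) < 2) stop("need at least 2 b-values", call. = FALSE)
  if (all(s[b > 0] <= 0)) {
    return(new_dwi_fit("mono", list(adc = NA_real_), s0 = s[1],
                       residual_sse = NA_real_, converged = FALSE,
                       n_points_used = length(b),
                       diagnostics = list(reason = "no positive signal at b > 0")))
  }
  cl <- clip_noise_floor(b, s); s <- cl$s
  if (diff(range(s)) <= 1e-12 * s[1]) {
    return(new_dwi_fit("mono", list(adc = 0), s0 = mean(s),
                       residual_sse = sum((s - mean(s))^2), converged = TRUE,
                       n_points_used = length(b), n_clipped = cl$n_clipped,
                       diagnostics = list(zero_decay = TRUE)))
  }
  st <- loglin_start(b, s)
  start <- c(A = max(st[["A"]], 1e-12), adc = min(max(st[["D"]], 1e-6), .DIFF_UPPER))
  res <- lm_fit(function(p) s - p[1] * exp(-b * p[2]),
                start, lower = c(1e-12, 0), upper = c(Inf, .DIFF_UPPER))
  new_dwi_fit("mono", list(adc = unname(res$par[2])), s0 = unname(res$par[1]),
              residual_sse = res$sse, converged = res$converged,
              n_points_used = length(b), n_clipped = cl$n_clipped)
}

#' Fit the bi-exponential (IVIM) model by segmented estimation
#'
#' Because the pseudo-diffusion coefficient is roughly an order of magnitude
#' larger than tissue diffusion, the perfusion compartment is fully decayed
#' at b > 200 s/mm^2. Step 1 therefore fits a single exponential
#' `A * exp(-b * d_slow)` to the b > `b_threshold` points only; step 2 holds
#' `d_slow` fixed and estimates the amplitude, perfusion fraction `f_p` and
#' pseudo-diffusion `d_fast` on the full curve by bounded nonlinear least
#' squares. An optional final joint refinement of all parameters can be
#' switched on with `joint_refine = TRUE` (off by default).
#'
#' @param decay a [signal_decay()].
#' @param b_threshold segmentation threshold, s/mm^2 (default 200); at
#'   least 3 b-values strictly above it and 2 at or below it are required.
#' @param joint_refine logical; refine all three parameters jointly after
#'   the segmented estimate.
#' @return A `dwi_fit` with `params$d_slow`, `params$d_fast` (mm^2/s) and
#'   `params$f_p`.
#' @export
fit_biexp_segmented <- function(decay, b_threshold = 200, joint_refine = FALSE) {
  stopifnot(inherits(decay, "signal_decay"))
  b <- decay$b_values; s <- decay$intensities
  hi <- b > b_threshold
  if (sum(hi) < 3) {
    stop(sprintf("segmented IVIM fit needs >= 3 b-values above %g s/mm^2 (got %d)",
                 b_threshold, sum(hi)), call. = FALSE)
  }
  if (sum(!hi) < 2) {
    stop(sprintf("segmented IVIM fit needs >= 2 b-values at or below %g s/mm^2 (got %d)",
                 b_threshold, sum(!hi)), call. = FALSE)
  }
  cl <- clip_noise_floor(b, s); s <- cl$s
  s0_obs <- s[1]

  # Step 1: mono-exponential on the high-b tail.
  st <- loglin_start(b[hi], s[hi])
  r1 <- lm_fit(function(p) s[hi] - p[1] * exp(-b[hi] * p[2]),
               c(A = max(st[["A"]], 1e-12),
                 D = min(max(st[["D"]], .DIFF_LOWER), .DIFF_UPPER)),
               lower = c(1e-12, .DIFF_LOWER), upper = c(Inf, .DIFF_UPPER))
  d_slow <- unname(r1$par[2]); a_high <- unname(r1$par[1])

  # Step 2: full curve with d_slow frozen.
  fp0 <- min(max(1 - a_high / s0_obs, 0.01), 0.9)
  start <- c(s0 = s0_obs, f_p = fp0, d_fast = max(20e-3, 10 * d_slow))
  r2 <- lm_fit(function(p) {
    s - p[1] * ((1 - p[2]) * exp(-b * d_slow) + p[2] * exp(-b * p[3]))
  }, start, lower = c(1e-12, 0, d_slow), upper = c(Inf, 1, .DFAST_UPPER))
  s0_hat <- unname(r2$par[1]); f_p <- unname(r2$par[2]); d_fast <- unname(r2$par[3])
  sse <- r2$sse; converged <- r1$converged && r2$converged

  if (isTRUE(joint_refine)) {
    r3 <- lm_fit(function(p) {
      s - p[1] * ((1 - p[3]) * exp(-b * p[2]) + p[3] * exp(-b * p[4]))
    }, c(s0_hat, d_slow, f_p, max(d_fast, d_slow + 1e-6)),
       lower = c(1e-12, .DIFF_LOWER, 0, .DIFF_LOWER),
       upper = c(Inf, .DIFF_UPPER, 1, .DFAST_UPPER))
    s0_hat <- unname(r3$par[1]); d_slow <- unname(r3$par[2])
    f_p <- unname(r3$par[3]); d_fast <- unname(r3$par[4])
    sse <- r3$sse; converged <- converged && r3$converged
  }

  new_dwi_fit("biexp",
              list(d_slow = d_slow, d_fast = max(d_fast, d_slow), f_p = f_p),
              s0 = s0_hat, residual_sse = sse, converged = converged,
              n_points_used = length(b), n_clipped = cl$n_clipped,
              diagnostics = list(b_threshold = b_threshold,
                                 n_high_b = sum(hi)))
}

#' Fit the stretched-exponential model
#'
#' Bounded nonlinear least squares of `s0 * exp(-(b * ddc)^alpha)` over all
#' b-values, initialized from the mono-exponential fit (ddc = ADC,
#' alpha = 0.8).
#'
#' @param decay a [signal_decay()].
#' @return A `dwi_fit` with `params$ddc` (mm^2/s) and `params$alpha`.
#' @export
fit_stretched <- function(decay) {
  stopifnot(inherits(decay, "signal_decay"))
  b <- decay$b_values; s <- decay$intensities
  if (sum(s > 0) < 3) stop("need >= 3 positive intensities", call. = FALSE)
  cl <- clip_noise_floor(b, s); s <- cl$s

  mono <- fit_mono(decay)
  ddc0 <- if (isTRUE(mono$converged) && is.finite(mono$params$adc)) {
    min(max(mono$params$adc, .DIFF_LOWER), .DIFF_UPPER)
  } else 1e-3
  start <- c(s0 = s[1], ddc = ddc0, alpha = 0.8)
  res <- lm_fit(function(p) s - p[1] * exp(-(b * p[2])^p[3]),
                start, lower = c(1e-12, .DIFF_LOWER, .ALPHA_LOWER),
                upper = c(Inf, .DIFF_UPPER, 1))
  new_dwi_fit("stretched",
              list(ddc = unname(res$par[2]), alpha = unname(res$par[3])),
              s0 = unname(res$par[1]), residual_sse = res$sse,
              converged = res$converged, n_points_used = length(b),
              n_clipped = cl$n_clipped)
}

# Dispatch a fitter by model name (used by fit_volume and tests).
fit_model <- function(model, decay, ...) {
  switch(model,
    mono = fit_mono(decay),
    biexp = fit_biexp_segmented(decay, ...),
    stretched = fit_stretched(decay),
    stop("unknown model: ", model, call. = FALSE)
  )
}
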