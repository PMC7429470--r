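#' Reference cohort parameter distributions
#'
#' Group-level means and standard deviations of the six DWI parameters at
#' baseline (T0), at the early intra-treatment time-point (T1), and of their
#' change (delta = T1 - T0), for complete responders ("CR") and incomplete
#' responders ("non-CR") to chemoradiotherapy in the cervical-cancer
#' reference cohort this package emulates (35 CR / 18 non-CR patients).
#' Diffusivities are in the conventional reporting unit of 1e-3 mm^2/s;
#' `f_p` and `alpha` are dimensionless.
#'
#' @param label `"CR"` or `"non-CR"`.
#' @return Data frame with columns `parameter`, `t0_mean`, `t0_sd`,
#'   `t1_mean`, `t1_sd`, `delta_mean`, `delta_sd`.
#' @export
#' @examples
#' reference_group_params("CR")
reference_group_params <- function(label = c("CR", "non-CR")) {
  label <- match.arg(label)
  if (label == "CR") {
    data.frame(
      parameter  = c("adc", "d_slow", "d_fast", "f_p", "ddc", "alpha"),
      t0_mean    = c(1.08, 0.93, 71.63, 0.26, 1.20, 0.65),
      t0_sd      = c(0.20, 0.15, 14.82, 0.06, 0.29, 0.10),
      t1_mean    = c(1.26, 1.07, 88.59, 0.28, 1.29, 0.68),
      t1_sd      = c(0.16, 0.16, 10.13, 0.06, 0.28, 0.10),
      delta_mean = c(0.18, 0.14, 16.95, 0.02, 0.08, 0.03),
      delta_sd   = c(0.20, 0.24, 20.31, 0.07, 0.44, 0.02)
    )
  } else {
    data.frame(
      parameter  = c("adc", "d_slow", "d_fast", "f_p", "ddc", "alpha"),
      t0_mean    = c(0.94, 0.76, 69.78, 0.25, 1.02, 0.66),
      t0_sd      = c(0.18, 0.13, 15.57, 0.06, 0.27, 0.06),
      t1_mean    = c(1.00, 0.92, 82.83, 0.28, 1.29, 0.67),
      t1_sd      = c(0.16, 0.16, 15.32, 0.07, 0.27, 0.06),
      delta_mean = c(0.05, 0.17, 13.06, 0.03, 0.28, 0.01),
      delta_sd   = c(0.17, 0.21, 21.27, 0.10, 0.31, 0.01)
    )
  }
}

#' Group specification for cohort simulation
#'
#' @param label `"CR"` or `"non-CR"`.
#' @param n_patients number of patients in the group (default: the reference
#'   cohort sizes, 35 CR and 18 non-CR).
#' @param params parameter distribution table in the format of
#'   [reference_group_params()].
#' @return A `group_spec` object.
#' @export
group_spec <- function(label = c("CR", "non-CR"),
                       n_patients = NULL,
                       params = reference_group_params(label)) {
  label <- match.arg(label)
  if (is.null(n_patients)) n_patients <- if (label == "CR") 35L else 18L
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  need <- c("parameter", "t0_mean", "t0_sd", "t1_mean", "t1_sd",
            "delta_mean", "delta_sd")
  if (!all(need %in% names(params))) {
    stop("params must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(params[c("t0_sd", "t1_sd", "delta_sd")] < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(label = label, n_patients = as.integer(n_patients),
                 params = params), class = "group_spec")
}

# Validity bounds for patient-level parameter draws (reporting units).
param_bounds <- function(p) {
  switch(p,
    adc = , d_slow = , d_fast = , ddc = c(1e-6, Inf),
    f_p = c(0, 1),
    alpha = c(1e-3, 1),
    c(-Inf, Inf))
}

# Bivariate truncated-normal draw of (t0, t1). The T0-T1 correlation is
# chosen so that Var(t1 - t0) matches the group's stated delta SD:
# rho = (s0^2 + s1^2 - sd_delta^2) / (2 s0 s1). Serial measurements on the
# same tumor are strongly correlated and independent draws would grossly
# overstate the dispersion of the change scores.
draw_timepoints <- function(n, m0, s0, m1, s1, sd_delta, lower, upper) {
  if (s0 == 0 && s1 == 0) {
    return(cbind(t0 = rep(m0, n), t1 = rep(m1, n)))
  }
  rho <- if (s0 > 0 && s1 > 0) {
    (s0^2 + s1^2 - sd_delta^2) / (2 * s0 * s1)
  } else 0
  rho <- min(max(rho, -0.999), 0.999)
  t0 <- rnorm_trunc(n, m0, s0, lower, upper)
  mu_c <- m1 + rho * (s1 / max(s0, .Machine$double.eps)) * (t0 - m0)
  sd_c <- s1 * sqrt(1 - rho^2)
  t1 <- vapply(seq_len(n), function(i) {
    rnorm_trunc(1, mu_c[i], sd_c, lower, upper)
  }, numeric(1))
  cbind(t0 = t0, t1 = t1)
}

#' Simulate a two-group, two-time-point patient cohort
#'
#' Draws per-patient ROI-mean DWI parameters at T0 and T1 from truncated
#' normal distributions with the group's means and SDs; within each
#' parameter, T0 and T1 are drawn jointly with the serial correlation
#' implied by the group's change-score SD, so that the delta columns
#' (`t1 - t0`) also have the stated dispersion. Parameters are independent
#' of one another across patients. The response label follows group
#' membership.
#'
#' @param cr,noncr [group_spec()] objects (defaults: the reference cohort).
#' @param seed integer seed for reproducibility.
#' @return Data frame with one row per patient: `patient_id`, `group`, and
#'   columns `<parameter>_t0`, `<parameter>_t1`, `<parameter>_delta` for the
#'   six parameters (diffusivities in 1e-3 mm^2/s).
#' @export
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' aggregate(adc_t1 ~ group, coh, mean)
simulate_cohort <- function(cr = group_spec("CR"), noncr = group_spec("non-CR"),
                            seed = NULL) {
  stopifnot(inherits(cr, "group_spec"), inherits(noncr, "group_spec"))
  if (!is.null(seed)) set.seed(seed)
  sim_group <- function(gs) {
    out <- data.frame(group = rep(gs$label, gs$n_patients))
    for (i in seq_len(nrow(gs$params))) {
      row <- gs$params[i, ]
      bb <- param_bounds(row$parameter)
      tp <- draw_timepoints(gs$n_patients, row$t0_mean, row$t0_sd,
                            row$t1_mean, row$t1_sd, row$delta_sd,
                            bb[1], bb[2])
      out[[paste0(row$parameter, "_t0")]] <- tp[, "t0"]
      out[[paste0(row$parameter, "_t1")]] <- tp[, "t1"]
      out[[paste0(row$parameter, "_delta")]] <- tp[, "t1"] - tp[, "t0"]
    }
    out
  }
  res <- rbind(sim_group(cr), sim_group(noncr))
  res <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(res))), res)
  res$group <- factor(res$group, levels = c("CR", "non-CR"))
  res
}

#' Simulate paired measurements by two independent raters
#'
#' Emulates two readers independently measuring the same ROI-mean parameter
#' on every patient: each rater observes the true value plus independent
#' additive Gaussian noise. Used to exercise the interobserver intraclass
#' correlation machinery.
#'
#' @param records cohort data frame from [simulate_cohort()].
#' @param parameters which parameter columns to measure (default: the six
#'   T0 columns).
#' @param rater_noise_sd measurement noise SD, either a single value or a
#'   named vector per parameter column.
#' @param seed integer seed.
#' @return Long data frame with columns `patient_id`, `parameter`, `rater1`,
#'   `rater2`.
#' @export
simulate_two_raters <- function(records,
                                parameters = paste0(c("adc", "d_slow", "d_fast",
                                                      "f_p", "ddc", "alpha"), "_t0"),
                                rater_noise_sd = 0.05, seed = NULL) {
  if (any(rater_noise_sd < 0)) stop("rater_noise_sd must be >= 0", call. = FALSE)
  missing_cols <- setdiff(parameters, names(records))
  if (length(missing_cols)) {
    stop("columns not in records: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  out <- lapply(parameters, function(p) {
    sdp <- if (length(rater_noise_sd) > 1) rater_noise_sd[[p]] else rater_noise_sd
    truth <- records[[p]]
    data.frame(patient_id = records$patient_id, parameter = p,
               rater1 = truth + rnorm(n, 0, sdp),
               rater2 = truth + rnorm(n, 0, sdp))
  })
  do.call(rbind, out)
}
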