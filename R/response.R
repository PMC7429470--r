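#' Classify treatment response from tumor diameters (RECIST v1.1 rules)
#'
#' Applies the diameter-based response rules used at post-treatment
#' follow-up: complete response (CR) when no residual tumor remains
#' (follow-up diameter 0), partial response (PR) when the largest residual
#' diameter shrank by at least 30% of baseline, progressive disease (PD)
#' when the longest diameter grew by at least 20%, and stable disease (SD)
#' otherwise. Both thresholds are inclusive. Patients are additionally
#' dichotomized into a CR group versus a non-CR group (PR, SD and PD
#' together).
#'
#' @param baseline_diameter longest tumor diameter before treatment, mm (> 0).
#' @param followup_diameter longest residual diameter at follow-up, mm
#'   (>= 0; 0 means no residual tumor). Vectorized with `baseline_diameter`.
#' @return Data frame with columns `baseline_diameter`, `followup_diameter`,
#'   `category` (factor CR/PR/SD/PD) and `dichotomy` (factor CR/non-CR).
#' @export
#' @examples
#' classify_recist(c(40, 40, 40, 40), c(0, 28, 48, 35))
classify_recist <- function(baseline_diameter, followup_diameter) {
  n <- max(length(baseline_diameter), length(followup_diameter))
  baseline_diameter <- rep_len(as.numeric(baseline_diameter), n)
  followup_diameter <- rep_len(as.numeric(followup_diameter), n)
  if (anyNA(baseline_diameter) || any(baseline_diameter <= 0)) {
    stop("baseline diameters must be positive", call. = FALSE)
  }
  if (anyNA(followup_diameter) || any(followup_diameter < 0)) {
    stop("follow-up diameters must be non-negative", call. = FALSE)
  }
  change <- (followup_diameter - baseline_diameter) / baseline_diameter
  category <- ifelse(followup_diameter == 0, "CR",
              ifelse(change <= -0.30, "PR",
              ifelse(change >= 0.20, "PD", "SD")))
  data.frame(
    baseline_diameter = baseline_diameter,
    followup_diameter = followup_diameter,
    category = factor(category, levels = c("CR", "PR", "SD", "PD")),
    dichotomy = factor(ifelse(category == "CR", "CR", "non-CR"),
                       levels = c("CR", "non-CR"))
  )
}

#' Response rates of a classified cohort
#'
#' Counts and percentages per RECIST category and per CR / non-CR dichotomy.
#' Percentages are rounded to two decimals.
#'
#' @param labels output of [classify_recist()], or a factor/character vector
#'   of categories.
#' @return List with data frames `by_category` and `by_dichotomy`, each with
#'   columns `label`, `n`, `percent`.
#' @export
#' @examples
#' lab <- classify_recist(rep(40, 53), c(rep(0, 35), rep(35, 18)))
#' cohort_response_rates(lab)$by_dichotomy
cohort_response_rates <- function(labels) {
  cat_vec <- if (is.data.frame(labels)) as.character(labels$category)
             else as.character(labels)
  if (!length(cat_vec)) stop("no labels supplied", call. = FALSE)
  tab <- function(f) {
    n <- as.integer(table(f))
    data.frame(label = levels(f), n = n,
               percent = round(100 * n / length(f), 2))
  }
  dichotomy <- factor(ifelse(cat_vec == "CR", "CR", "non-CR"),
                      levels = c("CR", "non-CR"))
  out <- list(by_dichotomy = tab(dichotomy))
  # a category breakdown only makes sense for RECIST-labelled input
  if (all(cat_vec %in% c("CR", "PR", "SD", "PD"))) {
    out$by_category <- tab(factor(cat_vec, levels = c("CR", "PR", "SD", "PD")))
  }
  out
}
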