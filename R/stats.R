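#' Normality screen with test routing
#'
#' Screens a sample for normality at alpha = 0.05 and recommends the
#' matching two-group test: normal samples are routed to the independent
#' t test, non-normal samples to the Mann-Whitney U test. The default
#' screen is the Lilliefors-corrected Kolmogorov-Smirnov test (mean and SD
#' estimated from the data); `method = "ks"` gives the plain KS test
#' against a normal with the sample moments.
#'
#' @param values numeric sample, n >= 5.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @param alpha significance level of the screen.
#' @return List with `verdict` (`"normal"` / `"non-normal"`), `p`,
#'   `recommended_test` (`"t"` / `"wilcox"`), `method`, and `degenerate`
#'   (TRUE for zero-variance input, which cannot be normal).
#' @export
ks_normality <- function(values, method = c("lilliefors", "ks"), alpha = 0.05) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("normality screen needs n >= 5", call. = FALSE)
  if (sd(values) == 0) {
    return(list(verdict = "non-normal", p = NA_real_,
                recommended_test = "wilcox", method = method,
                degenerate = TRUE))
  }
  p <- if (method == "lilliefors") {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value)
  }
  verdict <- if (p >= alpha) "normal" else "non-normal"
  list(verdict = verdict, p = p,
       recommended_test = if (verdict == "normal") "t" else "wilcox",
       method = method, degenerate = FALSE)
}

#' Two-group comparison with normality routing
#'
#' Compares a parameter between the CR and non-CR groups using either the
#' independent two-sample t test (pooled variance by default, Welch by
#' flag) or the Mann-Whitney U test (normal approximation with tie and
#' continuity correction). `route = "auto"` applies [ks_normality()] to
#' both groups and uses the t test only when both pass. The U statistic is
#' reported on the convention of the smaller of the two mutually
#' complementary U values, as clinical tables usually print it.
#'
#' @param cr_values,noncr_values numeric samples, each n >= 2.
#' @param route `"auto"`, `"t"` or `"wilcox"`.
#' @param welch use the Welch (unequal-variance) t test.
#' @param parameter optional name carried into the result.
#' @return A `group_comparison` list: `parameter`, group means and SDs,
#'   `test`, `statistic` (t or U), and the two-tailed `p`.
#' @export
#' @examples
#' two_group_test(rnorm(35, 1.26, 0.16), rnorm(18, 1.00, 0.16), route = "t")
two_group_test <- function(cr_values, noncr_values,
                           route = c("auto", "t", "wilcox"),
                           welch = FALSE, parameter = NA_character_) {
  route <- match.arg(route)
  cr_values <- cr_values[!is.na(cr_values)]
  noncr_values <- noncr_values[!is.na(noncr_values)]
  if (length(cr_values) < 2 || length(noncr_values) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (route == "auto") {
    route <- if (ks_normality(cr_values)$verdict == "normal" &&
                 ks_normality(noncr_values)$verdict == "normal") "t" else "wilcox"
  }
  if (route == "t") {
    ht <- t.test(cr_values, noncr_values, var.equal = !welch)
    statistic <- unname(abs(ht$statistic))
    test <- if (welch) "welch-t" else "t"
  } else {
    ht <- suppressWarnings(
      wilcox.test(cr_values, noncr_values, exact = FALSE, correct = TRUE))
    u1 <- unname(ht$statistic)   # U referenced to the first sample
    statistic <- min(u1, length(cr_values) * length(noncr_values) - u1)
    test <- "mann-whitney"
  }
  structure(list(parameter = parameter,
                 cr_mean = mean(cr_values), cr_sd = sd(cr_values),
                 noncr_mean = mean(noncr_values), noncr_sd = sd(noncr_values),
                 test = test, statistic = statistic,
                 p = unname(ht$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3f +/- %.3f vs %.3f +/- %.3f; %s = %.2f, p = %.3g\n",
              if (is.na(x$parameter)) "comparison" else x$parameter,
              x$cr_mean, x$cr_sd, x$noncr_mean, x$noncr_sd,
              x$test, x$statistic, x$p))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square without continuity correction (df = 1, two-tailed),
#' the form used for comparing clinical characteristics between response
#' groups.
#'
#' @param table 2x2 matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square_test(matrix(c(17, 18, 8, 10), nrow = 2))
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || anyNA(table)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-rater intraclass correlation coefficient
#'
#' Single-measures ICC from a two-way random-effects model. The default is
#' the absolute-agreement form ICC(A,1) (raters treated as a random sample,
#' systematic rater offsets count against agreement); `model = "C"` gives
#' the consistency form ICC(C,1). The 95% confidence interval is the
#' F-distribution interval of McGraw & Wong.
#'
#' @param ratings n x 2 matrix or data frame (one column per rater), no
#'   missing cells, n >= 5 subjects.
#' @param model `"A"` (absolute agreement, default) or `"C"` (consistency).
#' @param conf confidence level (default 0.95).
#' @return An `icc_result` list: `icc`, `lower`, `upper`, `model`, `n`.
#' @export
icc_two_rater <- function(ratings, model = c("A", "C"), conf = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  if (ncol(x) != 2) stop("need exactly 2 rater columns", call. = FALSE)
  if (anyNA(x)) stop("missing rating cells are not allowed", call. = FALSE)
  n <- nrow(x); k <- 2
  if (n < 5) stop("ICC needs at least 5 subjects", call. = FALSE)

  mpt <- rowMeans(x); mpr <- colMeans(x); gm <- mean(x)
  MSR <- k * sum((mpt - gm)^2) / (n - 1)                  # subjects
  MSC <- n * sum((mpr - gm)^2) / (k - 1)                  # raters
  MSE <- sum((x - outer(mpt, rep(1, k)) - outer(rep(1, n), mpr) + gm)^2) /
    ((n - 1) * (k - 1))
  alpha <- 1 - conf

  if (model == "A") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == MSR) icc <- 1
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    if (!is.finite(v) || icc >= 1) {
      lower <- upper <- 1
    } else {
      Fl <- qf(1 - alpha / 2, n - 1, v)
      Fu <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (MSR - Fl * MSE) /
        (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      upper <- n * (Fu * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
    }
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) icc <- 1
    if (MSE == 0) {
      lower <- upper <- 1
    } else {
      Fobs <- MSR / MSE
      Fl <- Fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      Fu <- Fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lower <- (Fl - 1) / (Fl + k - 1)
      upper <- (Fu - 1) / (Fu + k - 1)
    }
  }
  structure(list(icc = icc, lower = min(lower, 1), upper = min(upper, 1),
                 model = paste0("ICC(", model, ",1)"), n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$model, x$icc, x$lower, x$upper, x$n))
  invisible(x)
}

# Conventional test route per parameter, matching how the six DWI markers
# distribute in practice: the bi-/stretched-exponential tissue parameters
# behave normally (t test) while ADC, the pseudo-diffusion coefficient and
# the perfusion fraction are routed to the Mann-Whitney U test.
default_route_map <- function() {
  c(adc = "wilcox", d_fast = "wilcox", f_p = "wilcox",
    d_slow = "t", ddc = "t", alpha = "t")
}

#' Compare all cohort parameters between response groups
#'
#' Runs [two_group_test()] for every parameter column at T0, T1 and delta,
#' producing the familiar group-comparison table. Routing is taken from a
#' per-parameter map (default: [default_route_map()], the conventional
#' assignment); `route = "auto"` re-screens each column with
#' [ks_normality()].
#'
#' @param cohort data frame from [simulate_cohort()] (or the same layout
#'   with a `group` factor whose first level is CR).
#' @param route `"map"` (default), `"auto"`, `"t"` or `"wilcox"`.
#' @param route_map named vector parameter -> test used when `route = "map"`.
#' @param welch forwarded to [two_group_test()].
#' @return Data frame with one row per parameter/time-point: group means
#'   and SDs, test used, statistic, p.
#' @export
#' @examples
#' compare_groups(simulate_cohort(seed = 1))
compare_groups <- function(cohort, route = c("map", "auto", "t", "wilcox"),
                           route_map = default_route_map(), welch = FALSE) {
  route <- match.arg(route)
  grp <- cohort$group
  if (is.null(grp) || nlevels(factor(grp)) != 2) {
    stop("cohort must have a two-level 'group' column", call. = FALSE)
  }
  cr_lvl <- levels(factor(grp))[1]
  cols <- grep("_(t0|t1|delta)$", names(cohort), value = TRUE)
  rows <- lapply(cols, function(cn) {
    base <- sub("_(t0|t1|delta)$", "", cn)
    r <- if (route == "map") {
      if (!base %in% names(route_map)) "auto" else unname(route_map[base])
    } else route
    cmp <- two_group_test(cohort[[cn]][grp == cr_lvl],
                          cohort[[cn]][grp != cr_lvl],
                          route = r, welch = welch, parameter = cn)
    data.frame(parameter = cn, cr_mean = cmp$cr_mean, cr_sd = cmp$cr_sd,
               noncr_mean = cmp$noncr_mean, noncr_sd = cmp$noncr_sd,
               test = cmp$test, statistic = cmp$statistic, p = cmp$p)
  })
  do.call(rbind, rows)
}
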