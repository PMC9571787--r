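#' Kendall tau-b between ordinal grades and continuous values
#'
#' Tie-corrected Kendall rank correlation, the natural association measure
#' between an ordinal grading (four levels, so ties are guaranteed) and a
#' continuous measurement. The p-value uses the normal approximation with
#' the tie-adjusted variance of the concordance statistic; the confidence
#' interval is a bias-corrected percentile bootstrap (seeded, so
#' bit-reproducible).
#'
#' @param grades Ordinal vector (numeric or ordered factor).
#' @param values Continuous vector of equal length (>= 3).
#' @param conf_level Confidence level for the bootstrap interval.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param ci Compute the bootstrap interval? (Skipping it is much faster.)
#' @return A `correlation_result`: list with `tau`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
kendall_tau_b <- function(grades, values, conf_level = 0.95, n_boot = 10000,
                          seed = 20220914, ci = TRUE) {
  grades <- as.numeric(grades)
  values <- as.numeric(values)
  n <- length(grades)
  if (length(values) != n || n < 3)
    stop("grades and values must have equal length >= 3", call. = FALSE)
  if (anyNA(grades) || anyNA(values)) stop("missing values not supported",
                                           call. = FALSE)
  tau <- .tau_b(grades, values)
  if (!is.finite(tau))
    stop("tau-b undefined: a variable is constant (zero tie-corrected ",
         "denominator)", call. = FALSE)
  # tie-adjusted variance of S (Kendall 1970) and normal-approximation p
  S <- .tau_S(grades, values)
  tg <- table(grades); tv <- table(values)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tg * (tg - 1) * (2 * tg + 5))
  vu <- sum(tv * (tv - 1) * (2 * tv + 5))
  v1 <- sum(tg * (tg - 1)) * sum(tv * (tv - 1)) / (2 * n * (n - 1))
  v2 <- sum(tg * (tg - 1) * (tg - 2)) * sum(tv * (tv - 1) * (tv - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  p <- 2 * pnorm(-abs(z))
  ci_low <- ci_high <- NA_real_
  if (ci) {
    boot <- .with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      apply(idx, 2, function(i) .tau_b(grades[i], values[i]))
    })
    boot <- boot[is.finite(boot)]
    # bias-corrected percentile interval
    z0 <- qnorm((sum(boot < tau) + 0.5 * sum(boot == tau)) / length(boot))
    za <- qnorm(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    probs <- pnorm(2 * z0 + za)
    qs <- quantile(boot, probs, names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  structure(list(tau = tau, ci_low = ci_low, ci_high = ci_high,
                 p_value = p, n = n),
            class = "correlation_result")
}

# concordance statistic S = C - D (vectorized over all pairs)
.tau_S <- function(x, y) {
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])
}

.tau_b <- function(x, y) {
  n <- length(x)
  S <- .tau_S(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  S / den
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.3f (95%% CI [%.3f, %.3f]), p = %.3g, n = %d\n",
              x$tau, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Intraclass correlation for absolute agreement, ICC(2,1)
#'
#' Two-way random effects, single measures, absolute agreement:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#' F-based confidence interval and p-value of the Shrout-Fleiss /
#' McGraw-Wong conventions. Absolute agreement penalizes systematic rater
#' offsets (unlike consistency).
#'
#' @param ratings n x k numeric matrix: n subjects (>= 5) rated by k raters
#'   (>= 2), no missing cells.
#' @param conf_level Confidence level.
#' @return A `reliability_result`: list with `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `k` and the ANOVA mean squares.
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  X <- as.matrix(ratings)
  if (anyNA(X)) stop("missing cells not supported", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (n < 5 || k < 2)
    stop("need at least 5 subjects and 2 raters", call. = FALSE)
  grand <- mean(X)
  SSR <- k * sum((rowMeans(X) - grand)^2)       # between subjects
  SSC <- n * sum((colMeans(X) - grand)^2)       # between raters
  SST <- sum((X - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 1e-300 || var(rowMeans(X)) == 0) {
    warning("zero between-subject variance; ICC defined as 0", call. = FALSE)
    return(structure(list(icc = 0, ci_low = 0, ci_high = 0, p_value = 1,
                          n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
                     class = "reliability_result"))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  # significance: F test of the subject effect
  Fv <- MSR / MSE
  p <- pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  # McGraw & Wong CI with Satterthwaite df
  alpha <- 1 - conf_level
  if (MSE <= 0) {
    ci_low <- ci_high <- icc
  } else {
    Fj <- MSC / MSE
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * Fj + b)^2 /
      (a^2 * Fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    ci_high <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  ci_low <- min(ci_low, icc)
  ci_high <- max(ci_high, icc)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high, p_value = p,
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement = %.3f (95%% CI [%.3f, %.3f]), p = %.3g (n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$n, x$k))
  invisible(x)
}

#' Per-grade cohort summary
#'
#' Summary table stratified by Zhu grade: n, mean and SD of timepoint-zero
#' and follow-up volumes, and the mean per-patient resorption percentage
#' (printed signed, losses negative). A pooled `Total` row carries the
#' n-weighted means of the per-grade rows. Grades with no patients are
#' reported with `n = 0` and blanks; an SD over a single patient is
#' undefined (`NA`), not 0. With repeated measurements (rater/session), the
#' per-patient mean is summarized.
#'
#' @param table Data frame with columns `patient_id`, `zhu_grade`,
#'   `volume_t0_mm3`, `volume_followup_mm3` (optionally `rater`, `session`).
#' @return Data frame with one row per grade 0-3 plus `Total`.
#' @export
summarize_by_grade <- function(table) {
  req <- c("patient_id", "zhu_grade", "volume_t0_mm3", "volume_followup_mm3")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0) stop("empty rating table", call. = FALSE)
  # collapse repeated measurements to per-patient means
  per <- aggregate(table[c("volume_t0_mm3", "volume_followup_mm3")],
                   by = table[c("patient_id", "zhu_grade")], FUN = mean)
  per$resorption_signed_pct <-
    -100 * (per$volume_t0_mm3 - per$volume_followup_mm3) / per$volume_t0_mm3
  rows <- lapply(0:3, function(g) {
    sub <- per[per$zhu_grade == g, ]
    n <- nrow(sub)
    data.frame(
      grade = paste0("Grade ", c("0", "I", "II", "III")[g + 1]),
      n = n,
      mean_t0_mm3 = if (n) mean(sub$volume_t0_mm3) else NA_real_,
      sd_t0_mm3 = if (n > 1) sd(sub$volume_t0_mm3) else NA_real_,
      mean_followup_mm3 = if (n) mean(sub$volume_followup_mm3) else NA_real_,
      sd_followup_mm3 = if (n > 1) sd(sub$volume_followup_mm3) else NA_real_,
      mean_resorption_pct = if (n) mean(sub$resorption_signed_pct) else NA_real_)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(
    grade = "Total", n = nrow(per),
    mean_t0_mm3 = mean(per$volume_t0_mm3),
    sd_t0_mm3 = if (nrow(per) > 1) sd(per$volume_t0_mm3) else NA_real_,
    mean_followup_mm3 = mean(per$volume_followup_mm3),
    sd_followup_mm3 = if (nrow(per) > 1) sd(per$volume_followup_mm3) else NA_real_,
    mean_resorption_pct = mean(per$resorption_signed_pct))
  rbind(out, total)
}

#' Simulate a rating cohort from per-grade volume distributions
#'
#' Draws per-patient (timepoint-zero, follow-up) volume pairs from normal
#' distributions per grade stratum (truncated at 0), with optional additive
#' rater noise to emulate repeated measurements by several raters or
#' sessions. The defaults are the published per-grade summary volumes of
#' the validation cohort (31 patients: 8 grade I, 18 grade II, 5 grade III),
#' enabling stochastic validation of the tau/ICC layer when per-patient
#' data are unavailable.
#'
#' @param n_per_grade Named or ordered counts for grades 1..3.
#' @param t0_mean,t0_sd,fu_mean,fu_sd Per-grade normal parameters (mm^3).
#' @param rater_sigma SD of additive measurement noise (mm^3).
#' @param n_raters,n_sessions Repeated-measurement layout.
#' @param seed Integer seed.
#' @return Data frame with columns `patient_id`, `zhu_grade`, `rater`,
#'   `session`, `volume_t0_mm3`, `volume_followup_mm3`, `resorption_pct`
#'   (loss-positive).
#' @export
simulate_cohort <- function(n_per_grade = c(8, 18, 5),
                            t0_mean = c(2724, 3022, 2933),
                            t0_sd = c(492, 495, 447),
                            fu_mean = c(2369, 2068, 1228),
                            fu_sd = c(440, 410, 415),
                            rater_sigma = 0, n_raters = 1, n_sessions = 1,
                            seed = 1) {
  stopifnot(length(n_per_grade) == 3, all(t0_sd > 0), all(fu_sd > 0))
  .with_seed(seed, {
    rows <- list()
    pid <- 0
    for (g in 1:3) {
      for (i in seq_len(n_per_grade[g])) {
        pid <- pid + 1
        t0 <- max(1, rnorm(1, t0_mean[g], t0_sd[g]))
        fu <- max(0, rnorm(1, fu_mean[g], fu_sd[g]))
        for (r in seq_len(n_raters)) for (s in seq_len(n_sessions)) {
          t0m <- max(1, t0 + if (rater_sigma > 0) rnorm(1, 0, rater_sigma) else 0)
          fum <- max(0, fu + if (rater_sigma > 0) rnorm(1, 0, rater_sigma) else 0)
          rows[[length(rows) + 1]] <- data.frame(
            patient_id = sprintf("P%02d", pid), zhu_grade = g,
            rater = paste0("R", r), session = paste0("S", s),
            volume_t0_mm3 = t0m, volume_followup_mm3 = fum,
            resorption_pct = 100 * (t0m - fum) / t0m)
        }
      }
    }
    do.call(rbind, rows)
  })
}
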