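# the pair-enumeration oracle tau_b_oracle() lives in helper-oracles.R

test_that("tau-b is exact for perfect concordance and antisymmetric", {
  r <- kendall_tau_b(c(0, 1, 2, 3), c(10, 20, 30, 40), ci = FALSE)
  expect_equal(r$tau, 1.0)
  a <- kendall_tau_b(c(1, 1, 2, 2, 3), c(5, 7, 6, 9, 12), ci = FALSE)
  b <- kendall_tau_b(c(1, 1, 2, 2, 3), -c(5, 7, 6, 9, 12), ci = FALSE)
  expect_equal(a$tau, -b$tau)
})

test_that("tau-b equals pair-enumeration on tied data, including the worked case", {
  a <- kendall_tau_b(c(1, 1, 2, 2, 3), c(5, 7, 6, 9, 12), ci = FALSE)
  expect_equal(a$tau, tau_b_oracle(c(1, 1, 2, 2, 3), c(5, 7, 6, 9, 12)))
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    g <- sample(0:3, n, replace = TRUE)
    v <- round(rnorm(n), 1)          # rounding forces value ties too
    if (length(unique(g)) < 2) next
    expect_equal(kendall_tau_b(g, v, ci = FALSE)$tau, tau_b_oracle(g, v),
                 tolerance = 1e-12)
    # cross-check against the base-R implementation
    expect_equal(kendall_tau_b(g, v, ci = FALSE)$tau,
                 unname(cor(g, v, method = "kendall")), tolerance = 1e-12)
  }
})

test_that("tau-b errors on constant grades and bootstraps reproducibly", {
  expect_error(kendall_tau_b(c(1, 1, 1, 1), c(1, 2, 3, 4)), "undefined")
  g <- c(1, 1, 2, 2, 3, 3, 2, 1); v <- c(3, 5, 8, 6, 12, 11, 7, 4)
  r1 <- kendall_tau_b(g, v, n_boot = 2000, seed = 5)
  r2 <- kendall_tau_b(g, v, n_boot = 2000, seed = 5)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_identical(r1$ci_high, r2$ci_high)
  expect_true(r1$ci_low <= r1$tau && r1$tau <= r1$ci_high)
})

test_that("ICC(2,1) matches a from-scratch ANOVA computation", {
  # independent oracle via aov() mean squares and the published formula
  icc_oracle <- function(X) {
    n <- nrow(X); k <- ncol(X)
    df <- data.frame(y = as.vector(X),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  }
  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(6 * 2, 50, 10), 6, 2) + rnorm(6, 0, 8)
    expect_equal(icc_absolute(X)$icc, icc_oracle(X), tolerance = 1e-10)
  }
  X2 <- matrix(rnorm(8 * 3, 100, 20), 8, 3)
  expect_equal(icc_absolute(X2)$icc, icc_oracle(X2), tolerance = 1e-10)
})

test_that("identical raters give ICC 1; offsets reduce absolute agreement", {
  base <- c(10, 14, 9, 22, 17, 12)
  perfect <- icc_absolute(cbind(base, base))
  expect_equal(perfect$icc, 1.0)
  shifted <- icc_absolute(cbind(base, base + 10))
  expect_lt(shifted$icc, 1.0)
  expect_true(shifted$ci_low <= shifted$icc && shifted$icc <= shifted$ci_high)
})

test_that("degenerate rating matrices are handled explicitly", {
  expect_warning(r <- icc_absolute(matrix(5, 6, 2)), "zero between-subject")
  expect_equal(r$icc, 0)
  expect_error(icc_absolute(matrix(rnorm(8), 4, 2)), "at least 5")
})

test_that("per-grade summary reproduces pooled means by weighted arithmetic", {
  # per-patient data whose per-grade means equal the published Table values
  mk <- function(n, g, t0, fu) data.frame(
    patient_id = paste0(g, "_", seq_len(n)), zhu_grade = g,
    volume_t0_mm3 = t0, volume_followup_mm3 = fu)
  tab <- rbind(mk(8, 1, 2724, 2369), mk(18, 2, 3022, 2068),
               mk(5, 3, 2933, 1228))
  s <- summarize_by_grade(tab)
  total <- s[s$grade == "Total", ]
  expect_equal(total$n, 31)
  expect_equal(total$mean_t0_mm3, (8 * 2724 + 18 * 3022 + 5 * 2933) / 31)
  expect_equal(round(total$mean_t0_mm3), 2931)
  expect_equal(round(total$mean_followup_mm3), 2010)
  expect_equal(round(total$mean_t0_mm3 - total$mean_followup_mm3), 921)
  expect_equal(s$n[s$grade == "Grade 0"], 0)
  expect_true(is.na(s$mean_t0_mm3[s$grade == "Grade 0"]))
})

test_that("single-patient strata report an undefined SD, not zero", {
  tab <- data.frame(patient_id = c("a", "b"), zhu_grade = c(1, 2),
                    volume_t0_mm3 = c(2000, 3000),
                    volume_followup_mm3 = c(1500, 2500))
  s <- summarize_by_grade(tab)
  expect_true(is.na(s$sd_t0_mm3[s$grade == "Grade I"]))
})

test_that("simulated cohorts behave: no noise -> ICC 1, more noise -> lower ICC", {
  co0 <- simulate_cohort(rater_sigma = 0, n_raters = 2, seed = 3)
  X0 <- matrix(co0$volume_followup_mm3[order(co0$rater, co0$patient_id)],
               ncol = 2)
  expect_equal(icc_absolute(X0)$icc, 1.0)
  mean_icc <- vapply(c(50, 300, 900), function(sig) {
    mean(vapply(1:5, function(s) {
      co <- simulate_cohort(rater_sigma = sig, n_raters = 2, seed = s)
      m <- matrix(co$resorption_pct[order(co$rater, co$patient_id)], ncol = 2)
      icc_absolute(m)$icc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})
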