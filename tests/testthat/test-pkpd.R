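# Exposure-outcome analyses.

make_pd <- function(n = 60, seed = 1, link = -1.1) {
  set.seed(seed)
  trough <- exp(rnorm(n, log(350), 0.8))
  los <- pmax(2, round(exp(log(11) + link * (trough - 350) / 1000 +
                             rnorm(n, 0, 0.55))))
  pd <- data.frame(ID = 1:n, los = los,
                   death = runif(n) < 0.08,
                   icu_transfer = runif(n) < 0.15)
  pd$outcome <- composite_outcome(pd$death, pd$icu_transfer, pd$los)
  exposure <- data.frame(ID = 1:n, trough48 = trough,
                         trough72 = trough * 1.2)
  list(pd = pd, exposure = exposure)
}

test_that("composite outcome follows its clinical definition and boundaries", {
  expect_equal(as.character(composite_outcome(TRUE, FALSE, 3)), "poor")
  expect_equal(as.character(composite_outcome(FALSE, TRUE, 3)), "poor")
  expect_equal(as.character(composite_outcome(FALSE, FALSE, 9)), "good")
  expect_equal(as.character(composite_outcome(FALSE, FALSE, 10)), "poor")
  expect_true(is.na(composite_outcome(FALSE, FALSE, NA)))
  expect_equal(as.character(composite_outcome(TRUE, FALSE, NA)), "poor")
})

test_that("LOS regression returns OLS results and rejects degenerate input", {
  x <- make_pd()
  r <- regress_los_on_trough(x$pd, x$exposure, "48")
  fm <- lm(x$pd$los ~ x$exposure$trough48)
  expect_equal(r$slope, unname(coef(fm)[2]))
  expect_equal(r$r_squared, summary(fm)$r.squared)
  expect_equal(r$p_value, summary(fm)$coefficients[2, 4])
  # exactly collinear data: r2 = 1
  pd2 <- data.frame(ID = 1:5, los = c(10, 20, 30, 40, 50))
  ex2 <- data.frame(ID = 1:5, trough48 = c(1, 2, 3, 4, 5) * 100)
  expect_equal(suppressWarnings(
    regress_los_on_trough(pd2, ex2, "48")$r_squared), 1)
  ex2$trough48 <- 300
  expect_error(regress_los_on_trough(pd2, ex2, "48"), "zero variance")
  expect_error(regress_los_on_trough(pd2[1:2, ], ex2[1:2, ], "48"),
               "at least 3")
})

test_that("permuted exposure yields null regression p-values", {
  x <- make_pd(n = 80, seed = 5)
  set.seed(6)
  ps <- replicate(200, {
    ex <- x$exposure
    ex$trough48 <- sample(ex$trough48)
    regress_los_on_trough(x$pd, ex, "48")$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("ANOVA reports group moments and reduces to t-squared for two groups", {
  x <- make_pd(n = 70, seed = 9)
  a <- anova_trough_by_group(x$pd, x$exposure, "outcome", "48")
  expect_setequal(a$groups$group, c("good", "poor"))
  tt <- t.test(trough48 ~ outcome,
               data = merge(x$pd, x$exposure, by = "ID"),
               var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  # identical values in both groups: no between-group variance, F = 0
  pdc <- data.frame(ID = 1:6, outcome = rep(c("good", "poor"), each = 3))
  exc <- data.frame(ID = 1:6, trough48 = rep(c(400, 500, 600), 2))
  expect_equal(anova_trough_by_group(pdc, exc, "outcome", "48")$F, 0)
  # a group with < 2 members is rejected
  pd1 <- data.frame(ID = 1:5, outcome = c("good", rep("poor", 4)))
  ex1 <- data.frame(ID = 1:5, trough48 = c(100, 200, 300, 400, 500))
  expect_error(anova_trough_by_group(pd1, ex1, "outcome", "48"),
               "at least 2")
  # same-distribution groups give approximately uniform p-values
  set.seed(10)
  ps <- replicate(300, {
    pdn <- data.frame(ID = 1:40,
                      outcome = rep(c("good", "poor"), each = 20))
    exn <- data.frame(ID = 1:40, trough48 = rnorm(40, 350, 100))
    anova_trough_by_group(pdn, exn, "outcome", "48")$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("banded LOS eCDF partitions subjects and matches the dichotomy", {
  x <- make_pd(n = 90, seed = 13)
  e <- los_ecdf_by_band(x$pd, x$exposure, "48")
  expect_equal(sum(e$bands$n), e$n)              # partition
  expect_equal(sum(e$dichotomized$n), e$n)
  # merging bands reproduces the dichotomized proportions exactly
  hi <- e$bands[-1, ]
  merged <- sum(hi$n * hi$prop_below_cutoff, na.rm = TRUE) / sum(hi$n)
  expect_equal(merged, e$dichotomized$prop_below_cutoff[2])
  expect_equal(e$bands$prop_below_cutoff[1],
               e$dichotomized$prop_below_cutoff[1])
  # all LOS below the cutoff -> proportion 1 in every non-empty band
  pd_all <- x$pd; pd_all$los <- pmin(pd_all$los, 20)
  e2 <- los_ecdf_by_band(pd_all, x$exposure, "48")
  expect_true(all(e2$bands$prop_below_cutoff[e2$bands$n > 0] == 1))
  # designed negative link: longer stays in the low-trough group
  coh_like <- make_pd(n = 120, seed = 17)
  e3 <- los_ecdf_by_band(coh_like$pd, coh_like$exposure, "48")
  expect_gt(e3$dichotomized$prop_below_cutoff[2],
            e3$dichotomized$prop_below_cutoff[1])
  expect_error(los_ecdf_by_band(x$pd, x$exposure, "48",
                                bands = c(0, 300, 200, Inf)),
               "increasing")
})

test_that("Holm adjustment matches the step-down computation", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.37), 0.37)
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  set.seed(19)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the full report runs on a generated cohort with missing outcomes", {
  coh <- generate_cohort(cohort_config(n_subjects = 60), seed = 23)
  rep <- pkpd_report(coh$pd, coh$truth$exposure)
  expect_true(all(c("t48", "t72", "metabolites") %in% names(rep)))
  expect_equal(rep$t48$regression$n, sum(!is.na(coh$pd$los)))
  expect_true(all(rep$metabolites$p_holm >= rep$metabolites$p_raw))
})
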