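# Approximate marginal likelihood, EBEs, shrinkage, fitting.

toy_subject <- function(y) {
  # one observation of HCQ; the prediction function is supplied separately
  list(id = "toy", dose_time = 0, dose_umol = 1,
       obs_time = 1, obs_cmt = 1L, y_umol = y,
       covariates = data.frame())
}

test_that("eta mode matches a grid-search oracle on a one-dimensional toy", {
  # prediction linear in the first eta, additive error
  a <- 2; b <- 1.5; sigma <- 0.5; omega <- c(0.8, 0, 0, 0, 0)
  sub <- toy_subject(y = 4)
  predfun <- function(eta) a + b * eta[1]
  res <- hcqpk:::.subject_laplace(sub, hcqpk:::as_theta(ref_params()),
                                  omega, prop = rep(0, 4),
                                  add_umol = rep(sigma, 4),
                                  predfun = predfun)
  grid <- seq(-4, 4, by = 1e-4)
  joint <- (4 - (a + b * grid))^2 / sigma^2 + grid^2 / omega[1]^2
  expect_equal(res$eta[1], grid[which.min(joint)], tolerance = 1e-3)
  # closed-form posterior mode of the conjugate normal model
  mode <- b * (4 - a) / (b^2 + sigma^2 / omega[1]^2)
  expect_equal(res$eta[1], mode, tolerance = 1e-6)
})

test_that("Laplace objective is exact on the linear conjugate toy", {
  a <- 2; b <- 1.5; sigma <- 0.5; omega <- c(0.8, 0, 0, 0, 0)
  for (y in c(1.2, 3.7, 6)) {
    sub <- toy_subject(y = y)
    res <- hcqpk:::.subject_laplace(sub, hcqpk:::as_theta(ref_params()),
                                    omega, prop = rep(0, 4),
                                    add_umol = rep(sigma, 4),
                                    predfun = function(eta) a + b * eta[1])
    exact <- -2 * dnorm(y, mean = a, sd = sqrt(b^2 * omega[1]^2 + sigma^2),
                        log = TRUE)
    expect_equal(res$contrib, exact, tolerance = 1e-6)
  }
})

test_that("omega -> 0 reduces the objective to fixed-effects weighted least squares", {
  coh <- small_cohort(n_subjects = 4, seed = 11, pop = pop_no_bsv())
  pop <- pop_no_bsv()
  ofv <- hcq_neg2ll(pop, coh$data)
  subs <- hcqpk:::split_subjects(coh$data)
  add_umol <- hcqpk:::.sigma_add_umol(pop)
  wls <- sum(vapply(subs, function(s) {
    pred <- as.numeric(hcqpk:::cpp_pred_eta(rep(0, 5),
                                            hcqpk:::as_theta(pop$typical),
                                            s$dose_time, s$dose_umol,
                                            s$obs_time, s$obs_cmt))
    v <- (pop$sigma_prop[s$obs_cmt] * pred)^2 + add_umol[s$obs_cmt]^2
    sum(log(2 * pi * v) + (s$y_umol - pred)^2 / v)
  }, numeric(1)))
  expect_equal(ofv, wls, tolerance = 1e-10)
})

test_that("objective prefers the generating parameters and ignores subject order", {
  coh <- generate_cohort(cohort_config(n_subjects = 40), seed = 5)
  pop <- ref_pop()
  ofv0 <- hcq_neg2ll(pop, coh$data)
  for (f in c(0.5, 1.5)) {
    pert <- hcq_popparams(typical = hcq_params(cl_parent = 5.6 * f,
                                               v = 1850 * f))
    expect_gt(hcq_neg2ll(pert, coh$data), ofv0)
  }
  # permuting subjects leaves the objective unchanged
  d <- coh$data
  ids <- unique(d$ID)
  perm <- setNames(sample(ids), ids)
  d2 <- d; d2$ID <- perm[as.character(d$ID)]
  d2 <- d2[order(d2$ID, d2$TIME, d2$EVID), ]
  ofv_perm <- hcq_neg2ll(pop, hcq_dataset(d2))
  expect_equal(ofv_perm, ofv0, tolerance = 1e-9)
})

test_that("subjects without observations sit at the prior mode", {
  pop <- ref_pop()
  d <- data.frame(ID = 1, TIME = c(0, 12), EVID = 1, AMT = 200, CMT = 1,
                  DV = NA_real_, MDV = 1)
  em <- eta_modes(pop, hcq_dataset(d))
  expect_equal(unname(em[1, ]), rep(0, 5))
  # tiny omega pulls modes toward zero
  coh <- small_cohort(n_subjects = 3, seed = 9)
  pop_tight <- hcq_popparams(omega = c(cl_parent = 1e-4, v = 1e-4,
                                       cl_met_DesCQ = 1e-4,
                                       cl_met_DesHCQ = 1e-4,
                                       cl_met_DiDesCQ = 1e-4))
  em2 <- eta_modes(pop_tight, coh$data)
  expect_lt(max(abs(em2)), 1e-3)
})

test_that("noiseless rich data recover the typical values precisely", {
  pop_gen <- pop_no_bsv(sigma_prop = c(HCQ = 0.002, DesCQ = 0.002,
                                       DesHCQ = 0.002, DiDesCQ = 0.002),
                        sigma_add = c(HCQ = 0.02, DesCQ = 0.02,
                                      DesHCQ = 0.02, DiDesCQ = 0.02))
  coh <- generate_cohort(cohort_config(n_subjects = 8, pop = pop_gen,
                                       samples_p = 1), seed = 21)
  # start away from the truth; fix the variability layer at the
  # generating values so only the structural parameters are estimated
  init <- hcq_popparams(typical = hcq_params(v = 1400, cl_parent = 8),
                        omega = pop_gen$omega,
                        sigma_prop = pop_gen$sigma_prop,
                        sigma_add = pop_gen$sigma_add)
  fit <- hcqfit(coh$data, init = init,
                fixed = c("lag", "ka", var_par_names()),
                control = fast_control())
  expect_true(fit$convergence)
  expect_equal(coef(fit)[["cl_parent"]], 5.60, tolerance = 0.02)
  expect_equal(coef(fit)[["v"]], 1850, tolerance = 0.02)
  expect_equal(coef(fit)[["cl_form_DesHCQ"]], 9.63, tolerance = 0.02)
  # refitting from the optimum reproduces the same objective
  fit2 <- hcqfit(coh$data, init = fit$popparams,
                 fixed = c("lag", "ka", var_par_names()),
                 control = fast_control())
  expect_equal(fit2$ofv, fit$ofv, tolerance = 1e-6)
})

test_that("shrinkage is 100% for collapsed EBEs, 0% at full spread, and grows with sparsity", {
  fit <- list(shrinkage = hcqpk:::.shrinkage(matrix(0, 10, 5),
                                             rep(0.9, 5)))
  class(fit) <- "hcqfit"
  expect_equal(unname(eta_shrinkage(fit)), rep(100, 5))
  set.seed(4)
  ebe <- matrix(rnorm(5000, sd = 0.9), 1000, 5)
  shr <- hcqpk:::.shrinkage(ebe, rep(0.9, 5))
  expect_true(all(abs(shr) < 6))  # ~0 up to Monte-Carlo error
  # sparse sampling shrinks more than rich sampling
  pop <- ref_pop()
  rich <- generate_cohort(cohort_config(n_subjects = 25, samples_p = 1),
                          seed = 31)
  sparse <- generate_cohort(cohort_config(n_subjects = 25, samples_p = 0),
                            seed = 31)
  shr_rich <- hcqpk:::.shrinkage(eta_modes(pop, rich$data), pop$omega)
  shr_sparse <- hcqpk:::.shrinkage(eta_modes(pop, sparse$data), pop$omega)
  expect_gt(shr_sparse[["cl_parent"]], shr_rich[["cl_parent"]])
})

test_that("estimates are invariant to the dataset concentration unit", {
  coh <- small_cohort(n_subjects = 5, seed = 13)
  d_ugl <- coh$data
  d_umol <- as.data.frame(d_ugl)
  obs <- d_umol$EVID == 0
  cmp <- hcqpk:::cmt_to_compound(d_umol$CMT[obs])
  d_umol$DV[obs] <- convert_conc(d_umol$DV[obs], cmp, "ug/L", "umol/L")
  d_umol <- hcq_dataset(d_umol, dv_unit = "umol/L")
  pop <- ref_pop()
  # the objective differs only by the fixed Jacobian of the unit change,
  # so differences at two parameter values coincide => same optimizer path
  p2 <- hcq_popparams(typical = hcq_params(cl_parent = 7, v = 1500))
  expect_equal(hcq_neg2ll(pop, d_umol), hcq_neg2ll(pop, d_ugl),
               tolerance = 1e-10)
  expect_equal(hcq_neg2ll(p2, d_umol), hcq_neg2ll(p2, d_ugl),
               tolerance = 1e-10)
})
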