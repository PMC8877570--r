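# Shared fixtures built in code.

ref_params <- function() hcq_params()
ref_pop <- function() hcq_popparams()

# population with variability switched off (useful for deterministic checks)
pop_no_bsv <- function(sigma_prop = c(HCQ = 0.05, DesCQ = 0.05,
                                      DesHCQ = 0.05, DiDesCQ = 0.05),
                       sigma_add = c(HCQ = 1, DesCQ = 1,
                                     DesHCQ = 1, DiDesCQ = 1)) {
  hcq_popparams(omega = c(cl_parent = 0, v = 0, cl_met_DesCQ = 0,
                          cl_met_DesHCQ = 0, cl_met_DiDesCQ = 0),
                sigma_prop = sigma_prop, sigma_add = sigma_add)
}

# random valid structural parameters (log-uniform around the reference)
random_params <- function() {
  r <- function(x, f = 3) x * exp(stats::runif(length(x), -log(f), log(f)))
  hcq_params(lag = stats::runif(1, 0, 1), ka = r(1.15), v = r(1850),
             cl_parent = r(5.6),
             cl_form = r(c(DesCQ = 4.99, DesHCQ = 9.63, DiDesCQ = 1.84)),
             cl_met = r(c(DesCQ = 49.8, DesHCQ = 8.89, DiDesCQ = 11.6)))
}

# adaptive numeric ODE oracle (deSolve), amounts at `times`
ode_amounts <- function(params, regimen, times, tol = 1e-12) {
  A <- rate_matrix(params)
  dose_umol <- regimen$amount * 1000 / hcq_compounds()$molar_mass[1]
  ev <- data.frame(var = "depot", time = regimen$time + params$lag,
                   value = dose_umol, method = "add")
  tt <- sort(unique(c(0, ev$time, times)))
  y0 <- stats::setNames(rep(0, 5), rownames(A))
  out <- deSolve::ode(y = y0, times = tt,
                      func = function(t, y, p) list(as.vector(A %*% y)),
                      parms = NULL, events = list(data = ev),
                      rtol = tol, atol = tol)
  out[match(times, out[, 1]), 2:6, drop = FALSE]
}

# small rich-sampling cohort for fast estimation tests
small_cohort <- function(n_subjects = 12, seed = 42, pop = ref_pop(),
                         samples_p = 1) {
  generate_cohort(cohort_config(n_subjects = n_subjects, pop = pop,
                                samples_p = samples_p),
                  seed = seed)
}

fast_control <- function() hcqfit_control(outer_reltol = 1e-5,
                                          outer_maxit = 200)

# sigma/omega parameter names, to fix the variability layer in cheap fits
var_par_names <- function() {
  grep("^(omega_|sigma_)", hcqpk:::.FIT_PAR_NAMES, value = TRUE)
}
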