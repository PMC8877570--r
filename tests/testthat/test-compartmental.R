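# Structural model: rate matrix, analytic solver, unit handling, troughs.

test_that("molar masses follow from the molecular formulae", {
  aw <- c(C = 12.011, H = 1.008, Cl = 35.45, N = 14.007, O = 15.999)
  expect_equal(molar_mass("C18H26ClN3O"),
               18 * aw["C"] + 26 * aw["H"] + aw["Cl"] + 3 * aw["N"] + aw["O"],
               ignore_attr = TRUE)
  cmp <- hcq_compounds()
  expect_setequal(cmp$compound, c("HCQ", "DesCQ", "DesHCQ", "DiDesCQ"))
  mm <- setNames(cmp$molar_mass, cmp$compound)
  expect_true(all(mm[c("DesCQ", "DesHCQ", "DiDesCQ")] < mm["HCQ"]))
  # unit conversion round-trip
  x <- c(1.3, 0.2)
  expect_equal(convert_conc(convert_conc(x, "HCQ", "umol/L", "ug/L"),
                            "HCQ", "ug/L", "umol/L"), x)
})

test_that("rate matrix has the compartmental structure and closes mass balance", {
  p <- ref_params()
  A <- rate_matrix(p)
  expect_equal(A["HCQ", "depot"], 1.15)
  expect_equal(A["DesHCQ", "HCQ"], p$cl_form[["DesHCQ"]] / p$v)
  expect_equal(A["DesCQ", "DesHCQ"], 0)
  # column deficits equal each compartment's irreversible elimination
  deficit <- -colSums(A)
  expect_equal(unname(deficit),
               unname(c(0, p$cl_parent / p$v, p$cl_met / p$v)),
               tolerance = 1e-12)
  # all clearances zero: only the absorption entry off-diagonal
  p0 <- hcq_params(cl_parent = 0,
                   cl_form = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0),
                   cl_met = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0))
  A0 <- rate_matrix(p0)
  off <- A0; diag(off) <- 0
  expect_equal(sum(off != 0), 1L)
  expect_equal(A0["HCQ", "depot"], 1.15)
  expect_error(hcq_params(v = -1), "non-negative|> 0")
  expect_error(hcq_params(ka = NA), "finite")
})

test_that("single-dose parent amount matches the Bateman closed form", {
  p <- hcq_params(cl_form = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0))
  reg <- hcq_regimen(times = 0, amounts = 200)
  tt <- c(0.1, 0.389, 1, 6, 24, 120)
  amt <- solve_amounts(p, reg, tt)
  D <- 200 * 1000 / hcq_compounds()$molar_mass[1]
  k <- p$cl_parent / p$v
  tau <- pmax(tt - p$lag, 0)
  bateman <- D * p$ka / (p$ka - k) * (exp(-k * tau) - exp(-p$ka * tau))
  expect_equal(unname(amt[, "HCQ"]), bateman, tolerance = 1e-12)
  # before first dose + lag, everything is zero
  expect_equal(unname(amt[1, ]), rep(0, 5))
})

test_that("analytic solution matches the adaptive ODE oracle on random parameters", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  reg <- hcq_regimen(scenario = 1, duration = 72)
  for (i in 1:100) {
    p <- random_params()
    tt <- sort(runif(4, 1, 96))
    ours <- solve_amounts(p, reg, tt)
    oracle <- ode_amounts(p, reg, tt)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-8)
  }
})

test_that("mass balance closes against administered dose", {
  skip_if_not_installed("deSolve")
  # augment with elimination sinks: total moles in + out is conserved
  p <- ref_params()
  reg <- hcq_regimen(scenario = 3, duration = 96)
  A <- rate_matrix(p)
  aug <- matrix(0, 7, 7)
  aug[1:5, 1:5] <- A
  aug[6, 2] <- p$cl_parent / p$v              # parent elimination sink
  aug[7, 3:5] <- p$cl_met / p$v               # metabolite elimination sink
  dose_umol <- reg$amount * 1000 / hcq_compounds()$molar_mass[1]
  ev <- data.frame(var = "c1", time = reg$time + p$lag,
                   value = dose_umol, method = "add")
  y0 <- stats::setNames(rep(0, 7), paste0("c", 1:7))
  out <- deSolve::ode(y = y0, times = sort(unique(c(0, ev$time, c(24, 72, 120)))),
                      func = function(t, y, prm) list(as.vector(aug %*% y)),
                      parms = NULL, events = list(data = ev),
                      rtol = 1e-12, atol = 1e-12)
  for (t in c(24, 72, 120)) {
    row <- out[out[, 1] == t, -1]
    administered <- sum(dose_umol[reg$time + p$lag <= t])
    expect_equal(sum(row), administered, tolerance = 1e-8)
  }
  # and the analytic amounts agree with the oracle's drug compartments
  ana <- solve_amounts(p, reg, c(24, 72, 120))
  expect_equal(unname(ana),
               unname(out[match(c(24, 72, 120), out[, 1]), 2:6]),
               tolerance = 1e-8)
})

test_that("superposition: multi-dose response is the sum of shifted single doses", {
  p <- ref_params()
  reg <- hcq_regimen(scenario = 2, duration = 48)
  tt <- c(10, 30, 47.9, 60)
  full <- solve_amounts(p, reg, tt)
  parts <- Reduce(`+`, lapply(seq_len(nrow(reg)), function(d) {
    solve_amounts(p, hcq_regimen(times = reg$time[d], amounts = reg$amount[d]),
                  tt)
  }))
  expect_equal(full, parts, tolerance = 1e-10)
})

test_that("solver handles coincident rate constants via the matrix exponential", {
  skip_if_not_installed("deSolve")
  # ka equal to the parent elimination rate collides the exponents
  p <- hcq_params(ka = 0.5, v = 100, cl_parent = 50,
                  cl_form = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0))
  reg <- hcq_regimen(times = 0, amounts = 200)
  tt <- c(1, 5, 20)
  expect_equal(unname(solve_amounts(p, reg, tt)),
               unname(ode_amounts(p, reg, tt)), tolerance = 1e-7)
})

test_that("concentration prediction scales linearly and converts units", {
  p <- ref_params()
  reg1 <- hcq_regimen(scenario = 1, duration = 72)
  reg2 <- hcq_regimen(times = reg1$time, amounts = reg1$amount * 2)
  tt <- c(6, 24, 48)
  c1 <- predict_concentrations(p, reg1, tt, unit = "umol/L")
  c2 <- predict_concentrations(p, reg2, tt, unit = "umol/L")
  expect_equal(c2$conc, 2 * c1$conc, tolerance = 1e-12)
  cu <- predict_concentrations(p, reg1, tt, unit = "ug/L")
  mm <- setNames(hcq_compounds()$molar_mass, hcq_compounds()$compound)
  expect_equal(cu$conc, c1$conc * unname(mm[cu$compound]), tolerance = 1e-12)
  # zero doses -> all-zero profile
  c0 <- predict_concentrations(p, hcq_regimen(times = c(0, 12),
                                              amounts = 0), tt)
  expect_true(all(c0$conc == 0))
  expect_error(predict_concentrations(p, reg1, tt, unit = "ng/mL"))
  # empty regimen -> zero
  expect_true(all(solve_amounts(p, hcq_regimen(), tt) == 0))
  expect_error(solve_amounts(p, reg1, c(1, Inf)), "finite")
})

test_that("fraction metabolized follows the clearance-ratio formula", {
  p <- ref_params()
  expect_equal(fraction_metabolized(p),
               (4.99 + 9.63 + 1.84) / (5.60 + 4.99 + 9.63 + 1.84))
  expect_equal(round(100 * fraction_metabolized(p)), 75)
  expect_equal(fraction_metabolized(
    hcq_params(cl_form = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0))), 0)
  expect_equal(fraction_metabolized(hcq_params(cl_parent = 0)), 1)
  expect_error(fraction_metabolized(
    hcq_params(cl_parent = 0,
               cl_form = c(DesCQ = 0, DesHCQ = 0, DiDesCQ = 0))),
    "undefined")
  # monotone in each formation clearance, decreasing in parent clearance
  base <- fraction_metabolized(p)
  for (m in c("DesCQ", "DesHCQ", "DiDesCQ")) {
    cf <- p$cl_form; cf[m] <- cf[m] * 1.5
    expect_gt(fraction_metabolized(hcq_params(cl_form = cf)), base)
  }
  expect_lt(fraction_metabolized(hcq_params(cl_parent = 8)), base)
})

test_that("trough is the left limit at the dosing clock", {
  p <- ref_params()
  reg <- hcq_regimen(scenario = 1, duration = 96)
  tr48 <- trough_concentration(p, reg, 48)
  # a dose falls exactly at 48 h; the trough must exclude it
  pre <- predict_concentrations(p, hcq_regimen(times = reg$time[reg$time < 48],
                                               amounts = reg$amount[reg$time < 48]),
                                48)
  expect_equal(unname(tr48), pre$conc[match(names(tr48), pre$compound)])
  # at a non-dose time it equals the plain prediction
  tr50 <- trough_concentration(p, reg, 50)
  pl <- predict_concentrations(p, reg, 50)
  expect_equal(unname(tr50), pl$conc[match(names(tr50), pl$compound)])
  # accumulation before steady state
  tr72 <- trough_concentration(p, reg, 72)
  expect_gt(tr72[["HCQ"]], tr48[["HCQ"]])
  # zero-dose regimen and pre-first-dose behaviour
  expect_true(all(trough_concentration(p, hcq_regimen(), 48) == 0))
  expect_warning(tr <- trough_concentration(p, hcq_regimen(times = 10, amounts = 200), 5),
                 "precedes")
  expect_true(all(tr == 0))
})
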