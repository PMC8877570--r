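# Structural (fixed-effect) model: depot + parent + three metabolite
# compartments, all first order, metabolite volumes fixed to the parent's.

#' Structural pharmacokinetic parameters
#'
#' One individual's (or the population-typical) fixed-effect parameters of the
#' whole-blood HCQ model: a dosing depot with first-order absorption `ka` and
#' absorption lag, a parent compartment with apparent volume `v` (VP/F, also
#' used for each metabolite, VM/F), a non-metabolite apparent clearance
#' `cl_parent` (CL/F), and for each metabolite a formation clearance
#' (HCQ -> metabolite) and a metabolite elimination clearance.
#'
#' Defaults are the package's reference population estimates for hospitalized
#' adults on 200-400 mg oral regimens; `ka` and `lag` are literature-fixed
#' constants, not estimated.
#'
#' @param lag absorption lag time (h).
#' @param ka first-order absorption rate constant (1/h).
#' @param v apparent volume of distribution (L), shared by all compartments.
#' @param cl_parent apparent non-metabolite clearance of HCQ (L/h).
#' @param cl_form named numeric, formation clearances HCQ -> metabolite (L/h),
#'   names `DesCQ`, `DesHCQ`, `DiDesCQ`.
#' @param cl_met named numeric, metabolite elimination clearances (L/h).
#' @return object of class `hcq_params`.
#' @examples
#' p <- hcq_params()
#' fraction_metabolized(p)
#' @export
hcq_params <- function(lag = 0.389, ka = 1.15, v = 1850, cl_parent = 5.60,
                       cl_form = c(DesCQ = 4.99, DesHCQ = 9.63, DiDesCQ = 1.84),
                       cl_met = c(DesCQ = 49.8, DesHCQ = 8.89, DiDesCQ = 11.6)) {
  cl_form <- cl_form[.METABOLITES]
  cl_met <- cl_met[.METABOLITES]
  p <- list(lag = lag, ka = ka, v = v, cl_parent = cl_parent,
            cl_form = cl_form, cl_met = cl_met)
  validate_hcq_params(p)
  structure(p, class = "hcq_params")
}

validate_hcq_params <- function(p) {
  vals <- c(p$lag, p$ka, p$v, p$cl_parent, p$cl_form, p$cl_met)
  if (length(vals) != 10 || anyNA(vals) || any(!is.finite(vals)))
    stop("structural parameters must be finite and complete")
  if (any(vals < 0)) stop("structural parameters must be non-negative")
  if (p$v <= 0) stop("v must be > 0")
  if (p$ka <= 0) stop("ka must be > 0")
  invisible(p)
}

as_theta <- function(p) {
  th <- c(p$lag, p$ka, p$v, p$cl_parent, p$cl_form, p$cl_met)
  names(th) <- .THETA_NAMES
  th
}

theta_to_params <- function(th) {
  hcq_params(lag = th[[1]], ka = th[[2]], v = th[[3]], cl_parent = th[[4]],
             cl_form = stats::setNames(th[5:7], .METABOLITES),
             cl_met = stats::setNames(th[8:10], .METABOLITES))
}

#' @export
print.hcq_params <- function(x, ...) {
  cat("Structural PK parameters (apparent, /F)\n")
  cat(sprintf("  lag %.3g h, ka %.3g 1/h, V %.4g L, CL(parent) %.3g L/h\n",
              x$lag, x$ka, x$v, x$cl_parent))
  for (m in .METABOLITES)
    cat(sprintf("  %-8s CL(formation) %6.3g L/h, CL(metabolite) %6.3g L/h\n",
                m, x$cl_form[[m]], x$cl_met[[m]]))
  invisible(x)
}

#' First-order rate matrix of the compartment system
#'
#' Builds the 5 x 5 rate matrix A of the linear system dA/dt = A a over the
#' compartments (depot, HCQ, DesCQ, DesHCQ, DiDesCQ): absorption depot -> HCQ
#' at `ka`; HCQ -> metabolite m at `cl_form[m]/v`; metabolite elimination at
#' `cl_met[m]/v`; direct parent elimination at `cl_parent/v`. Diagonals are
#' the negated total outflow; there is no transfer between metabolites.
#'
#' @param params [hcq_params()].
#' @return 5 x 5 matrix with compartment dimnames.
#' @export
rate_matrix <- function(params) {
  validate_hcq_params(params)
  cmts <- c("depot", .COMPOUNDS)
  A <- matrix(0, 5, 5, dimnames = list(cmts, cmts))
  A["depot", "depot"] <- -params$ka
  A["HCQ", "depot"] <- params$ka
  A["HCQ", "HCQ"] <- -(params$cl_parent + sum(params$cl_form)) / params$v
  for (m in .METABOLITES) {
    A[m, "HCQ"] <- params$cl_form[[m]] / params$v
    A[m, m] <- -params$cl_met[[m]] / params$v
  }
  A
}

#' Dosing regimens
#'
#' Builds a multi-dose oral regimen, either from an explicit vector of dose
#' times/amounts or from one of five named scenarios:
#' 1. 200 mg every 12 h (bid);
#' 2. 200 mg every 8 h (tid);
#' 3. 400 mg every 12 h on day 1, then 200 mg every 12 h;
#' 4. 400 mg every 12 h on day 1, then 200 mg every 8 h;
#' 5. 400 mg every 12 h.
#' The first dose is at t = 0 and doses continue while time < `duration`.
#'
#' @param scenario integer 1-5, or `NULL` when `times`/`amounts` are given.
#' @param times dose times (h since first dose), strictly increasing.
#' @param amounts dose amounts (mg), recycled against `times`.
#' @param duration scheduling horizon (h) for scenario regimens.
#' @return data.frame of class `hcq_regimen` with columns `time`, `amount`.
#' @examples
#' hcq_regimen(scenario = 3, duration = 96)
#' @export
hcq_regimen <- function(scenario = NULL, times = NULL, amounts = NULL,
                        duration = 120) {
  if (!is.null(scenario)) {
    if (!scenario %in% 1:5) stop("scenario must be in 1..5")
    q12 <- seq(0, duration - 1e-9, by = 12)
    q8 <- seq(0, duration - 1e-9, by = 8)
    reg <- switch(scenario,
      data.frame(time = q12, amount = 200),
      data.frame(time = q8, amount = 200),
      data.frame(time = q12, amount = ifelse(q12 < 24, 400, 200)),
      {
        t2 <- sort(unique(c(0, 12, q8[q8 >= 24])))
        data.frame(time = t2, amount = ifelse(t2 < 24, 400, 200))
      },
      data.frame(time = q12, amount = 400)
    )
  } else {
    if (is.null(times)) times <- numeric(0)
    if (is.null(amounts)) amounts <- numeric(0)
    reg <- data.frame(time = as.numeric(times),
                      amount = rep_len(as.numeric(amounts),
                                       length(times)))
  }
  if (anyNA(reg) || any(!is.finite(as.matrix(reg))))
    stop("dose times and amounts must be finite")
  if (any(reg$time < 0) || any(reg$amount < 0))
    stop("dose times and amounts must be non-negative")
  if (is.unsorted(reg$time, strictly = TRUE) && nrow(reg) > 1)
    stop("dose times must be strictly increasing")
  structure(reg, class = c("hcq_regimen", "data.frame"),
            scenario = if (is.null(scenario)) NA_integer_ else scenario)
}

.dose_umol <- function(regimen) {
  # labeled mg of drug -> umol of parent (free-base molar mass); the
  # salt-to-base factor is absorbed into the apparent (/F) parameters
  regimen$amount * 1000 / .molar_masses()[["HCQ"]]
}

#' Molar amounts in each compartment over time
#'
#' Solves the linear compartment system for an arbitrary regimen by
#' superposition of single-dose responses (closed-form exponentials from the
#' triangular rate structure; a scaling-and-squaring matrix exponential is
#' used when absorption/elimination rate constants nearly coincide, where the
#' closed form is singular). Each dose enters the depot at its dose time plus
#' the absorption lag; before the first such entry all amounts are zero.
#'
#' @param params [hcq_params()].
#' @param regimen [hcq_regimen()].
#' @param times numeric vector of times (h) at which amounts are requested.
#' @return matrix `length(times)` x 5 of amounts (umol), columns `depot`,
#'   `HCQ`, `DesCQ`, `DesHCQ`, `DiDesCQ`.
#' @export
solve_amounts <- function(params, regimen, times) {
  validate_hcq_params(params)
  if (anyNA(times) || any(!is.finite(times)))
    stop("requested times must be finite")
  amt <- cpp_amounts(as_theta(params), regimen$time, .dose_umol(regimen),
                     as.numeric(times))
  amt <- t(amt)
  dimnames(amt) <- list(NULL, c("depot", .COMPOUNDS))
  amt
}

#' Predicted concentrations of the four compounds
#'
#' Concentration of each compound is its compartment amount divided by the
#' shared apparent volume `v`; umol/L is the model's working unit and ug/L is
#' obtained per compound with the molar masses of [hcq_compounds()].
#'
#' @inheritParams solve_amounts
#' @param unit `"ug/L"` (default) or `"umol/L"`.
#' @return tidy data.frame with columns `time`, `compound`, `conc`, `unit`.
#' @export
predict_concentrations <- function(params, regimen, times,
                                   unit = c("ug/L", "umol/L")) {
  unit <- match.arg(unit)
  amt <- solve_amounts(params, regimen, times)
  conc <- amt[, .COMPOUNDS, drop = FALSE] / params$v
  out <- data.frame(
    time = rep(as.numeric(times), times = length(.COMPOUNDS)),
    compound = rep(.COMPOUNDS, each = length(times)),
    conc = as.vector(conc),
    unit = unit,
    stringsAsFactors = FALSE
  )
  if (unit == "ug/L")
    out$conc <- convert_conc(out$conc, out$compound, "umol/L", "ug/L")
  out
}

#' Fraction of parent drug converted to the metabolites
#'
#' FM = sum(formation clearances) / (parent clearance + sum(formation
#' clearances)), a dimensionless number in `[0, 1]`.
#'
#' @param params [hcq_params()].
#' @return numeric scalar.
#' @export
fraction_metabolized <- function(params) {
  validate_hcq_params(params)
  tot <- params$cl_parent + sum(params$cl_form)
  if (tot <= 0)
    stop("fraction metabolized undefined when all elimination clearances are 0")
  sum(params$cl_form) / tot
}

#' Trough concentration immediately before a time point
#'
#' The concentration at the left limit t-, i.e. excluding any dose
#' administered at exactly `t` — the pre-dose ("trough") concentration when
#' `t` falls on the dosing clock.
#'
#' @inheritParams predict_concentrations
#' @param t single positive time (h).
#' @return named numeric vector of length 4 (one value per compound).
#' @export
trough_concentration <- function(params, regimen, t,
                                 unit = c("ug/L", "umol/L")) {
  unit <- match.arg(unit)
  if (length(t) != 1 || !is.finite(t) || t <= 0)
    stop("t must be a single positive time")
  keep <- regimen$time < t
  if (nrow(regimen) > 0 && !any(keep))
    warning("t precedes the first dose; trough is 0")
  reg <- hcq_regimen(times = regimen$time[keep], amounts = regimen$amount[keep])
  pr <- predict_concentrations(params, reg, t, unit = unit)
  stats::setNames(pr$conc, pr$compound)[.COMPOUNDS]
}
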