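# Population layer: log-normal between-subject variability on five
# parameters and combined proportional + additive residual error per
# compound.

#' Population pharmacokinetic parameters
#'
#' Typical structural values plus the variability layers: `omega` holds the
#' standard deviations of the zero-mean normal random effects applied
#' exponentially (log-normally) to the parent clearance, the volume and the
#' three metabolite clearances; `sigma_prop`/`sigma_add` hold the combined
#' residual-error model per compound, with the additive component expressed
#' in ug/L (converted internally to the umol/L working unit).
#'
#' Defaults are the package's reference estimates for hospitalized adults.
#'
#' @param typical [hcq_params()].
#' @param omega named SDs of the log-scale random effects.
#' @param sigma_prop named proportional residual-error fractions per compound.
#' @param sigma_add named additive residual-error SDs per compound (ug/L).
#' @return object of class `hcq_popparams`.
#' @export
hcq_popparams <- function(typical = hcq_params(),
                          omega = c(cl_parent = 1.327, v = 0.889,
                                    cl_met_DesCQ = 0.362,
                                    cl_met_DesHCQ = 0.860,
                                    cl_met_DiDesCQ = 0.953),
                          sigma_prop = c(HCQ = 0.448, DesCQ = 0.322,
                                         DesHCQ = 0.428, DiDesCQ = 0.0574),
                          sigma_add = c(HCQ = 86.9, DesCQ = 5.78,
                                        DesHCQ = 6.69, DiDesCQ = 2.49)) {
  validate_hcq_params(typical)
  omega <- omega[.ETA_NAMES]
  sigma_prop <- sigma_prop[.COMPOUNDS]
  sigma_add <- sigma_add[.COMPOUNDS]
  if (anyNA(omega) || any(omega < 0))
    stop("omega must be complete and non-negative")
  if (anyNA(sigma_prop) || any(sigma_prop < 0) ||
      anyNA(sigma_add) || any(sigma_add < 0))
    stop("sigma components must be complete and non-negative")
  if (any(sigma_prop == 0 & sigma_add == 0))
    stop("each compound needs at least one positive sigma component")
  structure(list(typical = typical, omega = omega,
                 sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "hcq_popparams")
}

#' @export
print.hcq_popparams <- function(x, ...) {
  cat("Population PK parameters\n\nTypical values:\n")
  print(x$typical)
  cat("\nBetween-subject variability (omega, SD of log-scale eta):\n")
  print(round(x$omega, 4))
  cat("\nResidual error (proportional fraction / additive ug/L):\n")
  print(data.frame(prop = x$sigma_prop, add_ugL = x$sigma_add))
  invisible(x)
}

# additive sigmas in the umol/L working unit
.sigma_add_umol <- function(pop) {
  convert_conc(pop$sigma_add, .COMPOUNDS, "ug/L", "umol/L")
}

#' Sample individual random effects
#'
#' Draws `n` independent eta vectors from zero-mean normals with SDs
#' `pop$omega` (the exponential BSV model).
#'
#' @param pop [hcq_popparams()].
#' @param n number of individuals.
#' @return `n` x 5 matrix of etas.
#' @export
sample_etas <- function(pop, n) {
  eta <- matrix(stats::rnorm(n * 5), n, 5) *
    matrix(pop$omega, n, 5, byrow = TRUE)
  colnames(eta) <- .ETA_NAMES
  eta
}

#' Individual parameters from population values and etas
#'
#' Applies `param_i = typical * exp(eta)` to the parameters carrying
#' between-subject variability (parent clearance, volume, metabolite
#' clearances); the remaining parameters equal the typical values.
#'
#' @param pop [hcq_popparams()].
#' @param eta numeric vector of length 5 (order `cl_parent`, `v`,
#'   `cl_met_DesCQ`, `cl_met_DesHCQ`, `cl_met_DiDesCQ`).
#' @return [hcq_params()] with attribute `eta`.
#' @export
individual_params <- function(pop, eta) {
  t <- pop$typical
  p <- hcq_params(
    lag = t$lag, ka = t$ka,
    v = t$v * exp(eta[[2]]),
    cl_parent = t$cl_parent * exp(eta[[1]]),
    cl_form = t$cl_form,
    cl_met = t$cl_met * exp(eta[3:5])
  )
  attr(p, "eta") <- stats::setNames(as.numeric(eta), .ETA_NAMES)
  p
}

#' Sample one or more individuals from the population
#'
#' @param pop [hcq_popparams()].
#' @param n number of individuals.
#' @return a single [hcq_params()] when `n = 1`, otherwise a list of them;
#'   each carries its generating `eta` as an attribute.
#' @export
sample_individual <- function(pop, n = 1) {
  eta <- sample_etas(pop, n)
  out <- lapply(seq_len(n), function(i) individual_params(pop, eta[i, ]))
  if (n == 1) out[[1]] else out
}

#' Residual-error variance at a model prediction
#'
#' variance = (prop * pred)^2 + add^2, with `pred` and `add` in the same
#' concentration unit.
#'
#' @param pred non-negative model prediction(s).
#' @param prop proportional error fraction.
#' @param add additive error SD (same unit as `pred`).
#' @return variance(s), same length as `pred`.
#' @export
observation_variance <- function(pred, prop, add) {
  if (any(pred < 0)) stop("pred must be non-negative")
  (prop * pred)^2 + add^2
}

#' Simulate observations under the residual-error model
#'
#' Draws `y = pred + e` with `e` zero-mean normal of variance
#' [observation_variance()]. Draws are not truncated: the additive-normal
#' error model admits negative values, which are retained for
#' estimation-facing simulation (VPC, NPDE) and only floored at zero where a
#' physical concentration table is produced.
#'
#' @inheritParams observation_variance
#' @return simulated observation(s).
#' @export
apply_residual_error <- function(pred, prop, add) {
  pred + stats::rnorm(length(pred),
                      sd = sqrt(observation_variance(pred, prop, add)))
}

#' Write population parameters to a flat YAML or JSON file
#'
#' Keys mirror the conventional reporting labels (`CL_F_HCQ`, `VP_F_HCQ`,
#' formation and metabolite clearances, `omega_*`, `sigma_prop_*`,
#' `sigma_add_*_ugL`); additive sigmas are stored in ug/L as printed.
#'
#' @param pop [hcq_popparams()].
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_popparams <- function(pop, path) {
  t <- pop$typical
  kv <- c(
    Lag = t$lag, KA = t$ka, CL_F_HCQ = t$cl_parent, VP_F_HCQ = t$v,
    CL_HCQ_DesCQ = t$cl_form[["DesCQ"]], CL_DesCQ = t$cl_met[["DesCQ"]],
    CL_HCQ_DesHCQ = t$cl_form[["DesHCQ"]], CL_DesHCQ = t$cl_met[["DesHCQ"]],
    CL_HCQ_DiDesCQ = t$cl_form[["DiDesCQ"]],
    CL_DiDesCQ = t$cl_met[["DiDesCQ"]],
    omega_CL_HCQ = pop$omega[["cl_parent"]],
    omega_VP_HCQ = pop$omega[["v"]],
    omega_CL_DesCQ = pop$omega[["cl_met_DesCQ"]],
    omega_CL_DesHCQ = pop$omega[["cl_met_DesHCQ"]],
    omega_CL_DiDesCQ = pop$omega[["cl_met_DiDesCQ"]]
  )
  for (cc in .COMPOUNDS) {
    kv[paste0("sigma_prop_", cc)] <- pop$sigma_prop[[cc]]
    kv[paste0("sigma_add_", cc, "_ugL")] <- pop$sigma_add[[cc]]
  }
  kv <- as.list(kv)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(kv, path)
  } else {
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read population parameters written by [write_popparams()]
#'
#' @param path YAML or JSON parameter file.
#' @return [hcq_popparams()].
#' @export
read_popparams <- function(path) {
  kv <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else jsonlite::read_json(path, simplifyVector = TRUE)
  g <- function(k) {
    if (is.null(kv[[k]])) stop("parameter file is missing key: ", k)
    as.numeric(kv[[k]])
  }
  hcq_popparams(
    typical = hcq_params(
      lag = g("Lag"), ka = g("KA"), v = g("VP_F_HCQ"),
      cl_parent = g("CL_F_HCQ"),
      cl_form = c(DesCQ = g("CL_HCQ_DesCQ"), DesHCQ = g("CL_HCQ_DesHCQ"),
                  DiDesCQ = g("CL_HCQ_DiDesCQ")),
      cl_met = c(DesCQ = g("CL_DesCQ"), DesHCQ = g("CL_DesHCQ"),
                 DiDesCQ = g("CL_DiDesCQ"))
    ),
    omega = c(cl_parent = g("omega_CL_HCQ"), v = g("omega_VP_HCQ"),
              cl_met_DesCQ = g("omega_CL_DesCQ"),
              cl_met_DesHCQ = g("omega_CL_DesHCQ"),
              cl_met_DiDesCQ = g("omega_CL_DiDesCQ")),
    sigma_prop = stats::setNames(
      vapply(.COMPOUNDS, function(cc) g(paste0("sigma_prop_", cc)),
             numeric(1)), .COMPOUNDS),
    sigma_add = stats::setNames(
      vapply(.COMPOUNDS, function(cc) g(paste0("sigma_add_", cc, "_ugL")),
             numeric(1)), .COMPOUNDS)
  )
}
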