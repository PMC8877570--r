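# Approximate maximum marginal likelihood (Laplace expansion at the
# per-subject eta mode, with interaction: observation variances evaluated at
# the individual predictions). The outer optimizer works on log-transformed
# parameters; KA and lag are fixed by default.

.FIT_PAR_NAMES <- c(.THETA_NAMES,
                    paste0("omega_", .ETA_NAMES),
                    paste0("sigma_prop_", .COMPOUNDS),
                    paste0("sigma_add_", .COMPOUNDS))

#' Control options for [hcqfit()]
#'
#' @param inner_reltol relative tolerance of the inner (eta-mode) optimizer.
#' @param outer_reltol relative tolerance of the outer optimizer.
#' @param outer_maxit iteration cap of the outer optimizer.
#' @param restarts number of outer starts; starts beyond the first are
#'   jittered (log-scale SD `jitter_sd`) and the best objective wins.
#' @param jitter_sd log-scale SD of the restart jitter.
#' @param fd_step relative finite-difference step for gradients/Hessians.
#' @return list of class `hcqfit_control`.
#' @export
hcqfit_control <- function(inner_reltol = 1e-10, outer_reltol = 1e-6,
                           outer_maxit = 400, restarts = 1,
                           jitter_sd = 0.2, fd_step = 1e-4) {
  structure(list(inner_reltol = inner_reltol, outer_reltol = outer_reltol,
                 outer_maxit = outer_maxit, restarts = restarts,
                 jitter_sd = jitter_sd, fd_step = fd_step),
            class = "hcqfit_control")
}

# pack a hcq_popparams into the named full parameter vector (natural scale)
.pop_to_vec <- function(pop) {
  c(as_theta(pop$typical),
    stats::setNames(pop$omega, paste0("omega_", .ETA_NAMES)),
    stats::setNames(pop$sigma_prop, paste0("sigma_prop_", .COMPOUNDS)),
    stats::setNames(pop$sigma_add, paste0("sigma_add_", .COMPOUNDS)))
}

.vec_to_pop <- function(v) {
  hcq_popparams(
    typical = theta_to_params(v[.THETA_NAMES]),
    omega = stats::setNames(v[paste0("omega_", .ETA_NAMES)], .ETA_NAMES),
    sigma_prop = stats::setNames(v[paste0("sigma_prop_", .COMPOUNDS)],
                                 .COMPOUNDS),
    sigma_add = stats::setNames(v[paste0("sigma_add_", .COMPOUNDS)],
                                .COMPOUNDS)
  )
}

# Laplace/FOCE-I contribution of one subject.
# Returns -2 log Li, the eta mode and the curvature used.
.subject_laplace <- function(sub, theta, omega, prop, add_umol,
                             eta0 = rep(0, 5), control = hcqfit_control(),
                             predfun = NULL) {
  if (length(sub$obs_time) == 0)
    return(list(contrib = 0, eta = rep(0, 5)))
  active <- which(omega > 0)
  k <- length(active)
  predf <- if (is.null(predfun)) {
    function(eta) cpp_pred_eta(eta, theta, sub$dose_time, sub$dose_umol,
                               sub$obs_time, sub$obs_cmt)
  } else predfun
  nll_full <- if (is.null(predfun)) {
    function(eta) cpp_subject_nll(eta, theta, sub$dose_time, sub$dose_umol,
                                  sub$obs_time, sub$obs_cmt, sub$y_umol,
                                  prop, add_umol, omega, TRUE)
  } else {
    function(eta) {
      pred <- as.numeric(predf(eta))
      v <- (prop[sub$obs_cmt] * pred)^2 + add_umol[sub$obs_cmt]^2
      act <- omega > 0
      0.5 * sum(log(2 * pi * v) + (sub$y_umol - pred)^2 / v) +
        0.5 * sum(eta[act]^2 / omega[act]^2 + log(2 * pi * omega[act]^2))
    }
  }
  if (k == 0) {
    eta <- rep(0, 5)
    return(list(contrib = 2 * nll_full(eta), eta = eta))
  }
  expand <- function(ea) {
    eta <- rep(0, 5); eta[active] <- ea; eta
  }
  opt <- stats::nlminb(eta0[active], function(ea) nll_full(expand(ea)),
                       control = list(rel.tol = control$inner_reltol,
                                      iter.max = 200))
  eta <- expand(opt$par)
  if (opt$iterations >= 200)
    warning("inner eta optimization hit its iteration cap for subject ",
            sub$id, "; returning the last iterate")
  # Gauss-Newton curvature with the interaction term from the
  # prediction-dependent variance
  pred <- predf(eta)
  h <- control$fd_step
  J <- matrix(0, length(pred), k)
  for (j in seq_len(k)) {
    ep <- eta; ep[active[j]] <- ep[active[j]] + h
    J[, j] <- (predf(ep) - pred) / h
  }
  pv <- as.numeric(prop[sub$obs_cmt])
  av <- as.numeric(add_umol[sub$obs_cmt])
  pred <- as.numeric(pred)
  v <- (pv * pred)^2 + av^2
  dv <- (2 * pv^2 * pred) * J          # d var / d eta
  H <- crossprod(J, J / v) + 0.5 * crossprod(dv, dv / v^2) +
    diag(1 / omega[active]^2, k)
  ld <- determinant(H, logarithm = TRUE)
  if (ld$sign <= 0) {
    H <- H + diag(1e-8 + abs(min(eigen(H, only.values = TRUE)$values)), k)
    ld <- determinant(H, logarithm = TRUE)
  }
  list(contrib = 2 * opt$objective + as.numeric(ld$modulus) - k * log(2 * pi),
       eta = eta)
}

# covariate multiplier on the typical value of one parameter for one subject
.cov_multiplier <- function(term, beta, covariates) {
  x <- covariates[[term$covariate]]
  if (is.null(x) || is.na(x)) return(1)
  if (term$type == "continuous") {
    (as.numeric(x) / term$ref)^beta
  } else {
    exp(beta * as.numeric(x == term$level))
  }
}

.subject_theta <- function(theta, cov_model, betas, covariates) {
  if (is.null(cov_model) || !length(cov_model)) return(theta)
  for (i in seq_along(cov_model)) {
    term <- cov_model[[i]]
    theta[term$parameter] <- theta[term$parameter] *
      .cov_multiplier(term, betas[i], covariates)
  }
  theta
}

# -2 approximate log marginal likelihood over all subjects.
# `state` optionally carries warm-start etas across calls.
.neg2ll_subjects <- function(subs, pop, cov_model = NULL, betas = numeric(0),
                             control = hcqfit_control(), state = NULL) {
  theta <- as_theta(pop$typical)
  prop <- pop$sigma_prop
  add_umol <- .sigma_add_umol(pop)
  total <- 0
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    th <- .subject_theta(theta, cov_model, betas, sub$covariates)
    eta0 <- if (!is.null(state) && !is.null(state$etas))
      state$etas[i, ] else rep(0, 5)
    res <- .subject_laplace(sub, th, pop$omega, prop, add_umol,
                            eta0 = eta0, control = control)
    if (!is.finite(res$contrib))
      stop("non-finite likelihood contribution for subject ", sub$id)
    total <- total + res$contrib
    if (!is.null(state)) state$etas[i, ] <- res$eta
  }
  total
}

#' Approximate -2 log marginal likelihood of a dataset
#'
#' The objective minimized by [hcqfit()]: a Laplace-type approximation
#' expanded at each subject's conditional (empirical Bayes) eta mode, with
#' observation variances evaluated at the individual predictions
#' (interaction), the log-normal eta prior, and the log-determinant
#' curvature correction.
#'
#' @param pop [hcq_popparams()].
#' @param data `hcq_dataset`.
#' @param control [hcqfit_control()].
#' @return numeric scalar (OFV).
#' @export
hcq_neg2ll <- function(pop, data, control = hcqfit_control()) {
  .neg2ll_subjects(split_subjects(data), pop, control = control)
}

#' Empirical Bayes eta modes for every subject
#'
#' Maximizes the joint density of each subject's observations and etas at
#' fixed population parameters.
#'
#' @inheritParams hcq_neg2ll
#' @return matrix (subjects x 5) of conditional eta modes.
#' @export
eta_modes <- function(pop, data, control = hcqfit_control()) {
  subs <- split_subjects(data)
  theta <- as_theta(pop$typical)
  add_umol <- .sigma_add_umol(pop)
  out <- t(vapply(subs, function(sub) {
    .subject_laplace(sub, theta, pop$omega, pop$sigma_prop, add_umol,
                     control = control)$eta
  }, numeric(5)))
  dimnames(out) <- list(vapply(subs, function(s) as.character(s$id),
                               character(1)), .ETA_NAMES)
  out
}

#' Fit the population PK model
#'
#' Minimizes the approximate -2 log marginal likelihood ([hcq_neg2ll()]) over
#' the non-fixed population parameters, all positivity-constrained via a log
#' transform. Absorption `ka` and `lag` are fixed by default (they are not
#' estimable from sparse trough-type sampling). Returns a fitted-model object
#' with empirical Bayes estimates, shrinkage and (optionally)
#' curvature-based relative standard errors.
#'
#' @param data `hcq_dataset` (see [read_dataset()], [generate_cohort()]).
#' @param init initial [hcq_popparams()]; defaults to the package reference
#'   estimates.
#' @param fixed names of parameters held fixed (any of
#'   `r paste(.FIT_PAR_NAMES, collapse = ", ")`).
#' @param covariates optional covariate model: a list of terms, each a list
#'   with `parameter` (a structural-parameter name), `covariate` (a dataset
#'   column), `type` (`"continuous"` or `"categorical"`), and for continuous
#'   terms a reference value `ref` (defaults to the dataset median), for
#'   categorical terms the non-reference `level`. Continuous covariates enter
#'   as power models `typical * (cov/ref)^beta`.
#' @param se compute standard errors from the numerically estimated Hessian
#'   (adds substantial runtime for the full model).
#' @param control [hcqfit_control()].
#' @return object of class `hcqfit`.
#' @export
hcqfit <- function(data, init = hcq_popparams(), fixed = c("lag", "ka"),
                   covariates = NULL, se = FALSE,
                   control = hcqfit_control()) {
  stopifnot(inherits(data, "hcq_dataset"))
  if (!all(fixed %in% .FIT_PAR_NAMES))
    stop("unknown fixed parameter(s): ",
         paste(setdiff(fixed, .FIT_PAR_NAMES), collapse = ", "))
  subs <- split_subjects(data)
  cov_model <- .prepare_cov_model(covariates, data)
  n_beta <- length(cov_model)

  full0 <- .pop_to_vec(init)
  free <- setdiff(.FIT_PAR_NAMES, fixed)
  if (any(full0[free] <= 0))
    stop("free parameters must have positive initial values")
  psi0 <- c(log(full0[free]), rep(0, n_beta))
  if (n_beta)
    names(psi0)[length(free) + seq_len(n_beta)] <-
      vapply(cov_model, function(tm)
        paste0("beta_", tm$parameter, "_", tm$covariate), character(1))

  state <- new.env()
  state$etas <- matrix(0, length(subs), 5)

  unpack <- function(psi) {
    full <- full0
    full[free] <- exp(psi[seq_along(free)])
    list(pop = .vec_to_pop(full),
         betas = if (n_beta) psi[length(free) + seq_len(n_beta)]
                 else numeric(0))
  }
  obj <- function(psi) {
    u <- unpack(psi)
    .neg2ll_subjects(subs, u$pop, cov_model, u$betas,
                     control = control, state = state)
  }

  best <- NULL
  for (r in seq_len(max(1, control$restarts))) {
    start <- psi0
    if (r > 1)
      start <- psi0 + stats::rnorm(length(psi0), sd = control$jitter_sd)
    state$etas[] <- 0
    opt <- stats::nlminb(start, obj,
                         control = list(rel.tol = control$outer_reltol,
                                        iter.max = control$outer_maxit,
                                        eval.max = 10 * control$outer_maxit))
    # polish runs: the warm-started inner modes make the objective mildly
    # path-dependent, so convergence is declared when a restart from the
    # candidate optimum no longer moves the objective
    stable <- FALSE
    for (pol in seq_len(5)) {
      polish <- stats::nlminb(opt$par, obj,
                              control = list(rel.tol = control$outer_reltol,
                                             iter.max = control$outer_maxit))
      improved <- opt$objective - polish$objective
      if (polish$objective <= opt$objective) opt <- polish
      if (is.finite(improved) && abs(improved) < 0.1) { stable <- TRUE; break }
    }
    opt$stable <- stable
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  u <- unpack(best$par)
  # refresh EBEs at the optimum
  ofv <- .neg2ll_subjects(subs, u$pop, cov_model, u$betas,
                          control = control, state = state)
  ebe <- state$etas
  rownames(ebe) <- vapply(subs, function(s) as.character(s$id), character(1))
  colnames(ebe) <- .ETA_NAMES

  estimates <- c(.pop_to_vec(u$pop)[free], u$betas)
  boundary <- names(which(.pop_to_vec(u$pop)[grep("^omega_", free, value = TRUE)] < 1e-3))

  fit <- structure(list(
    coefficients = estimates,
    popparams = u$pop,
    betas = u$betas,
    cov_model = cov_model,
    fixed = fixed,
    ofv = ofv,
    convergence = best$convergence == 0 || isTRUE(best$stable),
    message = best$message,
    boundary = boundary,
    ebe = ebe,
    shrinkage = .shrinkage(ebe, u$pop$omega),
    n_subjects = length(subs),
    n_obs = sum(vapply(subs, function(s) length(s$y_umol), numeric(1))),
    psi = best$par,
    free = free,
    full0 = full0,
    data = data,
    control = control,
    se = NULL, rse = NULL
  ), class = "hcqfit")

  if (se) {
    fit <- .add_se(fit, obj)
  }
  fit
}

.prepare_cov_model <- function(covariates, data) {
  if (is.null(covariates)) return(NULL)
  lapply(covariates, function(term) {
    if (!term$parameter %in% .THETA_NAMES)
      stop("unknown parameter in covariate term: ", term$parameter)
    if (!term$covariate %in% names(data))
      stop("covariate column not in dataset: ", term$covariate)
    x <- data[[term$covariate]][!duplicated(data$ID)]
    if (term$type == "continuous") {
      if (stats::var(as.numeric(x), na.rm = TRUE) == 0) {
        warning("covariate ", term$covariate, " has zero variance; skipped")
        return(NULL)
      }
      if (is.null(term$ref))
        term$ref <- stats::median(as.numeric(x), na.rm = TRUE)
    } else {
      if (is.null(term$level)) term$level <- sort(unique(x))[2]
      if (length(unique(x)) < 2) {
        warning("covariate ", term$covariate, " has one level; skipped")
        return(NULL)
      }
    }
    term
  }) |> Filter(f = Negate(is.null))
}

.shrinkage <- function(ebe, omega) {
  out <- rep(NA_real_, 5)
  names(out) <- .ETA_NAMES
  for (k in seq_len(5)) {
    if (omega[k] > 0)
      out[k] <- 100 * (1 - stats::sd(ebe[, k]) / omega[k])
  }
  out
}

.add_se <- function(fit, obj) {
  psi <- fit$psi
  np <- length(psi)
  h <- pmax(abs(psi), 1) * 1e-4
  H <- matrix(0, np, np)
  f0 <- fit$ofv
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    ei <- rep(0, np); ei[i] <- h[i]
    fp[i] <- obj(psi + ei); fm[i] <- obj(psi - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(np)) for (j in seq_len(np)) if (i < j) {
    eij <- rep(0, np); eij[i] <- h[i]; eij[j] <- h[j]
    fij <- obj(psi + eij)
    H[i, j] <- H[j, i] <- (fij - fp[i] - fp[j] + f0) / (h[i] * h[j])
  }
  cov_psi <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_psi) || any(diag(cov_psi) < 0)) {
    fit$rse <- rep(NA_real_, np)
    names(fit$rse) <- names(fit$coefficients)
    return(fit)
  }
  se_psi <- sqrt(diag(cov_psi))
  # log-scale SE is the relative SE of the natural-scale parameter
  rse <- 100 * se_psi
  nb <- length(fit$betas)
  if (nb) {  # betas are untransformed: report absolute SE as NA-safe RSE
    idx <- np - nb + seq_len(nb)
    rse[idx] <- 100 * se_psi[idx] / abs(psi[idx])
  }
  names(rse) <- names(fit$coefficients)
  fit$se <- se_psi
  fit$rse <- rse
  fit$vcov_psi <- cov_psi
  fit
}

#' Eta shrinkage of a fitted model
#'
#' `100 * (1 - SD(EBE)/omega)` per random effect; near 0 when the data
#' determine individual etas well, near 100 when the EBEs collapse to the
#' prior mode.
#'
#' @param fit `hcqfit` object.
#' @return named numeric vector (percent).
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "hcqfit"))
  fit$shrinkage
}

#' @export
coef.hcqfit <- function(object, ...) object$coefficients

#' @export
logLik.hcqfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.hcqfit <- function(x, ...) {
  cat("Population PK fit (Laplace/FOCE-type approximate marginal likelihood)\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f%s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  cat("\nEstimates:\n")
  print(signif(x$coefficients, 4))
  if (length(x$boundary))
    cat("\nBoundary omegas (near 0):", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hcqfit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients)
  if (!is.null(object$rse)) tab$rse_pct <- object$rse
  structure(list(table = tab, ofv = object$ofv,
                 shrinkage = object$shrinkage,
                 convergence = object$convergence,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.hcqfit")
}

#' @export
print.summary.hcqfit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations\nOFV = %.3f (converged: %s)\n\n",
              x$n_subjects, x$n_obs, x$ofv, x$convergence))
  print(signif(as.matrix(x$table), 4))
  cat("\nEta shrinkage (%):\n")
  print(round(x$shrinkage[!is.na(x$shrinkage)], 1))
  invisible(x)
}

#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' Empirical Bayes estimates of a fitted model
#' @param object `hcqfit` object.
#' @param ... unused.
#' @return matrix of per-subject eta modes.
#' @export
ranef.hcqfit <- function(object, ...) object$ebe

#' @export
fitted.hcqfit <- function(object, ...) {
  .predict_obs(object, level = "individual")
}

#' @export
residuals.hcqfit <- function(object, ...) {
  obs <- object$data[object$data$EVID == 0 & object$data$MDV == 0, ]
  obs$DV - .predict_obs(object, level = "individual")
}

# predictions (ug/L) aligned with the non-missing observation records
.predict_obs <- function(object, level = c("individual", "population")) {
  level <- match.arg(level)
  subs <- split_subjects(object$data)
  theta <- as_theta(object$popparams$typical)
  unlist(lapply(seq_along(subs), function(i) {
    sub <- subs[[i]]
    if (!length(sub$obs_time)) return(numeric(0))
    th <- .subject_theta(theta, object$cov_model, object$betas,
                         sub$covariates)
    eta <- if (level == "individual") object$ebe[i, ] else rep(0, 5)
    pred <- cpp_pred_eta(eta, th, sub$dose_time, sub$dose_umol,
                         sub$obs_time, sub$obs_cmt)
    convert_conc(pred, .COMPOUNDS[sub$obs_cmt], "umol/L", "ug/L")
  }))
}

#' Predict concentration profiles from a fitted model
#'
#' @param object `hcqfit` object.
#' @param regimen [hcq_regimen()].
#' @param times times (h).
#' @param level `"population"` (typical-value prediction) or `"individual"`
#'   (one profile per subject at its empirical Bayes etas).
#' @param unit output unit.
#' @param ... unused.
#' @return tidy data.frame of predicted concentrations.
#' @export
predict.hcqfit <- function(object, regimen, times,
                           level = c("population", "individual"),
                           unit = c("ug/L", "umol/L"), ...) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (level == "population")
    return(predict_concentrations(object$popparams$typical, regimen, times,
                                  unit = unit))
  out <- lapply(rownames(object$ebe), function(id) {
    p <- individual_params(object$popparams, object$ebe[id, ])
    cbind(ID = id, predict_concentrations(p, regimen, times, unit = unit))
  })
  do.call(rbind, out)
}

#' Goodness-of-fit plot
#'
#' Observed versus population and individual predictions on the
#' non-missing observation records.
#'
#' @param x `hcqfit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hcqfit <- function(x, ...) {
  obs <- x$data[x$data$EVID == 0 & x$data$MDV == 0, ]
  ipred <- .predict_obs(x, "individual")
  pred <- .predict_obs(x, "population")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(pred, obs$DV, xlab = "Population prediction (ug/L)",
                 ylab = "Observed (ug/L)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(ipred, obs$DV, xlab = "Individual prediction (ug/L)",
                 ylab = "Observed (ug/L)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
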