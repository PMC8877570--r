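# Stepwise covariate selection on the population model: power-model terms,
# likelihood-ratio criteria (chi-square, 1 df) of p < 0.05 forward and
# p < 0.001 backward.

#' Stepwise covariate selection
#'
#' Forward addition / backward deletion over candidate covariate-parameter
#' pairs. At each forward step the candidate with the largest objective
#' drop is added if the drop exceeds `qchisq(1 - forward_p, 1)` (3.84 at
#' p = 0.05); backward deletion then removes any term whose removal raises
#' the objective by less than `qchisq(1 - backward_p, 1)` (10.83 at
#' p = 0.001).
#'
#' @param data `hcq_dataset`.
#' @param init initial [hcq_popparams()].
#' @param candidates list of candidate terms, each as in the `covariates`
#'   argument of [hcqfit()].
#' @param fixed parameters held fixed during every fit.
#' @param forward_p,backward_p LRT significance levels.
#' @param control [hcqfit_control()].
#' @return list with the final `fit`, the `included` terms, the base-model
#'   fit and a `trace` data.frame of tested steps.
#' @export
select_covariates <- function(data, init = hcq_popparams(), candidates,
                              fixed = c("lag", "ka"),
                              forward_p = 0.05, backward_p = 0.001,
                              control = hcqfit_control()) {
  fwd_crit <- stats::qchisq(1 - forward_p, df = 1)
  bwd_crit <- stats::qchisq(1 - backward_p, df = 1)
  candidates <- .prepare_cov_model(candidates, data)
  base <- hcqfit(data, init = init, fixed = fixed, control = control)
  included <- list()
  pool <- candidates
  current <- base
  trace <- list()
  label <- function(tm) paste0(tm$parameter, "~", tm$covariate)

  repeat {  # forward
    if (!length(pool)) break
    # candidate fits warm-start at the current estimates so that the
    # likelihood-ratio statistic compares properly nested optima
    fits <- lapply(pool, function(tm)
      hcqfit(data, init = current$popparams, fixed = fixed,
             covariates = c(included, list(tm)), control = control))
    dofv <- current$ofv - vapply(fits, `[[`, numeric(1), "ofv")
    for (i in seq_along(pool))
      trace[[length(trace) + 1]] <- data.frame(
        step = "forward", term = label(pool[[i]]), dofv = dofv[i])
    best <- which.max(dofv)
    if (dofv[best] <= fwd_crit) break
    included <- c(included, pool[best])
    current <- fits[[best]]
    pool <- pool[-best]
  }

  repeat {  # backward
    if (!length(included)) break
    fits <- lapply(seq_along(included), function(i)
      hcqfit(data, init = current$popparams, fixed = fixed,
             covariates = included[-i], control = control))
    dofv <- vapply(fits, `[[`, numeric(1), "ofv") - current$ofv
    for (i in seq_along(included))
      trace[[length(trace) + 1]] <- data.frame(
        step = "backward", term = label(included[[i]]), dofv = dofv[i])
    worst <- which.min(dofv)
    if (dofv[worst] >= bwd_crit) break
    included <- included[-worst]
    current <- fits[[worst]]
  }

  list(fit = current, included = included, base = base,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = character(0), term = character(0),
                    dofv = numeric(0)))
}
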