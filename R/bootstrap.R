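# Nonparametric bootstrap: subjects resampled with replacement (each
# subject's full record block kept intact), percentile confidence intervals
# from the converged replicates.

# order-statistic percentile: the ceiling(q*n)-th sorted value
.boot_percentile <- function(x, probs) {
  s <- sort(x)
  idx <- pmin(pmax(ceiling(probs * length(s)), 1), length(s))
  stats::setNames(s[idx], paste0(format(100 * probs), "%"))
}

#' Bootstrap confidence intervals for the population parameters
#'
#' Refits the model to `n_boot` datasets built by resampling subjects with
#' replacement, then takes the 2.5th and 97.5th percentile of each parameter
#' across the converged replicates. More than 20% non-converged replicates
#' flags the result as unreliable.
#'
#' @inheritParams hcqfit
#' @param n_boot number of bootstrap datasets.
#' @param resample set `FALSE` to refit the original data in every replicate
#'   (degenerate intervals; mainly for testing).
#' @param level confidence level.
#' @return list of class `hcq_bootstrap`: `ci` (parameter x bounds matrix),
#'   `estimates` (replicate x parameter), `n_converged`, `reliable`.
#' @export
bootstrap_fit <- function(data, init = hcq_popparams(),
                          fixed = c("lag", "ka"), n_boot = 500,
                          resample = TRUE, level = 0.95,
                          control = hcqfit_control()) {
  ids <- unique(data$ID)
  reps <- vector("list", n_boot)
  conv <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    if (resample) {
      take <- sample(ids, length(ids), replace = TRUE)
      pieces <- lapply(seq_along(take), function(j) {
        block <- data[data$ID == take[j], , drop = FALSE]
        block$ID <- j
        block
      })
      dat_b <- hcq_dataset(do.call(rbind, pieces),
                           dv_unit = attr(data, "dv_unit") %||% "ug/L")
    } else {
      dat_b <- data
    }
    fit <- tryCatch(hcqfit(dat_b, init = init, fixed = fixed,
                           control = control),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$convergence) {
      conv[b] <- TRUE
      reps[[b]] <- coef(fit)
    }
  }
  est <- do.call(rbind, reps[conv])
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(est, 2, .boot_percentile, probs = probs))
  reliable <- mean(conv) >= 0.8
  if (!reliable)
    warning(sprintf("only %d/%d bootstrap replicates converged; intervals unreliable",
                    sum(conv), n_boot))
  structure(list(ci = ci, estimates = est, n_converged = sum(conv),
                 n_boot = n_boot, reliable = reliable),
            class = "hcq_bootstrap")
}

#' @export
print.hcq_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d converged replicates%s\n\n",
              x$n_converged, x$n_boot,
              if (x$reliable) "" else " [UNRELIABLE]"))
  print(signif(x$ci, 4))
  invisible(x)
}
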