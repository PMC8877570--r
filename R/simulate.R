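# Monte-Carlo machinery: dosing-regimen trough simulation, visual
# predictive checks and normalized prediction distribution errors.

#' Simulate trough concentrations under a dosing regimen
#'
#' Samples `n` individuals from the population (between-subject variability
#' only, no residual error), computes each individual's pre-dose HCQ
#' concentration at the requested clock times (left limit, doses at exactly
#' that time excluded) and summarizes the fraction below a threshold.
#'
#' @param pop [hcq_popparams()].
#' @param scenario dosing scenario 1-5 (see [hcq_regimen()]) or an
#'   `hcq_regimen` object.
#' @param n number of simulated individuals.
#' @param times trough clock times (h after first dose).
#' @param threshold exposure threshold (ug/L) for the summary.
#' @param seed optional RNG seed.
#' @return data.frame of class `hcq_troughs` (`id`, one `trough<t>` column
#'   per time, ug/L, HCQ), with attribute `pct_below` (percent of
#'   individuals below `threshold` per time) and `scenario`.
#' @examples
#' tr <- simulate_troughs(hcq_popparams(), scenario = 2, n = 50, seed = 1)
#' attr(tr, "pct_below")
#' @export
simulate_troughs <- function(pop, scenario, n = 500, times = c(48, 72),
                             threshold = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(scenario, "hcq_regimen")) {
    regimen <- scenario
    scen_lab <- attr(regimen, "scenario")
  } else {
    regimen <- hcq_regimen(scenario = scenario,
                           duration = max(times) + 24)
    scen_lab <- scenario
  }
  if (n < 1) stop("n must be >= 1")
  eta <- sample_etas(pop, n)
  tr <- matrix(0, n, length(times))
  for (i in seq_len(n)) {
    p <- individual_params(pop, eta[i, ])
    for (j in seq_along(times))
      tr[i, j] <- trough_concentration(p, regimen, times[j],
                                       unit = "ug/L")[["HCQ"]]
  }
  tr <- pmax(tr, 0)
  out <- data.frame(id = seq_len(n), tr)
  names(out) <- c("id", paste0("trough", times))
  pct <- 100 * colMeans(tr < threshold)
  names(pct) <- paste0("t", times)
  structure(out, class = c("hcq_troughs", "data.frame"),
            pct_below = pct, threshold = threshold, scenario = scen_lab)
}

# Simulate replicate observation vectors under the model for the design
# (doses + sampling times) of an existing dataset. Returns an
# n_obs x nsim matrix in ug/L, rows aligned with the non-missing
# observation records of `data`. Negative draws are retained.
simulate_observations <- function(pop, data, nsim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subs <- split_subjects(data)
  theta <- as_theta(pop$typical)
  add_umol <- .sigma_add_umol(pop)
  nobs <- vapply(subs, function(s) length(s$obs_time), integer(1))
  out <- matrix(NA_real_, sum(nobs), nsim)
  for (r in seq_len(nsim)) {
    row0 <- 0
    eta <- sample_etas(pop, length(subs))
    for (i in seq_along(subs)) {
      sub <- subs[[i]]
      if (!nobs[i]) next
      pred <- cpp_pred_eta(eta[i, ], theta, sub$dose_time, sub$dose_umol,
                           sub$obs_time, sub$obs_cmt)
      prop <- pop$sigma_prop[sub$obs_cmt]
      add <- add_umol[sub$obs_cmt]
      y <- pred + stats::rnorm(nobs[i], sd = sqrt((prop * pred)^2 + add^2))
      out[row0 + seq_len(nobs[i]), r] <-
        convert_conc(y, .COMPOUNDS[sub$obs_cmt], "umol/L", "ug/L")
      row0 <- row0 + nobs[i]
    }
  }
  out
}

# observation-record metadata aligned with simulate_observations rows
.obs_frame <- function(data) {
  subs <- split_subjects(data)
  do.call(rbind, lapply(subs, function(sub) {
    if (!length(sub$obs_time)) return(NULL)
    data.frame(ID = sub$id, time = sub$obs_time,
               compound = .COMPOUNDS[sub$obs_cmt],
               dv = convert_conc(sub$y_umol, .COMPOUNDS[sub$obs_cmt],
                                 "umol/L", "ug/L"))
  }))
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets under the model using each subject's
#' own design (doses and sampling times), then compares the observed 5th,
#' 50th and 95th concentration percentiles per time bin with the 90%
#' interval of the same percentiles across replicates, per compound.
#'
#' @param pop [hcq_popparams()].
#' @param data `hcq_dataset` supplying the design and the observations.
#' @param n_rep number of simulation replicates.
#' @param n_bins number of time bins (quantile-based); bins with fewer than
#'   3 observations are merged with a neighbour (with a warning).
#' @param ci width of the simulated percentile band.
#' @param lloq optional named vector of per-compound LLOQ values (ug/L)
#'   carried through to the output for plotting.
#' @param seed optional RNG seed.
#' @return data.frame of class `hcq_vpc`: one row per compound x bin x
#'   percentile with observed value and simulated band.
#' @export
vpc <- function(pop, data, n_rep = 500, n_bins = 10, ci = 0.90,
                lloq = NULL, seed = NULL) {
  sims <- simulate_observations(pop, data, n_rep, seed = seed)
  obs <- .obs_frame(data)
  qs <- c(0.05, 0.5, 0.95)
  alpha <- (1 - ci) / 2
  out <- list()
  for (cc in unique(obs$compound)) {
    sel <- obs$compound == cc
    ot <- obs$time[sel]
    breaks <- unique(stats::quantile(ot, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(ot, breaks = breaks, include.lowest = TRUE)
    # merge small bins with their left neighbour
    repeat {
      tab <- table(bin)
      small <- which(tab < 3 & tab > 0)
      if (!length(small) || length(tab) == 1) break
      warning("merging a VPC time bin with < 3 observations (", cc, ")")
      lv <- levels(bin)
      i <- small[1]
      into <- if (i == 1) 2 else i - 1
      levels(bin)[i] <- lv[into]
    }
    for (b in levels(bin)[table(bin) > 0]) {
      rows <- which(sel)[bin == b]
      obs_q <- stats::quantile(obs$dv[rows], qs, names = FALSE)
      sim_q <- apply(sims[rows, , drop = FALSE], 2, stats::quantile,
                     probs = qs, names = FALSE)
      lo <- apply(sim_q, 1, stats::quantile, probs = alpha, names = FALSE)
      hi <- apply(sim_q, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        compound = cc, bin = b, t_mid = stats::median(obs$time[rows]),
        n = length(rows), percentile = 100 * qs,
        observed = obs_q, sim_lo = lo, sim_hi = hi,
        lloq = if (!is.null(lloq) && cc %in% names(lloq)) lloq[[cc]]
               else NA_real_)
    }
  }
  structure(do.call(rbind, out), class = c("hcq_vpc", "data.frame"),
            n_rep = n_rep, ci = ci)
}

#' VPC plot
#'
#' @param x `hcq_vpc` object.
#' @param compound compound to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hcq_vpc <- function(x, compound = "HCQ", ...) {
  d <- x[x$compound == compound, ]
  graphics::plot(range(d$t_mid), range(c(d$observed, d$sim_lo, d$sim_hi)),
                 type = "n", xlab = "Time (h)",
                 ylab = paste(compound, "(ug/L)"), ...)
  for (p in unique(d$percentile)) {
    dd <- d[d$percentile == p, ]
    o <- order(dd$t_mid)
    graphics::polygon(c(dd$t_mid[o], rev(dd$t_mid[o])),
                      c(dd$sim_lo[o], rev(dd$sim_hi[o])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(dd$t_mid[o], dd$observed[o],
                    lty = if (p == 50) 1 else 2)
  }
  if (any(!is.na(d$lloq)))
    graphics::abline(h = d$lloq[1], lty = 3)
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' For each non-missing observation, the observed value is ranked within its
#' `n_rep` simulated counterparts (mid-rank convention for ties) and the
#' rank is mapped through the inverse normal. Under a correct model the
#' NPDE are approximately standard normal.
#'
#' @inheritParams vpc
#' @return data.frame of class `hcq_npde`: `ID`, `time`, `compound`,
#'   `pred` (population prediction, ug/L), `npde` (NA, with `flag = TRUE`,
#'   where all simulated counterparts are identical).
#' @export
npde <- function(pop, data, n_rep = 500, seed = NULL) {
  if (n_rep < 100) stop("n_rep must be >= 100 for NPDE")
  sims <- simulate_observations(pop, data, n_rep, seed = seed)
  obs <- .obs_frame(data)
  subs <- split_subjects(data)
  theta <- as_theta(pop$typical)
  pred <- unlist(lapply(subs, function(sub) {
    if (!length(sub$obs_time)) return(numeric(0))
    p <- cpp_pred_eta(rep(0, 5), theta, sub$dose_time, sub$dose_umol,
                      sub$obs_time, sub$obs_cmt)
    convert_conc(p, .COMPOUNDS[sub$obs_cmt], "umol/L", "ug/L")
  }))
  npde_val <- flag <- rep(NA, nrow(obs))
  for (j in seq_len(nrow(obs))) {
    s <- sims[j, ]
    if (all(s == s[1])) { flag[j] <- TRUE; next }
    flag[j] <- FALSE
    r <- sum(s < obs$dv[j]) + 0.5 * sum(s == obs$dv[j])
    u <- (r + 0.5) / (n_rep + 1)
    npde_val[j] <- stats::qnorm(u)
  }
  structure(data.frame(ID = obs$ID, time = obs$time,
                       compound = obs$compound, pred = pred,
                       npde = npde_val, flag = flag),
            class = c("hcq_npde", "data.frame"), n_rep = n_rep)
}

#' Simulate replicate datasets from a fitted model
#'
#' @param object `hcqfit` object.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `hcq_dataset` objects with simulated DV (ug/L, floored
#'   at 0 so the event-record invariants hold).
#' @export
simulate.hcqfit <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- simulate_observations(object$popparams, object$data, nsim,
                                seed = seed)
  obs_idx <- which(object$data$EVID == 0 & object$data$MDV == 0)
  lapply(seq_len(nsim), function(r) {
    d <- as.data.frame(object$data)
    d$DV[obs_idx] <- pmax(sims[, r], 0)
    hcq_dataset(d, dv_unit = attr(object$data, "dv_unit") %||% "ug/L")
  })
}
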