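# Exposure-outcome stage: length of stay and clinical outcome versus
# model-predicted trough concentrations.

#' Composite clinical outcome
#'
#' Poor outcome = death, transfer to ICU, or hospitalization lasting 10 days
#' or more; good otherwise; missing when the length of stay is missing and
#' neither death nor ICU transfer is recorded.
#'
#' @param death,icu_transfer logical vectors.
#' @param los_days length of stay (days), possibly `NA`.
#' @return factor with levels `good`, `poor` (NA where undetermined).
#' @examples
#' composite_outcome(FALSE, FALSE, c(9, 10, NA))
#' @export
composite_outcome <- function(death, icu_transfer, los_days) {
  n <- max(length(death), length(icu_transfer), length(los_days))
  death <- rep_len(as.logical(death), n)
  icu <- rep_len(as.logical(icu_transfer), n)
  los <- rep_len(los_days, n)
  poor <- (death %in% TRUE) | (icu %in% TRUE) | (!is.na(los) & los >= 10)
  out <- ifelse(poor, "poor", ifelse(is.na(los), NA, "good"))
  factor(out, levels = c("good", "poor"))
}

.get_exposure <- function(exposure, timepoint, var = "trough") {
  col <- paste0(var, timepoint)
  if (!col %in% names(exposure))
    stop("exposure table lacks column ", col)
  exposure[, c("ID", col)]
}

#' Linear regression of length of stay on trough concentration
#'
#' Ordinary least squares of length of stay (days) on the individual trough
#' concentration (ug/L) at 48 or 72 h; subjects with missing length of stay
#' are excluded listwise.
#'
#' @param pd data.frame with columns `ID`, `los` (days).
#' @param exposure data.frame with columns `ID` and `trough48`/`trough72`
#'   (ug/L); set `var` to regress on another exposure column (e.g.
#'   `"cl_parent"` for the clearance endpoint, column `cl_parent`).
#' @param timepoint `"48"` or `"72"` (ignored when `var` is not `"trough"`
#'   and names a full column).
#' @param var exposure column prefix, default `"trough"`.
#' @return list: `coefficients` (lm summary table), `slope`, `r_squared`,
#'   `p_value` (two-sided, slope), `n`.
#' @export
regress_los_on_trough <- function(pd, exposure, timepoint = c("48", "72"),
                                  var = "trough") {
  timepoint <- match.arg(timepoint)
  col <- if (paste0(var, timepoint) %in% names(exposure))
    paste0(var, timepoint) else var
  if (!col %in% names(exposure)) stop("exposure table lacks column ", col)
  d <- merge(pd[, c("ID", "los")], exposure[, c("ID", col)], by = "ID")
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 complete LOS-exposure pairs")
  if (stats::var(d[[col]]) == 0) stop("exposure has zero variance")
  fm <- stats::lm(stats::reformulate(col, "los"), data = d)
  sm <- summary(fm)
  list(coefficients = stats::coef(sm),
       slope = unname(stats::coef(fm)[2]),
       r_squared = sm$r.squared,
       p_value = stats::coef(sm)[2, "Pr(>|t|)"],
       n = nrow(d))
}

#' One-way ANOVA of trough concentration by outcome group
#'
#' Analyzes the trough concentration with death or composite outcome as a
#' fixed factor, reporting per-group mean +/- SD (ug/L) alongside the F
#' test.
#'
#' @param pd data.frame with `ID` and the grouping column (`outcome` or
#'   `death`).
#' @param exposure data.frame with `ID` and `trough48`/`trough72` (ug/L).
#' @param grouping `"outcome"` or `"death"`.
#' @param timepoint `"48"` or `"72"`.
#' @return list: `groups` (n, mean, sd per level), `F`, `p_value`, `df`.
#' @export
anova_trough_by_group <- function(pd, exposure,
                                  grouping = c("outcome", "death"),
                                  timepoint = c("48", "72")) {
  grouping <- match.arg(grouping)
  timepoint <- match.arg(timepoint)
  col <- paste0("trough", timepoint)
  d <- merge(pd[, c("ID", grouping)], exposure[, c("ID", col)], by = "ID")
  names(d) <- c("ID", "group", "trough")
  d <- d[stats::complete.cases(d), ]
  d$group <- factor(d$group)
  tab <- table(d$group)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 members")
  fm <- stats::aov(trough ~ group, data = d)
  an <- summary(fm)[[1]]
  groups <- do.call(rbind, lapply(levels(d$group), function(g) {
    x <- d$trough[d$group == g]
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x))
  }))
  list(groups = groups,
       F = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]))
}

#' Empirical CDF of length of stay by trough-concentration band
#'
#' Splits subjects into trough bands (closed on the left, open on the
#' right, last band open-ended), computes the empirical CDF of length of
#' stay per band and the proportion with stay below a cutoff, plus the
#' dichotomized comparison below/above the first cut.
#'
#' @inheritParams regress_los_on_trough
#' @param bands band edges (ug/L), e.g. `c(0, 200, 400, 600, 800, Inf)`.
#' @param los_cutoff length-of-stay cutoff (days).
#' @return list of class `hcq_los_ecdf`: `bands` (data.frame with n and
#'   proportion below cutoff), `ecdf` (list of stats::ecdf per non-empty
#'   band), `dichotomized` (below/above first cut), `cutoff`.
#' @export
los_ecdf_by_band <- function(pd, exposure, timepoint = c("48", "72"),
                             bands = c(0, 200, 400, 600, 800, Inf),
                             los_cutoff = 25) {
  timepoint <- match.arg(timepoint)
  if (is.unsorted(bands, strictly = TRUE) || bands[1] != 0 ||
      !is.infinite(bands[length(bands)]))
    stop("bands must be strictly increasing edges from 0 to Inf")
  col <- paste0("trough", timepoint)
  d <- merge(pd[, c("ID", "los")], exposure[, c("ID", col)], by = "ID")
  names(d) <- c("ID", "los", "trough")
  d <- d[stats::complete.cases(d), ]
  lab <- paste0("[", bands[-length(bands)], ",", bands[-1], ")")
  d$band <- cut(d$trough, breaks = bands, right = FALSE,
                include.lowest = FALSE, labels = lab)
  band_tab <- do.call(rbind, lapply(lab, function(b) {
    x <- d$los[d$band == b]
    data.frame(band = b, n = length(x),
               prop_below_cutoff = if (length(x)) mean(x < los_cutoff)
                                   else NA_real_)
  }))
  ecdfs <- lapply(stats::setNames(lab, lab), function(b) {
    x <- d$los[d$band == b]
    if (length(x)) stats::ecdf(x) else NULL
  })
  cut1 <- bands[2]
  dich <- data.frame(
    group = c(paste0("<", cut1), paste0(">=", cut1)),
    n = c(sum(d$trough < cut1), sum(d$trough >= cut1)),
    prop_below_cutoff = c(mean(d$los[d$trough < cut1] < los_cutoff),
                          mean(d$los[d$trough >= cut1] < los_cutoff))
  )
  structure(list(bands = band_tab, ecdf = ecdfs, dichotomized = dich,
                 cutoff = los_cutoff, n = nrow(d)),
            class = "hcq_los_ecdf")
}

#' Holm step-down multiplicity adjustment
#'
#' Adjusts a family of p-values (here, the exploratory metabolite analyses:
#' metabolites x endpoints x timepoints) by the Holm step-down procedure
#' with monotonicity enforcement.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order and names as the input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))
#' @export
holm_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Full exposure-outcome report
#'
#' Runs the four analyses of the PK/PD stage at both trough time points:
#' linear regression of length of stay on trough, ANOVA of trough by
#' composite outcome and by death, and the banded/dichotomized empirical
#' CDF of length of stay; metabolite troughs (columns
#' `trough48_<metabolite>` etc., if present) are tested exploratorily
#' against length of stay with Holm adjustment across the family.
#'
#' @inheritParams regress_los_on_trough
#' @param pd data.frame with `ID`, `los`, `death`, `icu_transfer`,
#'   `outcome`.
#' @return nested list of analysis results.
#' @export
pkpd_report <- function(pd, exposure) {
  out <- list()
  for (tp in c("48", "72")) {
    out[[paste0("t", tp)]] <- list(
      regression = regress_los_on_trough(pd, exposure, tp),
      anova_outcome = tryCatch(
        anova_trough_by_group(pd, exposure, "outcome", tp),
        error = function(e) NULL),
      anova_death = tryCatch(
        anova_trough_by_group(pd, exposure, "death", tp),
        error = function(e) NULL),
      los_ecdf = los_ecdf_by_band(pd, exposure, tp)
    )
  }
  met_cols <- grep("^trough(48|72)_", names(exposure), value = TRUE)
  if (length(met_cols)) {
    praw <- vapply(met_cols, function(cc) {
      regress_los_on_trough(pd, exposure, "48", var = cc)$p_value
    }, numeric(1))
    out$metabolites <- data.frame(test = met_cols, p_raw = praw,
                                  p_holm = holm_adjust(praw))
  }
  out
}
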