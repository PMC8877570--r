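# Event-record datasets: NONMEM-convention columns
#   ID, TIME, EVID (1 dose / 0 observation), AMT (mg), CMT, DV, MDV
# plus covariate columns. CMT codes: 1 depot (doses); observations 2 = HCQ,
# 3 = DesCQ, 4 = DesHCQ, 5 = DiDesCQ. DV is stored in ug/L by default.

.CMT_OFFSET <- 1L  # observation CMT = compound index + 1

.COVARIATE_COLS <- c("AGE", "WT", "HT", "BMI", "SEX", "AZT", "UNIT", "LOAD")

cmt_to_compound <- function(cmt) .COMPOUNDS[cmt - .CMT_OFFSET]
compound_to_cmt <- function(compound) match(compound, .COMPOUNDS) + .CMT_OFFSET

#' Assemble an event-record dataset
#'
#' Validates the invariants of an event-record table: every subject has at
#' least one dose; dose rows (`EVID = 1`) carry `AMT > 0`, `CMT = 1` (depot)
#' and no `DV`; observation rows (`EVID = 0`) carry a compound compartment
#' (2-5) and `DV >= 0` unless flagged missing (`MDV = 1`); times are
#' non-negative and non-decreasing within subject.
#'
#' @param records data.frame with at least columns `ID`, `TIME`, `EVID`,
#'   `AMT`, `CMT`, `DV`, `MDV`; extra columns (covariates) are retained.
#' @param dv_unit unit of the DV column, `"ug/L"` (default) or `"umol/L"`.
#' @return the validated data.frame, class `hcq_dataset`, with attribute
#'   `dv_unit`.
#' @export
hcq_dataset <- function(records, dv_unit = c("ug/L", "umol/L")) {
  dv_unit <- match.arg(dv_unit)
  need <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("dataset is missing mandatory column(s): ", paste(miss, collapse = ", "))
  rec <- as.data.frame(records)
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop(msg, " (row", if (length(i) > 1) "s", " ",
           paste(utils::head(i, 5), collapse = ", "), ")")
  }
  bad(!is.finite(rec$TIME) | rec$TIME < 0, "TIME must be finite and >= 0")
  bad(!rec$EVID %in% c(0, 1), "EVID must be 0 (observation) or 1 (dose)")
  dose <- rec$EVID == 1
  bad(dose & (is.na(rec$AMT) | rec$AMT <= 0), "dose rows need AMT > 0")
  bad(dose & rec$CMT != 1, "doses must enter the depot (CMT = 1)")
  bad(dose & !is.na(rec$DV), "dose rows must not carry DV")
  obs <- !dose
  bad(obs & !rec$CMT %in% (seq_along(.COMPOUNDS) + .CMT_OFFSET),
      "observation CMT must identify one of the four compounds (2-5)")
  bad(obs & rec$MDV == 0 & (is.na(rec$DV) | rec$DV < 0),
      "observation rows need DV >= 0 unless MDV = 1")
  for (id in unique(rec$ID)) {
    rows <- rec[rec$ID == id, ]
    if (!any(rows$EVID == 1))
      stop("subject ", id, " has no dose record")
    if (is.unsorted(rows$TIME))
      stop("times are not non-decreasing within subject ", id)
  }
  structure(rec, class = c("hcq_dataset", "data.frame"), dv_unit = dv_unit)
}

#' Read an event-record dataset from CSV
#'
#' @param path CSV file with the NONMEM-convention columns of
#'   [hcq_dataset()]; an empty `DV` field is read as missing.
#' @inheritParams hcq_dataset
#' @return `hcq_dataset`.
#' @export
read_dataset <- function(path, dv_unit = c("ug/L", "umol/L")) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  hcq_dataset(rec, dv_unit = match.arg(dv_unit))
}

#' Write an event-record dataset to CSV
#'
#' Columns are written in a fixed order and numeric fields with 15
#' significant digits, so a fixed-seed dataset round-trips bit-stably and
#' values reproduce to better than 1e-12 relative.
#'
#' @param data `hcq_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  need <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV")
  extra <- setdiff(names(data), need)
  out <- as.data.frame(data)[, c(need, extra), drop = FALSE]
  for (cc in names(out))
    if (is.numeric(out[[cc]]))
      out[[cc]] <- ifelse(is.na(out[[cc]]), "",
                          formatC(out[[cc]], digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Split a dataset into the per-subject structures used by the estimator.
# DV is converted to the umol/L working unit; MDV-flagged records are
# dropped from the likelihood.
split_subjects <- function(data) {
  dv_unit <- attr(data, "dv_unit") %||% "ug/L"
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    rows <- data[data$ID == id, , drop = FALSE]
    doses <- rows[rows$EVID == 1, , drop = FALSE]
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, , drop = FALSE]
    cmt <- as.integer(obs$CMT) - .CMT_OFFSET
    y <- obs$DV
    if (dv_unit == "ug/L" && nrow(obs))
      y <- convert_conc(y, .COMPOUNDS[cmt], "ug/L", "umol/L")
    cov1 <- rows[1, intersect(.COVARIATE_COLS, names(rows)), drop = FALSE]
    list(id = id,
         dose_time = doses$TIME,
         dose_umol = doses$AMT * 1000 / .molar_masses()[["HCQ"]],
         obs_time = obs$TIME,
         obs_cmt = cmt,          # 1..4 = HCQ, DesCQ, DesHCQ, DiDesCQ
         y_umol = as.numeric(y),
         covariates = cov1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
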