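# Compound registry and unit conversions.
#
# All internal computation is in micromolar (umol/L); microgram-per-litre
# values appear only at the I/O surface, converted with the molar masses
# derived from the molecular formulae below.

.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, Cl = 35.45, N = 14.007, O = 15.999)

.FORMULAE <- c(
  HCQ     = "C18H26ClN3O",
  DesCQ   = "C16H22ClN3",
  DesHCQ  = "C16H22ClN3O",
  DiDesCQ = "C14H18ClN3"
)

#' Molar mass from a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. `"C18H26ClN3O"`) and returns
#' the molar mass in g/mol using standard atomic weights.
#'
#' @param formula character vector of molecular formulae.
#' @return numeric vector of molar masses (g/mol).
#' @examples
#' molar_mass("C18H26ClN3O") # hydroxychloroquine free base
#' @export
molar_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!nzchar(f) || paste(m, collapse = "") != f)
      stop("cannot parse molecular formula: ", f)
    total <- 0
    for (tok in m) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% names(.ATOMIC_WEIGHTS))
        stop("unknown element '", el, "' in formula ", f)
      total <- total + n * .ATOMIC_WEIGHTS[[el]]
    }
    total
  }, numeric(1), USE.NAMES = !is.null(names(formula)))
}

#' Hydroxychloroquine and its three desethyl metabolites
#'
#' The four compounds quantified in whole blood: the parent drug HCQ and its
#' CYP2D6-derived metabolites desethylchloroquine (DesCQ),
#' desethylhydroxychloroquine (DesHCQ) and didesethylchloroquine (DiDesCQ).
#' Molar masses are computed from the molecular formulae (free base).
#'
#' @return data.frame with columns `compound`, `formula`, `molar_mass` (g/mol).
#' @export
hcq_compounds <- function() {
  data.frame(
    compound = .COMPOUNDS,
    formula = unname(.FORMULAE[.COMPOUNDS]),
    molar_mass = unname(molar_mass(.FORMULAE[.COMPOUNDS])),
    stringsAsFactors = FALSE
  )
}

.molar_masses <- function() {
  mm <- molar_mass(.FORMULAE)
  names(mm) <- names(.FORMULAE)
  mm
}

#' Convert concentrations between umol/L and ug/L
#'
#' @param x numeric concentrations.
#' @param compound compound name(s), recycled against `x`.
#' @param from,to `"umol/L"` or `"ug/L"`.
#' @return numeric vector in the target unit.
#' @export
convert_conc <- function(x, compound, from, to) {
  units <- c("umol/L", "ug/L")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(x)
  if (!all(compound %in% .COMPOUNDS)) stop("unknown compound")
  mm <- rep_len(unname(.molar_masses()[compound]), length(x))
  if (from == "umol/L") x * mm else x / mm
}
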