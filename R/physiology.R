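#' Relative electrolyte leakage
#'
#' REL(%) = (S1 - S0) / (S2 - S0) * 100, where S0 is the blank (ddH2O)
#' conductivity, S1 the conductivity after incubation of the leaf discs and
#' S2 the conductivity after boiling (total electrolyte release).
#'
#' @param s0,s1,s2 conductivities in the same units.
#' @return percentage; in `[0, 100]` whenever `s0 <= s1 <= s2`.
#' @export
rel_percent <- function(s0, s1, s2) {
  if (any(s2 <= s0)) stop("degenerate denominator: S2 must exceed S0")
  (s1 - s0) / (s2 - s0) * 100
}

#' Malondialdehyde content
#'
#' MDA (umol/mg protein) = (6.45 * (OD532 - OD600) - 0.56 * OD450) * V * A / W
#' with V the reaction volume (mL), A the dilution ratio and W the protein
#' content (mg/mL). Negative values (noisy blanks) are returned as-is with a
#' warning rather than clipped, since silent clipping hides assay problems.
#'
#' @param od532,od600,od450 absorbances.
#' @param v reaction volume (mL).
#' @param a dilution ratio.
#' @param w protein content (mg/mL), positive.
#' @export
mda_content <- function(od532, od600, od450, v, a, w) {
  if (any(w <= 0)) stop("protein content W must be positive")
  out <- (6.45 * (od532 - od600) - 0.56 * od450) * v * a / w
  if (any(out < 0)) warning("negative MDA content; check assay blanks")
  out
}

#' Relative expression by the 2^-ddCT method
#'
#' ddCT = (CT_target,treated - CT_ref,treated) -
#'        (CT_target,control - CT_ref,control); fold change = 2^-ddCT.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle thresholds.
#' @export
ddct_relative_expression <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Survival rate
#'
#' @param alive,total counts, `0 <= alive <= total`, `total > 0`.
#' @return percentage.
#' @export
survival_rate <- function(alive, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(alive < 0 | alive > total)) stop("alive must be in [0, total]")
  100 * alive / total
}
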