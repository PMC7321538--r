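# Mesophyll / chloroplast CO2-diffusion traits: variable-J mesophyll
# conductance, Rubisco CO2/O2 specificity (S) and its apparent estimate
# (S*), chloroplastic CO2, liquid-phase and internal conductances.

#' Variable-J mesophyll conductance
#'
#' From one steady-state step the chloroplastic CO2 implied by the
#' fluorescence-based electron transport is
#' \deqn{C_{c,J} = \Gamma^* \frac{J_T + 8 (A_{net} + R_d)}
#'                               {J_T - 4 (A_{net} + R_d)}}
#' and the mesophyll conductance is
#' \deqn{g_m = \frac{A_{net}}{C_i - C_{c,J}}.}
#' The identity \code{gm * (Ci - Cc_variableJ) == Anet} holds exactly.
#' The bracketed expression is also the quantity printed as the
#' "per-chloroplast-surface" term in some tabulations; it is exposed here
#' as \code{Cc_variableJ} (a CO2 mole fraction), while the tabulated
#' conductance \code{Clip} is treated as an independent input elsewhere.
#'
#' @param Anet Net assimilation (umol m-2 s-1).
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param Gamma_star CO2 compensation point (umol mol-1).
#' @param JT Total electron transport (umol m-2 s-1).
#' @param Rd Dark respiration (umol m-2 s-1).
#' @return Data frame with columns \code{gm} (mol CO2 m-2 s-1) and
#'   \code{Cc_variableJ} (umol mol-1), vectorised.
#' @export
variable_j_gm <- function(Anet, Ci, Gamma_star, JT, Rd) {
  x <- Anet + Rd
  denom <- JT - 4 * x
  if (any(denom <= 0))
    stop("variable-J domain error: JT must exceed 4 (Anet + Rd)")
  cc <- Gamma_star * (JT + 8 * x) / denom
  if (any(Ci <= cc))
    warning("Ci <= Cc_variableJ for ", sum(Ci <= cc),
            " step(s): negative gm")
  data.frame(gm = Anet / (Ci - cc), Cc_variableJ = cc)
}

#' Rubisco CO2/O2 specificity from the compensation point
#'
#' \deqn{S = O / (2 \Gamma^*)}
#' with the oxygen mole fraction \code{O} defaulting to 210000 umol mol-1
#' (21 percent O2 expressed in the same unit as Gamma*).
#'
#' @param Gamma_star CO2 compensation point (umol mol-1).
#' @param O Oxygen mole fraction (umol mol-1).
#' @return Specificity (mol mol-1), vectorised.
#' @export
specificity_S <- function(Gamma_star, O = 210000) {
  if (any(Gamma_star <= 0)) stop("Gamma_star must be > 0")
  O / (2 * Gamma_star)
}

#' Apparent Rubisco specificity from the Jc/Jo vs Ci/O regression
#'
#' OLS slope of \code{Jc/Jo} against \code{Ci/O} over the initial region
#' (\code{Ci/O <= initial_region_max}).  The regression is not forced
#' through the origin by default.
#'
#' @param ci_over_o Dimensionless Ci/O values (both in umol mol-1).
#' @param jc_over_jo Ratio of carboxylation to oxygenation electron
#'   transport.
#' @param initial_region_max Upper bound of the initial region.
#' @param through_origin Force a zero intercept.
#' @return Apparent specificity S* (mol mol-1).
#' @export
apparent_specificity_sstar <- function(ci_over_o, jc_over_jo,
                                       initial_region_max = 0.5,
                                       through_origin = FALSE) {
  keep <- is.finite(ci_over_o) & is.finite(jc_over_jo) &
    ci_over_o <= initial_region_max
  if (sum(keep) < 3) stop("need at least 3 points in the initial region")
  x <- ci_over_o[keep]; y <- jc_over_jo[keep]
  if (stats::var(y) == 0) return(0)
  fit <- if (through_origin) stats::lm(y ~ x - 1) else stats::lm(y ~ x)
  unname(stats::coef(fit)[["x"]])
}

#' Chloroplastic CO2 from the specificity ratio
#'
#' \deqn{C_c = C_i \times S^* / S}
#'
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param S_star Apparent specificity (mol mol-1).
#' @param S Specificity from the compensation point (mol mol-1).
#' @return Chloroplastic CO2 (umol mol-1), vectorised.
#' @export
cc_from_specificity <- function(Ci, S_star, S) {
  if (any(S <= 0)) stop("S must be > 0")
  Ci * S_star / S
}

#' Liquid-phase conductance
#'
#' \deqn{g_{lip} = C_{lip} \times S_c}
#' the product of the conductance per unit exposed chloroplast surface and
#' the chloroplast surface exposed to intercellular airspace per leaf area.
#'
#' @param Clip Conductance per exposed chloroplast surface
#'   (mol CO2 m-2 s-1).
#' @param Sc Exposed chloroplast surface per leaf area (m2 m-2).
#' @return Liquid-phase conductance (mol CO2 m-2 s-1), vectorised.
#' @export
liquid_phase_conductance <- function(Clip, Sc) {
  if (any(Clip < 0) || any(Sc < 0)) stop("Clip and Sc must be >= 0")
  Clip * Sc
}

#' Internal CO2 conductance
#'
#' \deqn{g_i = A_{max} / (C_i - C_c)}
#'
#' @param Amax Light-saturated assimilation (umol m-2 s-1).
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param Cc Chloroplastic CO2 (umol mol-1); must be below \code{Ci}.
#' @return Internal conductance (mol CO2 m-2 s-1), vectorised.
#' @export
internal_conductance <- function(Amax, Ci, Cc) {
  if (any(Ci <= Cc)) stop("domain error: Ci must exceed Cc")
  Amax / (Ci - Cc)
}

#' Mesophyll conductance per unit Rubisco content
#'
#' \code{1000 * gm / rubisco_content}: the millimole scaling matches the
#' magnitudes conventionally tabulated for this ratio.
#'
#' @param gm Mesophyll conductance (mol CO2 m-2 s-1).
#' @param rubisco_content Rubisco content (ug g-1).
#' @return Ratio (mmol CO2 m-2 s-1 per ug g-1), vectorised.
#' @export
gm_per_rubisco <- function(gm, rubisco_content) {
  if (any(rubisco_content <= 0)) stop("rubisco_content must be > 0")
  1000 * gm / rubisco_content
}
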