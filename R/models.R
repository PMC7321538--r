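#' Exponential light-response model
#'
#' Net assimilation as a function of incident PPFD:
#' \deqn{A_{net} = A_{max} - A_{max} C_0 e^{-\alpha \cdot PPFD / A_{max}}}
#' \code{A_max} is the light-saturated rate, \code{alpha} the apparent
#' quantum yield (initial slope scale) and \code{C0} indexes how far below
#' zero the curve starts in darkness: the model value at PPFD = 0 is
#' \code{A_max * (1 - C0)}, so \code{C0 > 1} implies dark respiration
#' \code{Rd = A_max * (C0 - 1)}.
#'
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1).
#' @param A_max Light-saturated net assimilation (umol CO2 m-2 s-1).
#' @param C0 Dimensionless intercept index.
#' @param alpha Apparent quantum yield (mol mol-1).
#' @return Net assimilation (umol CO2 m-2 s-1), vectorised over \code{ppfd}.
#' @export
light_response <- function(ppfd, A_max, C0, alpha) {
  stopifnot(A_max > 0, alpha > 0, all(ppfd >= 0))
  A_max - A_max * C0 * exp(-alpha * ppfd / A_max)
}

#' Farquhar-type A-Ci forward model
#'
#' Net assimilation on an intercellular-CO2 basis as the minimum of the
#' Rubisco-limited rate \eqn{A_c = V_{cmax}(C_i - \Gamma^*)/(C_i + K_m)}
#' with \eqn{K_m = K_c (1 + O/K_o)}, and the RuBP-regeneration-limited rate
#' \eqn{A_j = J_{max}(C_i - \Gamma^*)/(4 C_i + 8 \Gamma^*)}, minus dark
#' respiration.  Kinetic constants default to 25 degree C values
#' (Kc = 404.9 umol mol-1, Ko = 278.4 mmol mol-1, O = 210 mmol mol-1).
#'
#' @param ci Intercellular CO2 mole fraction (umol mol-1).
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param Jmax Maximum electron-transport rate (umol m-2 s-1).
#' @param Rd Dark respiration (umol m-2 s-1).
#' @param Gamma_star CO2 compensation point of the model (umol mol-1).
#' @param Kc Michaelis constant for CO2 (umol mol-1).
#' @param Ko Michaelis constant for O2 (mmol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @return Net assimilation (umol m-2 s-1), vectorised over \code{ci}.
#' @export
farquhar_anet <- function(ci, Vcmax, Jmax, Rd, Gamma_star,
                          Kc = 404.9, Ko = 278.4, O = 210) {
  stopifnot(Vcmax > 0, Jmax > 0, Rd >= 0, Gamma_star > 0)
  Km <- Kc * (1 + O / Ko)
  Ac <- Vcmax * (ci - Gamma_star) / (ci + Km)
  Aj <- Jmax * (ci - Gamma_star) / (4 * ci + 8 * Gamma_star)
  pmin(Ac, Aj) - Rd
}

#' Net assimilation implied by a known mesophyll conductance
#'
#' Inverts the variable-J relation: given \code{gm}, the chloroplastic CO2
#' mole fraction is \eqn{C_c = \Gamma^* (J_T + 8(A+R_d))/(J_T - 4(A+R_d))}
#' and \eqn{A = g_m (C_i - C_c)}.  Substituting the first into the second
#' gives a quadratic in \eqn{x = A + R_d}; the physically admissible root
#' (the one with \eqn{J_T - 4x > 0}) is returned.  This is the forward model
#' whose inverse is \code{\link{variable_j_gm}}.
#'
#' @param gm Mesophyll conductance (mol CO2 m-2 s-1).
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param Gamma_star CO2 compensation point (umol mol-1).
#' @param JT Total PSII electron transport (umol m-2 s-1).
#' @param Rd Dark respiration (umol m-2 s-1).
#' @return Net assimilation (umol m-2 s-1), vectorised.
#' @export
anet_from_gm <- function(gm, Ci, Gamma_star, JT, Rd) {
  stopifnot(all(gm > 0), all(JT > 0))
  # 4x^2 - b x + c = 0 with x = A + Rd
  b <- JT + 4 * Rd + 4 * gm * (Ci + 2 * Gamma_star)
  cc <- JT * (Rd + gm * (Ci - Gamma_star))
  disc <- b^2 - 16 * cc
  if (any(disc < 0)) stop("no real solution: inputs violate the variable-J domain")
  x <- (b - sqrt(disc)) / 8
  x - Rd
}
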