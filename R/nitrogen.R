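# Partitioning of leaf nitrogen into photosynthetic pools and PNUE.
#
# The pool equations divide each capacity trait by the specific activity of
# the machinery that carries it; the per-area nitrogen content SLN cancels
# algebraically in every pool and enters only the fractional allocations.

#' Photosynthetic machinery constants
#'
#' \itemize{
#'   \item \code{Vcr} = 20.8 umol CO2 g-1 Rubisco s-1, Rubisco specific
#'     activity;
#'   \item \code{Jmc} = 155.6 umol electrons umol-1 Cyt f s-1, maximum
#'     electron transport per unit cytochrome f;
#'   \item \code{CB} = 2.15 mmol Chl g-1 N, chlorophyll binding of the
#'     combined PSI/PSII/LHCII complement;
#'   \item \code{chl_molar_mass} = 893.5 g mol-1, mean chlorophyll a/b
#'     molar mass used to convert areal contents to mmol m-2.
#' }
#'
#' @param Vcr,Jmc,CB,chl_molar_mass Override any constant.
#' @return Named list of class \code{photo_constants}.
#' @export
photo_constants <- function(Vcr = 20.8, Jmc = 155.6, CB = 2.15,
                            chl_molar_mass = 893.5) {
  stopifnot(Vcr > 0, Jmc > 0, CB > 0, chl_molar_mass > 0)
  structure(list(Vcr = Vcr, Jmc = Jmc, CB = CB,
                 chl_molar_mass = chl_molar_mass),
            class = "photo_constants")
}

#' Nitrogen in the carboxylation pool
#'
#' \deqn{N_C = V_{cmax} / (6.25\, V_{cr})}
#' (6.25 g protein per g N; SLN cancels between the per-mass and per-area
#' forms of the published equation).
#'
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param const A \code{\link{photo_constants}} object.
#' @return N_C (g N m-2), vectorised.
#' @export
n_carboxylation <- function(Vcmax, const = photo_constants()) {
  if (any(Vcmax < 0)) stop("Vcmax must be >= 0")
  Vcmax / (6.25 * const$Vcr)
}

#' Nitrogen in the bioenergetics pool
#'
#' \deqn{N_B = J_{max} / (8.06\, J_{mc})}
#'
#' @param Jmax Maximum electron-transport rate (umol m-2 s-1).
#' @param const A \code{\link{photo_constants}} object.
#' @return N_B (g N m-2), vectorised.
#' @export
n_bioenergetics <- function(Jmax, const = photo_constants()) {
  if (any(Jmax < 0)) stop("Jmax must be >= 0")
  Jmax / (8.06 * const$Jmc)
}

#' Nitrogen in the light-harvesting pool
#'
#' Converts an areal chlorophyll content in ug cm-2 to mmol m-2 via the
#' chlorophyll molar mass, then
#' \deqn{N_L = Chl_{mmol\,m^{-2}} / C_B.}
#'
#' @param chl_area Chlorophyll content (ug cm-2).
#' @param const A \code{\link{photo_constants}} object.
#' @return N_L (g N m-2), vectorised.
#' @export
n_light_harvesting <- function(chl_area, const = photo_constants()) {
  if (any(chl_area < 0)) stop("chl_area must be >= 0")
  chl_mmol_m2 <- chl_area * 10 / const$chl_molar_mass  # ug cm-2 -> mg m-2 -> mmol m-2
  chl_mmol_m2 / const$CB
}

#' Total photosynthetic nitrogen
#'
#' \deqn{N_{photo} = N_C + N_B + N_L}
#'
#' @param NC,NB,NL Pool sizes (g N m-2).
#' @return Sum (g N m-2), vectorised.
#' @export
n_photo_total <- function(NC, NB, NL) {
  if (any(c(NC, NB, NL) < 0)) stop("pools must be >= 0")
  NC + NB + NL
}

#' Photosynthetic nitrogen-use efficiency
#'
#' \deqn{PNUE = A_{max} / SLN}
#'
#' @param Amax Light-saturated assimilation (umol CO2 m-2 s-1).
#' @param SLN Leaf nitrogen per area (g N m-2).
#' @return PNUE (umol CO2 g-1 N s-1), vectorised.
#' @export
pnue <- function(Amax, SLN) {
  if (any(SLN <= 0)) stop("domain error: SLN must be > 0")
  Amax / SLN
}

#' Full nitrogen budget for one or more leaves
#'
#' Computes the three pools, their total, fractional allocations to SLN and
#' PNUE.  Fractions above 1 are possible for inconsistent inputs and are
#' flagged with a warning.
#'
#' @param Vcmax,Jmax Capacity traits (umol m-2 s-1).
#' @param chl_area Chlorophyll content (ug cm-2).
#' @param SLN Leaf nitrogen per area (g N m-2).
#' @param Amax Light-saturated assimilation (umol m-2 s-1).
#' @param const A \code{\link{photo_constants}} object.
#' @return Data frame with columns \code{SLN}, \code{NC}, \code{NB},
#'   \code{NL}, \code{Nphoto}, \code{PNUE} and the four fractions.
#' @export
nitrogen_budget <- function(Vcmax, Jmax, chl_area, SLN, Amax,
                            const = photo_constants()) {
  nc <- n_carboxylation(Vcmax, const)
  nb <- n_bioenergetics(Jmax, const)
  nl <- n_light_harvesting(chl_area, const)
  np <- n_photo_total(nc, nb, nl)
  out <- data.frame(SLN = SLN, NC = nc, NB = nb, NL = nl, Nphoto = np,
                    PNUE = pnue(Amax, SLN),
                    frac_NC = nc / SLN, frac_NB = nb / SLN,
                    frac_NL = nl / SLN, frac_Nphoto = np / SLN)
  if (any(out$frac_Nphoto > 1))
    warning("Nphoto exceeds SLN for ", sum(out$frac_Nphoto > 1), " leaf/leaves")
  out
}
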