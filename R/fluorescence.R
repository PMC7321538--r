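# PSII quenching analysis and the Valentini partition of total electron
# transport into carboxylation (Jc) and oxygenation (Jo) streams.

#' PSII quenching parameters from raw fluorescence yields
#'
#' Computes the four standard ratios from dark- and light-adapted yields:
#' \itemize{
#'   \item \code{FvpFmp = (Fm' - Fo') / Fm'} (maximum light-adapted PSII
#'     efficiency),
#'   \item \code{PhiPSII = (Fm' - Fs) / Fm'} (operating efficiency),
#'   \item \code{qP = (Fm' - Fs) / (Fm' - Fo')} (photochemical quenching),
#'   \item \code{NPQ = (Fm - Fm') / Fm'} (non-photochemical quenching).
#' }
#' All are ratios of yields, hence invariant to a common rescaling of the
#' raw signals.
#'
#' @param Fo,Fm Dark-adapted minimum and maximum yields, or a data frame
#'   with columns \code{Fo}, \code{Fm}, \code{Fop}, \code{Fmp}, \code{Fs}
#'   (and optionally \code{PPFD}) as the first argument.
#' @param Fop,Fmp,Fs Light-adapted minimum, maximum and steady-state yields.
#' @param PPFD Optional PPFD carried through to the output.
#' @return Data frame with columns \code{FvpFmp}, \code{PhiPSII}, \code{qP},
#'   \code{NPQ} (plus \code{PPFD} when supplied), one row per step.
#' @export
quenching_params <- function(Fo, Fm = NULL, Fop = NULL, Fmp = NULL, Fs = NULL,
                             PPFD = NULL) {
  if (is.data.frame(Fo)) {
    d <- Fo
    PPFD <- d$PPFD
    Fs <- d$Fs; Fmp <- d$Fmp; Fop <- d$Fop; Fm <- d$Fm; Fo <- d$Fo
  }
  if (any(c(Fo, Fm, Fop, Fmp, Fs) <= 0)) stop("fluorescence yields must be > 0")
  if (any(Fo > Fm)) stop("invalid step: Fo > Fm")
  if (any(Fop > Fs + 1e-9) || any(Fs > Fmp + 1e-9))
    stop("invalid step: need Fo' <= Fs <= Fm'")
  if (any(Fmp - Fop <= 0)) stop("undefined qP: Fm' equals Fo'")
  out <- data.frame(FvpFmp = (Fmp - Fop) / Fmp,
                    PhiPSII = (Fmp - Fs) / Fmp,
                    qP = (Fmp - Fs) / (Fmp - Fop),
                    NPQ = (Fm - Fmp) / Fmp)
  if (!is.null(PPFD)) out <- cbind(PPFD = PPFD, out)
  out
}

#' Total PSII electron-transport rate
#'
#' \deqn{J_T = PPFD \times \Phi_{PSII} \times \alpha_{leaf} \times \beta}
#' with leaf absorptance \code{alpha_leaf} defaulting to 0.84 and the
#' PSII fraction of absorbed photons \code{beta} to 0.5 -- the conventional
#' fluorometer assumptions, adequate for comparisons among optically similar
#' leaves.
#'
#' @param PhiPSII PSII operating efficiency, in [0, 1].
#' @param PPFD Incident photon flux (umol m-2 s-1).
#' @param alpha_leaf Leaf absorptance (dimensionless).
#' @param beta Fraction of absorbed photons reaching PSII.
#' @return Electron-transport rate (umol electrons m-2 s-1), vectorised.
#' @export
total_etr <- function(PhiPSII, PPFD, alpha_leaf = 0.84, beta = 0.5) {
  if (any(PhiPSII < 0 | PhiPSII > 1)) stop("PhiPSII must lie in [0, 1]")
  PPFD * PhiPSII * alpha_leaf * beta
}

#' Partition electron transport into carboxylation and oxygenation
#'
#' Valentini partition:
#' \deqn{J_O = \tfrac{2}{3}\,(J_T - 4 (A_{net} + R_d)), \qquad
#'       J_C = \tfrac{1}{3}\,(J_T + 8 (A_{net} + R_d))}
#' which satisfy \code{JC + JO = JT} identically.  When
#' \code{JT <= 4 (Anet + Rd)} the oxygenation stream goes negative; the
#' values are returned unclipped with a warning, preserving the information
#' for quality control.
#'
#' @param JT Total electron transport (umol m-2 s-1).
#' @param Anet Net assimilation (umol m-2 s-1).
#' @param Rd Dark respiration (umol m-2 s-1).
#' @return Data frame with columns \code{JC} and \code{JO}.
#' @export
partition_etr <- function(JT, Anet, Rd) {
  x <- Anet + Rd
  jo <- 2 / 3 * (JT - 4 * x)
  jc <- 1 / 3 * (JT + 8 * x)
  if (any(jo < 0))
    warning("negative JO for ", sum(jo < 0),
            " step(s): JT <= 4 (Anet + Rd)")
  data.frame(JC = jc, JO = jo)
}
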