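#' Reference treatment-level trait means
#'
#' Published treatment-level means and standard deviations (n = 7 leaves per
#' nitrogen regime) for morphology, CO2-diffusion, steady-state photosynthesis
#' and pigment traits in a shade-tolerant perennial grown under low (LN),
#' moderate (MN) and high (HN) nitrogen supply.  These values parameterise the
#' default synthetic leaf profiles and provide the worked-example inputs used
#' throughout the documentation.
#'
#' @return A data frame with columns \code{group}, \code{trait}, \code{unit},
#'   \code{treatment}, \code{mean}, \code{sd}, \code{n}.
#' @export
reference_traits <- function() {
  path <- system.file("extdata", "reference_trait_means.csv",
                      package = "photraits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one reference trait value
#'
#' @param trait Trait name as it appears in \code{\link{reference_traits}}.
#' @param treatment One of \code{"LN"}, \code{"MN"}, \code{"HN"}.
#' @param what Column to return, \code{"mean"} (default) or \code{"sd"}.
#' @param traits Optional pre-loaded table from \code{reference_traits()}.
#' @return A single numeric value.
#' @export
ref_value <- function(trait, treatment, what = "mean", traits = reference_traits()) {
  row <- traits[traits$trait == trait & traits$treatment == treatment, ]
  if (nrow(row) != 1L)
    stop("no unique reference value for trait '", trait, "', treatment '",
         treatment, "'")
  row[[what]]
}

#' Construct a synthetic leaf profile
#'
#' A leaf profile holds the treatment-level mean parameters from which
#' replicate synthetic leaves are drawn: light-response parameters
#' (\code{A_max}, \code{C0}, \code{alpha}), Farquhar A-Ci parameters
#' (\code{Vcmax}, \code{Jmax}, \code{Gamma_star}), the true mesophyll
#' conductance \code{gm_true}, leaf nitrogen (\code{SLN}), pigment contents,
#' chloroplast surface exposure \code{Sc}, the per-chloroplast-surface
#' conductance \code{Clip}, and Rubisco content/activity.
#'
#' Either \code{C0} or \code{Rd} must be given; the other is derived through
#' the light-model identity \code{Rd = |A_max - A_max * C0|} (i.e.
#' \code{C0 = 1 + Rd / A_max} for a leaf that respires in darkness).
#'
#' @param treatment Treatment label, e.g. \code{"MN"}.
#' @param A_max Light-saturated net assimilation (umol CO2 m-2 s-1).
#' @param alpha Apparent quantum yield (mol CO2 mol-1 photons).
#' @param C0 Dimensionless intercept index of the exponential light model.
#' @param Rd Dark respiration (umol CO2 m-2 s-1); used to derive \code{C0}
#'   when that is missing.
#' @param Vcmax,Jmax Farquhar maximum carboxylation and electron-transport
#'   rates (umol m-2 s-1).
#' @param gm_true Mesophyll conductance used by the diffusion forward model
#'   (mol CO2 m-2 s-1).
#' @param Gamma_star CO2 compensation point driving the A-Ci model
#'   (umol mol-1).
#' @param SLN Leaf nitrogen per area (g N m-2).
#' @param chl Chlorophyll content (ug cm-2).
#' @param pigments Named numeric vector with elements \code{N} (neoxanthin),
#'   \code{V}, \code{A}, \code{Z}, \code{L}, \code{beta_car} (ug cm-2).
#' @param Sc Chloroplast surface exposed to intercellular airspace per leaf
#'   area (m2 m-2).
#' @param Clip Conductance per unit exposed chloroplast surface
#'   (mol CO2 m-2 s-1).
#' @param rubisco_content Rubisco content (ug g-1).
#' @param rubisco_activity Rubisco activity (nmol min-1 g-1).
#' @param noise_sd Named list of within-curve noise levels: \code{anet}
#'   (additive sd on A_net, umol m-2 s-1), \code{gs} (additive sd on g_s),
#'   \code{fluor} (relative sd on the quenching levels of the fluorescence
#'   generator).
#' @param trait_sd Named numeric vector of between-replicate standard
#'   deviations for any of the scalar traits above (names as in the
#'   constructor arguments, pigments as \code{pigment_V} etc.).  Traits
#'   without an entry are held fixed across replicates.
#' @return An object of class \code{leaf_profile}.
#' @export
leaf_profile <- function(treatment, A_max, alpha, C0 = NULL, Rd = NULL,
                         Vcmax, Jmax, gm_true, Gamma_star, SLN, chl,
                         pigments = c(N = 0.5, V = 0.5, A = 0.1, Z = 0.1,
                                      L = 2, beta_car = 2),
                         Sc, Clip, rubisco_content, rubisco_activity,
                         noise_sd = list(anet = 0.1, gs = 0.002, fluor = 0.02),
                         trait_sd = NULL) {
  if (!is.numeric(A_max) || A_max <= 0) stop("invalid profile: A_max must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) stop("invalid profile: alpha must be > 0")
  if (is.null(C0)) {
    if (is.null(Rd)) stop("one of C0 or Rd is required")
    C0 <- 1 + Rd / A_max
  }
  if (C0 <= 0) stop("invalid profile: C0 must be > 0")
  Rd <- abs(A_max - A_max * C0)
  stopifnot(Vcmax > 0, Jmax > 0, gm_true > 0, Gamma_star > 0, SLN > 0,
            chl > 0, Sc > 0, Clip > 0, rubisco_content > 0,
            rubisco_activity > 0)
  stopifnot(all(c("N", "V", "A", "Z", "L", "beta_car") %in% names(pigments)),
            all(pigments >= 0))
  ns <- utils::modifyList(list(anet = 0.1, gs = 0.002, fluor = 0.02),
                          as.list(noise_sd))
  if (any(unlist(ns) < 0)) stop("noise_sd entries must be >= 0")
  if (!is.null(trait_sd) && any(trait_sd < 0)) stop("trait_sd must be >= 0")
  structure(list(treatment = treatment, A_max = A_max, C0 = C0, alpha = alpha,
                 Rd = Rd, Vcmax = Vcmax, Jmax = Jmax, gm_true = gm_true,
                 Gamma_star = Gamma_star, SLN = SLN, chl = chl,
                 pigments = pigments, Sc = Sc, Clip = Clip,
                 rubisco_content = rubisco_content,
                 rubisco_activity = rubisco_activity,
                 noise_sd = ns, trait_sd = trait_sd),
            class = "leaf_profile")
}

#' @export
print.leaf_profile <- function(x, ...) {
  cat("Leaf profile [", x$treatment, "]\n", sep = "")
  cat(sprintf("  light model : A_max=%.3f  C0=%.3f  alpha=%.3f  Rd=%.3f\n",
              x$A_max, x$C0, x$alpha, x$Rd))
  cat(sprintf("  A-Ci model  : Vcmax=%.2f  Jmax=%.2f  Gamma*=%.2f  gm=%.3f\n",
              x$Vcmax, x$Jmax, x$Gamma_star, x$gm_true))
  cat(sprintf("  leaf        : SLN=%.3f g m-2  chl=%.2f ug cm-2  Sc=%.2f\n",
              x$SLN, x$chl, x$Sc))
  invisible(x)
}

#' Default leaf profiles for the three nitrogen regimes
#'
#' Builds LN/MN/HN \code{\link{leaf_profile}} objects from the published
#' treatment means in \code{\link{reference_traits}}.  Between-replicate
#' standard deviations are taken from the same table; the apparent quantum
#' yield, which is not tabulated, defaults to 0.05 mol mol-1 (a typical C3
#' value).
#'
#' @param alpha Apparent quantum yield used for every treatment.
#' @param anet_sd Within-curve additive noise on A_net (umol m-2 s-1).
#' @param fluor_sd Relative noise on the fluorescence quenching levels.
#' @return A named list of three \code{leaf_profile} objects.
#' @export
default_profiles <- function(alpha = 0.05, anet_sd = 0.1, fluor_sd = 0.02) {
  tr <- reference_traits()
  v <- function(trait, treatment, what = "mean")
    ref_value(trait, treatment, what, traits = tr)
  build <- function(lab) {
    leaf_profile(
      treatment = lab,
      A_max = v("Amax", lab), alpha = alpha, Rd = v("Rd", lab),
      Vcmax = v("Vcmax", lab), Jmax = v("Jmax", lab),
      gm_true = v("gm", lab), Gamma_star = v("Gamma_star", lab),
      SLN = v("SLN", lab), chl = v("chl", lab),
      pigments = c(N = v("neoxanthin", lab), V = v("violaxanthin", lab),
                   A = v("antheraxanthin", lab), Z = v("zeaxanthin", lab),
                   L = v("lutein", lab), beta_car = v("beta_carotene", lab)),
      Sc = v("Sc", lab), Clip = v("Clip", lab),
      rubisco_content = v("rubisco_content", lab),
      rubisco_activity = v("rubisco_activity", lab),
      noise_sd = list(anet = anet_sd, gs = 0.002, fluor = fluor_sd),
      trait_sd = c(A_max = v("Amax", lab, "sd"),
                   Vcmax = v("Vcmax", lab, "sd"),
                   Jmax = v("Jmax", lab, "sd"),
                   gm_true = v("gm", lab, "sd"),
                   Gamma_star = v("Gamma_star", lab, "sd"),
                   SLN = v("SLN", lab, "sd"),
                   chl = v("chl", lab, "sd"),
                   Sc = v("Sc", lab, "sd"),
                   Clip = v("Clip", lab, "sd"),
                   rubisco_content = v("rubisco_content", lab, "sd"),
                   rubisco_activity = v("rubisco_activity", lab, "sd"),
                   pigment_N = v("neoxanthin", lab, "sd"),
                   pigment_V = v("violaxanthin", lab, "sd"),
                   pigment_A = v("antheraxanthin", lab, "sd"),
                   pigment_Z = v("zeaxanthin", lab, "sd"),
                   pigment_L = v("lutein", lab, "sd"),
                   pigment_beta_car = v("beta_carotene", lab, "sd")))
  }
  labs <- c("LN", "MN", "HN")
  stats::setNames(lapply(labs, build), labs)
}
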