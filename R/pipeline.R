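# End-to-end derivation: raw synthetic (or imported) tables -> per-leaf
# fitted parameters, quenching, diffusion traits, nitrogen budget and
# pigment indices -> treatment-level report.

#' Configuration for the trait-derivation pipeline
#'
#' Collects every tunable constant in one place.  Units: \code{O} is the
#' oxygen mole fraction in umol mol-1 (used for S and the Ci/O axis);
#' \code{O_mmol}, \code{Kc}, \code{Ko} are the Farquhar kinetic settings
#' (mmol mol-1 / umol mol-1 / mmol mol-1).
#'
#' @param alpha_leaf Leaf absorptance (default 0.84).
#' @param beta PSII fraction of absorbed photons (default 0.5).
#' @param O Oxygen mole fraction, umol mol-1 (default 210000).
#' @param Vcr,Jmc,CB,chl_molar_mass Nitrogen-partitioning constants, see
#'   \code{\link{photo_constants}}.
#' @param linear_region_max_ppfd AQY region bound (umol m-2 s-1).
#' @param linear_region_max_ci CE region bound (umol mol-1).
#' @param sstar_region_max Initial-region bound on the Ci/O axis.
#' @param sstar_through_origin Force the S* regression through the origin.
#' @param reducer Which light step feeds the per-leaf variable-J estimate:
#'   \code{"max_ppfd"} (default, the highest-PPFD steady state) or
#'   \code{"mean"} (average over admissible steps).
#' @param prefer_tabulated_pool Passed to \code{\link{vaz_pool}}.
#' @param Kc,Ko,O_mmol Farquhar kinetic constants at 25 degrees C.
#' @return Named list of class \code{trait_config}.
#' @export
trait_config <- function(alpha_leaf = 0.84, beta = 0.5, O = 210000,
                         Vcr = 20.8, Jmc = 155.6, CB = 2.15,
                         chl_molar_mass = 893.5,
                         linear_region_max_ppfd = 100,
                         linear_region_max_ci = 200,
                         sstar_region_max = 0.5,
                         sstar_through_origin = FALSE,
                         reducer = c("max_ppfd", "mean"),
                         prefer_tabulated_pool = TRUE,
                         Kc = 404.9, Ko = 278.4, O_mmol = 210) {
  structure(list(alpha_leaf = alpha_leaf, beta = beta, O = O,
                 const = photo_constants(Vcr, Jmc, CB, chl_molar_mass),
                 linear_region_max_ppfd = linear_region_max_ppfd,
                 linear_region_max_ci = linear_region_max_ci,
                 sstar_region_max = sstar_region_max,
                 sstar_through_origin = sstar_through_origin,
                 reducer = match.arg(reducer),
                 prefer_tabulated_pool = prefer_tabulated_pool,
                 Kc = Kc, Ko = Ko, O_mmol = O_mmol),
            class = "trait_config")
}

#' Derive all leaf traits from a dataset
#'
#' Runs the full pipeline for every leaf: light-response and A-Ci fits,
#' per-step quenching and electron-transport partition (with the leaf's
#' fitted Rd held constant across light steps), variable-J mesophyll
#' conductance at the reducer step, Rubisco specificity S (from the curve's
#' compensation point) and apparent specificity S* (initial slope of Jc/Jo
#' vs Ci/O across the illuminated light steps), chloroplastic CO2, liquid
#' and internal conductances, the nitrogen budget and pigment indices.
#' Dark or light-limited steps with \code{JT <= 4 (Anet + Rd)} are excluded
#' from the partition-based regressions and flagged.
#'
#' @param dataset A \code{synthetic_leaf_dataset} or a list with
#'   \code{gas_exchange}, \code{fluorescence}, \code{leaf_scalars} data
#'   frames in the CSV dialect of \code{\link{write_dataset}}.
#' @param config A \code{\link{trait_config}}.
#' @return Object of class \code{leaf_traits}: list of data frames
#'   \code{fits}, \code{quenching}, \code{diffusion}, \code{nitrogen},
#'   \code{pigments}.
#' @export
derive_leaf_traits <- function(dataset, config = trait_config()) {
  gx <- dataset$gas_exchange
  fl <- dataset$fluorescence
  sc <- dataset$leaf_scalars
  stopifnot(!is.null(gx), !is.null(fl), !is.null(sc))
  leaves <- unique(sc$leaf_id)

  fits <- list(); quench <- list(); diff <- list(); nitro <- list()
  for (id in leaves) {
    srow <- sc[sc$leaf_id == id, ]
    treat <- srow$treatment[1]
    light <- gx[gx$leaf_id == id & gx$series_type == "light", ]
    co2 <- gx[gx$leaf_id == id & gx$series_type == "co2", ]
    lcurve <- as_gas_exchange_curve(light, id, treat, "light")
    acurve <- as_gas_exchange_curve(co2, id, treat, "co2")

    lf <- fit_light_response(lcurve)
    aqy <- estimate_aqy(lcurve, config$linear_region_max_ppfd)
    cf <- fit_co2_response(acurve, config$linear_region_max_ci,
                           Kc = config$Kc, Ko = config$Ko, O = config$O_mmol)

    # quenching + ETR partition over the light series, Rd constant per leaf
    fsteps <- fl[fl$leaf_id == id, ]
    qp <- quenching_params(fsteps)
    qp$JT <- total_etr(qp$PhiPSII, qp$PPFD, config$alpha_leaf, config$beta)
    m <- match(qp$PPFD, light$PPFD)
    qp$Anet <- light$Anet[m]
    qp$Ci <- light$Ci[m]
    admissible <- qp$JT > 4 * (qp$Anet + lf$Rd)
    part <- suppressWarnings(partition_etr(qp$JT, qp$Anet, lf$Rd))
    qp$JC <- ifelse(admissible, part$JC, NA_real_)
    qp$JO <- ifelse(admissible, part$JO, NA_real_)
    qp$admissible <- admissible
    quench[[id]] <- cbind(leaf_id = id, treatment = treat, qp)

    # variable-J at the reducer step(s)
    use <- which(admissible)
    if (length(use) == 0) stop("no admissible light step for leaf ", id)
    sel <- if (config$reducer == "max_ppfd") use[which.max(qp$PPFD[use])] else use
    vj <- variable_j_gm(qp$Anet[sel], qp$Ci[sel], cf$Gamma_star,
                        qp$JT[sel], lf$Rd)
    gm <- mean(vj$gm)
    cc_vj <- mean(vj$Cc_variableJ)
    ci_ref <- if (config$reducer == "max_ppfd") qp$Ci[sel] else mean(qp$Ci[sel])

    S <- specificity_S(cf$Gamma_star, config$O)
    # S*: Jc/Jo against Ci/O across the CO2 series.  Under the variable-J
    # relation Jc/Jo = Cc / (2 Gamma), with Cc = Ci - Anet/gm at constant
    # mesophyll conductance; the initial slope of that regression is the
    # apparent specificity.
    sstar <- NA_real_; cc <- NA_real_; gi <- NA_real_
    if (is.finite(gm) && gm > 0) {
      cc_co2 <- co2$Ci - co2$Anet / gm
      jcjo <- cc_co2 / (2 * cf$Gamma_star)
      sstar <- apparent_specificity_sstar(
        co2$Ci / config$O, jcjo,
        initial_region_max = config$sstar_region_max,
        through_origin = config$sstar_through_origin)
      cc <- cc_from_specificity(ci_ref, sstar, S)
      if (ci_ref > cc) gi <- internal_conductance(lf$A_max, ci_ref, cc)
    }
    glip <- if (!is.null(srow$Clip)) liquid_phase_conductance(srow$Clip, srow$Sc)
            else NA_real_

    fits[[id]] <- data.frame(
      leaf_id = id, treatment = treat,
      Amax = lf$A_max, C0 = lf$C0, alpha = lf$alpha, Rd = lf$Rd,
      AQY = aqy, r2_light = lf$r2,
      CE = cf$CE, Gamma_star = cf$Gamma_star, Vcmax = cf$Vcmax,
      Jmax = cf$Jmax, Jmax_over_Vcmax = cf$Jmax_over_Vcmax,
      Gamma_star_photo = cf$Gamma_star_photo, Amax_co2 = cf$Amax_co2,
      r2_co2 = cf$r2)
    diff[[id]] <- data.frame(
      leaf_id = id, treatment = treat,
      gm = gm, Cc_variableJ = cc_vj, S = S, S_star = sstar, Cc = cc,
      Ci_ref = ci_ref, glip = glip, gi = gi, Sc = srow$Sc, Clip = srow$Clip,
      gm_per_rubisco = gm_per_rubisco(gm, srow$rubisco_content))
    nitro[[id]] <- cbind(
      leaf_id = id, treatment = treat,
      nitrogen_budget(cf$Vcmax, cf$Jmax, srow$chl, srow$SLN, lf$A_max,
                      config$const))
  }
  structure(list(fits = do.call(rbind, fits),
                 quenching = do.call(rbind, quench),
                 diffusion = do.call(rbind, diff),
                 nitrogen = do.call(rbind, nitro),
                 pigments = pigment_indices(
                   sc, prefer_tabulated = config$prefer_tabulated_pool),
                 config = config),
            class = "leaf_traits")
}

#' @export
print.leaf_traits <- function(x, ...) {
  cat("Derived leaf traits for", nrow(x$fits), "leaves\n")
  cat("  tables: fits, quenching, diffusion, nitrogen, pigments\n")
  invisible(x)
}

#' Treatment-level report for derived traits
#'
#' For each trait column of the chosen tables, per-treatment mean, SD, n,
#' compact significance letters and the percent contrast of each treatment
#' against the reference.
#'
#' @param traits A \code{leaf_traits} object from
#'   \code{\link{derive_leaf_traits}}.
#' @param reference Reference treatment label for percent contrasts
#'   (default \code{"MN"}).
#' @param alpha Significance level for the letters.
#' @return Data frame with one row per trait x treatment: \code{trait},
#'   \code{treatment}, \code{mean}, \code{sd}, \code{n}, \code{letter},
#'   \code{pct_vs_reference}.
#' @export
treatment_report <- function(traits, reference = "MN", alpha = 0.05) {
  stopifnot(inherits(traits, "leaf_traits"))
  tabs <- list(traits$fits, traits$diffusion, traits$nitrogen,
               traits$pigments)
  out <- list()
  for (tab in tabs) {
    num <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                   c("leaf_id"))
    for (tr in num) {
      vals <- tab[[tr]]
      ok <- is.finite(vals)
      if (sum(ok) < 4 || length(unique(tab$treatment[ok])) < 2) next
      s <- summarize_treatments(vals[ok], tab$treatment[ok])
      lets <- tryCatch(letter_groups(vals[ok], tab$treatment[ok], alpha),
                       error = function(e) stats::setNames(
                         rep(NA_character_, nrow(s)), s$treatment))
      refm <- s$mean[s$treatment == reference]
      s$letter <- unname(lets[s$treatment])
      s$pct_vs_reference <- if (length(refm) == 1 && refm != 0)
        percent_vs_reference(s$mean, refm) else NA_real_
      s <- cbind(trait = tr, s)
      out[[length(out) + 1L]] <- s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
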