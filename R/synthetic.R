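# Synthetic-leaf generator: gas exchange, fluorescence, pigments, scalars.
# All randomness is driven by one root seed; each leaf gets its own child
# stream derived by a Weyl-increment hash of (seed, leaf index), so datasets
# are reproducible and independent of leaf insertion order.

child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index) * 2654435769) %% 2147483647)
}

# Gaussian draw truncated at (just above) zero, by resampling.
rtrunc_pos <- function(n, mean, sd, floor = 1e-9) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x <= floor
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, floor)
}

new_gas_exchange_curve <- function(df, leaf_id, treatment, series_type) {
  stopifnot(series_type %in% c("light", "co2"))
  structure(df, leaf_id = leaf_id, treatment = treatment,
            series_type = series_type,
            class = c("gas_exchange_curve", "data.frame"))
}

#' Coerce a data frame of gas-exchange steps to a curve object
#'
#' @param df Data frame with at least the driver column (\code{PPFD} for
#'   light series, \code{Ci} for CO2 series) and \code{Anet}; optionally
#'   \code{CO2_ref}, \code{gs}, \code{Tleaf}, \code{step_index}.
#' @param leaf_id Leaf identifier.
#' @param treatment Treatment label.
#' @param series_type \code{"light"} or \code{"co2"}.
#' @return A \code{gas_exchange_curve} object (a classed data frame).
#' @export
as_gas_exchange_curve <- function(df, leaf_id = "leaf1", treatment = "",
                                  series_type = c("light", "co2")) {
  series_type <- match.arg(series_type)
  driver <- if (series_type == "light") "PPFD" else "Ci"
  if (!all(c(driver, "Anet") %in% names(df)))
    stop("curve needs columns '", driver, "' and 'Anet'")
  if (any(df[[driver]] < 0)) stop("driver values must be non-negative")
  if (is.null(df$step_index)) df$step_index <- seq_len(nrow(df))
  new_gas_exchange_curve(as.data.frame(df), leaf_id, treatment, series_type)
}

#' Generate a synthetic light-response curve
#'
#' Evaluates the exponential light model of the profile at each PPFD level
#' and adds Gaussian noise of sd \code{noise_sd$anet}.  Stomatal conductance
#' follows a simple empirical coupling to A_net and the intercellular CO2 is
#' back-computed from Fick's law at an ambient CO2 of 400 umol mol-1, so the
#' light series carries realistic co-varying Ci values for the variable-J
#' stage.
#'
#' @param profile A \code{\link{leaf_profile}}.
#' @param ppfd_levels PPFD steps (umol m-2 s-1); default mirrors an 11-step
#'   Li-6400 autoprogram from 800 down to 0.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param leaf_id Leaf identifier stored on the curve.
#' @return A \code{gas_exchange_curve} with columns \code{step_index},
#'   \code{PPFD}, \code{CO2_ref}, \code{Anet}, \code{Ci}, \code{gs},
#'   \code{Tleaf}.
#' @export
generate_light_curve <- function(profile,
                                 ppfd_levels = c(800, 500, 400, 300, 200,
                                                 100, 80, 60, 40, 20, 0),
                                 seed = 1L, leaf_id = "leaf1") {
  stopifnot(inherits(profile, "leaf_profile"))
  if (length(ppfd_levels) == 0) stop("ppfd_levels must be non-empty")
  if (any(ppfd_levels < 0)) stop("ppfd_levels must be non-negative")
  set.seed(seed)
  mu <- light_response(ppfd_levels, profile$A_max, profile$C0, profile$alpha)
  a <- mu + stats::rnorm(length(mu), 0, profile$noise_sd$anet)
  gs <- pmax(0.005, 0.02 + 0.009 * pmax(a, 0) +
               stats::rnorm(length(a), 0, profile$noise_sd$gs))
  ca <- 400
  ci <- ca - 1.6 * a / gs
  new_gas_exchange_curve(
    data.frame(step_index = seq_along(ppfd_levels), PPFD = ppfd_levels,
               CO2_ref = ca, Anet = a, Ci = ci, gs = gs, Tleaf = 25),
    leaf_id, profile$treatment, "light")
}

#' Generate a synthetic A-Ci curve
#'
#' Evaluates the Farquhar forward model (\code{\link{farquhar_anet}}) of the
#' profile at \code{Ci = ci_ratio * CO2_ref} for each reference CO2 step and
#' adds Gaussian noise of sd \code{noise_sd$anet}.  The default step sequence
#' mirrors the measurement protocol (400 down to 50, back to 400, then up to
#' 1500 umol mol-1); the repeated 400 step is kept and averaged by the
#' fitter.
#'
#' @param profile A \code{\link{leaf_profile}}.
#' @param co2_levels Reference CO2 steps (umol mol-1).
#' @param seed Integer seed.
#' @param leaf_id Leaf identifier.
#' @param ci_ratio Constant Ci/Ca ratio used to map reference CO2 to
#'   intercellular CO2 (default 0.72).
#' @return A \code{gas_exchange_curve} of series type \code{"co2"}.
#' @export
generate_aci_curve <- function(profile,
                               co2_levels = c(400, 300, 200, 150, 100, 50,
                                              400, 600, 800, 1000, 1200, 1500),
                               seed = 1L, leaf_id = "leaf1", ci_ratio = 0.72) {
  stopifnot(inherits(profile, "leaf_profile"))
  if (length(co2_levels) == 0) stop("co2_levels must be non-empty")
  ci <- ci_ratio * co2_levels
  if (all(ci <= profile$Gamma_star))
    stop("degenerate curve: all Ci at or below the compensation point")
  set.seed(seed)
  mu <- farquhar_anet(ci, profile$Vcmax, profile$Jmax, profile$Rd,
                      profile$Gamma_star)
  a <- mu + stats::rnorm(length(mu), 0, profile$noise_sd$anet)
  gs <- pmax(0.005, 0.03 + stats::rnorm(length(a), 0, profile$noise_sd$gs))
  new_gas_exchange_curve(
    data.frame(step_index = seq_along(co2_levels), PPFD = 800,
               CO2_ref = co2_levels, Anet = a, Ci = ci, gs = gs, Tleaf = 25),
    leaf_id, profile$treatment, "co2")
}

#' Generate a synthetic fluorescence series over a light curve
#'
#' Emulates the light-step fluorescence protocol: dark-adapted \code{Fo} and
#' \code{Fm} are fixed for the leaf (Fv/Fm = 0.8) and at each PPFD step the
#' light-adapted yields are derived from saturating NPQ and declining qP
#' response curves, \code{NPQ = NPQmax * P/(P + k_npq)} and
#' \code{qP = 1/(1 + P/k_qp)}, via \code{Fm' = Fm/(1 + NPQ)} and
#' \code{Fs = Fm' - qP (Fm' - Fo')}.  \code{Fo'} rises mildly with light so
#' the full ordering \code{Fo <= Fo' <= Fs <= Fm' <= Fm} holds at every
#' step.  Noise of relative sd \code{noise_sd$fluor} is applied to the NPQ
#' and qP levels (truncated to preserve the ordering) and vanishes at the
#' dark step, where \code{Fm' = Fm} and \code{Fo' = Fo} exactly.
#'
#' The qP level is calibrated so that at the highest illuminated step the
#' implied electron transport \code{JT = PPFD * PhiPSII * alpha_leaf * beta}
#' is consistent with the profile's mesophyll conductance: the noiseless
#' light model gives A_net and Ci at that step, \code{gm_true} gives the
#' chloroplastic CO2, and the variable-J relation is inverted for the JT
#' that a fluorometer would have to report.  A noiseless synthetic leaf
#' therefore returns (approximately) its own \code{gm_true} when pushed
#' through the variable-J analysis.
#'
#' @param profile A \code{\link{leaf_profile}}.
#' @param ppfd_levels PPFD steps (umol m-2 s-1).
#' @param seed Integer seed.
#' @param leaf_id Leaf identifier.
#' @param Fo,FvFm Dark-adapted minimal yield (arbitrary units) and maximum
#'   PSII efficiency setting \code{Fm = Fo/(1 - FvFm)}.
#' @param npq_max,k_npq Saturating NPQ amplitude and half-saturation PPFD.
#' @param k_qp PPFD scale of the qP decline.
#' @param alpha_leaf,beta Absorptance and PSII fraction assumed in the JT
#'   calibration (conventional fluorometer values).
#' @return Data frame with columns \code{leaf_id}, \code{step_index},
#'   \code{PPFD}, \code{Fo}, \code{Fm}, \code{Fop}, \code{Fmp}, \code{Fs}.
#' @export
generate_fluorescence_series <- function(profile,
                                         ppfd_levels = c(800, 500, 400, 300,
                                                         200, 100, 80, 60,
                                                         40, 20, 0),
                                         seed = 1L, leaf_id = "leaf1",
                                         Fo = 500, FvFm = 0.8,
                                         npq_max = 2.5, k_npq = 400,
                                         k_qp = 500, alpha_leaf = 0.84,
                                         beta = 0.5) {
  stopifnot(inherits(profile, "leaf_profile"))
  if (length(ppfd_levels) == 0) stop("ppfd_levels must be non-empty")
  set.seed(seed)
  Fm <- Fo / (1 - FvFm)
  p <- ppfd_levels
  rel <- profile$noise_sd$fluor
  # noise on the quenching levels, zero in darkness so dark limits are exact
  e_npq <- stats::rnorm(length(p), 0, rel) * (p > 0)
  e_qp <- stats::rnorm(length(p), 0, rel) * (p > 0)
  npq0 <- npq_max * p / (p + k_npq)
  qp0 <- 1 / (1 + p / k_qp)

  # calibrate the qP level against gm_true at the brightest step
  pmax_lit <- max(p)
  if (pmax_lit > 0) {
    a_top <- light_response(pmax_lit, profile$A_max, profile$C0, profile$alpha)
    gs_top <- 0.02 + 0.009 * max(a_top, 0)
    ci_top <- 400 - 1.6 * a_top / gs_top
    cc_top <- ci_top - a_top / profile$gm_true
    x_top <- a_top + profile$Rd
    gamma_op <- operational_gamma(profile)
    if (cc_top > gamma_op && x_top > 0) {
      jt_target <- 4 * x_top * (cc_top + 2 * gamma_op) /
        (cc_top - gamma_op)
      phi_target <- jt_target / (pmax_lit * alpha_leaf * beta)
      i_top <- which(p == pmax_lit)[1]
      fvpfmp_top <- local({
        fmp_t <- Fm / (1 + npq0[i_top])
        fop_t <- Fo * (1 + 0.05 * pmax_lit / (pmax_lit + k_npq))
        (fmp_t - fop_t) / fmp_t
      })
      phi0 <- qp0[i_top] * fvpfmp_top
      s <- phi_target / phi0
      if (is.finite(s) && s > 0) qp0 <- pmin(qp0 * s, 1)
    }
  }

  npq <- npq0 * pmax(1 + e_npq, 0)
  qp <- pmin(pmax(qp0 * (1 + e_qp), 1e-6), 1)
  fmp <- Fm / (1 + npq)
  fop <- Fo * (1 + 0.05 * p / (p + k_npq))   # mild light-driven rise of Fo'
  fop <- pmin(fop, fmp - 1e-9)
  fs <- fmp - qp * (fmp - fop)
  data.frame(leaf_id = leaf_id, step_index = seq_along(p), PPFD = p,
             Fo = Fo, Fm = Fm, Fop = fop, Fmp = fmp, Fs = fs)
}

#' Generate a full synthetic treatment dataset
#'
#' Draws \code{n_reps} replicate leaves per profile (leaf-level trait values
#' Gaussian around the profile means with the profile's \code{trait_sd},
#' truncated at zero), and for each leaf generates a light-response curve, an
#' A-Ci curve and a fluorescence series, plus a row of leaf scalars (SLN,
#' Sc, Clip, pigments, Rubisco).  Each leaf uses its own child seed derived
#' from the root seed, so regenerating with the same seed reproduces the
#' dataset exactly.
#'
#' @param profiles List of \code{\link{leaf_profile}} objects (one per
#'   treatment).
#' @param n_reps Replicates per profile (>= 2).
#' @param seed Root integer seed.
#' @param light_levels,co2_levels Step sequences passed to the curve
#'   generators.
#' @return An object of class \code{synthetic_leaf_dataset}: a list with
#'   data frames \code{gas_exchange}, \code{fluorescence},
#'   \code{leaf_scalars}, the per-leaf \code{leaf_profiles}, and the
#'   generation \code{seed}.
#' @export
generate_treatment_dataset <- function(profiles, n_reps = 7, seed = 1L,
                                       light_levels = c(800, 500, 400, 300,
                                                        200, 100, 80, 60,
                                                        40, 20, 0),
                                       co2_levels = c(400, 300, 200, 150,
                                                      100, 50, 400, 600,
                                                      800, 1000, 1200, 1500)) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  if (inherits(profiles, "leaf_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "leaf_profile")))
  if (n_reps < 2) stop("n_reps must be >= 2")

  gas <- list(); flu <- list(); sca <- list(); leaf_profiles <- list()
  i <- 0L
  for (prof in profiles) {
    for (r in seq_len(n_reps)) {
      i <- i + 1L
      cs <- child_seed(seed, i)
      leaf_id <- sprintf("%s_%02d", prof$treatment, r)
      set.seed(cs)
      lp <- draw_leaf(prof)
      lc <- generate_light_curve(lp, light_levels, seed = child_seed(cs, 1),
                                 leaf_id = leaf_id)
      ac <- generate_aci_curve(lp, co2_levels, seed = child_seed(cs, 2),
                               leaf_id = leaf_id)
      fl <- generate_fluorescence_series(lp, light_levels,
                                         seed = child_seed(cs, 3),
                                         leaf_id = leaf_id)
      gx <- rbind(cbind(series_type = "light", as.data.frame(lc)),
                  cbind(series_type = "co2", as.data.frame(ac)))
      gx <- cbind(leaf_id = leaf_id, treatment = prof$treatment, gx)
      gas[[i]] <- gx
      flu[[i]] <- fl
      sca[[i]] <- data.frame(
        leaf_id = leaf_id, treatment = prof$treatment, SLN = lp$SLN,
        Sc = lp$Sc, Clip = lp$Clip, chl = lp$chl,
        neoxanthin = lp$pigments[["N"]], violaxanthin = lp$pigments[["V"]],
        antheraxanthin = lp$pigments[["A"]], zeaxanthin = lp$pigments[["Z"]],
        lutein = lp$pigments[["L"]], beta_carotene = lp$pigments[["beta_car"]],
        rubisco_content = lp$rubisco_content,
        rubisco_activity = lp$rubisco_activity,
        gm_true = lp$gm_true, Amax_true = lp$A_max, Rd_true = lp$Rd)
      leaf_profiles[[leaf_id]] <- lp
    }
  }
  structure(list(gas_exchange = do.call(rbind, gas),
                 fluorescence = do.call(rbind, flu),
                 leaf_scalars = do.call(rbind, sca),
                 leaf_profiles = leaf_profiles,
                 seed = seed, n_reps = n_reps),
            class = "synthetic_leaf_dataset")
}

# Operational CO2 compensation point of the noiseless forward A-Ci curve:
# the Ci-intercept of the OLS line over the initial linear region, i.e. the
# quantity the fitting stage will report as Gamma_star.  With Rd > 0 this
# sits above the mechanistic Gamma* of the Farquhar model.
operational_gamma <- function(profile,
                              co2_levels = c(400, 300, 200, 150, 100, 50,
                                             400, 600, 800, 1000, 1200, 1500),
                              ci_ratio = 0.72, linear_region_max_ci = 200) {
  ci <- sort(unique(ci_ratio * co2_levels))
  ci <- ci[ci <= linear_region_max_ci]
  if (length(ci) < 3) return(profile$Gamma_star)
  a <- farquhar_anet(ci, profile$Vcmax, profile$Jmax, profile$Rd,
                     profile$Gamma_star)
  cf <- stats::coef(stats::lm(a ~ ci))
  g <- -unname(cf[1]) / unname(cf[2])
  if (!is.finite(g) || g <= 0) profile$Gamma_star else g
}

# Draw one replicate leaf around the profile means (truncated Gaussian).
draw_leaf <- function(prof) {
  sd_of <- function(nm) {
    s <- prof$trait_sd
    if (is.null(s) || is.na(s[nm]) || !nm %in% names(s)) 0 else unname(s[nm])
  }
  d <- function(mean, nm) rtrunc_pos(1, mean, sd_of(nm))
  A_max <- d(prof$A_max, "A_max")
  pig <- prof$pigments
  for (k in c("N", "V", "A", "Z", "L", "beta_car"))
    pig[k] <- rtrunc_pos(1, prof$pigments[[k]], sd_of(paste0("pigment_", k)),
                         floor = 0)
  leaf_profile(
    treatment = prof$treatment, A_max = A_max, alpha = prof$alpha,
    C0 = prof$C0,
    Vcmax = d(prof$Vcmax, "Vcmax"), Jmax = d(prof$Jmax, "Jmax"),
    gm_true = d(prof$gm_true, "gm_true"),
    Gamma_star = d(prof$Gamma_star, "Gamma_star"),
    SLN = d(prof$SLN, "SLN"), chl = d(prof$chl, "chl"), pigments = pig,
    Sc = d(prof$Sc, "Sc"), Clip = d(prof$Clip, "Clip"),
    rubisco_content = d(prof$rubisco_content, "rubisco_content"),
    rubisco_activity = d(prof$rubisco_activity, "rubisco_activity"),
    noise_sd = prof$noise_sd, trait_sd = prof$trait_sd)
}

#' @export
print.synthetic_leaf_dataset <- function(x, ...) {
  cat("Synthetic leaf dataset: ", length(x$leaf_profiles), " leaves (",
      x$n_reps, " reps x ", length(x$leaf_profiles) / x$n_reps,
      " treatments), seed ", x$seed, "\n", sep = "")
  cat("  gas_exchange : ", nrow(x$gas_exchange), " steps\n", sep = "")
  cat("  fluorescence : ", nrow(x$fluorescence), " steps\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes \code{gas_exchange.csv}, \code{fluorescence.csv} and
#' \code{leaf_scalars.csv} (UTF-8, '.' decimal separator, header row) to
#' \code{outdir}.
#'
#' @param dataset A \code{synthetic_leaf_dataset}.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_leaf_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("gas_exchange.csv", "fluorescence.csv",
                               "leaf_scalars.csv"))
  utils::write.csv(dataset$gas_exchange, paths[1], row.names = FALSE)
  utils::write.csv(dataset$fluorescence, paths[2], row.names = FALSE)
  utils::write.csv(dataset$leaf_scalars, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a dataset written by \code{write_dataset}
#'
#' @param dir Directory containing the three CSV files.
#' @return A list with \code{gas_exchange}, \code{fluorescence} and
#'   \code{leaf_scalars} data frames.
#' @export
read_dataset <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(gas_exchange = rd("gas_exchange.csv"),
       fluorescence = rd("fluorescence.csv"),
       leaf_scalars = rd("leaf_scalars.csv"))
}
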