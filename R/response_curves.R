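# Fitting of light-response and A-Ci curves.
#
# The exponential light model is fitted by multi-start Levenberg-Marquardt
# least squares (the model surface has local minima when alpha and C0 trade
# off); the A-Ci curve is summarised two ways, as in routine gas-exchange
# practice: (i) carboxylation efficiency CE and the CO2 compensation point
# from an OLS regression over the initial linear region, and (ii) Vcmax and
# Jmax from a Farquhar fit (minimum of Rubisco- and RuBP-limited rates) with
# fixed 25 degree C kinetic constants.

condition_fit_error <- function(msg, diagnostics = NULL) {
  structure(class = c("photraits_fit_error", "error", "condition"),
            list(message = msg, call = sys.call(-1),
                 diagnostics = diagnostics))
}

# average replicate steps at identical driver values
collapse_steps <- function(x, driver) {
  agg <- stats::aggregate(x[setdiff(names(x), driver)],
                          by = x[driver], FUN = mean)
  agg[order(agg[[driver]]), , drop = FALSE]
}

r_squared <- function(obs, fitted) {
  1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
}

#' Fit the exponential light-response model
#'
#' Least-squares estimation of \code{A_max}, \code{C0} and \code{alpha} in
#' \deqn{A_{net} = A_{max} - A_{max} C_0 e^{-\alpha PPFD / A_{max}}}
#' by multi-start Levenberg-Marquardt.  Starting values are data-driven
#' (\code{A_max} from the plateau, \code{alpha} from the low-PPFD slope,
#' \code{C0} from the dark value) and perturbed on a small grid.  Dark
#' respiration is reported as the non-negative magnitude
#' \code{Rd = |A_max - A_max * C0|}.
#'
#' @param curve A \code{gas_exchange_curve} of series type \code{"light"}
#'   (or any data frame with \code{PPFD} and \code{Anet} columns).
#'   Replicated PPFD steps are averaged before fitting.
#' @param n_starts Number of starting points (>= 5).
#' @return An object of class \code{light_fit} with elements \code{A_max},
#'   \code{C0}, \code{alpha}, \code{Rd}, \code{rss}, \code{r2},
#'   \code{fitted}, \code{data}.
#' @export
fit_light_response <- function(curve, n_starts = 9) {
  st <- attr(curve, "series_type")
  if (!is.null(st) && st != "light")
    stop("fit_light_response needs a light series, got '", st, "'")
  d <- collapse_steps(as.data.frame(curve)[c("PPFD", "Anet")], "PPFD")
  if (nrow(d) < 5) stop("need at least 5 distinct PPFD steps")
  if (stats::sd(d$Anet) < 1e-12)
    stop(condition_fit_error("degenerate light curve: A_net has no variation",
                             diagnostics = list(sd_anet = stats::sd(d$Anet))))

  amax0 <- max(d$Anet)
  if (amax0 <= 0) amax0 <- 0.5
  low <- d[d$PPFD <= stats::quantile(d$PPFD, 0.4), ]
  alpha0 <- if (nrow(low) >= 2) unname(stats::coef(stats::lm(Anet ~ PPFD, low))[2]) else 0.05
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 0.05
  c00 <- 1 - d$Anet[which.min(d$PPFD)] / amax0
  if (!is.finite(c00) || c00 <= 0) c00 <- 1

  grid <- expand.grid(fa = c(0.5, 1, 2), fc = c(0.8, 1, 1.25))
  grid <- grid[seq_len(min(nrow(grid), max(n_starts, 5))), ]
  best <- NULL
  for (k in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Anet ~ A_max - A_max * C0 * exp(-alpha * PPFD / A_max),
        data = d,
        start = list(A_max = amax0, C0 = c00 * grid$fc[k],
                     alpha = alpha0 * grid$fa[k]),
        lower = c(A_max = 1e-8, C0 = 1e-8, alpha = 1e-10),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(condition_fit_error("light-response fit failed to converge from all starts",
                             diagnostics = list(starts = nrow(grid),
                                                amax0 = amax0, alpha0 = alpha0)))
  cf <- stats::coef(best$fit)
  out <- list(A_max = unname(cf["A_max"]), C0 = unname(cf["C0"]),
              alpha = unname(cf["alpha"]),
              Rd = unname(abs(cf["A_max"] - cf["A_max"] * cf["C0"])),
              rss = best$rss,
              r2 = r_squared(d$Anet, stats::fitted(best$fit)),
              fitted = stats::fitted(best$fit), data = d)
  class(out) <- "light_fit"
  out
}

#' @export
print.light_fit <- function(x, ...) {
  cat("Light-response fit (exponential model)\n")
  cat(sprintf("  A_max = %.4f  C0 = %.4f  alpha = %.5f  Rd = %.4f\n",
              x$A_max, x$C0, x$alpha, x$Rd))
  cat(sprintf("  rss = %.3g  r2 = %.5f  (%d steps)\n", x$rss, x$r2,
              nrow(x$data)))
  invisible(x)
}

#' @export
plot.light_fit <- function(x, ...) {
  plot(x$data$PPFD, x$data$Anet, xlab = "PPFD (umol m-2 s-1)",
       ylab = "Anet (umol m-2 s-1)", ...)
  pp <- seq(0, max(x$data$PPFD), length.out = 200)
  graphics::lines(pp, light_response(pp, x$A_max, x$C0, x$alpha))
  invisible(x)
}

#' Apparent quantum yield from the linear region of a light curve
#'
#' OLS slope of A_net against PPFD over steps with
#' \code{PPFD <= linear_region_max_ppfd}.
#'
#' @param curve Light-series \code{gas_exchange_curve} or data frame.
#' @param linear_region_max_ppfd Upper PPFD bound of the linear region
#'   (default 100 umol m-2 s-1, bracketing the lowest measured levels).
#' @return Slope (mol CO2 mol-1 photons).
#' @export
estimate_aqy <- function(curve, linear_region_max_ppfd = 100) {
  d <- as.data.frame(curve)
  d <- d[d$PPFD <= linear_region_max_ppfd, c("PPFD", "Anet")]
  if (nrow(d) < 3)
    stop("need at least 3 steps with PPFD <= ", linear_region_max_ppfd)
  unname(stats::coef(stats::lm(Anet ~ PPFD, d))[2])
}

#' Fit the CO2-response curve
#'
#' Two-part summary of an A-Ci curve: the initial linear region
#' (\code{Ci <= linear_region_max_ci}) gives the carboxylation efficiency
#' \code{CE} (OLS slope) and the operational CO2 compensation point
#' \code{Gamma_star} (the Ci-intercept of the same regression); a Farquhar
#' fit of \code{pmin(Ac, Aj) - Rd} over the whole curve gives \code{Vcmax},
#' \code{Jmax} and the model's photorespiratory compensation point
#' \code{Gamma_star_photo}.  Both compensation-point readings are reported
#' because curve-level tabulations conventionally label the operational
#' intercept with the Gamma* symbol.
#'
#' @param curve A \code{gas_exchange_curve} of series type \code{"co2"} (or
#'   a data frame with \code{Ci} and \code{Anet}).  Replicated Ci steps are
#'   averaged.
#' @param linear_region_max_ci Upper Ci bound of the linear region
#'   (umol mol-1).
#' @param gamma_star Photorespiratory compensation point to hold fixed in
#'   the Farquhar fit; \code{NULL} (default) estimates it.
#' @param Kc,Ko,O 25 degree C kinetic constants passed to
#'   \code{\link{farquhar_anet}} (Kc in umol mol-1, Ko and O in mmol mol-1).
#' @return An object of class \code{co2_fit} with elements \code{CE},
#'   \code{Gamma_star}, \code{Vcmax}, \code{Jmax}, \code{Rd_fit},
#'   \code{Gamma_star_photo}, \code{Amax_co2}, \code{Jmax_over_Vcmax},
#'   \code{rss}, \code{r2}, \code{diagnostics}.
#' @export
fit_co2_response <- function(curve, linear_region_max_ci = 200,
                             gamma_star = NULL,
                             Kc = 404.9, Ko = 278.4, O = 210) {
  st <- attr(curve, "series_type")
  if (!is.null(st) && st != "co2")
    stop("fit_co2_response needs a co2 series, got '", st, "'")
  d <- collapse_steps(as.data.frame(curve)[c("Ci", "Anet")], "Ci")
  if (nrow(d) < 6) stop("need at least 6 distinct Ci steps")

  diagnostics <- list(gamma_extrapolated = !any(d$Anet < 0))
  lowd <- d[d$Ci <= linear_region_max_ci, ]
  if (nrow(lowd) < 3)
    stop("need at least 3 steps with Ci <= ", linear_region_max_ci)
  lr <- stats::lm(Anet ~ Ci, lowd)
  ce <- unname(stats::coef(lr)[2])
  if (!is.finite(ce) || ce <= 0)
    stop(condition_fit_error("initial-slope regression has non-positive slope",
                             diagnostics = list(slope = ce)))
  gamma_op <- -unname(stats::coef(lr)[1]) / ce

  # Farquhar fit
  rd0 <- max(0.1, -min(d$Anet))
  g0 <- if (is.null(gamma_star)) max(min(gamma_op * 0.9, min(d$Ci) * 0.9), 5)
        else gamma_star
  Km <- Kc * (1 + O / Ko)
  amax_obs <- max(d$Anet)
  ci_hi <- max(d$Ci)
  ci_lo <- lowd$Ci[which.max(lowd$Ci)]
  a_lo <- lowd$Anet[which.max(lowd$Ci)]
  vc0 <- (a_lo + rd0) * (ci_lo + Km) / max(ci_lo - g0, 1)
  if (!is.finite(vc0) || vc0 <= 0) vc0 <- 20
  j0 <- (amax_obs + rd0) * (4 * ci_hi + 8 * g0) / max(ci_hi - g0, 1)
  if (!is.finite(j0) || j0 <= 0) j0 <- 4 * vc0

  fits <- list()
  grid <- expand.grid(fv = c(0.6, 1, 1.6), fj = c(0.6, 1, 1.6))
  for (k in seq_len(nrow(grid))) {
    start <- list(Vcmax = vc0 * grid$fv[k], Jmax = j0 * grid$fj[k], Rd = rd0)
    lower <- c(Vcmax = 1e-6, Jmax = 1e-6, Rd = 0)
    if (is.null(gamma_star)) {
      start$Gamma_star <- g0
      lower <- c(lower, Gamma_star = 1)
      form <- Anet ~ farquhar_anet(Ci, Vcmax, Jmax, Rd, Gamma_star,
                                   Kc = Kc, Ko = Ko, O = O)
    } else {
      form <- stats::as.formula(sprintf(
        "Anet ~ farquhar_anet(Ci, Vcmax, Jmax, Rd, %.10g, Kc = %.10g, Ko = %.10g, O = %.10g)",
        gamma_star, Kc, Ko, O))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0)
    stop(condition_fit_error("Farquhar A-Ci fit failed to converge from all starts",
                             diagnostics = list(vc0 = vc0, j0 = j0)))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  cf <- stats::coef(fit)
  gsp <- if (is.null(gamma_star)) unname(cf["Gamma_star"]) else gamma_star

  out <- list(CE = ce, Gamma_star = gamma_op,
              Vcmax = unname(cf["Vcmax"]), Jmax = unname(cf["Jmax"]),
              Rd_fit = unname(cf["Rd"]), Gamma_star_photo = gsp,
              Amax_co2 = amax_obs,
              Jmax_over_Vcmax = unname(cf["Jmax"] / cf["Vcmax"]),
              rss = min(rss), r2 = r_squared(d$Anet, stats::fitted(fit)),
              diagnostics = diagnostics, data = d,
              fitted = stats::fitted(fit))
  class(out) <- "co2_fit"
  out
}

#' @export
print.co2_fit <- function(x, ...) {
  cat("A-Ci fit\n")
  cat(sprintf("  CE = %.4f  Gamma (Ci-intercept) = %.2f\n", x$CE, x$Gamma_star))
  cat(sprintf("  Vcmax = %.3f  Jmax = %.3f  Jmax/Vcmax = %.3f  Rd = %.3f\n",
              x$Vcmax, x$Jmax, x$Jmax_over_Vcmax, x$Rd_fit))
  cat(sprintf("  Gamma*_photo = %.2f  rss = %.3g  r2 = %.5f\n",
              x$Gamma_star_photo, x$rss, x$r2))
  if (isTRUE(x$diagnostics$gamma_extrapolated))
    cat("  note: no sub-compensation points; Gamma extrapolated\n")
  invisible(x)
}

#' @export
plot.co2_fit <- function(x, ...) {
  plot(x$data$Ci, x$data$Anet, xlab = "Ci (umol mol-1)",
       ylab = "Anet (umol m-2 s-1)", ...)
  o <- order(x$data$Ci)
  graphics::lines(x$data$Ci[o], x$fitted[o])
  invisible(x)
}
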