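## Small quantitative fits: subunit-exchange kinetics from cross-link
## timecourses, ChIP/input ratios from qPCR CT values, and the
## cross-linked-fraction arithmetic used by the screen.

#' Construct an exchange timecourse
#'
#' Cross-linked heterodimer fraction versus incubation time, as produced
#' by mixing two singly-labeled populations and cross-linking aliquots at
#' intervals: the fraction rises from zero toward an equilibrium plateau
#' as subunits exchange.
#'
#' @param times minutes, non-negative, strictly increasing.
#' @param fractions cross-linked fraction in \[0, 1\] per timepoint.
#' @return object of class `exchange_timecourse` (a data frame).
#' @export
exchange_timecourse <- function(times, fractions) {
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) stopf("times and fractions differ in length")
  if (any(times < 0)) stopf("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stopf("times must strictly increase")
  if (any(fractions < 0 | fractions > 1)) stopf("fractions must lie in [0, 1]")
  out <- data.frame(time = times, fraction = fractions)
  class(out) <- c("exchange_timecourse", "data.frame")
  out
}

#' Fit first-order approach-to-equilibrium exchange kinetics
#'
#' Least-squares fit of `F(t) = F_eq * (1 - exp(-k t))` (two parameters,
#' `F(0) = 0` fixed: the heterodimer fraction starts at zero by the
#' mixing design). The fit is plain nonlinear least squares on the
#' fractions, not a log-linearization, to avoid bias near the plateau.
#' The half-life is `ln 2 / k`; its uncertainty comes from a seeded
#' bootstrap over timepoints. An optional three-parameter variant
#' `F0 + (F_eq - F0) * (1 - exp(-k t))` is available via `offset = TRUE`.
#'
#' @param tc an [exchange_timecourse()] (or data frame with `time`,
#'   `fraction`), >= 4 points, not all equal.
#' @param offset fit a free intercept `F0` (default FALSE).
#' @param n_boot bootstrap resamples for the half-life standard error
#'   (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `exchange_fit`: list with `rate_k` (per
#'   minute), `plateau_Feq`, `half_life` (minutes), `half_life_se`,
#'   `residual_rms`, `offset_F0` (when fitted), `fit` (the nls object).
#' @export
fit_exchange <- function(tc, offset = FALSE, n_boot = 1000, seed = 1L) {
  tc <- as.data.frame(tc)
  if (nrow(tc) < 4) stopf("need >= 4 timepoints to fit")
  if (length(unique(tc$fraction)) == 1) stopf("fractions are all equal; no kinetics to fit")
  if (coef(lm_slope <- stats::lm(fraction ~ time, tc))[2] < 0) {
    warnf("fractions decrease with time; the approach-to-equilibrium model is mis-specified")
  }
  fit1 <- function(d) {
    feq0 <- max(d$fraction)
    feq0 <- min(max(feq0, 0.05), 1)
    ## initial rate guess: time at which half the plateau is reached
    t_half0 <- d$time[which.min(abs(d$fraction - feq0 / 2))]
    k0 <- log(2) / max(t_half0, min(d$time[d$time > 0]))
    if (offset) {
      minpack.lm::nlsLM(fraction ~ F0 + (Feq - F0) * (1 - exp(-k * time)),
                        data = d, start = list(Feq = feq0, k = k0, F0 = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(fraction ~ Feq * (1 - exp(-k * time)), data = d,
                        start = list(Feq = feq0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  fit <- tryCatch(fit1(tc), error = function(e)
    stopf("exchange fit failed to converge: %s", conditionMessage(e)))
  cf <- coef(fit)
  k <- unname(cf["k"])
  if (k <= 0) warnf("fitted rate is non-positive (k = %g/min)", k)
  hl_se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    hl <- vapply(seq_len(n_boot), function(i) {
      idx <- sort(sample(nrow(tc), replace = TRUE))
      d <- tc[idx, , drop = FALSE]
      d <- d[!duplicated(d$time), , drop = FALSE]
      if (nrow(d) < 4 || length(unique(d$fraction)) == 1) return(NA_real_)
      f <- tryCatch(fit1(d), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      log(2) / unname(coef(f)["k"])
    }, numeric(1))
    hl_se <- sd(hl, na.rm = TRUE)
  }
  structure(list(rate_k = k, plateau_Feq = unname(cf["Feq"]),
                 half_life = log(2) / k, half_life_se = hl_se,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 offset_F0 = if (offset) unname(cf["F0"]) else NULL,
                 fit = fit),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> half-life %.1f min (k = %.4g/min, plateau %.3f)\n",
              x$half_life, x$rate_k, x$plateau_Feq))
  if (!is.na(x$half_life_se)) {
    cat(sprintf("  bootstrap SE of half-life: %.2f min\n", x$half_life_se))
  }
  invisible(x)
}

#' ChIP/input ratio from qPCR CT values
#'
#' `ratio = alpha * 2^(CT_input - CT_ChIP)`, where `alpha` collects the
#' extraction-volume and dilution factors. Vectorized over loci.
#'
#' @param ct_input,ct_chip CT cycle values.
#' @param alpha positive dilution/volume factor.
#' @return numeric ratio(s).
#' @export
chip_ratio <- function(ct_input, ct_chip, alpha = 1) {
  if (any(alpha <= 0)) stopf("alpha must be > 0")
  alpha * 2^(ct_input - ct_chip)
}

#' Cross-linked fraction from band intensities
#'
#' Fraction of the cross-linked species over the summed intensity of all
#' species in the lane (cross-linked plus monomeric and any other forms).
#'
#' @param crosslinked non-negative intensity of the cross-linked band.
#' @param species numeric vector of all species' intensities (including
#'   the cross-linked band).
#' @return fraction in \[0, 1\].
#' @export
crosslink_fraction <- function(crosslinked, species) {
  if (crosslinked < 0 || any(species < 0)) stopf("intensities must be non-negative")
  total <- sum(species)
  if (total <= 0) stopf("zero total intensity")
  crosslinked / total
}
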