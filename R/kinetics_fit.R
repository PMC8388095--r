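# Hydroxylamine-oxidation kinetics: progress-curve reduction to initial
# rates, Michaelis-Menten fitting, and derived catalytic constants.
#
# Rates are measured as reduction of the electron-acceptor cytochrome at
# 550 nm and converted to substrate (hydroxylamine) units through the
# 3-electron stoichiometry of NH2OH -> NO: three cytochromes are reduced
# per hydroxylamine oxidized.

#' Progress-curve container
#'
#' @param times seconds, strictly increasing.
#' @param A550 absorbance at 550 nm.
#' @param substrate_uM initial hydroxylamine concentration, uM.
#' @param enzyme_ug enzyme mass in the cuvette, ug.
#' @param volume_mL reaction volume, mL.
#' @param epsilon550 differential extinction coefficient for acceptor
#'   reduction, mM^-1 cm^-1 (19.1 for the Kustc0563 construct, 19.6 for
#'   bovine cytochrome c).
#' @param path_cm optical path length, cm.
#' @return Object of class `ProgressCurve`.
#' @export
progress_curve <- function(times, A550, substrate_uM, enzyme_ug,
                           volume_mL = 0.5, epsilon550 = 19.1,
                           path_cm = 1) {
  stopifnot(length(times) == length(A550))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (epsilon550 <= 0) stop("epsilon550 must be positive")
  structure(list(times = as.numeric(times), A550 = as.numeric(A550),
                 substrate_uM = substrate_uM, enzyme_ug = enzyme_ug,
                 volume_mL = volume_mL, epsilon550 = epsilon550,
                 path_cm = path_cm),
            class = "ProgressCurve")
}

#' Initial rate from a progress curve
#'
#' Fits a line to the early part of the curve; the slope (A/min) divided by
#' `epsilon550 * path` gives the cytochrome-reduction rate, which the
#' electron stoichiometry converts to hydroxylamine units; scaling by the
#' reaction volume and enzyme mass yields the specific rate. The default
#' window is the first 20 s or the first 10% of substrate consumption,
#' whichever ends first.
#'
#' @param curve `ProgressCurve`.
#' @param window seconds from t = 0, or NULL for the default rule.
#' @param stoichiometry electrons (cytochromes reduced) per substrate.
#' @return data.frame row with `S` (uM) and `v` (umol min^-1 mg^-1),
#'   attribute `v_cyt_uM_min` carrying the raw cytochrome-reduction rate.
#' @export
initial_rate <- function(curve, window = NULL, stoichiometry = 3) {
  t <- curve$times; A <- curve$A550
  if (is.null(window)) {
    # A rise equivalent to 10% substrate consumption, in absorbance units
    dA10 <- 0.1 * curve$substrate_uM * stoichiometry *
      curve$epsilon550 * curve$path_cm / 1000
    i10 <- which(A - A[1] > dA10)
    t10 <- if (length(i10)) t[i10[1]] else max(t)
    window <- min(20, t10)
  }
  sel <- t - t[1] <= window
  if (sum(sel) < 2L) stop("window shorter than two samples")
  if (window > max(t) - t[1]) stop("window exceeds the recorded curve")
  sl <- unname(coef(lm(A[sel] ~ t[sel]))[2]) * 60   # A/min
  if (sl < 0) stop("negative slope: no acceptor reduction in window")
  v_cyt <- sl / (curve$epsilon550 * curve$path_cm) * 1000   # uM cyt / min
  v_sub <- v_cyt / stoichiometry                            # uM NH2OH / min
  v_spec <- v_sub * (curve$volume_mL / 1000) / (curve$enzyme_ug / 1000)
  structure(data.frame(S = curve$substrate_uM, v = v_spec),
            v_cyt_uM_min = v_cyt)
}

#' Michaelis-Menten fit of initial rates
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)` on replicate-averaged
#' rates (averaging per substrate level, as for technical triplicates).
#'
#' @param points data.frame with columns `S` (uM) and `v`
#'   (umol min^-1 mg^-1); replicate rows share an `S`.
#' @param average_replicates average rates per substrate level before
#'   fitting?
#' @return Object of class `MMFit`: `Vmax`, `se_Vmax`, `Km`, `se_Km`,
#'   `data`, `rss`.
#' @export
fit_mm <- function(points, average_replicates = TRUE) {
  stopifnot(all(c("S", "v") %in% names(points)))
  if (any(points$S < 0)) stop("negative substrate concentration")
  d <- points
  if (average_replicates)
    d <- aggregate(v ~ S, data = d, FUN = mean)
  if (length(unique(d$S)) < 4L)
    stop("need at least 4 distinct substrate levels")
  start <- list(Vmax = max(d$v) * 1.2,
                Km = d$S[which.min(abs(d$v - max(d$v) / 2))])
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) d$v - p[["Vmax"]] * d$S / (p[["Km"]] + d$S),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 0 || fit$info == 9)
    stop("Michaelis-Menten fit did not converge: ", fit$message)
  cf <- coef(fit)
  if (any(cf <= 0)) stop("non-positive Michaelis-Menten estimates")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  rss <- sum((d$v - cf[["Vmax"]] * d$S / (cf[["Km"]] + d$S))^2)
  structure(list(Vmax = unname(cf[["Vmax"]]), se_Vmax = unname(se[["Vmax"]]),
                 Km = unname(cf[["Km"]]), se_Km = unname(se[["Km"]]),
                 data = d, rss = rss, fit = fit),
            class = "MMFit")
}

#' @export
print.MMFit <- function(x, ...) {
  cat(sprintf(
    "MMFit: Vmax = %.2f +/- %.2f umol min^-1 mg^-1, Km = %.2f +/- %.2f uM\n",
    x$Vmax, x$se_Vmax, x$Km, x$se_Km))
  invisible(x)
}

#' Turnover number from a specific activity
#'
#' `kcat [s^-1] = Vmax [umol min^-1 mg^-1] * 1e-3 [mol/g per umol/mg]
#' * M [g/mol] / 60 [s/min]`.
#'
#' @param vmax specific activity, umol min^-1 mg^-1.
#' @param molar_mass enzyme molar mass, g/mol (per catalytic unit, e.g. the
#'   HAO trimer).
#' @return kcat in s^-1.
#' @export
kcat_from_vmax <- function(vmax, molar_mass) {
  if (molar_mass <= 0) stop("molar mass must be positive")
  vmax * 1e-3 * molar_mass / 60
}

#' Catalytic efficiency
#'
#' @param kcat s^-1.
#' @param Km uM.
#' @return `kcat/Km` in uM^-1 s^-1.
#' @export
catalytic_efficiency <- function(kcat, Km) kcat / Km

#' Derived catalytic constants of a Michaelis-Menten fit
#'
#' @param fit an `MMFit`.
#' @param molar_mass enzyme molar mass, g/mol.
#' @return List with `kcat` (s^-1) and `efficiency` (`kcat/Km`,
#'   uM^-1 s^-1).
#' @export
catalytic_constants <- function(fit, molar_mass) {
  kcat <- kcat_from_vmax(fit$Vmax, molar_mass)
  list(kcat = kcat, efficiency = catalytic_efficiency(kcat, fit$Km))
}
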