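# Spectroelectrochemical analysis: baseline correction, SHE referencing,
# per-limb normalization and joint Nernst fitting of titration curves.
#
# Model: A(E) = A_ox + a / (1 + exp(n F (E - E_m) / (R T))), the one-electron
# Nernstian sigmoid in the direction where the reduced species absorbs more
# at the Soret band (A -> A_ox fully oxidized at high potential, A_ox + a
# fully reduced at low potential). Constants F = 96485.34 J V^-1 mol^-1,
# R = 8.3145 J mol^-1 K^-1, T = 293 K by default.

#' Nernstian absorbance sigmoid
#'
#' @param E applied potential, mV vs SHE.
#' @param E_m midpoint potential, mV vs SHE.
#' @param A_ox absorbance of the fully oxidized state.
#' @param a amplitude (reduced minus oxidized absorbance).
#' @param n number of electrons.
#' @param temperature K.
#' @return Absorbance at `E`. `A = A_ox + a/2` at `E = E_m`; the 10-90%
#'   transition width is `2 ln(9) RT/(nF)` (about 110.9 mV for n = 1 at
#'   293 K).
#' @export
nernst_absorbance <- function(E, E_m, A_ox = 0, a = 1, n = 1,
                              temperature = 293) {
  f <- .const$faraday / (.const$R_gas * temperature)   # 1/V
  A_ox + a / (1 + exp(n * f * (E - E_m) / 1000))
}

#' Baseline-correct a spectrum
#'
#' Subtracts the absorbance at 700 nm from the whole spectrum so that
#' A(700) = 0; if 700 nm was not recorded the nearest wavelength is used
#' with a warning.
#'
#' @param spectrum data.frame with columns `wavelength` (nm) and
#'   `absorbance`.
#' @param reference_wavelength nm.
#' @return The spectrum with corrected `absorbance`.
#' @export
baseline_correct <- function(spectrum, reference_wavelength = 700) {
  stopifnot(all(c("wavelength", "absorbance") %in% names(spectrum)))
  d <- abs(spectrum$wavelength - reference_wavelength)
  i <- which.min(d)
  if (d[i] > 1e-9)
    warning(sprintf("%g nm not in spectrum; using nearest wavelength %g nm",
                    reference_wavelength, spectrum$wavelength[i]))
  spectrum$absorbance <- spectrum$absorbance - spectrum$absorbance[i]
  spectrum
}

#' Reference applied potentials to SHE
#'
#' `E_SHE = E_measured + patch_offset + reference_potential`, where
#' `patch_offset` is the measured voltage between the on-slide Ag/AgCl patch
#' and a commercial Ag/AgCl/4 M KCl electrode (+200 mV vs SHE). Apply once.
#'
#' @param E_measured measured potential(s), mV vs the patch electrode.
#' @param patch_offset patch vs commercial reference, mV.
#' @param reference_potential commercial reference vs SHE, mV.
#' @return Potential(s) in mV vs SHE.
#' @export
correct_reference <- function(E_measured, patch_offset = 0,
                              reference_potential = 200) {
  E_measured + patch_offset + reference_potential
}

# split a titration table into per-(experiment, limb) groups, validated
titration_groups <- function(curves) {
  stopifnot(all(c("experiment", "limb", "E_mV", "A420") %in% names(curves)))
  if (any(!is.finite(curves$E_mV))) stop("non-finite potentials")
  split(curves, interaction(curves$experiment, curves$limb, drop = TRUE))
}

# Levenberg-Marquardt core shared by the per-limb and joint fits; nls.lm
# copes with exact (zero-residual) fits, which nls-style wrappers do not
nernst_lm <- function(E, A, start, n, temperature) {
  res <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) A - nernst_absorbance(E, p[["E_m"]], p[["A_ox"]],
                                           p[["a"]], n = n,
                                           temperature = temperature),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (res$info == 0 || res$info == 9)
    stop("Nernst fit did not converge: ", res$message)
  res
}

# per-limb Nernst fit with free E_m, A_ox, a (used for plateau estimation)
fit_limb <- function(limb, n, temperature) {
  if (nrow(limb) < 4L) stop("fewer than 4 points in a limb")
  if (diff(range(limb$A420)) < 1e-12) stop("degenerate limb: no absorbance spread")
  start <- list(E_m = limb$E_mV[which.min(abs(limb$A420 - mean(range(limb$A420))))],
                A_ox = min(limb$A420), a = diff(range(limb$A420)))
  coef(nernst_lm(limb$E_mV, limb$A420, start, n, temperature))
}

#' Normalize titration limbs
#'
#' Rescales each (experiment, limb) series affinely so that its plateaus
#' map to \[0, 1\] (0 fully oxidized, 1 fully reduced), removing hysteresis
#' offsets between the oxidative and reductive limbs before joint fitting.
#' `method = "fitted"` (default) estimates the plateaus from a per-limb
#' Nernst fit, which stays unbiased when the potential window does not reach
#' a plateau; `"observed"` uses the mean of the `n_extreme` most extreme
#' potential points of the limb.
#'
#' @param curves data.frame with columns `experiment`, `limb`
#'   (`"oxidative"`/`"reductive"`), `E_mV`, `A420`.
#' @param method plateau estimation rule.
#' @param n_extreme points per plateau for `method = "observed"`.
#' @param n,temperature Nernst parameters for `method = "fitted"`.
#' @return `curves` with `A420` replaced by its normalized value.
#' @export
normalize_limbs <- function(curves, method = c("fitted", "observed"),
                            n_extreme = 3, n = 1, temperature = 293) {
  method <- match.arg(method)
  groups <- titration_groups(curves)
  out <- lapply(groups, function(g) {
    if (diff(range(g$A420)) < 1e-12)
      stop("degenerate limb: no absorbance spread")
    if (method == "fitted") {
      cf <- fit_limb(g, n, temperature)
      lo <- cf[["A_ox"]]; hi <- cf[["A_ox"]] + cf[["a"]]
    } else {
      ord <- order(g$E_mV)
      hi <- mean(g$A420[head(ord, n_extreme)])   # low potential: reduced
      lo <- mean(g$A420[tail(ord, n_extreme)])   # high potential: oxidized
    }
    if (abs(hi - lo) < 1e-12) stop("degenerate limb: zero plateau span")
    g$A420 <- (g$A420 - lo) / (hi - lo)
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(paste(res$experiment, res$limb, res$E_mV),
                  paste(curves$experiment, curves$limb, curves$E_mV))), ,
      drop = FALSE]
}

#' Joint Nernst fit of titration curves
#'
#' Nonlinear least squares of the Nernstian sigmoid with a single shared
#' midpoint potential (and shared offset/amplitude, which normalization
#' reduces to approximately 0 and 1) across all limbs and experiments, as
#' when two individual experiments are fitted together.
#'
#' @param curves normalized titration table (see [normalize_limbs()]).
#' @param n number of electrons, fixed (1 for a c-type heme).
#' @param temperature K.
#' @return Object of class `NernstFit`: `E_m` (mV vs SHE), `se_E_m`,
#'   `A_ox`, `a`, `n`, `temperature`, `rss`, `residuals`.
#' @export
fit_nernst <- function(curves, n = 1, temperature = 293) {
  titration_groups(curves)   # validates columns and potentials
  npts <- nrow(curves)
  if (npts < 4L) stop("fewer points than parameters")
  start <- list(E_m = median(curves$E_mV[order(abs(curves$A420 - 0.5))][1:3]),
                A_ox = min(curves$A420), a = diff(range(curves$A420)))
  fit <- nernst_lm(curves$E_mV, curves$A420, start, n, temperature)
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  res <- curves
  res$fitted <- nernst_absorbance(curves$E_mV, cf[["E_m"]], cf[["A_ox"]],
                                  cf[["a"]], n = n, temperature = temperature)
  res$residual <- res$A420 - res$fitted
  structure(list(E_m = unname(cf[["E_m"]]),
                 se_E_m = unname(se[["E_m"]]),
                 A_ox = unname(cf[["A_ox"]]), a = unname(cf[["a"]]),
                 n = n, temperature = temperature,
                 rss = sum(res$residual^2),
                 n_experiments = length(unique(curves$experiment)),
                 residuals = res, fit = fit),
            class = "NernstFit")
}

#' @export
print.NernstFit <- function(x, ...) {
  cat(sprintf(
    "NernstFit: E_m = %.1f +/- %.1f mV vs SHE (n = %d, T = %g K, %d experiments, RSS = %.4g)\n",
    x$E_m, x$se_E_m, x$n, x$temperature, x$n_experiments, x$rss))
  invisible(x)
}
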