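# Curve analyses for the wet-lab side: CD ellipticity, two-state melts,
# FP binding (saturation and competition), Hill dose-response, and HDX
# uptake differences. Nonlinear fits use minpack.lm::nlsLM; confidence
# intervals are likelihood profiles where available.

#' Mean residue ellipticity from raw CD signal
#'
#' `[theta] = M0 * theta / (10 * l * c)`, converting millidegrees into the
#' concentration-independent mean residue ellipticity.
#'
#' @param theta_mdeg raw ellipticity, millidegrees
#' @param M0 mean residue weight, g/mol
#' @param l path length, cm (> 0)
#' @param c protein concentration, mg/ml (> 0)
#' @return mean residue ellipticity, deg cm^2 dmol^-1
#' @export
mean_residue_ellipticity <- function(theta_mdeg, M0, l, c) {
  if (l <= 0 || c <= 0) stop("path length and concentration must be positive")
  M0 * theta_mdeg / (10 * l * c)
}

#' Fraction denatured from signal and baselines
#'
#' `fD = (y - yN) / (yD - yN)`, the two-state lever rule.
#'
#' @param y observed signal
#' @param yN,yD native and denatured baseline values at the same temperature
#' @return fraction denatured
#' @export
fraction_denatured <- function(y, yN, yD) {
  if (any(yD == yN)) stop("yD must differ from yN")
  (y - yN) / (yD - yN)
}

#' Fit a two-state thermal melt by Gibbs-Helmholtz linearization
#'
#' Procedure: (1) fit linear native/denatured baselines on the leading and
#' trailing `baseline_frac` of the temperature grid; (2) convert signal to
#' fraction denatured by [fraction_denatured()]; (3) compute
#' `dG(T) = -R T ln(fD / (1 - fD))` in Kelvin (R = 1.987e-3 kcal/mol/K);
#' (4) keep points with `|dG| <= dG_window` (default 1.3 kcal/mol, near the
#' midpoint where the linearization is reliable); (5) least-squares line of
#' dG versus T. The apparent Tm is the zero crossing, the entropy change is
#' `dSm = -slope`, and `dHm_app = Tm * dSm`.
#'
#' @param curve data.frame with columns `T_C`, `theta_mdeg` (e.g. from
#'   [make_melting_curve()])
#' @param dG_window half-width of the dG fitting window, kcal/mol
#'   (default 1.3)
#' @param baseline_frac fraction of the grid used for each baseline
#'   (default 0.2)
#' @return list of class `melt_fit`: `Tm_K`, `Tm_C`, `dHm`, `dSm`,
#'   `baselines`, `n_window`, plus the per-point `dG` table
#' @export
fit_two_state_melt <- function(curve, dG_window = 1.3, baseline_frac = 0.2) {
  stopifnot(all(c("T_C", "theta_mdeg") %in% names(curve)))
  t_c <- curve$T_C
  y <- curve$theta_mdeg
  n <- length(t_c)
  if (is.unsorted(t_c, strictly = TRUE)) stop("temperatures must be strictly increasing")
  k <- max(3L, floor(n * baseline_frac))
  lead <- seq_len(k)
  trail <- (n - k + 1L):n
  fitN <- stats::lm(y ~ T_C, data = data.frame(T_C = t_c[lead], y = y[lead]))
  fitD <- stats::lm(y ~ T_C, data = data.frame(T_C = t_c[trail], y = y[trail]))
  yN <- stats::predict(fitN, newdata = data.frame(T_C = t_c))
  yD <- stats::predict(fitD, newdata = data.frame(T_C = t_c))
  fD <- fraction_denatured(y, yN, yD)
  ok <- fD > 0 & fD < 1
  t_k <- celsius_to_kelvin(t_c)
  dG <- rep(NA_real_, n)
  dG[ok] <- -R_KCAL * t_k[ok] * log(fD[ok] / (1 - fD[ok]))
  window <- which(ok & abs(dG) <= dG_window)
  if (length(window) < 3L) {
    stop("fewer than 3 points inside the dG window; transition not resolved")
  }
  line <- stats::lm(dG ~ T_K, data = data.frame(T_K = t_k[window],
                                                dG = dG[window]))
  slope <- unname(stats::coef(line)[2])
  intercept <- unname(stats::coef(line)[1])
  if (slope >= 0) stop("dG does not decrease with temperature: no melting transition")
  Tm_K <- -intercept / slope
  if (Tm_K < min(t_k) || Tm_K > max(t_k)) {
    stop("fitted Tm falls outside the measured range")
  }
  dSm <- -slope
  structure(list(Tm_K = Tm_K, Tm_C = kelvin_to_celsius(Tm_K),
                 dHm = Tm_K * dSm, dSm = dSm,
                 baselines = list(yN = stats::coef(fitN),
                                  yD = stats::coef(fitD)),
                 n_window = length(window),
                 dG_table = data.frame(T_K = t_k[window], dG = dG[window])),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f K (%.2f C), apparent dHm = %.1f kcal/mol\n",
              x$Tm_K, x$Tm_C, x$dHm))
  invisible(x)
}

profile_ci <- function(fit, param) {
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, parm = param, level = 0.95))),
    error = function(e) c(NA_real_, NA_real_))
  as.numeric(ci)
}

#' Fit a one-site saturation binding curve
#'
#' Least-squares fit of the one-site hyperbola
#' `mP(x) = mP_free + (mP_bound - mP_free) x / (Kd + x)` with a
#' profile-likelihood 95% confidence interval on Kd.
#'
#' @param curve data.frame with columns `conc_nM`, `mP` (at least 5
#'   concentrations spanning the inflection)
#' @return list of class `binding_fit`: `Kd`, `Kd_ci`, `mP_free`,
#'   `mP_bound`, and the `nls` fit object
#' @export
fit_saturation_binding <- function(curve) {
  stopifnot(all(c("conc_nM", "mP") %in% names(curve)))
  if (nrow(curve) < 5L) stop("need at least 5 concentrations")
  x <- curve$conc_nM
  y <- curve$mP
  start <- list(f0 = min(y), fb = max(y),
                Kd = stats::median(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ f0 + (fb - f0) * x / (Kd + x), start = start,
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("saturation fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(Kd = unname(co["Kd"]), Kd_ci = profile_ci(fit, "Kd"),
                 mP_free = unname(co["f0"]), mP_bound = unname(co["fb"]),
                 fit = fit),
            class = "binding_fit")
}

#' Fit a competition binding curve and convert to Ki
#'
#' Fits a sigmoidal displacement model on log10 concentration,
#' `mP = bottom + (top - bottom) / (1 + 10^(log10(x) - log10(IC50)))`,
#' then applies the Cheng-Prusoff correction
#' `Ki = IC50 / (1 + probe_conc / probe_kd)`.
#'
#' @param curve data.frame with columns `conc_nM`, `mP`
#' @param probe_conc labeled-probe concentration, nM (> 0)
#' @param probe_kd probe dissociation constant, nM (> 0)
#' @return list of class `binding_fit`: `Ki`, `IC50`, `Ki_ci`, `top`,
#'   `bottom`, and the `nls` fit object
#' @export
fit_competition_ki <- function(curve, probe_conc, probe_kd) {
  stopifnot(all(c("conc_nM", "mP") %in% names(curve)))
  if (probe_conc <= 0 || probe_kd <= 0) stop("probe parameters must be positive")
  lx <- log10(curve$conc_nM)
  y <- curve$mP
  if (stats::cor(lx, y) >= 0) {
    stop("competition curve is not decreasing with concentration")
  }
  start <- list(top = max(y), bottom = min(y), logIC50 = stats::median(lx))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + 10^(lx - logIC50)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("competition fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  ic50 <- 10^unname(co["logIC50"])
  ic50_ci <- 10^profile_ci(fit, "logIC50")
  factor <- 1 + probe_conc / probe_kd
  structure(list(Ki = ic50 / factor, IC50 = ic50,
                 Ki_ci = ic50_ci / factor,
                 top = unname(co["top"]), bottom = unname(co["bottom"]),
                 fit = fit),
            class = "binding_fit")
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `F(d) = bottom + (Emax - bottom) /
#' (1 + (EC50 / d)^hill_n)`. A flat response (signal range below
#' `flat_factor` times the residual noise estimate) is reported as
#' no-activation: `EC50 = NA`, modelling ligands that do not activate.
#'
#' @param curve data.frame with columns `dose_nM`, `fold_activation`
#'   (at least 5 doses)
#' @param flat_factor flat-response threshold as a multiple of the noise
#'   estimate (default 3)
#' @return list of class `dose_fit`: `EC50`, `EC50_ci`, `Emax`, `bottom`,
#'   `hill_n`, `activated` (logical), and the `nls` fit object (or `NULL`)
#' @export
fit_dose_response <- function(curve, flat_factor = 3) {
  stopifnot(all(c("dose_nM", "fold_activation") %in% names(curve)))
  if (nrow(curve) < 5L) stop("need at least 5 doses")
  d <- curve$dose_nM
  y <- curve$fold_activation
  ord <- order(d)
  d <- d[ord]
  y <- y[ord]
  # noise estimate from successive differences (robust to the sigmoid trend)
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (diff(range(y)) < flat_factor * noise || diff(range(y)) == 0) {
    return(structure(list(EC50 = NA_real_, EC50_ci = c(NA_real_, NA_real_),
                          Emax = NA_real_, bottom = mean(y),
                          hill_n = NA_real_, activated = FALSE, fit = NULL),
                     class = "dose_fit"))
  }
  ld <- log10(d)
  start <- list(bottom = min(y), Emax = max(y),
                logEC50 = stats::median(ld), hill_n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (Emax - bottom) / (1 + 10^((logEC50 - ld) * hill_n)),
      start = start, lower = c(-Inf, -Inf, -12, 0.1),
      upper = c(Inf, Inf, 12, 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("dose-response fit failed: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(EC50 = 10^unname(co["logEC50"]),
                 EC50_ci = 10^profile_ci(fit, "logEC50"),
                 Emax = unname(co["Emax"]), bottom = unname(co["bottom"]),
                 hill_n = unname(co["hill_n"]), activated = TRUE, fit = fit),
            class = "dose_fit")
}

#' HDX uptake difference between two states
#'
#' For each peptide present in both states at the timepoint:
#' `RFU = centroid uptake / n_exchangeable` with
#' `n_exchangeable = length - 1 - n_prolines`;
#' `dRFU = RFU_A - RFU_B`, `dcentroid = uptake_A - uptake_B` (Da), and the
#' difference is significant when `|dcentroid| >= threshold_da` (default
#' 0.5 Da). Swapping the states negates both differences.
#'
#' @param hdx an `hdx_table` from [make_hdx_table()] (or any data.frame in
#'   the same long format)
#' @param state_a,state_b state labels (default `"A"`, `"B"`)
#' @param exposure_min timepoint to compare (default: the single timepoint
#'   present)
#' @param threshold_da significance threshold on the centroid difference,
#'   Da (default 0.5)
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `n_exchangeable`, `rfu_a`, `rfu_b`, `delta_rfu`, `delta_centroid_Da`,
#'   `significant`
#' @export
delta_rfu <- function(hdx, state_a = "A", state_b = "B",
                      exposure_min = NULL, threshold_da = 0.5) {
  need <- c("peptide", "start", "end", "length", "n_prolines", "state",
            "exposure_min", "centroid_uptake_Da")
  stopifnot(all(need %in% names(hdx)))
  if (is.null(exposure_min)) {
    ex <- unique(hdx$exposure_min)
    if (length(ex) != 1L) stop("multiple timepoints present; pick one")
    exposure_min <- ex
  }
  sub <- hdx[hdx$exposure_min == exposure_min, ]
  a <- sub[sub$state == state_a, ]
  b <- sub[sub$state == state_b, ]
  m <- merge(a, b, by = c("peptide", "start", "end", "length", "n_prolines"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no peptides shared by states ", state_a, " and ",
                          state_b, " at ", exposure_min, " min")
  n_exch <- m$length - 1L - m$n_prolines
  if (any(n_exch < 1L)) stop("peptide with no exchangeable amides")
  rfu_a <- m$centroid_uptake_Da_a / n_exch
  rfu_b <- m$centroid_uptake_Da_b / n_exch
  dcent <- m$centroid_uptake_Da_a - m$centroid_uptake_Da_b
  data.frame(peptide = m$peptide, start = m$start, end = m$end,
             n_exchangeable = n_exch, rfu_a = rfu_a, rfu_b = rfu_b,
             delta_rfu = rfu_a - rfu_b, delta_centroid_Da = dcent,
             significant = abs(dcent) >= threshold_da,
             stringsAsFactors = FALSE)
}
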