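# Forward models for the wet-lab analyses: two-state melts, one-site
# binding/competition, Hill dose-response, and HDX uptake tables. Curves are
# stored in the units instruments report (degrees C, nM, mdeg, mP, Da);
# thermodynamics are computed in Kelvin.

#' Molar gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.987e-3

celsius_to_kelvin <- function(t_c) t_c + 273.15
kelvin_to_celsius <- function(t_k) t_k - 273.15

# Reported assay points are means over technical replicates; the mean of
# n replicates with per-replicate sd s has sd s / sqrt(n).
replicate_mean_noise <- function(n_points, noise_sd, n_replicates) {
  stopifnot(n_replicates >= 1)
  stats::rnorm(n_points, sd = noise_sd / sqrt(n_replicates))
}

#' Simulate a two-state thermal melting curve
#'
#' Generates a CD-style melting signal `y(T) = (1 - fD) yN(T) + fD yD(T) +
#' noise`, where the denatured fraction follows the van't Hoff two-state
#' model `dG(T) = dHm (1 - T/Tm)` and `fD = 1 / (1 + exp(dG / (R T)))`
#' (temperatures in Kelvin, `R` = 1.987e-3 kcal/mol/K). Baselines are linear
#' in temperature (degrees C).
#'
#' @param Tm midpoint temperature, Kelvin; must lie inside the grid range
#' @param dHm apparent van't Hoff enthalpy, kcal/mol (> 0)
#' @param baselines list with `yN = c(intercept, slope)` and
#'   `yD = c(intercept, slope)` (signal units, slope per degree C)
#' @param noise_sd Gaussian noise sd in signal units (default 0)
#' @param T_grid temperature grid in degrees C (default 20-70 by 0.5)
#' @param seed integer seed or `NULL`
#' @return data.frame of class `melting_curve` with columns `T_C`,
#'   `theta_mdeg`
#' @export
make_melting_curve <- function(Tm, dHm,
                               baselines = list(yN = c(-11000, -5),
                                                yD = c(-3000, -2)),
                               noise_sd = 0,
                               T_grid = seq(20, 70, by = 0.5),
                               seed = NULL) {
  if (dHm <= 0) stop("dHm must be positive")
  t_k <- celsius_to_kelvin(T_grid)
  if (Tm < min(t_k) || Tm > max(t_k)) {
    stop("Tm must lie inside the temperature grid")
  }
  if (!is.null(seed)) set.seed(seed)
  dG <- dHm * (1 - t_k / Tm)
  fD <- 1 / (1 + exp(dG / (R_KCAL * t_k)))
  yN <- baselines$yN[1] + baselines$yN[2] * T_grid
  yD <- baselines$yD[1] + baselines$yD[2] * T_grid
  y <- (1 - fD) * yN + fD * yD + stats::rnorm(length(T_grid), sd = noise_sd)
  out <- data.frame(T_C = T_grid, theta_mdeg = y)
  attr(out, "truth") <- list(Tm = Tm, dHm = dHm, baselines = baselines)
  class(out) <- c("melting_curve", "data.frame")
  out
}

#' Simulate a fluorescence-polarization saturation binding curve
#'
#' `mP(x) = mP_free + (mP_bound - mP_free) x / (Kd + x) + noise`, the
#' one-site hyperbola.
#'
#' @param Kd dissociation constant, nM (> 0)
#' @param conc_nM receptor concentration grid, nM (> 0); default spans
#'   0.45 nM to 7500 nM in log steps
#' @param mP_free,mP_bound polarization of free and bound probe
#' @param noise_sd per-replicate Gaussian noise sd in mP
#' @param n_replicates technical replicates averaged per point (default 6,
#'   the usual FP plate layout); the curve reports the replicate mean
#' @param seed integer seed or `NULL`
#' @return data.frame of class `binding_curve` with columns `conc_nM`, `mP`
#' @export
make_saturation_curve <- function(Kd, conc_nM = 10^seq(-0.35, 3.88,
                                                       length.out = 16),
                                  mP_free = 50, mP_bound = 200,
                                  noise_sd = 0, n_replicates = 6L,
                                  seed = NULL) {
  if (Kd <= 0) stop("Kd must be positive")
  if (any(conc_nM <= 0)) stop("concentrations must be positive")
  if (!is.null(seed)) set.seed(seed)
  mp <- mP_free + (mP_bound - mP_free) * conc_nM / (Kd + conc_nM) +
    replicate_mean_noise(length(conc_nM), noise_sd, n_replicates)
  out <- data.frame(conc_nM = conc_nM, mP = mp)
  attr(out, "truth") <- list(Kd = Kd, mP_free = mP_free, mP_bound = mP_bound)
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Simulate a fluorescence-polarization competition curve
#'
#' Polarization decreases logistically with log10 competitor concentration,
#' with midpoint `IC50 = Ki * (1 + probe_conc / probe_kd)` (Cheng-Prusoff).
#'
#' @param Ki inhibition constant of the competitor, nM (> 0)
#' @param probe_conc labeled-probe concentration, nM (default 10)
#' @param probe_kd probe dissociation constant, nM (default 180)
#' @param conc_nM competitor grid, nM (default 0.1 nM to 10 uM, log steps)
#' @param mP_top,mP_bottom polarization at zero and saturating competitor
#' @param noise_sd per-replicate Gaussian noise sd in mP
#' @param n_replicates replicates averaged per point (default 3)
#' @param seed integer seed or `NULL`
#' @return data.frame of class `binding_curve` with columns `conc_nM`, `mP`;
#'   the implied IC50 is stored in the `truth` attribute
#' @export
make_competition_curve <- function(Ki, probe_conc = 10, probe_kd = 180,
                                   conc_nM = 10^seq(-1, 4, length.out = 16),
                                   mP_top = 200, mP_bottom = 50,
                                   noise_sd = 0, n_replicates = 3L,
                                   seed = NULL) {
  if (Ki <= 0) stop("Ki must be positive")
  if (probe_conc <= 0 || probe_kd <= 0) stop("probe parameters must be positive")
  if (any(conc_nM <= 0)) stop("concentrations must be positive")
  if (!is.null(seed)) set.seed(seed)
  ic50 <- cheng_prusoff_ic50(Ki, probe_conc, probe_kd)
  mp <- mP_bottom + (mP_top - mP_bottom) /
    (1 + 10^(log10(conc_nM) - log10(ic50))) +
    replicate_mean_noise(length(conc_nM), noise_sd, n_replicates)
  out <- data.frame(conc_nM = conc_nM, mP = mp)
  attr(out, "truth") <- list(Ki = Ki, IC50 = ic50, probe_conc = probe_conc,
                             probe_kd = probe_kd, mP_top = mP_top,
                             mP_bottom = mP_bottom)
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Cheng-Prusoff conversions between IC50 and Ki
#'
#' `IC50 = Ki (1 + [probe] / Kd_probe)` and its inverse.
#'
#' @param Ki,IC50 nM
#' @param probe_conc,probe_kd probe concentration and Kd, nM
#' @return nM
#' @export
cheng_prusoff_ic50 <- function(Ki, probe_conc, probe_kd) {
  Ki * (1 + probe_conc / probe_kd)
}

#' @rdname cheng_prusoff_ic50
#' @export
cheng_prusoff_ki <- function(IC50, probe_conc, probe_kd) {
  IC50 / (1 + probe_conc / probe_kd)
}

#' Simulate a Hill dose-response curve
#'
#' `F(d) = bottom + (Emax - bottom) / (1 + (EC50 / d)^hill_n) + noise`.
#'
#' @param EC50 half-maximal dose, nM (> 0)
#' @param Emax maximal response (fold activation)
#' @param bottom basal response (default 1)
#' @param hill_n Hill coefficient (default 1)
#' @param dose_nM dose grid, nM (> 0); default 0.01 nM to 1 uM, log steps
#' @param noise_sd per-replicate Gaussian noise sd in response units
#' @param n_replicates replicates averaged per dose (default 3)
#' @param seed integer seed or `NULL`
#' @return data.frame of class `dose_response_curve` with columns `dose_nM`,
#'   `fold_activation`
#' @export
make_dose_response <- function(EC50, Emax, bottom = 1, hill_n = 1,
                               dose_nM = 10^seq(-2, 3, length.out = 12),
                               noise_sd = 0, n_replicates = 3L,
                               seed = NULL) {
  if (EC50 <= 0) stop("EC50 must be positive")
  if (any(dose_nM <= 0)) stop("doses must be positive")
  if (!is.null(seed)) set.seed(seed)
  y <- bottom + (Emax - bottom) / (1 + (EC50 / dose_nM)^hill_n) +
    replicate_mean_noise(length(dose_nM), noise_sd, n_replicates)
  out <- data.frame(dose_nM = dose_nM, fold_activation = y)
  attr(out, "truth") <- list(EC50 = EC50, Emax = Emax, bottom = bottom,
                             hill_n = hill_n)
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' Build a paired-state HDX centroid uptake table
#'
#' Creates matched state-A/state-B uptake tables for one peptide set at one
#' exposure. Exchangeable amides per peptide are `length - 1 - n_prolines`
#' (the N-terminal amide and prolines after the first residue do not retain
#' deuterium); uptake must not exceed that count.
#'
#' @param peptides data.frame with columns `peptide`, `start`, `end`,
#'   `length`, `n_prolines` (prolines after the first residue)
#' @param uptake_a,uptake_b centroid uptake per peptide, Da
#' @param exposure_min exposure time label, minutes (default 10)
#' @param noise_sd Gaussian noise sd in Da (default 0)
#' @param seed integer seed or `NULL`
#' @return data.frame of class `hdx_table`, long format: `peptide`, `start`,
#'   `end`, `length`, `n_prolines`, `state`, `exposure_min`,
#'   `centroid_uptake_Da`
#' @export
make_hdx_table <- function(peptides, uptake_a, uptake_b, exposure_min = 10,
                           noise_sd = 0, seed = NULL) {
  need <- c("peptide", "start", "end", "length", "n_prolines")
  stopifnot(all(need %in% names(peptides)),
            length(uptake_a) == nrow(peptides),
            length(uptake_b) == nrow(peptides))
  n_exch <- peptides$length - 1L - peptides$n_prolines
  if (any(n_exch < 1L)) stop("peptide with no exchangeable amides")
  if (any(uptake_a < 0) || any(uptake_b < 0)) stop("uptake must be >= 0")
  if (any(uptake_a > n_exch) || any(uptake_b > n_exch)) {
    bad <- which(uptake_a > n_exch | uptake_b > n_exch)[1]
    stop("uptake exceeds exchangeable amides for peptide ",
         peptides$peptide[bad])
  }
  if (!is.null(seed)) set.seed(seed)
  mk <- function(state, uptake) {
    data.frame(peptides[need], state = state, exposure_min = exposure_min,
               centroid_uptake_Da = pmax(
                 uptake + stats::rnorm(length(uptake), sd = noise_sd), 0),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("A", uptake_a), mk("B", uptake_b))
  class(out) <- c("hdx_table", "data.frame")
  out
}
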