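#' Dual-boost accelerated-MD parameters
#'
#' Computes the four dual-boost parameters from classical-MD average
#' energies and system sizes, using the standard selection rules:
#' `ED = EavgD + 3.5 * Nsr`, `aD = 0.2 * ED`, `aP = 0.16 * Natom`,
#' `EP = EavgP + 0.16 * Natom` (all kcal/mol). The dihedral boost factor is
#' one fifth of the dihedral threshold by construction, and the total
#' potential boost factor scales with 0.16 kcal/mol per atom.
#'
#' @param EavgD average dihedral energy, kcal/mol
#' @param EavgP average total potential energy, kcal/mol
#' @param Nsr number of solute residues (>= 0)
#' @param Natom total number of atoms (>= 0)
#' @return list of class `boost_params` with `aD`, `ED`, `aP`, `EP` and the
#'   inputs
#' @export
compute_boost_params <- function(EavgD, EavgP, Nsr, Natom) {
  if (Nsr < 0 || Natom < 0) stop("Nsr and Natom must be non-negative")
  ED <- EavgD + 3.5 * Nsr
  aD <- 0.2 * ED
  aP <- 0.16 * Natom
  EP <- EavgP + 0.16 * Natom
  structure(list(aD = aD, ED = ED, aP = aP, EP = EP,
                 EavgD = EavgD, EavgP = EavgP, Nsr = Nsr, Natom = Natom),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat(sprintf(
    "<boost_params> ED = %.2f, aD = %.2f, EP = %.2f, aP = %.2f kcal/mol\n",
    x$ED, x$aD, x$EP, x$aP))
  invisible(x)
}
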