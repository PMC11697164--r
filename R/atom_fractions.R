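# Isotope ratio <-> atom fraction algebra shared by the SIP and
# nitrification modules.

#' Natural-abundance constants
#'
#' Air-N2 15N/14N ratio and the default natural atom fractions of 15N and
#' 13C used as generator defaults and delta-notation standards.
#'
#' @format Named numeric vector with elements `r_std_15N` (0.0036765),
#'   `x_nat_15N` (0.003663) and `x_nat_13C` (0.0107).
#' @export
isotope_constants <- c(
  r_std_15N = 0.0036765,
  x_nat_15N = 0.003663,
  x_nat_13C = 0.0107
)

#' Convert a 12C15N-/12C14N- ion ratio to a 15N atom fraction
#'
#' The CN- secondary ion carries one nitrogen atom, so the measured ratio
#' R = 15N/14N maps to the atom fraction x = R / (1 + R).
#'
#' @param ratio Non-negative numeric vector of 12C15N-/12C14N- ratios.
#' @return Atom fraction(s) in `[0, 1)`.
#' @examples
#' ratio15N_to_atom_fraction(0.0036765)  # natural abundance, ~0.003663
#' @export
ratio15N_to_atom_fraction <- function(ratio) {
  check_nonneg(ratio, "ratio")
  ratio / (1 + ratio)
}

#' Convert a 13C12C-/12C2- ion ratio to a 13C atom fraction
#'
#' The C2- dimer samples two carbon atoms: with atom fraction x the
#' mixed-dimer to light-dimer ratio is R = 2x(1-x)/(1-x)^2 = 2x/(1-x),
#' hence x = R / (2 + R).
#'
#' @param ratio Non-negative numeric vector of 13C12C-/12C2- ratios.
#' @return Atom fraction(s) in `[0, 1)`.
#' @export
ratio13C_to_atom_fraction <- function(ratio) {
  check_nonneg(ratio, "ratio")
  ratio / (2 + ratio)
}

#' Invert atom fractions back to ion ratios
#'
#' Inverse maps of [ratio15N_to_atom_fraction()] and
#' [ratio13C_to_atom_fraction()]; used by the synthetic-data generator to
#' plant cell ratios from target atom fractions.
#'
#' @param x Atom fraction(s) in `[0, 1)`.
#' @return Ion ratio(s).
#' @export
atom_fraction_to_ratio15N <- function(x) {
  stopifnot(all(x >= 0 & x < 1))
  x / (1 - x)
}

#' @rdname atom_fraction_to_ratio15N
#' @export
atom_fraction_to_ratio13C <- function(x) {
  stopifnot(all(x >= 0 & x < 1))
  2 * x / (1 - x)
}

#' Convert delta-15N (per mil vs air-N2) to a 15N atom fraction
#'
#' R = (delta/1000 + 1) * R_std, then x = R / (1 + R).
#'
#' @param delta_permil Numeric vector of delta values (per mil), each
#'   strictly greater than -1000.
#' @param r_standard 15N/14N ratio of the standard (air N2 by default).
#' @return Atom fraction(s).
#' @examples
#' delta15N_to_atom_fraction(0)  # 0.0036630
#' @export
delta15N_to_atom_fraction <- function(delta_permil,
                                      r_standard = isotope_constants[["r_std_15N"]]) {
  if (any(!is.finite(delta_permil)) || any(delta_permil <= -1000)) {
    stop("delta_permil must be finite and > -1000 per mil")
  }
  r <- (delta_permil / 1000 + 1) * r_standard
  r / (1 + r)
}

#' Convert a 15N atom fraction to delta notation
#'
#' Inverse of [delta15N_to_atom_fraction()]; used when the generator
#' back-computes measured delta values from planted tracer excess.
#'
#' @param x Atom fraction(s) in `(0, 1)`.
#' @param r_standard Standard 15N/14N ratio.
#' @return Delta value(s) in per mil.
#' @export
atom_fraction_to_delta15N <- function(x,
                                      r_standard = isotope_constants[["r_std_15N"]]) {
  stopifnot(all(x > 0 & x < 1))
  (x / (1 - x) / r_standard - 1) * 1000
}

#' Labeling context for an isotope-amendment incubation
#'
#' Bundles the bookkeeping needed to compute the labeled atom fraction of
#' the substrate pool: amendment and ambient concentrations (of molecules),
#' isotopic purity of the label, the natural atom fraction of the ambient
#' pool, the incubation duration and the number of atoms of the traced
#' element per substrate molecule (urea N = 2, ammonium N = 1, urea C = 1).
#'
#' @param amendment_nM Amendment concentration in nmol molecules per liter.
#' @param label_purity Atom fraction of the heavy isotope in the label.
#' @param ambient_nM Ambient substrate concentration, same units.
#' @param natural_atom_fraction Heavy-isotope atom fraction of the ambient
#'   pool (defaults to natural 15N abundance).
#' @param incubation_h Incubation duration in hours.
#' @param n_per_molecule Atoms of the traced element per molecule.
#' @return A list of class `labeling_context`.
#' @examples
#' ctx <- labeling_context(amendment_nM = 50, label_purity = 0.98,
#'                         ambient_nM = 50, n_per_molecule = 1)
#' substrate_label_fraction(ctx)  # ~0.4918
#' @export
labeling_context <- function(amendment_nM = 50,
                             label_purity = 0.98,
                             ambient_nM = 0,
                             natural_atom_fraction = isotope_constants[["x_nat_15N"]],
                             incubation_h = 72,
                             n_per_molecule = 1) {
  stopifnot(
    amendment_nM >= 0, ambient_nM >= 0,
    label_purity >= 0, label_purity <= 1,
    natural_atom_fraction >= 0, natural_atom_fraction <= 1,
    incubation_h > 0, n_per_molecule >= 1
  )
  structure(
    list(
      amendment_nM = amendment_nM, label_purity = label_purity,
      ambient_nM = ambient_nM,
      natural_atom_fraction = natural_atom_fraction,
      incubation_h = incubation_h, n_per_molecule = n_per_molecule
    ),
    class = "labeling_context"
  )
}

#' Labeled atom fraction of the substrate pool after amendment
#'
#' Pool-dilution mass balance: concentrations are converted to element
#' atoms (molecules x atoms per molecule) and the amendment at its isotopic
#' purity is mixed with the ambient pool at natural abundance.
#'
#' @param ctx A [labeling_context()].
#' @return Atom fraction of the mixed substrate pool.
#' @export
substrate_label_fraction <- function(ctx) {
  stopifnot(inherits(ctx, "labeling_context"))
  amend_atoms <- ctx$amendment_nM * ctx$n_per_molecule
  ambient_atoms <- ctx$ambient_nM * ctx$n_per_molecule
  total <- amend_atoms + ambient_atoms
  if (total <= 0) stop("total substrate pool is zero; label fraction undefined")
  (amend_atoms * ctx$label_purity + ambient_atoms * ctx$natural_atom_fraction) /
    total
}

# shared argument check
check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be finite and >= 0", name))
  }
  invisible(x)
}
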