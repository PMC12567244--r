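#' Conceptual-DFT global reactivity descriptors from frontier-orbital energies
#'
#' Derives the standard conceptual-DFT reactivity set from a compound's
#' HOMO/LUMO energies under the Koopmans mapping (ionization potential
#' \eqn{I = -E_{HOMO}}, electron affinity \eqn{A = -E_{LUMO}}):
#' gap \eqn{\Delta E = E_{LUMO} - E_{HOMO}}, electronegativity
#' \eqn{\chi = (I + A)/2}, chemical potential \eqn{\mu = -\chi}, hardness
#' \eqn{\eta = \Delta E / 2}, softness \eqn{S}, electrophilicity index
#' \eqn{\omega}, maximal charge acceptance \eqn{\Delta N_{max} = \chi/\eta},
#' and the inverse gap \eqn{1/\Delta E}.
#'
#' Two descriptor conventions are supported. The default, `"paper"`, uses
#' \eqn{S = 1/\eta} and \eqn{\omega = \chi^2/\eta}; the `"textbook"`
#' convention uses \eqn{S = 1/(2\eta)} and \eqn{\omega = \chi^2/(2\eta)}.
#' Both agree on gap, \eqn{\chi}, \eqn{\mu}, \eqn{\eta} and
#' \eqn{\Delta N_{max}}.
#'
#' Energies are treated as being in one consistent but opaque unit system:
#' no unit conversion is performed, and every energy-valued descriptor is
#' reported in the input unit (inverse-energy descriptors in its reciprocal).
#'
#' @param e_homo Numeric scalar, HOMO energy (typically negative).
#' @param e_lumo Numeric scalar, LUMO energy, strictly greater than `e_homo`.
#' @param convention `"paper"` (default) or `"textbook"`; see Details.
#'
#' @return A one-row `data.frame` with columns `gap`, `ionization_potential`,
#'   `electron_affinity`, `electronegativity`, `chemical_potential`,
#'   `hardness`, `softness`, `electrophilicity`, `delta_n_max`, `inv_gap`.
#'
#' @examples
#' # widest-gap compound of a 16-member pyridopyrimidine cohort:
#' d <- compute_descriptors(e_homo = -0.2744, e_lumo = -0.1680)
#' round(d$softness, 2)          # 18.80
#' round(d$electrophilicity, 2)  # 0.92
#' @export
compute_descriptors <- function(e_homo, e_lumo,
                                convention = c("paper", "textbook")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(e_homo), is.numeric(e_lumo),
            length(e_homo) == length(e_lumo), length(e_homo) >= 1L)
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("orbital energies must be finite", call. = FALSE)
  if (any(e_homo >= e_lumo))
    stop("degenerate orbital gap: e_homo must be strictly below e_lumo ",
         "(got e_homo = ", e_homo[e_homo >= e_lumo][1L],
         ", e_lumo = ", e_lumo[e_homo >= e_lumo][1L], ")", call. = FALSE)

  gap <- e_lumo - e_homo
  ip  <- -e_homo
  ea  <- -e_lumo
  chi <- (ip + ea) / 2
  eta <- gap / 2
  # softness as 1/(gap/2): bit-identical to 2 * (1/gap) because scaling by
  # a power of two is exact in binary floating point
  if (convention == "paper") {
    softness <- 1 / eta
    omega    <- chi^2 / eta
  } else {
    softness <- 1 / (2 * eta)
    omega    <- chi^2 / (2 * eta)
  }
  data.frame(
    gap                  = gap,
    ionization_potential = ip,
    electron_affinity    = ea,
    electronegativity    = chi,
    chemical_potential   = -chi,
    hardness             = eta,
    softness             = softness,
    electrophilicity     = omega,
    delta_n_max          = chi / eta,
    inv_gap              = 1 / gap
  )
}

#' Descriptor table for a cohort of compounds
#'
#' Batch form of [compute_descriptors()] over a cohort table of
#' frontier-orbital energies, preserving input row order.
#'
#' @param cohort `data.frame` with columns `compound_id`, `e_homo`, `e_lumo`
#'   (an optional `unit` column is carried through untouched).
#' @param convention Passed to [compute_descriptors()].
#'
#' @return A `data.frame` with `compound_id` followed by all descriptor
#'   columns, one row per input compound, in input order.
#' @export
compute_descriptor_table <- function(cohort, convention = c("paper", "textbook")) {
  convention <- match.arg(convention)
  req <- c("compound_id", "e_homo", "e_lumo")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ids <- as.character(cohort$compound_id)
  if (any(is.na(ids) | !nzchar(ids)))
    stop("compound_id must be non-empty for every row", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate compound_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (nrow(cohort) == 0L) {
    empty <- compute_descriptors(-1, 0)[0L, ]
    return(cbind(data.frame(compound_id = character(0)), empty))
  }
  bad <- which(cohort$e_homo >= cohort$e_lumo)
  if (length(bad))
    stop("degenerate orbital gap for compound ", ids[bad[1L]],
         " (e_homo >= e_lumo)", call. = FALSE)
  desc <- compute_descriptors(cohort$e_homo, cohort$e_lumo, convention)
  out <- cbind(data.frame(compound_id = ids, stringsAsFactors = FALSE), desc)
  if ("unit" %in% names(cohort)) out$unit <- cohort$unit
  rownames(out) <- NULL
  out
}

#' Charge transfer toward a reference partner system
#'
#' Fraction of electronic charge transferred between a compound and an
#' explicit reference system, \eqn{\Delta N = (\chi_{ref} - \chi) /
#' (2(\eta_{ref} + \eta))}. The reference electronegativity and hardness
#' must be supplied by the caller; no default partner is assumed, and this
#' quantity is not part of the composite scoring pipeline. The sign follows
#' the usual convention: positive \eqn{\Delta N} means the compound accepts
#' charge from the reference.
#'
#' @param electronegativity,hardness Compound descriptors (e.g. from
#'   [compute_descriptors()]).
#' @param chi_ref,eta_ref Reference-system electronegativity and hardness,
#'   in the same unit system; `eta_ref` must be positive.
#' @return Numeric, the charge-transfer fraction.
#' @export
charge_transfer <- function(electronegativity, hardness, chi_ref, eta_ref) {
  stopifnot(is.numeric(chi_ref), is.numeric(eta_ref))
  if (any(!is.finite(chi_ref)) || any(!is.finite(eta_ref)) || any(eta_ref <= 0))
    stop("reference hardness must be finite and positive", call. = FALSE)
  if (any(hardness <= 0))
    stop("compound hardness must be positive", call. = FALSE)
  (chi_ref - electronegativity) / (2 * (eta_ref + hardness))
}
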