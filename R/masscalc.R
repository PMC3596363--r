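# Peptide mass and anion-adduct m/z computation for negative-mode ESI-MS
# assignments.

# CODATA/IUPAC atomic masses (Da).
ATOMIC_MASS <- list(
  monoisotopic = c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069, P = 30.97376151),
  average = c(H = 1.008, C = 12.011, N = 14.007,
              O = 15.999, S = 32.06, P = 30.974)
)
ELECTRON_MASS <- 0.000548579909  # Da

formula_mass <- function(counts, mode) {
  am <- ATOMIC_MASS[[mode]]
  sum(counts * am[names(counts)])
}

#' Peptide mass from sequence and caps
#'
#' Sums residue (chain-unit) masses plus one water, then applies the cap
#' deltas: N-acetyl adds C2H2O; the C-amide replaces the terminal OH
#' with NH2 (net -O +N +H, -0.98402 Da monoisotopic).
#'
#' @param peptide a `cann_peptide` (see [peptide_model()]).
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(peptide, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (!length(peptide$residues)) stop("peptide has no residues")
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (r in peptide$residues) {
    spec <- residue_spec(r)  # errors on unknown codes
    counts <- counts + RESIDUE_TABLE[[spec$code]]$formula
  }
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + water
  if (peptide$n_cap == "acetyl") {
    counts <- counts + c(C = 2, H = 2, N = 0, O = 1, S = 0)
  }
  if (peptide$c_cap == "amide") {
    counts <- counts + c(C = 0, H = 1, N = 1, O = -1, S = 0)
  }
  formula_mass(counts, mode)
}

# Monoisotopic masses of the intact anions.
anion_mass <- function(kind = c("sulfate", "phosphate"),
                       mode = "monoisotopic") {
  kind <- match.arg(kind)
  if (kind == "sulfate") {
    formula_mass(c(S = 1, O = 4), mode)
  } else {
    formula_mass(c(H = 1, P = 1, O = 4), mode)
  }
}

#' m/z of a peptide-anion adduct in negative mode
#'
#' Models the observed species as the neutral peptide plus the intact
#' dianion, `[M + anion]^z-`:
#' `m/z = (M_peptide + M_anion + |z| m_e) / |z|`, using monoisotopic
#' masses (SO4 95.9517 Da, HPO4 95.9612 Da).  The isotopic peak spacing
#' is `1/|z|`.
#'
#' @param peptide a `cann_peptide`.
#' @param anion `"sulfate"`, `"phosphate"`, or `NULL` for the bare
#'   peptide.
#' @param charge negative integer charge state (e.g. -2).
#' @return list with `mz`, `spacing`, `mass_peptide`, `mass_anion`,
#'   `charge`.
#' @export
adduct_mz <- function(peptide, anion = "sulfate", charge = -2) {
  if (!is.numeric(charge) || charge == 0 || charge != round(charge)) {
    stop("charge must be a non-zero (negative) integer")
  }
  z <- abs(charge)
  mp <- peptide_mass(peptide, "monoisotopic")
  ma <- if (is.null(anion)) 0 else anion_mass(anion)
  list(mz = (mp + ma + z * ELECTRON_MASS) / z,
       spacing = 1 / z,
       mass_peptide = mp,
       mass_anion = ma,
       charge = -z)
}

#' Small m/z table for a peptide and its anion adducts
#'
#' @param peptide_id a registry peptide id (see [peptide_model()]).
#' @param anion `"sulfate"`, `"phosphate"` or `NULL`.
#' @param charge negative integer charge state.
#' @return data frame with species, charge, m/z and isotopic spacing.
#' @export
mz_table <- function(peptide_id, anion = "sulfate", charge = -2) {
  pep <- peptide_model(peptide_id)
  if (is.null(anion)) {
    m <- peptide_mass(pep)
    return(data.frame(species = pep$id, z = 0, mz = m, spacing = NA_real_))
  }
  a <- adduct_mz(pep, anion, charge)
  data.frame(species = sprintf("[%s + %s]%d-", pep$id,
                               if (anion == "sulfate") "SO4" else "HPO4",
                               abs(charge)),
             z = a$charge, mz = a$mz, spacing = a$spacing)
}
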