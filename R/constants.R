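# Physical constants and lookup tables shared across modules.

#' Physical constants used throughout the package
#'
#' `hdx_constants()` returns the fixed physical constants the package relies
#' on: the deuterium-hydrogen mass difference added per exchanged amide, the
#' proton mass used for m/z conversion, and the probe radius convention for
#' solvent-accessible surface area.
#'
#' @return A named list with elements `delta_mass_D` (Da), `proton_mass` (Da)
#'   and `default_probe_radius` (Angstrom).
#' @export
#' @examples
#' hdx_constants()$delta_mass_D
hdx_constants <- function() {
  list(
    delta_mass_D = DELTA_MASS_D,
    proton_mass = PROTON_MASS,
    default_probe_radius = 1.4
  )
}

# mass added when an amide H is replaced by D
DELTA_MASS_D <- 1.006277
PROTON_MASS <- 1.007276

# stable-isotope masses (Da) and natural abundances per element; `k` is the
# nominal neutron excess over the lightest isotope, the binning unit for
# envelope convolution
ISOTOPE_TABLE <- list(
  C = data.frame(
    k = c(0L, 1L),
    mass = c(12.0000000, 13.0033548378),
    abundance = c(0.9893, 0.0107)
  ),
  H = data.frame(
    k = c(0L, 1L),
    mass = c(1.0078250319, 2.0141017780),
    abundance = c(0.999885, 0.000115)
  ),
  N = data.frame(
    k = c(0L, 1L),
    mass = c(14.0030740052, 15.0001088984),
    abundance = c(0.99632, 0.00368)
  ),
  O = data.frame(
    k = c(0L, 1L, 2L),
    mass = c(15.9949146221, 16.9991315000, 17.9991604000),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  S = data.frame(
    k = c(0L, 1L, 2L, 4L),
    mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
    abundance = c(0.9493, 0.0076, 0.0429, 0.0002)
  )
)

# elemental composition of amino-acid residues as incorporated in a chain
# (free amino acid minus water); full peptide = sum of residues + H2O
AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

WATER_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# side-chain hydrophobicity classification used for interface burial
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "P", "Y")

# three-letter to one-letter residue codes (PDB ingestion)
AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# van der Waals radii (Angstrom) for heavy atoms; fallback used for anything
# else encountered in HETATM records
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_RADIUS_DEFAULT <- 1.70

#' Monoisotopic mass of a peptide
#'
#' Computed from the elemental composition of the residue chain plus one
#' water, using the lightest isotope of each element.
#'
#' @param sequence Peptide sequence, one-letter amino-acid codes.
#' @return Monoisotopic neutral mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("SASEL")
monoisotopic_mass <- function(sequence) {
  vapply(sequence, function(s) {
    comp <- peptide_formula(s)
    sum(vapply(names(comp), function(el) {
      comp[[el]] * ISOTOPE_TABLE[[el]]$mass[1]
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# elemental composition (C,H,N,O,S counts) of a peptide chain + water
peptide_formula <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(AA_FORMULA))
  if (length(bad) > 0) {
    abort(paste0("unknown residue letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  comp <- Reduce(`+`, AA_FORMULA[aa], accumulate = FALSE) + WATER_FORMULA
  as.list(comp)
}

#' Convert neutral mass to m/z and back
#'
#' Uses the proton mass 1.007276 Da and the recorded charge.
#'
#' @param mass Neutral mass (Da).
#' @param mz Mass-to-charge ratio.
#' @param charge Positive integer charge state.
#' @return `mass_to_mz()` returns m/z; `mz_to_mass()` returns neutral mass.
#' @export
mass_to_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * PROTON_MASS) / charge
}

#' @rdname mass_to_mz
#' @export
mz_to_mass <- function(mz, charge) {
  stopifnot(all(charge >= 1))
  mz * charge - charge * PROTON_MASS
}

#' Classify residues as hydrophobic
#'
#' The default classification treats A, V, L, I, M, F, W, P and Y as
#' hydrophobic, i.e. aliphatic and aromatic side chains plus proline,
#' matching the treatment of exposed Trp/Val/Leu/Pro stretches in
#' interface analyses.
#'
#' @param residue Character vector of one-letter codes.
#' @param hydrophobic_set Character vector defining the classification.
#' @return Logical vector.
#' @export
#' @examples
#' is_hydrophobic(c("V", "L", "P", "S"))
is_hydrophobic <- function(residue, hydrophobic_set = HYDROPHOBIC_AA) {
  toupper(residue) %in% hydrophobic_set
}
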