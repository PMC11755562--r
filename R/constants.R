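#' Residue-level constant tables
#'
#' The twenty standard amino acids and the per-residue constants used by the
#' descriptor functions: Expasy average residue masses (Da), Kyte-Doolittle
#' hydropathy, Bjellqvist ionizable-group pKa values (with residue-specific
#' N-terminal amine pKas as used by ProtParam), the Guruprasad dipeptide
#' instability weight matrix (DIWV), Ikai's aliphatic-index coefficients,
#' the aromatic residue set F/H/W/Y, the hydrophilic residue set used by the
#' Bachem-style hydrophilic percentage, and the per-residue net-charge
#' increments at pH 7.
#'
#' @return A named list with components `residues`, `average_mass`,
#'   `water_mass`, `hydropathy`, `pka_pos`, `pka_neg`, `pka_nterm`,
#'   `pka_cterm`, `diwv`, `aliphatic_coeffs`, `aromatic_set`,
#'   `hydrophilic_set`, `charge_increments`.
#' @examples
#' rc <- residue_constants()
#' rc$average_mass[["G"]]
#' rc$aliphatic_coeffs
#' @export
residue_constants <- function() .pia_constants

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Expasy average residue masses (amino acid minus water), Da
.aa_mass <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

# Kyte & Doolittle hydropathy scale
.aa_kd <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
  M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Guruprasad dipeptide instability weights; rows = first residue, columns =
# second residue, residue order ACDEFGHIKLMNPQRSTVWY.  K->Q is 24.68 as in
# ProtParam output (some redistributions carry 24.64 in that cell).
.diwv <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.68, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA20, AA20))

# Bjellqvist ionizable-group pKas.  The N-terminal amine pKa depends on the
# first residue (ProtParam convention); all other first residues use 7.50.
.pka_pos <- c(K = 10.0, R = 12.0, H = 5.98)
.pka_neg <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.pka_nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70)
.pka_nterm_default <- 7.50
.pka_cterm <- 3.55

.pia_constants <- list(
  residues = AA20,
  average_mass = .aa_mass,
  water_mass = 18.01524,
  hydropathy = .aa_kd,
  pka_pos = .pka_pos,
  pka_neg = .pka_neg,
  pka_nterm = .pka_nterm,
  pka_nterm_default = .pka_nterm_default,
  pka_cterm = .pka_cterm,
  diwv = .diwv,
  aliphatic_coeffs = c(a = 2.9, b = 3.9),
  aromatic_set = c("F", "H", "W", "Y"),
  hydrophilic_set = c("D", "E", "K", "R", "N", "Q", "S"),
  charge_increments = c(H = 0.09, C = -0.05)
)

#' Round half away from zero
#'
#' The rounding used by the printed descriptor tables (R's `round()` rounds
#' half to even).  Guarded against binary representation error.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

split_residues <- function(sequence) strsplit(sequence, "")[[1]]

check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop(what, " must contain at least one residue", call. = FALSE)
  bad <- setdiff(unique(split_residues(sequence)), AA20)
  if (length(bad) > 0L)
    stop("non-standard residue letter(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  sequence
}
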