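#' Average molecular weight of a peptide
#'
#' Sum of Expasy average residue masses plus one water (free termini).
#' A single residue therefore gives the mass of the free amino acid.
#'
#' @param sequence residue string (20 standard letters).
#' @return Mass in Da (full precision; tables report 2 decimal places).
#' @examples
#' molecular_weight("G")  # glycine, 75.07
#' @export
molecular_weight <- function(sequence) {
  sequence <- check_sequence(sequence)
  rc <- .pia_constants
  sum(rc$average_mass[split_residues(sequence)]) + rc$water_mass
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues; by construction it lies
#' within the scale range \[-4.5, 4.5\].
#'
#' @inheritParams molecular_weight
#' @return Dimensionless value (tables report 3 decimal places).
#' @export
gravy <- function(sequence) {
  sequence <- check_sequence(sequence)
  mean(.pia_constants$hydropathy[split_residues(sequence)])
}

#' Net charge of a peptide at a given pH (Henderson-Hasselbalch)
#'
#' Positive groups: N-terminal amine (residue-specific pKa), Lys, Arg, His.
#' Negative groups: C-terminal carboxyl, Asp, Glu, Cys, Tyr.
#'
#' @inheritParams molecular_weight
#' @param ph pH at which to evaluate the charge.
#' @return Net charge in elementary charges.
#' @export
charge_at_ph <- function(sequence, ph) {
  sequence <- check_sequence(sequence)
  rc <- .pia_constants
  res <- split_residues(sequence)
  nterm_pk <- rc$pka_nterm[res[1]]
  if (is.na(nterm_pk)) nterm_pk <- rc$pka_nterm_default
  q <- 1 / (1 + 10^(ph - nterm_pk)) - 1 / (1 + 10^(rc$pka_cterm - ph))
  for (aa in names(rc$pka_pos))
    q <- q + sum(res == aa) / (1 + 10^(ph - rc$pka_pos[[aa]]))
  for (aa in names(rc$pka_neg))
    q <- q - sum(res == aa) / (1 + 10^(rc$pka_neg[[aa]] - ph))
  unname(q)
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge crosses zero, found by
#' bisection on \[0, 14\] starting from pH 7 and terminating when both sides
#' of the bracket are within 1e-4 (the iteration used by the ProtParam-style
#' calculators, whose reported value is the final bracket point).  The free
#' N- and C-termini guarantee a zero crossing for any sequence.
#'
#' @inheritParams molecular_weight
#' @param eps bracket half-width at which the bisection terminates.
#' @return pI in pH units (tables report 2 decimal places).
#' @examples
#' isoelectric_point("SNKKQSNRLTEQHK")  # 10.29
#' @export
isoelectric_point <- function(sequence, eps = 1e-4) {
  sequence <- check_sequence(sequence)
  lo <- 0; hi <- 14; ph <- 7
  repeat {
    if (charge_at_ph(sequence, ph) > 0) {
      lo <- ph; ph <- ph + (hi - ph) / 2
    } else {
      hi <- ph; ph <- ph - (ph - lo) / 2
    }
    if ((ph - lo) < eps && (hi - ph) < eps) return(ph)
  }
}

#' Aliphatic index
#'
#' Ikai's relative volume of aliphatic side chains:
#' X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu)) with X in mole percent.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless value (tables report 2 decimal places).
#' @export
aliphatic_index <- function(sequence) {
  sequence <- check_sequence(sequence)
  res <- split_residues(sequence)
  co <- .pia_constants$aliphatic_coeffs
  100 * (sum(res == "A") + co[["a"]] * sum(res == "V") +
         co[["b"]] * (sum(res == "I") + sum(res == "L"))) / length(res)
}

#' Instability index
#'
#' Guruprasad dipeptide statistic: (10 / L) * sum of DIWV weights over the
#' L - 1 adjacent residue pairs.  Unlike the other descriptors it depends on
#' residue order, so it changes under composition-preserving shuffles.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless value (tables report 2 decimal places).
#' @export
instability_index <- function(sequence) {
  sequence <- check_sequence(sequence)
  res <- split_residues(sequence)
  L <- length(res)
  if (L < 2L) stop("instability index requires at least 2 residues",
                   call. = FALSE)
  w <- .pia_constants$diwv[cbind(res[-L], res[-1])]
  10 * sum(w) / L
}

#' Number of aromatic side chains
#'
#' Count of residues in \{F, H, W, Y\}.
#'
#' @inheritParams molecular_weight
#' @return Integer count.
#' @export
aromatic_count <- function(sequence) {
  sequence <- check_sequence(sequence)
  sum(split_residues(sequence) %in% .pia_constants$aromatic_set)
}

#' Percentage of hydrophilic residues
#'
#' Share of residues in \{D, E, K, R, N, Q, S\} (the set used by the Bachem
#' peptide calculator), reported as a percentage rounded to the nearest
#' integer.
#'
#' @inheritParams molecular_weight
#' @return Integer percentage in \[0, 100\].
#' @export
hydrophilic_percent <- function(sequence) {
  sequence <- check_sequence(sequence)
  res <- split_residues(sequence)
  round_half_up(100 * sum(res %in% .pia_constants$hydrophilic_set) /
                  length(res))
}

#' Net charge at pH 7
#'
#' Default model (`"bachem"`) reproduces the Bachem calculator column of the
#' descriptor tables: +1 per Lys/Arg and the N-terminus, -1 per Asp/Glu and
#' the C-terminus, +0.09 per His, -0.05 per Cys.  `"pka"` evaluates the
#' Henderson-Hasselbalch charge at pH 7 instead.
#'
#' @inheritParams molecular_weight
#' @param model `"bachem"` (table-matching increments, default) or `"pka"`.
#' @return Charge in elementary charges (tables report 2 decimal places).
#' @export
net_charge_ph7 <- function(sequence, model = c("bachem", "pka")) {
  model <- match.arg(model)
  sequence <- check_sequence(sequence)
  if (model == "pka") return(charge_at_ph(sequence, 7))
  res <- split_residues(sequence)
  inc <- .pia_constants$charge_increments
  sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")) +
    inc[["H"]] * sum(res == "H") + inc[["C"]] * sum(res == "C")
}

#' Descriptor table for a peptide panel
#'
#' Computes the nine per-peptide physicochemical descriptors for every
#' peptide of a panel.  Values are rounded as the printed tables round them
#' (MW, pI, aliphatic index, instability index and net charge to 2 decimal
#' places; GRAVY to 3; hydrophilic percentage to the nearest integer) unless
#' `raw = TRUE`.
#'
#' @param panel a [pia_panel()] or data.frame with columns `id`, `sequence`.
#' @param charge_model passed to [net_charge_ph7()].
#' @param raw if TRUE, return full-precision values.
#' @return data.frame with one row per peptide: `peptide_id`, `length`,
#'   `mw`, `pi`, `gravy`, `ai`, `hydrophilic_pct`, `aromatic_n`,
#'   `instability`, `net_charge`.
#' @export
describe_panel <- function(panel, charge_model = c("bachem", "pka"),
                           raw = FALSE) {
  charge_model <- match.arg(charge_model)
  stopifnot(is.data.frame(panel), all(c("id", "sequence") %in% names(panel)))
  s <- as.character(panel$sequence)
  out <- data.frame(
    peptide_id = as.character(panel$id),
    length = nchar(s),
    mw = vapply(s, molecular_weight, 0),
    pi = vapply(s, isoelectric_point, 0),
    gravy = vapply(s, gravy, 0),
    ai = vapply(s, aliphatic_index, 0),
    hydrophilic_pct = vapply(s, hydrophilic_percent, 0),
    aromatic_n = vapply(s, aromatic_count, 0L),
    instability = vapply(s, instability_index, 0),
    net_charge = vapply(s, net_charge_ph7, 0, model = charge_model),
    row.names = NULL
  )
  if (!raw) {
    for (col in c("mw", "pi", "ai", "instability", "net_charge"))
      out[[col]] <- round_half_up(out[[col]], 2)
    out$gravy <- round_half_up(out$gravy, 3)
  }
  out
}
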