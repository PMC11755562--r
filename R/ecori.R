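#' The reconstructed EcoRI chain (M1-K277)
#'
#' The 277-residue EcoRI protein chain, reconstructed by stitching the 25
#' overlapping original blocking peptides and prepending the initiator M at
#' position 1 (the initiator is removed after translation but is counted in
#' the numbering).  The chain is a reconstruction, not a database download;
#' it is packaged as a FASTA fixture and can be re-derived at any time with
#' [stitch_chain()] from [ecori_windows()].
#'
#' @return A [protein_chain()] of length 277.
#' @examples
#' nchar(ecori_chain()$sequence)  # 277
#' @export
ecori_chain <- function() {
  read_fasta(pia_extdata("ecori_chain_reconstructed.fasta"))[[1]]
}

#' Published blocking-peptide tables for EcoRI
#'
#' `ecori_golden()` returns the packaged table of all 85 blocking peptides
#' (id, category, parent, printed interval, sequence) together with the nine
#' printed physicochemical descriptor values used as golden references.
#' `ecori_windows()` returns the 25 original windows (id, start, end,
#' sequence).  `ecori_anomalies()` returns the whitelist of printed cells
#' that are internally inconsistent (value scrambles between adjacent rows,
#' composition-impossible pI entries, manual aromatic-count slips) and are
#' therefore excluded from golden comparisons.
#'
#' @return data.frame (see description).
#' @export
ecori_golden <- function() read_fixture_tsv("ecori_panel_golden.tsv")

#' @rdname ecori_golden
#' @export
ecori_windows <- function() {
  g <- ecori_golden()
  g[g$category == "original", c("id", "start", "end", "sequence")]
}

#' @rdname ecori_golden
#' @export
ecori_anomalies <- function() read_fixture_tsv("ecori_golden_anomalies.tsv")

# windows with the one width-inconsistent printed interval (BP22) recomputed
# by locating its sequence on the chain
ecori_windows_corrected <- function(chain = ecori_chain()) {
  w <- ecori_windows()
  for (i in seq_len(nrow(w))) {
    if (w$end[i] - w$start[i] + 1L != nchar(w$sequence[i])) {
      at <- regexpr(w$sequence[i], chain$sequence, fixed = TRUE)
      if (at < 0) stop("window sequence ", w$id[i], " not on chain",
                       call. = FALSE)
      w$start[i] <- as.integer(at) + chain$first_pos - 1L
      w$end[i] <- w$start[i] + nchar(w$sequence[i]) - 1L
    }
  }
  w
}

#' Build the complete published EcoRI blocking-peptide panel
#'
#' Reassembles the 85-peptide panel from the design rules: 25 original
#' window peptides, 22 staggered junction peptides (midpoint rule, printed
#' lengths), the BP19.5 deletion pair, 30 short N/M/C peptides for the 10
#' short-peptide parents (with the packaged offset overrides where the
#' published rows deviate from the rule), and the 6 randomized peptides
#' (packaged verbatim: the original randomization was drawn by hand and is
#' not reproducible from a seed).  The result is verified against the
#' packaged golden sequences; any mismatch is an assembly error listing the
#' differing ids.
#'
#' @param chain the target chain (default [ecori_chain()]).
#' @return A [pia_panel()] of 85 peptides (79 endogenous + 6 randomized).
#' @examples
#' p <- build_paper_panel()
#' table(p$category)
#' @export
build_paper_panel <- function(chain = ecori_chain()) {
  golden <- ecori_golden()
  windows <- ecori_windows_corrected(chain)

  orig <- design_original(chain, windows)

  stag_gold <- golden[golden$category == "staggered", ]
  lengths <- stats::setNames(nchar(stag_gold$sequence), stag_gold$id)
  stag <- design_staggered(chain, windows, lengths = lengths)
  # rows where the published designer applied the rule to a typo'd printed
  # coordinate: replace by the packaged sequence, located on the chain
  sov <- read_fixture_tsv("ecori_staggered_overrides.tsv")
  for (i in seq_len(nrow(sov))) {
    at <- as.integer(regexpr(sov$sequence[i], chain$sequence, fixed = TRUE)) +
      chain$first_pos - 1L
    j <- match(sov$id[i], stag$id)
    message("staggered override for ", sov$id[i], ": ", stag$start[j], "-",
            stag$end[j], " replaced by ", at, "-",
            at + nchar(sov$sequence[i]) - 1L)
    stag$start[j] <- at
    stag$end[j] <- at + nchar(sov$sequence[i]) - 1L
    stag$sequence[j] <- sov$sequence[i]
  }

  dele <- design_deletions(stag[stag$id == "BP19.5", ], sub_len = 6L,
                           overlap = 2L)

  short_parents <- unique(golden$parent_id[startsWith(golden$category,
                                                      "short")])
  shrt <- design_short(chain, orig[orig$id %in% short_parents, ], k = 6L,
                       overrides = read_fixture_tsv("ecori_short_overrides.tsv"))

  rand_gold <- golden[golden$category == "randomized", ]
  rand <- pia_panel(data.frame(
    id = rand_gold$id, category = "randomized",
    start = NA_integer_, end = NA_integer_,
    sequence = rand_gold$sequence, parent_id = rand_gold$parent_id))

  panel <- pia_panel(rbind(as.data.frame(orig), as.data.frame(stag),
                           as.data.frame(dele), as.data.frame(shrt),
                           as.data.frame(rand)),
                     provenance = list(design = "paper_panel"))

  # golden-sequence gate
  m <- match(golden$id, panel$id)
  if (anyNA(m))
    stop("assembly error: missing peptides ",
         paste(golden$id[is.na(m)], collapse = ", "), call. = FALSE)
  diff <- golden$id[panel$sequence[m] != golden$sequence]
  if (length(diff) > 0L)
    stop("assembly error: sequence mismatch for ",
         paste(diff, collapse = ", "), call. = FALSE)
  panel
}
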