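#' Protein chain with 1-based numbering
#'
#' A minimal container for a single protein chain.  Numbering is 1-based and
#' includes the initiator residue: for EcoRI, position 1 is M1 even though
#' the initiator methionine is removed after translation, so the first
#' blocking peptide starts at position 2.
#'
#' @param name chain identifier.
#' @param sequence one-letter residue string (standard 20 residues only;
#'   lower case is accepted and uppercased).
#' @param first_pos chain position of the first residue in `sequence`
#'   (default 1; a partially reconstructed chain may start later).
#' @return An object of class `pia_chain` with fields `name`, `sequence` and
#'   `first_pos`.
#' @examples
#' ch <- protein_chain("toy", "MSNKKQ")
#' nchar(ch$sequence)
#' @export
protein_chain <- function(name, sequence, first_pos = 1L) {
  sequence <- check_sequence(sequence, paste0("sequence of '", name, "'"))
  stopifnot(length(first_pos) == 1L, first_pos >= 1L)
  structure(list(name = as.character(name), sequence = sequence,
                 first_pos = as.integer(first_pos)),
            class = "pia_chain")
}

#' @export
print.pia_chain <- function(x, ...) {
  last <- x$first_pos + nchar(x$sequence) - 1L
  cat("<pia_chain> ", x$name, ": ", nchar(x$sequence), " residues (positions ",
      x$first_pos, "-", last, ")\n", sep = "")
  invisible(x)
}

#' @export
length.pia_chain <- function(x) nchar(x$sequence)

#' Extract a 1-based inclusive subsequence of a chain
#'
#' @param chain a [protein_chain()].
#' @param start,end 1-based inclusive residue positions (in chain numbering,
#'   which includes the initiator residue).
#' @return Residue string of length `end - start + 1`.
#' @export
chain_subseq <- function(chain, start, end) {
  stopifnot(inherits(chain, "pia_chain"))
  last <- chain$first_pos + nchar(chain$sequence) - 1L
  if (!(start >= chain$first_pos && start <= end && end <= last))
    stop("interval [", start, ", ", end, "] out of range for chain spanning ",
         chain$first_pos, "-", last, call. = FALSE)
  off <- chain$first_pos - 1L
  substr(chain$sequence, start - off, end - off)
}

#' Read protein chains from a FASTA file
#'
#' Records are returned in file order.  Sequences are uppercased and must use
#' the 20 standard residue letters; anything else is a format error naming
#' the offending record.
#'
#' @param path path to a FASTA file.
#' @return A list of [protein_chain()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  lapply(seq_along(set), function(i) {
    nm <- sub("\\s.*$", "", names(set)[i])
    protein_chain(nm, as.character(set[[i]]))
  })
}

#' Write protein chains to a FASTA file
#'
#' @param chains a [protein_chain()] or list of them.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path, width = 60L) {
  if (inherits(chains, "pia_chain")) chains <- list(chains)
  seqs <- Biostrings::BStringSet(vapply(chains, `[[`, "", "sequence"))
  names(seqs) <- vapply(chains, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Reconstruct a chain from overlapping positioned peptides
#'
#' Assembles the unique chain consistent with a set of peptides given as
#' 1-based inclusive intervals plus sequences.  Where intervals overlap the
#' sequences must agree letter-for-letter; a disagreement is a conflict error
#' naming the position and the two letters.  Peptides whose printed interval
#' width does not equal their sequence length are treated as
#' sequence-authoritative: they are placed afterwards at the unique position
#' consistent with the already-assembled residues (a warning reports the
#' recomputed interval).  Positions covered by no peptide are filled from
#' `known_prefix` (anchored at position 1); any remaining gap is an error
#' listing the missing positions.
#'
#' @param peptides data.frame with columns `start`, `end`, `sequence`
#'   (optionally `id` for error messages).
#' @param known_prefix optional sequence anchored at position 1 used to fill
#'   residues not covered by any peptide (e.g. the initiator "M").
#' @param name name for the resulting chain.
#' @return A [protein_chain()].
#' @examples
#' peps <- data.frame(start = c(2, 12), end = c(15, 23),
#'   sequence = c("SNKKQSNRLTEQHK", "EQHKLSQGVIGI"))
#' stitch_chain(peps, known_prefix = "M")
#' @export
stitch_chain <- function(peptides, known_prefix = NULL, name = "stitched") {
  stopifnot(is.data.frame(peptides),
            all(c("start", "end", "sequence") %in% names(peptides)))
  ids <- if ("id" %in% names(peptides)) as.character(peptides$id) else
    paste0("peptide", seq_len(nrow(peptides)))
  seqs <- vapply(seq_len(nrow(peptides)), function(i)
    check_sequence(peptides$sequence[i], ids[i]), "")
  widths <- peptides$end - peptides$start + 1L
  consistent <- widths == nchar(seqs)

  # upper bound on chain length from consistent placements
  n_max <- max(peptides$end[consistent], nchar(seqs),
               if (!is.null(known_prefix)) nchar(known_prefix) else 0L)
  resid <- rep(NA_character_, n_max + max(nchar(seqs)))

  place <- function(start, seq, id) {
    for (k in seq_len(nchar(seq))) {
      p <- start + k - 1L
      ch <- substr(seq, k, k)
      if (!is.na(resid[p]) && resid[p] != ch)
        stop("stitch conflict at position ", p, ": '", resid[p],
             "' vs '", ch, "' (", id, ")", call. = FALSE)
      resid[p] <<- ch
    }
  }
  for (i in which(consistent)) place(peptides$start[i], seqs[i], ids[i])

  # sequence-authoritative placement for width-inconsistent records
  inconsistent <- which(!consistent)
  for (i in inconsistent[order(peptides$start[inconsistent])]) {
    L <- nchar(seqs[i])
    cand <- integer(0)
    for (s in seq_len(length(resid) - L)) {
      ok <- TRUE; new <- 0L
      for (k in seq_len(L)) {
        p <- s + k - 1L
        if (is.na(resid[p])) new <- new + 1L
        else if (resid[p] != substr(seqs[i], k, k)) { ok <- FALSE; break }
      }
      # require the placement to touch existing coverage (no floating islands)
      if (ok && new > 0L && new < L) cand <- c(cand, s)
    }
    if (length(cand) != 1L)
      stop("cannot place ", ids[i],
           " (interval width != sequence length and ",
           length(cand), " consistent anchored placements)", call. = FALSE)
    warning("interval of ", ids[i], " (", peptides$start[i], "-",
            peptides$end[i], ") disagrees with its sequence length; ",
            "recomputed as ", cand, "-", cand + L - 1L, call. = FALSE)
    place(cand, seqs[i], ids[i])
  }

  if (!is.null(known_prefix)) {
    known_prefix <- check_sequence(known_prefix, "known_prefix")
    for (k in seq_len(nchar(known_prefix)))
      if (is.na(resid[k])) resid[k] <- substr(known_prefix, k, k)
  }
  n <- max(which(!is.na(resid)))
  first <- min(which(!is.na(resid)))
  gaps <- which(is.na(resid[first:n])) + first - 1L
  if (length(gaps) > 0L)
    stop("coverage gap: no residue for position(s) ",
         paste(gaps, collapse = ", "), call. = FALSE)
  protein_chain(name, paste(resid[first:n], collapse = ""), first_pos = first)
}
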