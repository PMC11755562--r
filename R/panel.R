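#' Peptide panel container
#'
#' A panel is an ordered data.frame of peptide records with unique ids.
#' Columns: `id`, `category` (one of original, staggered, short_N, short_M,
#' short_C, deletion_N, deletion_C, randomized), `start`, `end` (NA for
#' randomized peptides, which have no chain position), `sequence`,
#' `parent_id` (originating peptide for derived categories, NA otherwise).
#'
#' @param df data.frame with the columns above (missing `start`, `end`,
#'   `parent_id` are filled with NA).
#' @param provenance optional list of design parameters, kept as an
#'   attribute.
#' @return data.frame of class `pia_panel`.
#' @export
pia_panel <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df), all(c("id", "category", "sequence") %in%
                                     names(df)))
  for (col in c("start", "end")) if (!col %in% names(df)) df[[col]] <- NA_integer_
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_character_
  df <- df[, c("id", "category", "start", "end", "sequence", "parent_id")]
  df$id <- as.character(df$id)
  df$sequence <- toupper(as.character(df$sequence))
  if (anyDuplicated(df$id))
    stop("duplicate peptide ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  cats <- c("original", "staggered", "short_N", "short_M", "short_C",
            "deletion_N", "deletion_C", "randomized")
  bad <- setdiff(unique(df$category), cats)
  if (length(bad) > 0L)
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("pia_panel", "data.frame"))
}

#' @export
print.pia_panel <- function(x, ...) {
  cat("<pia_panel> ", nrow(x), " peptides (",
      paste(names(table(x$category)), table(x$category),
            sep = ":", collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

check_positioned <- function(panel, chain) {
  pos <- !is.na(panel$start)
  for (i in which(pos)) {
    got <- chain_subseq(chain, panel$start[i], panel$end[i])
    if (got != panel$sequence[i])
      stop("sequence of ", panel$id[i], " does not match chain at ",
           panel$start[i], "-", panel$end[i], call. = FALSE)
  }
  invisible(panel)
}

#' Design the original secondary-structure window panel
#'
#' One peptide per window, carrying the exact chain substring.
#'
#' @param chain a [protein_chain()].
#' @param windows data.frame with columns `id`, `start`, `end` (1-based
#'   inclusive, chain numbering).
#' @param min_len smallest admissible window (default 6, the shortest peptide
#'   length used in the assay design).
#' @return A [pia_panel()] of category `original`.
#' @export
design_original <- function(chain, windows, min_len = 6L) {
  stopifnot(inherits(chain, "pia_chain"),
            all(c("id", "start", "end") %in% names(windows)))
  w <- windows$end - windows$start + 1L
  if (any(w < min_len))
    stop("window(s) shorter than ", min_len, ": ",
         paste(windows$id[w < min_len], collapse = ", "), call. = FALSE)
  seqs <- vapply(seq_len(nrow(windows)), function(i)
    chain_subseq(chain, windows$start[i], windows$end[i]), "")
  pia_panel(data.frame(id = windows$id, category = "original",
                       start = as.integer(windows$start),
                       end = as.integer(windows$end), sequence = seqs),
            provenance = list(design = "original", min_len = min_len))
}

# length-L window centred on c (possibly half-integer); even L at an integer
# centre has no symmetric window, tie-break shifts toward the C-terminus
centered_window <- function(center, len) {
  if (len %% 2 == 1) {
    h <- (len - 1) / 2
    start <- center - h
  } else {
    start <- center - len / 2 + 0.5
  }
  if (start != floor(start)) start <- start + 0.5  # integer-centre even case
  c(start = as.integer(start), end = as.integer(start + len - 1))
}

#' Design staggered junction peptides
#'
#' For each pair of consecutive original windows (ending at e_i, next
#' starting at s_(i+1)) a peptide of the requested length is centred at the
#' junction midpoint c = (e_i + s_(i+1)) / 2, so that it carries the
#' C-terminal part of the first window and the N-terminal part of the next.
#' Ids follow the `BP<i>.5` convention.
#'
#' @inheritParams design_original
#' @param windows original windows data.frame (`id`, `start`, `end`),
#'   ordered N to C.
#' @param lengths named numeric: staggered peptide length per staggered id
#'   (or a single length recycled for all pairs); lengths must lie in
#'   \[6, 20\].
#' @param out_of_bounds `"error"` (default) or `"clip"` when a computed
#'   window exceeds the chain (clipping warns).
#' @return A [pia_panel()] of category `staggered`.
#' @examples
#' # junction between windows ending at 15 and starting at 12, length 12:
#' # centre 13.5, interval 8-19
#' @export
design_staggered <- function(chain, windows, lengths = 12L,
                             out_of_bounds = c("error", "clip")) {
  out_of_bounds <- match.arg(out_of_bounds)
  stopifnot(inherits(chain, "pia_chain"), nrow(windows) >= 2L)
  n_pair <- nrow(windows) - 1L
  ids <- paste0(windows$id[seq_len(n_pair)], ".5")
  if (length(lengths) == 1L && is.null(names(lengths)))
    lengths <- stats::setNames(rep(lengths, n_pair), ids)
  # a named length map restricts the design to the listed junctions
  keep <- which(ids %in% names(lengths))
  if (length(keep) == 0L)
    stop("no staggered lengths match the window junctions", call. = FALSE)
  if (any(lengths < 6 | lengths > 20))
    stop("staggered lengths must lie in [6, 20]", call. = FALSE)
  last <- chain$first_pos + nchar(chain$sequence) - 1L
  rows <- lapply(keep, function(i) {
    L <- lengths[[ids[i]]]
    ctr <- (windows$end[i] + windows$start[i + 1L]) / 2
    w <- centered_window(ctr, L)
    if (w["start"] < chain$first_pos || w["end"] > last) {
      if (out_of_bounds == "error")
        stop("staggered window ", ids[i], " (", w["start"], "-", w["end"],
             ") exceeds chain bounds", call. = FALSE)
      warning("clipping staggered window ", ids[i], call. = FALSE)
      w["start"] <- max(w["start"], chain$first_pos)
      w["end"] <- min(w["end"], last)
    }
    data.frame(id = ids[i], category = "staggered",
               start = w[["start"]], end = w[["end"]],
               sequence = chain_subseq(chain, w[["start"]], w[["end"]]))
  })
  pia_panel(do.call(rbind, rows),
            provenance = list(design = "staggered", lengths = lengths))
}

#' Design short N / middle / C peptides
#'
#' For each parent peptide of length L, three k-mers: the N-terminal k
#' residues, the C-terminal k residues, and the middle window starting at
#' offset floor((L - k) / 2).  Explicit overrides (1-based start within the
#' parent) replace the rule's window and emit a message, mirroring the few
#' panel rows that deviate from the rule.
#'
#' @inheritParams design_original
#' @param parents a [pia_panel()] (or data.frame with `id`, `start`, `end`,
#'   `sequence`) of parent peptides positioned on `chain`.
#' @param k short-peptide length (default 6).
#' @param overrides optional data.frame with columns `id`, `parent_id`,
#'   `start_in_parent`.
#' @return A [pia_panel()] with categories `short_N`, `short_M`, `short_C`.
#' @export
design_short <- function(chain, parents, k = 6L, overrides = NULL) {
  stopifnot(all(c("id", "start", "end", "sequence") %in% names(parents)))
  if (any(nchar(parents$sequence) < k))
    stop("parent(s) shorter than k = ", k, ": ",
         paste(parents$id[nchar(parents$sequence) < k], collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(parents))) {
    L <- nchar(parents$sequence[i])
    offs <- c(N = 1L, M = as.integer(floor((L - k) / 2)) + 1L, C = L - k + 1L)
    for (part in names(offs)) {
      id <- paste0(parents$id[i], part)
      o <- offs[[part]]
      if (!is.null(overrides) && id %in% overrides$id) {
        o <- overrides$start_in_parent[overrides$id == id]
        message("short-peptide override for ", id,
                ": parent offset ", o, " (rule gives ", offs[[part]], ")")
      }
      st <- parents$start[i] + o - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, category = paste0("short_", part),
        start = st, end = st + k - 1L,
        sequence = chain_subseq(chain, st, st + k - 1L),
        parent_id = parents$id[i])
    }
  }
  pia_panel(do.call(rbind, rows),
            provenance = list(design = "short", k = k))
}

#' Design an N/C deletion pair from a parent peptide
#'
#' Splits a parent into two sub-peptides of length `sub_len`: the first
#' `sub_len` residues and a C-side window chosen so that the pair overlaps
#' by `overlap` residues.
#'
#' @param parent one-row data.frame (`id`, `start`, `end`, `sequence`) or a
#'   [pia_panel()] row.
#' @param sub_len deletion-peptide length.
#' @param overlap number of shared residues between the two windows
#'   (0 <= overlap < sub_len).
#' @return A [pia_panel()] with categories `deletion_N`, `deletion_C`.
#' @export
design_deletions <- function(parent, sub_len, overlap = 0L) {
  stopifnot(nrow(parent) == 1L, sub_len >= 1L,
            overlap >= 0L, overlap < sub_len)
  L <- nchar(parent$sequence)
  if (sub_len > L) stop("sub_len exceeds parent length", call. = FALSE)
  c_start <- 2L * sub_len - overlap - sub_len + 1L  # = sub_len - overlap + 1
  if (c_start + sub_len - 1L > L || c_start <= 1L)
    stop("deletion geometry impossible: parent length ", L, ", sub_len ",
         sub_len, ", overlap ", overlap, call. = FALSE)
  seqs <- c(substr(parent$sequence, 1L, sub_len),
            substr(parent$sequence, c_start, c_start + sub_len - 1L))
  starts <- parent$start + c(0L, c_start - 1L)
  pia_panel(data.frame(
    id = paste0(parent$id, c("N", "C")),
    category = c("deletion_N", "deletion_C"),
    start = as.integer(starts), end = as.integer(starts + sub_len - 1L),
    sequence = seqs, parent_id = parent$id),
    provenance = list(design = "deletions", sub_len = sub_len,
                      overlap = overlap))
}

#' Seeded composition-preserving randomizations of a peptide
#'
#' Uniform (Fisher-Yates) shuffles of the parent sequence; every variant has
#' the identical residue multiset, so all composition-only descriptors are
#' unchanged while the order-dependent instability index may differ.
#' Randomized peptides carry no chain position.
#'
#' @param parent one-row data.frame (`id`, `sequence`).
#' @param n_variants number of shuffles.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return A [pia_panel()] of category `randomized`, ids `<parent>R1`,
#'   `<parent>R2`, ...
#' @export
randomize_peptides <- function(parent, n_variants = 2L, seed = 1L) {
  stopifnot(nrow(parent) == 1L, n_variants >= 1L)
  res <- split_residues(toupper(parent$sequence))
  seqs <- with_seed(seed, vapply(seq_len(n_variants), function(i)
    paste(sample(res), collapse = ""), ""))
  pia_panel(data.frame(
    id = paste0(parent$id, "R", seq_len(n_variants)),
    category = "randomized", start = NA_integer_, end = NA_integer_,
    sequence = seqs, parent_id = parent$id),
    provenance = list(design = "randomized", seed = seed))
}

#' Write / read a panel as TSV
#'
#' Columns id, category, start, end, sequence, parent_id; lines starting
#' with `#` are provenance comments and are skipped on read.
#'
#' @param panel a [pia_panel()].
#' @param path file path.
#' @param provenance_header optional character vector written as `#` comment
#'   lines.
#' @return `path` invisibly (write); a [pia_panel()] (read).
#' @export
write_panel <- function(panel, path, provenance_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance_header))
    writeLines(paste0("# ", provenance_header), con)
  utils::write.table(as.data.frame(panel), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = "NA")
  pia_panel(df)
}
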