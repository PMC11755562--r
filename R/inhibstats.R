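#' Control-normalized relative fluorescence intensity
#'
#' Each replicate measured at the reference time is divided by the mean
#' no-peptide control fluorescence of its batch at that time; mean and sd
#' are then taken over replicates.  The control's own relative mean is 1 by
#' construction, and rescaling all raw fluorescences by a constant leaves
#' every value unchanged.  A peptide whose replicates are all zero (no
#' measurable product band) is flagged.
#'
#' @param measurements data.frame in the [simulate_panel()] format (an
#'   optional `batch` column splits the data into batches, each carrying its
#'   own control).
#' @param ref_time reference time (hours).
#' @param control_id identifier of the no-peptide control rows.
#' @return data.frame: `peptide_id`, `rel_mean`, `rel_sd`, `n`, `flag`
#'   (`"no measurable band"` or `""`).
#' @export
relative_intensity <- function(measurements, ref_time = 3,
                               control_id = "no_peptide") {
  m <- measurements[measurements$time_h == ref_time, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements at reference time ", ref_time,
                          call. = FALSE)
  if (is.null(m$batch)) m$batch <- 1L
  out <- list()
  for (b in unique(m$batch)) {
    mb <- m[m$batch == b, , drop = FALSE]
    ctrl <- mb$fluorescence_au[mb$peptide_id == control_id]
    if (length(ctrl) == 0L)
      stop("batch ", b, ": no '", control_id, "' control at reference time",
           call. = FALSE)
    cmean <- mean(ctrl)
    if (cmean <= 0) stop("batch ", b, ": control mean fluorescence is zero",
                         call. = FALSE)
    rel <- mb$fluorescence_au / cmean
    agg <- tapply(rel, mb$peptide_id, function(x)
      c(mean(x), stats::sd(x), length(x)))
    ids <- names(agg)
    vals <- do.call(rbind, agg)
    out[[length(out) + 1L]] <- data.frame(
      peptide_id = ids, batch = b, rel_mean = vals[, 1], rel_sd = vals[, 2],
      n = as.integer(vals[, 3]),
      flag = ifelse(vals[, 1] == 0, "no measurable band", ""),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (length(unique(m$batch)) == 1L) res$batch <- NULL
  res
}

#' Dunnett many-to-one comparison against a shared control
#'
#' Compares each treatment group with the common control using the pooled
#' error variance across all groups.  Family-wise adjusted p values come
#' from the null distribution of the maximum absolute Dunnett statistic,
#' which carries the correlation induced by the shared control; the null is
#' evaluated by seeded Monte Carlo.  With a single treatment group the
#' adjusted p equals the pooled two-sample two-sided t-test p (up to Monte
#' Carlo error); adding groups can only increase adjusted p values.
#'
#' @param groups named list of numeric vectors (one per treatment group,
#'   each with >= 2 observations).
#' @param control numeric vector of control observations.
#' @param alpha family-wise significance level used for the star labels
#'   (`*` below `alpha`, `**` below `alpha / 5`, mirroring the usual
#'   0.05 / 0.01 legend).
#' @param nsim Monte Carlo draws for the max-|t| null (>= 1e5 by default).
#' @param seed RNG seed for the Monte Carlo draws.
#' @return data.frame: `peptide_id`, `n`, `mean_diff`, `t`, `raw_p`,
#'   `adj_p`, `significance`.
#' @export
dunnett_test <- function(groups, control, alpha = 0.05, nsim = 1e5,
                         seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, length(control) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  nc <- length(control)
  df <- sum(ns) + nc - (k + 1L)
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) +
    sum((control - mean(control))^2)
  if (ss <= 0) stop("degenerate variance: all observations identical",
                    call. = FALSE)
  s2 <- ss / df
  se <- sqrt(s2 * (1 / ns + 1 / nc))
  tstat <- (vapply(groups, mean, 0) - mean(control)) / se
  raw_p <- 2 * stats::pt(-abs(tstat), df)

  maxT <- with_seed(seed, {
    zc <- stats::rnorm(nsim, 0, 1 / sqrt(nc))
    s <- sqrt(stats::rchisq(nsim, df) / df)
    tmat <- vapply(seq_len(k), function(j) {
      zj <- stats::rnorm(nsim, 0, 1 / sqrt(ns[j]))
      abs(zj - zc) / (s * sqrt(1 / ns[j] + 1 / nc))
    }, numeric(nsim))
    if (k == 1L) tmat[, 1] else apply(tmat, 1, max)
  })
  adj_p <- vapply(abs(tstat), function(t0) mean(maxT >= t0), 0)
  adj_p <- pmax(adj_p, raw_p)  # guard against Monte Carlo undershoot at k=1
  sig <- ifelse(adj_p < alpha / 5, "**", ifelse(adj_p < alpha, "*", "ns"))
  data.frame(peptide_id = names(groups), n = ns,
             mean_diff = vapply(groups, mean, 0) - mean(control),
             t = tstat, raw_p = raw_p, adj_p = adj_p, significance = sig,
             row.names = NULL)
}

# critical value of the max-|t| Dunnett null (shared Monte Carlo machinery)
dunnett_crit <- function(k, n, nc = n, alpha = 0.05, nsim = 1e5, seed = 1L) {
  df <- k * n + nc - (k + 1L)
  maxT <- with_seed(seed, {
    zc <- stats::rnorm(nsim, 0, 1 / sqrt(nc))
    s <- sqrt(stats::rchisq(nsim, df) / df)
    tmat <- vapply(seq_len(k), function(j) {
      zj <- stats::rnorm(nsim, 0, 1 / sqrt(n))
      abs(zj - zc) / (s * sqrt(1 / n + 1 / nc))
    }, numeric(nsim))
    if (k == 1L) tmat[, 1] else apply(tmat, 1, max)
  })
  stats::quantile(maxT, 1 - alpha, names = FALSE)
}

#' Two-sided pooled t-test from summary statistics
#'
#' Unpaired two-sided Student's t-test with pooled variance and
#' n1 + n2 - 2 degrees of freedom, computed from group means and standard
#' deviations (the form reported for the DNA-concentration comparison).
#'
#' @param n1,mean1,sd1 first group size, mean and sd.
#' @param n2,mean2,sd2 second group size, mean and sd.
#' @return list with `t`, `df`, `p_value`.
#' @examples
#' t_test_summary(3, 3.297, 0.006, 3, 0.332, 0.003)$p_value  # << 1e-10
#' @export
t_test_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Rank peptides by inhibition and flag the most inhibitory subset
#'
#' Sorts ascending by relative intensity (rank 1 = most inhibitory, i.e.
#' smallest relative fluorescence), breaking ties by peptide id in
#' lexicographic order, and marks peptides strictly below the threshold
#' (default 0.3, the promising-inhibitor cut).
#'
#' @param results data.frame with `peptide_id` and `rel_mean` (e.g. from
#'   [relative_intensity()]), the control row excluded or included at will.
#' @param threshold relative-intensity cut for the "most inhibitory" flag.
#' @return `results` sorted by rank with added columns `rank` and
#'   `most_inhibitory`.
#' @export
rank_and_classify <- function(results, threshold = 0.3) {
  stopifnot(all(c("peptide_id", "rel_mean") %in% names(results)))
  o <- order(results$rel_mean, results$peptide_id)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$most_inhibitory <- out$rel_mean < threshold
  rownames(out) <- NULL
  out
}

#' Pearson correlations between inhibition and descriptors
#'
#' Pairs each requested physicochemical factor with the relative intensity
#' (after dropping peptides on the exclusion list) and reports the Pearson
#' coefficient with its two-sided t-transform p value.  A constant factor
#' yields an NA row with a message rather than an error for the whole run.
#'
#' @param results data.frame with `peptide_id`, `rel_mean`.
#' @param descriptors data.frame from [describe_panel()].
#' @param factors descriptor column names to test (default: the nine
#'   descriptor columns).
#' @param exclude peptide ids dropped before pairing (e.g. the
#'   nuclease-induction outliers).
#' @return data.frame: `factor`, `pearson_r`, `p_value`, `n`.
#' @export
correlate_descriptors <- function(results, descriptors,
                                  factors = c("length", "mw", "pi", "gravy",
                                              "ai", "hydrophilic_pct",
                                              "aromatic_n", "instability",
                                              "net_charge"),
                                  exclude = character(0)) {
  merged <- merge(results, descriptors, by = "peptide_id")
  merged <- merged[!(merged$peptide_id %in% exclude), , drop = FALSE]
  if (nrow(merged) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  rows <- lapply(factors, function(f) {
    x <- merged[[f]]
    if (is.null(x)) stop("unknown factor: ", f, call. = FALSE)
    if (stats::sd(x) == 0) {
      message("factor '", f, "' is constant; correlation undefined")
      return(data.frame(factor = f, pearson_r = NA_real_,
                        p_value = NA_real_, n = nrow(merged)))
    }
    ct <- stats::cor.test(x, merged$rel_mean, method = "pearson")
    data.frame(factor = f, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(merged))
  })
  do.call(rbind, rows)
}

#' Full inhibition analysis of a measurement table
#'
#' Relative intensity at the reference time, Dunnett comparison of every
#' peptide against the no-peptide control, and ranking with the
#' most-inhibitory threshold, bundled into a single classed result.
#'
#' @inheritParams relative_intensity
#' @inheritParams dunnett_test
#' @param threshold passed to [rank_and_classify()].
#' @return Object of class `pia_inhibition`: a data.frame with columns
#'   `peptide_id`, `rel_mean`, `rel_sd`, `n`, `raw_p`, `adj_p`,
#'   `significance`, `rank`, `most_inhibitory`.
#' @export
pia_analyze <- function(measurements, ref_time = 3, control_id = "no_peptide",
                        alpha = 0.05, threshold = 0.3, nsim = 1e5,
                        seed = 1L) {
  rel <- relative_intensity(measurements, ref_time, control_id)
  m <- measurements[measurements$time_h == ref_time, , drop = FALSE]
  ctrl <- m$fluorescence_au[m$peptide_id == control_id]
  ids <- setdiff(unique(m$peptide_id), control_id)
  groups <- lapply(ids, function(id)
    m$fluorescence_au[m$peptide_id == id])
  names(groups) <- ids
  dt <- dunnett_test(groups, ctrl, alpha = alpha, nsim = nsim, seed = seed)
  res <- merge(rel[rel$peptide_id != control_id, ],
               dt[, c("peptide_id", "raw_p", "adj_p", "significance")],
               by = "peptide_id")
  res <- rank_and_classify(res, threshold)
  class(res) <- c("pia_inhibition", "data.frame")
  attr(res, "ref_time") <- ref_time
  res
}

#' @export
print.pia_inhibition <- function(x, ...) {
  cat("<pia_inhibition> ", nrow(x), " peptides at t = ",
      attr(x, "ref_time"), " h; ", sum(x$most_inhibitory),
      " below the inhibition threshold\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
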