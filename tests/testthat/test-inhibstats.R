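test_that("relative intensity self-normalizes the control to exactly 1", {
  nf <- noise_free_panel()
  rel <- relative_intensity(nf$measurements, ref_time = 3)
  expect_equal(rel$rel_mean[rel$peptide_id == "no_peptide"], 1)
  # scaling all raw fluorescences leaves every result unchanged
  m2 <- nf$measurements
  m2$fluorescence_au <- m2$fluorescence_au * 37.5
  expect_equal(relative_intensity(m2, 3), rel)
})

test_that("noise-free relative intensity matches the kinetic closed form", {
  cfg <- assay_config(noise_cv = 0)
  eff <- peptide_effect("half", d50 = 500)  # dose 500 -> k_eff = k0/2
  m <- simulate_panel(eff, cfg, dose = 500)
  rel <- relative_intensity(m, ref_time = 3)
  expect_equal(rel$rel_mean[rel$peptide_id == "half"],
               (1 - exp(-1.5)) / (1 - exp(-3)), tolerance = 1e-12)
})

test_that("an all-zero peptide is reported as having no measurable band", {
  cfg <- assay_config(noise_cv = 0)
  m <- simulate_panel(peptide_effect("dead", 100, plateau_shift = 0), cfg)
  rel <- relative_intensity(m, 3)
  expect_equal(rel$rel_mean[rel$peptide_id == "dead"], 0)
  expect_equal(rel$flag[rel$peptide_id == "dead"], "no measurable band")
  expect_error(relative_intensity(m[m$peptide_id == "dead", ], 3),
               "no_peptide")
})

test_that("single-group Dunnett reduces to the two-sample t-test", {
  x <- c(9.8, 10.4, 10.1, 10.6)
  ctrl <- c(11.2, 11.9, 11.4, 12.1)
  d <- dunnett_test(list(g = x), ctrl, nsim = 2e5, seed = 4)
  p_t <- stats::t.test(x, ctrl, var.equal = TRUE)$p.value
  expect_equal(d$raw_p, p_t, tolerance = 1e-12)
  expect_lt(abs(d$adj_p - p_t), 0.002)
})

test_that("identical group and control samples give p near 1", {
  d <- dunnett_test(list(g = c(1, 2, 3)), c(3, 1, 2), nsim = 1e4, seed = 2)
  expect_equal(d$t, 0)
  expect_gt(d$adj_p, 0.99)
  expect_error(dunnett_test(list(g = c(1, 1)), c(1, 1)), "degenerate")
})

test_that("Dunnett adjusted p values agree with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  dat <- data.frame(
    g = factor(rep(c("ctrl", "a", "b", "c"), each = 5),
               levels = c("ctrl", "a", "b", "c")),
    y = c(rnorm(5, 10), rnorm(5, 10.5), rnorm(5, 12), rnorm(5, 10)))
  fit <- multcomp::glht(stats::aov(y ~ g, dat),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  groups <- split(dat$y, dat$g)
  d <- dunnett_test(groups[c("a", "b", "c")], groups$ctrl,
                    nsim = 2e5, seed = 8)
  expect_equal(unname(d$adj_p), as.numeric(ref), tolerance = 0.01)
})

test_that("adding treatment groups never decreases an adjusted p", {
  g1 <- list(a = c(10.1, 9.7, 10.4))
  g2 <- c(g1, list(b = c(11.2, 10.8, 11.5), c = c(9.1, 9.5, 8.8)))
  ctrl <- c(10.0, 10.3, 9.8)
  d1 <- dunnett_test(g1, ctrl, nsim = 1e5, seed = 6)
  d2 <- dunnett_test(g2, ctrl, nsim = 1e5, seed = 6)
  expect_gte(d2$adj_p[d2$peptide_id == "a"], d1$adj_p)
})

test_that("summary-statistic t-test matches t.test and a permutation oracle", {
  x <- c(3.1, 2.7, 3.4, 2.9)
  y <- c(3.6, 3.9, 3.3, 4.0)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  got <- t_test_summary(length(x), mean(x), stats::sd(x),
                        length(y), mean(y), stats::sd(y))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, 6)
  # exhaustive permutation null on 8 values agrees with the t approximation
  expect_lt(abs(perm_test_p(x, y) - got$p_value), 0.05)
  # equal summaries give p = 1
  expect_equal(t_test_summary(3, 5, 1, 3, 5, 1)$p_value, 1)
})

test_that("the reported DNA-concentration contrast is overwhelmingly significant", {
  p <- t_test_summary(3, 3.297, 0.006, 3, 0.332, 0.003)$p_value
  expect_lt(p, 1e-10)
})

test_that("ranking sorts ascending with lexicographic tie-break and threshold", {
  res <- data.frame(peptide_id = c("B", "A", "C", "D"),
                    rel_mean = c(0.5, 0.2, 0.2, 0.9))
  r <- rank_and_classify(res, threshold = 0.3)
  expect_equal(r$peptide_id, c("A", "C", "B", "D"))
  expect_equal(r$rank, 1:4)
  expect_equal(r$most_inhibitory, c(TRUE, TRUE, FALSE, FALSE))
  none <- rank_and_classify(data.frame(peptide_id = "A", rel_mean = 0.4))
  expect_false(any(none$most_inhibitory))
  inc <- data.frame(peptide_id = c("x", "y", "z"), rel_mean = c(0.1, 0.2, 0.3))
  expect_equal(rank_and_classify(inc)$peptide_id, inc$peptide_id)
})

test_that("descriptor correlations recover exact and null relationships", {
  res <- data.frame(peptide_id = letters[1:6], rel_mean = seq(0.9, 0.4, -0.1))
  desc <- data.frame(peptide_id = letters[1:6],
                     up = 1:6, flat = rep(2, 6),
                     noise = c(0.3, 0.9, 0.1, 0.8, 0.2, 0.7))
  cr <- correlate_descriptors(res, desc, factors = c("up", "noise"))
  expect_equal(cr$pearson_r[cr$factor == "up"], -1, tolerance = 1e-12)
  expect_message(
    cf <- correlate_descriptors(res, desc, factors = "flat"), "constant")
  expect_true(is.na(cf$pearson_r))
  # closed-form cross-check on a 4-point set
  r4 <- data.frame(peptide_id = letters[1:4],
                   rel_mean = c(0.2, 0.5, 0.4, 0.9))
  d4 <- data.frame(peptide_id = letters[1:4], f = c(3, 1, 4, 2))
  got <- correlate_descriptors(r4, d4, factors = "f")
  expect_equal(got$pearson_r, pearson_r_closed(d4$f, r4$rel_mean),
               tolerance = 1e-12)
  # exclusion list drops peptides before pairing
  ex <- correlate_descriptors(res, desc, factors = "up", exclude = c("a", "b"))
  expect_equal(ex$n, 4L)
})

test_that("an independent factor correlates near zero at large n", {
  n <- 2000
  dat <- withr::with_seed(21, data.frame(peptide_id = as.character(seq_len(n)),
                                  rel_mean = runif(n)))
  desc <- withr::with_seed(22, data.frame(peptide_id = as.character(seq_len(n)),
                                   f = rnorm(n)))
  cr <- correlate_descriptors(dat, desc, factors = "f")
  expect_lt(abs(cr$pearson_r), 0.05)
})

test_that("the bundled analysis pipeline is deterministic and coherent", {
  cfg <- assay_config(noise_cv = 0.05, seed = 17)
  effects <- rbind(peptide_effect("strong", 20),
                   peptide_effect("weak", 2000),
                   peptide_effect("mid", 200))
  m <- simulate_panel(effects, cfg)
  a <- pia_analyze(m, seed = 30)
  b <- pia_analyze(m, seed = 30)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sort(a$rank), 1:3)
  expect_true(all(a$adj_p >= a$raw_p))
  # stronger suppression ranks as more inhibitory
  expect_lt(a$rank[a$peptide_id == "strong"], a$rank[a$peptide_id == "weak"])
})
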