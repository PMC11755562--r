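chain <- ecori_chain()

test_that("original windows extract the printed sequences", {
  w <- ecori_windows()
  p <- design_original(chain, w[w$end - w$start + 1L == nchar(w$sequence), ])
  expect_equal(p$sequence[p$id == "BP1"], "SNKKQSNRLTEQHK")
  expect_equal(p$sequence[p$id == "BP25"], "LGRDLFEQLTSK")
  expect_error(design_original(chain, data.frame(id = "w", start = 1, end = 1)),
               "shorter than 6")
})

test_that("staggered windows are centred on the junction midpoint", {
  w <- data.frame(id = c("BP1", "BP2"), start = c(2L, 12L), end = c(15L, 23L))
  p <- design_staggered(chain, w, lengths = c("BP1.5" = 12))
  expect_equal(p$start, 8L)   # centre (15+12)/2 = 13.5
  expect_equal(p$end, 19L)
  expect_equal(p$sequence, "NRLTEQHKLSQG")

  w78 <- data.frame(id = c("BP7", "BP8"), start = c(73L, 82L),
                    end = c(84L, 93L))
  p78 <- design_staggered(chain, w78, lengths = c("BP7.5" = 11))
  expect_equal(c(p78$start, p78$end), c(78L, 88L))  # odd length, centre 83
  expect_equal(p78$sequence, "GGTLFVSNSSI")
})

test_that("abutting windows give a window symmetric about the junction", {
  w <- data.frame(id = c("A", "B"), start = c(2L, 11L), end = c(10L, 20L))
  p <- design_staggered(chain, w, lengths = c("A.5" = 10))
  expect_equal(c(p$start, p$end), c(6L, 15L))  # symmetric about 10.5
})

test_that("out-of-bounds staggered windows error or clip per configuration", {
  w <- data.frame(id = c("A", "B"), start = c(2L, 3L), end = c(4L, 9L))
  expect_error(design_staggered(chain, w, lengths = c("A.5" = 12)), "bounds")
  expect_warning(pc <- design_staggered(chain, w, lengths = c("A.5" = 12),
                                        out_of_bounds = "clip"), "clip")
  expect_gte(pc$start, 1L)
})

test_that("short N/M/C peptides follow the terminal and floored-middle rule", {
  w <- ecori_windows()
  parents <- design_original(chain,
                             w[w$id %in% c("BP6", "BP9"), ])
  p <- design_short(chain, parents, k = 6)
  got <- setNames(p$sequence, p$id)
  expect_equal(got[["BP6N"]], "IKKTEI")
  expect_equal(got[["BP6M"]], "EINEAL")
  expect_equal(got[["BP6C"]], "ALKKID")
  expect_equal(got[["BP9N"]], "KPDGGI")
  expect_equal(got[["BP9M"]], "GIVEVK")
  expect_equal(got[["BP9C"]], "VKDDYG")
  expect_true(all(p$parent_id %in% c("BP6", "BP9")))
})

test_that("a parent of length exactly k gives N = M = C = parent", {
  parent <- pia_panel(data.frame(id = "P", category = "original",
                                 start = 61L, end = 66L,
                                 sequence = chain_subseq(chain, 61, 66)))
  p <- design_short(chain, parent, k = 6)
  expect_equal(unique(p$sequence), parent$sequence)
  expect_error(design_short(chain, parent, k = 7), "shorter than k")
})

test_that("short-peptide overrides replace the rule output with a message", {
  w <- ecori_windows()
  parents <- design_original(chain, w[w$id == "BP12", ])
  ov <- data.frame(id = "BP12N", parent_id = "BP12", start_in_parent = 2L)
  expect_message(p <- design_short(chain, parents, overrides = ov),
                 "override for BP12N")
  expect_equal(p$sequence[p$id == "BP12N"], "NGLLVG")
})

test_that("deletion pairs split a parent with the requested overlap", {
  parent <- data.frame(id = "BP19.5", start = 212L, end = 221L,
                       sequence = "PINSNLCINK")
  p <- design_deletions(parent, sub_len = 6, overlap = 2)
  expect_equal(p$sequence, c("PINSNL", "NLCINK"))
  expect_equal(p$id, c("BP19.5N", "BP19.5C"))
  expect_equal(p$start, c(212L, 216L))

  ten <- data.frame(id = "T", start = 1L, end = 10L,
                    sequence = "ACDEFGHIKL")
  p2 <- design_deletions(ten, sub_len = 5, overlap = 0)
  expect_equal(p2$sequence, c("ACDEF", "GHIKL"))  # first 5 + last 5
  six <- data.frame(id = "S", start = 1L, end = 6L, sequence = "ACDEFG")
  expect_error(design_deletions(six, sub_len = 6, overlap = 0), "impossible")
})

test_that("randomization preserves composition and is seed-deterministic", {
  parent <- data.frame(id = "BP7", sequence = "IDPDLGGTLFVS")
  a <- randomize_peptides(parent, n_variants = 3, seed = 7)
  b <- randomize_peptides(parent, n_variants = 3, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_equal(a$id, c("BP7R1", "BP7R2", "BP7R3"))
  expect_true(all(is.na(a$start)))
  for (s in a$sequence)
    expect_identical(sort(strsplit(s, "")[[1]]),
                     sort(strsplit(parent$sequence, "")[[1]]))
  one <- randomize_peptides(data.frame(id = "X", sequence = "P"), 1, 1)
  expect_equal(one$sequence, "P")
})

test_that("the published panel reassembles with its category counts", {
  p <- suppressMessages(build_paper_panel(chain))
  expect_equal(nrow(p), 85L)
  counts <- table(p$category)
  expect_equal(unname(counts[["original"]]), 25L)
  expect_equal(unname(counts[["staggered"]]), 22L)
  expect_equal(unname(counts[["deletion_N"]] + counts[["deletion_C"]]), 2L)
  expect_equal(unname(counts[["short_N"]] + counts[["short_M"]] +
                        counts[["short_C"]]), 30L)
  expect_equal(unname(counts[["randomized"]]), 6L)
  expect_equal(sum(p$category != "randomized"), 79L)
  expect_false(anyDuplicated(p$id) > 0)
})

test_that("every positioned peptide matches the chain substring at its interval", {
  p <- suppressMessages(build_paper_panel(chain))
  pos <- p[!is.na(p$start), ]
  for (i in seq_len(nrow(pos)))
    expect_equal(chain_subseq(chain, pos$start[i], pos$end[i]),
                 pos$sequence[i])
})

test_that("panels survive a TSV round trip", {
  p <- suppressMessages(build_paper_panel(chain))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, f, provenance_header = "test")
  back <- read_panel(f)
  expect_equal(as.data.frame(back), as.data.frame(p), ignore_attr = TRUE)
})
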