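# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

pia_extdata <- function(file) {
  path <- system.file("extdata", file, package = "piakit", mustWork = FALSE)
  if (!nzchar(path))
    stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

read_fixture_tsv <- function(file) {
  utils::read.table(pia_extdata(file), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    comment.char = "", quote = "")
}
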