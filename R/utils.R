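# Internal helpers shared across modules.

# The 20 standard amino acids; '-' is the alignment gap.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP <- "-"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Read FASTA from a file path or from in-memory text (">..." lines).
read_fasta_input <- function(x) {
  if (length(x) == 1L && !startsWith(x, ">") && file.exists(x)) {
    set <- Biostrings::readAAStringSet(x)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(x, tf)
    set <- Biostrings::readAAStringSet(tf)
  }
  list(headers = names(set), seqs = as.character(set))
}

write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
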