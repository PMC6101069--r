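# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package route their randomness through this so nothing leaks global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Accept either a file path or a character vector of lines.
as_lines <- function(x, what = "input") {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  as.character(x)
}

# Coerce to an AAStringSet, accepting a path, character vector or XStringSet.
as_aa_set <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  if (methods::is(x, "XStringSet")) return(Biostrings::AAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(Biostrings::readAAStringSet(x))
  }
  Biostrings::AAStringSet(x)
}

# Coerce to a DNAStringSet, accepting a path, character vector or XStringSet.
as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "XStringSet")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(x)
}

# BLOSUM62 is shipped as package data by Biostrings; cache it once.
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
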