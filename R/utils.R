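# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Run `code` under a temporary RNG state when `seed` is non-NULL; otherwise use
# the ambient RNG stream. Mirrors withr::with_seed without the dependency so
# that generator calls are bit-reproducible under a fixed seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number or NULL.")
  }
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
  force(code)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, format(min)))
  }
  as.integer(x)
}

assert_proportion <- function(x, name, lt1 = FALSE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(x >= 0) &&
    all(if (lt1) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be in [0, %s.", name, if (lt1) "1)" else "1]"))
  }
  as.numeric(x)
}

# Phred+33 <-> integer quality scores.
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

# Split sequences of equal length into a character matrix (reads x positions).
seq_to_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L) abort("sequences must all have equal length.")
  matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = n, byrow = TRUE)
}

logistic2 <- function(log2_em) 2^log2_em / (1 + 2^log2_em)

`%||%` <- function(x, y) if (is.null(x)) y else x
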