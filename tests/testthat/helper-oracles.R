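# Shared fixtures and independent oracles used across test files.

# Naive per-pair Hamming distance (independent of the package's
# column-tabulation implementation).
naive_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

naive_mean_pairwise <- function(barcodes) {
  pairs <- utils::combn(length(barcodes), 2)
  mean(apply(pairs, 2, function(ij) naive_hamming(barcodes[ij[1]], barcodes[ij[2]])))
}

# Brute-force reimplementation of the iterative-radius abundance collapse,
# written as an explicit while-loop over a data frame (no shared code with
# collapse_barcodes). For <= 20 barcodes only.
brute_collapse <- function(barcodes, counts, max_distance = 4, min_count = 2) {
  keep <- counts >= min_count
  df <- data.frame(bc = barcodes[keep], ct = counts[keep],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  for (d in seq_len(max_distance)) {
    df <- df[order(-df$ct, df$bc), ]
    merged <- rep(FALSE, nrow(df))
    absorbed <- rep(FALSE, nrow(df))  # already merged into a parent this round
    i <- 1
    while (i <= nrow(df)) {
      if (!absorbed[i]) {
        j <- i + 1
        while (j <= nrow(df)) {
          if (!absorbed[j] && naive_hamming(df$bc[i], df$bc[j]) <= d) {
            df$ct[i] <- df$ct[i] + df$ct[j]
            absorbed[j] <- TRUE
          }
          j <- j + 1
        }
      }
      i <- i + 1
    }
    df <- df[!absorbed, ]
  }
  df[order(-df$ct, df$bc), ]
}

# Barcodes farther than the collapse radius from every other barcode in the
# set. Clones whose barcodes fall within the merge radius of another clone
# are unidentifiable by the error-collapsing design (their reads legitimately
# merge), so parameter-recovery comparisons condition on isolation.
isolated_barcodes <- function(barcodes, min_dist = 5) {
  m <- matrix(unlist(strsplit(barcodes, "", fixed = TRUE)),
              ncol = nchar(barcodes[1]), byrow = TRUE)
  n <- nrow(m)
  near <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    hit <- which(d < min_dist)
    if (length(hit)) {
      near[i] <- TRUE
      near[i + hit] <- TRUE
    }
  }
  barcodes[!near]
}

# Adjusted Rand index from the pair-counting formula.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# All permutations of 1..n (recursive enumeration; n <= 6).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# A small, fully deterministic count table over two libraries / two states,
# used by the quantification unit tests.
tiny_libraries <- function() {
  tibble::tibble(
    library_id = c("t0_E_r1", "t0_E_r2", "t0_M_r1", "t0_M_r2",
                   "t1_E_r1", "t1_E_r2", "t1_M_r1", "t1_M_r2"),
    timepoint = rep(c(0, 1), each = 4),
    state = rep(c("E", "E", "M", "M"), 2),
    replicate = rep(c(1, 2), 4)
  )
}

# Small mda157-style population shared by the faster pipeline tests.
small_population <- function(n = 120, seed = 421) {
  gen_mda157_population(seed = seed, n_clones = n)
}
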