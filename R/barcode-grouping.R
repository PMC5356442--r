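#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming_distance("AAAA", "TTTT")
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("`a` and `b` must have equal length.")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Mean pairwise Hamming distance of a barcode set
#'
#' Average Hamming distance over all unordered pairs. For `n` uniform-random
#' barcodes of length `L` the expectation is `3L/4` (10.5 for 14-mers),
#' a measure of how well-separated a random pool is in sequence space.
#'
#' @param barcodes Character vector (>= 2 equal-length strings).
#' @return Mean pairwise distance (double).
#' @export
mean_pairwise_hamming <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2) abort("need at least 2 barcodes.")
  m <- seq_to_matrix(barcodes)
  # sum of pairwise mismatches per position: for each position, pairs that
  # differ = (n choose 2) - sum_b (count_b choose 2)
  total_pairs <- n * (n - 1) / 2
  mismatch_pairs <- sum(apply(m, 2, function(col) {
    tab <- tabulate(factor(col, levels = DNA_BASES))
    total_pairs - sum(tab * (tab - 1) / 2)
  }))
  mismatch_pairs / total_pairs
}

# Integer-coded barcode matrix for fast row-vs-rows distances.
barcode_code_matrix <- function(barcodes) {
  m <- seq_to_matrix(barcodes)
  matrix(match(m, DNA_BASES), nrow = nrow(m))
}

#' Collapse sequencing-error barcodes into their parent barcodes
#'
#' Implements the iterative-radius abundance collapse: barcodes seen fewer
#' than `min_count` times are discarded, then for radii d = 1, 2, ...,
#' `max_distance` in order the surviving barcodes are traversed in
#' descending abundance (ties broken lexicographically) and every less
#' abundant barcode within Hamming distance d of the current barcode is
#' merged into it, the parent inheriting the group's summed reads. Merged
#' barcodes are removed before the next radius. Total reads of the surviving
#' input are conserved.
#'
#' @param counts Tibble with `barcode`, `count` (or a named numeric vector).
#' @param max_distance Largest merge radius (default 4).
#' @param min_count Minimum reads for a barcode to enter the collapse
#'   (default 2, i.e. "seen at least twice").
#' @return List: `counts` (tibble `barcode`, `count`, abundance-ordered),
#'   `report` (list with `merges` tibble (`parent`, `child`, `child_count`,
#'   `distance`, `round`), `round_merges` per-round counts, and
#'   `discarded_reads` lost to the `min_count` filter).
#' @export
collapse_barcodes <- function(counts, max_distance = 4, min_count = 2) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(barcode = names(counts), count = as.numeric(counts))
  }
  if (nrow(counts) == 0) abort("`counts` must be non-empty.")
  if (length(unique(nchar(counts$barcode))) != 1) {
    abort("all barcodes in one table must have equal length.")
  }
  discarded <- counts$count < min_count
  discarded_reads <- sum(counts$count[discarded])
  bc <- counts$barcode[!discarded]
  ct <- counts$count[!discarded]
  merges <- list()
  if (length(bc) > 1) {
    for (d in seq_len(max_distance)) {
      ord <- order(-ct, bc)
      bc <- bc[ord]; ct <- ct[ord]
      code <- barcode_code_matrix(bc)
      alive <- rep(TRUE, length(bc))
      i <- 1L
      while (i <= length(bc)) {
        if (alive[i]) {
          js <- which(alive & seq_along(bc) > i)
          if (length(js)) {
            dist <- rowSums(
              code[js, , drop = FALSE] !=
                matrix(code[i, ], length(js), ncol(code), byrow = TRUE)
            )
            hit <- js[dist <= d]
            if (length(hit)) {
              merges[[length(merges) + 1L]] <- tibble(
                parent = bc[i], child = bc[hit], child_count = ct[hit],
                distance = dist[dist <= d], round = d
              )
              ct[i] <- ct[i] + sum(ct[hit])
              alive[hit] <- FALSE
            }
          }
        }
        i <- i + 1L
      }
      bc <- bc[alive]; ct <- ct[alive]
      if (length(bc) <= 1) break
    }
  }
  merges <- if (length(merges)) bind_rows(merges) else {
    tibble(parent = character(), child = character(), child_count = double(),
           distance = integer(), round = integer())
  }
  ord <- order(-ct, bc)
  list(
    counts = tibble(barcode = bc[ord], count = ct[ord]),
    report = list(
      merges = merges,
      round_merges = merges %>% dplyr::count(.data$round, name = "merged"),
      discarded_reads = discarded_reads
    )
  )
}

#' Collapse barcodes within each library of a count table
#'
#' Applies [collapse_barcodes()] independently to every library (the
#' `min_count` "seen at least twice" rule is per library).
#'
#' @param counts Tibble: `library_id`, `barcode`, `count`.
#' @inheritParams collapse_barcodes
#' @return Tibble: `library_id`, `barcode`, `count` after collapse.
#' @export
collapse_libraries <- function(counts, max_distance = 4, min_count = 2) {
  counts %>%
    dplyr::group_split(.data$library_id) %>%
    purrr::map_dfr(function(tb) {
      if (all(tb$count < min_count)) {
        return(tibble(library_id = character(), barcode = character(),
                      count = double()))
      }
      out <- collapse_barcodes(tb[, c("barcode", "count")],
                               max_distance = max_distance,
                               min_count = min_count)$counts
      mutate(out, library_id = tb$library_id[1], .before = 1)
    })
}

#' Retain barcodes detected at every time point
#'
#' A barcode is kept iff, for every time point, it is detected in at least
#' one library sequenced at that time point; barcodes missing from all
#' libraries of any time point are removed from analysis.
#'
#' @param counts Tibble: `library_id`, `barcode`, `count`.
#' @param libraries Tibble mapping `library_id` to `timepoint`.
#' @return Character vector of retained barcodes.
#' @export
filter_persistent <- function(counts, libraries) {
  if (nrow(counts) == 0) return(character())
  timepoints <- unique(libraries$timepoint)
  seen <- counts %>%
    left_join(libraries[, c("library_id", "timepoint")], by = "library_id") %>%
    distinct(.data$barcode, .data$timepoint) %>%
    dplyr::count(.data$barcode, name = "n_timepoints")
  sort(seen$barcode[seen$n_timepoints == length(timepoints)])
}
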