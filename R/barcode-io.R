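#' Read-quality acceptance policy
#'
#' A read passes when it has strictly fewer than `max_low_q_bases` bases with
#' quality below `low_q_threshold` and no base below `min_base_q`. When
#' `require_flank_q` is set, every base of the index and flank regions must
#' additionally exceed that score (checked during demultiplexing, where the
#' layout is known).
#'
#' Two presets mirror the pipeline's two sequencing contexts:
#' `policy_plasmid_pool()` (fewer than 14 bases under Q25, none under Q10,
#' index/flank bases over Q25) and `policy_sorted_cells()` (fewer than 6
#' bases under Q25, none under Q15, no flank-quality condition).
#'
#' @param max_low_q_bases Reject when at least this many bases fall below
#'   `low_q_threshold`.
#' @param low_q_threshold Phred score defining a "low quality" base.
#' @param min_base_q Minimum acceptable per-base Phred score.
#' @param require_flank_q Optional Phred score the index/flank bases must
#'   exceed; NULL disables the check.
#' @return A `quality_policy` list.
#' @export
quality_policy <- function(max_low_q_bases, low_q_threshold, min_base_q,
                           require_flank_q = NULL) {
  if (min_base_q > low_q_threshold) {
    abort("`min_base_q` must be <= `low_q_threshold`.")
  }
  structure(
    list(max_low_q_bases = max_low_q_bases, low_q_threshold = low_q_threshold,
         min_base_q = min_base_q, require_flank_q = require_flank_q),
    class = "quality_policy"
  )
}

#' @rdname quality_policy
#' @export
policy_plasmid_pool <- function() quality_policy(14, 25, 10, require_flank_q = 25)

#' @rdname quality_policy
#' @export
policy_sorted_cells <- function() quality_policy(6, 25, 15, require_flank_q = NULL)

#' Read a barcode amplicon FASTQ into a tibble
#'
#' Parses a (possibly gzipped) 4-line FASTQ via Biostrings.
#'
#' @param path FASTQ path.
#' @return Tibble: `read_id`, `sequence`, `quality` (Phred+33 string).
#' @export
read_barcode_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTQ files.")
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Quality-filter barcode reads
#'
#' Applies a [quality_policy()]: a read is accepted iff the number of bases
#' with quality below the low-quality threshold is strictly less than the
#' allowed maximum AND its minimum base quality is at least `min_base_q`.
#' (The flank/index quality condition, when configured, is applied during
#' demultiplexing.) Filtering is idempotent and tallies rejection reasons.
#'
#' @param reads Tibble with `sequence` and `quality` columns (and any others,
#'   which are preserved).
#' @param policy A [quality_policy()].
#' @return List: `accepted` (filtered tibble), `tally` (tibble `reason`,
#'   `reads` covering `accepted`, `too_many_low_q`, `min_base_q`).
#' @export
filter_reads <- function(reads, policy) {
  if (!all(c("sequence", "quality") %in% names(reads))) {
    abort("`reads` must have `sequence` and `quality` columns.")
  }
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    abort(sprintf("malformed FASTQ record: %s (sequence/quality length mismatch)",
                  reads$read_id[which(bad_len)[1]] %||% which(bad_len)[1]))
  }
  quals <- phred_to_int(reads$quality)
  n_low <- vapply(quals, function(q) sum(q < policy$low_q_threshold), integer(1))
  min_q <- vapply(quals, min, integer(1))
  fail_low <- n_low >= policy$max_low_q_bases
  fail_min <- min_q < policy$min_base_q
  keep <- !fail_low & !fail_min
  tally <- tibble(
    reason = c("accepted", "too_many_low_q", "min_base_q"),
    reads = c(sum(keep), sum(fail_low), sum(fail_min & !fail_low))
  )
  list(accepted = reads[keep, , drop = FALSE], tally = tally)
}

#' Fixed amplicon read layout
#'
#' Declares where the index, flanks and barcode sit in each read:
#' `index | flank_5 | barcode | flank_3`.
#'
#' @param index_length,flank_5,flank_3,barcode_length Layout fields; flanks
#'   are the constant sequences shared by all barcodes.
#' @return A `library_layout` list with precomputed coordinate ranges.
#' @export
library_layout <- function(index_length = 6, flank_5 = "ACGCTT",
                           flank_3 = "GGATCC", barcode_length = 14) {
  i1 <- 1L; i2 <- index_length
  f5a <- i2 + 1L; f5b <- i2 + nchar(flank_5)
  b1 <- f5b + 1L; b2 <- f5b + barcode_length
  f3a <- b2 + 1L; f3b <- b2 + nchar(flank_3)
  structure(list(
    index_length = index_length, flank_5 = flank_5, flank_3 = flank_3,
    barcode_length = barcode_length,
    index_range = c(i1, i2), flank5_range = c(f5a, f5b),
    barcode_range = c(b1, b2), flank3_range = c(f3a, f3b),
    read_length = f3b
  ), class = "library_layout")
}

#' Demultiplex reads and extract barcodes
#'
#' Assigns each read to a library by exact match of its index bases against
#' the library index sequences (indexes are designed at pairwise Hamming
#' distance >= 2, and no mismatch rescue is attempted), verifies both
#' constant flanks exactly, and excises the barcode. When the quality policy
#' carries a flank-quality requirement, every index and flank base must
#' exceed it.
#'
#' @param reads Tibble with `sequence`, `quality` (already quality-filtered).
#' @param specs Library metadata tibble with `library_id` and
#'   `index_sequence` (e.g. from [gen_sorted_read_libraries()]).
#' @param layout A [library_layout()].
#' @param policy Optional [quality_policy()]; only its `require_flank_q`
#'   field is used here.
#' @return List: `assignments` (tibble `library_id`, `barcode`), `tally`
#'   (tibble `reason`, `reads`: `assigned`, `no_index`, `flank_fail`,
#'   `too_short`, `flank_quality`).
#' @export
demultiplex_and_extract <- function(reads, specs, layout = library_layout(),
                                    policy = NULL) {
  if (anyDuplicated(specs$index_sequence)) {
    abort("library specs contain duplicated index sequences.")
  }
  if (any(nchar(specs$index_sequence) != layout$index_length)) {
    abort("index sequences do not match the layout's index length.")
  }
  n <- nrow(reads)
  long_enough <- nchar(reads$sequence) >= layout$read_length
  idx_seq <- substr(reads$sequence, layout$index_range[1], layout$index_range[2])
  lib <- specs$library_id[match(idx_seq, specs$index_sequence)]
  lib[!long_enough] <- NA
  has_index <- !is.na(lib)
  f5 <- substr(reads$sequence, layout$flank5_range[1], layout$flank5_range[2])
  f3 <- substr(reads$sequence, layout$flank3_range[1], layout$flank3_range[2])
  flank_ok <- f5 == layout$flank_5 & f3 == layout$flank_3
  flank_q_ok <- rep(TRUE, n)
  if (!is.null(policy) && !is.null(policy$require_flank_q)) {
    const_pos <- c(
      seq(layout$index_range[1], layout$index_range[2]),
      seq(layout$flank5_range[1], layout$flank5_range[2]),
      seq(layout$flank3_range[1], layout$flank3_range[2])
    )
    quals <- phred_to_int(reads$quality)
    flank_q_ok <- vapply(
      quals,
      function(q) length(q) >= layout$read_length &&
        all(q[const_pos] > policy$require_flank_q),
      logical(1)
    )
  }
  assigned <- has_index & flank_ok & flank_q_ok & long_enough
  tally <- tibble(
    reason = c("assigned", "too_short", "no_index", "flank_fail", "flank_quality"),
    reads = c(
      sum(assigned),
      sum(!long_enough),
      sum(long_enough & !has_index),
      sum(long_enough & has_index & !flank_ok),
      sum(long_enough & has_index & flank_ok & !flank_q_ok)
    )
  )
  assignments <- tibble(
    library_id = lib[assigned],
    barcode = substr(reads$sequence[assigned],
                     layout$barcode_range[1], layout$barcode_range[2])
  )
  list(assignments = assignments, tally = tally)
}

#' Tabulate barcodes per library
#'
#' Exact multiset counting of demultiplexed barcodes, ordered by library then
#' barcode (lexicographic) so output is deterministic and order-invariant to
#' the input stream.
#'
#' @param assignments Tibble with `library_id`, `barcode` (one row per read).
#' @return Tibble: `library_id`, `barcode`, `count` (all counts >= 1).
#' @export
count_barcodes <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(library_id = character(), barcode = character(),
                  count = integer()))
  }
  assignments %>%
    dplyr::count(.data$library_id, .data$barcode, name = "count") %>%
    arrange(.data$library_id, .data$barcode)
}
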