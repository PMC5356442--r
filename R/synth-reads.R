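#' Configuration for simulated FACS sorting and sequencing
#'
#' Bundles the knobs of the sorted-library simulator: per-time-point mis-sort
#' proportions, the population state split at sorting, sequencing depth and
#' per-base substitution error rate, and the fixed read layout
#' (index + 5' flank + barcode + 3' flank).
#'
#' @param sigma_e,sigma_m Mis-sort proportions per time point (recycled):
#'   `sigma_e[t]` is the fraction of epithelial-sorted cells at time point t
#'   that are really mesenchymal, and vice versa. Must be < 0.5.
#' @param state_fraction_e Population fraction of cells in the epithelial
#'   state at sorting (default 0.6; the mesenchymal fraction is its
#'   complement).
#' @param read_depth Reads per library; each library's counts sum to this
#'   exactly.
#' @param error_rate Per-base substitution probability applied across the
#'   whole read.
#' @param timepoints,replicates Number of weekly time points and of sequenced
#'   replicate libraries per sort.
#' @param flank_5,flank_3 Constant sequences flanking the barcode.
#' @param index_length Length of the library-specific index.
#' @return A `sort_sim_config` list.
#' @export
sort_sim_config <- function(sigma_e = 0.02, sigma_m = 0.02,
                            state_fraction_e = 0.6,
                            read_depth = 1e5, error_rate = 0.005,
                            timepoints = 3, replicates = 2,
                            flank_5 = "ACGCTT", flank_3 = "GGATCC",
                            index_length = 6) {
  timepoints <- assert_count(timepoints, "timepoints")
  replicates <- assert_count(replicates, "replicates")
  sigma_e <- rep_len(assert_proportion(sigma_e, "sigma_e", lt1 = TRUE), timepoints)
  sigma_m <- rep_len(assert_proportion(sigma_m, "sigma_m", lt1 = TRUE), timepoints)
  if (any(c(sigma_e, sigma_m) >= 0.5)) abort("sigma values must be < 0.5.")
  state_fraction_e <- assert_proportion(state_fraction_e, "state_fraction_e")
  structure(list(
    sigma_e = sigma_e, sigma_m = sigma_m,
    state_fraction_e = state_fraction_e,
    state_fraction_m = 1 - state_fraction_e,
    read_depth = read_depth, error_rate = error_rate,
    timepoints = timepoints, replicates = replicates,
    flank_5 = flank_5, flank_3 = flank_3, index_length = index_length
  ), class = "sort_sim_config")
}

# Index sequences pairwise Hamming distance >= 2, deterministically from the
# ambient RNG stream.
gen_index_sequences <- function(n, length = 6) {
  out <- character(0)
  tries <- 0L
  while (base::length(out) < n) {
    cand <- paste0(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    ok <- all(vapply(out, function(x) hamming_distance(x, cand) >= 2, logical(1)))
    if (ok) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 1e4) abort("could not design enough well-separated indexes.")
  }
  out
}

# Library metadata for a timepoints x {E,M} x replicates design.
make_library_specs <- function(cfg) {
  grid <- expand.grid(
    replicate = seq_len(cfg$replicates), state = c("E", "M"),
    timepoint = seq_len(cfg$timepoints) - 1L,
    stringsAsFactors = FALSE
  )
  tibble(
    library_id = sprintf("t%d_%s_r%d", grid$timepoint, grid$state, grid$replicate),
    index_sequence = gen_index_sequences(nrow(grid), cfg$index_length),
    timepoint = grid$timepoint,
    state = grid$state,
    replicate = grid$replicate,
    flank_5 = cfg$flank_5,
    flank_3 = cfg$flank_3
  )
}

#' Simulate sorted, sequenced barcode libraries (count level)
#'
#' For each weekly time point the clonal population is grown per clone at its
#' own doubling rate, each clone's realized log2(E/M) fluctuates around its
#' equilibrium (`fluctuation_sd`), cells are split into sorted epithelial and
#' mesenchymal pools with mis-sorting at the configured sigma, and each
#' replicate library draws `read_depth` reads multinomially from the sorted
#' pool's clone proportions. No sequencing errors are applied at this level;
#' use [gen_sorted_read_libraries()] for error-bearing FASTQ output.
#'
#' @param truth Population tibble from [gen_clonal_population()].
#' @param cfg A [sort_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `counts` (tibble: `library_id`, `barcode`, `count`),
#'   `libraries` (the library metadata), and `state_truth` (tibble of each
#'   clone's realized per-time-point fraction epithelial and cell numbers).
#' @export
gen_sorted_counts <- function(truth, cfg = sort_sim_config(), seed = NULL) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one clone.")
  with_seed(seed, {
    libraries <- make_library_specs(cfg)
    state_truth <- purrr::map_dfr(seq_len(cfg$timepoints) - 1L, function(tp) {
      cells <- truth$initial_cells * 2^(truth$doubling_rate * tp)
      wobble <- rnorm(nrow(truth), 0, truth$fluctuation_sd)
      frac_e <- ifelse(
        is.na(truth$pure_state),
        logistic2(truth$true_log2_em + wobble),
        ifelse(truth$pure_state == "E", 1, 0)
      )
      tibble(
        clone_id = truth$clone_id, barcode = truth$barcode, timepoint = tp,
        frac_e = frac_e, cells_e = cells * frac_e, cells_m = cells * (1 - frac_e)
      )
    })
    counts <- purrr::map_dfr(seq_len(nrow(libraries)), function(i) {
      lib <- libraries[i, ]
      st <- state_truth[state_truth$timepoint == lib$timepoint, ]
      tp_i <- lib$timepoint + 1L
      p_e <- st$cells_e / sum(st$cells_e)
      p_m <- st$cells_m / sum(st$cells_m)
      p <- if (lib$state == "E") {
        (1 - cfg$sigma_e[tp_i]) * p_e + cfg$sigma_e[tp_i] * p_m
      } else {
        (1 - cfg$sigma_m[tp_i]) * p_m + cfg$sigma_m[tp_i] * p_e
      }
      if (cfg$read_depth == 0) {
        return(tibble(library_id = character(), barcode = character(),
                      count = integer()))
      }
      k <- as.integer(rmultinom(1, cfg$read_depth, p))
      keep <- k > 0
      tibble(library_id = lib$library_id, barcode = st$barcode[keep],
             count = k[keep])
    })
    list(counts = counts, libraries = libraries, state_truth = state_truth)
  })
}

# Apply per-base substitutions to reads (character vector, equal lengths).
# Error-free reads draw their quality string from a pre-sampled pool of
# high-quality strings (cheap at millions of reads); erroneous reads get
# per-base strings with low-quality scores at the mutated positions.
mutate_reads <- function(seqs, error_rate) {
  len <- nchar(seqs[1])
  n <- length(seqs)
  n_err <- rbinom(n, len, error_rate)
  idx <- which(n_err > 0)
  pool_n <- min(2000L, max(n, 1L))
  pool <- vapply(
    seq_len(pool_n),
    function(i) intToUtf8(sample(28:40, len, replace = TRUE) + 33L),
    character(1)
  )
  quals <- pool[sample.int(pool_n, n, replace = TRUE)]
  if (length(idx)) {
    m <- seq_to_matrix(seqs[idx])
    for (j in seq_along(idx)) {
      pos <- sample.int(len, n_err[idx[j]])
      for (p in pos) {
        m[j, p] <- sample(setdiff(DNA_BASES, m[j, p]), 1)
      }
      q <- sample(28:40, len, replace = TRUE)
      q[pos] <- sample(2:24, length(pos), replace = TRUE)
      quals[idx[j]] <- intToUtf8(q + 33L)
    }
    seqs[idx] <- apply(m, 1, paste0, collapse = "")
  }
  list(sequences = seqs, qualities = quals, n_errors = n_err)
}

#' Simulate sorted barcode libraries down to FASTQ reads
#'
#' Builds on [gen_sorted_counts()]: every counted read becomes a full
#' amplicon read `index + flank_5 + barcode + flank_3`, per-base substitution
#' errors are applied at `cfg$error_rate` across the whole read, and Phred+33
#' quality strings are attached (erroneous bases draw from a lower-quality
#' distribution). All libraries are pooled into a single FASTQ, as on a
#' shared sequencing lane.
#'
#' @inheritParams gen_sorted_counts
#' @param dir Optional output directory; when given, writes `reads.fastq`,
#'   `libraries.tsv` and `truth_counts.tsv` there.
#' @return List: `reads` (tibble `read_id`, `sequence`, `quality`),
#'   `libraries`, `truth_counts` (the error-free per-library counts),
#'   `state_truth`, and `files` (paths, when `dir` was given).
#' @export
gen_sorted_read_libraries <- function(truth, cfg = sort_sim_config(),
                                      seed = NULL, dir = NULL) {
  with_seed(seed, {
    sim <- gen_sorted_counts(truth, cfg)
    counts <- sim$counts
    libs <- sim$libraries
    if (nrow(counts) == 0) {
      reads <- tibble(read_id = character(), sequence = character(),
                      quality = character())
    } else {
      expanded <- counts[rep(seq_len(nrow(counts)), counts$count), ]
      lib_row <- match(expanded$library_id, libs$library_id)
      seqs <- paste0(libs$index_sequence[lib_row], cfg$flank_5,
                     expanded$barcode, cfg$flank_3)
      mut <- mutate_reads(seqs, cfg$error_rate)
      reads <- tibble(
        read_id = sprintf("read_%07d", seq_along(seqs)),
        sequence = mut$sequences,
        quality = mut$qualities
      )
      # shuffle so library order carries no information, as on a real lane
      reads <- reads[sample.int(nrow(reads)), ]
    }
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fq <- file.path(dir, "reads.fastq")
      write_fastq(reads, fq)
      libf <- file.path(dir, "libraries.tsv")
      utils::write.table(libs, libf, sep = "\t", quote = FALSE, row.names = FALSE)
      ctf <- file.path(dir, "truth_counts.tsv")
      utils::write.table(counts, ctf, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(fastq = fq, libraries = libf, truth_counts = ctf)
    }
    list(reads = reads, libraries = libs, truth_counts = counts,
         state_truth = sim$state_truth, files = files)
  })
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (Phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4 * nrow(reads))
  if (nrow(reads)) {
    lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
    lines[seq(2, length(lines), 4)] <- reads$sequence
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- reads$quality
  }
  writeLines(lines, path)
  invisible(path)
}
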