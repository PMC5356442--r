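#' Generate a random DNA barcode library
#'
#' Draws `n_barcodes` sequences uniformly at random (with replacement) over the
#' four-letter DNA alphabet, emulating a plasmid pool of short random barcodes.
#' For 14-mers the expected mean pairwise Hamming distance is
#' `14 * 3/4 = 10.5` base pairs, so random pools of this length are
#' well-separated in sequence space.
#'
#' @param n_barcodes Number of barcodes to draw (>= 1).
#' @param length Barcode length in nucleotides (>= 1; default 14).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n_barcodes` DNA strings. Duplicates are
#'   possible, as in a real pool sampled with replacement.
#' @examples
#' gen_barcode_library(5, length = 14, seed = 1)
#' @export
gen_barcode_library <- function(n_barcodes, length = 14, seed = NULL) {
  n_barcodes <- assert_count(n_barcodes, "n_barcodes")
  length <- assert_count(length, "length")
  with_seed(seed, {
    m <- matrix(
      sample(DNA_BASES, n_barcodes * length, replace = TRUE),
      nrow = n_barcodes
    )
    apply(m, 1, paste0, collapse = "")
  })
}

#' Generate a clonal population with known plasticity ground truth
#'
#' Each clone carries a fixed equilibrium log2(epithelial/mesenchymal) ratio
#' drawn from a normal distribution (so ratios are log-normally distributed
#' across clones), a growth rate in doublings/week, an initial cell count, and
#' a unique DNA barcode. A configurable fraction of clones is state-pure
#' (progeny in one state only), encoded with an explicit `pure_state` flag
#' rather than an infinite log-ratio.
#'
#' @param n_clones Number of clones (0 allowed; returns an empty population).
#' @param log2em_mean,log2em_sd Mean and SD of the per-clone true
#'   log2(E/M) equilibrium ratio (`log2em_sd >= 0`).
#' @param growth_mean,growth_sd Mean and SD of per-clone growth rates in
#'   doublings/week; draws are truncated to be > 0.
#' @param size_meanlog,size_sdlog Log-normal clone-size distribution
#'   parameters. `size_coupling` adds `size_coupling * fraction_epithelial`
#'   to the meanlog, making epithelial-biased clones systematically larger.
#' @param pure_frac_e,pure_frac_m Fractions of clones that are purely
#'   epithelial / purely mesenchymal.
#' @param fluctuation_sd SD of the per-time-point fluctuation of a clone's
#'   realized log2(E/M) around its equilibrium (biological week-to-week
#'   wobble); consumed by [gen_sorted_read_libraries()].
#' @param total_cells If non-NULL, clone sizes are rescaled to sum to this
#'   population size (each clone keeps >= 1 cell).
#' @param barcode_length Barcode length passed to [gen_barcode_library()].
#' @param seed Optional integer seed.
#' @return Tibble with one row per clone: `clone_id`, `barcode`,
#'   `true_log2_em`, `true_fraction_epithelial`, `pure_state` (NA, "E" or
#'   "M"), `doubling_rate` (doublings/week), `initial_cells`,
#'   `fluctuation_sd`. Satisfies
#'   `true_fraction_epithelial == 2^true_log2_em / (1 + 2^true_log2_em)`
#'   for non-pure clones.
#' @seealso [mda157_preset()] for defaults calibrated to the barcoded
#'   MDA-MB-157 study population.
#' @export
gen_clonal_population <- function(n_clones,
                                  log2em_mean = 0,
                                  log2em_sd = 1,
                                  growth_mean = 3,
                                  growth_sd = 0.5,
                                  size_meanlog = 0,
                                  size_sdlog = 1,
                                  size_coupling = 0,
                                  pure_frac_e = 0,
                                  pure_frac_m = 0,
                                  fluctuation_sd = 0,
                                  total_cells = NULL,
                                  barcode_length = 14,
                                  seed = NULL) {
  n_clones <- assert_count(n_clones, "n_clones", min = 0)
  if (log2em_sd < 0 || growth_sd < 0) abort("sd parameters must be >= 0.")
  assert_proportion(pure_frac_e + pure_frac_m, "pure_frac_e + pure_frac_m")
  if (n_clones == 0) {
    return(tibble(
      clone_id = character(), barcode = character(),
      true_log2_em = double(), true_fraction_epithelial = double(),
      pure_state = character(), doubling_rate = double(),
      initial_cells = double(), fluctuation_sd = double()
    ))
  }
  with_seed(seed, {
    barcode <- gen_barcode_library(n_clones, length = barcode_length)
    pure <- sample(
      c(NA_character_, "E", "M"), n_clones, replace = TRUE,
      prob = c(1 - pure_frac_e - pure_frac_m, pure_frac_e, pure_frac_m)
    )
    log2_em <- rnorm(n_clones, log2em_mean, log2em_sd)
    frac_e <- logistic2(log2_em)
    log2_em[!is.na(pure)] <- NA_real_
    frac_e[which(pure == "E")] <- 1
    frac_e[which(pure == "M")] <- 0
    growth <- rnorm(n_clones, growth_mean, growth_sd)
    while (any(growth <= 0)) {
      bad <- growth <= 0
      growth[bad] <- rnorm(sum(bad), growth_mean, growth_sd)
    }
    size <- rlnorm(n_clones, size_meanlog + size_coupling * frac_e, size_sdlog)
    if (!is.null(total_cells)) {
      size <- size / sum(size) * total_cells
    }
    size <- pmax(1, size)  # a clone is at least one founder cell
    tibble(
      clone_id = sprintf("clone_%04d", seq_len(n_clones)),
      barcode = barcode,
      true_log2_em = log2_em,
      true_fraction_epithelial = frac_e,
      pure_state = pure,
      doubling_rate = growth,
      initial_cells = size,
      fluctuation_sd = fluctuation_sd
    )
  })
}

#' Study-population preset for the barcoded MDA-MB-157 experiment
#'
#' Default parameters calibrated once to the headline marginals of the
#' barcoded breast-cancer population the package models: 1372 clones; about
#' 60% of *cells* epithelial (epithelial-biased clones are systematically
#' larger) while roughly 64% of detected *clones* are mesenchymal-biased;
#' around 11% of clones called mono-lineage (a small truly-pure fraction
#' plus extreme-ratio clones); clone log-ratios approximately normal with a
#' spread giving a binned Shannon entropy near 3.5 bits; and a week-to-week
#' fluctuation of each clone's realized log-ratio sized so the
#' between-time-point Pearson correlation of measured log2(E/M) is near
#' 0.89 while most clones change their fraction epithelial by under 0.15
#' over two weeks. Because detection, contamination correction and
#' pseudo-values all shape the measured marginals, the constants were fixed
#' by a one-time calibration of the full generator-plus-pipeline against
#' those targets (see the methods vignette) and are not revisited.
#'
#' @param n_clones Number of clones (default 1372).
#' @return Named list of arguments for [gen_clonal_population()].
#' @export
mda157_preset <- function(n_clones = 1372) {
  list(
    n_clones = n_clones,
    log2em_mean = -qnorm(0.68) * 1.9,
    log2em_sd = 1.9,
    growth_mean = 3,
    growth_sd = 0.5,
    size_meanlog = 0,
    size_sdlog = 1,
    # cell-weighted fraction epithelial 0.6 given the log2_em marginal
    size_coupling = 3.05,
    pure_frac_e = 0.04 * 0.36,
    pure_frac_m = 0.04 * 0.64,
    fluctuation_sd = 0.50,
    total_cells = 2.9e7,
    barcode_length = 14
  )
}

#' Generate the mda157 preset population
#'
#' Convenience wrapper: `gen_clonal_population` with [mda157_preset()]
#' parameters.
#'
#' @param seed Optional integer seed.
#' @param n_clones Number of clones.
#' @return See [gen_clonal_population()].
#' @export
gen_mda157_population <- function(seed = NULL, n_clones = 1372) {
  args <- mda157_preset(n_clones)
  args$seed <- seed
  do.call(gen_clonal_population, args)
}

#' Export a population as an empirical clone table for the simulator
#'
#' Writes the per-clone phenotype/growth/size summary consumed by
#' [build_tumour()]: one row per clone with `clone_id`,
#' `fraction_epithelial`, `doubling_time` (days; `7 / doubling_rate`) and
#' `initial_cells`. This is schema-identical to the reader for observed clone
#' tables, so measured data can drop in for the synthetic truth.
#'
#' @param truth Population tibble from [gen_clonal_population()].
#' @param path Optional TSV path; when given the table is also written there.
#' @return Tibble with the four simulator seed columns.
#' @export
gen_empirical_clone_table <- function(truth, path = NULL) {
  out <- tibble(
    clone_id = truth$clone_id,
    fraction_epithelial = truth$true_fraction_epithelial,
    doubling_time = 7 / truth$doubling_rate,
    initial_cells = truth$initial_cells
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Read an empirical clone table
#'
#' Reads a TSV with columns `clone_id`, `fraction_epithelial`,
#' `doubling_time` (days) and `initial_cells`, as written by
#' [gen_empirical_clone_table()].
#'
#' @param path TSV path.
#' @return Tibble with the four columns.
#' @export
read_empirical_clone_table <- function(path) {
  out <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  need <- c("clone_id", "fraction_epithelial", "doubling_time", "initial_cells")
  if (!all(need %in% names(out))) {
    abort(paste0("empirical clone table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  out[need]
}

#' Simulate a single-cell subcloning experiment
#'
#' Picks `n_subclones` clones from a population, expands each from one cell,
#' and reports the clone's log2(E/M) measured in the parental pool alongside
#' the ratio measured in the expanded subclone. Transmission noise
#' (`transmission_sd`, on the log2 scale) models drift through single-cell
#' cloning plus flow-cytometry measurement error; pure-state clones are
#' excluded (their ratios are not finite).
#'
#' @param truth Population tibble from [gen_clonal_population()].
#' @param n_subclones Number of single-cell clones (default 28).
#' @param transmission_sd SD of the noise between pooled and subclone
#'   log-ratio measurements (applied to each, independently).
#' @param seed Optional integer seed.
#' @return Tibble: `clone_id`, `barcode`, `pooled_log2_em`,
#'   `subclone_log2_em`.
#' @export
gen_subclone_experiment <- function(truth, n_subclones = 28,
                                    transmission_sd = 0.69, seed = NULL) {
  finite <- truth[is.na(truth$pure_state), ]
  if (nrow(finite) < n_subclones) {
    abort("not enough non-pure clones to subclone.")
  }
  with_seed(seed, {
    # larger clones are more likely to be picked by random single-cell sorting
    idx <- sample(nrow(finite), n_subclones, prob = finite$initial_cells)
    picked <- finite[idx, ]
    tibble(
      clone_id = picked$clone_id,
      barcode = picked$barcode,
      pooled_log2_em = picked$true_log2_em +
        rnorm(n_subclones, 0, transmission_sd),
      subclone_log2_em = picked$true_log2_em +
        rnorm(n_subclones, 0, transmission_sd)
    )
  })
}
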