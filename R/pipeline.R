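#' Run the full barcode analysis pipeline on a clonal population
#'
#' End-to-end orchestration: simulate sorted sequencing libraries for the
#' population, optionally at full FASTQ resolution (quality filtering with
#' the sorted-cell policy, demultiplexing, counting), collapse
#' sequencing-error barcodes, keep barcodes detected at every time point,
#' normalize and contamination-correct clone abundances, derive phenotype
#' metrics and growth rates, and run the bi-lineage and state-bias tests.
#' Every stage is seeded from `seed`, so reruns are bit-reproducible.
#'
#' @param truth Population tibble from [gen_clonal_population()] /
#'   [gen_mda157_population()].
#' @param cfg A [sort_sim_config()].
#' @param seed Integer seed for the simulated experiment.
#' @param full_reads If TRUE, simulate individual FASTQ reads with
#'   sequencing errors and run the read-level stages; if FALSE (default),
#'   work from error-free count tables (fast path).
#' @param fdr FDR level for the lineage and bias tests.
#' @return Object of class `clonotype_pipeline`: list with `counts`,
#'   `libraries`, `matrix` (clone-state matrix), `metrics` (per
#'   time point), `phenotypes` (per clone), `growth`, `bilineage`, `bias`,
#'   `stability` (pairwise between-time-point Pearson correlations of
#'   log2(E/M)), `entropy`, `truth`, `summary` (one-row tibble), `seed`.
#' @export
run_pipeline <- function(truth, cfg = sort_sim_config(), seed = 1,
                         full_reads = FALSE, fdr = 0.05) {
  sim <- gen_sorted_read_libraries2(truth, cfg, seed, full_reads)
  counts <- sim$counts
  libraries <- sim$libraries
  collapsed <- collapse_libraries(counts, max_distance = 4, min_count = 2)
  retained <- filter_persistent(collapsed, libraries)
  collapsed <- collapsed[collapsed$barcode %in% retained, ]
  spec <- sort_spec(sigma_e = cfg$sigma_e, sigma_m = cfg$sigma_m,
                    state_fraction_e = cfg$state_fraction_e)
  normalized <- normalize_counts(collapsed, libraries, spec,
                                 barcodes = retained)
  mat <- correct_contamination(normalized, spec)
  metrics <- phenotype_metrics(mat)
  phenotypes <- clone_phenotypes(metrics)
  growth <- growth_rates(mat, spec)
  sums <- clone_read_sums(collapsed, libraries, barcodes = retained)
  probs <- contamination_probabilities(
    sums %>% group_by(.data$timepoint) %>%
      summarise(sum_e = sum(.data$r_e), sum_m = sum(.data$r_m),
                .groups = "drop"),
    cfg$sigma_e, cfg$sigma_m
  )
  bilineage <- bilineage_test(sums, probs, fdr = fdr)
  bias <- bias_test(sums, fdr = fdr)
  tps <- sort(unique(metrics$timepoint))
  wide <- metrics %>%
    select("clone", "timepoint", "log2_em") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "log2_em",
                       names_prefix = "t")
  pairs <- utils::combn(tps, 2, simplify = FALSE)
  stability <- purrr::map_dfr(pairs, function(pr) {
    a <- wide[[paste0("t", pr[1])]]
    b <- wide[[paste0("t", pr[2])]]
    tibble(timepoint_a = pr[1], timepoint_b = pr[2], rho = cor(a, b))
  })
  entropy <- ratio_entropy(phenotypes$log2_em_avg)
  summary <- tibble(
    n_clones = nrow(phenotypes),
    frac_bilineage = mean(bilineage$calls$call == "bilineage"),
    frac_mono = mean(bilineage$calls$call %in% c("mono_E", "mono_M")),
    frac_biased = mean(bias$calls$call == "biased"),
    frac_mes_biased = mean(phenotypes$log2_em_avg < 0),
    entropy = entropy,
    mean_stability_rho = mean(stability$rho),
    frac_stable_015 = mean(phenotypes$delta_fraction < 0.15)
  )
  structure(
    list(counts = counts, libraries = libraries, matrix = mat,
         metrics = metrics, phenotypes = phenotypes, growth = growth,
         bilineage = bilineage, bias = bias, stability = stability,
         entropy = entropy, truth = truth, state_truth = sim$state_truth,
         summary = summary, seed = seed),
    class = "clonotype_pipeline"
  )
}

# Internal: counts either straight from the count-level simulator or via the
# full FASTQ read-level path (errors, quality filter, demultiplex, count).
gen_sorted_read_libraries2 <- function(truth, cfg, seed, full_reads) {
  if (!full_reads) {
    sim <- gen_sorted_counts(truth, cfg, seed = seed)
    return(list(counts = sim$counts, libraries = sim$libraries,
                state_truth = sim$state_truth))
  }
  sim <- gen_sorted_read_libraries(truth, cfg, seed = seed)
  filtered <- filter_reads(sim$reads, policy_sorted_cells())
  layout <- library_layout(
    index_length = cfg$index_length, flank_5 = cfg$flank_5,
    flank_3 = cfg$flank_3,
    barcode_length = nchar(truth$barcode[1])
  )
  demux <- demultiplex_and_extract(filtered$accepted, sim$libraries, layout,
                                   policy = policy_sorted_cells())
  list(counts = count_barcodes(demux$assignments), libraries = sim$libraries,
       state_truth = sim$state_truth,
       filter_tally = filtered$tally, demux_tally = demux$tally)
}

#' @export
print.clonotype_pipeline <- function(x, ...) {
  cat("<clonotype_pipeline>\n")
  cat(sprintf("  %d clones across %d libraries (seed %s)\n",
              nrow(x$phenotypes), nrow(x$libraries), format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @export
glance.clonotype_pipeline <- function(x, ...) x$summary
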