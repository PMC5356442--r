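#' Sorting specification for clone quantification
#'
#' Captures what is known about each sort: per-time-point mis-sort
#' proportions measured by post-sort flow cytometry, the population state
#' split at sorting, the pseudo-value used for undetected or over-corrected
#' entries, and the population-size model used for growth rates.
#'
#' @param sigma_e,sigma_m Mis-sort proportions per time point (recycled to
#'   the time points present): `sigma_e[t]` is the fraction of
#'   epithelial-sorted cells at time point t that are really mesenchymal
#'   (and symmetrically for `sigma_m`).
#' @param state_fraction_e Fraction of the population in the epithelial
#'   state at sorting (default 0.6).
#' @param pseudo Pseudo-value assigned to barcodes missing from a library
#'   and to entries driven to zero or below by contamination subtraction
#'   (default 1e-6).
#' @param pop_t0 Population size at the first sort (default 2.9e7 cells).
#' @param doublings_per_week Population growth rate used to extrapolate
#'   population size to later time points (default 3).
#' @return A `sort_spec` list.
#' @export
sort_spec <- function(sigma_e = 0.02, sigma_m = 0.02, state_fraction_e = 0.6,
                      pseudo = 1e-6, pop_t0 = 2.9e7, doublings_per_week = 3) {
  assert_proportion(sigma_e, "sigma_e", lt1 = TRUE)
  assert_proportion(sigma_m, "sigma_m", lt1 = TRUE)
  structure(list(
    sigma_e = sigma_e, sigma_m = sigma_m,
    state_fraction_e = assert_proportion(state_fraction_e, "state_fraction_e"),
    state_fraction_m = 1 - state_fraction_e,
    pseudo = pseudo, pop_t0 = pop_t0, doublings_per_week = doublings_per_week
  ), class = "sort_spec")
}

sigma_for <- function(spec, which, timepoints) {
  sig <- rep_len(spec[[which]], length(timepoints))
  setNames(sig, timepoints)
}

#' Normalize barcode counts into per-state clone abundances
#'
#' Each library's counts are divided by the library read sum and multiplied
#' by the fraction of the population in that library's cell state at
#' sorting (`state_fraction_e` for epithelial sorts, its complement for
#' mesenchymal). Barcodes from the clone universe that are absent from a
#' library receive the pseudo-value.
#'
#' @param counts Tibble: `library_id`, `barcode`, `count` (collapsed,
#'   persistence-filtered).
#' @param libraries Tibble: `library_id`, `timepoint`, `state` ("E"/"M"),
#'   `replicate`.
#' @param spec A [sort_spec()].
#' @param barcodes Clone universe; defaults to all barcodes in `counts`.
#' @return Tibble: `clone`, `library_id`, `timepoint`, `state`,
#'   `replicate`, `raw_fraction` (count / library sum; pseudo-scaled for
#'   absents), `value` (state-scaled normalized abundance), `pseudo` flag.
#' @export
normalize_counts <- function(counts, libraries, spec = sort_spec(),
                             barcodes = NULL) {
  barcodes <- barcodes %||% sort(unique(counts$barcode))
  sums <- counts %>% group_by(.data$library_id) %>%
    summarise(lib_sum = sum(.data$count), .groups = "drop")
  empty <- setdiff(libraries$library_id, sums$library_id)
  if (length(empty)) {
    abort(sprintf("library with no reads: %s", paste(empty, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(clone = barcodes, library_id = libraries$library_id)
  grid %>%
    left_join(counts, by = c(clone = "barcode", "library_id")) %>%
    left_join(sums, by = "library_id") %>%
    left_join(libraries[, c("library_id", "timepoint", "state", "replicate")],
              by = "library_id") %>%
    mutate(
      state_fraction = ifelse(.data$state == "E", spec$state_fraction_e,
                              spec$state_fraction_m),
      pseudo = is.na(.data$count),
      value = ifelse(.data$pseudo, spec$pseudo,
                     .data$count / .data$lib_sum * .data$state_fraction),
      raw_fraction = .data$value / .data$state_fraction
    ) %>%
    select("clone", "library_id", "timepoint", "state", "replicate",
           "raw_fraction", "value", "pseudo")
}

#' Subtract sort contamination and combine replicates
#'
#' For each clone, time point and sorted library, subtracts the clone's
#' average fraction of total reads in the other-state libraries of the same
#' time point multiplied by that sort's mis-sort proportion. Entries driven
#' to zero or below are floored at the pseudo-value. Replicate libraries
#' are then combined by their mean, yielding the clone-by-time-point state
#' matrix.
#'
#' @param normalized Output of [normalize_counts()].
#' @param spec A [sort_spec()].
#' @return Tibble (one row per clone x time point): `clone`, `timepoint`,
#'   `E`, `M`, `floored_e`, `floored_m` (TRUE when any contributing entry
#'   was pseudo-floored), `pseudo_e`, `pseudo_m` (TRUE when the clone was
#'   undetected in every library of that state/time point).
#' @export
correct_contamination <- function(normalized, spec = sort_spec()) {
  timepoints <- sort(unique(normalized$timepoint))
  sig_e <- sigma_for(spec, "sigma_e", timepoints)
  sig_m <- sigma_for(spec, "sigma_m", timepoints)
  other_frac <- normalized %>%
    group_by(.data$clone, .data$timepoint, .data$state) %>%
    summarise(avg_fraction = mean(.data$raw_fraction), .groups = "drop")
  corrected <- normalized %>%
    left_join(
      other_frac %>%
        mutate(state = ifelse(.data$state == "E", "M", "E")) %>%
        rename(other_avg_fraction = "avg_fraction"),
      by = c("clone", "timepoint", "state")
    ) %>%
    mutate(
      sigma = ifelse(.data$state == "E",
                     sig_e[as.character(.data$timepoint)],
                     sig_m[as.character(.data$timepoint)]),
      corrected = .data$value - .data$other_avg_fraction * .data$sigma,
      floored = .data$corrected <= 0,
      corrected = ifelse(.data$floored, spec$pseudo, .data$corrected)
    )
  corrected %>%
    group_by(.data$clone, .data$timepoint, .data$state) %>%
    summarise(
      value = mean(.data$corrected),
      floored = any(.data$floored),
      pseudo = all(.data$pseudo),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(
      names_from = "state",
      values_from = c("value", "floored", "pseudo"),
      names_glue = "{.value}_{tolower(state)}"
    ) %>%
    rename(E = "value_e", M = "value_m") %>%
    arrange(.data$clone, .data$timepoint)
}

#' Per-time-point phenotype metrics
#'
#' Fraction epithelial `E/(E + M)` and `log2(E/M)` per clone and time
#' point. Because both are ratios of normalized abundances, any global
#' rescaling of the E and M columns cancels. Pseudo-values keep both
#' defined for undetected states.
#'
#' @param mat Clone-state matrix from [correct_contamination()] (columns
#'   `clone`, `timepoint`, `E`, `M`).
#' @return Input tibble with `fraction_epithelial` and `log2_em` columns.
#' @export
phenotype_metrics <- function(mat) {
  mat %>%
    mutate(
      fraction_epithelial = .data$E / (.data$E + .data$M),
      log2_em = log2(.data$E / .data$M)
    )
}

#' Per-clone phenotype summary
#'
#' Averages the per-time-point log2(E/M) ratios arithmetically (the
#' geometric average of the ratios) and reports the matching fraction
#' epithelial, plus the spread of the per-time-point fractions.
#'
#' @param metrics Output of [phenotype_metrics()].
#' @return Tibble per clone: `clone`, `n_timepoints`, `log2_em_avg`,
#'   `fraction_epithelial_avg`, `delta_fraction` (absolute change in
#'   fraction epithelial between the first and last time points, i.e. over
#'   the full time course).
#' @export
clone_phenotypes <- function(metrics) {
  metrics %>%
    group_by(.data$clone) %>%
    arrange(.data$timepoint, .by_group = TRUE) %>%
    summarise(
      n_timepoints = dplyr::n(),
      log2_em_avg = mean(.data$log2_em),
      fraction_epithelial_avg = logistic2(mean(.data$log2_em)),
      delta_fraction = abs(dplyr::last(.data$fraction_epithelial) -
                             dplyr::first(.data$fraction_epithelial)),
      .groups = "drop"
    )
}

#' Clone growth rates in doublings per week
#'
#' Converts each clone's fraction of the population into absolute cell
#' numbers using the population-size model (`pop_t0` cells at the first
#' sort, growing at `doublings_per_week`), then computes
#' `log2(N_t / N_0) / t` for each later time point (time points are weeks)
#' and averages the interval rates.
#'
#' @param mat Clone-state matrix from [correct_contamination()].
#' @param spec A [sort_spec()].
#' @return Tibble per clone: `clone`, `k` (doublings/week), `unreliable`
#'   (TRUE when the clone was pseudo-only at the first time point).
#' @export
growth_rates <- function(mat, spec = sort_spec()) {
  timepoints <- sort(unique(mat$timepoint))
  if (length(timepoints) < 2) abort("need at least two time points.")
  t0 <- timepoints[1]
  sizes <- mat %>%
    mutate(total = .data$E + .data$M) %>%
    group_by(.data$timepoint) %>%
    mutate(pop_frac = .data$total / sum(.data$total)) %>%
    ungroup() %>%
    mutate(
      weeks = .data$timepoint - t0,
      pop_size = spec$pop_t0 * 2^(spec$doublings_per_week * .data$weeks),
      cells = .data$pop_frac * .data$pop_size
    )
  base <- sizes %>% filter(.data$timepoint == t0) %>%
    select("clone", n0 = "cells",
           pseudo_e0 = "pseudo_e", pseudo_m0 = "pseudo_m")
  sizes %>%
    filter(.data$timepoint != t0) %>%
    left_join(base, by = "clone") %>%
    mutate(rate = log2(.data$cells / .data$n0) / .data$weeks) %>%
    group_by(.data$clone) %>%
    summarise(
      k = mean(.data$rate),
      unreliable = any(.data$pseudo_e0 & .data$pseudo_m0),
      .groups = "drop"
    )
}

#' Shannon entropy of binned log-ratio values
#'
#' Bins finite values from their minimum to their maximum in bins of width
#' `bin_width` (width 1 on the log2 scale corresponds to a two-fold change
#' in ratio) and returns the Shannon entropy, in bits, of the bin
#' occupancy distribution.
#'
#' @param x Numeric values (non-finite entries are dropped).
#' @param bin_width Bin width (default 1).
#' @return Entropy in bits (0 when all values share one bin).
#' @export
ratio_entropy <- function(x, bin_width = 1) {
  x <- x[is.finite(x)]
  if (!length(x)) abort("need at least one finite value.")
  if (diff(range(x)) == 0) return(0)
  breaks <- seq(min(x), max(x) + bin_width, by = bin_width)
  p <- tabulate(findInterval(x, breaks, rightmost.closed = FALSE),
                nbins = length(breaks) - 1)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Gate single-cell-clone flow events against a pooled control
#'
#' Reproduces the internal-control gating strategy: the dye-labelled pooled
#' control events define K8/18 intensity thresholds such that the epithelial
#' and mesenchymal gates contain the configured proportions of control
#' cells; clone events are then classified with those thresholds.
#'
#' @param events Flow event tibble (see [gen_flow_events()]): columns
#'   `population`, `dye`, `intensity`.
#' @param gate_proportions Length-2 proportions `c(e, m)` the sorting gates
#'   contained (default `c(0.6, 0.4)`).
#' @param pseudo Pseudo-count used when a gate captures no clone events.
#' @return Tibble: `n_e`, `n_m`, `fraction_epithelial`, `log2_em`.
#' @export
gate_flow_clone <- function(events, gate_proportions = c(e = 0.6, m = 0.4),
                            pseudo = 1) {
  if (!"dye" %in% names(events) || length(unique(events$dye)) < 2) {
    abort("control and clone events must be distinguishable by the dye label.")
  }
  ctrl <- events$intensity[events$dye]
  clone <- events$intensity[!events$dye]
  if (length(ctrl) < 100 || length(clone) < 100) {
    abort("need at least 100 control and 100 clone events.")
  }
  hi <- quantile(ctrl, 1 - gate_proportions[[1]], names = FALSE)
  lo <- quantile(ctrl, gate_proportions[[2]], names = FALSE)
  n_e <- sum(clone > hi)
  n_m <- sum(clone <= lo)
  tibble(
    n_e = n_e, n_m = n_m,
    fraction_epithelial = n_e / (n_e + n_m),
    log2_em = log2((n_e + (n_e == 0) * pseudo) / (n_m + (n_m == 0) * pseudo))
  )
}
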