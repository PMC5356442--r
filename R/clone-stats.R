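#' Per-time-point contamination probabilities
#'
#' From the summed reads of each sorted state and the measured mis-sort
#' proportions, computes the probability that a read from a truly epithelial
#' cell appears in the mesenchymal-sorted library (`pC_e`) and vice versa
#' (`pC_m`). The epithelial-sorted reads decompose into correctly sorted
#' epithelial read mass `E = (1 - sigma_e) * sum(r_e)` and the mis-sorted
#' epithelial mass in the mesenchymal sort `E' = sigma_m * sum(r_m)`, giving
#' `pC_e = E' / (E + E')`; the mesenchymal case is symmetric.
#'
#' @param read_sums Tibble with `timepoint`, `sum_e`, `sum_m` (summed reads
#'   of the epithelial- and mesenchymal-sorted libraries).
#' @param sigma_e,sigma_m Mis-sort proportions per time point (recycled).
#' @return Tibble: `timepoint`, `E`, `E_prime`, `M`, `M_prime`, `pC_e`,
#'   `pC_m`.
#' @export
contamination_probabilities <- function(read_sums, sigma_e, sigma_m) {
  tps <- read_sums$timepoint
  sig_e <- rep_len(assert_proportion(sigma_e, "sigma_e", lt1 = TRUE), length(tps))
  sig_m <- rep_len(assert_proportion(sigma_m, "sigma_m", lt1 = TRUE), length(tps))
  out <- read_sums %>%
    mutate(
      E = (1 - sig_e) * .data$sum_e,
      E_prime = sig_m * .data$sum_m,
      M = (1 - sig_m) * .data$sum_m,
      M_prime = sig_e * .data$sum_e,
      pC_e = .data$E_prime / (.data$E + .data$E_prime),
      pC_m = .data$M_prime / (.data$M + .data$M_prime)
    )
  if (any(!is.finite(out$pC_e)) || any(!is.finite(out$pC_m))) {
    abort("contamination probability undefined (zero read mass).")
  }
  out
}

#' Summed clone reads per state and time point
#'
#' Helper shaping a count table into the un-normalized per-clone read sums
#' (`r_e`, `r_m`) the lineage tests consume: replicate libraries of the same
#' state and time point are summed.
#'
#' @param counts Tibble: `library_id`, `barcode`, `count`.
#' @param libraries Tibble: `library_id`, `timepoint`, `state`.
#' @param barcodes Clone universe (default: barcodes present in `counts`).
#' @return Tibble: `clone`, `timepoint`, `r_e`, `r_m` (absent = 0 reads).
#' @export
clone_read_sums <- function(counts, libraries, barcodes = NULL) {
  barcodes <- barcodes %||% sort(unique(counts$barcode))
  counts %>%
    left_join(libraries[, c("library_id", "timepoint", "state")],
              by = "library_id") %>%
    group_by(clone = .data$barcode, .data$timepoint, .data$state) %>%
    summarise(reads = sum(as.numeric(.data$count)), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "state", values_from = "reads",
                       values_fill = 0) %>%
    (function(tb) {
      for (s in c("E", "M")) if (!s %in% names(tb)) tb[[s]] <- 0
      tb
    }) %>%
    rename(r_e = "E", r_m = "M") %>%
    tidyr::complete(clone = barcodes,
                    timepoint = sort(unique(libraries$timepoint)),
                    fill = list(r_e = 0, r_m = 0)) %>%
    arrange(.data$clone, .data$timepoint)
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up false-discovery-rate control: returns which p-values are rejected
#' at level `alpha`.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Logical vector, TRUE where rejected (empty input gives empty
#'   output).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(logical(0))
  p.adjust(pvalues, method = "BH") <= alpha
}

#' Contamination-aware bi-lineage test
#'
#' For each clone and time point, tests the null hypothesis that the clone
#' is entirely epithelial: its mesenchymal-sorted reads should then be
#' explained by mis-sorting alone, so the observed `r_m` is referred to the
#' upper tail `P(X >= r_m)` of Binomial(n = r_e + r_m, p = pC_e). The
#' symmetric null (entirely mesenchymal) refers `r_e` to
#' Binomial(n, pC_m). All p-values across clones, states and time points
#' form one Benjamini-Hochberg family at FDR `fdr`. A clone is called
#' `mono_E`/`mono_M` when the opposite-state null is rejected at every time
#' point while its own-state null is never rejected; `bilineage` when both
#' nulls are rejected at one or more shared time points; otherwise
#' `indeterminate`. Time points where a clone has zero reads are excluded
#' and flagged.
#'
#' @param reads Tibble from [clone_read_sums()]: `clone`, `timepoint`,
#'   `r_e`, `r_m` (replicates summed, un-normalized).
#' @param probs Tibble from [contamination_probabilities()].
#' @param fdr FDR level (default 0.05).
#' @return Object of class `bilineage_test`: list with `per_timepoint`
#'   (tibble: clone, timepoint, n, p_all_e, p_all_m, reject_all_e,
#'   reject_all_m, excluded) and `calls` (tibble: clone, call).
#' @export
bilineage_test <- function(reads, probs, fdr = 0.05) {
  tb <- reads %>%
    left_join(probs[, c("timepoint", "pC_e", "pC_m")], by = "timepoint") %>%
    mutate(
      n = .data$r_e + .data$r_m,
      excluded = .data$n == 0,
      # upper tail including the observed count: P(X >= x)
      p_all_e = ifelse(.data$excluded, NA_real_,
                       pbinom(.data$r_m - 1, .data$n, .data$pC_e,
                              lower.tail = FALSE)),
      p_all_m = ifelse(.data$excluded, NA_real_,
                       pbinom(.data$r_e - 1, .data$n, .data$pC_m,
                              lower.tail = FALSE))
    )
  pool <- c(tb$p_all_e[!tb$excluded], tb$p_all_m[!tb$excluded])
  rej <- bh_fdr(pool, fdr)
  k <- sum(!tb$excluded)
  tb$reject_all_e <- tb$reject_all_m <- NA
  tb$reject_all_e[!tb$excluded] <- rej[seq_len(k)]
  tb$reject_all_m[!tb$excluded] <- rej[k + seq_len(k)]
  calls <- tb %>%
    filter(!.data$excluded) %>%
    group_by(.data$clone) %>%
    summarise(
      call = dplyr::case_when(
        any(.data$reject_all_e & .data$reject_all_m) ~ "bilineage",
        all(.data$reject_all_m) && !any(.data$reject_all_e) ~ "mono_E",
        all(.data$reject_all_e) && !any(.data$reject_all_m) ~ "mono_M",
        TRUE ~ "indeterminate"
      ),
      .groups = "drop"
    )
  structure(
    list(per_timepoint = tb %>%
           select("clone", "timepoint", "r_e", "r_m", "n", "p_all_e",
                  "p_all_m", "reject_all_e", "reject_all_m", "excluded"),
         calls = calls, fdr = fdr),
    class = "bilineage_test"
  )
}

#' Chi-squared test for clone state bias
#'
#' Tests, per clone and time point, whether the clone's split of reads
#' between the sorted states matches the population split. Expected reads
#' scale the clone's total to the state totals'
#' proportions: `E_e = r_total * sum_e / (sum_e + sum_m)` (and
#' symmetrically), and the statistic
#' `x = (r_e - E_e)^2 / E_e + (r_m - E_m)^2 / E_m` is referred to the upper
#' tail of chi-squared with one degree of freedom. All p-values form one
#' Benjamini-Hochberg family at FDR `fdr`; a clone is called `biased` when
#' the null is rejected at every time point.
#'
#' @param reads Tibble from [clone_read_sums()].
#' @param fdr FDR level (default 0.05).
#' @return Object of class `bias_test`: list with `per_timepoint` (tibble:
#'   clone, timepoint, statistic, p, reject, skipped) and `calls` (tibble:
#'   clone, call in {"biased", "population_like"}).
#' @export
bias_test <- function(reads, fdr = 0.05) {
  totals <- reads %>%
    group_by(.data$timepoint) %>%
    summarise(sum_e = sum(.data$r_e), sum_m = sum(.data$r_m), .groups = "drop")
  tb <- reads %>%
    left_join(totals, by = "timepoint") %>%
    mutate(
      total = .data$r_e + .data$r_m,
      exp_e = .data$total * .data$sum_e / (.data$sum_e + .data$sum_m),
      exp_m = .data$total * .data$sum_m / (.data$sum_e + .data$sum_m),
      skipped = .data$exp_e == 0 | .data$exp_m == 0,
      statistic = ifelse(.data$skipped, NA_real_,
                         (.data$r_e - .data$exp_e)^2 / .data$exp_e +
                           (.data$r_m - .data$exp_m)^2 / .data$exp_m),
      p = pchisq(.data$statistic, df = 1, lower.tail = FALSE)
    )
  tb$reject <- NA
  tb$reject[!tb$skipped] <- bh_fdr(tb$p[!tb$skipped], fdr)
  calls <- tb %>%
    filter(!.data$skipped) %>%
    group_by(.data$clone) %>%
    summarise(call = ifelse(all(.data$reject), "biased", "population_like"),
              .groups = "drop")
  structure(
    list(per_timepoint = tb %>%
           select("clone", "timepoint", "r_e", "r_m", "exp_e", "exp_m",
                  "statistic", "p", "reject", "skipped"),
         calls = calls, fdr = fdr),
    class = "bias_test"
  )
}

#' Permutation test for a Pearson correlation
#'
#' Shuffles the pairing of `y` against `x` `reps` times, recording the
#' Pearson correlation of each shuffled pairing, and reports the proportion
#' of shuffles with a correlation at least as large as observed. The
#' empirical p-value is reported with the `(k + 1) / (reps + 1)` correction
#' so it is never exactly zero; the raw exceed count is also returned.
#'
#' @param x,y Paired numeric vectors (finite, length >= 3).
#' @param reps Number of random permutations (default 1e5).
#' @param seed Optional integer seed.
#' @return Object of class `permutation_cor`: list with `rho` (observed),
#'   `exceed` (number of permutations with rho_perm >= rho), `reps`,
#'   `p` (= (exceed + 1) / (reps + 1)), and `perm_rho` (the permuted
#'   correlations, for plotting).
#' @export
permutation_correlation <- function(x, y, reps = 1e5, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be paired vectors of length >= 3.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance.")
  }
  reps <- assert_count(reps, "reps")
  n <- length(x)
  rho <- cor(x, y)
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  with_seed(seed, {
    chunk <- 50000L
    exceed <- 0L
    done <- 0L
    keep <- min(reps, 100000L)
    perm_rho <- numeric(0)
    while (done < reps) {
      m <- min(chunk, reps - done)
      perm <- matrix(0, n, m)
      for (j in seq_len(m)) perm[, j] <- ys[sample.int(n)]
      r <- as.numeric(crossprod(xs, perm)) / (n - 1)
      # small tolerance so permutations reproducing the observed pairing
      # are counted despite floating-point rounding
      exceed <- exceed + sum(r >= rho - 1e-12)
      if (length(perm_rho) < keep) {
        perm_rho <- c(perm_rho, r[seq_len(min(m, keep - length(perm_rho)))])
      }
      done <- done + m
    }
    structure(
      list(rho = rho, exceed = exceed, reps = reps,
           p = (exceed + 1) / (reps + 1), perm_rho = perm_rho),
      class = "permutation_cor"
    )
  })
}

#' Narrow-sense heritability of clone phenotype
#'
#' Pearson correlation between each clone's log2(E/M) measured in expanded
#' single-cell subclones and the same clone's ratio in the parental pooled
#' population, with a permutation test of its significance. Clones present
#' in only one of the two tables are dropped with a warning.
#'
#' @param pooled Tibble: `clone_id` (or `barcode`), `log2_em` in the pooled
#'   population.
#' @param subclones Tibble: same id column, `log2_em` in the subclone.
#' @param reps Permutations for the significance test.
#' @param seed Optional integer seed.
#' @return Object of class `heritability`: list with `rho`, `n`,
#'   `permutation` (a `permutation_cor`), and `pairs` (the matched tibble).
#' @export
heritability <- function(pooled, subclones, reps = 1e5, seed = NULL) {
  id <- intersect(c("clone_id", "barcode"), intersect(names(pooled), names(subclones)))
  if (!length(id)) abort("no shared id column (clone_id or barcode).")
  id <- id[1]
  pairs <- dplyr::inner_join(
    pooled %>% select(!!id, pooled_log2_em = "log2_em"),
    subclones %>% select(!!id, subclone_log2_em = "log2_em"),
    by = id
  )
  dropped <- nrow(pooled) + nrow(subclones) - 2 * nrow(pairs)
  if (dropped > 0) {
    warn(sprintf("%d unmatched clone record(s) dropped.", dropped))
  }
  if (nrow(pairs) < 3) abort("need at least 3 matched clone pairs.")
  perm <- permutation_correlation(pairs$pooled_log2_em, pairs$subclone_log2_em,
                                  reps = reps, seed = seed)
  structure(
    list(rho = perm$rho, n = nrow(pairs), permutation = perm, pairs = pairs),
    class = "heritability"
  )
}
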