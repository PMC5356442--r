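#' Coverage-based library complexity estimate
#'
#' Estimates a lower bound on the number of distinct barcodes in a pool from
#' a read sample, using the sample-coverage (Good) estimator: coverage
#' `C = 1 - f1/n` and `N_hat = D / C`, where `n` is the sample size, `D` the
#' number of distinct barcodes observed and `f1` the number observed exactly
#' once.
#'
#' @param n Sample size (reads), > 0.
#' @param D Distinct barcodes observed (`f1 <= D <= n`).
#' @param f1 Barcodes observed exactly once.
#' @return Tibble: `n`, `D`, `f1`, `coverage`, `N_hat`.
#' @examples
#' estimate_complexity(n = 2447204, D = 1530822, f1 = 989844)
#' @export
estimate_complexity <- function(n, D, f1) {
  if (!(n > 0 && f1 >= 0 && f1 <= D && D <= n)) {
    abort("require 0 <= f1 <= D <= n and n > 0.")
  }
  coverage <- 1 - f1 / n
  if (coverage <= 0) {
    abort("every barcode was seen once (coverage 0); complexity not estimable.")
  }
  tibble(n = n, D = D, f1 = f1, coverage = coverage, N_hat = D / coverage)
}

#' Sampling experiment for the complexity estimator
#'
#' Draws `n` reads uniformly (with replacement) from `N_true` equally likely
#' barcodes, tabulates `D` and `f1`, applies [estimate_complexity()], and
#' repeats. Documents the estimator's lower-bound behaviour: `N_hat >= D`
#' always, with `N_hat` near `N_true` only once coverage is high.
#'
#' @param N_true True pool complexity.
#' @param n Reads per replicate.
#' @param reps Replicates (>= 1).
#' @param seed Optional integer seed.
#' @return Tibble with one row per replicate: `rep`, `D`, `f1`, `coverage`,
#'   `N_hat`, `ratio` (= N_hat / N_true).
#' @export
complexity_recovery_sim <- function(N_true, n, reps = 20, seed = NULL) {
  reps <- assert_count(reps, "reps")
  with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      draws <- sample.int(N_true, n, replace = TRUE)
      tab <- tabulate(draws)
      D <- sum(tab > 0)
      f1 <- sum(tab == 1)
      est <- estimate_complexity(n, D, f1)
      tibble(rep = r, D = D, f1 = f1, coverage = est$coverage,
             N_hat = est$N_hat, ratio = est$N_hat / N_true)
    })
  })
}

#' Poisson model of viral integrations per cell
#'
#' With a fraction `frac_infected` of cells carrying at least one
#' integration and integration counts Poisson distributed, the multiplicity
#' of infection is `m = -ln(1 - frac_infected)`; the returned table gives
#' `P(n)` for n = 0..`max_n`. Infecting 13% of cells gives m = 0.139.
#'
#' @param frac_infected Proportion of cells infected, in [0, 1).
#' @param max_n Largest integration count tabulated.
#' @return List: `m` (the MOI) and `pmf` (tibble `n`, `p`).
#' @export
moi_model <- function(frac_infected, max_n = 10) {
  frac_infected <- assert_proportion(frac_infected, "frac_infected", lt1 = TRUE)
  m <- -log(1 - frac_infected)
  list(m = m, pmf = tibble(n = 0:max_n, p = dpois(0:max_n, m)))
}

#' Probability any two cells share a barcode (birthday problem)
#'
#' With `c` cells each independently labelled by one of `N` equally likely
#' barcodes, the probability all labels are distinct is
#' `P(A') = prod_{i=0}^{c-1} (N - i)/N`, computed in log space to avoid
#' underflow; the returned value is `P(A) = 1 - P(A')`.
#'
#' @param N Pool size.
#' @param c Number of cells; if `c > N`, returns 1 (pigeonhole).
#' @return Probability that at least two cells share a barcode.
#' @examples
#' prob_any_shared_barcode(N = 365, c = 23)  # ~0.507
#' @export
prob_any_shared_barcode <- function(N, c) {
  c <- assert_count(c, "c")
  if (c > N) return(1.0)
  if (c == 1) return(0.0)
  log_p_unique <- sum(log1p(-(seq_len(c - 1)) / N))
  1 - exp(log_p_unique)
}

#' Simulate the distribution of barcode sharing among cells
#'
#' Each replicate draws `c` barcodes uniformly (with replacement) from a
#' pool of `N` and counts how many cells carry a barcode that occurs in two
#' or more cells. Returns the empirical distribution of that count, whose
#' `P(count > 0)` is consistent with [prob_any_shared_barcode()].
#'
#' @param N Pool size.
#' @param c Cells per replicate.
#' @param reps Replicates.
#' @param seed Optional integer seed.
#' @return Tibble: `cells_sharing`, `n_reps`, `p` (empirical probability).
#' @export
barcode_sharing_sim <- function(N, c, reps = 1000, seed = NULL) {
  reps <- assert_count(reps, "reps")
  with_seed(seed, {
    shared <- vapply(seq_len(reps), function(r) {
      draws <- sample.int(N, c, replace = TRUE)
      dup <- duplicated(draws) | duplicated(draws, fromLast = TRUE)
      sum(dup)
    }, integer(1))
    tibble(cells_sharing = sort(unique(shared))) %>%
      mutate(
        n_reps = vapply(.data$cells_sharing, function(k) sum(shared == k), integer(1)),
        p = .data$n_reps / reps
      )
  })
}
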