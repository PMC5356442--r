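# Simulation clock: 15 time points model one day; a course of therapy is a
# 30-point treatment block followed by a 20-point rest block.
POINTS_PER_DAY <- 15
TREAT_BLOCK <- 30
REST_BLOCK <- 20

#' Seed a simulated tumour from an empirical clone table
#'
#' Samples `n_clones` clones with replacement from the observed clone table
#' so the simulated tumour matches the observed joint distribution of
#' plasticity, growth rate and clone size. Each clone keeps its fraction
#' epithelial (as an equilibrium ratio `R = f/(1-f)`), its doubling time
#' converted to simulation time points, and its starting cells split
#' between the states at the equilibrium fractions.
#'
#' @param table Tibble with `fraction_epithelial`, `doubling_time` (days)
#'   and `initial_cells` (from [gen_empirical_clone_table()] or
#'   [read_empirical_clone_table()]).
#' @param n_clones Clones per tumour (default 500).
#' @param seed Optional integer seed.
#' @return Tibble, one row per clone: `clone`, `frac_e` (equilibrium),
#'   `R` (E:M ratio, Inf/0 for pure clones), `D` (doubling time in time
#'   points), `N_e`, `N_m` (real-valued cell counts).
#' @export
build_tumour <- function(table, n_clones = 500, seed = NULL) {
  if (nrow(table) == 0) abort("empirical clone table is empty.")
  n_clones <- assert_count(n_clones, "n_clones")
  with_seed(seed, {
    idx <- sample.int(nrow(table), n_clones, replace = TRUE)
    picked <- table[idx, ]
    f <- picked$fraction_epithelial
    tibble(
      clone = seq_len(n_clones),
      frac_e = f,
      R = f / (1 - f),
      D = picked$doubling_time * POINTS_PER_DAY,
      N_e = picked$initial_cells * f,
      N_m = picked$initial_cells * (1 - f)
    )
  })
}

#' Exponential growth for one simulation step
#'
#' Multiplies both state populations by `2^(dt / D)`: after `D` time points
#' a clone's cells have doubled.
#'
#' @param clones Tumour tibble from [build_tumour()].
#' @param dt Time step in simulation points (default 1).
#' @return The tibble with updated `N_e`, `N_m`.
#' @export
advance_growth <- function(clones, dt = 1) {
  g <- 2^(dt / clones$D)
  clones$N_e <- clones$N_e * g
  clones$N_m <- clones$N_m * g
  clones
}

# Per-time-point transition probabilities for a clone: a fraction psi of
# cells changes state per division, split so that P(m->e)/P(e->m) = R
# (making R the fixed point), then spread across the D steps of a division.
transition_probs <- function(R, D, psi) {
  p_em <- psi / (1 + R)        # epithelial -> mesenchymal, per division
  p_me <- psi * R / (1 + R)    # mesenchymal -> epithelial, per division
  p_em[!is.finite(R)] <- 0     # pure-E clones never leave E
  p_me[!is.finite(R)] <- psi   # ... and absorb any M cells
  pure_m <- R == 0
  p_em[pure_m] <- psi
  p_me[pure_m] <- 0
  list(p_em = p_em / D, p_me = p_me / D)
}

#' Stochastic state switching for one simulation step
#'
#' Deterministic flux form of the per-cell switching probabilities:
#' `dN_e = N_m * P(m->e) - N_e * P(e->m)`, with the per-division switch
#' probability `psi` split between the directions in the ratio of the
#' clone's equilibrium (`P(m->e)/P(e->m) = R`) and divided across the `D`
#' steps of one division. Total cells are conserved and the equilibrium
#' fraction `R/(1+R)` is a fixed point. State-pure clones (R of 0 or Inf)
#' send all switching toward their pure state.
#'
#' @param clones Tumour tibble.
#' @param psi Fraction of cells changing state per division (default 0.2).
#' @return The tibble with updated `N_e`, `N_m`.
#' @export
advance_differentiation <- function(clones, psi = 0.2) {
  assert_proportion(psi, "psi")
  pr <- transition_probs(clones$R, clones$D, psi)
  flux <- clones$N_m * pr$p_me - clones$N_e * pr$p_em
  clones$N_e <- clones$N_e + flux
  clones$N_m <- clones$N_m - flux
  clones
}

#' Phenotype-selective kill for one treatment time point
#'
#' A treatment targeting one state kills `kill_frac` of that state's cells
#' and `kill_frac / selectivity` of the other state's cells at each treated
#' time point.
#'
#' @param clones Tumour tibble.
#' @param target "E" or "M".
#' @param kill_frac Fraction of targeted cells killed per time point, in
#'   [0, 1).
#' @param selectivity Fold difference between on- and off-target kill
#'   (default 10, >= 1).
#' @return The tibble with updated `N_e`, `N_m`.
#' @export
apply_treatment <- function(clones, target, kill_frac, selectivity = 10) {
  if (!target %in% c("E", "M")) abort('`target` must be "E" or "M".')
  if (kill_frac < 0 || kill_frac >= 1) abort("`kill_frac` must be in [0, 1).")
  if (selectivity < 1) abort("`selectivity` must be >= 1.")
  off <- kill_frac / selectivity
  if (off >= 1) abort("off-target kill fraction must be < 1.")
  if (target == "E") {
    clones$N_e <- clones$N_e * (1 - kill_frac)
    clones$N_m <- clones$N_m * (1 - off)
  } else {
    clones$N_m <- clones$N_m * (1 - kill_frac)
    clones$N_e <- clones$N_e * (1 - off)
  }
  clones
}

#' Treatment schedule constructors
#'
#' A schedule is a tibble of blocks (`mode` in {"treat_E", "treat_M",
#' "rest"}, `duration` in time points). Every course of therapy is a
#' 30-point treatment block followed by a 20-point rest; `rate` scales the
#' alternation frequency (rate 2 halves block durations while doubling
#' their number, conserving total treated time points).
#'
#' `schedule_mono()` repeats one treatment; `schedule_sequential()` gives
#' all courses of the first treatment then all of the second (e.g. 3:3 or
#' 7:1); `schedule_alternating()` interleaves them; `schedule_library()`
#' returns the named designs used in the treatment comparisons.
#'
#' @param target,first "E" or "M".
#' @param courses,courses_e,courses_m Number of treatment courses.
#' @param cycles Repetitions of the whole pattern.
#' @param rate Alternation-rate multiplier (integer >= 1).
#' @return A tibble with columns `mode`, `duration`.
#' @export
schedule_mono <- function(target = "E", courses = 3, cycles = 1) {
  block <- tibble(mode = c(paste0("treat_", target), "rest"),
                  duration = c(TREAT_BLOCK, REST_BLOCK))
  purrr::map_dfr(seq_len(courses * cycles), ~block)
}

#' @rdname schedule_mono
#' @export
schedule_sequential <- function(courses_e = 3, courses_m = 3, cycles = 1,
                                first = "E") {
  course <- function(target) tibble(mode = c(paste0("treat_", target), "rest"),
                                    duration = c(TREAT_BLOCK, REST_BLOCK))
  second <- setdiff(c("E", "M"), first)
  one_cycle <- bind_rows(
    purrr::map_dfr(seq_len(if (first == "E") courses_e else courses_m),
                   ~course(first)),
    purrr::map_dfr(seq_len(if (first == "E") courses_m else courses_e),
                   ~course(second))
  )
  purrr::map_dfr(seq_len(cycles), ~one_cycle)
}

#' @rdname schedule_mono
#' @export
schedule_alternating <- function(courses = 3, cycles = 1, rate = 1,
                                 first = "E") {
  rate <- assert_count(rate, "rate")
  treat_len <- TREAT_BLOCK / rate
  rest_len <- REST_BLOCK / rate
  if (treat_len != floor(treat_len) || rest_len != floor(rest_len)) {
    abort("`rate` must divide the 30-point treatment and 20-point rest blocks.")
  }
  second <- setdiff(c("E", "M"), first)
  pair <- tibble(
    mode = c(paste0("treat_", first), "rest", paste0("treat_", second), "rest"),
    duration = c(treat_len, rest_len, treat_len, rest_len)
  )
  purrr::map_dfr(seq_len(courses * rate * cycles), ~pair)
}

#' @rdname schedule_mono
#' @export
schedule_library <- function(cycles = 1) {
  list(
    mono_E = schedule_mono("E", courses = 3, cycles = cycles),
    mono_M = schedule_mono("M", courses = 3, cycles = cycles),
    sequential_3_3 = schedule_sequential(3, 3, cycles = cycles),
    sequential_7_1 = schedule_sequential(7, 1, cycles = cycles),
    sequential_1_7 = schedule_sequential(1, 7, cycles = cycles),
    alternating = schedule_alternating(3, cycles = cycles, rate = 1),
    alternating_2x = schedule_alternating(3, cycles = cycles, rate = 2)
  )
}

# Expand a schedule into a per-time-point mode vector.
schedule_modes <- function(schedule) {
  if (any(schedule$duration <= 0)) abort("schedule durations must be > 0.")
  rep(schedule$mode, schedule$duration)
}

#' Run a treatment schedule over simulated tumours
#'
#' Seeds `reps` tumours (the only stochastic step: clones are resampled
#' from the empirical table per replicate), then advances deterministic
#' population dynamics one time point at a time: growth, then state
#' switching, then—during treatment blocks—the phenotype-selective kill.
#' Each clone's fold change `fc = N(end) / N(start)` is recorded; clones
#' are binned by their equilibrium fraction epithelial, the per-bin median
#' fold change and the total surviving cells are computed per replicate,
#' and the 0.1/0.5/0.9 quantiles across replicates are reported.
#'
#' @param table Empirical clone table (see [build_tumour()]).
#' @param schedule Schedule tibble (see [schedule_mono()]).
#' @param reps Number of simulated tumours (default 500).
#' @param n_clones Clones per tumour (default 500).
#' @param kill_frac On-target kill fraction per treated time point
#'   (default 0.142, so one 30-point course kills ~99% of the targeted
#'   state).
#' @param selectivity On/off-target kill ratio (default 10).
#' @param psi Per-division state-switch probability (default 0.2).
#' @param bins Bin breaks for fraction epithelial (default 10 equal bins).
#' @param seed Optional integer seed.
#' @return Object of class `treatment_sim`: list with `fold_change`
#'   (tibble: `bin`, `bin_mid`, `q10`, `median`, `q90` of the per-bin
#'   median fold change), `surviving` (tibble: `q10`, `median`, `q90` of
#'   total surviving cells), `schedule`, and parameters.
#' @export
run_schedule <- function(table, schedule, reps = 500, n_clones = 500,
                         kill_frac = 0.142, selectivity = 10, psi = 0.2,
                         bins = seq(0, 1, by = 0.1), seed = NULL) {
  reps <- assert_count(reps, "reps")
  modes <- schedule_modes(schedule)
  with_seed(seed, {
    idx <- matrix(sample.int(nrow(table), reps * n_clones, replace = TRUE),
                  n_clones, reps)
    f <- matrix(table$fraction_epithelial[idx], n_clones, reps)
    D <- matrix(table$doubling_time[idx] * POINTS_PER_DAY, n_clones, reps)
    size <- matrix(table$initial_cells[idx], n_clones, reps)
    R <- f / (1 - f)
    N_e <- size * f
    N_m <- size * (1 - f)
    N0 <- N_e + N_m
    pr <- transition_probs(R, D, psi)  # already per time point (per-division / D)
    p_em <- pr$p_em
    p_me <- pr$p_me
    off <- kill_frac / selectivity
    for (mode in modes) {
      g <- 2^(1 / D)
      N_e <- N_e * g
      N_m <- N_m * g
      flux <- N_m * p_me - N_e * p_em
      N_e <- N_e + flux
      N_m <- N_m - flux
      if (mode == "treat_E") {
        N_e <- N_e * (1 - kill_frac)
        N_m <- N_m * (1 - off)
      } else if (mode == "treat_M") {
        N_m <- N_m * (1 - kill_frac)
        N_e <- N_e * (1 - off)
      }
    }
    fc <- (N_e + N_m) / N0
    bin <- matrix(cut(f, breaks = bins, include.lowest = TRUE, labels = FALSE),
                  n_clones, reps)
    per_bin <- purrr::map_dfr(seq_len(length(bins) - 1), function(b) {
      med <- vapply(seq_len(reps), function(r) {
        v <- fc[bin[, r] == b & !is.na(bin[, r]), r]
        if (length(v)) median(v) else NA_real_
      }, numeric(1))
      med <- med[!is.na(med)]
      if (!length(med)) {
        return(tibble(bin = b, bin_mid = (bins[b] + bins[b + 1]) / 2,
                      q10 = NA_real_, median = NA_real_, q90 = NA_real_))
      }
      tibble(
        bin = b, bin_mid = (bins[b] + bins[b + 1]) / 2,
        q10 = quantile(med, 0.1, names = FALSE),
        median = median(med),
        q90 = quantile(med, 0.9, names = FALSE)
      )
    })
    totals <- colSums(N_e + N_m)
    structure(
      list(
        fold_change = per_bin,
        surviving = tibble(
          q10 = quantile(totals, 0.1, names = FALSE),
          median = median(totals),
          q90 = quantile(totals, 0.9, names = FALSE)
        ),
        schedule = schedule, reps = reps, n_clones = n_clones,
        kill_frac = kill_frac, selectivity = selectivity, psi = psi
      ),
      class = "treatment_sim"
    )
  })
}
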