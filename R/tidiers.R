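# broom-style tidiers for the package's result objects.

#' Tidy per-observation results
#'
#' `tidy()` returns per-clone/per-time-point detail; `glance()` returns a
#' one-row summary.
#'
#' @param x A `bilineage_test`, `bias_test`, `permutation_cor`,
#'   `heritability` or `treatment_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.bilineage_test <- function(x, ...) {
  x$per_timepoint %>% left_join(x$calls, by = "clone")
}

#' @rdname tidiers
#' @export
glance.bilineage_test <- function(x, ...) {
  calls <- x$calls$call
  tibble(
    n_clones = length(calls),
    frac_bilineage = mean(calls == "bilineage"),
    frac_mono_e = mean(calls == "mono_E"),
    frac_mono_m = mean(calls == "mono_M"),
    frac_indeterminate = mean(calls == "indeterminate"),
    fdr = x$fdr
  )
}

#' @rdname tidiers
#' @export
tidy.bias_test <- function(x, ...) {
  x$per_timepoint %>% left_join(x$calls, by = "clone")
}

#' @rdname tidiers
#' @export
glance.bias_test <- function(x, ...) {
  tibble(
    n_clones = nrow(x$calls),
    frac_biased = mean(x$calls$call == "biased"),
    fdr = x$fdr
  )
}

#' @rdname tidiers
#' @export
tidy.permutation_cor <- function(x, ...) {
  tibble(perm_rho = x$perm_rho)
}

#' @rdname tidiers
#' @export
glance.permutation_cor <- function(x, ...) {
  tibble(rho = x$rho, exceed = x$exceed, reps = x$reps, p = x$p)
}

#' @rdname tidiers
#' @export
tidy.heritability <- function(x, ...) as_tibble(x$pairs)

#' @rdname tidiers
#' @export
glance.heritability <- function(x, ...) {
  tibble(rho = x$rho, n = x$n, p = x$permutation$p,
         exceed = x$permutation$exceed, reps = x$permutation$reps)
}

#' @rdname tidiers
#' @export
tidy.treatment_sim <- function(x, ...) x$fold_change

#' @rdname tidiers
#' @export
glance.treatment_sim <- function(x, ...) {
  dplyr::bind_cols(
    x$surviving %>% rename(surviving_q10 = "q10", surviving_median = "median",
                           surviving_q90 = "q90"),
    tibble(reps = x$reps, n_clones = x$n_clones, kill_frac = x$kill_frac)
  )
}

#' @export
print.bilineage_test <- function(x, ...) {
  cat("<bilineage_test>\n")
  print(glance(x))
  invisible(x)
}

#' @export
print.bias_test <- function(x, ...) {
  cat("<bias_test>\n")
  print(glance(x))
  invisible(x)
}

#' @export
print.permutation_cor <- function(x, ...) {
  cat(sprintf("<permutation_cor> rho = %.4f, p = %.3g (%d of %d permutations >= observed)\n",
              x$rho, x$p, x$exceed, x$reps))
  invisible(x)
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("<heritability> rho = %.4f over %d clone pairs, permutation p = %.3g\n",
              x$rho, x$n, x$permutation$p))
  invisible(x)
}

#' @export
print.treatment_sim <- function(x, ...) {
  cat(sprintf("<treatment_sim> %d reps x %d clones, kill_frac %.3f\n",
              x$reps, x$n_clones, x$kill_frac))
  cat(sprintf("  surviving cells median %.3g [%.3g, %.3g]\n",
              x$surviving$median, x$surviving$q10, x$surviving$q90))
  invisible(x)
}
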