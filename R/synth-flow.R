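#' Simulate flow-cytometry events for a single-cell clone assay
#'
#' Emulates the internal-control design used to phenotype expanded
#' single-cell clones: the parental pooled population is covalently labelled
#' with a live/dead discrimination dye, mixed 1:1 with the clone, and both
#' are stained for keratin 8/18. Intensities are drawn from a two-component
#' log-normal model (a low, mesenchymal component and a high, epithelial
#' component); the control mixes the components at `control_mix`, the clone
#' at `clone_fraction_e`.
#'
#' @param clone_fraction_e Fraction of clone events drawn from the high
#'   (epithelial) component.
#' @param control_mix Length-2 proportions `c(e, m)` for the control
#'   population (must sum to 1).
#' @param n_events Events per population (>= 100).
#' @param channel_model List with `meanlog_low`, `meanlog_high`, `sdlog`
#'   describing the two intensity components. A zero-variance model is
#'   flagged degenerate (warning) but still generated.
#' @param seed Optional integer seed.
#' @return Tibble: `population` ("control"/"clone"), `dye` (TRUE for the
#'   dye-labelled control), `state_truth` ("E"/"M" component of origin),
#'   `intensity`.
#' @export
gen_flow_events <- function(clone_fraction_e,
                            control_mix = c(e = 0.6, m = 0.4),
                            n_events = 10000,
                            channel_model = list(meanlog_low = 4, meanlog_high = 6,
                                                 sdlog = 0.5),
                            seed = NULL) {
  n_events <- assert_count(n_events, "n_events", min = 100)
  clone_fraction_e <- assert_proportion(clone_fraction_e, "clone_fraction_e")
  if (abs(sum(control_mix) - 1) > 1e-9) abort("`control_mix` must sum to 1.")
  if (channel_model$sdlog <= 0) {
    warn("degenerate channel model (zero variance); generating anyway.")
    channel_model$sdlog <- max(channel_model$sdlog, 0)
  }
  with_seed(seed, {
    draw <- function(frac_e, n) {
      is_e <- runif(n) < frac_e
      meanlog <- ifelse(is_e, channel_model$meanlog_high, channel_model$meanlog_low)
      tibble(
        state_truth = ifelse(is_e, "E", "M"),
        intensity = rlnorm(n, meanlog, channel_model$sdlog)
      )
    }
    ctrl <- draw(control_mix[[1]], n_events)
    clone <- draw(clone_fraction_e, n_events)
    dplyr::bind_rows(
      dplyr::mutate(ctrl, population = "control", dye = TRUE),
      dplyr::mutate(clone, population = "clone", dye = FALSE)
    )[, c("population", "dye", "state_truth", "intensity")]
  })
}
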