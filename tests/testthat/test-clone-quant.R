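two_clone_counts <- function() {
  libs <- tiny_libraries()
  tidyr::expand_grid(library_id = libs$library_id,
                     tibble::tibble(barcode = c("c1", "c2"), count = c(60, 40)))
}

test_that("normalization scales by library sum and state fraction", {
  libs <- tiny_libraries()[1:4, ]  # one time point, E/M x 2 replicates
  counts <- tibble::tibble(
    library_id = c("t0_E_r1", "t0_E_r1", "t0_E_r2",
                   "t0_M_r1", "t0_M_r1", "t0_M_r2", "t0_M_r2"),
    barcode = c("c1", "c2", "c1", "c1", "c2", "c1", "c2"),
    count = c(60, 40, 100, 50, 50, 10, 10)
  )
  norm <- normalize_counts(counts, libs, sort_spec())
  e1 <- norm[norm$library_id == "t0_E_r1", ]
  expect_equal(e1$value[e1$clone == "c1"], 0.36)
  expect_equal(e1$value[e1$clone == "c2"], 0.24)
  # clone missing from a library gets exactly the pseudo-value
  e2 <- norm[norm$library_id == "t0_E_r2", ]
  expect_true(e2$pseudo[e2$clone == "c2"])
  expect_equal(e2$value[e2$clone == "c2"], 1e-6)
  expect_equal(e2$value[e2$clone == "c1"], 0.6)
  # within-library values sum to the state fraction (plus pseudo mass)
  by_lib <- tapply(norm$value, norm$library_id, sum)
  expect_equal(unname(by_lib[["t0_E_r1"]]), 0.6, tolerance = 1e-12)
  expect_equal(unname(by_lib[["t0_M_r1"]]), 0.4, tolerance = 1e-12)

  # an empty library is an error that names the library
  expect_error(normalize_counts(counts[counts$library_id != "t0_M_r2", ],
                                libs, sort_spec()),
               "t0_M_r2")
})

test_that("contamination subtraction follows the read-fraction formula", {
  libs <- tiny_libraries()[c(1, 3), ]  # single replicate per state
  counts <- tibble::tibble(
    library_id = c("t0_E_r1", "t0_E_r1", "t0_M_r1", "t0_M_r1"),
    barcode = c("c1", "c2", "c1", "c2"),
    count = c(50, 50, 20, 80)
  )
  spec <- sort_spec(sigma_e = 0.05, sigma_m = 0)
  mat <- correct_contamination(normalize_counts(counts, libs, spec), spec)
  # c1: E = 0.5*0.6 = 0.30 minus (M-fraction 0.20) * 0.05 = 0.29
  expect_equal(mat$E[mat$clone == "c1"], 0.29, tolerance = 1e-12)
  # sigma = 0 leaves the mesenchymal side untouched
  expect_equal(mat$M[mat$clone == "c1"], 0.2 * 0.4, tolerance = 1e-12)

  zero <- sort_spec(sigma_e = 0, sigma_m = 0)
  mat0 <- correct_contamination(normalize_counts(counts, libs, zero), zero)
  expect_equal(mat0$E[mat0$clone == "c1"], 0.30, tolerance = 1e-12)
})

test_that("over-corrected entries floor at the pseudo-value, never increase", {
  libs <- tiny_libraries()[c(1, 3), ]
  # c2 is pure-M; its small E signal is entirely attributable to mis-sorting
  counts <- tibble::tibble(
    library_id = c("t0_E_r1", "t0_E_r1", "t0_M_r1", "t0_M_r1"),
    barcode = c("c1", "c2", "c1", "c2"),
    count = c(995, 5, 100, 900)
  )
  spec <- sort_spec(sigma_e = 0.05, sigma_m = 0.05)
  norm <- normalize_counts(counts, libs, spec)
  mat <- correct_contamination(norm, spec)
  expect_equal(mat$E[mat$clone == "c2"], 1e-6)
  expect_true(mat$floored_e[mat$clone == "c2"])
  # subtraction never increases any entry
  pre <- tidyr::pivot_wider(norm[, c("clone", "timepoint", "state", "value")],
                            names_from = "state", values_from = "value")
  expect_true(all(mat$E <= pre$E + 1e-15))
  expect_true(all(mat$M <= pre$M + 1e-15))
})

test_that("replicates combine by mean after correction", {
  libs <- tiny_libraries()[1:4, ]
  counts <- tibble::tibble(
    library_id = c("t0_E_r1", "t0_E_r2", "t0_M_r1", "t0_M_r2"),
    barcode = "c1",
    count = c(10, 30, 5, 5)
  )
  spec <- sort_spec(sigma_e = 0, sigma_m = 0)
  mat <- correct_contamination(normalize_counts(counts, libs, spec), spec)
  expect_equal(mat$E, 0.6, tolerance = 1e-12)  # mean of 0.6 and 0.6
  expect_equal(mat$M, 0.4, tolerance = 1e-12)
})

test_that("phenotype metrics compute ratios and cancel global rescaling", {
  mat <- tibble::tibble(clone = c("a", "b", "c"), timepoint = 0,
                        E = c(0.5, 0.75, 3), M = c(0.5, 0.25, 1))
  met <- phenotype_metrics(mat)
  expect_equal(met$fraction_epithelial, c(0.5, 0.75, 0.75))
  expect_equal(met$log2_em[1], 0)
  expect_equal(met$log2_em[2], log2(3), tolerance = 1e-12)

  scaled <- phenotype_metrics(dplyr::mutate(mat, E = E * 7, M = M * 7))
  expect_equal(scaled$fraction_epithelial, met$fraction_epithelial)
  expect_equal(scaled$log2_em, met$log2_em)

  avg <- clone_phenotypes(tibble::tibble(
    clone = "a", timepoint = 0:2, E = 2^(1:3), M = 1,
    fraction_epithelial = 2^(1:3) / (2^(1:3) + 1), log2_em = 1:3
  ))
  expect_equal(avg$log2_em_avg, 2)
})

test_that("growth rates inherit the population model", {
  # constant fractions -> every clone grows at the population rate
  mat <- tidyr::expand_grid(clone = c("a", "b"), timepoint = 0:2) |>
    dplyr::mutate(E = ifelse(clone == "a", 0.4, 0.2),
                  M = ifelse(clone == "a", 0.3, 0.1),
                  pseudo_e = FALSE, pseudo_m = FALSE)
  k <- growth_rates(mat, sort_spec())
  expect_equal(k$k, c(3, 3), tolerance = 1e-12)

  # clone halving its share each week loses one doubling per week
  mat2 <- tibble::tibble(
    clone = rep(c("a", "b"), each = 3), timepoint = rep(0:2, 2),
    E = c(0.4, 0.2, 0.1, 0.2, 0.4, 0.5), M = 0,
    pseudo_e = FALSE, pseudo_m = FALSE
  )
  mat2$E <- mat2$E + 1e-9  # keep totals positive
  mat2$M <- 1e-9
  k2 <- growth_rates(mat2, sort_spec())
  # clone a's share halves relative to total each week (approximately,
  # since shares are renormalized); check direction and magnitude
  expect_lt(k2$k[k2$clone == "a"], 3)
  expect_gt(k2$k[k2$clone == "b"], 3)

  expect_error(growth_rates(mat[mat$timepoint == 0, ], sort_spec()),
               "two time points")
})

test_that("single-clone population grows exactly at the population rate", {
  mat <- tibble::tibble(clone = "only", timepoint = 0:2, E = 0.6, M = 0.4,
                        pseudo_e = FALSE, pseudo_m = FALSE)
  expect_equal(growth_rates(mat, sort_spec())$k, 3, tolerance = 1e-12)
})

test_that("ratio entropy bins from the minimum in unit widths", {
  expect_equal(ratio_entropy(rep(0.3, 10)), 0)
  # equal mass in 8 unit bins -> 3 bits
  x <- rep(seq(0.5, 7.5, by = 1), each = 5)
  expect_equal(ratio_entropy(x), 3)
  # two bins at 3:1 occupancy
  y <- c(rep(0.1, 3), 1.6)
  expect_equal(ratio_entropy(y), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(ratio_entropy(c(Inf, NA)), "finite")
})

test_that("flow gating reproduces the control proportions", {
  # clone identical to the control mix: gated fraction equals the gate
  ev <- gen_flow_events(clone_fraction_e = 0.6, control_mix = c(0.6, 0.4),
                        n_events = 40000, seed = 8)
  g <- gate_flow_clone(ev, gate_proportions = c(0.6, 0.4))
  expect_lt(abs(g$fraction_epithelial - 0.6), 0.02)
  expect_lt(abs(g$log2_em - log2(0.6 / 0.4)), 0.1)

  # all-high clone gates almost entirely epithelial
  hi <- gen_flow_events(clone_fraction_e = 1, n_events = 5000, seed = 2)
  gh <- gate_flow_clone(hi)
  expect_gt(gh$fraction_epithelial, 0.97)
  expect_gt(gh$log2_em, 5)

  # symmetric 50/50 gates put the threshold at the control median
  sym <- gen_flow_events(clone_fraction_e = 0.5, control_mix = c(0.5, 0.5),
                         n_events = 20000, seed = 3)
  gs <- gate_flow_clone(sym, gate_proportions = c(0.5, 0.5))
  expect_lt(abs(gs$fraction_epithelial - 0.5), 0.02)

  nodye <- dplyr::mutate(ev, dye = FALSE)
  expect_error(gate_flow_clone(nodye), "dye")
})
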