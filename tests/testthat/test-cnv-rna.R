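test_that("cnv profiles clip, slide within chromosomes, and centre", {
  # constant matrix -> all-zero centred profiles
  gene_order <- tibble::tibble(gene = sprintf("g%03d", 1:202),
                               chrom = rep(c("chr1", "chr2"), each = 101))
  expr <- matrix(1, 202, 3, dimnames = list(gene_order$gene, c("a", "b", "c")))
  prof <- cnv_profiles(expr, gene_order, window = 101)
  expect_equal(unname(prof$profile), matrix(0, 2, 3))
  # one window per chromosome; windows never straddle the boundary
  expect_equal(prof$windows$chrom, c("chr1", "chr2"))
  expect_equal(prof$windows$start, c(1, 102))
  expect_equal(prof$windows$end, c(101, 202))

  # clipping bounds the influence of outlier values
  expr2 <- expr
  expr2[1, 1] <- 50  # clipped to 3
  prof2 <- cnv_profiles(expr2, gene_order, window = 101)
  raw_shift <- (3 - 1) / 101  # what the clipped outlier adds to window 1
  expect_equal(prof2$profile[1, 1] - prof2$profile[2, 1], raw_shift,
               tolerance = 1e-12)

  # per-cell centring removes any per-cell constant
  expr3 <- expr + rep(c(0, 1, 2), each = 202)
  prof3 <- cnv_profiles(pmin(expr3, 3), gene_order, window = 101)
  expect_equal(unname(prof3$profile), matrix(0, 2, 3), tolerance = 1e-12)

  # a chromosome shorter than the window contributes no windows
  short_order <- tibble::tibble(gene = sprintf("s%03d", 1:151),
                                chrom = rep(c("chr1", "chr2"), c(101, 50)))
  expect_warning(
    short <- cnv_profiles(matrix(0, 151, 2), short_order, window = 101),
    "no windows"
  )
  expect_equal(short$windows$chrom, "chr1")
})

test_that("sliding mean equals the naive window mean", {
  set.seed(5)
  gene_order <- tibble::tibble(gene = sprintf("g%03d", 1:30), chrom = "chr1")
  expr <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(gene_order$gene, c("x", "y")))
  prof <- cnv_profiles(expr, gene_order, window = 5, clip = 3)
  x <- pmin(pmax(expr, -3), 3)
  naive <- vapply(1:26, function(i) mean(x[i:(i + 4), 1]), numeric(1))
  expect_equal(unname(prof$profile[, 1]), naive - mean(naive), tolerance = 1e-12)
})

test_that("baseline normalization applies the 0.3 dead zone", {
  prof <- structure(
    list(profile = matrix(c(0.2, 0.585, -0.5, 0), 4, 1,
                          dimnames = list(NULL, "cell1"))),
    class = "cnv_profiles"
  )
  base <- rep(0, 4)
  norm <- normalize_to_baseline(prof, base, dead_zone = 0.3)
  expect_equal(unname(norm[, 1]), c(0, 0.585, -0.5, 0))
  # one extra copy on a diploid locus is log2(3/2) ~ 0.585, past the zone
  expect_gt(2^0.585, 1.49)
  expect_error(normalize_to_baseline(prof, rep(0, 3)), "window")
})

test_that("Ward clustering recovers synthetic clones exactly", {
  ds <- gen_scrna_dataset(
    60, 30,
    clone_spec = list(gain = c(chr1 = 0.585), loss = c(chr2 = -0.585)),
    n_genes = 909, n_chromosomes = 9, noise_sd = 0.4, seed = 21
  )
  prof <- cnv_profiles(ds$expr, ds$gene_order, window = 101)
  normal <- ds$cells$cell[ds$cells$group == "normal"]
  base <- cnv_baseline(prof, normal)
  norm <- normalize_to_baseline(prof, base)
  tumour <- ds$cells$cell[ds$cells$group != "normal"]
  cl <- cluster_cells_into_clones(norm[, tumour], k = 2)
  truth <- ds$cells$group[match(tumour, ds$cells$cell)]
  expect_equal(adjusted_rand(cl$labels$clone, truth), 1.0)

  # injected events detected with the injected sign in the affected cells
  chr1_wins <- which(prof$windows$chrom == "chr1")
  gain_cells <- ds$cells$cell[ds$cells$group == "gain"]
  detected <- colMeans(norm[chr1_wins, gain_cells, drop = FALSE] > 0)
  expect_gte(mean(detected >= 0.5), 0.95)

  # Ward linkage heights are monotone non-decreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-9))

  # duplicated profiles merge at zero height first
  dup <- cbind(norm[, tumour[1:3]], dup = norm[, tumour[1]])
  hc <- cluster_cells_into_clones(dup, k = 2)$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  expect_error(cluster_cells_into_clones(norm[, 1:3, drop = FALSE], k = 5),
               "exceed")
})

test_that("subtype scores subtract the cell's global mean", {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   2, 2, 2, 2, 2), 5, 2,
                 dimnames = list(paste0("g", 1:5), c("cellA", "cellB")))
  sc <- subtype_scores(expr, list(top3 = c("g3", "g4", "g5")))
  expect_equal(sc$score[sc$cell == "cellA"], mean(c(3, 4, 5)) - 3)
  expect_equal(sc$score[sc$cell == "cellB"], 0)  # uniform cell scores zero

  allg <- subtype_scores(expr, list(all = paste0("g", 1:5)))
  expect_equal(allg$score, c(0, 0))

  expect_error(subtype_scores(expr, list(bad = "nope")), "unmeasured")
  expect_error(subtype_scores(expr, list()), "non-empty")
})

test_that("score significance calls are calibrated on random sets", {
  set.seed(31)
  expr <- matrix(rnorm(500 * 300), 500, 300,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
  expr <- expr - rowMeans(expr)
  rand_set <- sample(rownames(expr), 30)
  calls <- score_significance(expr, rand_set, n_random = 100, seed = 2)
  expect_gte(mean(calls$call == "enriched"), 0.01)
  expect_lte(mean(calls$call == "enriched"), 0.12)

  # a strongly up-shifted program is called enriched in program cells
  expr2 <- expr
  prog <- rownames(expr)[1:25]
  expr2[prog, 1:150] <- expr2[prog, 1:150] + 2
  expr2 <- expr2 - rowMeans(expr2)
  calls2 <- score_significance(expr2, prog, n_random = 100, seed = 3)
  expect_gte(mean(calls2$call[1:150] == "enriched"), 0.95)

  # constant expression scores are never called
  flat <- matrix(0, 50, 20, dimnames = list(sprintf("f%02d", 1:50), NULL))
  flat_calls <- score_significance(flat, sprintf("f%02d", 1:5),
                                   n_random = 50, seed = 4)
  expect_true(all(flat_calls$call == "neither"))

  expect_warning(score_significance(expr, rand_set, n_random = 10, seed = 1),
                 "unstable")
})

test_that("Kruskal-Wallis comparison flags shifted clones, not null ones", {
  set.seed(61)
  scores <- tibble::tibble(
    cell = sprintf("c%03d", 1:150),
    set = "Mes",
    score = c(rnorm(50), rnorm(50), rnorm(50) + 1)  # clone 3 shifted 1 SD
  )
  labels <- tibble::tibble(cell = scores$cell, clone = rep(1:3, each = 50))
  res <- compare_clone_scores(scores, labels)
  expect_lt(res$p, 1e-4)
  # matches a direct call to the reference implementation
  ref <- kruskal.test(scores$score, factor(labels$clone))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  null_scores <- dplyr::mutate(scores, score = rnorm(150))
  expect_gt(compare_clone_scores(null_scores, labels)$p, 0.001)

  single <- labels[labels$clone == 1, ]
  expect_error(compare_clone_scores(scores, single), "at least 2 clones")
  lone <- dplyr::bind_rows(labels[labels$clone != 3, ],
                           tibble::tibble(cell = "c150", clone = 3))
  expect_warning(compare_clone_scores(scores, lone), "excluding")
})

test_that("dendrogram exports as readable Newick", {
  skip_if_not_installed("ape")
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(NULL, paste0("cell", 1:10)))
  cl <- cluster_cells_into_clones(m, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_clone_dendrogram(cl, path)
  tree <- ape::read.tree(path)
  expect_equal(sort(tree$tip.label), sort(paste0("cell", 1:10)))
})
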