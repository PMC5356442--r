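#' Sliding-window copy-number profiles from single-cell expression
#'
#' Estimates relative copy number per cell from per-gene mean-centred
#' log2(TPM + 1) expression: values are clipped to `[-clip, clip]`, a
#' sliding mean over `window` consecutive genes (in chromosomal order,
#' advancing one gene at a time and never straddling a chromosome boundary)
#' is computed per cell, and each cell's profile is centred at zero to
#' remove residual global expression differences.
#'
#' @param expr Genes x cells numeric matrix, per-gene mean-normalized
#'   log2(TPM + 1); rownames must match `gene_order$gene`.
#' @param gene_order Tibble with `gene`, `chrom` (and optionally `pos`)
#'   giving chromosomal order; rows are taken in the given order.
#' @param window Genes per window (default 101). Chromosomes with fewer
#'   genes contribute no windows (warning).
#' @param clip Symmetric clipping threshold on the input values (default 3).
#' @return Object of class `cnv_profiles`: list with `profile` (windows x
#'   cells matrix, each column mean zero), `windows` (tibble: `window`,
#'   `chrom`, `start`, `end`, `mid_gene` row indices into `gene_order`).
#' @export
cnv_profiles <- function(expr, gene_order, window = 101, clip = 3) {
  window <- assert_count(window, "window")
  if (nrow(expr) != nrow(gene_order)) {
    abort("`expr` and `gene_order` must have one row per gene, aligned.")
  }
  x <- pmin(pmax(expr, -clip), clip)
  chroms <- unique(gene_order$chrom)
  profs <- list()
  wins <- list()
  for (ch in chroms) {
    rows <- which(gene_order$chrom == ch)
    if (length(rows) < window) {
      warn(sprintf("chromosome %s has %d genes (< window %d): no windows.",
                   ch, length(rows), window))
      next
    }
    cs <- apply(x[rows, , drop = FALSE], 2, cumsum)
    n_win <- length(rows) - window + 1L
    sliding <- (cs[window:length(rows), , drop = FALSE] -
                  rbind(0, cs[seq_len(n_win - 1L), , drop = FALSE])) / window
    profs[[ch]] <- sliding
    wins[[ch]] <- tibble(
      chrom = ch,
      start = rows[seq_len(n_win)],
      end = rows[seq_len(n_win) + window - 1L],
      mid_gene = rows[seq_len(n_win) + (window - 1L) %/% 2]
    )
  }
  if (!length(profs)) abort("no chromosome has enough genes for one window.")
  profile <- do.call(rbind, profs)
  windows <- bind_rows(wins) %>% mutate(window = row_number(), .before = 1)
  profile <- sweep(profile, 2, colMeans(profile))  # centre each cell at 0
  rownames(profile) <- sprintf("win_%05d", windows$window)
  structure(list(profile = profile, windows = windows, window = window,
                 clip = clip),
            class = "cnv_profiles")
}

#' Baseline profile from normal cells
#'
#' Averages the window profiles of the declared normal cells, producing the
#' positional baseline used by [normalize_to_baseline()].
#'
#' @param profiles A [cnv_profiles()] object.
#' @param normal_cells Column names (or indices) of the normal cells.
#' @return Numeric vector, one value per window.
#' @export
cnv_baseline <- function(profiles, normal_cells) {
  rowMeans(profiles$profile[, normal_cells, drop = FALSE])
}

#' Normalize profiles to a normal-cell baseline with a dead zone
#'
#' Subtracts the baseline from each cell's profile and records a value only
#' where the deviation exceeds `dead_zone` in magnitude (a difference of
#' 0.3 on the log2 scale corresponds to a 23% change); smaller deviations
#' are set to zero.
#'
#' @param profiles A [cnv_profiles()] object.
#' @param baseline Vector from [cnv_baseline()] (same window indexing).
#' @param dead_zone Magnitude below which deviations are zeroed
#'   (default 0.3).
#' @return Matrix of normalized profiles (windows x cells).
#' @export
normalize_to_baseline <- function(profiles, baseline, dead_zone = 0.3) {
  if (length(baseline) != nrow(profiles$profile)) {
    abort("baseline and profiles index different window sets.")
  }
  d <- profiles$profile - baseline
  d[abs(d) <= dead_zone] <- 0
  d
}

#' Cluster cells into clones from CNV profiles
#'
#' Agglomerative hierarchical clustering with Ward's method on the
#' Euclidean distances between cells' normalized CNV profiles; clone labels
#' come from cutting the dendrogram at `k` clusters or at height `h`.
#'
#' @param cnv_norm Windows x cells matrix from [normalize_to_baseline()]
#'   (or a `cnv_profiles` object's profile).
#' @param k Number of clones to cut (default 4).
#' @param h Optional cut height (used instead of `k` when given).
#' @return Object of class `clone_clusters`: list with `hclust`, `labels`
#'   (tibble `cell`, `clone`), `k`.
#' @export
cluster_cells_into_clones <- function(cnv_norm, k = 4, h = NULL) {
  if (inherits(cnv_norm, "cnv_profiles")) cnv_norm <- cnv_norm$profile
  n <- ncol(cnv_norm)
  if (n < 2) abort("need at least 2 cells.")
  if (is.null(h) && k > n) abort("`k` cannot exceed the number of cells.")
  hc <- hclust(dist(t(cnv_norm)), method = "ward.D2")
  cl <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  structure(
    list(hclust = hc,
         labels = tibble(cell = colnames(cnv_norm) %||% as.character(seq_len(n)),
                         clone = as.integer(cl)),
         k = length(unique(cl))),
    class = "clone_clusters"
  )
}

#' Export a clone dendrogram as Newick
#'
#' @param clusters A `clone_clusters` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clone_dendrogram <- function(clusters, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("ape is required for Newick export.")
  }
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}

#' Subtype and stemness scores per cell
#'
#' Scores cell i for gene set j as the mean expression of the set's genes
#' in that cell minus the mean expression of every measured gene in that
#' cell; by construction the score of the all-genes set is zero.
#'
#' @param expr Genes x cells matrix (per-gene mean-normalized
#'   log2(TPM + 1)).
#' @param gene_sets Named list of character vectors (gene names, subsets of
#'   `rownames(expr)`) or integer row indices.
#' @return Tibble: `cell`, `set`, `score`.
#' @export
subtype_scores <- function(expr, gene_sets) {
  if (!length(gene_sets)) abort("`gene_sets` must be non-empty.")
  cell_mean <- colMeans(expr)
  cells <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  purrr::imap_dfr(gene_sets, function(genes, set) {
    rows <- if (is.character(genes)) {
      if (!all(genes %in% rownames(expr))) {
        abort(sprintf("gene set '%s' contains unmeasured genes.", set))
      }
      match(genes, rownames(expr))
    } else {
      genes
    }
    if (!length(rows)) abort(sprintf("gene set '%s' is empty.", set))
    tibble(cell = cells, set = set,
           score = unname(colMeans(expr[rows, , drop = FALSE]) - cell_mean))
  })
}

#' Significance calls for subtype scores via random gene sets
#'
#' Builds `n_random` random gene sets of the same size as the real set by
#' sampling the measured genes, scores each cell against every random set,
#' and calls the real score enriched when it exceeds the `level` quantile
#' of the cell's random scores, depleted when it falls below the
#' `1 - level` quantile, and neither otherwise.
#'
#' @param expr Genes x cells matrix.
#' @param gene_set Character vector of gene names (or row indices).
#' @param n_random Number of random sets (default 100; fewer than 20 gives
#'   unstable percentiles, warned).
#' @param level Calling quantile (default 0.95).
#' @param seed Optional integer seed.
#' @return Tibble: `cell`, `score`, `call` in
#'   {"enriched", "depleted", "neither"}.
#' @export
score_significance <- function(expr, gene_set, n_random = 100, level = 0.95,
                               seed = NULL) {
  n_random <- assert_count(n_random, "n_random")
  if (n_random < 20) warn("fewer than 20 random sets: unstable percentiles.")
  size <- length(gene_set)
  real <- subtype_scores(expr, list(real = gene_set))$score
  with_seed(seed, {
    rand <- vapply(seq_len(n_random), function(i) {
      rows <- sample.int(nrow(expr), size)
      colMeans(expr[rows, , drop = FALSE]) - colMeans(expr)
    }, numeric(ncol(expr)))
    # rand: cells x n_random
    hi <- apply(rand, 1, quantile, probs = level, names = FALSE)
    lo <- apply(rand, 1, quantile, probs = 1 - level, names = FALSE)
    tibble(
      cell = colnames(expr) %||% as.character(seq_len(ncol(expr))),
      score = real,
      call = dplyr::case_when(
        real > hi ~ "enriched",
        real < lo ~ "depleted",
        TRUE ~ "neither"
      )
    )
  })
}

#' Compare subtype-score distributions across clones
#'
#' Kruskal-Wallis rank test of each gene set's per-cell scores grouped by
#' clone label. Clones with fewer than 2 cells are excluded with a warning.
#'
#' @param scores Tibble from [subtype_scores()] (`cell`, `set`, `score`).
#' @param clone_labels Tibble (`cell`, `clone`) from
#'   [cluster_cells_into_clones()] (its `labels` element) or equivalent.
#' @return Tibble: `set`, `statistic` (H), `df`, `p`.
#' @export
compare_clone_scores <- function(scores, clone_labels) {
  if (inherits(clone_labels, "clone_clusters")) clone_labels <- clone_labels$labels
  sizes <- clone_labels %>% dplyr::count(.data$clone)
  small <- sizes$clone[sizes$n < 2]
  if (length(small)) {
    warn(sprintf("excluding clone(s) with < 2 cells: %s",
                 paste(small, collapse = ", ")))
    clone_labels <- clone_labels[!clone_labels$clone %in% small, ]
  }
  if (length(unique(clone_labels$clone)) < 2) {
    abort("need at least 2 clones with >= 2 cells each.")
  }
  scores %>%
    dplyr::inner_join(clone_labels, by = "cell") %>%
    group_by(.data$set) %>%
    dplyr::group_modify(function(d, key) {
      kt <- kruskal.test(d$score, factor(d$clone))
      tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value)
    }) %>%
    ungroup()
}
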