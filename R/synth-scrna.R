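#' Simulate a single-cell expression matrix with clone-level CNV structure
#'
#' Generates a genes x cells matrix of log2(TPM + 1)-scale expression with
#' genes laid out in chromosomal order, whole-chromosome copy-number shifts
#' injected per tumour clone, optional cell-program (subtype) shifts on
#' declared gene sets, and a set of normal cells with no events. The returned
#' matrix is per-gene mean-centred across cells, matching the normalized
#' input expected by [cnv_profiles()].
#'
#' @param n_tumour_cells Total tumour cells, split across clones.
#' @param n_normal_cells Normal (baseline) cells.
#' @param clone_spec Named list: one element per clone, each a named numeric
#'   vector of per-chromosome log2 shifts, e.g.
#'   `list(cloneA = c(chr7 = 0.585), cloneB = c(chr10 = -1))`. Clone cell
#'   counts are split as evenly as possible; a clone allocated zero cells is
#'   an error.
#' @param subtype_spec Optional named list of programs, each a list with
#'   `genes` (indices or names), `cells` (a clone name or "normal"), and
#'   `shift` (added to those genes in those cells).
#' @param n_genes Total genes.
#' @param n_chromosomes Chromosome count; genes are split evenly in order.
#' @param noise_sd SD of i.i.d. Gaussian expression noise.
#' @param seed Optional integer seed.
#' @return List: `expr` (genes x cells, per-gene centred), `gene_order`
#'   (tibble `gene`, `chrom`, `pos`), `cells` (tibble `cell`, `group` with
#'   clone name or "normal").
#' @export
gen_scrna_dataset <- function(n_tumour_cells, n_normal_cells,
                              clone_spec = list(),
                              subtype_spec = NULL,
                              n_genes = 2000, n_chromosomes = 10,
                              noise_sd = 0.5, seed = NULL) {
  n_tumour_cells <- assert_count(n_tumour_cells, "n_tumour_cells", min = 0)
  n_normal_cells <- assert_count(n_normal_cells, "n_normal_cells", min = 0)
  n_clones <- length(clone_spec)
  if (n_clones > 0 && n_tumour_cells < n_clones) {
    abort("every clone in `clone_spec` needs at least one cell.")
  }
  with_seed(seed, {
    chrom <- rep(paste0("chr", seq_len(n_chromosomes)),
                 each = ceiling(n_genes / n_chromosomes))[seq_len(n_genes)]
    gene_order <- tibble(
      gene = sprintf("gene_%05d", seq_len(n_genes)),
      chrom = chrom,
      pos = as.integer(stats::ave(seq_len(n_genes), chrom, FUN = seq_along))
    )
    groups <- if (n_clones > 0) {
      sizes <- diff(round(seq(0, n_tumour_cells, length.out = n_clones + 1)))
      rep(names(clone_spec), sizes)
    } else {
      rep("tumour", n_tumour_cells)
    }
    cells <- tibble(
      cell = sprintf("cell_%04d", seq_len(n_tumour_cells + n_normal_cells)),
      group = c(groups, rep("normal", n_normal_cells))
    )
    n_cells <- nrow(cells)
    base_mean <- rnorm(n_genes, 0, 1)   # gene-level baseline (centred out later)
    expr <- matrix(rnorm(n_genes * n_cells, 0, noise_sd), n_genes, n_cells,
                   dimnames = list(gene_order$gene, cells$cell)) + base_mean
    for (cl in names(clone_spec)) {
      cols <- which(cells$group == cl)
      for (ch in names(clone_spec[[cl]])) {
        rows <- which(gene_order$chrom == ch)
        if (!length(rows)) abort(sprintf("unknown chromosome '%s' in clone_spec.", ch))
        expr[rows, cols] <- expr[rows, cols] + clone_spec[[cl]][[ch]]
      }
    }
    for (prog in (subtype_spec %||% list())) {
      rows <- if (is.character(prog$genes)) match(prog$genes, gene_order$gene) else prog$genes
      cols <- which(cells$group %in% prog$cells)
      expr[rows, cols] <- expr[rows, cols] + prog$shift
    }
    expr <- expr - rowMeans(expr)
    list(expr = expr, gene_order = gene_order, cells = cells)
  })
}
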