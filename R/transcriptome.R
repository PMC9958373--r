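# Minimal single-cell transcriptome stage: mitochondrial QC, Ig-gene
# removal, library-size normalization, variable-gene selection, PCA,
# graph-based clustering, and Wilcoxon differential expression.
#
# Matrices are sparse (Matrix::dgCMatrix), cells in rows, genes in columns,
# matching the orientation produced by read_counts().

#' Per-cell mitochondrial fraction
#'
#' @param m counts matrix (cells x genes).
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#'   (murine convention `"mt-"`); matched case-insensitively.
#' @return numeric vector, one fraction per cell.
#' @export
mito_fraction <- function(m, mito_prefix = "mt-") {
  is_mito <- startsWith(tolower(colnames(m)), tolower(mito_prefix))
  tot <- Matrix::rowSums(m)
  mito <- if (any(is_mito)) Matrix::rowSums(m[, is_mito, drop = FALSE])
          else rep(0, nrow(m))
  frac <- ifelse(tot > 0, mito / tot, 0)
  names(frac) <- rownames(m)
  frac
}

#' Mitochondrial-content QC filter
#'
#' Retains cells whose mitochondrial read fraction is below `mito_max`
#' (strictly: "less than 20%"). If no gene matches the mitochondrial
#' prefix a warning is emitted and no cell is dropped.
#'
#' @param m counts matrix (cells x genes).
#' @param mito_max maximum mitochondrial fraction (default 0.20).
#' @param mito_prefix mitochondrial gene-name prefix.
#' @return filtered matrix with attribute `"mito_fraction"` for the
#'   retained cells.
#' @export
qc_filter <- function(m, mito_max = 0.20, mito_prefix = "mt-") {
  has_mito <- any(startsWith(tolower(colnames(m)), tolower(mito_prefix)))
  if (!has_mito) {
    warning("no genes match mito prefix '", mito_prefix,
            "'; no cells dropped")
    attr(m, "mito_fraction") <- rep(0, nrow(m))
    return(m)
  }
  frac <- mito_fraction(m, mito_prefix)
  keep <- frac < mito_max
  out <- m[keep, , drop = FALSE]
  attr(out, "mito_fraction") <- frac[keep]
  out
}

BCR_GENE_PATTERN <- paste0(
  "^(Ighv|Ighd|Ighj|Ighg|Igha|Ighm|Ighe|",
  "Igkv|Igkj|Igkc|Iglv|Iglj|Iglc|Jchain)")

#' Remove BCR-related genes
#'
#' Drops V(D)J segments, isotype constant regions, and J-chain so that
#' clonotype-driven transcription does not dominate clustering. Matching is
#' by murine gene-symbol prefix, case-insensitive.
#'
#' @param m counts matrix (cells x genes).
#' @param verbose log the removed genes via `message()`.
#' @return matrix without BCR genes; removed names in attribute
#'   `"removed_genes"`.
#' @export
drop_bcr_genes <- function(m, verbose = FALSE) {
  drop <- grepl(BCR_GENE_PATTERN, colnames(m), ignore.case = TRUE)
  out <- m[, !drop, drop = FALSE]
  attr(out, "removed_genes") <- colnames(m)[drop]
  if (verbose && any(drop)) {
    message("removed ", sum(drop), " BCR-related genes: ",
            paste(utils::head(colnames(m)[drop], 10), collapse = ", "),
            if (sum(drop) > 10) ", ..." else "")
  }
  out
}

#' Library-size normalization with log transform
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`
#' (natural log). Cells with zero total counts are dropped with a warning.
#'
#' @param m counts matrix (cells x genes).
#' @param scale_factor per-cell target total (default 10000).
#' @return sparse normalized matrix, zero pattern preserved.
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  tot <- Matrix::rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with zero total counts dropped")
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  norm <- Matrix::Diagonal(x = scale_factor / tot) %*% m
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Graph-based clustering of normalized expression
#'
#' Selects the `n_hvg` most variable genes on the log-normalized data,
#' standardizes each gene (values clipped at `clip`), reduces to `n_pcs`
#' principal components, builds a shared-nearest-neighbor graph
#' (k = `k_nn`, Jaccard edge weights, weak edges pruned), and partitions it
#' with Louvain modularity optimization at the given `resolution`.
#' Labels are integers `0..K-1`, ordered by cluster size descending.
#'
#' @param m_norm normalized matrix from [normalize_log()].
#' @param n_hvg number of highly variable genes (default 2000).
#' @param n_pcs number of principal components (default 15).
#' @param resolution Louvain resolution (default 0.5).
#' @param k_nn neighbors per cell (default 20).
#' @param clip standardized-value clip bound (default 10).
#' @param prune minimum SNN Jaccard weight kept (default 1/15).
#' @param seed RNG seed for Louvain.
#' @return integer cluster labels named by cell barcode, with the PCA
#'   embedding in attribute `"pca"`.
#' @export
cluster_cells <- function(m_norm, n_hvg = 2000, n_pcs = 15,
                          resolution = 0.5, k_nn = 20, clip = 10,
                          prune = 1 / 15, seed = 1L) {
  n_cells <- nrow(m_norm)
  if (n_cells <= n_pcs) {
    abort_cs(sprintf("need more cells (%d) than principal components (%d)",
                     n_cells, n_pcs), "cs_validation_error")
  }
  gene_var <- col_vars(m_norm)
  n_hvg <- min(n_hvg, sum(gene_var > 0))
  if (n_hvg == 0) {  # all cells identical: one cluster by definition
    labels <- rep(0L, n_cells)
    names(labels) <- rownames(m_norm)
    return(labels)
  }
  hvg <- order(gene_var, decreasing = TRUE)[seq_len(n_hvg)]
  x <- as.matrix(m_norm[, hvg, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  n_pcs <- min(n_pcs, ncol(x), n_cells - 1)
  pca <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  k_nn <- min(k_nn, n_cells - 1)
  snn <- snn_graph(pca, k_nn, prune)
  set.seed(seed)
  comm <- igraph::cluster_louvain(snn, resolution = resolution)
  memb <- igraph::membership(comm)
  # relabel 0..K-1 by size descending (ties by first appearance)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relab[as.character(memb)])
  names(labels) <- rownames(m_norm)
  attr(labels, "pca") <- pca
  labels
}

col_vars <- function(m) {
  mu <- Matrix::colMeans(m)
  mu2 <- Matrix::colMeans(m^2)
  n <- nrow(m)
  (mu2 - mu^2) * n / max(1, n - 1)
}

snn_graph <- function(emb, k, prune) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  # include self in neighborhoods for the Jaccard computation (Seurat-style)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1),
    j = as.integer(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- as.matrix(shared) / (2 * (k + 1) - as.matrix(shared))
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Tests genes detected in at least `min_pct` of either group with a
#' two-sided Wilcoxon rank-sum test on the normalized values, applies
#' Bonferroni correction over the tested genes, and reports the natural-log
#' fold change of mean de-logged expression with a pseudocount of 1.
#' Output rows are ranked by logFC, descending.
#'
#' @param m_norm normalized matrix (cells x genes).
#' @param group_a,group_b logical masks or barcode vectors selecting the
#'   two cell groups (each needs >= 3 cells; must not overlap).
#' @param min_pct minimum detection fraction in either group (default 0.25).
#' @param alpha_adj adjusted-p significance cutoff (default 0.01).
#' @return data.frame `gene, logFC, p, p_adj, pct_a, pct_b, significant`.
#' @export
differential_expression <- function(m_norm, group_a, group_b,
                                    min_pct = 0.25, alpha_adj = 0.01) {
  a <- resolve_mask(m_norm, group_a)
  b <- resolve_mask(m_norm, group_b)
  assert_that(sum(a) >= 3 && sum(b) >= 3,
              "both groups need at least 3 cells")
  assert_that(!any(a & b), "groups must not overlap")
  ma <- m_norm[a, , drop = FALSE]
  mb <- m_norm[b, , drop = FALSE]
  pct_a <- Matrix::colMeans(ma > 0)
  pct_b <- Matrix::colMeans(mb > 0)
  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  if (!length(tested)) {
    return(data.frame(gene = character(), logFC = numeric(), p = numeric(),
                      p_adj = numeric(), pct_a = numeric(),
                      pct_b = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  p <- vapply(tested, function(j) {
    stats::wilcox.test(ma[, j], mb[, j], exact = FALSE)$p.value
  }, numeric(1))
  lfc <- vapply(tested, function(j) {
    log((mean(expm1(ma[, j])) + 1) / (mean(expm1(mb[, j])) + 1))
  }, numeric(1))
  p_adj <- pmin(1, p * length(tested))
  out <- data.frame(gene = colnames(m_norm)[tested], logFC = lfc, p = p,
                    p_adj = p_adj, pct_a = pct_a[tested],
                    pct_b = pct_b[tested],
                    significant = p_adj < alpha_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$logFC), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_mask <- function(m, g) {
  if (is.logical(g)) {
    stopifnot(length(g) == nrow(m))
    return(g)
  }
  rownames(m) %in% g
}
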