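# Repertoire-level statistics: SHM counting against germline alignments,
# overlap/Jaccard between repertoires, shared (organ-overlapping / public)
# clone detection, V-J pairing matrices, and CDR3 position-frequency
# matrices.

#' Count somatic hypermutations between an observed and germline alignment
#'
#' Counts alignment columns in which both characters are unambiguous
#' nucleotides (A/C/G/T) and differ. Columns containing gaps (`-`/`.`) or
#' `N` on either side are skipped. When a `region_mask` is supplied, only
#' columns labeled `"V"` or `"J"` are counted, excluding the junction/NP
#' region; without a mask the whole alignment is used (cellranger outputs do
#' not always delimit regions).
#'
#' @param observed_alignment,germline_alignment equal-length gapped
#'   nucleotide strings.
#' @param region_mask optional character vector (one label per column);
#'   columns labeled `"V"` or `"J"` are counted.
#' @return non-negative integer substitution count.
#' @export
count_shm <- function(observed_alignment, germline_alignment,
                      region_mask = NULL) {
  obs <- toupper(observed_alignment)
  germ <- toupper(germline_alignment)
  if (nchar(obs) != nchar(germ)) {
    abort_cs(sprintf(
      "alignment length mismatch: observed %d vs germline %d",
      nchar(obs), nchar(germ)), "cs_validation_error")
  }
  if (nchar(obs) == 0) return(0L)
  a <- strsplit(obs, "")[[1]]
  b <- strsplit(germ, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!is.null(region_mask)) {
    assert_that(length(region_mask) == length(a),
                "region_mask length must equal alignment length")
    ok <- ok & region_mask %in% c("V", "J")
  }
  sum(ok & a != b)
}

#' Per-clone SHM summary
#'
#' Mean over member cells of the summed heavy + light chain substitution
#' counts relative to germline. Cells missing any of the four alignments are
#' skipped; a clone with no usable cell is flagged missing (`NA`) so it can
#' be excluded from group comparisons.
#'
#' @param cells member-cell rows (from a `clone_set$cells` table) carrying
#'   `h_seq_align, h_germ_align, l_seq_align, l_germ_align`.
#' @return list with `mean_shm` (numeric, possibly `NA`), `n_cells` used,
#'   and the per-cell totals `per_cell`.
#' @export
clone_shm_summary <- function(cells) {
  usable <- nzchar(cells$h_seq_align) & nzchar(cells$h_germ_align) &
    nzchar(cells$l_seq_align) & nzchar(cells$l_germ_align)
  sub <- cells[usable, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(mean_shm = NA_real_, n_cells = 0L, per_cell = numeric(0)))
  }
  per_cell <- vapply(seq_len(nrow(sub)), function(i) {
    count_shm(sub$h_seq_align[i], sub$h_germ_align[i]) +
      count_shm(sub$l_seq_align[i], sub$l_germ_align[i])
  }, numeric(1))
  list(mean_shm = mean(per_cell), n_cells = nrow(sub), per_cell = per_cell)
}

#' SHM table for every clone in a clone set
#'
#' @param cs `clone_set` from [assign_clones()].
#' @return data.frame `clone_id, clone_key, mean_shm, n_cells_shm`.
#' @export
shm_by_clone <- function(cs) {
  res <- lapply(split(cs$cells, cs$cells$clone_id), clone_shm_summary)
  ids <- names(res)
  out <- data.frame(
    clone_id = ids,
    mean_shm = vapply(res, `[[`, numeric(1), "mean_shm"),
    n_cells_shm = vapply(res, `[[`, integer(1), "n_cells"),
    stringsAsFactors = FALSE)
  out <- out[match(cs$clones$clone_id, out$clone_id), , drop = FALSE]
  out$clone_key <- cs$clones$clone_key
  rownames(out) <- NULL
  out[, c("clone_id", "clone_key", "mean_shm", "n_cells_shm")]
}

#' Jaccard index of two key sets
#'
#' Size of the intersection divided by the size of the union; defined as 0
#' when both sets are empty.
#'
#' @param keys_a,keys_b character vectors (treated as sets).
#' @return numeric in [0, 1].
#' @export
jaccard <- function(keys_a, keys_b) {
  a <- unique(keys_a); b <- unique(keys_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise repertoire overlap
#'
#' Clone-key overlap between every pair of samples: shared keys and the
#' Jaccard index (computed on clone keys, not cells, since overlap is
#' defined on CDR3 identity).
#'
#' @param clones clone table with `samples` membership (comma-separated) or
#'   a named list mapping sample_id to a character vector of clone keys.
#' @return data.frame `sample_a, sample_b, n_shared, jaccard, shared_keys`
#'   (semicolon-separated).
#' @export
repertoire_overlap <- function(clones) {
  keysets <- as_keysets(clones)
  ids <- names(keysets)
  if (length(ids) < 2) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      n_shared = integer(), jaccard = numeric(),
                      shared_keys = character(), stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(ids, 2)
  rows <- apply(pairs, 2, function(p) {
    sh <- sort(intersect(keysets[[p[1]]], keysets[[p[2]]]))
    data.frame(sample_a = p[1], sample_b = p[2], n_shared = length(sh),
               jaccard = jaccard(keysets[[p[1]]], keysets[[p[2]]]),
               shared_keys = paste(sh, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_keysets <- function(clones) {
  if (is.list(clones) && !is.data.frame(clones)) {
    return(lapply(clones, unique))
  }
  samp <- strsplit(clones$samples, ",", fixed = TRUE)
  long_sample <- unlist(samp)
  long_key <- rep(clones$clone_key, lengths(samp))
  lapply(split(long_key, long_sample), unique)
}

#' Find organ-overlapping or public clones
#'
#' `organ_overlapping_within_mouse`: clone keys present in both bone marrow
#' and spleen of the same mouse, with per-organ sizes.
#' `public_across_mice`: clone keys present in two or more distinct mice.
#' Sharing is always on identical CDRH3+CDRL3 amino acids.
#'
#' @param clones_by_sample named list: sample_id -> clone table as returned
#'   in `assign_clones()$clones` (one repertoire each).
#' @param meta sample metadata table (`sample_id, mouse_id, organ, cohort`).
#' @param grouping which sharing structure to report.
#' @return data.frame; for organ overlap: `mouse_id, clone_key, size_bm,
#'   size_sp, isotype_bm, isotype_sp`; for public clones: `clone_key,
#'   n_mice, mice`.
#' @export
find_shared_clones <- function(clones_by_sample, meta,
    grouping = c("organ_overlapping_within_mouse", "public_across_mice")) {
  grouping <- match.arg(grouping)
  meta <- validate_sample_meta(meta)
  stopifnot(all(names(clones_by_sample) %in% meta$sample_id))
  long <- do.call(rbind, lapply(names(clones_by_sample), function(s) {
    cl <- clones_by_sample[[s]]
    if (nrow(cl) == 0) return(NULL)
    m <- meta[meta$sample_id == s, ]
    data.frame(sample_id = s, mouse_id = m$mouse_id, organ = m$organ,
               clone_key = cl$clone_key, size = cl$size,
               isotype = cl$isotype, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) long <- data.frame(sample_id = character(),
    mouse_id = character(), organ = character(), clone_key = character(),
    size = integer(), isotype = character(), stringsAsFactors = FALSE)
  if (grouping == "organ_overlapping_within_mouse") {
    bm <- long[long$organ == "bone_marrow", ]
    sp <- long[long$organ == "spleen", ]
    merged <- merge(bm, sp, by = c("mouse_id", "clone_key"),
                    suffixes = c("_bm", "_sp"))
    out <- merged[, c("mouse_id", "clone_key", "size_bm", "size_sp",
                      "isotype_bm", "isotype_sp")]
    out <- out[order(out$mouse_id, out$clone_key), , drop = FALSE]
  } else {
    per_key <- split(long$mouse_id, long$clone_key)
    n_mice <- vapply(per_key, function(m) length(unique(m)), integer(1))
    keys <- names(per_key)[n_mice >= 2]
    out <- data.frame(
      clone_key = keys,
      n_mice = n_mice[n_mice >= 2],
      mice = vapply(per_key[keys], function(m)
        paste(sort(unique(m)), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    out <- out[order(out$clone_key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Heavy/light germline gene pairing counts
#'
#' Counts clones per (heavy gene, light gene) combination using each
#' clone's representative germline calls. Genes whose total clone count is
#' below `label_threshold` are aggregated into `"other"` (the same
#' convention as circos-plot label thresholds of 2 or 5). Rows and columns
#' are sorted by total count, descending, with `"other"` last.
#'
#' @param clones clone table with `vh_call`/`vl_call` (use `segment = "j"`
#'   for J-gene pairing via `jh_call`/`jl_call`).
#' @param label_threshold positive integer; genes with total count below
#'   this are pooled into `"other"`.
#' @param segment `"v"` or `"j"`.
#' @return integer matrix, heavy genes in rows, light genes in columns;
#'   entries sum to the number of input clones.
#' @export
vj_pairing_counts <- function(clones, label_threshold = 2, segment = c("v", "j")) {
  segment <- match.arg(segment)
  assert_that(label_threshold >= 1, "label_threshold must be >= 1")
  hg <- if (segment == "v") clones$vh_call else clones$jh_call
  lg <- if (segment == "v") clones$vl_call else clones$jl_call
  hg[!nzchar(hg) | is.na(hg)] <- "other"
  lg[!nzchar(lg) | is.na(lg)] <- "other"
  htot <- table(hg); ltot <- table(lg)
  hg[hg %in% names(htot)[htot < label_threshold]] <- "other"
  lg[lg %in% names(ltot)[ltot < label_threshold]] <- "other"
  tab <- table(hg, lg)
  ord_rows <- order(-rowSums(tab), rownames(tab))
  ord_cols <- order(-colSums(tab), colnames(tab))
  tab <- tab[ord_rows, ord_cols, drop = FALSE]
  move_last <- function(m, margin) {
    nm <- dimnames(m)[[margin]]
    if ("other" %in% nm && length(nm) > 1) {
      ord <- c(setdiff(seq_along(nm), which(nm == "other")),
               which(nm == "other"))
      if (margin == 1) m <- m[ord, , drop = FALSE]
      else m <- m[, ord, drop = FALSE]
    }
    m
  }
  tab <- move_last(move_last(tab, 1), 2)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' CDR3 position-frequency matrix at the modal length
#'
#' Restricts the input to sequences of the most frequent length (ties go to
#' the shorter length) and returns per-position relative frequencies over
#' the 20 standard amino acids. Non-standard characters (`*`, `X`) are
#' ignored; each column is normalized over the residues actually counted,
#' so every column sums to 1.
#'
#' @param sequences character vector of CDR3 amino-acid strings.
#' @return 20 x L numeric matrix (rows: amino acids, columns: positions),
#'   with attributes `"modal_length"` and `"n_sequences"`.
#' @export
cdr3_pfm <- function(sequences) {
  sequences <- sequences[!is.na(sequences) & nzchar(sequences)]
  assert_that(length(sequences) >= 1, "cdr3_pfm needs at least one sequence")
  len <- nchar(sequences)
  tab <- table(len)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  seqs <- sequences[len == modal]
  chars <- do.call(rbind, strsplit(seqs, ""))
  pfm <- vapply(seq_len(modal), function(j) {
    col <- chars[, j]
    col <- col[col %in% AA20]
    counts <- table(factor(col, levels = AA20))
    tot <- sum(counts)
    if (tot == 0) rep(0, 20) else as.numeric(counts) / tot
  }, numeric(20))
  rownames(pfm) <- AA20
  colnames(pfm) <- seq_len(modal)
  attr(pfm, "modal_length") <- modal
  attr(pfm, "n_sequences") <- length(seqs)
  pfm
}
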