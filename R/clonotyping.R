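# Cell-level QC and clonal-family assignment.
#
# A cell enters the analysis only if its barcode carries exactly one
# productive heavy (IGH) contig and exactly one productive light (IGK/IGL)
# contig, both with a non-empty CDR3 amino-acid sequence. Cells are then
# grouped into clones by identical CDRH3+CDRL3 amino acids.

#' Pair contigs into QC-passing cells
#'
#' Applies the one-heavy-one-light rule: keep barcodes with exactly one
#' productive IGH contig and exactly one productive IGK or IGL contig, both
#' with non-empty CDR3 amino acids. The productivity filter is applied
#' before counting chains (cellranger's filtered output is already
#' productive-biased; this assumption is documented). A per-reason QC report
#' is attached as attribute `"qc_report"` and emitted via `message()`.
#'
#' @param contigs unified-schema contig data.frame (see [read_contigs()]).
#' @param meta single-row sample metadata data.frame
#'   (`sample_id, mouse_id, organ, cohort`).
#' @param verbose emit the QC report as a message.
#' @return data.frame with one row per retained cell: barcode, sample
#'   metadata, heavy-chain fields (prefix `h_`), light-chain fields
#'   (prefix `l_`), and the heavy-chain derived `isotype`.
#' @export
filter_cells <- function(contigs, meta, verbose = FALSE) {
  stopifnot(nrow(meta) == 1)
  validate_sample_meta(meta)
  prod <- contigs[contigs$is_productive & nzchar(contigs$barcode), ,
                  drop = FALSE]
  n_nonprod <- nrow(contigs) - nrow(prod)
  heavy <- prod[prod$chain == "IGH", , drop = FALSE]
  light <- prod[prod$chain %in% c("IGK", "IGL"), , drop = FALSE]
  all_bc <- unique(contigs$barcode[nzchar(contigs$barcode)])
  nh <- table(factor(heavy$barcode, levels = all_bc))
  nl <- table(factor(light$barcode, levels = all_bc))

  reasons <- c(
    no_heavy = sum(nh == 0), multi_heavy = sum(nh > 1),
    no_light = sum(nh == 1 & nl == 0), multi_light = sum(nh == 1 & nl > 1))
  keep_bc <- all_bc[nh == 1 & nl == 1]

  h <- heavy[match(keep_bc, heavy$barcode), , drop = FALSE]
  l <- light[match(keep_bc, light$barcode), , drop = FALSE]
  cdr3_ok <- nzchar(h$cdr3_aa) & nzchar(l$cdr3_aa)
  reasons <- c(reasons, empty_cdr3 = sum(!cdr3_ok))
  h <- h[cdr3_ok, , drop = FALSE]
  l <- l[cdr3_ok, , drop = FALSE]

  cells <- data.frame(
    barcode = h$barcode,
    sample_id = meta$sample_id, mouse_id = meta$mouse_id,
    organ = meta$organ, cohort = meta$cohort,
    cdrh3_aa = h$cdr3_aa, cdrl3_aa = l$cdr3_aa,
    cdrh3_nt = h$cdr3_nt, cdrl3_nt = l$cdr3_nt,
    vh_call = h$v_call, jh_call = h$j_call, ch_call = h$c_call,
    vl_call = l$v_call, jl_call = l$j_call, cl_call = l$c_call,
    vh_nt = h$vdj_nt, vl_nt = l$vdj_nt,
    h_seq_align = h$sequence_alignment, h_germ_align = h$germline_alignment,
    l_seq_align = l$sequence_alignment, l_germ_align = l$germline_alignment,
    h_umis = h$umis, l_umis = l$umis,
    isotype = isotype_from_c_call(h$c_call),
    stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  qc <- c(n_contigs = nrow(contigs), n_nonproductive = n_nonprod,
          n_barcodes = length(all_bc), reasons,
          n_cells = nrow(cells))
  attr(cells, "qc_report") <- qc
  if (verbose) {
    message(sprintf("[%s] QC: %d barcodes -> %d cells (dropped: %s)",
                    meta$sample_id, length(all_bc), nrow(cells),
                    paste(names(reasons), reasons, sep = "=",
                          collapse = ", ")))
  }
  cells
}

clone_key_of <- function(cdrh3, cdrl3) paste(cdrh3, cdrl3, sep = "|")

#' Group cells into clonal families
#'
#' Cells sharing identical CDRH3+CDRL3 amino-acid sequences form one clone.
#' The grouping scope controls the unit within which clones are keyed:
#' `per_sample` (one mouse-organ repertoire; the default, matching
#' within-repertoire expansion analyses), `per_mouse` (both organs pooled),
#' or `global` (all cells; used for overlap analyses).
#'
#' @param cells QC-passing cell table from [filter_cells()] (rows from
#'   several samples may be concatenated).
#' @param scope grouping scope.
#' @return object of class `clone_set`: a list with `$clones` (one row per
#'   clone: clone_id, clone_key, CDR3s, group, size, expanded, isotype,
#'   n_variants_nt, n_variants_aa, representative germline calls, member
#'   sample/mouse/organ sets) and `$cells` (the input cells plus their
#'   `clone_id`), plus the `scope`.
#' @export
assign_clones <- function(cells,
                          scope = c("per_sample", "per_mouse", "global")) {
  scope <- match.arg(scope)
  group <- switch(scope,
    per_sample = cells$sample_id,
    per_mouse = cells$mouse_id,
    global = rep("all", nrow(cells)))
  if (nrow(cells) == 0) {
    clones <- data.frame(clone_id = character(), clone_key = character(),
                         cdrh3_aa = character(), cdrl3_aa = character(),
                         group = character(), size = integer(),
                         expanded = logical(), isotype = character(),
                         n_variants_nt = integer(), n_variants_aa = integer(),
                         vh_call = character(), vl_call = character(),
                         jh_call = character(), jl_call = character(),
                         mouse_id = character(), organ = character(),
                         cohort = character(), samples = character(),
                         stringsAsFactors = FALSE)
    out <- list(clones = clones, cells = cbind(cells,
                clone_id = character(0)), scope = scope)
    class(out) <- "clone_set"
    return(out)
  }
  key <- clone_key_of(cells$cdrh3_aa, cells$cdrl3_aa)
  gk <- paste(group, key, sep = "\r")
  # deterministic clone order: by group, then key, independent of row order
  levels_gk <- sort(unique(gk))
  idx <- split(seq_len(nrow(cells)), factor(gk, levels = levels_gk))
  clone_rows <- lapply(seq_along(idx), function(i) {
    rows <- idx[[i]]
    sub <- cells[rows, , drop = FALSE]
    rep_row <- representative_member(sub)
    data.frame(
      clone_key = clone_key_of(sub$cdrh3_aa[1], sub$cdrl3_aa[1]),
      cdrh3_aa = sub$cdrh3_aa[1], cdrl3_aa = sub$cdrl3_aa[1],
      group = group[rows[1]],
      size = length(unique(sub$barcode)),
      isotype = clone_isotype(sub$isotype),
      n_variants_nt = count_variants(sub$vh_nt, sub$vl_nt, mode = "nt"),
      n_variants_aa = suppressWarnings(
        count_variants(sub$vh_nt, sub$vl_nt, mode = "aa")),
      vh_call = rep_row$vh_call, vl_call = rep_row$vl_call,
      jh_call = rep_row$jh_call, jl_call = rep_row$jl_call,
      mouse_id = paste(sort(unique(sub$mouse_id)), collapse = ","),
      organ = paste(sort(unique(sub$organ)), collapse = ","),
      cohort = paste(sort(unique(sub$cohort)), collapse = ","),
      samples = paste(sort(unique(sub$sample_id)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  clones <- do.call(rbind, clone_rows)
  clones$expanded <- clones$size >= 2L
  clones$clone_id <- sprintf("clone%05d", seq_len(nrow(clones)))
  clones <- clones[, c("clone_id", "clone_key", "cdrh3_aa", "cdrl3_aa",
                       "group", "size", "expanded", "isotype",
                       "n_variants_nt", "n_variants_aa",
                       "vh_call", "vl_call", "jh_call", "jl_call",
                       "mouse_id", "organ", "cohort", "samples")]
  rownames(clones) <- NULL
  cell_clone <- rep(clones$clone_id, times = lengths(idx))
  cells2 <- cells
  cells2$clone_id <- NA_character_
  cells2$clone_id[unlist(idx)] <- cell_clone
  out <- list(clones = clones, cells = cells2, scope = scope)
  class(out) <- "clone_set"
  out
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set: %d clones over %d cells (scope: %s)\n",
              nrow(x$clones), nrow(x$cells), x$scope))
  cat(sprintf("  expanded: %d (%.1f%%)\n", sum(x$clones$expanded),
              100 * mean(x$clones$expanded)))
  invisible(x)
}

# representative member = cell belonging to the most-supported nt variant
# (ties: lexicographically smallest VH+VL concatenation, matching
# representative_variant)
representative_member <- function(sub) {
  rv <- representative_variant(sub$vh_nt, sub$vl_nt)
  hit <- which(sub$vh_nt == rv$vh_nt & sub$vl_nt == rv$vl_nt)[1]
  sub[hit, , drop = FALSE]
}

#' Majority isotype of a clone
#'
#' Modal isotype over member cells' heavy-chain isotypes. `"Unknown"` cells
#' participate in the vote; ties are broken by preferring non-Unknown
#' isotypes, then alphabetical order (a deterministic convention).
#'
#' @param isotypes character vector of member-cell isotype labels.
#' @return single isotype label.
#' @export
clone_isotype <- function(isotypes) {
  stopifnot(length(isotypes) >= 1)
  tab <- table(isotypes)
  top <- names(tab)[tab == max(tab)]
  known <- setdiff(top, "Unknown")
  if (length(known)) sort(known)[1] else "Unknown"
}

#' Count clone variants
#'
#' A nucleotide variant is a distinct (VH nt, VL nt) full-length pair among
#' member cells; the amino-acid mode counts distinct translated
#' (VH aa, VL aa) pairs. Cells whose VH or VL length is not divisible by 3
#' are excluded from the amino-acid count with a warning.
#'
#' @param vh_nt,vl_nt parallel character vectors over member cells.
#' @param mode `"nt"` or `"aa"`.
#' @return non-negative integer count of distinct pairs.
#' @export
count_variants <- function(vh_nt, vl_nt, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  stopifnot(length(vh_nt) == length(vl_nt))
  if (length(vh_nt) == 0) return(0L)
  if (mode == "aa") {
    vh_nt <- translate_nt(vh_nt)
    vl_nt <- translate_nt(vl_nt)
    ok <- !is.na(vh_nt) & !is.na(vl_nt)
    vh_nt <- vh_nt[ok]; vl_nt <- vl_nt[ok]
    if (length(vh_nt) == 0) return(0L)
  }
  length(unique(paste(vh_nt, vl_nt, sep = "|")))
}

#' Clonal expansion profile of a repertoire
#'
#' Sorts clones by size (descending; ties broken by clone key) and reports
#' each clone's fraction of all cells in the repertoire plus its rank. The
#' fraction of size-1 clones among all clones is attached as attribute
#' `"percent_unexpanded"` (and its complement as `"percent_expanded"`).
#'
#' @param clones clone table (`$clones` of a [assign_clones()] result, or a
#'   subset of its rows for one repertoire).
#' @return data.frame `clone_key, size, fraction_of_cells, rank`.
#' @export
expansion_profile <- function(clones) {
  assert_that(nrow(clones) >= 1, "expansion_profile needs at least one clone")
  ord <- order(-clones$size, clones$clone_key)
  out <- clones[ord, c("clone_key", "size"), drop = FALSE]
  total <- sum(out$size)
  out$fraction_of_cells <- out$size / total
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "percent_unexpanded") <- 100 * mean(clones$size == 1)
  attr(out, "percent_expanded") <- 100 * mean(clones$size >= 2)
  out
}

#' Percent of clones that are expanded (size >= 2)
#'
#' @param clones clone table.
#' @return percent in [0, 100].
#' @export
percent_expanded <- function(clones) {
  if (nrow(clones) == 0) return(NA_real_)
  100 * mean(clones$size >= 2)
}
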