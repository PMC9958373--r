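# Selection of clones and representative sequences for recombinant
# antibody expression.

#' Select clones for antibody expression
#'
#' Applies three selection rules and unions the results, keeping every rule
#' a clone satisfied as a reason tag:
#' \itemize{
#'   \item \code{top_expanded_IgG}: the `top_n` largest IgG-majority clones
#'     within each (mouse, organ) repertoire (ties by clone key).
#'   \item \code{organ_overlapping}: expanded IgG-majority clones found in
#'     both bone marrow and spleen of the same mouse.
#'   \item \code{public}: clones found in two or more distinct mice
#'     (no isotype restriction).
#' }
#' Each selected clone carries its representative variant, the VH+VL
#' nucleotide pair supported by the most unique cell barcodes.
#'
#' @param cs `clone_set` from [assign_clones()] with `per_sample` scope.
#' @param meta sample metadata table.
#' @param top_n positive integer: clones taken per (mouse, organ) group.
#' @param include_overlapping,include_public toggle rules (b) and (c).
#' @return data.frame `clone_key, sample_id, size, isotype, reasons`
#'   (comma-separated tag set), `vh_nt, vl_nt` of the representative
#'   variant; one row per (clone_key, repertoire) occurrence.
#' @export
select_for_expression <- function(cs, meta, top_n = 10,
                                  include_overlapping = TRUE,
                                  include_public = TRUE) {
  assert_that(top_n >= 1, "top_n must be a positive integer")
  meta <- validate_sample_meta(meta)
  clones <- cs$clones
  clones$mouse_id <- meta$mouse_id[match(clones$group, meta$sample_id)]
  clones$organ <- meta$organ[match(clones$group, meta$sample_id)]
  is_igg <- grepl("^IgG", clones$isotype)

  reason_list <- rep(list(character(0)), nrow(clones))

  # (a) top-n expanded IgG per (mouse, organ) repertoire
  grp <- paste(clones$mouse_id, clones$organ, sep = "/")
  for (g in unique(grp)) {
    rows <- which(grp == g & is_igg)
    if (!length(rows)) next
    ord <- rows[order(-clones$size[rows], clones$clone_key[rows])]
    take <- utils::head(ord, top_n)
    for (i in take) reason_list[[i]] <- c(reason_list[[i]],
                                          "top_expanded_IgG")
  }

  by_sample <- split(clones, clones$group)
  if (include_overlapping) {
    ov <- find_shared_clones(by_sample, meta,
                             "organ_overlapping_within_mouse")
    if (nrow(ov)) {
      for (i in seq_len(nrow(ov))) {
        rows <- which(clones$mouse_id == ov$mouse_id[i] &
                        clones$clone_key == ov$clone_key[i] &
                        is_igg & clones$size >= 2)
        for (r in rows) reason_list[[r]] <- c(reason_list[[r]],
                                              "organ_overlapping")
      }
    }
  }
  if (include_public) {
    pub <- find_shared_clones(by_sample, meta, "public_across_mice")
    if (nrow(pub)) {
      rows <- which(clones$clone_key %in% pub$clone_key)
      for (r in rows) reason_list[[r]] <- c(reason_list[[r]], "public")
    }
  }

  sel <- which(lengths(reason_list) > 0)
  if (!length(sel)) {
    return(data.frame(clone_key = character(), sample_id = character(),
                      size = integer(), isotype = character(),
                      reasons = character(), vh_nt = character(),
                      vl_nt = character(), stringsAsFactors = FALSE))
  }
  reps <- lapply(sel, function(i) {
    members <- cs$cells[cs$cells$clone_id == clones$clone_id[i], ,
                        drop = FALSE]
    representative_variant(members$vh_nt, members$vl_nt)
  })
  out <- data.frame(
    clone_key = clones$clone_key[sel],
    sample_id = clones$group[sel],
    size = clones$size[sel],
    isotype = clones$isotype[sel],
    reasons = vapply(reason_list[sel], function(r)
      paste(sort(unique(r)), collapse = ","), character(1)),
    vh_nt = vapply(reps, `[[`, character(1), "vh_nt"),
    vl_nt = vapply(reps, `[[`, character(1), "vl_nt"),
    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, -out$size, out$clone_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative variant of a clone
#'
#' The (VH nt, VL nt) pair supported by the most unique cell barcodes;
#' ties are broken by the lexicographically smallest concatenated VH+VL
#' sequence.
#'
#' @param vh_nt,vl_nt parallel vectors over member cells (one entry per
#'   barcode).
#' @return list with `vh_nt`, `vl_nt`, and `support` (barcode count).
#' @export
representative_variant <- function(vh_nt, vl_nt) {
  stopifnot(length(vh_nt) == length(vl_nt), length(vh_nt) >= 1)
  key <- paste(vh_nt, vl_nt, sep = "\r")
  support <- table(key)
  top <- names(support)[support == max(support)]
  concat <- vapply(strsplit(top, "\r", fixed = TRUE),
                   function(p) paste0(p[1], p[2]), character(1))
  best <- top[order(concat)][1]
  parts <- strsplit(best, "\r", fixed = TRUE)[[1]]
  list(vh_nt = parts[1], vl_nt = parts[2],
       support = as.integer(max(support)))
}

#' Write a selection table with FASTA export
#'
#' @param selection output of [select_for_expression()].
#' @param dir output directory; writes `selection.tsv` and
#'   `selection_vh_vl.fasta` (VH and VL records per selected clone).
#' @return `dir`, invisibly.
#' @export
write_selection <- function(selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(selection, file.path(dir, "selection.tsv"))
  if (nrow(selection)) {
    fa <- character(0)
    for (i in seq_len(nrow(selection))) {
      tag <- paste0(selection$sample_id[i], "_", i)
      fa <- c(fa, paste0(">", tag, "_VH"), selection$vh_nt[i],
              paste0(">", tag, "_VL"), selection$vl_nt[i])
    }
    writeLines(fa, file.path(dir, "selection_vh_vl.fasta"))
  }
  invisible(dir)
}
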