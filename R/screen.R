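# ELISA binder classification and cohort-level specificity summaries.

#' Classify ELISA results into binder / non-binder / no-expression calls
#'
#' A clone whose antibody could not be expressed is called `no_expression`.
#' Otherwise it is a `binder` when its OD450 signal is at least
#' `fold` times the negative background control ("at least three times"
#' is implemented inclusively, >=).
#'
#' @param plate data.frame with columns `clone_key, od450, expressed`
#'   (see [read_elisa()]); extra columns (cohort, organ, ...) are carried
#'   through.
#' @param negative_control_od positive background OD450.
#' @param fold positive fold-over-background threshold (default 3).
#' @return the plate with added columns `call` (factor-like character:
#'   binder / non_binder / no_expression) and `threshold_od`.
#' @export
call_binders <- function(plate, negative_control_od, fold = 3.0) {
  assert_that(is.numeric(negative_control_od) && negative_control_od > 0,
              "negative_control_od must be > 0")
  assert_that(fold > 0, "fold must be > 0")
  bad <- which(!is.na(plate$od450) & plate$od450 < 0)
  if (length(bad)) {
    abort_cs(paste0("negative od450 at row ", bad[1]),
             "cs_validation_error")
  }
  thr <- fold * negative_control_od
  call <- ifelse(!plate$expressed, "no_expression",
                 ifelse(plate$od450 >= thr, "binder", "non_binder"))
  plate$call <- call
  plate$threshold_od <- thr
  plate
}

#' Cohort-level specificity summary
#'
#' Percent of tested clones that bind antigen, grouped by arbitrary
#' columns. `n_tested` counts clones with a definitive binder/non-binder
#' call; `no_expression` clones are excluded from the denominator (they are
#' reported separately), reproducing printed ratios of the form 31/99.
#' Percentages are reported to one decimal.
#'
#' @param results output of [call_binders()].
#' @param group_by character vector of grouping column names (e.g.
#'   `c("cohort", "organ")`); `NULL` summarizes everything together.
#' @return data.frame with the grouping columns plus `n_tested, n_binders,
#'   n_no_expression, percent_specific` (NA when nothing was tested).
#' @export
specificity_summary <- function(results, group_by = NULL) {
  if (is.null(group_by)) {
    grp <- rep("all", nrow(results))
    gdf <- data.frame(group = unique(grp))
  } else {
    missing <- setdiff(group_by, names(results))
    assert_that(length(missing) == 0,
                paste0("grouping column(s) not found: ",
                       paste(missing, collapse = ", ")))
    grp <- do.call(paste, c(results[group_by], sep = "\r"))
  }
  out <- lapply(unique(grp), function(g) {
    sub <- results[grp == g, , drop = FALSE]
    tested <- sub$call %in% c("binder", "non_binder")
    n_tested <- sum(tested)
    n_binders <- sum(sub$call == "binder")
    row <- if (is.null(group_by)) data.frame(row.names = 1) else
      sub[1, group_by, drop = FALSE]
    row$n_tested <- n_tested
    row$n_binders <- n_binders
    row$n_no_expression <- sum(sub$call == "no_expression")
    row$percent_specific <- if (n_tested == 0) NA_real_ else
      round(100 * n_binders / n_tested, 1)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relate clonal-expansion rank to antigen specificity
#'
#' Joins screen calls to each clone's expansion rank within its repertoire
#' and reports a rank-biserial correlation between rank and binder status,
#' with a seeded permutation p-value. Positive correlation means binders
#' sit at numerically larger (less expanded) ranks; a value near 0 supports
#' "expansion is not correlated with specificity". `no_expression` clones
#' are excluded.
#'
#' @param results output of [call_binders()] carrying a `rank` column (join
#'   the repertoire's [expansion_profile()] beforehand), or pass `ranks`.
#' @param ranks optional numeric vector overriding `results$rank`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutation null.
#' @return list with `table` (rank, call), `rank_biserial`, `p_value`
#'   (both NA when fewer than 2 distinct calls are present), `n_perm`.
#' @export
rank_vs_specificity <- function(results, ranks = NULL, n_perm = 10000,
                                seed = 1L) {
  if (is.null(ranks)) {
    assert_that("rank" %in% names(results),
                "results must carry a 'rank' column (or supply ranks=)")
    ranks <- results$rank
  }
  keep <- results$call %in% c("binder", "non_binder")
  ranks <- ranks[keep]
  call <- results$call[keep]
  tab <- data.frame(rank = ranks, call = call, stringsAsFactors = FALSE)
  if (length(unique(call)) < 2) {
    return(list(table = tab, rank_biserial = NA_real_, p_value = NA_real_,
                n_perm = n_perm))
  }
  is_b <- call == "binder"
  stat <- rank_biserial_stat(ranks, is_b)
  set.seed(seed)
  null <- replicate(n_perm, rank_biserial_stat(ranks, sample(is_b)))
  p <- (1 + sum(abs(null) >= abs(stat))) / (n_perm + 1)
  list(table = tab, rank_biserial = stat, p_value = p, n_perm = n_perm)
}

# rank-biserial r = 2 * (U / (n1*n2)) - 1, computed on the rank values
rank_biserial_stat <- function(ranks, is_b) {
  r <- rank(ranks)
  n1 <- sum(is_b); n2 <- sum(!is_b)
  u <- sum(r[is_b]) - n1 * (n1 + 1) / 2
  2 * (u / (n1 * n2)) - 1
}
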