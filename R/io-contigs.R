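# Contig table ingest: 10x filtered_contig_annotations.csv and AIRR
# Rearrangement TSV dialects, mapped onto one unified schema.

CONTIG_COLS <- c("barcode", "contig_id", "chain", "cdr3_aa", "cdr3_nt",
                 "v_call", "d_call", "j_call", "c_call", "vdj_nt",
                 "sequence_alignment", "germline_alignment", "umis",
                 "is_productive")

TENX_MANDATORY <- c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene",
                    "j_gene", "c_gene", "productive")
AIRR_MANDATORY <- c("cell_id", "locus", "junction_aa", "junction", "v_call",
                    "j_call", "c_call", "productive")

parse_logical_flag <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x %in% c("TRUE", "T", "YES", "1")
}

clean_seq_col <- function(x, n) {
  if (is.null(x)) return(rep("", n))
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | x %in% c("NA", "NONE", "NULL")] <- ""
  x
}

clean_chr_col <- function(x, n) {
  if (is.null(x)) return(rep("", n))
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% c("NA", "None", "NONE", "null")] <- ""
  x
}

#' Read contig annotation tables
#'
#' Reads per-cell V(D)J contig annotations in either the 10x Genomics
#' `filtered_contig_annotations.csv` dialect or the AIRR Rearrangement TSV
#' dialect, and maps both onto a unified schema with columns
#' `barcode, contig_id, chain, cdr3_aa, cdr3_nt, v_call, d_call, j_call,
#' c_call, vdj_nt, sequence_alignment, germline_alignment, umis,
#' is_productive`. CDR3 strings are upper-cased and whitespace-trimmed on
#' ingest so clonotype keys are deterministic. Non-productive contigs are
#' retained here and filtered during cell QC, keeping QC auditable.
#'
#' @param path file path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return data.frame with one row per contig, row order preserved.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_cs(paste0("cannot read contig file: ", path), "cs_io_error")
  }
  raw <- if (dialect == "tenx_csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  mandatory <- if (dialect == "tenx_csv") TENX_MANDATORY else AIRR_MANDATORY
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort_cs(paste0("contig table is missing mandatory column(s): ",
                    paste(missing, collapse = ", ")), "cs_schema_error")
  }
  n <- nrow(raw)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = clean_chr_col(raw$barcode, n),
      contig_id = clean_chr_col(raw$contig_id, n),
      chain = clean_chr_col(raw$chain, n),
      cdr3_aa = clean_seq_col(raw$cdr3, n),
      cdr3_nt = clean_seq_col(raw$cdr3_nt, n),
      v_call = clean_chr_col(raw$v_gene, n),
      d_call = clean_chr_col(raw$d_gene, n),
      j_call = clean_chr_col(raw$j_gene, n),
      c_call = clean_chr_col(raw$c_gene, n),
      vdj_nt = clean_seq_col(raw$sequence, n),
      sequence_alignment = clean_seq_col(raw$sequence_alignment, n),
      germline_alignment = clean_seq_col(raw$germline_alignment, n),
      umis = if (is.null(raw$umis)) rep(0L, n) else as.integer(raw$umis),
      is_productive = parse_logical_flag(raw$productive),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      barcode = clean_chr_col(raw$cell_id, n),
      contig_id = clean_chr_col(raw$sequence_id, n),
      chain = clean_chr_col(raw$locus, n),
      cdr3_aa = clean_seq_col(raw$junction_aa, n),
      cdr3_nt = clean_seq_col(raw$junction, n),
      v_call = clean_chr_col(raw$v_call, n),
      d_call = clean_chr_col(raw$d_call, n),
      j_call = clean_chr_col(raw$j_call, n),
      c_call = clean_chr_col(raw$c_call, n),
      vdj_nt = clean_seq_col(raw$sequence, n),
      sequence_alignment = clean_seq_col(raw$sequence_alignment, n),
      germline_alignment = clean_seq_col(raw$germline_alignment, n),
      umis = if (is.null(raw$duplicate_count)) rep(0L, n)
             else as.integer(raw$duplicate_count),
      is_productive = parse_logical_flag(raw$productive),
      stringsAsFactors = FALSE)
  }
  out$umis[is.na(out$umis)] <- 0L
  validate_contigs(out)
  out
}

validate_contigs <- function(contigs) {
  if (nrow(contigs) == 0) return(invisible(contigs))
  bad_chain <- which(!contigs$chain %in% c("IGH", "IGK", "IGL"))
  if (length(bad_chain)) {
    abort_cs(paste0("unknown chain/locus value '",
                    contigs$chain[bad_chain[1]], "' at row ",
                    bad_chain[1]), "cs_validation_error")
  }
  has_both <- nchar(contigs$sequence_alignment) > 0 &
    nchar(contigs$germline_alignment) > 0
  mismatch <- which(has_both &
    nchar(contigs$sequence_alignment) != nchar(contigs$germline_alignment))
  if (length(mismatch)) {
    abort_cs(paste0("sequence/germline alignment length mismatch at row ",
                    mismatch[1]), "cs_validation_error")
  }
  bad_aa <- which(vapply(strsplit(contigs$cdr3_aa, ""), function(ch)
    any(!ch %in% CDR3_ALPHABET), logical(1)))
  if (length(bad_aa)) {
    abort_cs(paste0("invalid CDR3 amino-acid characters at row ",
                    bad_aa[1], ": ", contigs$cdr3_aa[bad_aa[1]]),
             "cs_validation_error")
  }
  invisible(contigs)
}

#' Write contigs back out in a supported dialect
#'
#' Inverse of [read_contigs()] for the mandatory fields; used for lossless
#' round-trip checks and for exchanging simulated data.
#'
#' @param contigs unified-schema contig data.frame.
#' @param path output path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = contigs$barcode, contig_id = contigs$contig_id,
      chain = contigs$chain, cdr3 = contigs$cdr3_aa,
      cdr3_nt = contigs$cdr3_nt, v_gene = contigs$v_call,
      d_gene = contigs$d_call, j_gene = contigs$j_call,
      c_gene = contigs$c_call, sequence = contigs$vdj_nt,
      sequence_alignment = contigs$sequence_alignment,
      germline_alignment = contigs$germline_alignment,
      umis = contigs$umis,
      productive = ifelse(contigs$is_productive, "True", "False"),
      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      cell_id = contigs$barcode, sequence_id = contigs$contig_id,
      locus = contigs$chain, junction_aa = contigs$cdr3_aa,
      junction = contigs$cdr3_nt, v_call = contigs$v_call,
      d_call = contigs$d_call, j_call = contigs$j_call,
      c_call = contigs$c_call, sequence = contigs$vdj_nt,
      sequence_alignment = contigs$sequence_alignment,
      germline_alignment = contigs$germline_alignment,
      duplicate_count = contigs$umis,
      productive = ifelse(contigs$is_productive, "T", "F"),
      stringsAsFactors = FALSE)
    write_tsv(out, path)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with columns `sample_id, mouse_id, organ, cohort`; organ must be
#' `bone_marrow` or `spleen`, cohort one of `3m, 12m, 18m`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "mouse_id", "organ", "cohort")
  missing <- setdiff(need, names(meta))
  assert_that(length(missing) == 0,
              paste0("sample metadata missing column(s): ",
                     paste(missing, collapse = ", ")), "cs_schema_error")
  assert_that(!anyDuplicated(meta$sample_id),
              "sample_id values must be unique")
  assert_that(all(meta$organ %in% ORGAN_LEVELS),
              paste0("organ must be one of: ",
                     paste(ORGAN_LEVELS, collapse = ", ")))
  assert_that(all(meta$cohort %in% COHORT_LEVELS),
              paste0("cohort must be one of: ",
                     paste(COHORT_LEVELS, collapse = ", ")))
  meta
}

#' Read an ELISA plate table
#'
#' CSV with columns `clone_key, od450, expressed` and optionally
#' `negative_control_od` (constant per plate, or supplied separately to
#' [call_binders()]).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_elisa <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clone_key", "od450", "expressed")
  missing <- setdiff(need, names(x))
  assert_that(length(missing) == 0,
              paste0("ELISA table missing column(s): ",
                     paste(missing, collapse = ", ")), "cs_schema_error")
  x$expressed <- parse_logical_flag(x$expressed)
  x
}
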