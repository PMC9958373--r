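# Contig/matrix/metadata readers and the dialect-equivalence property.

tenx_header <- paste("barcode,contig_id,chain,cdr3,cdr3_nt,v_gene,d_gene",
                     "j_gene,c_gene,sequence,umis,productive", sep = ",")

write_tenx_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(tenx_header, rows), path)
  path
}

test_that("read_contigs maps the 10x dialect onto the unified schema", {
  path <- write_tenx_fixture(c(
    "BC1,BC1_c1,IGH,CARDYW,TGTGCTAGAGATTATTGG,IGHV1-26,IGHD1-1,IGHJ2,IGHG1,ACGT,5,True",
    "BC1,BC1_c2,IGK,CQQYNSYPLTF,TGTCAACAG,IGKV4-53,,IGKJ1,IGKC,ACGG,3,True",
    "BC2,BC2_c1,IGH,CARWFDVW,TGTGCTAGA,IGHV1-53,,IGHJ4,IGHM,,2,False"))
  x <- read_contigs(path, "tenx_csv")
  expect_equal(nrow(x), 3)
  expect_equal(x$barcode, c("BC1", "BC1", "BC2"))
  expect_equal(x$cdr3_aa[1], "CARDYW")
  expect_equal(x$v_call, c("IGHV1-26", "IGKV4-53", "IGHV1-53"))
  expect_equal(x$is_productive, c(TRUE, TRUE, FALSE))
  expect_equal(x$umis, c(5L, 3L, 2L))
  expect_equal(x$vdj_nt[3], "")  # empty optional field
})

test_that("header-only file yields an empty contig table", {
  path <- write_tenx_fixture(character(0))
  x <- read_contigs(path, "tenx_csv")
  expect_equal(nrow(x), 0)
  expect_true(all(clonescreen:::CONTIG_COLS %in% names(x)))
})

test_that("schema and validation errors name the offending column/row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,cdr3", "BC1,IGH,CAR"), path)
  expect_error(read_contigs(path, "tenx_csv"), "cdr3_nt",
               class = "cs_schema_error")
  path2 <- write_tenx_fixture(
    "BC1,c1,TRB,CASSL,TGT,TRBV1,,TRBJ1,TRBC1,,1,True")
  expect_error(read_contigs(path2, "tenx_csv"), "row 1",
               class = "cs_validation_error")
  expect_error(read_contigs(file.path(tempdir(), "absent.csv")),
               class = "cs_io_error")
})

test_that("both dialects read the same logical data identically", {
  contigs <- rbind(
    contig_row("BC1", "IGH", "CARDYW", c_call = "IGHG1",
               vdj_nt = "ACGTACGTA", sequence_alignment = "ACGTACGTA",
               germline_alignment = "ACGTACGTT"),
    contig_row("BC1", "IGK", "CQQYNSYPLTF", c_call = "IGKC",
               vdj_nt = "GGGCCCAAA"),
    contig_row("BC2", "IGL", "CARDFW", c_call = "IGLC1",
               is_productive = FALSE))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_contigs(contigs, p1, "tenx_csv")
  write_contigs(contigs, p2, "airr_tsv")
  a <- read_contigs(p1, "tenx_csv")
  b <- read_contigs(p2, "airr_tsv")
  expect_identical(a, b)
  expect_equal(b$cdr3_aa[1], "CARDYW")  # junction_aa mapping
})

test_that("read_contigs round-trips losslessly through both dialects", {
  sim <- small_sim()
  contigs <- utils::head(sim$samples[[1]], 50)
  for (d in c("tenx_csv", "airr_tsv")) {
    p <- withr::local_tempfile()
    write_contigs(contigs, p, d)
    back <- read_contigs(p, d)
    rownames(contigs) <- NULL
    expect_identical(back, contigs)
  }
})

test_that("read_counts reads an MTX trio and checks dimensions", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 4", "1 1 5", "2 1 1", "1 2 2", "2 3 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("BC1", "BC2", "BC3"), file.path(dir, "barcodes.tsv"))
  writeLines(c("GeneA", "GeneB"), file.path(dir, "features.tsv"))
  m <- read_counts(file.path(dir, "matrix.mtx"),
                   file.path(dir, "barcodes.tsv"),
                   file.path(dir, "features.tsv"))
  expect_equal(dim(m), c(3, 2))  # transposed to cells x genes
  expect_equal(Matrix::nnzero(m), 4)
  expect_equal(m["BC1", "GeneA"], 5)
  writeLines(c("BC1", "BC2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "barcodes.tsv"),
                           file.path(dir, "features.tsv")),
               "3 cells.*2", class = "cs_validation_error")
})

test_that("write_counts / read_counts round-trips a random sparse matrix", {
  set.seed(11)
  m <- Matrix::rsparsematrix(10, 8, density = 0.3,
                             rand.x = function(n) rpois(n, 4) + 1)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(sprintf("BC%02d", 1:10), sprintf("G%02d", 1:8))
  dir <- withr::local_tempdir()
  write_counts(m, dir)
  back <- read_counts(file.path(dir, "matrix.mtx"),
                      file.path(dir, "barcodes.tsv"),
                      file.path(dir, "features.tsv"))
  expect_equal(as.matrix(back), as.matrix(m))
})

test_that("sample metadata and ELISA tables are validated on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,mouse_id,organ,cohort",
               "s1,m01,bone_marrow,3m", "s2,m01,spleen,3m"), p)
  meta <- read_sample_meta(p)
  expect_equal(meta$organ, c("bone_marrow", "spleen"))
  writeLines(c("sample_id,mouse_id,organ,cohort",
               "s1,m01,liver,3m"), p)
  expect_error(read_sample_meta(p), "organ")
  writeLines(c("sample_id,mouse_id,organ,cohort",
               "s1,m01,bone_marrow,3m", "s1,m02,spleen,3m"), p)
  expect_error(read_sample_meta(p), "unique")
  e <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clone_key,od450,expressed", "k1,0.9,True", "k2,0.1,False"),
             e)
  plate <- read_elisa(e)
  expect_equal(plate$expressed, c(TRUE, FALSE))
})

test_that("the packaged synthetic example fixture loads end to end", {
  p <- system.file("extdata", "synthetic_contigs_10x.csv",
                   package = "clonescreen")
  meta <- read_sample_meta(system.file("extdata",
                                       "synthetic_sample_meta.csv",
                                       package = "clonescreen"))
  contigs <- read_contigs(p, "tenx_csv")
  cells <- filter_cells(contigs, meta)
  expect_equal(nrow(cells), 15)  # QC-fail barcodes in the file drop out
  expect_gt(nrow(contigs), 2 * 15)
})

test_that("isotype mapping follows constant-gene prefixes", {
  expect_equal(
    isotype_from_c_call(c("IGHM", "IGHD", "IGHG1", "IGHG2B", "IGHG2C",
                          "IGHG3", "IGHA", "IGKC", "IGLC1", "", NA)),
    c("IgM", "IgD", "IgG1", "IgG2B", "IgG2C", "IgG3", "IgA",
      "Unknown", "Unknown", "Unknown", "Unknown"))
})
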