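# Cell QC (one heavy + one light), clone assignment, isotype majority,
# variant counting, and expansion profiles.

test_that("filter_cells enforces the one-heavy-one-light rule", {
  # 10 barcodes: 3 valid, 2 heavy-only, 2 light-only, 1 double-heavy,
  # 1 double-light, 1 empty-CDR3 -> 3 cells
  contigs <- rbind(
    contig_row("V1", "IGH"), contig_row("V1", "IGK"),
    contig_row("V2", "IGH"), contig_row("V2", "IGL"),
    contig_row("V3", "IGH"), contig_row("V3", "IGK"),
    contig_row("H1", "IGH"), contig_row("H2", "IGH"),
    contig_row("L1", "IGK"), contig_row("L2", "IGL"),
    contig_row("DH", "IGH", contig_id = "DH_a"),
    contig_row("DH", "IGH", contig_id = "DH_b"), contig_row("DH", "IGK"),
    contig_row("DL", "IGH"),
    contig_row("DL", "IGK", contig_id = "DL_a"),
    contig_row("DL", "IGK", contig_id = "DL_b"),
    contig_row("EC", "IGH", cdr3_aa = ""), contig_row("EC", "IGK"))
  cells <- filter_cells(contigs, meta_row())
  expect_setequal(cells$barcode, c("V1", "V2", "V3"))
  qc <- attr(cells, "qc_report")
  expect_equal(unname(qc["multi_heavy"]), 1)
  expect_equal(unname(qc["multi_light"]), 1)
  expect_equal(unname(qc["empty_cdr3"]), 1)
  expect_equal(unname(qc["no_heavy"]), 2)
  expect_equal(unname(qc["no_light"]), 2)
})

test_that("productivity is applied before chain counting", {
  # 2 IGH but one non-productive -> counts as exactly one heavy
  contigs <- rbind(
    contig_row("B1", "IGH", contig_id = "a"),
    contig_row("B1", "IGH", contig_id = "b", is_productive = FALSE),
    contig_row("B1", "IGK"))
  cells <- filter_cells(contigs, meta_row())
  expect_equal(cells$barcode, "B1")
  expect_equal(cells$isotype, "IgG1")
})

test_that("assign_clones partitions by identical CDRH3+CDRL3", {
  cells <- rbind(
    cell_row("B1", cdrh3_aa = "CARDYW", cdrl3_aa = "CQQYNSYPLTF"),
    cell_row("B2", cdrh3_aa = "CARDYW", cdrl3_aa = "CQQYNSYPLTF"),
    cell_row("B3", cdrh3_aa = "CARDYW", cdrl3_aa = "CQQYNSYPLTF"),
    cell_row("B4", cdrh3_aa = "CARDFW", cdrl3_aa = "CQQYNSYPLTF"))
  cs <- assign_clones(cells)
  expect_equal(nrow(cs$clones), 2)
  expect_setequal(cs$clones$size, c(3L, 1L))
  small <- cs$clones[cs$clones$size == 1, ]
  expect_false(small$expanded)
  expect_equal(small$cdrh3_aa, "CARDFW")
  # conservation: clone sizes sum to cell count
  expect_equal(sum(cs$clones$size), nrow(cells))
  # empty input is legal
  expect_equal(nrow(assign_clones(cells[0, ])$clones), 0)
})

test_that("assign_clones matches a brute-force grouping oracle", {
  set.seed(101)
  keys <- replicate(40, paste(random_aa(10), random_aa(8), sep = "@"))
  pick <- sample(keys, 200, replace = TRUE)
  parts <- strsplit(pick, "@", fixed = TRUE)
  cells <- do.call(rbind, lapply(seq_along(parts), function(i)
    cell_row(sprintf("BC%03d", i), cdrh3_aa = parts[[i]][1],
             cdrl3_aa = parts[[i]][2])))
  cs <- assign_clones(cells)
  oracle <- table(pick)  # independent hash-grouping
  expect_equal(nrow(cs$clones), length(oracle))
  got <- stats::setNames(cs$clones$size,
                         paste(cs$clones$cdrh3_aa, cs$clones$cdrl3_aa,
                               sep = "@"))
  expect_equal(got[names(oracle)], stats::setNames(as.integer(oracle),
                                                   names(oracle)))
})

test_that("assign_clones is order-independent and respects scope", {
  set.seed(7)
  cells <- do.call(rbind, lapply(1:30, function(i)
    cell_row(sprintf("BC%02d", i),
             sample_id = sample(c("s1", "s2"), 1),
             mouse_id = "m01",
             cdrh3_aa = sample(c("CARAW", "CARBW", "CARCW"), 1))))
  cs1 <- assign_clones(cells, "per_sample")
  shuffled <- cells[sample(nrow(cells)), ]
  cs2 <- assign_clones(shuffled, "per_sample")
  expect_equal(cs1$clones, cs2$clones)
  # per_mouse pools the two samples: never more clones than per_sample
  cs3 <- assign_clones(cells, "per_mouse")
  expect_lte(nrow(cs3$clones), nrow(cs1$clones))
  expect_equal(sum(cs3$clones$size), nrow(cells))
})

test_that("clone_isotype takes the majority with deterministic ties", {
  expect_equal(clone_isotype(c("IgG1", "IgG1", "IgM")), "IgG1")
  expect_equal(clone_isotype("IgM"), "IgM")
  # tie -> alphabetically first among tied non-Unknown isotypes
  expect_equal(clone_isotype(c("IgG1", "IgM")), "IgG1")
  expect_equal(clone_isotype(c("IgM", "IgA")), "IgA")
  expect_equal(clone_isotype(c("Unknown", "IgM")), "IgM")
  expect_equal(clone_isotype(c("Unknown", "Unknown")), "Unknown")
  # exhaustive 2-cell pairs agree with an explicit tie-break oracle
  iso <- c("IgA", "IgG1", "IgM", "Unknown")
  for (a in iso) for (b in iso) {
    got <- clone_isotype(c(a, b))
    want <- if (a == b) a else {
      known <- setdiff(c(a, b), "Unknown")
      if (length(known)) sort(known)[1] else "Unknown"
    }
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("count_variants counts distinct VH+VL pairs", {
  expect_equal(count_variants(rep("AAA", 3), rep("CCC", 3)), 1L)
  expect_equal(count_variants(c("AAA", "AAA", "AAT"), rep("CCC", 3)), 2L)
  # 50-member clone with 7 planted nt variants
  set.seed(3)
  vh <- sprintf("AAA%03d", 1:7)[sample(1:7, 50, replace = TRUE)]
  vh[1:7] <- sprintf("AAA%03d", 1:7)  # ensure all present
  expect_equal(count_variants(vh, rep("CCC", 50)),
               length(unique(vh)))
  # aa mode: synonymous variants collapse, untranslatable cells excluded
  expect_equal(count_variants(c("TTA", "CTA"), c("GGG", "GGG"),
                              mode = "aa"), 1L)  # both Leu
  expect_warning(
    n <- count_variants(c("TTA", "CTAA"), c("GGG", "GGG"), mode = "aa"),
    "not divisible")
  expect_equal(n, 1L)
})

test_that("expansion_profile ranks clones and reports fractions", {
  clones <- data.frame(
    clone_key = c("a|x", "b|x", "c|x", "d|x"),
    size = c(5L, 3L, 1L, 1L), stringsAsFactors = FALSE)
  p <- expansion_profile(clones)
  expect_equal(p$fraction_of_cells, c(0.5, 0.3, 0.1, 0.1))
  expect_equal(p$rank, 1:4)
  expect_equal(attr(p, "percent_unexpanded"), 50)
  single <- expansion_profile(clones[1, ])
  expect_equal(single$fraction_of_cells, 1.0)
  expect_equal(single$rank, 1L)
})

test_that("clone-set invariants hold on simulated data", {
  sim <- small_sim()
  cs <- small_clone_set()
  # conservation of cells across the partition
  expect_equal(sum(cs$clones$size), nrow(cs$cells))
  expect_true(all(cs$clones$n_variants_nt >= 1))
  expect_true(all(cs$clones$n_variants_nt <= cs$clones$size))
  expect_true(all(table(cs$cells$clone_id) ==
                    cs$clones$size[match(names(table(cs$cells$clone_id)),
                                         cs$clones$clone_id)]))
})
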