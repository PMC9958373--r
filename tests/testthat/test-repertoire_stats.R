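# SHM counting, Jaccard overlap, shared-clone detection, V-J pairing,
# and CDR3 position-frequency matrices.

test_that("count_shm counts substitutions, skipping gaps and N columns", {
  expect_equal(count_shm("ACGT", "ACGT"), 0L)
  expect_equal(count_shm("ACGT", "ACGA"), 1L)
  # per-column enumeration: (A,A) match, (C,T) sub, (-,A) skip,
  # (G,G) match, (T,T) match, (N,A) skip -> 1
  expect_equal(count_shm("AC-GTN", "ATAGTA"), 1L)
  expect_error(count_shm("ACG", "ACGT"), "length mismatch",
               class = "cs_validation_error")
  # region mask excludes the junction
  mask <- c("V", "V", "NP", "NP", "J", "J")
  expect_equal(count_shm("AAAAAA", "TTTTTT", mask), 4L)
})

test_that("count_shm matches a per-column enumeration oracle and is
           symmetric", {
  set.seed(5)
  alphabet <- c("A", "C", "G", "T", "N", "-", ".")
  for (i in 1:25) {
    a <- paste(sample(alphabet, 30, replace = TRUE, prob = c(rep(5, 4), 1,
                                                             1, 1)),
               collapse = "")
    b <- paste(sample(alphabet, 30, replace = TRUE, prob = c(rep(5, 4), 1,
                                                             1, 1)),
               collapse = "")
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    valid <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    oracle <- sum(valid & ca != cb)
    expect_equal(count_shm(a, b), oracle)
    expect_equal(count_shm(b, a), count_shm(a, b))  # symmetry
    expect_equal(count_shm(a, a), 0L)
  }
})

test_that("clone_shm_summary averages HC+LC totals over member cells", {
  cells <- rbind(
    cell_row("B1", h_seq_align = "AAAA", h_germ_align = "TTTA",  # 3 subs
             l_seq_align = "AC", l_germ_align = "AT"),           # 1 sub
    cell_row("B2", h_seq_align = "AAAA", h_germ_align = "TTAA",  # 2
             l_seq_align = "GGGG", l_germ_align = "TTAA"))       # 4
  one <- clone_shm_summary(cells[1, ])
  expect_equal(one$mean_shm, 4.0)
  both <- clone_shm_summary(cells)
  expect_equal(both$mean_shm, 5.0)
  # no usable alignments -> flagged missing
  none <- clone_shm_summary(cell_row("B3"))
  expect_true(is.na(none$mean_shm))
  expect_equal(none$n_cells, 0L)
})

test_that("SHM recovery: planted Poisson substitutions are recovered", {
  set.seed(9)
  lambda <- 5
  germ <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  plant <- function() {
    k <- rpois(1, lambda)
    ch <- strsplit(germ, "")[[1]]
    pos <- sample(300, min(k, 300))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    list(seq = paste(ch, collapse = ""), k = length(pos))
  }
  n <- 20
  hs <- replicate(n, plant(), simplify = FALSE)
  ls <- replicate(n, plant(), simplify = FALSE)
  cells <- do.call(rbind, lapply(seq_len(n), function(i)
    cell_row(sprintf("B%02d", i),
             h_seq_align = hs[[i]]$seq, h_germ_align = germ,
             l_seq_align = ls[[i]]$seq, l_germ_align = germ)))
  res <- clone_shm_summary(cells)
  planted <- vapply(hs, `[[`, numeric(1), "k") +
    vapply(ls, `[[`, numeric(1), "k")
  expect_equal(res$per_cell, unname(planted))  # exact per-cell recovery
  se <- sqrt(2 * lambda / n)
  expect_lt(abs(res$mean_shm - 2 * lambda), 3 * se)
})

test_that("jaccard follows |intersection| / |union|", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard(c("a"), c("b")), 0.0)
  expect_equal(jaccard(character(0), character(0)), 0)
  # properties: symmetry and range on random sets
  set.seed(2)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
  }
})

test_that("find_shared_clones recovers planted overlap and public sets", {
  sim <- small_sim()
  cs <- small_clone_set()
  by_sample <- split(cs$clones, cs$clones$group)
  truth <- sim$truth$clones

  ov <- find_shared_clones(by_sample, sim$meta,
                           "organ_overlapping_within_mouse")
  planted_ov <- unique(truth[truth$planted == "organ_overlapping",
                             c("mouse_id", "clone_key")])
  got <- paste(ov$mouse_id, ov$clone_key)
  want <- paste(planted_ov$mouse_id, planted_ov$clone_key)
  expect_setequal(got, want)  # exactly the planted keys, per mouse
  # per-organ sizes agree with truth
  for (i in seq_len(nrow(ov))) {
    tr <- truth[truth$mouse_id == ov$mouse_id[i] &
                  truth$clone_key == ov$clone_key[i], ]
    expect_equal(ov$size_bm[i],
                 tr$size[tr$organ == "bone_marrow"])
    expect_equal(ov$size_sp[i], tr$size[tr$organ == "spleen"])
  }

  pub <- find_shared_clones(by_sample, sim$meta, "public_across_mice")
  planted_pub <- unique(truth$clone_key[truth$planted == "public"])
  expect_setequal(pub$clone_key, planted_pub)
  expect_true(all(pub$n_mice >= 2))
})

test_that("organ-overlapping and public classifications are disjoint
           concepts", {
  meta <- rbind(meta_row("s1", "m01", "bone_marrow"),
                meta_row("s2", "m01", "spleen"),
                meta_row("s3", "m02", "bone_marrow"))
  mk <- function(keys, sizes) data.frame(
    clone_key = keys, size = sizes, isotype = "IgG1",
    stringsAsFactors = FALSE)
  clones <- list(s1 = mk(c("k1", "k2"), c(4L, 2L)),
                 s2 = mk("k1", 3L),
                 s3 = mk("k2", 5L))
  ov <- find_shared_clones(clones, meta,
                           "organ_overlapping_within_mouse")
  expect_equal(ov$clone_key, "k1")
  expect_equal(ov$size_bm, 4L)
  expect_equal(ov$size_sp, 3L)
  pub <- find_shared_clones(clones, meta, "public_across_mice")
  expect_equal(pub$clone_key, "k2")  # BM of m01 and BM of m02: public only
})

test_that("vj_pairing_counts tabulates and aggregates rare genes", {
  clones <- data.frame(
    vh_call = c(rep("IGHV1-26", 3), "IGHV2-2"),
    vl_call = c(rep("IGKV4-53", 3), "IGKV3-2"),
    jh_call = "IGHJ2", jl_call = "IGKJ1", stringsAsFactors = FALSE)
  m <- vj_pairing_counts(clones, label_threshold = 2)
  expect_equal(m["IGHV1-26", "IGKV4-53"], 3L)
  expect_equal(m["other", "other"], 1L)
  expect_equal(sum(m), nrow(clones))  # conservation including "other"
  # 1 clone per combination, threshold 2 -> everything aggregated
  singles <- data.frame(vh_call = paste0("V", 1:4),
                        vl_call = paste0("L", 1:4),
                        jh_call = "J", jl_call = "J",
                        stringsAsFactors = FALSE)
  m2 <- vj_pairing_counts(singles, label_threshold = 2)
  expect_equal(dim(m2), c(1, 1))
  expect_equal(m2["other", "other"], 4L)
})

test_that("vj_pairing_counts equals a brute-force tabulation oracle", {
  set.seed(31)
  clones <- data.frame(
    vh_call = sample(paste0("IGHV", 1:5), 120, replace = TRUE,
                     prob = c(8, 4, 2, 1, 1)),
    vl_call = sample(paste0("IGKV", 1:4), 120, replace = TRUE,
                     prob = c(6, 3, 2, 1)),
    jh_call = "J", jl_call = "J", stringsAsFactors = FALSE)
  thr <- 5
  m <- vj_pairing_counts(clones, label_threshold = thr)
  hg <- clones$vh_call; lg <- clones$vl_call
  hg[hg %in% names(which(table(hg) < thr))] <- "other"
  lg[lg %in% names(which(table(lg) < thr))] <- "other"
  oracle <- table(hg, lg)
  expect_equal(sum(m), 120L)
  for (r in rownames(oracle)) for (cc in colnames(oracle)) {
    got <- if (r %in% rownames(m) && cc %in% colnames(m)) m[r, cc] else 0L
    expect_equal(got, as.integer(oracle[r, cc]), info = paste(r, cc))
  }
})

test_that("cdr3_pfm restricts to the modal length and normalizes columns", {
  p <- cdr3_pfm(c("CAR", "CAR"))
  expect_equal(attr(p, "modal_length"), 3)
  expect_equal(p["C", 1], 1)
  expect_equal(p["A", 2], 1)
  expect_equal(p["R", 3], 1)
  p2 <- cdr3_pfm(c("CAR", "CGR", "CARD"))
  expect_equal(attr(p2, "modal_length"), 3)  # tie 3 vs 4 -> shorter? no tie
  expect_equal(p2["A", 2], 0.5)
  expect_equal(p2["G", 2], 0.5)
  # length tie goes to the shorter length
  p3 <- cdr3_pfm(c("CA", "CA", "CARD", "CARD"))
  expect_equal(attr(p3, "modal_length"), 2)
  expect_true(all(abs(colSums(p2) - 1) < 1e-9))
})

test_that("cdr3_pfm recovers a planted position-frequency matrix", {
  set.seed(13)
  L <- 6; n <- 400
  planted <- matrix(0, 20, L, dimnames = list(clonescreen:::AA20, NULL))
  for (j in seq_len(L)) {
    w <- rexp(20) + 0.5; planted[, j] <- w / sum(w)
  }
  seqs <- replicate(n, paste(
    vapply(seq_len(L), function(j)
      sample(clonescreen:::AA20, 1, prob = planted[, j]), character(1)),
    collapse = ""))
  est <- cdr3_pfm(seqs)
  expect_true(all(abs(colSums(est) - 1) < 1e-9))
  for (j in seq_len(L)) {
    se <- sqrt(planted[, j] * (1 - planted[, j]) / n)
    expect_true(all(abs(est[, j] - planted[, j]) <= 3 * se + 1e-12),
                info = paste("column", j))
  }
})
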