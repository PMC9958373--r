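# Fixture builders and independent oracles shared across test files.

# one unified-schema contig row with overridable fields
contig_row <- function(barcode = "BC1", chain = "IGH", cdr3_aa = "CARDYW",
                       cdr3_nt = "TGTGCTAGAGATTATTGG", v_call = "IGHV1-26",
                       d_call = "", j_call = "IGHJ2", c_call = "IGHG1",
                       vdj_nt = "", sequence_alignment = "",
                       germline_alignment = "", umis = 3L,
                       is_productive = TRUE,
                       contig_id = paste0(barcode, "_", chain)) {
  data.frame(barcode = barcode, contig_id = contig_id, chain = chain,
             cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt, v_call = v_call,
             d_call = d_call, j_call = j_call, c_call = c_call,
             vdj_nt = vdj_nt, sequence_alignment = sequence_alignment,
             germline_alignment = germline_alignment, umis = umis,
             is_productive = is_productive, stringsAsFactors = FALSE)
}

meta_row <- function(sample_id = "s1", mouse_id = "m01",
                     organ = "bone_marrow", cohort = "3m") {
  data.frame(sample_id = sample_id, mouse_id = mouse_id, organ = organ,
             cohort = cohort, stringsAsFactors = FALSE)
}

# one QC-passing cell row as produced by filter_cells()
cell_row <- function(barcode = "BC1", sample_id = "s1", mouse_id = "m01",
                     organ = "bone_marrow", cohort = "3m",
                     cdrh3_aa = "CARDYW", cdrl3_aa = "CQQYNSYPLTF",
                     vh_call = "IGHV1-26", jh_call = "IGHJ2",
                     ch_call = "IGHG1", vl_call = "IGKV4-53",
                     jl_call = "IGKJ1", cl_call = "IGKC",
                     vh_nt = "TGTGCTAGA", vl_nt = "TGTCAACAG",
                     h_seq_align = "", h_germ_align = "",
                     l_seq_align = "", l_germ_align = "",
                     isotype = NULL) {
  data.frame(barcode = barcode, sample_id = sample_id,
             mouse_id = mouse_id, organ = organ, cohort = cohort,
             cdrh3_aa = cdrh3_aa, cdrl3_aa = cdrl3_aa,
             cdrh3_nt = "", cdrl3_nt = "",
             vh_call = vh_call, jh_call = jh_call, ch_call = ch_call,
             vl_call = vl_call, jl_call = jl_call, cl_call = cl_call,
             vh_nt = vh_nt, vl_nt = vl_nt,
             h_seq_align = h_seq_align, h_germ_align = h_germ_align,
             l_seq_align = l_seq_align, l_germ_align = l_germ_align,
             h_umis = 3L, l_umis = 3L,
             isotype = isotype %||% clonescreen::isotype_from_c_call(ch_call),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent dynamic-programming Levenshtein oracle
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# adjusted Rand index (Hubert & Arabie) for cluster-recovery checks
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

random_aa <- function(len) {
  paste(sample(clonescreen:::AA20, len, replace = TRUE), collapse = "")
}

# small simulated dataset reused by several files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_mice = 2, cohorts = c("3m", "18m"),
                        cells_per_sample = 400)
      cache <<- simulate_repertoire(cfg)
    }
    cache
  }
})

small_clone_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cells <- do.call(rbind, lapply(names(sim$samples), function(s)
        filter_cells(sim$samples[[s]],
                     sim$meta[sim$meta$sample_id == s, , drop = FALSE])))
      cache <<- assign_clones(cells, "per_sample")
    }
    cache
  }
})
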