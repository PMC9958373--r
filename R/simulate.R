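# Synthetic paired-chain repertoire, expression, and ELISA generators.
#
# The generator emits cellranger-style contig tables (10x CSV / AIRR TSV
# via write_contigs), MTX count trios, and ELISA CSVs with the statistical
# structure the analysis assumes: truncated power-law clone sizes
# calibrated to a target percent-expanded, within-clone nucleotide
# variants, per-cell SHM against an emitted germline alignment, per-organ
# isotype distributions with within-clone majority coherence, planted
# organ-overlapping and public clones, and per-cohort antigen-specificity
# rates. Every planted quantity is recorded in truth tables.

NT <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults state the emulated world: 3 mice (one per age cohort), two
#' organs, 3200 cells per sample, bone-marrow percent-expanded target 75
#' and spleen 35, IgM-dominated isotype distributions, per-base SHM rate
#' 0.01, within-clone new-variant probability 0.2, antigen-specificity
#' rates of 0.31 (young, 3m) and 0.07 (old, 12m/18m), 5 planted
#' organ-overlapping clones per mouse and 2 public clones, and
#' well-separated ELISA OD distributions over a 0.1 background with a 15%
#' expression-failure rate.
#'
#' @param seed integer RNG seed; the entire simulation is deterministic
#'   given it.
#' @param n_mice number of mice; cohorts are assigned round-robin.
#' @param cohorts cohort labels cycled over mice.
#' @param organs organs sampled per mouse.
#' @param cells_per_sample QC-passing cells per (mouse, organ) repertoire.
#' @param max_clone_size truncation of the clone-size power law.
#' @param target_pct_expanded named per-organ target percent of clones
#'   with size >= 2; the power-law exponent is solved per organ to match.
#' @param isotype_probs named list of per-organ isotype probability
#'   vectors.
#' @param shm_rate per-base founder substitution probability (V and J
#'   regions, both chains).
#' @param variant_rate probability that a cell founds a new nucleotide
#'   variant of its clone.
#' @param pct_specific named per-cohort probability that a clone is
#'   antigen-specific.
#' @param n_overlapping planted organ-overlapping clones per mouse
#'   (requires both organs).
#' @param n_public planted public clones (shared across all mice).
#' @param frac_qc_fail fraction of extra barcodes that fail the
#'   one-heavy-one-light QC rule (split over failure modes).
#' @param isotype_coherence probability a member cell carries its clone's
#'   majority isotype.
#' @param elisa list: `control_od`, `binder_meanlog`, `binder_sdlog`,
#'   `nonbinder_meanlog`, `nonbinder_sdlog`, `p_expression_failure`.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_mice = 3L,
                       cohorts = c("3m", "12m", "18m"),
                       organs = c("bone_marrow", "spleen"),
                       cells_per_sample = 3200L,
                       max_clone_size = 100L,
                       target_pct_expanded = c(bone_marrow = 75,
                                               spleen = 35),
                       isotype_probs = NULL,
                       shm_rate = 0.01,
                       variant_rate = 0.2,
                       pct_specific = c("3m" = 0.31, "12m" = 0.07,
                                        "18m" = 0.07),
                       n_overlapping = 5L,
                       n_public = 2L,
                       frac_qc_fail = 0.08,
                       isotype_coherence = 0.85,
                       elisa = list(control_od = 0.1,
                                    binder_meanlog = log(1.0),
                                    binder_sdlog = 0.25,
                                    nonbinder_meanlog = log(0.12),
                                    nonbinder_sdlog = 0.3,
                                    p_expression_failure = 0.15)) {
  if (is.null(isotype_probs)) {
    isotype_probs <- list(
      bone_marrow = c(IgM = 0.50, IgD = 0.03, IgG1 = 0.10, IgG2B = 0.06,
                      IgG2C = 0.06, IgG3 = 0.04, IgA = 0.16,
                      Unknown = 0.05),
      spleen = c(IgM = 0.40, IgD = 0.05, IgG1 = 0.18, IgG2B = 0.10,
                 IgG2C = 0.10, IgG3 = 0.05, IgA = 0.07, Unknown = 0.05))
  }
  cfg <- list(seed = as.integer(seed), n_mice = as.integer(n_mice),
              cohorts = cohorts, organs = organs,
              cells_per_sample = as.integer(cells_per_sample),
              max_clone_size = as.integer(max_clone_size),
              target_pct_expanded = target_pct_expanded,
              isotype_probs = isotype_probs, shm_rate = shm_rate,
              variant_rate = variant_rate, pct_specific = pct_specific,
              n_overlapping = as.integer(n_overlapping),
              n_public = as.integer(n_public),
              frac_qc_fail = frac_qc_fail,
              isotype_coherence = isotype_coherence, elisa = elisa)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$cells_per_sample > 0, "cells_per_sample must be > 0")
  assert_that(all(cfg$organs %in% ORGAN_LEVELS),
              "organs must be bone_marrow and/or spleen")
  assert_that(all(cfg$cohorts %in% COHORT_LEVELS),
              "cohorts must be among 3m, 12m, 18m")
  for (p in cfg$isotype_probs) {
    assert_that(abs(sum(p) - 1) < 1e-8 && all(p >= 0),
                "isotype_probs must be non-negative and sum to 1")
  }
  assert_that(all(cfg$pct_specific >= 0 & cfg$pct_specific <= 1),
              "pct_specific must lie in [0,1]")
  for (org in cfg$organs) {
    zipf_exponent(cfg$target_pct_expanded[[org]], cfg$max_clone_size)
  }
  invisible(cfg)
}

#' Solve the truncated-Zipf exponent for a target percent expanded
#'
#' Clone sizes follow P(size = k) proportional to k^-a on 1..max_size.
#' Percent expanded equals 100 * (1 - P(size = 1)) = 100 * (1 - 1/H(a))
#' with H(a) the truncated generalized harmonic number, so a is the root
#' of H(a) = 100 / (100 - target).
#'
#' @param target_pct target percent of clones with size >= 2.
#' @param max_size truncation bound.
#' @return the exponent a.
#' @export
zipf_exponent <- function(target_pct, max_size) {
  assert_that(target_pct >= 0 && target_pct < 100,
              "target percent expanded must lie in [0, 100)")
  h <- function(a) sum(seq_len(max_size)^(-a))
  target_h <- 100 / (100 - target_pct)
  if (target_h > h(1e-8)) {
    abort_cs(sprintf(
      "target_pct_expanded %.1f unreachable with max clone size %d",
      target_pct, max_size), "cs_config_error")
  }
  if (target_pct == 0) return(50)  # effectively all singletons
  stats::uniroot(function(a) h(a) - target_h, c(1e-8, 50),
                 tol = 1e-10)$root
}

rzipf <- function(n, exponent, max_size) {
  p <- seq_len(max_size)^(-exponent)
  sample.int(max_size, n, replace = TRUE, prob = p)
}

random_nt <- function(n_len) paste(sample(NT, n_len, replace = TRUE),
                                   collapse = "")

mutate_nt <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), min(n_mut, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(NT, ch[p]), 1)
  paste(ch, collapse = "")
}

# substitute each base independently with probability rate
shm_mutate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(NT, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

random_cdr3 <- function(chain) {
  if (chain == "IGH") {
    len <- sample(9:17, 1, prob = c(2, 5, 10, 18, 22, 18, 12, 8, 5))
    last <- "W"
  } else {
    len <- sample(8:11, 1, prob = c(10, 45, 30, 15))
    last <- "F"
  }
  mid <- paste(sample(AA20, len - 2, replace = TRUE), collapse = "")
  paste0("C", mid, last)
}

# naive reverse translation: one fixed codon per residue for determinism
REV_CODON <- local({
  inv <- tapply(names(CODON_TABLE), CODON_TABLE, function(x) sort(x)[1])
  inv[AA20]
})

reverse_translate <- function(aa) {
  paste(REV_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

GERMLINE_VH <- paste0("IGHV", c("1-26", "1-53", "1-64", "2-2", "3-6",
                                "5-17", "6-3", "9-3", "14-3", "1-82"))
GERMLINE_JH <- paste0("IGHJ", 1:4)
GERMLINE_VK <- paste0("IGKV", c("4-53", "1-117", "3-2", "6-15", "10-96",
                                "12-41", "19-93"))
GERMLINE_JK <- paste0("IGKJ", c(1, 2, 4, 5))
GERMLINE_VL <- paste0("IGLV", 1:2)
GERMLINE_JL <- paste0("IGLJ", 1:2)

ISOTYPE_TO_CGENE <- c(IgM = "IGHM", IgD = "IGHD", IgG1 = "IGHG1",
                      IgG2B = "IGHG2B", IgG2C = "IGHG2C", IgG3 = "IGHG3",
                      IgA = "IGHA", Unknown = "")

# one germline nucleotide sequence per gene name, fixed within a run
make_germline_seqs <- function(genes, len) {
  stats::setNames(vapply(genes, function(g) random_nt(len), character(1)),
                  genes)
}

new_clone_spec <- function(germ, cfg, organ, cohort) {
  light_is_kappa <- stats::runif(1) < 0.95
  vh <- sample(GERMLINE_VH, 1); jh <- sample(GERMLINE_JH, 1)
  if (light_is_kappa) {
    vl <- sample(GERMLINE_VK, 1); jl <- sample(GERMLINE_JK, 1)
    l_chain <- "IGK"; l_cgene <- "IGKC"
  } else {
    vl <- sample(GERMLINE_VL, 1); jl <- sample(GERMLINE_JL, 1)
    l_chain <- "IGL"; l_cgene <- "IGLC1"
  }
  cdrh3 <- random_cdr3("IGH")
  cdrl3 <- random_cdr3("IGK")
  iso <- sample(names(cfg$isotype_probs[[organ]]), 1,
                prob = cfg$isotype_probs[[organ]])
  list(cdrh3_aa = cdrh3, cdrl3_aa = cdrl3,
       cdrh3_nt = reverse_translate(cdrh3),
       cdrl3_nt = reverse_translate(cdrl3),
       vh = vh, jh = jh, vl = vl, jl = jl,
       l_chain = l_chain, l_cgene = l_cgene,
       isotype = iso,
       specific = stats::runif(1) < cfg$pct_specific[[cohort]])
}

#' Simulate a multi-sample paired-chain repertoire
#'
#' Draws, per (mouse, organ) sample, clone sizes from a truncated Zipf law
#' whose exponent is solved to match the organ's target percent-expanded,
#' then emits per-cell heavy and light contigs: founder sequences mutated
#' from a germline at `shm_rate`, within-clone nucleotide variants at
#' `variant_rate`, isotypes drawn per organ with within-clone majority
#' coherence, planted organ-overlapping and public clones, and a fraction
#' of QC-failing barcodes (heavy-only, light-only, doublets, empty CDR3).
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `$samples` (named list of unified-schema contig
#'   data.frames, one per sample), `$meta` (sample metadata), and `$truth`
#'   (list of `clones` and `cells` tables recording every planted
#'   quantity: sizes, variant counts, per-cell SHM, isotypes, specificity,
#'   overlapping/public flags, QC-failure barcodes in `qc_fail`).
#' @export
simulate_repertoire <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  v_germ_h <- make_germline_seqs(GERMLINE_VH, 294)
  j_germ_h <- make_germline_seqs(GERMLINE_JH, 48)
  v_germ_l <- make_germline_seqs(c(GERMLINE_VK, GERMLINE_VL), 285)
  j_germ_l <- make_germline_seqs(c(GERMLINE_JK, GERMLINE_JL), 36)
  germ <- list(vh = v_germ_h, jh = j_germ_h, vl = v_germ_l, jl = j_germ_l)

  mice <- sprintf("m%02d", seq_len(cfg$n_mice))
  cohort_of <- stats::setNames(
    rep(cfg$cohorts, length.out = cfg$n_mice), mice)
  meta <- expand.grid(mouse_id = mice, organ = cfg$organs,
                      stringsAsFactors = FALSE)
  meta$cohort <- cohort_of[meta$mouse_id]
  meta$sample_id <- paste0(meta$mouse_id, "_",
                           ifelse(meta$organ == "bone_marrow", "bm", "sp"))
  meta <- meta[, c("sample_id", "mouse_id", "organ", "cohort")]

  both_organs <- all(c("bone_marrow", "spleen") %in% cfg$organs)
  # planted shared clones: specs created up front so keys coincide
  overlap_specs <- list()
  if (both_organs && cfg$n_overlapping > 0) {
    for (m in mice) {
      overlap_specs[[m]] <- lapply(seq_len(cfg$n_overlapping), function(i)
        new_clone_spec(germ, cfg, "bone_marrow", cohort_of[[m]]))
      # selection rules want expanded IgG organ-overlapping clones
      for (i in seq_along(overlap_specs[[m]])) {
        overlap_specs[[m]][[i]]$isotype <- "IgG1"
      }
    }
  }
  public_specs <- list()
  if (cfg$n_mice >= 2 && cfg$n_public > 0) {
    public_specs <- lapply(seq_len(cfg$n_public), function(i)
      new_clone_spec(germ, cfg, cfg$organs[1], cfg$cohorts[1]))
  }

  samples <- list()
  truth_clones <- list()
  truth_cells <- list()
  qc_fail <- list()
  for (si in seq_len(nrow(meta))) {
    sm <- meta[si, ]
    res <- simulate_sample(sm, cfg, germ, cohort_of,
                           overlap_specs[[sm$mouse_id]], public_specs)
    samples[[sm$sample_id]] <- res$contigs
    truth_clones[[sm$sample_id]] <- res$clones
    truth_cells[[sm$sample_id]] <- res$cells
    qc_fail[[sm$sample_id]] <- res$qc_fail
  }
  truth <- list(clones = do.call(rbind, truth_clones),
                cells = do.call(rbind, truth_cells),
                qc_fail = do.call(rbind, qc_fail))
  rownames(truth$clones) <- rownames(truth$cells) <- NULL
  list(samples = samples, meta = meta, truth = truth)
}

simulate_sample <- function(sm, cfg, germ, cohort_of, overlap_specs,
                            public_specs) {
  organ <- sm$organ; cohort <- sm$cohort
  a <- zipf_exponent(cfg$target_pct_expanded[[organ]], cfg$max_clone_size)
  sizes <- integer(0)
  while (sum(sizes) < cfg$cells_per_sample) {
    sizes <- c(sizes, rzipf(64, a, cfg$max_clone_size))
  }
  # keep clones up to the target; trim the boundary clone so cells sum
  # exactly to cells_per_sample
  cum <- cumsum(sizes)
  last <- which(cum >= cfg$cells_per_sample)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - cfg$cells_per_sample)
  if (sizes[last] == 0L) sizes <- sizes[-last]
  specs <- lapply(sizes, function(s) new_clone_spec(germ, cfg, organ,
                                                    cohort))
  planted_flag <- rep("none", length(specs))
  # planted shared clones replace ordinary expanded clones so the total
  # cell count is preserved
  plant <- function(specs, planted_flag, new_specs, flag) {
    if (!length(new_specs)) return(list(specs, planted_flag))
    candidates <- which(sizes >= 2 & planted_flag == "none")
    stopifnot(length(candidates) >= length(new_specs))
    slots <- candidates[seq_along(new_specs)]
    for (i in seq_along(new_specs)) {
      specs[[slots[i]]] <- new_specs[[i]]
      planted_flag[slots[i]] <- flag
    }
    list(specs, planted_flag)
  }
  if (!is.null(overlap_specs)) {
    tmp <- plant(specs, planted_flag, overlap_specs, "organ_overlapping")
    specs <- tmp[[1]]; planted_flag <- tmp[[2]]
  }
  # public clones live in the first organ only, so they are public but
  # not organ-overlapping
  if (length(public_specs) && organ == cfg$organs[1]) {
    tmp <- plant(specs, planted_flag, public_specs, "public")
    specs <- tmp[[1]]; planted_flag <- tmp[[2]]
  }

  contig_rows <- vector("list", length(specs))
  clone_rows <- vector("list", length(specs))
  cell_rows <- vector("list", length(specs))
  cell_counter <- 0L
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    n <- sizes[ci]
    emit <- emit_clone_cells(sp, n, sm, cfg, germ, cell_counter)
    cell_counter <- cell_counter + n
    contig_rows[[ci]] <- emit$contigs
    cell_rows[[ci]] <- emit$cells
    clone_rows[[ci]] <- data.frame(
      sample_id = sm$sample_id, mouse_id = sm$mouse_id, organ = organ,
      cohort = cohort, cdrh3_aa = sp$cdrh3_aa, cdrl3_aa = sp$cdrl3_aa,
      clone_key = clone_key_of(sp$cdrh3_aa, sp$cdrl3_aa),
      size = n, expanded = n >= 2, isotype = sp$isotype,
      vh_call = sp$vh, vl_call = sp$vl, jh_call = sp$jh, jl_call = sp$jl,
      n_variants_nt = emit$n_variants,
      mean_shm = mean(emit$cells$shm_total),
      specific = sp$specific, planted = planted_flag[ci],
      stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, contig_rows)
  qc <- emit_qc_failures(sm, cfg, germ, cell_counter)
  contigs <- rbind(contigs, qc$contigs)
  rownames(contigs) <- NULL
  list(contigs = contigs, clones = do.call(rbind, clone_rows),
       cells = do.call(rbind, cell_rows), qc_fail = qc$truth)
}

emit_clone_cells <- function(sp, n, sm, cfg, germ, cell_offset) {
  vh_g <- germ$vh[[sp$vh]]; jh_g <- germ$jh[[sp$jh]]
  vl_g <- germ$vl[[sp$vl]]; jl_g <- germ$jl[[sp$jl]]
  # clone founder: germline V and J mutated at the per-base SHM rate
  founder <- list(
    vh = shm_mutate(vh_g, cfg$shm_rate), jh = shm_mutate(jh_g, cfg$shm_rate),
    vl = shm_mutate(vl_g, cfg$shm_rate), jl = shm_mutate(jl_g, cfg$shm_rate))
  variants <- list(founder)
  v_of_cell <- integer(n)
  v_of_cell[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      if (stats::runif(1) < cfg$variant_rate) {
        mut <- founder
        mut$vh <- mutate_nt(mut$vh, sample(1:2, 1))
        variants[[length(variants) + 1L]] <- mut
        v_of_cell[i] <- length(variants)
      } else {
        v_of_cell[i] <- sample.int(length(variants), 1)
      }
    }
  }
  iso_pool <- cfg$isotype_probs[[sm$organ]]
  coherent <- stats::runif(n) < cfg$isotype_coherence
  iso <- ifelse(coherent, sp$isotype,
                sample(names(iso_pool), n, replace = TRUE,
                       prob = iso_pool))
  barcodes <- sprintf("%s:cell%05d-1", sm$sample_id,
                      cell_offset + seq_len(n))
  vh_seq <- vapply(v_of_cell, function(v)
    paste0(variants[[v]]$vh, sp$cdrh3_nt, variants[[v]]$jh), character(1))
  vl_seq <- vapply(v_of_cell, function(v)
    paste0(variants[[v]]$vl, sp$cdrl3_nt, variants[[v]]$jl), character(1))
  h_germ <- paste0(vh_g, sp$cdrh3_nt, jh_g)
  l_germ <- paste0(vl_g, sp$cdrl3_nt, jl_g)
  shm_h <- vapply(vh_seq, function(s) hamming_nt(s, h_germ), integer(1))
  shm_l <- vapply(vl_seq, function(s) hamming_nt(s, l_germ), integer(1))
  heavy <- data.frame(
    barcode = barcodes,
    contig_id = paste0(barcodes, "_contig_1"),
    chain = "IGH", cdr3_aa = sp$cdrh3_aa, cdr3_nt = sp$cdrh3_nt,
    v_call = sp$vh, d_call = "IGHD1-1", j_call = sp$jh,
    c_call = unname(ISOTYPE_TO_CGENE[iso]),
    vdj_nt = vh_seq, sequence_alignment = vh_seq,
    germline_alignment = h_germ,
    umis = stats::rpois(n, 3) + 1L, is_productive = TRUE,
    stringsAsFactors = FALSE)
  light <- data.frame(
    barcode = barcodes,
    contig_id = paste0(barcodes, "_contig_2"),
    chain = sp$l_chain, cdr3_aa = sp$cdrl3_aa, cdr3_nt = sp$cdrl3_nt,
    v_call = sp$vl, d_call = "", j_call = sp$jl, c_call = sp$l_cgene,
    vdj_nt = vl_seq, sequence_alignment = vl_seq,
    germline_alignment = l_germ,
    umis = stats::rpois(n, 3) + 1L, is_productive = TRUE,
    stringsAsFactors = FALSE)
  cells <- data.frame(
    barcode = barcodes, sample_id = sm$sample_id,
    clone_key = clone_key_of(sp$cdrh3_aa, sp$cdrl3_aa),
    variant = v_of_cell, isotype = unname(iso),
    shm_total = unname(shm_h + shm_l), specific = sp$specific,
    stringsAsFactors = FALSE)
  list(contigs = rbind(heavy, light), cells = cells,
       # sequence-level count: independently mutated variants can collide
       n_variants = length(unique(paste(vh_seq, vl_seq))))
}

hamming_nt <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# extra barcodes violating the one-heavy-one-light rule, for QC testing
emit_qc_failures <- function(sm, cfg, germ, cell_offset) {
  n_fail <- round(cfg$frac_qc_fail * cfg$cells_per_sample)
  modes <- c("heavy_only", "light_only", "double_heavy", "double_light",
             "empty_cdr3", "nonproductive_heavy")
  if (n_fail == 0) {
    return(list(contigs = NULL,
                truth = data.frame(sample_id = character(),
                                   barcode = character(),
                                   mode = character(),
                                   stringsAsFactors = FALSE)))
  }
  mode_of <- sample(modes, n_fail, replace = TRUE)
  rows <- vector("list", n_fail)
  for (i in seq_len(n_fail)) {
    bc <- sprintf("%s:fail%05d-1", sm$sample_id, cell_offset + i)
    sp <- new_clone_spec(germ, cfg, sm$organ, sm$cohort)
    h <- contig_stub(bc, "IGH", sp$cdrh3_aa, sp$cdrh3_nt, sp$vh, sp$jh,
                     unname(ISOTYPE_TO_CGENE[sp$isotype]))
    l <- contig_stub(bc, sp$l_chain, sp$cdrl3_aa, sp$cdrl3_nt, sp$vl,
                     sp$jl, sp$l_cgene)
    rows[[i]] <- switch(mode_of[i],
      heavy_only = h,
      light_only = l,
      double_heavy = rbind(h, h2 <- transform(h,
        contig_id = paste0(bc, "_contig_x")), l),
      double_light = rbind(h, l, transform(l,
        contig_id = paste0(bc, "_contig_x"))),
      empty_cdr3 = rbind(transform(h, cdr3_aa = "", cdr3_nt = ""), l),
      nonproductive_heavy = rbind(transform(h, is_productive = FALSE), l))
  }
  contigs <- do.call(rbind, rows)
  list(contigs = contigs,
       truth = data.frame(sample_id = sm$sample_id,
                          barcode = sprintf("%s:fail%05d-1", sm$sample_id,
                                            cell_offset + seq_len(n_fail)),
                          mode = mode_of, stringsAsFactors = FALSE))
}

contig_stub <- function(bc, chain, cdr3_aa, cdr3_nt, v, j, cgene) {
  data.frame(barcode = bc, contig_id = paste0(bc, "_contig_", chain),
             chain = chain, cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt,
             v_call = v, d_call = "", j_call = j, c_call = cgene,
             vdj_nt = "", sequence_alignment = "",
             germline_alignment = "", umis = 2L, is_productive = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate a count matrix with planted structure
#'
#' Negative-binomial counts with planted cluster markers, planted
#' mitochondrial fractions (realized to within rounding by setting the
#' mitochondrial total from the drawn non-mito total), planted Ig genes
#' for removal testing, and optional planted differential expression
#' between a marked cell subset (e.g. binders) and the rest.
#'
#' @param barcodes cell barcodes.
#' @param cluster_of integer cluster label per cell (default: all 1).
#' @param n_genes number of non-mito, non-Ig background genes.
#' @param markers_per_cluster planted marker genes per cluster.
#' @param marker_fold fold change of planted markers (default 4).
#' @param mito_fracs per-cell planted mitochondrial fraction (default
#'   `rbeta(n, 8, 92)`, mean 0.08).
#' @param de_mask logical per-cell mask for planted DE (e.g. binder cells);
#'   `NULL` for none.
#' @param n_de planted DE genes between `de_mask` groups.
#' @param de_fold fold change of planted DE genes.
#' @param seed RNG seed.
#' @return list `$counts` (cells x genes dgCMatrix) and `$truth`
#'   (cluster labels, planted mito fractions, marker/DE/Ig/mito gene
#'   names).
#' @export
simulate_expression <- function(barcodes, cluster_of = NULL,
                                n_genes = 200, markers_per_cluster = 25,
                                marker_fold = 4, mito_fracs = NULL,
                                de_mask = NULL, n_de = 10, de_fold = 2,
                                seed = 1L) {
  set.seed(seed)
  n <- length(barcodes)
  if (is.null(cluster_of)) cluster_of <- rep(1L, n)
  if (is.null(mito_fracs)) mito_fracs <- stats::rbeta(n, 8, 92)
  stopifnot(length(cluster_of) == n, length(mito_fracs) == n)
  k <- length(unique(cluster_of))
  ig_genes <- c("Ighv1-26", "Ighv5-17", "Ighg1", "Ighm", "Igha",
                "Igkv4-53", "Igkc", "Iglv1", "Iglc1", "Jchain")
  mito_genes <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Cytb"))
  bg_genes <- sprintf("Gene%04d", seq_len(n_genes))
  genes <- c(bg_genes, ig_genes, mito_genes)

  mu_bg <- stats::rlnorm(n_genes + length(ig_genes), log(2), 1)
  mu <- matrix(rep(mu_bg, each = n), nrow = n)
  marker_genes <- character(0)
  if (k > 1) {
    for (c_i in seq_len(k)) {
      gidx <- ((c_i - 1) * markers_per_cluster + 1):(c_i *
                                                     markers_per_cluster)
      stopifnot(max(gidx) <= n_genes)
      mu[cluster_of == c_i, gidx] <- mu[cluster_of == c_i, gidx] *
        marker_fold
      marker_genes <- c(marker_genes, bg_genes[gidx])
    }
  }
  de_genes <- character(0)
  if (!is.null(de_mask) && n_de > 0) {
    stopifnot(length(de_mask) == n)
    # plant DE on well-expressed non-marker genes so the planted effect
    # is detectable by design rather than drowned in sampling zeros
    n_marker <- if (k > 1) k * markers_per_cluster else 0
    free <- setdiff(seq_len(n_genes), seq_len(n_marker))
    gidx <- free[order(mu_bg[free], decreasing = TRUE)][seq_len(n_de)]
    mu[de_mask, gidx] <- mu[de_mask, gidx] * de_fold
    de_genes <- bg_genes[gidx]
  }
  counts_main <- matrix(stats::rnbinom(n * ncol(mu), mu = as.vector(mu),
                                       size = 10), nrow = n)
  # mito totals set from the realized non-mito totals so the planted
  # fraction is honored to within rounding
  nonmito_tot <- rowSums(counts_main)
  mito_tot <- round(mito_fracs / (1 - mito_fracs) * nonmito_tot)
  counts_mito <- t(vapply(mito_tot, function(m)
    as.integer(stats::rmultinom(1, m, rep(1 / 5, 5))), integer(5)))
  counts <- cbind(counts_main, counts_mito)
  dimnames(counts) <- list(barcodes, genes)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  realized_mito <- rowSums(counts_mito) / (rowSums(counts_mito) +
                                           nonmito_tot)
  list(counts = counts,
       truth = list(cluster = stats::setNames(cluster_of, barcodes),
                    mito_fracs = stats::setNames(mito_fracs, barcodes),
                    realized_mito = stats::setNames(realized_mito,
                                                    barcodes),
                    marker_genes = marker_genes, de_genes = de_genes,
                    ig_genes = ig_genes, mito_genes = mito_genes))
}

#' Simulate an ELISA screen for a clone selection
#'
#' OD450 values are drawn from lognormal binder / non-binder distributions
#' according to each clone's planted specificity; expression fails
#' independently at the configured rate.
#'
#' @param selection data.frame with a `clone_key` column (e.g. from
#'   [select_for_expression()]); duplicate keys are screened once.
#' @param truth_clones truth clone table from [simulate_repertoire()]
#'   (carries `clone_key` and planted `specific`).
#' @param cfg a [sim_config()] (its `$elisa` block is used).
#' @param seed RNG seed.
#' @return data.frame `clone_key, od450, expressed,
#'   negative_control_od, true_specific`.
#' @export
simulate_screen <- function(selection, truth_clones, cfg = sim_config(),
                            seed = 1L) {
  assert_that(nrow(selection) >= 1, "selection must be non-empty")
  set.seed(seed)
  keys <- unique(selection$clone_key)
  spec <- truth_clones$specific[match(keys, truth_clones$clone_key)]
  spec[is.na(spec)] <- FALSE
  e <- cfg$elisa
  expressed <- stats::runif(length(keys)) >= e$p_expression_failure
  od <- ifelse(spec,
               stats::rlnorm(length(keys), e$binder_meanlog,
                             e$binder_sdlog),
               stats::rlnorm(length(keys), e$nonbinder_meanlog,
                             e$nonbinder_sdlog))
  od[!expressed] <- 0
  data.frame(clone_key = keys, od450 = od, expressed = expressed,
             negative_control_od = e$control_od, true_specific = spec,
             stringsAsFactors = FALSE)
}
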