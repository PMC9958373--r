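# End-to-end orchestration and the command-line entry point.

#' Default pipeline configuration
#'
#' Every stage parameter defaults to the documented analysis value:
#' mitochondrial cutoff 0.20, normalization scale 10000, 2000 variable
#' genes, 15 principal components, cluster resolution 0.5, DE min.pct 0.25
#' with Bonferroni-adjusted p < 0.01, network edit-distance threshold 5,
#' ELISA fold-over-background 3, selection top_n 10 per group.
#'
#' @param seed integer seed driving simulation and clustering.
#' @param outdir output directory.
#' @param ... overrides for any config entry.
#' @return named list.
#' @export
default_config <- function(seed = 1L, outdir = "clonescreen_out", ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    dialect = "tenx_csv",
    sim = sim_config(seed = seed),
    scope = "per_sample",
    network_threshold = 5, network_mode = "sum",
    label_threshold = 2,
    top_n = 10, include_overlapping = TRUE, include_public = TRUE,
    fold = 3.0,
    mito_max = 0.20, n_hvg = 2000, n_pcs = 15, resolution = 0.5,
    min_pct = 0.25, alpha_adj = 0.01,
    gex_cells_per_sample = 150)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate, ingest, clonotype, stats, network, select,
#' screen, and gex stages, writing every result as TSV under
#' `config$outdir` together with a plain-text run log and a config echo.
#' Stages can be skipped; later stages reuse in-memory results of earlier
#' ones. Deterministic given `config$seed`.
#'
#' @param config list from [default_config()].
#' @param stages character vector of stages to run.
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "clonotype", "stats",
                                    "network", "select", "screen",
                                    "gex")) {
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  cat(sprintf("clonescreen run, seed %d, %s\n", config$seed,
              format(Sys.time())), file = logf)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  echo <- config
  echo$sim <- unclass(echo$sim)
  writeLines(utils::capture.output(utils::str(echo, max.level = 2)),
             file.path(out, "config_echo.txt"))
  res <- list(config = config)
  tic <- function() Sys.time()
  stage_done <- function(name, t0)
    log_line("stage %-9s done in %.2fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if ("simulate" %in% stages) {
    t0 <- tic()
    sim <- simulate_repertoire(config$sim)
    indir <- file.path(out, "inputs")
    dir.create(indir, showWarnings = FALSE)
    for (s in names(sim$samples)) {
      write_contigs(sim$samples[[s]],
                    file.path(indir, paste0(s, "_contigs.csv")),
                    dialect = "tenx_csv")
    }
    utils::write.csv(sim$meta, file.path(indir, "sample_meta.csv"),
                     row.names = FALSE)
    write_tsv(sim$truth$clones, file.path(out, "truth_clones.tsv"))
    res$sim <- sim
    stage_done("simulate", t0)
  }

  if ("clonotype" %in% stages) {
    t0 <- tic()
    sim <- res$sim %||% abort_cs("clonotype stage needs simulate output",
                                 "cs_pipeline_error")
    cells_by_sample <- lapply(names(sim$samples), function(s) {
      filter_cells(sim$samples[[s]],
                   sim$meta[sim$meta$sample_id == s, , drop = FALSE])
    })
    cells <- do.call(rbind, cells_by_sample)
    cs <- assign_clones(cells, scope = config$scope)
    write_tsv(cs$clones, file.path(out, "clones.tsv"))
    write_tsv(cs$cells[, c("barcode", "sample_id", "clone_id")],
              file.path(out, "cells.tsv"))
    prof <- do.call(rbind, lapply(split(cs$clones, cs$clones$group),
      function(cl) {
        p <- expansion_profile(cl)
        p$group <- cl$group[1]
        p$percent_expanded <- attr(p, "percent_expanded")
        p
      }))
    write_tsv(prof, file.path(out, "expansion_profile.tsv"))
    res$clones <- cs
    stage_done("clonotype", t0)
  }

  if ("stats" %in% stages) {
    t0 <- tic()
    cs <- res$clones
    by_sample <- split(cs$clones, cs$clones$group)
    write_tsv(repertoire_overlap(cs$clones),
              file.path(out, "overlap.tsv"))
    write_tsv(shm_by_clone(cs), file.path(out, "shm_by_clone.tsv"))
    ov <- find_shared_clones(by_sample, res$sim$meta,
                             "organ_overlapping_within_mouse")
    write_tsv(ov, file.path(out, "organ_overlapping.tsv"))
    pub <- find_shared_clones(by_sample, res$sim$meta,
                              "public_across_mice")
    write_tsv(pub, file.path(out, "public_clones.tsv"))
    vj <- vj_pairing_counts(cs$clones, config$label_threshold)
    write_tsv(data.frame(heavy = rownames(vj)[row(vj)],
                         light = colnames(vj)[col(vj)],
                         n_clones = as.vector(vj)),
              file.path(out, "vj_matrix.tsv"))
    pfm <- cdr3_pfm(cs$clones$cdrh3_aa)
    write_tsv(data.frame(aa = rownames(pfm), pfm, check.names = FALSE),
              file.path(out, "pfm_cdrh3.tsv"))
    res$shared <- list(overlapping = ov, public = pub)
    stage_done("stats", t0)
  }

  if ("network" %in% stages) {
    t0 <- tic()
    cs <- res$clones
    # expanded clones only keeps the all-pairs computation modest
    nodes <- cs$clones[cs$clones$expanded, , drop = FALSE]
    net <- build_network(nodes, threshold = config$network_threshold,
                         mode = config$network_mode)
    write_network(net, out)
    res$network <- net
    stage_done("network", t0)
  }

  if ("select" %in% stages) {
    t0 <- tic()
    sel <- select_for_expression(res$clones, res$sim$meta,
                                 top_n = config$top_n,
                                 include_overlapping =
                                   config$include_overlapping,
                                 include_public = config$include_public)
    write_selection(sel, out)
    res$selection <- sel
    stage_done("select", t0)
  }

  if ("screen" %in% stages) {
    t0 <- tic()
    if (nrow(res$selection) == 0) {
      log_line("stage screen skipped: empty selection")
    } else {
      plate <- simulate_screen(res$selection, res$sim$truth$clones,
                               config$sim, seed = config$seed)
      calls <- call_binders(plate, plate$negative_control_od[1],
                            fold = config$fold)
      # young = 3m, old = 12m/18m, following the screening cohorts
      key_meta <- res$sim$truth$clones[
        match(calls$clone_key, res$sim$truth$clones$clone_key), ]
      calls$cohort <- ifelse(key_meta$cohort == "3m", "young", "old")
      calls$organ <- key_meta$organ
      write_tsv(calls, file.path(out, "screen_calls.tsv"))
      summ <- specificity_summary(calls, c("cohort", "organ"))
      write_tsv(summ, file.path(out, "specificity_summary.tsv"))
      res$screen <- list(calls = calls, summary = summ)
    }
    stage_done("screen", t0)
  }

  if ("gex" %in% stages) {
    t0 <- tic()
    cs <- res$clones
    n_gex <- min(config$gex_cells_per_sample * length(res$sim$samples),
                 nrow(cs$cells))
    set.seed(config$seed)
    take <- sort(sample.int(nrow(cs$cells), n_gex))
    bc <- cs$cells$barcode[take]
    cluster_planted <- 1L + (seq_along(bc) %% 2L)
    gex <- simulate_expression(bc, cluster_of = cluster_planted,
                               seed = config$seed)
    write_counts(gex$counts, file.path(out, "gex"))
    m <- read_counts(file.path(out, "gex", "matrix.mtx"),
                     file.path(out, "gex", "barcodes.tsv"),
                     file.path(out, "gex", "features.tsv"))
    m <- qc_filter(m, mito_max = config$mito_max)
    m <- drop_bcr_genes(m)
    mn <- normalize_log(m)
    labels <- cluster_cells(mn, n_hvg = config$n_hvg,
                            n_pcs = min(config$n_pcs, nrow(mn) - 1),
                            resolution = config$resolution,
                            seed = config$seed)
    write_tsv(data.frame(barcode = names(labels), cluster = labels),
              file.path(out, "clusters.tsv"))
    if (length(unique(labels)) >= 2) {
      de <- differential_expression(mn, labels == 0, labels != 0,
                                    min_pct = config$min_pct,
                                    alpha_adj = config$alpha_adj)
      write_tsv(de, file.path(out, "de_cluster0_vs_rest.tsv"))
      res$de <- de
    }
    res$gex <- list(matrix = mn, labels = labels, truth = gex$truth)
    stage_done("gex", t0)
  }

  invisible(res)
}

#' Command-line entry point
#'
#' Usage: `clonescreen <stage> [--seed N] [--outdir DIR] [--threshold N]
#' [--top-n N] [--fold X] [--resolution X] [--dialect D]` where stage is
#' one of `simulate, clonotype, stats, network, select, screen, gex, all`.
#' Stages are cumulative: asking for a later stage runs the earlier ones
#' it depends on.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stage_order <- c("simulate", "clonotype", "stats", "network", "select",
                   "screen", "gex")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: clonescreen <stage> [options]\n",
        "stages: ", paste(c(stage_order, "all"), collapse = ", "), "\n",
        "options: --seed N --outdir DIR --threshold N --top-n N",
        " --fold X --resolution X --dialect tenx_csv|airr_tsv\n",
        sep = "")
    return(invisible(0L))
  }
  stage <- args[1]
  if (!stage %in% c(stage_order, "all")) {
    message("unknown stage: ", stage)
    return(invisible(2L))
  }
  status <- tryCatch({
    opt <- parse_cli_options(args[-1])
    config <- default_config(seed = opt$seed, outdir = opt$outdir,
                             network_threshold = opt$threshold,
                             top_n = opt$top_n, fold = opt$fold,
                             resolution = opt$resolution,
                             dialect = opt$dialect)
    stages <- if (stage == "all") stage_order else
      stage_order[seq_len(match(stage, stage_order))]
    run_pipeline(config, stages = stages)
    0L
  }, error = function(e) {
    message("clonescreen error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opt <- list(seed = 1L, outdir = "clonescreen_out", threshold = 5,
              top_n = 10, fold = 3.0, resolution = 0.5,
              dialect = "tenx_csv")
  flag_map <- c("--seed" = "seed", "--outdir" = "outdir",
                "--threshold" = "threshold", "--top-n" = "top_n",
                "--fold" = "fold", "--resolution" = "resolution",
                "--dialect" = "dialect")
  i <- 1
  while (i <= length(args)) {
    f <- args[i]
    if (!f %in% names(flag_map)) {
      abort_cs(paste0("unknown option: ", f), "cs_cli_error")
    }
    assert_that(i + 1 <= length(args), paste0("missing value for ", f),
                "cs_cli_error")
    val <- args[i + 1]
    key <- flag_map[[f]]
    opt[[key]] <- if (key %in% c("seed", "top_n", "threshold"))
      as.integer(val)
    else if (key %in% c("fold", "resolution")) as.numeric(val)
    else val
    i <- i + 2
  }
  opt
}
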