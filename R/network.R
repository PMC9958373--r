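# Clone similarity networks from per-chain CDR3 edit distances.

#' Levenshtein distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion each
#' cost 1), vectorized over all pairs of `a` and `b`.
#'
#' @param a,b character vectors.
#' @return integer matrix of distances (`length(a)` x `length(b)`), or a
#'   single integer when both are scalars.
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1 && length(b) == 1) return(as.integer(d[1, 1]))
  storage.mode(d) <- "integer"
  d
}

#' Build a clone similarity network
#'
#' Nodes are clones; edit distances are computed separately for the heavy
#' and light CDR3s of every clone pair, then combined by the edge rule:
#' `mode = "sum"` draws an edge when the HC + LC distance is at most
#' `threshold` (one combined edit distance, the default reading of
#' "edit distance of 5 amino acids or less"); `mode = "both_chains"` draws
#' an edge when each chain's distance is individually at most `threshold`.
#' Both readings are exposed because the underlying method description is
#' ambiguous; the comparison is inclusive (<=).
#'
#' @param clones clone table (rows of `assign_clones()$clones`); every clone
#'   must have non-empty CDRH3 and CDRL3. Extra columns (isotype, organ,
#'   specificity labels) are carried onto the nodes.
#' @param threshold non-negative integer distance threshold.
#' @param mode edge rule, `"sum"` or `"both_chains"`.
#' @return object of class `clone_network`: list with `$nodes` (clone table
#'   plus `component` label), `$edges` (`from, to, hc_distance,
#'   lc_distance`), `$graph` (igraph object), `$threshold`, `$mode`.
#' @export
build_network <- function(clones, threshold = 5,
                          mode = c("sum", "both_chains")) {
  mode <- match.arg(mode)
  assert_that(threshold >= 0, "threshold must be non-negative")
  assert_that(all(nzchar(clones$cdrh3_aa)) && all(nzchar(clones$cdrl3_aa)),
              "every clone needs non-empty CDRH3 and CDRL3")
  n <- nrow(clones)
  ids <- if (!is.null(clones$clone_id)) clones$clone_id else
    paste0("c", seq_len(n))
  if (n >= 2) {
    dh <- utils::adist(clones$cdrh3_aa)
    dl <- utils::adist(clones$cdrl3_aa)
    pass <- if (mode == "sum") (dh + dl) <= threshold
            else dh <= threshold & dl <= threshold
    pass[lower.tri(pass, diag = TRUE)] <- FALSE
    idx <- which(pass, arr.ind = TRUE)
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        hc_distance = dh[idx], lc_distance = dl[idx],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        hc_distance = integer(), lc_distance = integer(),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  nodes <- clones
  nodes$clone_id <- ids
  nodes$component <- unname(comp[ids])
  out <- list(nodes = nodes, edges = edges, graph = g,
              threshold = threshold, mode = mode)
  class(out) <- "clone_network"
  out
}

#' @export
print.clone_network <- function(x, ...) {
  cat(sprintf(
    "clone_network: %d nodes, %d edges (threshold %s, mode %s), %d components\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, x$mode,
    length(unique(x$nodes$component))))
  invisible(x)
}

#' Annotate germline convergence in a similarity network
#'
#' Assigns every node a convergence-group id, the tuple (VH gene, VL gene,
#' CDRH3 length, CDRL3 length), and flags connected components that contain
#' two or more specificity-positive nodes drawn from different convergence
#' groups — candidate convergent motifs, where clones reach similar CDR3s
#' through different germline genes.
#'
#' @param network `clone_network` from [build_network()].
#' @param specific_col name of a logical node column marking
#'   antigen-specific clones (default `"specific"`; if absent, no component
#'   is flagged but group ids are still returned).
#' @return data.frame of nodes with `convergence_group` and
#'   `flagged_component` (logical).
#' @export
annotate_convergence <- function(network, specific_col = "specific") {
  nodes <- network$nodes
  nodes$convergence_group <- paste(
    nodes$vh_call, nodes$vl_call,
    nchar(nodes$cdrh3_aa), nchar(nodes$cdrl3_aa), sep = "|")
  flagged <- rep(FALSE, nrow(nodes))
  if (specific_col %in% names(nodes)) {
    spec <- isTRUE_vec(nodes[[specific_col]])
    for (comp in unique(nodes$component)) {
      in_comp <- nodes$component == comp
      pos <- in_comp & spec
      if (sum(pos) >= 2 &&
          length(unique(nodes$convergence_group[pos])) >= 2) {
        flagged[in_comp] <- TRUE
      }
    }
  }
  nodes$flagged_component <- flagged
  nodes
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Export network tables
#'
#' Writes the node attribute table and edge list as TSV, and optionally a
#' GraphML file for external viewers.
#'
#' @param network `clone_network`.
#' @param dir output directory.
#' @param graphml also write `network.graphml`.
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir, graphml = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(network$nodes, file.path(dir, "network_nodes.tsv"))
  write_tsv(network$edges, file.path(dir, "network_edges.tsv"))
  if (graphml) {
    igraph::write_graph(network$graph, file.path(dir, "network.graphml"),
                        format = "graphml")
  }
  invisible(dir)
}
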