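# Functionally related miRNA network construction.
#
# Two miRNAs are linked when the overlap of their predicted target-gene
# sets is larger than expected by chance: a one-sided Fisher exact test
# (the hypergeometric upper tail) across all miRNA pairs, corrected with
# Benjamini-Hochberg, keeping either adjusted p < alpha or the k smallest
# raw p-values.

#' One-sided Fisher exact p-value for target-set overlap
#'
#' Probability of observing an overlap at least as large as
#' `length(intersect(targets_a, targets_b))` when `|targets_a|` genes are
#' drawn without replacement from a universe of `universe_size` genes of
#' which `|targets_b|` are "successes" -- the enrichment-sided Fisher exact
#' test on the 2x2 overlap table.
#'
#' @param targets_a,targets_b character vectors of gene IDs.
#' @param universe_size total number of genes in the testing universe.
#' @return p-value in (0, 1].
#' @export
overlap_pvalue <- function(targets_a, targets_b, universe_size) {
  a <- unique(as.character(targets_a))
  b <- unique(as.character(targets_b))
  if (length(a) > universe_size || length(b) > universe_size) {
    stop("universe smaller than a target set", call. = FALSE)
  }
  ov <- length(intersect(a, b))
  stats::phyper(ov - 1L, length(a), universe_size - length(a), length(b),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#' Adjusted values satisfy `adj >= raw` and `adj <= 1`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Construct a miRNA network from an edge list
#'
#' Low-level constructor used by [build_network()] and by the edge-list
#' reader. Nodes are exactly the miRNAs incident to at least one edge.
#'
#' @param edges data frame with columns `mirna_a`, `mirna_b`, `raw_p`,
#'   `adj_p`; one row per unordered pair, no self-loops.
#' @return an object of class `mirna_network` with elements `nodes`
#'   (sorted character vector), `edges` (data frame, `mirna_a < mirna_b`)
#'   and `adjacency` (named list of neighbor vectors).
#' @export
mirna_network <- function(edges) {
  edges <- as.data.frame(edges)
  need <- c("mirna_a", "mirna_b", "raw_p", "adj_p")
  if (!all(need %in% names(edges))) {
    stop("edge list needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  a <- canon_mirna(edges$mirna_a)
  b <- canon_mirna(edges$mirna_b)
  if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$adj_p < edges$raw_p - 1e-12)) {
    stop("adjusted p smaller than raw p", call. = FALSE)
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- data.frame(mirna_a = lo, mirna_b = hi,
                      raw_p = edges$raw_p, adj_p = edges$adj_p)
  edges <- edges[!duplicated(edges[c("mirna_a", "mirna_b")]), , drop = FALSE]
  edges <- edges[order(edges$mirna_a, edges$mirna_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$mirna_a, edges$mirna_b)))
  adjacency <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(c(edges$mirna_b[edges$mirna_a == v], edges$mirna_a[edges$mirna_b == v]))
  })
  structure(list(nodes = nodes, edges = edges, adjacency = adjacency),
            class = "mirna_network")
}

#' Build the functionally related miRNA network from a target catalog
#'
#' Every unordered pair of catalog miRNAs is tested with
#' [overlap_pvalue()]; the whole family of tested pairs (including
#' zero-overlap pairs, whose p is 1) is BH-corrected. In `threshold` mode
#' an edge is kept when the adjusted p-value is strictly below `alpha`; in
#' `top_k` mode the `k` pairs with the smallest raw p-values are kept (ties
#' at the boundary broken by lexicographic pair order). Zero-overlap pairs
#' never become edges.
#'
#' @param catalog a [target_catalog].
#' @param mode `"threshold"` (default) or `"top_k"`.
#' @param alpha significance level on the adjusted p-value (default 0.001).
#' @param k number of edges to keep in `top_k` mode.
#' @param universe_size gene universe for the overlap test; defaults to the
#'   size of the catalog universe (union of all retained targets).
#' @return a [mirna_network].
#' @export
build_network <- function(catalog, mode = c("threshold", "top_k"),
                          alpha = 0.001, k = 15000L, universe_size = NULL) {
  stopifnot(inherits(catalog, "target_catalog"))
  mode <- match.arg(mode)
  mirnas <- names(catalog$targets)
  if (length(mirnas) < 2L) stop("catalog has fewer than 2 miRNAs", call. = FALSE)
  U <- if (is.null(universe_size)) length(catalog$universe) else universe_size
  sizes <- lengths(catalog$targets)
  if (any(sizes > U)) stop("universe smaller than a target set", call. = FALSE)

  # overlap counts for all pairs via the bipartite incidence matrix
  inc <- matrix(0L, length(mirnas), length(catalog$universe),
                dimnames = list(mirnas, catalog$universe))
  inc[cbind(rep(seq_along(mirnas), sizes),
            match(unlist(catalog$targets, use.names = FALSE),
                  catalog$universe))] <- 1L
  ov <- tcrossprod(inc)

  idx <- which(upper.tri(ov), arr.ind = TRUE)
  # order pairs lexicographically by (mirna_a, mirna_b); mirnas are sorted
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  o <- ov[idx]
  sa <- sizes[idx[, 1]]
  sb <- sizes[idx[, 2]]
  raw_p <- stats::phyper(o - 1L, sa, U - sa, sb, lower.tail = FALSE)
  adj_p <- bh_adjust(raw_p)

  keep <- if (mode == "threshold") {
    adj_p < alpha & o > 0L
  } else {
    cand <- which(o > 0L)
    if (k > length(cand)) {
      warning("k = ", k, " exceeds the ", length(cand),
              " overlapping pairs; keeping all", call. = FALSE)
      k <- length(cand)
    }
    sel <- cand[order(raw_p[cand])[seq_len(k)]]
    seq_along(o) %in% sel
  }
  net <- mirna_network(data.frame(
    mirna_a = mirnas[idx[keep, 1]],
    mirna_b = mirnas[idx[keep, 2]],
    raw_p = raw_p[keep],
    adj_p = adj_p[keep]
  ))
  net
}

#' Neighbors of a network miRNA
#' @param network a [mirna_network].
#' @param mirna a node ID.
#' @return character vector of adjacent miRNA IDs.
#' @export
network_neighbors <- function(network, mirna) {
  stopifnot(inherits(network, "mirna_network"))
  mirna <- canon_mirna(mirna)
  if (!mirna %in% network$nodes) {
    stop("miRNA not in network: ", mirna, call. = FALSE)
  }
  network$adjacency[[mirna]]
}

#' Convert a miRNA network to an igraph object
#' @param network a [mirna_network].
#' @return an undirected `igraph` graph whose vertices are the network nodes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mirna_network"))
  igraph::graph_from_data_frame(network$edges[c("mirna_a", "mirna_b")],
                                directed = FALSE,
                                vertices = network$nodes)
}

#' Read/write a network edge list
#'
#' TSV columns: `mirna_a`, `mirna_b`, `raw_p`, `adj_p` (no header).
#' @param path edge-list file.
#' @return `read_edge_list`: a [mirna_network].
#' @export
read_edge_list <- function(path) {
  rows <- read_tsv_rows(path)
  if (!length(rows$fields)) stop("empty edge list: ", path, call. = FALSE)
  bad <- which(lengths(rows$fields) < 4L)
  if (length(bad)) {
    stop_io(path, rows$lineno[bad[1]],
            "expected 4 fields (miRNA, miRNA, raw_p, adj_p)")
  }
  mirna_network(data.frame(
    mirna_a = vapply(rows$fields, `[`, "", 1L),
    mirna_b = vapply(rows$fields, `[`, "", 2L),
    raw_p = parse_num(vapply(rows$fields, `[`, "", 3L)),
    adj_p = parse_num(vapply(rows$fields, `[`, "", 4L))
  ))
}

#' @rdname read_edge_list
#' @param network a [mirna_network].
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "mirna_network"))
  df <- network$edges
  df$raw_p <- format(df$raw_p, digits = 17)
  df$adj_p <- format(df$adj_p, digits = 17)
  write_tsv(df, path)
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("Functionally related miRNA network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
summary.mirna_network <- function(object, ...) {
  deg <- lengths(object$adjacency)
  cat(sprintf("Functionally related miRNA network\n  nodes: %d\n  edges: %d\n",
              length(object$nodes), nrow(object$edges)))
  cat(sprintf("  degree: min %d, median %g, max %d\n",
              min(deg), stats::median(deg), max(deg)))
  cat(sprintf("  adjusted p range: [%.3g, %.3g]\n",
              min(object$edges$adj_p), max(object$edges$adj_p)))
  invisible(object)
}
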