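# Coherence analyses: do functionally related miRNAs associate with
# phenotypically similar diseases?
#
# Disease pairs sharing an associated miRNA are compared with random
# disease pairs on mean phenotypic similarity; miRNA pairs sharing an
# associated disease are compared with random network-miRNA pairs on mean
# shared-neighbor count and on exp(-shortest path) relatedness, using
# empirical permutation null distributions.

#' Pairs of diseases (or miRNAs) sharing an association partner
#'
#' @param associations an [association_set].
#' @param by `"disease"` returns unordered disease pairs linked to at least
#'   one common miRNA; `"mirna"` returns unordered miRNA pairs linked to at
#'   least one common disease.
#' @return two-column character matrix (one unordered pair per row, first
#'   column lexicographically smaller).
#' @export
shared_partner_pairs <- function(associations, by = c("disease", "mirna")) {
  stopifnot(inherits(associations, "association_set"))
  by <- match.arg(by)
  p <- associations$pairs
  if (!nrow(p)) stop("empty association set", call. = FALSE)
  groups <- if (by == "disease") split(p$disease, p$mirna) else split(p$mirna, p$disease)
  out <- list()
  for (g in groups) {
    g <- sort(unique(g))
    if (length(g) >= 2L) {
      idx <- utils::combn(length(g), 2L)
      out[[length(out) + 1L]] <- cbind(g[idx[1, ]], g[idx[2, ]])
    }
  }
  if (!length(out)) {
    return(matrix(character(), 0, 2, dimnames = list(NULL, c("a", "b"))))
  }
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("a", "b"))
  m
}

#' Number of network neighbors shared by two miRNAs
#'
#' @param network a [mirna_network].
#' @param a,b node IDs (the endpoints themselves are not counted).
#' @return integer count.
#' @export
shared_neighbors <- function(network, a, b) {
  na <- network_neighbors(network, a)
  nb <- network_neighbors(network, b)
  length(setdiff(intersect(na, nb), canon_mirna(c(a, b))))
}

#' Shortest-path functional relatedness of two miRNAs
#'
#' `exp(-x)` where `x` is the unweighted shortest-path length between the
#' two nodes; 0 when no path exists (the natural `x -> Inf` limit).
#'
#' @param network a [mirna_network].
#' @param a,b distinct node IDs.
#' @return relatedness in `[0, 1)`.
#' @export
path_relatedness <- function(network, a, b) {
  a <- canon_mirna(a); b <- canon_mirna(b)
  if (a == b) stop("self-relatedness is undefined", call. = FALSE)
  if (!all(c(a, b) %in% network$nodes)) {
    stop("miRNA not in network", call. = FALSE)
  }
  d <- igraph::distances(as_igraph(network), v = a, to = b)[1, 1]
  if (is.infinite(d)) 0 else exp(-d)
}

# Precompute the full pairwise statistic matrix over the population.
statistic_matrix <- function(statistic, phenome = NULL, network = NULL) {
  switch(
    statistic,
    phenotype_similarity = {
      if (is.null(phenome)) {
        stop("statistic 'phenotype_similarity' requires `phenome`", call. = FALSE)
      }
      phenome$matrix
    },
    shared_neighbors = {
      if (is.null(network)) {
        stop("statistic 'shared_neighbors' requires `network`", call. = FALSE)
      }
      adj <- matrix(0L, length(network$nodes), length(network$nodes),
                    dimnames = list(network$nodes, network$nodes))
      e <- network$edges
      adj[cbind(e$mirna_a, e$mirna_b)] <- 1L
      adj <- adj + t(adj)
      # paths of length 2 through a third node; endpoints never counted
      # because the diagonal of adj is zero
      tcrossprod(adj)
    },
    path_relatedness = {
      if (is.null(network)) {
        stop("statistic 'path_relatedness' requires `network`", call. = FALSE)
      }
      d <- igraph::distances(as_igraph(network))
      r <- exp(-d)
      r[is.infinite(d)] <- 0
      r
    },
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
}

#' Permutation test of pair-set coherence
#'
#' Compares the mean of a pairwise statistic over an observed set of
#' unordered pairs against `n_sets` random sets of the same size, each
#' drawn uniformly (distinct pairs within a set) from all unordered pairs
#' of the population. The population is the full phenome for
#' `phenotype_similarity` and the network node set for the two graph
#' statistics.
#'
#' The reported `p_value` is the +1-corrected empirical upper-tail
#' probability `(1 + #\{null >= observed\}) / (1 + n_sets)` (never zero);
#' the uncorrected fraction is reported alongside as `p_raw`.
#'
#' @param observed_pairs two-column matrix or data frame of entity-ID pairs
#'   (e.g. from [shared_partner_pairs()]).
#' @param statistic `"phenotype_similarity"`, `"shared_neighbors"` or
#'   `"path_relatedness"`.
#' @param phenome a [phenotype_similarity]; required for the similarity
#'   statistic.
#' @param network a [mirna_network]; required for the graph statistics.
#' @param n_sets number of random control sets (the conventional choice is
#'   10,000).
#' @param seed integer RNG seed.
#' @return an object of class `permutation_result`: list with `observed`,
#'   `null_means`, `n_sets`, `p_value`, `p_raw`, `statistic`.
#' @export
permutation_test <- function(observed_pairs, statistic, phenome = NULL,
                             network = NULL, n_sets = 10000L, seed = 1L) {
  stopifnot(n_sets >= 1)
  statistic <- match.arg(statistic, c("phenotype_similarity",
                                      "shared_neighbors", "path_relatedness"))
  mat <- statistic_matrix(statistic, phenome, network)
  pop <- rownames(mat)
  obs <- as.matrix(observed_pairs)
  if (ncol(obs) != 2L) stop("observed_pairs must have two columns", call. = FALSE)
  if (!nrow(obs)) stop("no observed pairs", call. = FALSE)
  a <- if (statistic == "phenotype_similarity") canon_mim(obs[, 1]) else canon_mirna(obs[, 1])
  b <- if (statistic == "phenotype_similarity") canon_mim(obs[, 2]) else canon_mirna(obs[, 2])
  if (!all(c(a, b) %in% pop)) {
    stop("observed pair member missing from the population", call. = FALSE)
  }
  observed <- mean(mat[cbind(a, b)])
  P <- length(pop)
  n_pairs <- nrow(obs)
  total <- P * (P - 1) / 2
  if (n_pairs > total) {
    stop("population too small to sample ", n_pairs, " distinct pairs",
         call. = FALSE)
  }
  # unordered pairs indexed 0..total-1; decode linear index to (i, j), i < j
  null_means <- with_seed(seed, {
    vapply(seq_len(n_sets), function(s) {
      idx <- sample(total, n_pairs) - 1
      i <- floor((2 * P - 1 - sqrt((2 * P - 1)^2 - 8 * idx)) / 2)
      j <- idx - i * P + (i + 1) * (i + 2) / 2
      # guard against sqrt() rounding at block boundaries
      over <- j > P - 1
      if (any(over)) {
        i[over] <- i[over] + 1
        j[over] <- idx[over] - i[over] * P + (i[over] + 1) * (i[over] + 2) / 2
      }
      mean(mat[cbind(pop[i + 1], pop[j + 1])])
    }, 0)
  })
  n_ge <- sum(null_means >= observed)
  structure(
    list(observed = observed, null_means = null_means, n_sets = n_sets,
         p_value = (1 + n_ge) / (1 + n_sets), p_raw = n_ge / n_sets,
         statistic = statistic),
    class = "permutation_result"
  )
}

#' Run the three coherence tests of a fitted model
#'
#' Convenience wrapper: tests (i) the mean phenotypic similarity of disease
#' pairs sharing an associated miRNA, and the mean (ii) shared-neighbor
#' count and (iii) shortest-path relatedness of miRNA pairs sharing an
#' associated disease, each against `n_sets` random control sets.
#'
#' Association pairs whose members are absent from the relevant population
#' (phenome or network) are dropped before testing.
#'
#' @param fit a fitted [mirphen()] model.
#' @param n_sets number of random control sets per test.
#' @param seed integer RNG seed.
#' @return named list of three `permutation_result` objects
#'   (`phenotype_similarity`, `shared_neighbors`, `path_relatedness`).
#' @export
coherence_test <- function(fit, n_sets = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "mirphen"))
  p <- fit$associations$pairs
  keep_d <- p$disease %in% sim_diseases(fit$phenome)
  keep_m <- p$mirna %in% fit$network$nodes
  assoc_d <- association_set(p$mirna[keep_d], p$disease[keep_d])
  assoc_m <- association_set(p$mirna[keep_m], p$disease[keep_m])
  dpairs <- shared_partner_pairs(assoc_d, by = "disease")
  mpairs <- shared_partner_pairs(assoc_m, by = "mirna")
  mpairs <- mpairs[mpairs[, 1] %in% fit$network$nodes &
                     mpairs[, 2] %in% fit$network$nodes, , drop = FALSE]
  list(
    phenotype_similarity = permutation_test(
      dpairs, "phenotype_similarity", phenome = fit$phenome,
      n_sets = n_sets, seed = seed),
    shared_neighbors = permutation_test(
      mpairs, "shared_neighbors", network = fit$network,
      n_sets = n_sets, seed = seed + 1L),
    path_relatedness = permutation_test(
      mpairs, "path_relatedness", network = fit$network,
      n_sets = n_sets, seed = seed + 2L)
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed mean %.4g\n",
              x$statistic, x$observed))
  cat(sprintf("  %d null sets: mean %.4g, max %.4g\n",
              x$n_sets, mean(x$null_means), max(x$null_means)))
  cat(sprintf("  p = %.4g (+1-corrected; uncorrected %.4g)\n",
              x$p_value, x$p_raw))
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$null_means, breaks = 30, main = x$statistic,
                 xlab = "null set mean",
                 xlim = range(c(x$null_means, x$observed)), ...)
  graphics::arrows(x$observed, graphics::par("usr")[4] * 0.5, x$observed, 0,
                   col = "red", length = 0.1)
  invisible(x)
}

#' Write permutation-test output
#'
#' One null-set mean per line in the TSV; the JSON summary records the
#' observed mean, set count and both p-values.
#' @param result a `permutation_result`.
#' @param tsv_path,json_path output files (either may be `NULL`).
#' @export
write_permutation <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "permutation_result"))
  if (!is.null(tsv_path)) write_tsv(data.frame(result$null_means), tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(statistic = result$statistic, observed = result$observed,
           n_sets = result$n_sets, p_value = result$p_value,
           p_raw = result$p_raw),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
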