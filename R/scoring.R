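# Module scoring: the cumulative hypergeometric statistic.
#
# For a query disease d, the candidate module is a miRNA plus its direct
# network neighbors. With N network miRNAs of which M are associated with
# a disease phenotypically similar to d, a module of size n containing m
# such miRNAs is scored by the upper hypergeometric tail P(X >= m); small
# tails mean the module is enriched for miRNAs of similar diseases.

#' Diseases phenotypically similar to a query disease
#'
#' Returns every phenotype whose similarity score with `disease` is at
#' least `cutoff` (0.3 by default, the conventional MimMiner "similar"
#' threshold). The query disease itself is always included because
#' self-similarity is 1.
#'
#' @param phenome a [phenotype_similarity].
#' @param disease query MIM ID.
#' @param cutoff similarity threshold in `[0, 1]`; inclusive (`>= cutoff`).
#' @return character vector of MIM IDs.
#' @export
similar_diseases <- function(phenome, disease, cutoff = 0.3) {
  stopifnot(inherits(phenome, "phenotype_similarity"),
            cutoff >= 0, cutoff <= 1)
  disease <- canon_mim(disease)
  if (!disease %in% rownames(phenome$matrix)) {
    stop("unknown disease phenotype: ", disease, call. = FALSE)
  }
  s <- phenome$matrix[disease, ]
  colnames(phenome$matrix)[s >= cutoff]
}

#' Module of a candidate miRNA
#'
#' The candidate itself (module center) plus its direct network neighbors.
#'
#' @param network a [mirna_network].
#' @param mirna a node ID.
#' @return character vector of module member IDs (size >= 2 for any node).
#' @export
module_members <- function(network, mirna) {
  mirna <- canon_mirna(mirna)
  sort(unique(c(mirna, network_neighbors(network, mirna))))
}

#' Cumulative hypergeometric tail probability
#'
#' Probability that a sample of `n` draws without replacement from a
#' population of `N` objects, `M` of which are successes, contains at least
#' `m` successes (or strictly more than `m` with `tail = "gt"`). Computed
#' exactly.
#'
#' @param N population size (miRNAs in the whole network).
#' @param M successes in the population (miRNAs linked to similar diseases).
#' @param n draws (module size).
#' @param m observed successes in the module.
#' @param tail `"geq"` for P(X >= m) (default) or `"gt"` for P(X > m).
#' @return probability in `[0, 1]`; `(0, 1]` for `tail = "geq"`.
#' @export
hypergeom_tail <- function(N, M, n, m, tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  if (any(M > N) || any(n > N) || any(m > pmin(n, M)) || any(m < 0) ||
      any(n < 0) || any(M < 0)) {
    stop("invalid hypergeometric parameters (need 0 <= m <= min(n, M), n <= N, M <= N)",
         call. = FALSE)
  }
  q <- if (tail == "geq") m - 1 else m
  stats::phyper(q, M, N - M, n, lower.tail = FALSE)
}

#' Fit a phenome-microRNAome prioritization model
#'
#' Combines a functionally related miRNA network, a phenotype similarity
#' store and a set of known miRNA-disease associations into a model object
#' from which per-disease rankings of the whole network microRNAome are
#' obtained with [predict.mirphen()] (or [prioritize()] directly).
#'
#' Either pass a pre-built `network` or a target `catalog` from which the
#' network is constructed via [build_network()].
#'
#' @param catalog a [target_catalog] (ignored when `network` is given).
#' @param phenome a [phenotype_similarity].
#' @param associations an [association_set].
#' @param network optional pre-built [mirna_network].
#' @param mode,alpha,k,universe_size passed to [build_network()].
#' @param similarity_cutoff phenotype similarity threshold defining
#'   "similar" diseases (default 0.3).
#' @param tail hypergeometric tail convention, `"geq"` or `"gt"`.
#' @return an object of class `mirphen`.
#' @seealso [predict.mirphen()], [loocv()], [coherence_test()]
#' @examples
#' syn <- synth_generate(synth_config(seed = 1))
#' fit <- mirphen(syn$catalog, syn$phenome, syn$associations)
#' fit
#' head(predict(fit, disease = sim_diseases(syn$phenome)[1], top_k = 5))
#' @export
mirphen <- function(catalog = NULL, phenome, associations, network = NULL,
                    mode = c("threshold", "top_k"), alpha = 0.001,
                    k = 15000L, universe_size = NULL,
                    similarity_cutoff = 0.3, tail = c("geq", "gt")) {
  stopifnot(inherits(phenome, "phenotype_similarity"),
            inherits(associations, "association_set"))
  tail <- match.arg(tail)
  if (is.null(network)) {
    if (is.null(catalog)) {
      stop("supply either `catalog` or `network`", call. = FALSE)
    }
    network <- build_network(catalog, mode = mode, alpha = alpha, k = k,
                             universe_size = universe_size)
  }
  stopifnot(inherits(network, "mirna_network"))
  structure(
    list(network = network, phenome = phenome, associations = associations,
         similarity_cutoff = similarity_cutoff, tail = tail,
         call = match.call()),
    class = "mirphen"
  )
}

#' Rank the network microRNAome for a query disease
#'
#' Scores every network miRNA: `N` is the network size, `M` the number of
#' network miRNAs associated with any disease similar to the query, `n` the
#' candidate's module size and `m` the number of module members associated
#' with similar diseases; the score is the upper hypergeometric tail
#' `P(X >= m)`, ranked ascending (rank 1 = most significant), ties getting
#' their average rank.
#'
#' @param network a [mirna_network].
#' @param phenome a [phenotype_similarity].
#' @param associations an [association_set].
#' @param disease query MIM ID (must be known to `phenome`).
#' @param cutoff similarity threshold (default 0.3).
#' @param tail `"geq"` or `"gt"` tail convention.
#' @return a data frame of class `mirna_ranking`, one row per network node,
#'   ordered by increasing `tail_p`, with columns `rank`, `mirna`,
#'   `tail_p`, `score` (`-log10(tail_p)`), `N`, `M`, `n`, `m`; the query
#'   disease is stored in `attr(, "disease")`.
#' @export
prioritize <- function(network, phenome, associations, disease,
                       cutoff = 0.3, tail = c("geq", "gt")) {
  stopifnot(inherits(network, "mirna_network"),
            inherits(phenome, "phenotype_similarity"),
            inherits(associations, "association_set"))
  tail <- match.arg(tail)
  if (!length(network$nodes)) stop("empty network", call. = FALSE)
  sims <- similar_diseases(phenome, disease, cutoff)
  nodes <- network$nodes
  N <- length(nodes)
  linked <- unique(associations$pairs$mirna[associations$pairs$disease %in% sims])
  is_linked <- nodes %in% linked
  M <- sum(is_linked)
  n <- integer(N)
  m <- integer(N)
  for (i in seq_len(N)) {
    mod <- c(i, match(network$adjacency[[i]], nodes))
    n[i] <- length(mod)
    m[i] <- sum(is_linked[mod])
  }
  tail_p <- hypergeom_tail(N, M, n, m, tail = tail)
  rk <- rank(tail_p, ties.method = "average")
  out <- data.frame(rank = rk, mirna = nodes, tail_p = tail_p,
                    score = -log10(tail_p), N = N, M = M, n = n, m = m)
  out <- out[order(out$tail_p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mirna_ranking", "data.frame"),
            disease = canon_mim(disease))
}

#' @describeIn mirphen rank the microRNAome for one or more query diseases;
#'   returns a single `mirna_ranking` for one disease, otherwise a named
#'   list of rankings. `top_k` truncates each ranking to its top rows.
#' @param object a fitted `mirphen` model.
#' @param disease MIM ID(s) to prioritize for.
#' @param top_k optional: keep only the `top_k` best-ranked rows.
#' @param ... unused.
#' @export
predict.mirphen <- function(object, disease, top_k = NULL, ...) {
  one <- function(d) {
    r <- prioritize(object$network, object$phenome, object$associations, d,
                    cutoff = object$similarity_cutoff, tail = object$tail)
    if (!is.null(top_k)) r <- r[seq_len(min(top_k, nrow(r))), , drop = FALSE]
    r
  }
  if (length(disease) == 1L) one(disease)
  else stats::setNames(lapply(disease, one), canon_mim(disease))
}

#' Write a ranking to TSV
#'
#' Columns: rank, miRNA, tail_p, score, N, M, n, m, query MIM.
#' @param ranking a `mirna_ranking`.
#' @param path output file.
#' @param top_k rows to keep (default 100, `Inf` for all).
#' @export
write_ranking <- function(ranking, path, top_k = 100) {
  stopifnot(inherits(ranking, "mirna_ranking"))
  df <- as.data.frame(ranking)[seq_len(min(top_k, nrow(ranking))), , drop = FALSE]
  df$disease <- attr(ranking, "disease")
  write_tsv(df, path)
}

#' @export
print.mirphen <- function(x, ...) {
  cat("Phenome-microRNAome prioritization model\n")
  cat(sprintf("  network: %d miRNAs, %d edges\n",
              length(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  phenome: %d diseases (similarity cutoff %.2g)\n",
              nrow(x$phenome$matrix), x$similarity_cutoff))
  cat(sprintf("  known associations: %d\n", nrow(x$associations$pairs)))
  invisible(x)
}

#' @export
summary.mirphen <- function(object, ...) {
  print(object)
  in_net <- object$associations$pairs$mirna %in% object$network$nodes
  cat(sprintf("  associations with network defector: %d of %d\n",
              sum(in_net), length(in_net)))
  known <- unique(object$associations$pairs$disease) %in%
    rownames(object$phenome$matrix)
  cat(sprintf("  associated diseases known to phenome: %d of %d\n",
              sum(known), length(known)))
  invisible(object)
}

#' @export
print.mirna_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked microRNAome for disease %s (%d candidates)\n",
              attr(x, "disease"), nrow(x)))
  print(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}
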