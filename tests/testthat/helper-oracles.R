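# Independent brute-force oracles and shared fixtures.

# Upper hypergeometric tail P(X >= m) by direct summation of binomial
# coefficient terms (independent of stats::phyper).
bf_hyper_tail <- function(N, M, n, m) {
  ks <- seq(m, min(n, M))
  if (m > min(n, M)) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# Reference Benjamini-Hochberg step-up: sort descending, scale by n/rank,
# take the running minimum from the largest rank, cap at 1.
bf_bh <- function(p) {
  n <- length(p)
  if (!n) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / (n:1)))[ro]
}

# Six-node fixture: candidate c's module {c, a, b} holds both associated
# miRNAs; remaining nodes x-y-z form a path with no associated members.
fixture_six_node <- function() {
  net <- mirna_network(data.frame(
    mirna_a = c("c", "c", "x", "y"),
    mirna_b = c("a", "b", "y", "z"),
    raw_p = 1e-6, adj_p = 1e-5
  ))
  phenome <- phenotype_similarity(
    matrix(1, 1, 1, dimnames = list("100100", "100100")))
  assoc <- association_set(c("a", "b"), c("100100", "100100"))
  list(network = net, phenome = phenome, associations = assoc)
}

# Small two-cluster catalog whose clusters become cliques.
fixture_catalog <- function(genes_per = 20L, n_per_cluster = 3L) {
  g1 <- sprintf("a%02d", seq_len(genes_per))
  g2 <- sprintf("b%02d", seq_len(genes_per))
  targets <- c(
    setNames(replicate(n_per_cluster, g1, simplify = FALSE),
             sprintf("mir-a%d", seq_len(n_per_cluster))),
    setNames(replicate(n_per_cluster, g2, simplify = FALSE),
             sprintf("mir-b%d", seq_len(n_per_cluster)))
  )
  target_catalog(targets)
}
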