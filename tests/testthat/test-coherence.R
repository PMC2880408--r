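# Shared-partner census, graph relatedness and permutation nulls.

test_that("shared_partner_pairs enumerates common-partner pairs", {
  a1 <- association_set(c("m1", "m2"), c("d1", "d1"))
  expect_equal(shared_partner_pairs(a1, by = "mirna"),
               matrix(c("m1", "m2"), 1, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(shared_partner_pairs(a1, by = "disease")), 0L)

  a2 <- association_set(c("m1", "m1", "m2"), c("d1", "d2", "d2"))
  expect_equal(shared_partner_pairs(a2, by = "disease")[1, ],
               c(a = "d1", b = "d2"))
  expect_equal(shared_partner_pairs(a2, by = "mirna")[1, ],
               c(a = "m1", b = "m2"))

  # census size is invariant to association row order
  p <- synth_generate(synth_config(seed = 11))$associations$pairs
  sh <- association_set(rev(p$mirna), rev(p$disease))
  expect_equal(shared_partner_pairs(association_set(p$mirna, p$disease), "disease"),
               shared_partner_pairs(sh, "disease"))
})

test_that("shared_neighbors counts common neighbors, excluding endpoints", {
  net <- mirna_network(data.frame(
    mirna_a = c("a", "a", "b", "b", "a"),
    mirna_b = c("x", "y", "x", "y", "b"),
    raw_p = 1e-6, adj_p = 1e-5))
  expect_equal(shared_neighbors(net, "a", "b"), 2L)  # x and y, not each other
  tri <- mirna_network(data.frame(mirna_a = c("a", "b", "a"),
                                  mirna_b = c("b", "c", "c"),
                                  raw_p = 1e-6, adj_p = 1e-5))
  expect_equal(shared_neighbors(tri, "a", "b"), 1L)  # only c
  two <- mirna_network(data.frame(mirna_a = c("a", "x"), mirna_b = c("b", "y"),
                                  raw_p = 1e-6, adj_p = 1e-5))
  expect_equal(shared_neighbors(two, "a", "x"), 0L)  # disjoint components
  expect_error(shared_neighbors(two, "a", "zz"), "not in network")
})

test_that("path relatedness is exp(-shortest path), zero when disconnected", {
  fx <- fixture_six_node()
  expect_equal(path_relatedness(fx$network, "c", "a"), exp(-1))
  expect_equal(path_relatedness(fx$network, "a", "b"), exp(-2))
  expect_equal(path_relatedness(fx$network, "a", "z"), 0)   # other component
  expect_error(path_relatedness(fx$network, "a", "a"), "undefined")
  # strictly decreasing in path length on a path graph
  chain <- mirna_network(data.frame(mirna_a = c("p1", "p2", "p3"),
                                    mirna_b = c("p2", "p3", "p4"),
                                    raw_p = 1e-6, adj_p = 1e-5))
  r <- c(path_relatedness(chain, "p1", "p2"),
         path_relatedness(chain, "p1", "p3"),
         path_relatedness(chain, "p1", "p4"))
  expect_true(all(diff(r) < 0))
})

test_that("the shared-neighbor statistic matrix matches pairwise calls", {
  syn <- synth_generate(synth_config(seed = 13, n_mirnas = 16, n_genes = 250))
  net <- build_network(syn$catalog)
  mat <- mirphen:::statistic_matrix("shared_neighbors", network = net)
  pick <- utils::combn(net$nodes[1:4], 2)
  for (i in seq_len(ncol(pick))) {
    expect_equal(mat[pick[1, i], pick[2, i]],
                 shared_neighbors(net, pick[1, i], pick[2, i]))
  }
  rmat <- mirphen:::statistic_matrix("path_relatedness", network = net)
  for (i in seq_len(ncol(pick))) {
    expect_equal(rmat[pick[1, i], pick[2, i]],
                 path_relatedness(net, pick[1, i], pick[2, i]))
  }
})

test_that("permutation p-values carry the +1 correction and reproduce by seed", {
  syn <- synth_generate(synth_config(seed = 3, association_fidelity = 1))
  dpairs <- shared_partner_pairs(syn$associations, by = "disease")
  r1 <- permutation_test(dpairs, "phenotype_similarity", phenome = syn$phenome,
                         n_sets = 50, seed = 21)
  r2 <- permutation_test(dpairs, "phenotype_similarity", phenome = syn$phenome,
                         n_sets = 50, seed = 21)
  expect_equal(r1$null_means, r2$null_means)
  expect_length(r1$null_means, 50L)
  expect_equal(r1$p_value, (1 + sum(r1$null_means >= r1$observed)) / 51)
  expect_gte(r1$p_value, 1 / 51)
})

test_that("a constant statistic yields p = 1", {
  m <- matrix(0.5, 4, 4, dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  diag(m) <- 1
  ps <- phenotype_similarity(m)
  obs <- rbind(c("d1", "d2"), c("d3", "d4"))
  r <- permutation_test(obs, "phenotype_similarity", phenome = ps,
                        n_sets = 200, seed = 2)
  # null pairs are never self-pairs, so every null mean equals the observed
  expect_equal(r$p_value, 1)
})

test_that("null-set pairs are distinct within a set and drawn from the population", {
  # with a 4-entity population and 6 requested pairs, each null set must be
  # all of C(4,2): its mean is then a constant we can enumerate
  m <- diag(4)
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m <- pmax(m, t(m)); diag(m) <- 1
  dimnames(m) <- list(paste0("d", 1:4), paste0("d", 1:4))
  ps <- phenotype_similarity(m)
  obs <- rbind(c("d1", "d2"), c("d1", "d3"), c("d1", "d4"),
               c("d2", "d3"), c("d2", "d4"), c("d3", "d4"))
  r <- permutation_test(obs, "phenotype_similarity", phenome = ps,
                        n_sets = 25, seed = 4)
  expect_true(all(abs(r$null_means - mean(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))) < 1e-12))
  expect_error(permutation_test(rbind(obs, c("d1", "d2")),
                                "phenotype_similarity", phenome = ps,
                                n_sets = 2, seed = 1),
               "too small")
})

test_that("coherence_test wires the three statistics of a fitted model", {
  syn <- synth_generate(synth_config(seed = 3, association_fidelity = 1))
  fit <- mirphen(syn$catalog, syn$phenome, syn$associations)
  res <- coherence_test(fit, n_sets = 100, seed = 7)
  expect_named(res, c("phenotype_similarity", "shared_neighbors",
                      "path_relatedness"))
  # perfect planted coherence beats every null set
  for (r in res) expect_equal(r$p_value, 1 / 101)
  dir <- withr::local_tempdir()
  write_permutation(res[[1]], tsv_path = file.path(dir, "null.tsv"),
                    json_path = file.path(dir, "sum.json"))
  expect_equal(nrow(read.delim(file.path(dir, "null.tsv"), header = FALSE)), 100L)
  js <- jsonlite::read_json(file.path(dir, "sum.json"))
  expect_equal(js$p_value, 1 / 101, tolerance = 1e-12)
})
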