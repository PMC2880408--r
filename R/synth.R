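# Seeded synthetic benchmark generator.
#
# Emulates the statistical structure the prioritization method relies on:
# clusters of miRNAs drawing targets from shared gene pools (so
# within-cluster target overlap is significant), a block-structured
# phenotype similarity matrix whose blocks are separated by the 0.3
# "similar" cutoff, and miRNA-disease associations that link each miRNA
# cluster to its paired disease block with a configurable fidelity.

#' Configuration of the synthetic benchmark
#'
#' Defaults are sized for desk-scale experiments: 60 miRNAs targeting a
#' 1,000-gene universe in 4 clusters, 40 diseases in 4 similarity blocks,
#' and 80 planted associations.
#'
#' @param n_mirnas,n_genes,n_clusters catalog dimensions; clusters are
#'   paired 1:1 with disease blocks, so `n_clusters` must equal `n_blocks`.
#' @param targets_per_mirna target-set size per miRNA.
#' @param within_cluster_target_overlap fraction of each target set drawn
#'   from the cluster's shared gene pool (the rest is background).
#' @param n_diseases,n_blocks phenome dimensions.
#' @param within_block_similarity similarity between diseases of the same
#'   block, in `[0.3, 1]`.
#' @param between_block_similarity similarity across blocks, in `[0, 0.3)`;
#'   the 0.3 cutoff then separates blocks by construction.
#' @param n_associations number of planted miRNA-disease associations.
#' @param association_fidelity probability that an association links a
#'   cluster miRNA to a disease of its paired block (otherwise the disease
#'   is drawn uniformly); 0 plants no signal, 1 plants perfect coherence.
#' @param seed integer; the generator is fully determined by it.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_mirnas = 60L, n_genes = 1000L, n_clusters = 4L,
                         targets_per_mirna = 40L,
                         within_cluster_target_overlap = 0.8,
                         n_diseases = 40L, n_blocks = n_clusters,
                         within_block_similarity = 0.6,
                         between_block_similarity = 0.1,
                         n_associations = 80L, association_fidelity = 0.9,
                         seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              targets_per_mirna = as.integer(targets_per_mirna),
              within_cluster_target_overlap = within_cluster_target_overlap,
              n_diseases = as.integer(n_diseases),
              n_blocks = as.integer(n_blocks),
              within_block_similarity = within_block_similarity,
              between_block_similarity = between_block_similarity,
              n_associations = as.integer(n_associations),
              association_fidelity = association_fidelity,
              seed = as.integer(seed))
  if (cfg$n_clusters != cfg$n_blocks) {
    stop("n_clusters must equal n_blocks (clusters pair 1:1 with blocks)",
         call. = FALSE)
  }
  if (cfg$within_block_similarity < 0.3 || cfg$within_block_similarity > 1) {
    stop("within_block_similarity must lie in [0.3, 1]", call. = FALSE)
  }
  if (cfg$between_block_similarity < 0 || cfg$between_block_similarity >= 0.3) {
    stop("between_block_similarity must lie in [0, 0.3)", call. = FALSE)
  }
  if (cfg$within_cluster_target_overlap < 0 ||
      cfg$within_cluster_target_overlap > 1) {
    stop("within_cluster_target_overlap must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$association_fidelity < 0 || cfg$association_fidelity > 1) {
    stop("association_fidelity must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_clusters * cfg$targets_per_mirna > cfg$n_genes) {
    stop("n_genes too small for ", cfg$n_clusters, " disjoint cluster pools ",
         "of ", cfg$targets_per_mirna, " genes", call. = FALSE)
  }
  if (cfg$n_associations > cfg$n_mirnas * cfg$n_diseases) {
    stop("more associations requested than distinct pairs exist", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic benchmark dataset
#'
#' Deterministic given `config$seed`. Each miRNA cluster has a private gene
#' pool (pools are disjoint); a miRNA draws
#' `round(overlap * targets_per_mirna)` targets from its pool and the rest
#' uniformly from the remaining genes. The similarity matrix is
#' block-constant plus uniform jitter of +/-0.02 (symmetrized by averaging
#' and clamped so the within/between separation at 0.3 is preserved), with
#' unit diagonal. Associations are distinct pairs; with probability
#' `association_fidelity` a pair links a cluster miRNA to a disease of its
#' paired block. Families are the first four miRNAs of each cluster.
#'
#' @param config a [synth_config()].
#' @return list with elements `catalog` ([target_catalog]), `phenome`
#'   ([phenotype_similarity]), `associations` ([association_set]),
#'   `families` ([family_map]), and bookkeeping vectors `cluster_of`
#'   (miRNA -> cluster index) and `block_of` (disease -> block index).
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    mirnas <- sprintf("mir-%03d", seq_len(config$n_mirnas))
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    diseases <- as.character(100000 + 7 * seq_len(config$n_diseases))

    cluster_of <- stats::setNames(
      sort(rep_len(seq_len(config$n_clusters), config$n_mirnas)), mirnas)
    block_of <- stats::setNames(
      sort(rep_len(seq_len(config$n_blocks), config$n_diseases)), diseases)

    # disjoint per-cluster gene pools
    pool_genes <- sample(genes, config$n_clusters * config$targets_per_mirna)
    pools <- split(pool_genes,
                   rep(seq_len(config$n_clusters), each = config$targets_per_mirna))

    n_core <- round(config$within_cluster_target_overlap * config$targets_per_mirna)
    targets <- lapply(mirnas, function(m) {
      pool <- pools[[cluster_of[[m]]]]
      core <- if (n_core > 0) sample(pool, n_core) else character()
      n_bg <- config$targets_per_mirna - n_core
      bg <- if (n_bg > 0) sample(setdiff(genes, pool), n_bg) else character()
      c(core, bg)
    })
    names(targets) <- mirnas
    catalog <- target_catalog(targets)

    # block-structured similarity with symmetric jitter
    base <- matrix(config$between_block_similarity,
                   config$n_diseases, config$n_diseases,
                   dimnames = list(diseases, diseases))
    same <- outer(block_of, block_of, `==`)
    base[same] <- config$within_block_similarity
    jit <- matrix(stats::runif(config$n_diseases^2, -0.02, 0.02),
                  config$n_diseases)
    sim <- base + (jit + t(jit)) / 2
    sim[same] <- pmin(pmax(sim[same], 0.3), 1)
    sim[!same] <- pmin(pmax(sim[!same], 0), 0.3 - 1e-6)
    diag(sim) <- 1
    phenome <- phenotype_similarity(sim)

    # distinct planted associations
    pairs <- character(0)
    mir_v <- character(0)
    dis_v <- character(0)
    block_members <- split(diseases, block_of)
    while (length(pairs) < config$n_associations) {
      m <- sample(mirnas, 1)
      d <- if (stats::runif(1) < config$association_fidelity) {
        sample(block_members[[cluster_of[[m]]]], 1)
      } else {
        sample(diseases, 1)
      }
      key <- paste(m, d)
      if (!key %in% pairs) {
        pairs <- c(pairs, key)
        mir_v <- c(mir_v, m)
        dis_v <- c(dis_v, d)
      }
    }
    associations <- association_set(mir_v, dis_v)

    fam_members <- lapply(split(mirnas, cluster_of), utils::head, 4L)
    families <- family_map(stats::setNames(
      rep(sprintf("fam-%d", seq_along(fam_members)), lengths(fam_members)),
      unlist(fam_members, use.names = FALSE)))

    list(catalog = catalog, phenome = phenome, associations = associations,
         families = families, cluster_of = cluster_of, block_of = block_of)
  })
}

#' Write a synthetic dataset as the standard TSV fixtures
#'
#' Emits `catalog.tsv`, `similarity.tsv`, `associations.tsv`,
#' `families.tsv` and `config.json` under `dir`.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the generated dataset list.
#' @export
write_synth_fixtures <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syn <- synth_generate(config)
  write_target_catalog(syn$catalog, file.path(dir, "catalog.tsv"))
  write_phenotype_similarity(syn$phenome, file.path(dir, "similarity.tsv"))
  write_associations(syn$associations, file.path(dir, "associations.tsv"))
  write_family_map(syn$families, file.path(dir, "families.tsv"))
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(syn)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic benchmark configuration\n")
  cat(sprintf("  %d miRNAs in %d clusters, %d targets each (overlap %.2f) over %d genes\n",
              x$n_mirnas, x$n_clusters, x$targets_per_mirna,
              x$within_cluster_target_overlap, x$n_genes))
  cat(sprintf("  %d diseases in %d blocks (similarity %.2f within / %.2f between)\n",
              x$n_diseases, x$n_blocks, x$within_block_similarity,
              x$between_block_similarity))
  cat(sprintf("  %d associations at fidelity %.2f, seed %d\n",
              x$n_associations, x$association_fidelity, x$seed))
  invisible(x)
}
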