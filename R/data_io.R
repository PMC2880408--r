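# Input data types and their TSV readers/writers.
#
# All tabular inputs are UTF-8 TSV, '#' starts a comment line, and gzipped
# files are read transparently. The four container types (target_catalog,
# phenotype_similarity, association_set, family_map) are plain S3 objects
# validated at construction.

## ---- target catalog ---------------------------------------------------

#' Construct a miRNA target catalog
#'
#' A `target_catalog` maps each miRNA to its set of predicted target genes
#' and records the gene universe (the union of all retained targets), which
#' is the default population for the overlap significance test.
#'
#' @param targets named list; one character vector of gene IDs per miRNA.
#' @param dropped character vector of miRNA IDs removed because score
#'   filtering emptied their target sets (kept for logging).
#' @return an object of class `target_catalog` with elements `targets`
#'   (named list of sorted unique gene-ID vectors), `universe` (sorted
#'   character vector) and `dropped`.
#' @export
target_catalog <- function(targets, dropped = character()) {
  if (length(targets) && is.null(names(targets))) {
    stop("`targets` must be a named list (names are miRNA IDs)", call. = FALSE)
  }
  names(targets) <- canon_mirna(names(targets))
  targets <- lapply(targets, function(g) sort(unique(as.character(g))))
  empty <- vapply(targets, length, 1L) == 0L
  dropped <- unique(c(canon_mirna(dropped), names(targets)[empty]))
  targets <- targets[!empty]
  targets <- targets[order(names(targets))]
  structure(
    list(
      targets = targets,
      universe = sort(unique(unlist(targets, use.names = FALSE))),
      dropped = dropped
    ),
    class = "target_catalog"
  )
}

#' Read a miRNA-to-target prediction catalog
#'
#' Reads tab-delimited rows `miRNA <tab> gene [<tab> score]`. When
#' `score_cutoff` is given, only rows whose score is below the cutoff are
#' retained (strictly below by default, matching the usual "score less
#' than -10.0" convention of energy-like target-prediction scores, where
#' more negative means stronger). miRNAs whose target set becomes empty
#' after filtering are dropped and reported in `$dropped`.
#'
#' @param path TSV file (optionally gzipped).
#' @param score_cutoff numeric or `NULL` (no filtering).
#' @param strict logical; `TRUE` keeps `score < cutoff`, `FALSE` keeps
#'   `score <= cutoff`.
#' @return a [target_catalog].
#' @export
read_target_catalog <- function(path, score_cutoff = NULL, strict = TRUE) {
  rows <- read_tsv_rows(path)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop_io(path, rows$lineno[bad[1]],
            "expected at least 2 tab-separated fields (miRNA, gene)")
  }
  if (!is.null(score_cutoff)) {
    noscore <- which(nf < 3L)
    if (length(noscore)) {
      stop_io(path, rows$lineno[noscore[1]],
              "score_cutoff given but row has no score column")
    }
    score <- parse_num(vapply(rows$fields, `[`, "", 3L))
    badnum <- which(is.na(score))
    if (length(badnum)) {
      stop_io(path, rows$lineno[badnum[1]], "score is not numeric")
    }
    keep <- if (strict) score < score_cutoff else score <= score_cutoff
  } else {
    keep <- rep(TRUE, length(rows$fields))
  }
  mirna <- canon_mirna(vapply(rows$fields, `[`, "", 1L))
  gene <- trimws(vapply(rows$fields, `[`, "", 2L))
  all_mirnas <- unique(mirna)
  targets <- split(gene[keep], factor(mirna[keep], levels = all_mirnas))
  cat_ <- target_catalog(targets)
  n_dropped <- length(cat_$dropped)
  if (n_dropped) {
    message(n_dropped, " miRNA(s) dropped (empty target set after filtering)")
  }
  message(sprintf("catalog: %d miRNAs, %d genes, %d retained pairs",
                  length(cat_$targets), length(cat_$universe),
                  sum(vapply(cat_$targets, length, 1L))))
  cat_
}

#' Write a target catalog as `miRNA <tab> gene` rows
#' @param catalog a [target_catalog].
#' @param path output file.
#' @export
write_target_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "target_catalog"))
  df <- data.frame(
    mirna = rep(names(catalog$targets), lengths(catalog$targets)),
    gene = unlist(catalog$targets, use.names = FALSE)
  )
  write_tsv(df, path)
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("Target catalog: %d miRNAs, %d genes in universe\n",
              length(x$targets), length(x$universe)))
  if (length(x$dropped)) {
    cat(sprintf("  (%d miRNAs dropped by score filtering)\n", length(x$dropped)))
  }
  invisible(x)
}

## ---- phenotype similarity --------------------------------------------

#' Construct a phenotype similarity store
#'
#' Holds the symmetric matrix of pairwise phenotypic similarity scores in
#' `[0, 1]` between disease phenotypes (MIM IDs). Identical phenotypes have
#' similarity 1, so the diagonal is fixed at 1.
#'
#' @param mat square numeric matrix with MIM IDs as dimnames; symmetrized
#'   values must agree, all entries in `[0, 1]`.
#' @return an object of class `phenotype_similarity`.
#' @export
phenotype_similarity <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("similarity matrix needs MIM IDs as dimnames", call. = FALSE)
  }
  rownames(mat) <- canon_mim(rownames(mat))
  colnames(mat) <- canon_mim(colnames(mat))
  if (!identical(rownames(mat), colnames(mat))) {
    stop("row and column phenotype IDs differ", call. = FALSE)
  }
  if (anyNA(mat) || any(mat < 0) || any(mat > 1)) {
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(mat - t(mat)) > 1e-8)) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 1
  structure(list(matrix = mat), class = "phenotype_similarity")
}

#' Diseases known to a similarity store
#' @param phenome a [phenotype_similarity].
#' @return character vector of MIM IDs.
#' @export
sim_diseases <- function(phenome) {
  stopifnot(inherits(phenome, "phenotype_similarity"))
  rownames(phenome$matrix)
}

#' Pairwise similarity score lookup
#' @param phenome a [phenotype_similarity].
#' @param a,b MIM IDs.
#' @return numeric similarity in `[0, 1]`.
#' @export
sim_score <- function(phenome, a, b) {
  stopifnot(inherits(phenome, "phenotype_similarity"))
  a <- canon_mim(a); b <- canon_mim(b)
  ids <- rownames(phenome$matrix)
  if (!all(a %in% ids) || !all(b %in% ids)) {
    stop("unknown phenotype ID", call. = FALSE)
  }
  phenome$matrix[cbind(a, b)]
}

#' Read phenotype similarity scores
#'
#' Two dialects are auto-detected by column count: (i) triples
#' `MIM <tab> MIM <tab> score`, symmetrized on read with missing self-pairs
#' filled with 1; (ii) a full square matrix with a header row and a leading
#' ID column. Conflicting duplicate triples (same pair, different score)
#' and scores outside `[0, 1]` are rejected.
#'
#' @param path TSV file (optionally gzipped).
#' @return a [phenotype_similarity].
#' @export
read_phenotype_similarity <- function(path) {
  rows <- read_tsv_rows(path)
  if (!length(rows$fields)) stop("empty similarity file: ", path, call. = FALSE)
  nf <- lengths(rows$fields)
  header <- rows$fields[[1]]
  ndata <- length(rows$fields) - 1L
  # matrix dialect: a header of phenotype IDs (with or without a corner
  # cell) followed by one row per phenotype whose leading field repeats the
  # header IDs in order; anything else with 3 columns is the triple dialect
  data_first <- if (ndata > 0) {
    canon_mim(vapply(rows$fields[-1], `[`, "", 1L))
  } else character()
  is_matrix <- ndata >= 2L && all(nf[-1] == ndata + 1L) &&
    ((length(header) == ndata + 1L &&
        identical(canon_mim(header[-1]), data_first)) ||
       (length(header) == ndata &&
          identical(canon_mim(header), data_first)))
  if (!is_matrix && !all(nf == 3L)) {
    stop_io(path, rows$lineno[which(nf != 3L)[1]],
            "expected MIM <tab> MIM <tab> score")
  }
  if (!is_matrix) {
    a <- canon_mim(vapply(rows$fields, `[`, "", 1L))
    b <- canon_mim(vapply(rows$fields, `[`, "", 2L))
    s <- parse_num(vapply(rows$fields, `[`, "", 3L))
    bad <- which(is.na(s))
    if (length(bad)) stop_io(path, rows$lineno[bad[1]], "score is not numeric")
    out <- which(s < 0 | s > 1)
    if (length(out)) {
      stop_io(path, rows$lineno[out[1]], "similarity score outside [0, 1]")
    }
    key <- ifelse(a <= b, paste(a, b), paste(b, a))
    for (k in unique(key[duplicated(key)])) {
      vals <- s[key == k]
      if (max(vals) - min(vals) > 1e-8) {
        stop(path, ": conflicting duplicate similarity entries for pair ", k,
             call. = FALSE)
      }
    }
    ids <- sort(unique(c(a, b)))
    mat <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    mat[cbind(a, b)] <- s
    mat[cbind(b, a)] <- s
    diag(mat) <- 1
    phenotype_similarity(mat)
  } else {
    body <- rows$fields[-1]
    ids <- canon_mim(if (length(header) == length(body) + 1L) header[-1] else header)
    mat <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(body)) {
      f <- body[[i]]
      if (length(f) != length(ids) + 1L) {
        stop_io(path, rows$lineno[-1][i], "wrong number of matrix columns")
      }
      mat[canon_mim(f[1]), ] <- parse_num(f[-1])
    }
    if (anyNA(mat)) stop(path, ": non-numeric matrix entries", call. = FALSE)
    if (any(mat < 0 | mat > 1)) {
      stop(path, ": similarity score outside [0, 1]", call. = FALSE)
    }
    phenotype_similarity(mat)
  }
}

#' Write phenotype similarity as upper-triangle triples
#'
#' Self-pairs (always 1) are omitted; the reader restores them.
#' @param phenome a [phenotype_similarity].
#' @param path output file.
#' @export
write_phenotype_similarity <- function(phenome, path) {
  stopifnot(inherits(phenome, "phenotype_similarity"))
  m <- phenome$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(a = rownames(m)[idx[, 1]], b = colnames(m)[idx[, 2]],
                   s = m[idx])
  write_tsv(df, path)
}

#' @export
print.phenotype_similarity <- function(x, ...) {
  cat(sprintf("Phenotype similarity store: %d diseases\n", nrow(x$matrix)))
  invisible(x)
}

## ---- association set --------------------------------------------------

#' Construct a set of known miRNA-disease associations
#'
#' @param mirna,disease character vectors of equal length (one association
#'   per element); duplicates are removed.
#' @return an object of class `association_set` with element `pairs`, a
#'   data frame with columns `mirna` and `disease`.
#' @export
association_set <- function(mirna = character(), disease = character()) {
  stopifnot(length(mirna) == length(disease))
  df <- unique(data.frame(mirna = canon_mirna(mirna),
                          disease = canon_mim(disease)))
  df <- df[order(df$mirna, df$disease), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df), class = "association_set")
}

#' Read known miRNA-disease associations
#' @param path TSV of `miRNA <tab> MIM` rows.
#' @return an [association_set] (duplicates removed, counts logged).
#' @export
read_associations <- function(path) {
  rows <- read_tsv_rows(path)
  if (!length(rows$fields)) stop("empty association file: ", path, call. = FALSE)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop_io(path, rows$lineno[bad[1]], "expected 2 fields (miRNA, MIM)")
  }
  as_ <- association_set(vapply(rows$fields, `[`, "", 1L),
                         vapply(rows$fields, `[`, "", 2L))
  message(sprintf("associations: %d unique pairs (%d rows read)",
                  nrow(as_$pairs), length(rows$fields)))
  as_
}

#' Write associations as `miRNA <tab> MIM` rows
#' @param associations an [association_set].
#' @param path output file.
#' @export
write_associations <- function(associations, path) {
  stopifnot(inherits(associations, "association_set"))
  write_tsv(associations$pairs, path)
}

#' Remove associations without mutating the original set
#'
#' Exactly one removal rule applies per call: drop one exact pair, drop
#' every association of one disease, or drop the pairs of one disease whose
#' miRNA falls in a given set (used for the family-holdout evaluation).
#'
#' @param associations an [association_set].
#' @param mirna,disease the pair to drop (`assoc_remove_pair`), the disease
#'   to drop (`assoc_remove_disease`), or the disease whose associations
#'   with `mirnas` to drop (`assoc_remove_mirnas`).
#' @param mirnas character vector of miRNA IDs.
#' @return a new [association_set].
#' @export
assoc_remove_pair <- function(associations, mirna, disease) {
  stopifnot(inherits(associations, "association_set"))
  p <- associations$pairs
  keep <- !(p$mirna == canon_mirna(mirna) & p$disease == canon_mim(disease))
  association_set(p$mirna[keep], p$disease[keep])
}

#' @rdname assoc_remove_pair
#' @export
assoc_remove_disease <- function(associations, disease) {
  stopifnot(inherits(associations, "association_set"))
  p <- associations$pairs
  keep <- p$disease != canon_mim(disease)
  association_set(p$mirna[keep], p$disease[keep])
}

#' @rdname assoc_remove_pair
#' @export
assoc_remove_mirnas <- function(associations, disease, mirnas) {
  stopifnot(inherits(associations, "association_set"))
  p <- associations$pairs
  keep <- !(p$disease == canon_mim(disease) & p$mirna %in% canon_mirna(mirnas))
  association_set(p$mirna[keep], p$disease[keep])
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("Association set: %d miRNA-disease pairs (%d miRNAs, %d diseases)\n",
              nrow(x$pairs), length(unique(x$pairs$mirna)),
              length(unique(x$pairs$disease))))
  invisible(x)
}

## ---- family map -------------------------------------------------------

#' Construct a miRNA family map
#'
#' Partial map from miRNA ID to family ID; a miRNA belongs to at most one
#' family (seed-sharing miRBase-style families).
#'
#' @param family named character vector: `names` are miRNA IDs, values are
#'   family IDs.
#' @return an object of class `family_map`.
#' @export
family_map <- function(family = character()) {
  if (length(family) && is.null(names(family))) {
    stop("`family` must be a named vector (names are miRNA IDs)", call. = FALSE)
  }
  names(family) <- canon_mirna(names(family))
  family <- family[!duplicated(cbind(names(family), family))]
  dup <- unique(names(family)[duplicated(names(family))])
  if (length(dup)) {
    stop("miRNA(s) listed under more than one family: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family[order(names(family))]), class = "family_map")
}

#' Read a miRNA family map
#' @param path TSV of `family <tab> miRNA` rows.
#' @return a [family_map].
#' @export
read_family_map <- function(path) {
  rows <- read_tsv_rows(path)
  if (!length(rows$fields)) stop("empty family file: ", path, call. = FALSE)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop_io(path, rows$lineno[bad[1]], "expected 2 fields (family, miRNA)")
  }
  fam <- trimws(vapply(rows$fields, `[`, "", 1L))
  mir <- vapply(rows$fields, `[`, "", 2L)
  fm <- family_map(stats::setNames(fam, mir))
  message(sprintf("families: %d miRNAs in %d families",
                  length(fm$family), length(unique(fm$family))))
  fm
}

#' Write a family map as `family <tab> miRNA` rows
#' @param fm a [family_map].
#' @param path output file.
#' @export
write_family_map <- function(fm, path) {
  stopifnot(inherits(fm, "family_map"))
  write_tsv(data.frame(family = unname(fm$family), mirna = names(fm$family)),
            path)
}

#' Family of a miRNA, or `NA` when unmapped
#' @param fm a [family_map].
#' @param mirna miRNA ID(s).
#' @return character vector of family IDs (NA where unmapped).
#' @export
family_of <- function(fm, mirna) {
  stopifnot(inherits(fm, "family_map"))
  unname(fm$family[canon_mirna(mirna)])
}
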