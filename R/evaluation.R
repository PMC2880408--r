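# Leave-one-out cross-validation and ROC/AUC summaries.
#
# Each known association <m, d> is held out in turn; the "defector" miRNA m
# must be recovered by prioritizing the whole network microRNAome for d.
# Four variants differ in what else is removed before scoring:
#   standard        - only <m, d> itself
#   disease_holdout - every association of d (emulates a disease with no
#                     known miRNAs)
#   family_holdout  - <m, d> plus d's associations with miRNAs of m's
#                     family (controls the seed-family confounder)
#   random_control  - the association set is replaced by uniformly random
#                     pairs of the same size, then standard LOOCV is run

#' Construct a LOOCV result container
#'
#' Normally produced by [loocv()]; the constructor is exported so that
#' rankings obtained elsewhere can reuse the ROC machinery.
#'
#' @param records data frame with columns `mirna`, `disease`, `rank`
#'   (defector rank, average-rank convention, may be fractional) and
#'   `list_size` (length of the ranked list).
#' @param variant label of the evaluation variant.
#' @param n_skipped number of held-out associations that could not be
#'   evaluated (defector absent from the network, or disease unknown).
#' @return an object of class `loocv_result`.
#' @export
loocv_result <- function(records, variant = "standard", n_skipped = 0L) {
  records <- as.data.frame(records)
  need <- c("mirna", "disease", "rank", "list_size")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) &&
      (any(records$rank < 1) || any(records$rank > records$list_size))) {
    stop("ranks must lie in [1, list_size]", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, variant = variant,
                 n_skipped = as.integer(n_skipped)),
            class = "loocv_result")
}

#' Leave-one-out cross-validation of the prioritization model
#'
#' @param fit a fitted [mirphen()] model.
#' @param variant one of `"standard"`, `"disease_holdout"`,
#'   `"family_holdout"`, `"random_control"`.
#' @param family_map a [family_map]; required for `family_holdout`.
#' @param seed integer; required for `random_control` (drives the random
#'   association set).
#' @return a [loocv_result()]; held-out associations whose defector is not
#'   a network node, or whose disease is unknown to the phenome, are
#'   skipped with a warning and counted in `n_skipped`.
#' @export
loocv <- function(fit, variant = c("standard", "disease_holdout",
                                   "family_holdout", "random_control"),
                  family_map = NULL, seed = NULL) {
  stopifnot(inherits(fit, "mirphen"))
  variant <- match.arg(variant)
  if (variant == "family_holdout" && !inherits(family_map, "family_map")) {
    stop("family_holdout requires a family_map", call. = FALSE)
  }
  if (variant == "random_control" && is.null(seed)) {
    stop("random_control requires a seed", call. = FALSE)
  }
  assoc <- fit$associations
  if (variant == "random_control") {
    assoc <- with_seed(seed, random_associations(
      n = nrow(fit$associations$pairs),
      mirnas = fit$network$nodes,
      diseases = sim_diseases(fit$phenome)
    ))
  }
  pairs <- assoc$pairs
  nodes <- fit$network$nodes
  phen <- rownames(fit$phenome$matrix)
  evaluable <- pairs$mirna %in% nodes & pairs$disease %in% phen
  n_skipped <- sum(!evaluable)
  if (n_skipped) {
    warning(n_skipped, " association(s) skipped (defector not a network node",
            " or disease unknown to phenome)", call. = FALSE)
  }
  pairs <- pairs[evaluable, , drop = FALSE]
  records <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna[i]
    d <- pairs$disease[i]
    reduced <- switch(
      variant,
      standard = ,
      random_control = assoc_remove_pair(assoc, m, d),
      disease_holdout = assoc_remove_disease(assoc, d),
      family_holdout = {
        fam <- family_of(family_map, m)
        if (is.na(fam)) {
          assoc_remove_pair(assoc, m, d)
        } else {
          kin <- names(family_map$family)[family_map$family == fam]
          assoc_remove_mirnas(assoc, d, union(kin, m))
        }
      }
    )
    r <- prioritize(fit$network, fit$phenome, reduced, d,
                    cutoff = fit$similarity_cutoff, tail = fit$tail)
    records[[i]] <- data.frame(mirna = m, disease = d,
                               rank = r$rank[match(m, r$mirna)],
                               list_size = nrow(r))
  }
  loocv_result(do.call(rbind, c(records, list(make.row.names = FALSE))),
               variant = variant, n_skipped = n_skipped)
}

# Uniformly random distinct (network miRNA, phenome disease) pairs.
random_associations <- function(n, mirnas, diseases) {
  total <- length(mirnas) * length(diseases)
  if (n > total) stop("cannot draw ", n, " distinct pairs", call. = FALSE)
  cells <- sample.int(total, n) - 1L
  association_set(mirnas[cells %% length(mirnas) + 1L],
                  diseases[cells %/% length(mirnas) + 1L])
}

#' Sensitivity and specificity at a rank threshold
#'
#' Sensitivity is the fraction of defector miRNAs recovered at rank
#' `threshold` or better; specificity is the mean fraction of the ranked
#' list lying beyond the threshold (out of the `list_size - 1`
#' non-defector positions).
#'
#' @param result a [loocv_result()].
#' @param threshold rank cutoff in `[1, list_size]`.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(result, threshold) {
  stopifnot(inherits(result, "loocv_result"))
  rec <- result$records
  if (!nrow(rec)) stop("empty LOOCV result", call. = FALSE)
  if (threshold < 1 || threshold > max(rec$list_size)) {
    stop("threshold outside [1, list size]", call. = FALSE)
  }
  sens <- mean(rec$rank <= threshold)
  spec <- mean(pmin(1, pmax(0, (rec$list_size - threshold) /
                                 (rec$list_size - 1))))
  c(sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC from LOOCV defector ranks
#'
#' Sweeps the rank threshold over every attained defector rank (plus the
#' two degenerate endpoints), recording sensitivity and specificity at
#' each, and integrates sensitivity over (1 - specificity) as a step
#' function. With a common list size this equals the mean over cases of
#' `(list_size - rank) / (list_size - 1)`; tied candidates carry their
#' average rank, so the AUC is invariant to tie order.
#'
#' @param result a [loocv_result()] with at least one case and list sizes
#'   greater than 1.
#' @return an object of class `roc_curve`: a data frame with columns
#'   `threshold`, `sensitivity`, `specificity`, with the AUC in
#'   `attr(, "auc")` (also `$auc` via the print method).
#' @export
roc_auc <- function(result) {
  stopifnot(inherits(result, "loocv_result"))
  rec <- result$records
  if (!nrow(rec)) stop("empty LOOCV result", call. = FALSE)
  if (any(rec$list_size <= 1)) {
    stop("AUC undefined for ranked lists of size 1", call. = FALSE)
  }
  thr <- sort(unique(c(0, rec$rank, max(rec$list_size))))
  sens <- vapply(thr, function(t) mean(rec$rank <= t), 0)
  spec <- vapply(thr, function(t) {
    mean(pmin(1, pmax(0, (rec$list_size - t) / (rec$list_size - 1))))
  }, 0)
  x <- 1 - spec
  # sensitivity is constant on [thr_j, thr_{j+1}); step integration in x
  auc <- sum(sens[-length(sens)] * diff(x))
  curve <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  structure(curve, class = c("roc_curve", "data.frame"), auc = auc,
            variant = result$variant)
}

#' AUC of a LOOCV result
#' @param result a [loocv_result()].
#' @return the area under the ROC curve, in `[0, 1]`.
#' @export
auc <- function(result) attr(roc_auc(result), "auc")

#' Write LOOCV per-case records / an ROC curve to TSV
#' @param result a [loocv_result()].
#' @param path output file.
#' @export
write_loocv <- function(result, path) {
  stopifnot(inherits(result, "loocv_result"))
  df <- result$records
  df$variant <- result$variant
  write_tsv(df, path)
}

#' @rdname write_loocv
#' @param curve a `roc_curve`.
#' @export
write_roc <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  write_tsv(as.data.frame(curve), path)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV result (%s): %d cases", x$variant, nrow(x$records)))
  if (x$n_skipped) cat(sprintf(", %d skipped", x$n_skipped))
  cat("\n")
  if (nrow(x$records)) {
    cat(sprintf("  defector rank: median %.1f of %d;  AUC = %.4f\n",
                stats::median(x$records$rank), max(x$records$list_size),
                auc(x)))
  }
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve (%s): %d thresholds, AUC = %.4f\n",
              attr(x, "variant"), nrow(x), attr(x, "auc")))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", attr(x, "auc")))
  invisible(x)
}
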