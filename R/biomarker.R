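#' Indicator-value (IndVal) analysis
#'
#' Dufrene-Legendre indicator statistic for a two-group study: for species
#' \code{i} and group \code{g}, specificity \code{A = mean abundance in g /
#' sum over groups of mean abundances} and fidelity \code{B = fraction of
#' g's samples where the species is detected} (screened-in abundance > 0);
#' \code{indval_i = max_g A * B}, reported with the group attaining the
#' maximum. Significance by group-label permutation with the add-one
#' convention. Species absent everywhere are skipped with a message.
#' The statistic is invariant to rescaling all abundances by a positive
#' constant.
#'
#' @param study an \code{\link{abundance_study}} with two groups, each with
#'   at least 2 samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed.
#' @return data.frame sorted by decreasing indval: species, group, A, B,
#'   indval, p.
#' @export
indval <- function(study, n_perm = 999, seed = NULL) {
  stopifnot(inherits(study, "abundance_study"))
  g <- study$groups
  if (nlevels(g) != 2L) stop("indval needs exactly two groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  M <- study$matrix
  zero <- rowSums(M) == 0
  if (any(zero)) {
    message("skipping ", sum(zero), " species absent from every sample")
    M <- M[!zero, , drop = FALSE]
  }
  if (nrow(M) == 0L) stop("no species with nonzero abundance")
  D <- (M > 0) * 1
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])

  stat <- function(lab1) {  # lab1: logical, membership of group 1
    m1 <- rowSums(M[, lab1, drop = FALSE]) / n1
    m2 <- rowSums(M[, !lab1, drop = FALSE]) / n2
    A1 <- m1 / (m1 + m2)
    B1 <- rowSums(D[, lab1, drop = FALSE]) / n1
    B2 <- rowSums(D[, !lab1, drop = FALSE]) / n2
    iv1 <- A1 * B1
    iv2 <- (1 - A1) * B2
    cbind(iv1, iv2)
  }
  lab1 <- g == levels(g)[1]
  iv <- stat(lab1)
  best <- max.col(iv, ties.method = "first")
  obs <- iv[cbind(seq_len(nrow(iv)), best)]

  if (!is.null(seed)) set.seed(seed)
  exceed <- integer(nrow(M))
  for (b in seq_len(n_perm)) {
    pv <- stat(sample(lab1))
    pmax_iv <- pmax(pv[, 1], pv[, 2])
    exceed <- exceed + (pmax_iv >= obs - 1e-12)
  }
  m1 <- rowSums(M[, lab1, drop = FALSE]) / n1
  m2 <- rowSums(M[, !lab1, drop = FALSE]) / n2
  A <- ifelse(best == 1L, m1 / (m1 + m2), m2 / (m1 + m2))
  B <- ifelse(best == 1L,
              rowSums(D[, lab1, drop = FALSE]) / n1,
              rowSums(D[, !lab1, drop = FALSE]) / n2)
  out <- data.frame(
    species = rownames(M),
    group = levels(g)[best],
    A = A, B = B, indval = obs,
    p = (1 + exceed) / (1 + n_perm),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$indval, out$species), , drop = FALSE]
}

#' Simplified LEfSe-style differential abundance ranking
#'
#' A documented simplification of the LEfSe procedure used to rank taxa
#' between two classes: a per-taxon Kruskal-Wallis test selects survivors at
#' \code{alpha}, then abundances are scaled (default to a per-million scale)
#' and the effect size is \code{log10(|mean_1 - mean_2| + 1)}, signed
#' positive when the taxon is enriched in the first group level. The
#' bootstrap-LDA internals of published LEfSe are deliberately not
#' reproduced; this score preserves the ranking/display role.
#'
#' @param study an \code{\link{abundance_study}} with two groups.
#' @param alpha Kruskal-Wallis significance cutoff (default 0.05).
#' @param scale abundance scaling factor before the mean difference
#'   (default 1e6).
#' @return data.frame sorted by decreasing |effect|: species, kw_p,
#'   enriched_group, lda_like_score. Constant taxa are excluded.
#' @export
lefse_lite <- function(study, alpha = 0.05, scale = 1e6) {
  stopifnot(inherits(study, "abundance_study"))
  g <- study$groups
  if (nlevels(g) != 2L) stop("lefse_lite needs exactly two groups")
  M <- study$matrix
  rows <- list()
  for (i in seq_len(nrow(M))) {
    x <- M[i, ]
    if (length(unique(x)) == 1L) next  # constant taxon: kw_p = 1, excluded
    kw <- suppressWarnings(kruskal.test(x, g))
    p <- kw$p.value
    if (is.na(p) || p >= alpha) next
    xm <- tapply(x * scale, g, mean)
    effect <- log10(abs(xm[1] - xm[2]) + 1)
    enriched <- names(xm)[which.max(xm)]
    signed <- if (enriched == levels(g)[1]) effect else -effect
    rows[[length(rows) + 1L]] <- data.frame(
      species = rownames(M)[i], kw_p = p, enriched_group = enriched,
      lda_like_score = unname(signed), stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(species = character(0), kw_p = numeric(0),
                      enriched_group = character(0),
                      lda_like_score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-abs(out$lda_like_score), out$species), , drop = FALSE]
}

#' Random-forest feature importance for group discrimination
#'
#' Trains a random forest (bagged decision trees, \code{mtry =
#' floor(sqrt(p))}) on species abundances as features and returns both
#' importance measures: mean decrease in Gini impurity and mean decrease in
#' out-of-bag accuracy under per-feature permutation. Deterministic given
#' the seed; ties in the output ordering are broken by species name.
#' Backed by \code{randomForest::randomForest}.
#'
#' @param study an \code{\link{abundance_study}} with at least 2 samples per
#'   group.
#' @param n_trees number of trees (default 500).
#' @param seed optional RNG seed.
#' @return data.frame sorted by decreasing Gini importance: species,
#'   mean_decrease_gini, mean_decrease_accuracy.
#' @export
ensemble_importance <- function(study, n_trees = 500, seed = NULL) {
  stopifnot(inherits(study, "abundance_study"))
  y <- study$groups
  if (nlevels(y) < 2L) stop("group labels are single-class")
  if (any(table(y) < 2L)) stop("each group needs at least 2 samples")
  X <- t(study$matrix)
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(X)))), importance = TRUE
  )
  imp <- fit$importance
  out <- data.frame(
    species = rownames(imp),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    stringsAsFactors = FALSE
  )
  out[order(-out$mean_decrease_gini, out$species), , drop = FALSE]
}

#' ROC curve and AUC for a single score
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for ties:
#' the probability that a random positive-class sample scores above a random
#' negative-class sample. The curve sweeps thresholds over the observed
#' score values only, predicting positive when \code{score >= threshold}.
#'
#' @param scores numeric vector (e.g. a species' relative abundance per
#'   sample).
#' @param labels class label per sample (exactly two classes, both present).
#' @param positive the positive-class label; defaults to \code{"case"} when
#'   present, otherwise the second factor level.
#' @return list of class \code{roc_result}: \code{auc}, \code{curve}
#'   (data.frame threshold, fpr, tpr), \code{positive}, \code{n_positive},
#'   \code{n_negative}.
#' @examples
#' roc_auc(c(3, 1, 2, 0), c("case", "case", "control", "control"))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if ("case" %in% classes) "case" else sort(classes)[2]
  }
  if (!positive %in% classes) stop("positive class not present in labels")
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L) stop("one class is empty")
  r <- rank(c(pos, neg))  # midranks give half credit for ties
  n1 <- length(pos); n0 <- length(neg)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(ti) mean(neg >= ti), numeric(1)),
    tpr = vapply(thr, function(ti) mean(pos >= ti), numeric(1))
  )
  structure(
    list(auc = auc, curve = curve, positive = positive,
         n_positive = n1, n_negative = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive class '%s', %d vs %d samples)\n",
              x$auc, x$positive, x$n_positive, x$n_negative))
  invisible(x)
}
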