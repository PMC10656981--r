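#' Chao1 richness estimator (bias-corrected)
#'
#' \code{S_obs + F1 (F1 - 1) / (2 (F2 + 1))} where \code{F1} and \code{F2}
#' are the numbers of singleton and doubleton species. Chao1 is defined on
#' integer read counts, not proportions; non-integer input is an error.
#'
#' @param counts non-negative integer vector of per-species read counts.
#' @return Chao1 estimate (0 for an all-zero sample).
#' @examples
#' chao1(c(4, 3, 2, 1, 1))  # 5.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("Chao1 requires integer read counts, not proportions")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' \code{H = -sum(p log p)}; input is renormalized to proportions internally,
#' so counts are accepted.
#'
#' @param x non-negative vector of counts or proportions.
#' @return Shannon index; 0 for a single-species or empty sample.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  if (length(x) == 0L) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Simpson diversity (1 - sum p^2)
#'
#' @param x non-negative vector of counts or proportions.
#' @return Simpson index in [0, 1); 0 for a single-species or empty sample.
#' @export
simpson <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) return(0)
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Per-sample alpha diversity table
#'
#' Chao1 runs on the integer read counts (it is undefined on proportions);
#' Shannon and Simpson use the same counts renormalized.
#'
#' @param study an \code{\link{abundance_study}}.
#' @return data.frame: sample, group, chao1, shannon, simpson.
#' @export
alpha_diversity <- function(study) {
  stopifnot(inherits(study, "abundance_study"))
  cnt <- study$counts
  data.frame(
    sample = colnames(cnt),
    group = as.character(study$groups),
    chao1 = apply(cnt, 2, chao1),
    shannon = apply(cnt, 2, shannon),
    simpson = apply(cnt, 2, simpson),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis and Euclidean distances are computed on relative abundances
#' (comparable across sequencing depths); binary Jaccard on presence/absence.
#' Backed by \code{vegan::vegdist}.
#'
#' @param study an \code{\link{abundance_study}}.
#' @param metric one of \code{"bray_curtis"}, \code{"jaccard_binary"},
#'   \code{"euclidean"}.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
beta_distance <- function(study,
                          metric = c("bray_curtis", "jaccard_binary",
                                     "euclidean")) {
  stopifnot(inherits(study, "abundance_study"))
  metric <- match.arg(metric)
  if (ncol(study$matrix) < 2L) stop("need at least 2 samples")
  x <- t(study$matrix)  # vegan wants samples as rows
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    jaccard_binary = vegan::vegdist(x, method = "jaccard", binary = TRUE),
    euclidean = vegan::vegdist(x, method = "euclidean")
  )
  as.matrix(d)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances (one-way design):
#' \code{SS_T = sum_{i<j} d_ij^2 / N}, \code{SS_W = sum_g sum_{i<j in g}
#' d_ij^2 / n_g}, \code{F = (SS_A / (a-1)) / (SS_W / (N-a))}. The p-value
#' uses group-label permutation with the add-one convention
#' \code{p = (1 + #\{F* >= F\}) / (1 + n_perm)}, so the minimal attainable p
#' at 999 permutations is 0.001.
#'
#' @param dm symmetric distance matrix (or \code{dist}) with sample labels.
#' @param groups group label per sample (named vector matched against the
#'   matrix labels when names are present).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed for the permutation set.
#' @return object of class \code{permanova}: list with \code{pseudo_F},
#'   \code{p_value}, \code{df_among}, \code{df_within}, \code{n_perm}.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (!is.null(names(groups)) && !is.null(rownames(dm))) {
    if (!setequal(names(groups), rownames(dm))) {
      stop("group names do not match distance matrix labels")
    }
    groups <- groups[rownames(dm)]
  }
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 samples; sizes: ",
         paste(table(g), collapse = ", "))
  }
  d2 <- dm^2
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / n
  if (ss_total <= .Machine$double.eps) {
    # no multivariate variation at all: nothing to partition
    return(structure(
      list(pseudo_F = NaN, p_value = 1, df_among = nlevels(g) - 1L,
           df_within = n - nlevels(g), n_perm = n_perm),
      class = "permanova"))
  }

  pseudo_f <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    a <- nlevels(g)
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f(g)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (pseudo_f(sample(g)) >= f_obs) exceed <- exceed + 1L
  }
  structure(
    list(pseudo_F = f_obs, p_value = (1 + exceed) / (1 + n_perm),
         df_among = nlevels(g) - 1L, df_within = n - nlevels(g),
         n_perm = n_perm),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_among, x$df_within, x$p_value, x$n_perm))
  invisible(x)
}

#' Wilcoxon rank test between two groups
#'
#' Unpaired rank-sum by default; exact enumeration when both groups have at
#' most 10 observations and no ties, otherwise the normal approximation with
#' tie correction (both via \code{stats::wilcox.test}). In paired mode with
#' identical vectors (no nonzero differences) the p-value is 1 by contract.
#'
#' @param x,y numeric vectors (equal length required when \code{paired}).
#' @param paired logical.
#' @return list with \code{statistic}, \code{p_value}, \code{method}.
#' @export
rank_sum_test <- function(x, y, paired = FALSE) {
  if (length(x) == 0L || length(y) == 0L) stop("empty input vector")
  if (paired && length(x) != length(y)) {
    stop("paired mode requires equal-length vectors")
  }
  if (paired && all(x == y)) {
    return(list(statistic = NA_real_, p_value = 1,
                method = "Wilcoxon signed rank (no nonzero differences)"))
  }
  use_exact <- length(x) <= 10L && length(y) <= 10L
  wt <- suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Shared and unique species between two groups
#'
#' A species is detected in a group when it is screened-in (abundance > 0)
#' in at least one sample of the group (the default rule); detection in both
#' groups makes it shared.
#'
#' @param study an \code{\link{abundance_study}} with exactly two groups.
#' @param min_samples minimum number of group samples with nonzero abundance
#'   for detection (default 1).
#' @return list with \code{shared}, \code{unique_<group1>},
#'   \code{unique_<group2>} counts, the corresponding \code{percent} vector,
#'   and \code{species} (the membership per species).
#' @export
venn_counts <- function(study, min_samples = 1L) {
  stopifnot(inherits(study, "abundance_study"))
  if (nlevels(study$groups) != 2L) stop("venn_counts needs exactly two groups")
  levs <- levels(study$groups)
  pres <- study$matrix > 0
  det <- sapply(levs, function(lev) {
    rowSums(pres[, study$groups == lev, drop = FALSE]) >= min_samples
  })
  member <- ifelse(det[, 1] & det[, 2], "shared",
                   ifelse(det[, 1], paste0("unique_", levs[1]),
                          ifelse(det[, 2], paste0("unique_", levs[2]),
                                 "absent")))
  names(member) <- rownames(study$matrix)
  keys <- c("shared", paste0("unique_", levs[1]), paste0("unique_", levs[2]))
  counts <- setNames(vapply(keys, function(k) sum(member == k), integer(1)),
                     keys)
  total <- sum(counts)
  list(shared = counts[[1]],
       unique_1 = counts[[2]], unique_2 = counts[[3]],
       counts = counts,
       percent = if (total > 0) 100 * counts / total else counts * NA_real_,
       species = member[member != "absent"])
}

#' Inter-kingdom Spearman correlation network
#'
#' Aggregates species abundances to the requested taxonomic rank (summing
#' member species per sample), then computes the Spearman correlation between
#' every pair of taxa drawn from the two kingdoms of \code{scope}, within
#' each group of samples. Edges with \code{|rho|} below the threshold are
#' dropped.
#'
#' @param study an \code{\link{abundance_study}} whose \code{taxonomy}
#'   carries the requested rank column and a \code{kingdom} column.
#' @param level taxonomic rank to aggregate to (\code{"species"},
#'   \code{"genus"}, \code{"phylum"}, ...).
#' @param scope length-2 character: the two kingdoms to correlate
#'   (default bacteria vs fungi).
#' @param rho_threshold drop edges with \code{|rho|} below this (default 0,
#'   i.e. keep all).
#' @return data.frame edge list: taxon1, taxon2, rho, p, group.
#' @export
correlation_network <- function(study, level = "genus",
                                scope = c("bacteria", "fungi"),
                                rho_threshold = 0) {
  stopifnot(inherits(study, "abundance_study"))
  tax <- study$taxonomy
  if (is.null(tax)) stop("study has no taxonomy table")
  if (!level %in% names(tax)) {
    stop("rank '", level, "' absent from taxonomy (has: ",
         paste(setdiff(names(tax), "species"), collapse = ", "), ")")
  }
  if (!"kingdom" %in% names(tax)) stop("taxonomy needs a 'kingdom' column")
  tax <- tax[match(rownames(study$matrix), tax$species), , drop = FALSE]
  if (any(is.na(tax$species))) stop("taxonomy does not cover all study species")

  agg <- rowsum(study$matrix, group = tax[[level]])
  taxon_kingdom <- tapply(tax$kingdom, tax[[level]], function(k) unique(k)[1])
  set1 <- rownames(agg)[taxon_kingdom[rownames(agg)] == scope[1]]
  set2 <- rownames(agg)[taxon_kingdom[rownames(agg)] == scope[2]]

  edges <- list()
  for (lev in levels(study$groups)) {
    cols <- study$groups == lev
    for (a in set1) for (b in set2) {
      ct <- suppressWarnings(
        cor.test(agg[a, cols], agg[b, cols], method = "spearman",
                 exact = FALSE)
      )
      rho <- unname(ct$estimate)
      if (is.na(rho) || abs(rho) < rho_threshold) next
      edges[[length(edges) + 1L]] <- data.frame(
        taxon1 = a, taxon2 = b, rho = rho, p = ct$p.value, group = lev,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(taxon1 = character(0), taxon2 = character(0),
                      rho = numeric(0), p = numeric(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
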