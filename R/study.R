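#' Two-group abundance study container
#'
#' Holds the species-by-sample relative-abundance matrix, the matching
#' integer read-count matrix, per-sample group labels, and (optionally) a
#' taxonomy table giving each species' lineage. Columns of the abundance
#' matrix sum to 1 over detected species, or are all zero for an empty sample.
#'
#' @param matrix numeric species x samples matrix of relative abundances
#'   (dimnames required).
#' @param counts integer species x samples matrix of assigned read counts,
#'   same shape and dimnames.
#' @param groups named character vector or factor: sample -> group label
#'   (names may be omitted if already ordered like \code{colnames(matrix)}).
#' @param taxonomy optional data.frame with a \code{species} column plus rank
#'   columns (\code{kingdom}, \code{phylum}, \code{genus}, ...).
#' @return object of class \code{abundance_study} with fields \code{matrix},
#'   \code{counts}, \code{groups} (factor), \code{kingdom} (named vector or
#'   NULL), \code{taxonomy}.
#' @export
abundance_study <- function(matrix, counts = NULL, groups, taxonomy = NULL) {
  if (is.null(dimnames(matrix)) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix))) {
    stop("abundance matrix needs species rownames and sample colnames")
  }
  if (is.null(counts)) {
    counts <- matrix * 0L
    storage.mode(counts) <- "integer"
  }
  if (!identical(dim(matrix), dim(counts)) ||
      !identical(dimnames(matrix), dimnames(counts))) {
    stop("matrix and counts must share shape and dimnames")
  }
  cs <- colSums(matrix)
  bad <- which(abs(cs - 1) > 1e-6 & cs != 0)
  if (length(bad) > 0L) {
    stop("abundance columns must sum to 1 (or 0 for empty samples); offending: ",
         paste(colnames(matrix)[bad], collapse = ", "))
  }
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(matrix))) {
      stop("group labels do not cover the study samples")
    }
    groups <- groups[colnames(matrix)]
  } else if (length(groups) != ncol(matrix)) {
    stop("length(groups) must equal the number of samples")
  }
  groups <- factor(as.character(groups))
  kingdom <- NULL
  if (!is.null(taxonomy)) {
    if (!"species" %in% names(taxonomy)) {
      stop("taxonomy needs a 'species' column")
    }
    if ("kingdom" %in% names(taxonomy)) {
      kingdom <- setNames(taxonomy$kingdom, taxonomy$species)[rownames(matrix)]
      names(kingdom) <- rownames(matrix)
    }
  }
  structure(
    list(matrix = matrix, counts = counts, groups = groups,
         kingdom = kingdom, taxonomy = taxonomy),
    class = "abundance_study"
  )
}

#' @export
print.abundance_study <- function(x, ...) {
  cat("Abundance study: ", nrow(x$matrix), " species x ", ncol(x$matrix),
      " samples\n", sep = "")
  cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                 table(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$kingdom)) {
    cat("  kingdoms:", paste(sprintf("%s (%d)", names(table(x$kingdom)),
                                     table(x$kingdom)), collapse = ", "), "\n")
  }
  invisible(x)
}
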