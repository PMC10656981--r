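#' Assign tag reads to species-specific markers
#'
#' Each read is truncated to the tag length, canonicalized, and matched
#' exactly (0 mismatches) against the marker index. A hit increments
#' \code{S} of the marker's species and adds the marker to that species'
#' observed set, whose size is \code{t}. Reads shorter than the tag length,
#' or containing non-ACGT bases in the tag window, are counted as unassigned.
#'
#' @param reads character vector of read sequences (see
#'   \code{\link{read_fastq}} / \code{\link{read_fasta}} for files).
#' @param db a \code{\link{build_marker_db}} result.
#' @return data.frame with one row per database species carrying markers:
#'   \code{species}, \code{S} (reads assigned), \code{t} (distinct markers
#'   observed), \code{T} (markers in the database). Attributes
#'   \code{n_reads_total}, \code{n_reads_assigned}, \code{n_reads_short}.
#' @export
assign_reads <- function(reads, db) {
  stopifnot(inherits(db, "marker_db"))
  if (length(reads) == 0L) stop("empty read set")
  if (length(db$markers) == 0L) stop("marker database is empty")
  L <- db$enzyme$tag_length

  short <- nchar(reads) < L
  prefix <- substr(reads[!short], 1L, L)
  valid <- grepl("^[ACGT]+$", prefix)
  canon <- canonicalize(prefix[valid])
  idx <- match(canon, names(db$markers))
  hit <- !is.na(idx)
  sp_hit <- unname(db$markers[idx[hit]])
  marker_hit <- names(db$markers)[idx[hit]]

  species <- names(db$species_marker_count)
  S <- as.integer(table(factor(sp_hit, levels = species)))
  t_obs <- integer(length(species))
  if (any(hit)) {
    uniq <- !duplicated(marker_hit)
    t_tab <- table(factor(sp_hit[uniq], levels = species))
    t_obs <- as.integer(t_tab)
  }
  out <- data.frame(species = species, S = S, t = t_obs,
                    T = as.integer(db$species_marker_count),
                    stringsAsFactors = FALSE)
  attr(out, "n_reads_total") <- length(reads)
  attr(out, "n_reads_assigned") <- sum(hit)
  attr(out, "n_reads_short") <- sum(short)
  out
}

#' G score
#'
#' \code{G = sqrt(S * t)}, where \code{S} is the number of reads assigned to
#' a species' markers in a sample and \code{t} the number of distinct markers
#' observed. Vectorized.
#'
#' @param S,t non-negative numbers.
#' @return \code{sqrt(S * t)}.
#' @examples
#' g_score(9, 4)  # 6
#' @export
g_score <- function(S, t) {
  if (any(S < 0) || any(t < 0)) stop("S and t must be non-negative")
  sqrt(S * t)
}

#' Screen candidate species by G score
#'
#' Species with G scores at or above the threshold (default 5) are retained
#' as candidate species to control false positives. The boundary is inclusive
#' by default (a printed threshold value of exactly 5 passes); set
#' \code{strict = TRUE} for a strict inequality.
#'
#' @param quants data.frame with columns \code{S}, \code{t} (a
#'   \code{g_score} column is computed if absent).
#' @param threshold G-score threshold, default 5.
#' @param strict logical; if TRUE retain only \code{g_score > threshold}.
#' @return the subset of rows passing the screen, with \code{g_score} column.
#'   Species with no assigned reads are never candidates, whatever the
#'   threshold.
#' @export
screen_candidates <- function(quants, threshold = 5, strict = FALSE) {
  if (is.null(quants$g_score)) quants$g_score <- g_score(quants$S, quants$t)
  keep <- if (strict) quants$g_score > threshold else quants$g_score >= threshold
  quants[keep & quants$S > 0, , drop = FALSE]
}

#' Marker-normalized relative abundance
#'
#' \code{rel_abundance_i = (S_i / T_i) / sum_j (S_j / T_j)} over the screened
#' species. The denominator \code{T} is by default the species' marker total
#' in the database (\code{denominator_mode = "database"}), which normalizes
#' read counts for marker content; \code{"observed"} instead divides by the
#' markers actually observed in the sample (\code{t}).
#'
#' @param quants screened data.frame with columns \code{S}, \code{t}, \code{T}.
#' @param denominator_mode \code{"database"} (T) or \code{"observed"} (t).
#' @return \code{quants} with a \code{rel_abundance} column summing to 1.
#' @examples
#' q <- data.frame(species = c("A", "B"), S = c(30, 10),
#'                 t = c(5, 5), T = c(10, 10))
#' relative_abundance(q)$rel_abundance  # 0.75 0.25
#' @export
relative_abundance <- function(quants,
                               denominator_mode = c("database", "observed")) {
  denominator_mode <- match.arg(denominator_mode)
  if (nrow(quants) == 0L) stop("no screened species: relative abundance undefined")
  denom <- if (denominator_mode == "database") quants$T else quants$t
  if (any(denom <= 0)) {
    stop("internal error: zero denominator in relative abundance")
  }
  ratio <- quants$S / denom
  quants$rel_abundance <- ratio / sum(ratio)
  quants
}

#' Quantify one sample: reads -> screened species profile
#'
#' Runs \code{\link{assign_reads}}, computes G scores, applies the screen,
#' and computes relative abundance over the retained species. Species that
#' fail the screen stay in the table with \code{rel_abundance = NA}.
#'
#' @param reads character vector of read sequences.
#' @param db a \code{marker_db}.
#' @param sample_id sample identifier.
#' @param threshold G-score screen threshold (default 5).
#' @param denominator_mode see \code{\link{relative_abundance}}.
#' @param strict strict screen inequality, see \code{\link{screen_candidates}}.
#' @return object of class \code{sample_profile}: list with \code{sample_id},
#'   \code{quants} (species, S, t, T, g_score, screened, rel_abundance),
#'   \code{n_reads_total}, \code{n_reads_assigned}, \code{screen_threshold},
#'   \code{denominator_mode}.
#' @export
quantify_sample <- function(reads, db, sample_id = "sample", threshold = 5,
                            denominator_mode = c("database", "observed"),
                            strict = FALSE) {
  denominator_mode <- match.arg(denominator_mode)
  q <- assign_reads(reads, db)
  q$g_score <- g_score(q$S, q$t)
  q$screened <- (if (strict) q$g_score > threshold else q$g_score >= threshold) &
    q$S > 0
  q$rel_abundance <- NA_real_
  if (any(q$screened)) {
    scr <- relative_abundance(q[q$screened, , drop = FALSE], denominator_mode)
    q$rel_abundance[q$screened] <- scr$rel_abundance
  }
  structure(
    list(sample_id = sample_id, quants = q,
         n_reads_total = attr(q, "n_reads_total"),
         n_reads_assigned = attr(q, "n_reads_assigned"),
         screen_threshold = threshold,
         denominator_mode = denominator_mode),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  n_in <- sum(x$quants$screened)
  cat("Sample profile '", x$sample_id, "': ", x$n_reads_assigned, "/",
      x$n_reads_total, " reads assigned, ", n_in,
      " species passed G-score screen (threshold ", x$screen_threshold,
      ")\n", sep = "")
  top <- x$quants[x$quants$screened, , drop = FALSE]
  if (nrow(top) > 0L) {
    top <- top[order(-top$rel_abundance), , drop = FALSE]
    print(utils::head(top[, c("species", "S", "t", "T", "g_score",
                              "rel_abundance")], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Merge per-sample profiles into a two-group abundance study
#'
#' Builds the species-by-sample relative-abundance and read-count matrices
#' from a list of \code{\link{quantify_sample}} profiles. Screened-out
#' species get abundance 0 in that sample.
#'
#' @param profiles list of \code{sample_profile} objects.
#' @param groups named character vector: sample_id -> group label.
#' @param taxonomy optional data.frame with \code{species} plus rank columns
#'   (\code{kingdom}, \code{phylum}, \code{genus}, ...).
#' @return an \code{\link{abundance_study}}.
#' @export
profiles_to_study <- function(profiles, groups, taxonomy = NULL) {
  stopifnot(length(profiles) > 0L)
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in profiles")
  species <- sort(unique(unlist(lapply(profiles, function(p) p$quants$species))))
  rel <- matrix(0, nrow = length(species), ncol = length(ids),
                dimnames = list(species, ids))
  cnt <- matrix(0L, nrow = length(species), ncol = length(ids),
                dimnames = list(species, ids))
  for (j in seq_along(profiles)) {
    q <- profiles[[j]]$quants
    i <- match(q$species, species)
    ra <- q$rel_abundance
    ra[!q$screened | is.na(ra)] <- 0
    rel[i, j] <- ra
    cnt[i, j] <- q$S
  }
  abundance_study(rel, cnt, groups[ids], taxonomy = taxonomy)
}
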