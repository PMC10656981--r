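#' Type IIB enzyme geometry
#'
#' A type IIB restriction enzyme cuts on both sides of its recognition site
#' and excises a fragment of fixed length. The geometry is described by an
#' IUPAC recognition pattern plus the number of flanking bases kept on each
#' side of the pattern on the top strand; the tag length is
#' \code{left_flank + nchar(recognition) + right_flank} and every extracted
#' tag has exactly this length.
#'
#' @param name enzyme name (e.g. \code{"BcgI"}).
#' @param recognition IUPAC degenerate recognition pattern. Default is the
#'   double-stranded BcgI core \code{"CGANNNNNNTGC"}.
#' @param left_flank,right_flank non-negative integers: bases kept upstream /
#'   downstream of the pattern on the top strand. Defaults give 32-bp tags.
#' @return an object of class \code{enzyme_spec} with fields \code{name},
#'   \code{recognition}, \code{left_flank}, \code{right_flank},
#'   \code{tag_length}.
#' @examples
#' bcgi <- enzyme_spec("BcgI")
#' bcgi$tag_length  # 32
#' @export
enzyme_spec <- function(name = "BcgI", recognition = "CGANNNNNNTGC",
                        left_flank = 10L, right_flank = 10L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(recognition)
  bad <- setdiff(strsplit(recognition, "")[[1]], names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC character(s) in recognition pattern: ",
         paste(unique(bad), collapse = ", "))
  }
  left_flank <- as.integer(left_flank)
  right_flank <- as.integer(right_flank)
  if (is.na(left_flank) || is.na(right_flank) ||
      left_flank < 0L || right_flank < 0L) {
    stop("left_flank and right_flank must be non-negative integers")
  }
  structure(
    list(name = name, recognition = recognition,
         left_flank = left_flank, right_flank = right_flank,
         tag_length = left_flank + nchar(recognition) + right_flank),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat("Type IIB enzyme spec:", x$name, "\n")
  cat("  recognition:", x$recognition, "\n")
  cat("  flanks: ", x$left_flank, " / ", x$right_flank,
      "  -> tag length ", x$tag_length, " bp\n", sep = "")
  invisible(x)
}

# IUPAC code -> set of bases it stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Built-in enzyme registry
#'
#' Ships the BcgI default geometry; user-defined type IIB enzymes are added by
#' constructing an \code{\link{enzyme_spec}} directly. The registry is a plain
#' named list so it extends to the other type IIB enzymes (AlfI, BsaXI, ...)
#' once their recognition patterns and flank conventions are supplied.
#'
#' @return named list of \code{enzyme_spec} objects.
#' @export
enzyme_registry <- function() {
  list(BcgI = enzyme_spec("BcgI"))
}

#' Look up an enzyme by name
#'
#' @param name enzyme name present in \code{\link{enzyme_registry}}.
#' @return an \code{enzyme_spec}.
#' @export
get_enzyme <- function(name) {
  reg <- enzyme_registry()
  if (!name %in% names(reg)) {
    stop("unknown enzyme '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Reverse complement of DNA strings
#'
#' Vectorized; accepts IUPAC ambiguity codes.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (strand-independent) tag sequence
#'
#' Returns the lexicographic minimum of a sequence and its reverse complement,
#' giving each excised duplex a single strand-independent identity.
#' Idempotent.
#'
#' @param x character vector of ACGT-only DNA strings.
#' @return character vector, same length as \code{x}.
#' @examples
#' canonicalize("TTTTGCA")  # "TGCAAAA"
#' @export
canonicalize <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (any(!grepl("^[ACGT]+$", x))) {
    stop("canonicalize() requires ACGT-only sequences")
  }
  rc <- reverse_complement(x)
  ifelse(x <= rc, x, rc)
}

#' Locate type IIB recognition sites on both strands
#'
#' Finds every position where the recognition pattern (or its reverse
#' complement) matches with full flanks available inside the sequence.
#' Overlapping matches are all reported; no greedy consumption is applied
#' since this models in-silico tag sampling, not digestion kinetics.
#'
#' @param sequence a single DNA string (character or \code{DNAString}).
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @return data.frame with columns \code{start} (0-based position of the
#'   recognition-site match on the top strand) and \code{strand}
#'   (\code{"+"} or \code{"-"}), sorted by position.
#' @export
match_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("'sequence' must be a single nonempty DNA string")
  }
  len <- nchar(sequence)
  plen <- nchar(enzyme$recognition)
  empty <- data.frame(start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (len < enzyme$tag_length) return(empty)
  subj <- Biostrings::DNAString(sequence)

  # pattern ambiguity codes are interpreted; subject letters are literal
  fwd <- Biostrings::matchPattern(enzyme$recognition, subj, fixed = "subject")
  rev <- Biostrings::matchPattern(reverse_complement(enzyme$recognition),
                                  subj, fixed = "subject")
  f0 <- BiocGenerics::start(fwd) - 1L
  r0 <- BiocGenerics::start(rev) - 1L
  # full flanks must fit inside the sequence
  f0 <- f0[f0 >= enzyme$left_flank &
             f0 + plen + enzyme$right_flank <= len]
  r0 <- r0[r0 >= enzyme$right_flank &
             r0 + plen + enzyme$left_flank <= len]
  out <- data.frame(
    start = c(f0, r0),
    strand = c(rep("+", length(f0)), rep("-", length(r0))),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract equal-length canonical tags from a genome
#'
#' In-silico digestion: one tag per matched recognition site with full flanks.
#' Tags containing any non-ACGT base are dropped (tallied in the
#' \code{n_dropped} attribute); sequences are stored in canonical orientation
#' (lexicographic minimum of tag and reverse complement). Contigs shorter than
#' the tag length contribute no tags.
#'
#' @param contigs named character vector or \code{DNAStringSet} of contig
#'   sequences for one genome.
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @param genome_id genome identifier recorded with each tag.
#' @return data.frame with columns \code{sequence} (canonical), \code{genome_id},
#'   \code{contig}, \code{start} (0-based start of the tag window on the top
#'   strand), \code{strand}; attribute \code{n_dropped} counts ambiguous tags.
#' @export
extract_tags <- function(contigs, enzyme, genome_id = "genome") {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- as.character(contigs)
  }
  if (length(contigs) == 0L) stop("empty genome: no contigs")
  if (is.null(names(contigs))) {
    names(contigs) <- paste0("contig_", seq_along(contigs))
  }
  plen <- nchar(enzyme$recognition)
  pieces <- vector("list", length(contigs))
  n_dropped <- 0L
  for (i in seq_along(contigs)) {
    seq_i <- toupper(contigs[[i]])
    sites <- match_sites(seq_i, enzyme)
    if (nrow(sites) == 0L) next
    # tag window on the top strand: the left flank of a minus-strand site lies
    # on the right side in top-strand coordinates
    ws <- ifelse(sites$strand == "+",
                 sites$start - enzyme$left_flank,
                 sites$start - enzyme$right_flank)
    raw <- substr(rep(seq_i, nrow(sites)), ws + 1L, ws + enzyme$tag_length)
    ok <- grepl("^[ACGT]+$", raw)
    n_dropped <- n_dropped + sum(!ok)
    if (!any(ok)) next
    pieces[[i]] <- data.frame(
      sequence = canonicalize(raw[ok]),
      genome_id = genome_id,
      contig = names(contigs)[i],
      start = as.integer(ws[ok]),
      strand = sites$strand[ok],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), genome_id = character(0),
                      contig = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
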