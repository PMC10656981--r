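#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; gzip-compressed input is transparent.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              format = "fasta")
  invisible(path)
}

#' Read / write FASTQ
#'
#' Reading validates the record structure (sequence and quality lengths must
#' match); qualities are not used downstream. Writing emits a constant
#' quality character since the pipeline ignores base qualities.
#'
#' @param path file path.
#' @return \code{read_fastq}: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (near line ", length(lines), ")")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) stop("empty FASTQ file: ", path)
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0L) {
    stop("malformed FASTQ: missing '@' header at line ", 4L * (bad_hdr[1] - 1L) + 1L)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    stop("malformed FASTQ: missing '+' separator at line ",
         4L * (bad_plus[1] - 1L) + 3L)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0L) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         4L * (bad_len[1] - 1L) + 2L)
  }
  setNames(toupper(seqs), sub("^@", "", sub("\\s.*$", "", hdr)))
}

#' @rdname read_fastq
#' @param reads character vector of read sequences (names used as ids when
#'   present).
#' @param quality_char constant quality character (default \code{"I"}).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  out <- character(4L * length(reads))
  out[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = length(reads))] <- reads
  out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads))] <-
    strrep(quality_char, nchar(reads))
  writeLines(out, path)
  invisible(path)
}

#' Read / write TSV tables
#'
#' Tab-separated with a header row, UTF-8, no quoting (taxon names may
#' contain commas, never tabs).
#'
#' @param path file path.
#' @return \code{read_tsv}: data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata (sample_id, group)
#'
#' @param path TSV with columns \code{sample_id} and \code{group}.
#' @return named character vector: sample_id -> group.
#' @export
read_metadata <- function(path) {
  meta <- read_tsv(path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(dup), collapse = ", "))
  }
  setNames(as.character(meta$group), meta$sample_id)
}

#' Read a genome taxonomy table
#'
#' @param path TSV with columns \code{genome_id}, \code{kingdom},
#'   \code{phylum}, \code{class}, \code{order}, \code{family}, \code{genus},
#'   \code{species} (only \code{genome_id} and \code{species} are mandatory).
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  tax <- read_tsv(path)
  miss <- setdiff(c("genome_id", "species"), names(tax))
  if (length(miss) > 0L) {
    stop("taxonomy missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- tax$genome_id[duplicated(tax$genome_id)]
  if (length(dup) > 0L) {
    stop("duplicate genome_id in taxonomy: ",
         paste(unique(dup), collapse = ", "))
  }
  tax$species <- trimws(tax$species)
  tax
}

#' Write a species x sample abundance matrix as TSV
#'
#' First column \code{species}, one column per sample.
#'
#' @param mat matrix with species rownames and sample colnames.
#' @param path output path.
#' @export
write_abundance_matrix <- function(mat, path) {
  df <- data.frame(species = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "species") stop("expected first column 'species'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  m
}
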