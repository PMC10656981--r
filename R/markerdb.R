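#' Canonical tags occurring exactly once within a genome
#'
#' Species-specific markers must first be single-copy within their genome of
#' origin; a tag whose canonical sequence occurs at two loci (including a
#' locus and its own reverse-complement occurrence elsewhere) is excluded.
#'
#' @param tags data.frame from \code{\link{extract_tags}} (column
#'   \code{sequence}), or a character vector of canonical tag sequences, all
#'   from one genome.
#' @return sorted character vector of canonical sequences with multiplicity 1.
#' @export
within_genome_unique <- function(tags) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (length(seqs) == 0L) return(character(0))
  tab <- table(seqs)
  sort(names(tab)[tab == 1L])
}

#' Build a species-specific marker database
#'
#' A canonical tag is a marker for species \code{s} iff (i) it is single-copy
#' within every genome where it occurs and (ii) it occurs in genomes of no
#' other species ("no overlap with other species"). When a species has several
#' genomes, the union of its genomes' tags is considered, with the single-copy
#' requirement enforced per genome. \code{T_i} is the number of distinct
#' marker sequences of species \code{i}; species ending up with zero markers
#' stay in the index (without a \code{T_i} entry) and are reported via
#' \code{message()}.
#'
#' @param genomes named list: genome_id -> contigs (named character vector or
#'   \code{DNAStringSet}).
#' @param taxonomy data.frame with at least columns \code{genome_id} and
#'   \code{species} (see \code{\link{read_taxonomy}}); species strings are
#'   whitespace-trimmed, no further normalization.
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @return object of class \code{marker_db}: list with \code{markers} (named
#'   character vector, canonical sequence -> species, sorted by sequence),
#'   \code{species_marker_count} (named integer \code{T_i}), \code{species}
#'   (all species seen), \code{zero_marker_species}, \code{enzyme},
#'   \code{provenance}.
#' @export
build_marker_db <- function(genomes, taxonomy, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"), is.list(genomes))
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) stop("genomes must be a named list")
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(taxonomy$genome_id)) {
    stop("duplicate genome_id in taxonomy: ",
         paste(unique(taxonomy$genome_id[duplicated(taxonomy$genome_id)]),
               collapse = ", "))
  }
  missing_tax <- setdiff(ids, taxonomy$genome_id)
  if (length(missing_tax) > 0L) {
    stop("genome(s) without taxonomy record: ",
         paste(missing_tax, collapse = ", "))
  }
  species_of_genome <- setNames(trimws(taxonomy$species), taxonomy$genome_id)
  if (any(!nzchar(species_of_genome[ids]))) {
    stop("empty species name in taxonomy")
  }

  per_genome <- vector("list", length(ids))
  n_dropped <- 0L
  for (i in seq_along(ids)) {
    tg <- extract_tags(genomes[[i]], enzyme, genome_id = ids[i])
    n_dropped <- n_dropped + attr(tg, "n_dropped")
    if (nrow(tg) == 0L) next
    cnt <- table(tg$sequence)
    per_genome[[i]] <- data.frame(
      sequence = names(cnt),
      count = as.integer(cnt),
      species = species_of_genome[[ids[i]]],
      stringsAsFactors = FALSE
    )
  }
  all_tags <- do.call(rbind, per_genome[!vapply(per_genome, is.null, logical(1))])
  all_species <- sort(unique(species_of_genome[ids]))

  markers <- character(0)
  if (!is.null(all_tags) && nrow(all_tags) > 0L) {
    n_sp <- tapply(all_tags$species, all_tags$sequence,
                   function(s) length(unique(s)))
    max_count <- tapply(all_tags$count, all_tags$sequence, max)
    keep <- names(n_sp)[n_sp == 1L & max_count == 1L]
    first_sp <- tapply(all_tags$species, all_tags$sequence, `[`, 1L)
    markers <- setNames(as.character(first_sp[keep]), keep)
    markers <- markers[sort(names(markers))]
  }
  t_count <- table(factor(markers, levels = all_species))
  t_i <- setNames(as.integer(t_count), names(t_count))
  zero <- names(t_i)[t_i == 0L]
  t_i <- t_i[t_i > 0L]
  if (length(zero) > 0L) {
    message("species with zero species-specific markers: ",
            paste(zero, collapse = ", "))
  }

  structure(
    list(markers = markers,
         species_marker_count = t_i,
         species = all_species,
         zero_marker_species = zero,
         enzyme = enzyme,
         provenance = list(genomes = ids, n_genomes = length(ids),
                           n_tags_dropped = n_dropped)),
    class = "marker_db"
  )
}

#' @export
print.marker_db <- function(x, ...) {
  cat("2b-RAD marker database (", x$enzyme$name, ", ",
      x$enzyme$tag_length, "-bp tags)\n", sep = "")
  cat("  ", length(x$markers), " markers over ",
      length(x$species_marker_count), " species (",
      length(x$zero_marker_species), " species without markers)\n", sep = "")
  invisible(x)
}

#' Write / read a marker database as TSV
#'
#' Sorted two-column TSV (\code{marker}, \code{species}) preceded by a
#' \code{#}-prefixed header block carrying the enzyme geometry, the genome
#' list, and an md5 content hash of the table body for deterministic diffs.
#'
#' @param db a \code{marker_db}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_db <- function(db, path) {
  stopifnot(inherits(db, "marker_db"))
  body <- c("marker\tspecies",
            if (length(db$markers) > 0L)
              paste(names(db$markers), db$markers, sep = "\t"))
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(body, tmp)
  hash <- unname(tools::md5sum(tmp))
  header <- c(
    "# rad2bm marker database v1",
    paste0("# enzyme: ", db$enzyme$name),
    paste0("# recognition: ", db$enzyme$recognition),
    paste0("# left_flank: ", db$enzyme$left_flank),
    paste0("# right_flank: ", db$enzyme$right_flank),
    paste0("# genomes: ", paste(db$provenance$genomes, collapse = ";")),
    paste0("# zero_marker_species: ",
           paste(db$zero_marker_species, collapse = ";")),
    paste0("# md5: ", hash)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_marker_db
#' @export
read_marker_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  if (any(is_header & cumsum(!is_header) > 0)) {
    stop("malformed marker database: header line after body, near line ",
         which(is_header & cumsum(!is_header) > 0)[1])
  }
  hdr <- lines[is_header]
  body <- lines[!is_header]
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  for (key in c("enzyme", "recognition", "left_flank", "right_flank")) {
    if (is.na(get_field(key))) {
      stop("malformed marker database: missing '", key, "' header field")
    }
  }
  enzyme <- enzyme_spec(get_field("enzyme"), get_field("recognition"),
                        as.integer(get_field("left_flank")),
                        as.integer(get_field("right_flank")))
  if (length(body) == 0L || body[1] != "marker\tspecies") {
    stop("malformed marker database: expected 'marker\\tspecies' header at line ",
         sum(is_header) + 1L)
  }
  rows <- body[-1]
  markers <- character(0)
  if (length(rows) > 0L) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L) {
      stop("malformed marker database: bad row at line ",
           sum(is_header) + 1L + bad[1])
    }
    seqs <- vapply(parts, `[`, character(1), 1L)
    sp <- vapply(parts, `[`, character(1), 2L)
    dup <- duplicated(seqs)
    if (any(dup)) {
      stop("marker sequence mapped to more than one species at line ",
           sum(is_header) + 1L + which(dup)[1], ": ", seqs[dup][1])
    }
    markers <- setNames(sp, seqs)[order(seqs)]
  }
  hash_stored <- get_field("md5")
  if (!is.na(hash_stored)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(body, tmp)
    if (unname(tools::md5sum(tmp)) != hash_stored) {
      stop("marker database content hash mismatch (file corrupted?)")
    }
  }
  zero_raw <- get_field("zero_marker_species")
  zero <- if (is.na(zero_raw) || !nzchar(zero_raw)) character(0) else
    strsplit(zero_raw, ";", fixed = TRUE)[[1]]
  genomes_raw <- get_field("genomes")
  genome_ids <- if (is.na(genomes_raw) || !nzchar(genomes_raw)) character(0) else
    strsplit(genomes_raw, ";", fixed = TRUE)[[1]]
  tab <- table(markers)
  t_i <- setNames(as.integer(tab), names(tab))
  structure(
    list(markers = markers,
         species_marker_count = t_i[sort(names(t_i))],
         species = sort(unique(c(unname(markers), zero))),
         zero_marker_species = zero,
         enzyme = enzyme,
         provenance = list(genomes = genome_ids,
                           n_genomes = length(genome_ids),
                           n_tags_dropped = NA_integer_)),
    class = "marker_db"
  )
}
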