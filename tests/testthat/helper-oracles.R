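# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a concrete BcgI tag: 10-nt flank + CGA + 6 random + TGC + 10-nt flank
random_bcgi_tag <- function() {
  paste0(random_dna(10), "CGA", random_dna(6), "TGC", random_dna(10))
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = BASES
)

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force position-by-position scan for one strand's pattern: returns
# 0-based match starts
brute_force_pattern_starts <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  plen <- nchar(pattern)
  if (n < plen) return(integer(0))
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, n - plen + 1L)
  for (k in seq_len(plen)) {
    ok <- ok & chars[k:(k + n - plen)] %in% iupac_sets[[pat[k]]]
  }
  which(ok) - 1L
}

# brute-force double-strand site scan with flank filtering, mirroring the
# match_sites contract
brute_force_sites <- function(sequence, pattern = "CGANNNNNNTGC",
                              left = 10L, right = 10L) {
  len <- nchar(sequence)
  plen <- nchar(pattern)
  f <- brute_force_pattern_starts(sequence, pattern)
  r <- brute_force_pattern_starts(sequence, revcomp_chr(pattern))
  f <- f[f >= left & f + plen + right <= len]
  r <- r[r >= right & r + plen + left <= len]
  out <- data.frame(start = c(f, r),
                    strand = c(rep("+", length(f)), rep("-", length(r))),
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# expected canonical tag multiset from a brute-force scan
brute_force_tags <- function(sequence, pattern = "CGANNNNNNTGC",
                             left = 10L, right = 10L) {
  sites <- brute_force_sites(sequence, pattern, left, right)
  if (nrow(sites) == 0L) return(character(0))
  ws <- ifelse(sites$strand == "+", sites$start - left, sites$start - right)
  raw <- substr(rep(sequence, nrow(sites)), ws + 1L,
                ws + left + nchar(pattern) + right)
  raw <- raw[grepl("^[ACGT]+$", raw)]
  rc <- revcomp_chr(raw)
  sort(ifelse(raw <= rc, raw, rc))
}

# plant given 32-bp tag windows into a site-free background at fixed spacing
plant_tags <- function(tags, enzyme, pad = 20L, seed = 1) {
  tagL <- enzyme$tag_length
  stopifnot(all(nchar(tags) == tagL))
  len <- length(tags) * (tagL + pad) + pad
  bg <- make_genome(len, 0, enzyme, seed = seed)$sequence
  for (i in seq_along(tags)) {
    s <- pad + (i - 1L) * (tagL + pad)
    substr(bg, s + 1L, s + tagL) <- tags[i]
  }
  bg
}

# small multi-species genome collection built from explicit tag assignments:
# tag_map is a named list species -> list of per-genome tag vectors
build_genome_set <- function(tag_map, enzyme, seed = 1) {
  genomes <- list()
  tax <- list()
  k <- 0L
  for (sp in names(tag_map)) {
    for (g in seq_along(tag_map[[sp]])) {
      k <- k + 1L
      gid <- sprintf("G%03d", k)
      genomes[[gid]] <- setNames(
        plant_tags(tag_map[[sp]][[g]], enzyme, seed = seed + k), "c1")
      tax[[k]] <- data.frame(genome_id = gid, species = sp,
                             stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, taxonomy = do.call(rbind, tax))
}

# brute-force marker computation: single-copy within each genome where
# present, and present in genomes of exactly one species
brute_force_markers <- function(genomes, taxonomy, enzyme) {
  per <- list()
  for (gid in names(genomes)) {
    tg <- extract_tags(genomes[[gid]], enzyme, genome_id = gid)
    sp <- taxonomy$species[taxonomy$genome_id == gid]
    per[[gid]] <- list(species = sp, counts = table(tg$sequence))
  }
  all_seqs <- sort(unique(unlist(lapply(per, function(x) names(x$counts)))))
  res <- list()
  for (s in all_seqs) {
    sp_here <- character(0)
    single <- TRUE
    for (gid in names(per)) {
      cnt <- per[[gid]]$counts[s]
      if (!is.na(cnt)) {
        sp_here <- c(sp_here, per[[gid]]$species)
        if (cnt > 1L) single <- FALSE
      }
    }
    if (single && length(unique(sp_here)) == 1L) {
      res[[s]] <- unique(sp_here)
    }
  }
  unlist(res)
}

# five synthetic single-genome species with distinct tag counts, plus their
# tag sets, marker database and ground-truth community
five_species_fixture <- function(seed = 101, n_sites = c(60, 80, 100, 120, 140),
                                 genome_length = 15000) {
  enz <- enzyme_spec("BcgI")
  sp <- paste0("Species_", LETTERS[1:5])
  genomes <- list()
  tag_sets <- list()
  for (i in 1:5) {
    g <- make_genome(genome_length, n_sites[i], enz, seed = seed + i)
    gid <- paste0("GCF_", i)
    genomes[[gid]] <- setNames(g$sequence, "c1")
    tag_sets[[sp[i]]] <- extract_tags(genomes[[gid]], enz, gid)$sequence
  }
  taxonomy <- data.frame(genome_id = names(genomes), species = sp,
                         stringsAsFactors = FALSE)
  db <- suppressMessages(build_marker_db(genomes, taxonomy, enz))
  list(enzyme = enz, species = sp, genomes = genomes, tag_sets = tag_sets,
       taxonomy = taxonomy, db = db,
       community = community_spec(setNames(c(0.4, 0.3, 0.15, 0.1, 0.05), sp)))
}

# minimal abundance study from an explicit matrix
toy_study <- function(mat, groups, counts = NULL, taxonomy = NULL) {
  abundance_study(mat, counts, groups, taxonomy = taxonomy)
}
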