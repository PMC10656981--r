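#' Community specification (ground-truth proportions)
#'
#' @param proportions named positive numeric vector summing to 1 (renormalized
#'   when within 1e-8 of 1; error otherwise).
#' @return object of class \code{community_spec}: named proportions.
#' @export
community_spec <- function(proportions) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions)))) {
    stop("proportions must be named by species")
  }
  if (any(proportions <= 0)) stop("proportions must be positive")
  s <- sum(proportions)
  if (abs(s - 1) > 1e-8) stop("proportions must sum to 1 (got ", s, ")")
  structure(proportions / s, class = "community_spec")
}

# sample one concrete base for each IUPAC code in a pattern
.instantiate_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

.random_bases <- function(n, gc_content) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
}

#' Synthetic genome with an exact number of recognition sites
#'
#' Generates a random background sequence (at the requested GC content),
#' plants exactly \code{n_sites} non-overlapping sites (degenerate pattern
#' positions filled with random bases, random flanks), then scrubs every
#' incidental recognition match by point-mutating a position that cannot
#' damage a planted site's recognition core, so planted counts are exact.
#' Deterministic per seed.
#'
#' @param length genome length in bp.
#' @param n_sites number of recognition sites to plant.
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @param gc_content background GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return list of class \code{synthetic_genome}: \code{sequence} (character),
#'   \code{sites} (data.frame start/strand of planted sites), \code{enzyme}.
#' @export
make_genome <- function(length, n_sites, enzyme, gc_content = 0.5,
                        seed = NULL) {
  stopifnot(inherits(enzyme, "enzyme_spec"), length > 0, n_sites >= 0)
  L <- as.integer(length)
  tagL <- enzyme$tag_length
  if (n_sites * tagL > L) {
    stop("infeasible packing: ", n_sites, " non-overlapping ", tagL,
         "-bp tag windows do not fit in ", L, " bp")
  }
  if (!is.null(seed)) set.seed(seed)
  plen <- nchar(enzyme$recognition)
  fixed_pos <- which(strsplit(enzyme$recognition, "")[[1]] != "N")

  seq_str <- paste(.random_bases(L, gc_content), collapse = "")
  starts <- integer(0)
  if (n_sites > 0L) {
    # non-overlapping window starts via the gaps construction
    starts <- sort(sample.int(L - n_sites * tagL + 1L, n_sites,
                              replace = TRUE) - 1L)
    starts <- starts + (seq_len(n_sites) - 1L) * tagL
    for (s in starts) {
      site <- paste0(paste(.random_bases(enzyme$left_flank, gc_content),
                           collapse = ""),
                     .instantiate_pattern(enzyme$recognition),
                     paste(.random_bases(enzyme$right_flank, gc_content),
                           collapse = ""))
      substr(seq_str, s + 1L, s + tagL) <- site
    }
  }
  # positions (1-based) that must not be touched: the non-degenerate bases of
  # every planted recognition instance; flanks and spacer bases may be mutated
  # freely (tags stay valid random tags)
  planted_fixed <- if (n_sites > 0L) {
    as.integer(outer(starts + enzyme$left_flank, fixed_pos, `+`))
  } else integer(0)
  planted_key <- paste(starts + enzyme$left_flank, "+")

  for (iter in 1:100) {
    found <- match_sites_unfiltered(seq_str, enzyme)
    extra <- found[!(paste(found$start, found$strand) %in% planted_key), ,
                   drop = FALSE]
    if (nrow(extra) == 0L) break
    for (k in seq_len(nrow(extra))) {
      cand <- setdiff((extra$start[k] + 1L):(extra$start[k] + plen),
                      planted_fixed)
      pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      cur <- substr(seq_str, pos, pos)
      substr(seq_str, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                          1L)
    }
  }
  found <- match_sites(seq_str, enzyme)
  if (nrow(found) != n_sites ||
      !all(sort(found$start) == sort(starts + enzyme$left_flank))) {
    stop("could not construct a genome with exactly ", n_sites, " sites")
  }
  structure(
    list(sequence = seq_str,
         sites = data.frame(start = starts + enzyme$left_flank,
                            strand = rep("+", n_sites),
                            stringsAsFactors = FALSE),
         enzyme = enzyme),
    class = "synthetic_genome"
  )
}

# all pattern matches on both strands, ignoring flank availability
# (internal: used to scrub incidental sites anywhere in a background)
match_sites_unfiltered <- function(sequence, enzyme) {
  plen <- nchar(enzyme$recognition)
  if (nchar(sequence) < plen) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::matchPattern(enzyme$recognition, subj, fixed = "subject")
  rev <- Biostrings::matchPattern(reverse_complement(enzyme$recognition),
                                  subj, fixed = "subject")
  data.frame(
    start = c(BiocGenerics::start(fwd) - 1L, BiocGenerics::start(rev) - 1L),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE
  )
}

#' Simulate error-prone tag reads from a community
#'
#' Each read draws a species with probability proportional to
#' \code{proportion x number of tags} (a genome-copy model: more deeply
#' represented genomes contribute more tags — exactly the bias the S/T
#' marker normalization corrects), then a uniform tag of that species, a
#' random strand, and per-base substitution errors at \code{error_rate}.
#' Deterministic per seed.
#'
#' @param tag_sets named list: species -> character vector of tag sequences
#'   (e.g. \code{extract_tags(...)$sequence}).
#' @param community a \code{\link{community_spec}} over (a subset of) the
#'   tag-set species.
#' @param n_reads positive integer.
#' @param error_rate per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @return list of class \code{simulated_reads}: \code{reads} (character),
#'   \code{species} (truth label per read), \code{weights} (the effective
#'   sampling weights).
#' @export
simulate_reads <- function(tag_sets, community, n_reads, error_rate = 0,
                           seed = NULL) {
  stopifnot(inherits(community, "community_spec"))
  if (n_reads <= 0) stop("n_reads must be positive")
  sp <- names(community)
  missing_sp <- sp[!sp %in% names(tag_sets) |
                     lengths(tag_sets[sp]) == 0L]
  if (length(missing_sp) > 0L) {
    stop("community species without tags: ", paste(missing_sp, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  w <- unclass(community) * lengths(tag_sets[sp])
  w <- w / sum(w)
  draw <- sample(sp, n_reads, replace = TRUE, prob = w)
  reads <- character(n_reads)
  for (s in sp) {
    m <- draw == s
    if (!any(m)) next
    reads[m] <- tag_sets[[s]][sample.int(length(tag_sets[[s]]), sum(m),
                                         replace = TRUE)]
  }
  flip <- runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- reverse_complement(reads[flip])
  if (error_rate > 0) {
    L <- nchar(reads[1])
    n_err <- rbinom(n_reads, L, error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(L, n_err[i])
      for (p in pos) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                         1L)
      }
    }
  }
  structure(list(reads = reads, species = draw, weights = w),
            class = "simulated_reads")
}

# default oral-like taxa table: 25 bacteria + 5 fungi
default_taxa <- function() {
  bacteria <- c(
    "Prevotella_melaninogenica", "Streptococcus_salivarius",
    "Streptococcus_mitis", "Neisseria_flavescens",
    "Haemophilus_parainfluenzae", "Veillonella_parvula",
    "Rothia_mucilaginosa", "Actinomyces_oris", "Fusobacterium_nucleatum",
    "Porphyromonas_gingivalis", "Gemella_haemolysans",
    "Granulicatella_adiacens", "Leptotrichia_buccalis",
    "Capnocytophaga_gingivalis", "Campylobacter_concisus",
    "Aggregatibacter_segnis", "Lautropia_mirabilis", "Kingella_oralis",
    "Selenomonas_sputigena", "Tannerella_forsythia",
    "Treponema_denticola", "Eikenella_corrodens", "Corynebacterium_matruchotii",
    "Abiotrophia_defectiva", "Solobacterium_moorei"
  )
  bact_phyla <- c("Bacteroidetes", "Firmicutes", "Firmicutes", "Proteobacteria",
                  "Proteobacteria", "Firmicutes", "Actinobacteria",
                  "Actinobacteria", "Fusobacteria", "Bacteroidetes",
                  "Firmicutes", "Firmicutes", "Fusobacteria", "Bacteroidetes",
                  "Proteobacteria", "Proteobacteria", "Proteobacteria",
                  "Proteobacteria", "Firmicutes", "Bacteroidetes",
                  "Spirochaetes", "Proteobacteria", "Actinobacteria",
                  "Firmicutes", "Firmicutes")
  fungi <- c("Malassezia_globosa", "Saccharomyces_cerevisiae",
             "Candida_albicans", "Aspergillus_fumigatus",
             "Cryptococcus_neoformans")
  fung_phyla <- c("Basidiomycota", "Ascomycota", "Ascomycota", "Ascomycota",
                  "Basidiomycota")
  species <- c(bacteria, fungi)
  data.frame(
    species = species,
    kingdom = c(rep("bacteria", length(bacteria)), rep("fungi", length(fungi))),
    phylum = c(bact_phyla, fung_phyla),
    genus = sub("_.*$", "", species),
    stringsAsFactors = FALSE
  )
}

# default base composition: geometric rank-abundance for bacteria plus
# explicit fungal shares (S. cerevisiae abundant in controls, M. globosa low)
default_base_proportions <- function() {
  taxa <- default_taxa()
  bacteria <- taxa$species[taxa$kingdom == "bacteria"]
  fungal_share <- c(Malassezia_globosa = 0.02,
                    Saccharomyces_cerevisiae = 0.0015,
                    Candida_albicans = 0.03, Aspergillus_fumigatus = 0.01,
                    Cryptococcus_neoformans = 0.005)
  bact_total <- 1 - sum(fungal_share)
  w <- 0.85^(seq_along(bacteria) - 1)
  bact <- setNames(bact_total * w / sum(w), bacteria)
  p <- c(bact, fungal_share)[taxa$species]
  community_spec(p / sum(p))
}

#' Two-group study design with planted differential taxa
#'
#' Defaults emulate a 26-case vs 18-control oral mycobiome comparison with
#' one strongly enriched fungal taxon in cases (10x) and one depleted one
#' (0.1x) over log-normal within-group noise.
#'
#' @param n_case,n_control group sizes (defaults 26 and 18).
#' @param base_proportions a \code{\link{community_spec}}; default is a
#'   30-taxon (25 bacteria + 5 fungi) oral-like composition.
#' @param fold_changes named positive vector of per-taxon fold changes
#'   applied in cases; default enriches Malassezia_globosa 10x and depletes
#'   Saccharomyces_cerevisiae 10x.
#' @param noise_sigma SD of the per-taxon log-normal noise (default 0.5).
#' @param depth multinomial read depth per sample (default 50000).
#' @param detection_limit relative-abundance floor emulating the G-score
#'   screen of the quantification stage: taxa below the limit in a sample
#'   are recorded as absent (0) and the remaining taxa renormalized
#'   (default 1e-3). Set to 0 to disable.
#' @param seed RNG seed (default 1).
#' @return object of class \code{study_design}.
#' @export
study_design <- function(n_case = 26, n_control = 18,
                         base_proportions = NULL,
                         fold_changes = c(Malassezia_globosa = 10,
                                          Saccharomyces_cerevisiae = 0.1),
                         noise_sigma = 0.5, depth = 50000,
                         detection_limit = 1e-3, seed = 1) {
  if (is.null(base_proportions)) base_proportions <- default_base_proportions()
  stopifnot(inherits(base_proportions, "community_spec"))
  if (n_case < 2 || n_control < 2) stop("n_case and n_control must be >= 2")
  if (length(fold_changes) > 0) {
    if (any(fold_changes <= 0)) stop("fold changes must be positive")
    extra <- setdiff(names(fold_changes), names(base_proportions))
    if (length(extra) > 0L) {
      stop("fold-change taxa not in the community: ",
           paste(extra, collapse = ", "))
    }
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (depth < 1) stop("depth must be positive")
  if (detection_limit < 0 || detection_limit >= 1) {
    stop("detection_limit must be in [0, 1)")
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         base_proportions = base_proportions, fold_changes = fold_changes,
         noise_sigma = noise_sigma, depth = as.integer(depth),
         detection_limit = detection_limit, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Generate a case-control abundance study
#'
#' Per sample, taxon proportions are the base composition, multiplied by the
#' fold changes for case samples, perturbed by per-taxon log-normal noise
#' \code{exp(N(0, sigma^2))}, and renormalized. Taxa falling below the
#' design's \code{detection_limit} are then recorded as absent in that
#' sample — emulating the zero-inflation the G-score screen imposes on real
#' marker-based profiles — and the detected taxa are renormalized again.
#' The abundance matrix stores these exact proportions while the count
#' matrix draws a multinomial sample at the design depth (for count-based
#' alpha diversity). Deterministic per design seed.
#'
#' @param design a \code{\link{study_design}}.
#' @return an \code{\link{abundance_study}} with groups \code{case} /
#'   \code{control}, kingdom labels and the default taxonomy attached when
#'   the default community is used. The true fold changes are kept in
#'   \code{attr(study, "design")}.
#' @export
make_case_control <- function(design) {
  stopifnot(inherits(design, "study_design"))
  base <- unclass(design$base_proportions)
  if (any(base <= 0) || sum(base) <= 0) stop("degenerate base proportions")
  taxa <- names(base)
  fold <- setNames(rep(1, length(taxa)), taxa)
  fold[names(design$fold_changes)] <- design$fold_changes
  n <- design$n_case + design$n_control
  ids <- c(sprintf("case_%02d", seq_len(design$n_case)),
           sprintf("control_%02d", seq_len(design$n_control)))
  grp <- setNames(rep(c("case", "control"),
                      c(design$n_case, design$n_control)), ids)
  set.seed(design$seed)
  rel <- matrix(0, nrow = length(taxa), ncol = n,
                dimnames = list(taxa, ids))
  cnt <- matrix(0L, nrow = length(taxa), ncol = n,
                dimnames = list(taxa, ids))
  for (j in seq_len(n)) {
    p <- base
    if (grp[j] == "case") p <- p * fold
    if (design$noise_sigma > 0) {
      p <- p * exp(rnorm(length(p), 0, design$noise_sigma))
    }
    p <- p / sum(p)
    if (design$detection_limit > 0) {
      p[p < design$detection_limit] <- 0
      if (sum(p) == 0) stop("detection limit wiped out an entire sample")
      p <- p / sum(p)
    }
    rel[, j] <- p
    cnt[, j] <- as.integer(rmultinom(1, design$depth, p))
  }
  tax <- default_taxa()
  if (!all(taxa %in% tax$species)) {
    tax <- data.frame(species = taxa, kingdom = "bacteria",
                      phylum = NA_character_,
                      genus = sub("_.*$", "", taxa),
                      stringsAsFactors = FALSE)
  } else {
    tax <- tax[tax$species %in% taxa, , drop = FALSE]
  }
  study <- abundance_study(rel, cnt, grp, taxonomy = tax)
  attr(study, "design") <- design
  study
}
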