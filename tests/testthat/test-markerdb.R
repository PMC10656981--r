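enz <- enzyme_spec("BcgI")

test_that("within-genome uniqueness counts canonical multiplicity", {
  expect_equal(within_genome_unique(c("AAA", "CCC", "CCC")), "AAA")

  # a site and its reverse complement elsewhere collapse to multiplicity 2
  set.seed(21)
  tag <- random_bcgi_tag()
  other <- random_bcgi_tag()
  g <- plant_tags(c(tag, revcomp_chr(tag), other), enz, seed = 9)
  tg <- extract_tags(setNames(g, "c1"), enz, "g1")
  u <- within_genome_unique(tg)
  expect_false(canonicalize(tag) %in% u)
  expect_true(canonicalize(other) %in% u)

  expect_equal(within_genome_unique(character(0)), character(0))
})

test_that("species specificity excludes shared tags and counts T_i", {
  set.seed(22)
  shared <- random_bcgi_tag()
  privA <- random_bcgi_tag()
  privB <- random_bcgi_tag()
  fx <- build_genome_set(
    list(A = list(c(shared, privA)), B = list(c(shared, privB))), enz,
    seed = 30)
  db <- suppressMessages(build_marker_db(fx$genomes, fx$taxonomy, enz))
  expect_false(canonicalize(shared) %in% names(db$markers))
  expect_equal(db$species_marker_count, c(A = 1L, B = 1L))
  expect_equal(unname(db$markers[canonicalize(privA)]), "A")

  # one species, one genome, k single-copy tags -> T = k
  set.seed(23)
  tags <- replicate(7, random_bcgi_tag())
  fx1 <- build_genome_set(list(S = list(tags)), enz, seed = 40)
  db1 <- build_marker_db(fx1$genomes, fx1$taxonomy, enz)
  expect_equal(unname(db1$species_marker_count["S"]), 7L)
})

test_that("marker database equals brute-force all-pairs computation", {
  set.seed(24)
  # 10 genomes over 5 species (2 genomes each) with engineered overlaps
  sp <- paste0("sp", 1:5)
  tag_map <- lapply(sp, function(s) {
    list(replicate(6, random_bcgi_tag()), replicate(6, random_bcgi_tag()))
  })
  names(tag_map) <- sp
  # one tag shared across species 1 and 2; one tag duplicated within a
  # genome of species 3; one tag shared between both genomes of species 4
  cross <- random_bcgi_tag()
  tag_map$sp1[[1]][1] <- cross
  tag_map$sp2[[2]][1] <- cross
  tag_map$sp3[[1]][2] <- tag_map$sp3[[1]][3]
  tag_map$sp4[[2]][4] <- tag_map$sp4[[1]][4]
  fx <- build_genome_set(tag_map, enz, seed = 50)
  db <- suppressMessages(build_marker_db(fx$genomes, fx$taxonomy, enz))
  want <- brute_force_markers(fx$genomes, fx$taxonomy, enz)
  want <- want[sort(names(want))]
  expect_identical(db$markers, want)
  # shared-across-species excluded; within-genome duplicate excluded;
  # shared-within-species (single copy in each genome) retained
  expect_false(canonicalize(cross) %in% names(db$markers))
  expect_false(canonicalize(tag_map$sp3[[1]][2]) %in% names(db$markers))
  expect_true(canonicalize(tag_map$sp4[[1]][4]) %in% names(db$markers))
  # no marker under two species
  expect_false(anyDuplicated(names(db$markers)) > 0)
})

test_that("build errors on missing taxonomy and duplicate genome ids", {
  set.seed(25)
  fx <- build_genome_set(list(A = list(replicate(3, random_bcgi_tag()))), enz,
                         seed = 60)
  expect_error(
    build_marker_db(fx$genomes, data.frame(genome_id = "other", species = "X"),
                    enz),
    "G001")
  tax_dup <- rbind(fx$taxonomy, fx$taxonomy)
  expect_error(build_marker_db(fx$genomes, tax_dup, enz), "duplicate")
})

test_that("database round-trips through its TSV format", {
  set.seed(26)
  tag_map <- list(A = list(replicate(4, random_bcgi_tag())),
                  B = list(replicate(3, random_bcgi_tag())))
  fx <- build_genome_set(tag_map, enz, seed = 70)
  db <- build_marker_db(fx$genomes, fx$taxonomy, enz)
  path <- tempfile(fileext = ".tsv")
  write_marker_db(db, path)
  db2 <- read_marker_db(path)
  expect_identical(db2$markers, db$markers)
  expect_identical(db2$species_marker_count, db$species_marker_count)
  expect_identical(db2$species, db$species)
  expect_identical(db2$zero_marker_species, db$zero_marker_species)
  expect_identical(db2$enzyme, db$enzyme)
  expect_identical(db2$provenance$genomes, db$provenance$genomes)

  # duplicated marker sequence mapping to two species is rejected
  lines <- readLines(path)
  row <- grep("^[ACGT]+\t", lines, value = TRUE)[1]
  bad <- c(lines[!grepl("^# md5", lines)],
           paste0(sub("\t.*", "", row), "\tOtherSpecies"))
  badpath <- tempfile()
  writeLines(bad, badpath)
  expect_error(read_marker_db(badpath), "more than one species")

  # empty database round-trip
  empty <- db
  empty$markers <- character(0)
  empty$species_marker_count <- setNames(integer(0), character(0))
  empty$species <- character(0)
  empty$zero_marker_species <- character(0)
  p2 <- tempfile()
  write_marker_db(empty, p2)
  e2 <- read_marker_db(p2)
  expect_equal(length(e2$markers), 0L)
  expect_equal(length(e2$species_marker_count), 0L)
})

test_that("adding a genome to one species never adds markers to another", {
  set.seed(27)
  tag_map <- list(A = list(replicate(5, random_bcgi_tag())),
                  B = list(replicate(5, random_bcgi_tag())))
  fx1 <- build_genome_set(tag_map, enz, seed = 80)
  db1 <- suppressMessages(build_marker_db(fx1$genomes, fx1$taxonomy, enz))

  # new genome of species A reuses one of B's tags (and adds fresh ones)
  tag_map$A[[2]] <- c(tag_map$B[[1]][1], replicate(3, random_bcgi_tag()))
  fx2 <- build_genome_set(tag_map, enz, seed = 80)
  db2 <- suppressMessages(build_marker_db(fx2$genomes, fx2$taxonomy, enz))

  b1 <- names(db1$markers)[db1$markers == "B"]
  b2 <- names(db2$markers)[db2$markers == "B"]
  expect_true(all(b2 %in% b1))          # B never gains markers
  expect_false(canonicalize(tag_map$B[[1]][1]) %in% b2)  # and lost the reused one
})
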