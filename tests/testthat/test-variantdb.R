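test_that("apply_variant substitutes the stated residue and nothing else", {
  expect_equal(apply_variant("KYRQVASHV", 3, "R", "L"), "KYLQVASHV")
  expect_equal(apply_variant("TGAASFDEF", 5, "S", "R"), "TGAARFDEF")
  expect_error(apply_variant("KYRQVASHV", 3, "Q", "L"), "reference mismatch")
  expect_error(apply_variant("KYRQVASHV", 10, "V", "L"), "out of range")
  expect_error(apply_variant("KYRQVASHV", 0, "K", "L"), "out of range")
  expect_error(apply_variant("KYRQVASHV", 3, "R", "R"), "identical")
})

make_protein <- function(n, id = "P1") {
  stats::setNames(paste(rep(AA_LETTERS, length.out = n), collapse = ""), id)
}

test_that("long-peptide windows are mutation-centered and truncate only at termini", {
  prot <- make_protein(200)
  v <- list(protein_id = "P1", position = 100,
            ref_aa = substr(prot, 100, 100), alt_aa = "W")
  lp <- build_long_peptide(prot, v, flank = 15)
  expect_equal(nchar(lp$sequence), 31)
  expect_equal(lp$mutation_offset, 16)
  expect_equal(substr(lp$sequence, 16, 16), "W")
  expect_equal(lp$wt_sequence, substr(prot, 85, 115), ignore_attr = TRUE)

  v1 <- list(protein_id = "P1", position = 1,
             ref_aa = substr(prot, 1, 1), alt_aa = "W")
  lp1 <- build_long_peptide(make_protein(100), v1, flank = 15)
  expect_equal(nchar(lp1$sequence), 16)
  expect_equal(lp1$mutation_offset, 1)

  tiny <- make_protein(9)
  v2 <- list(protein_id = "P1", position = 5,
             ref_aa = substr(tiny, 5, 5), alt_aa = "W")
  lp2 <- build_long_peptide(tiny, v2, flank = 15)
  expect_equal(nchar(lp2$sequence), 9)
  expect_equal(lp2$mutation_offset, 5)
})

test_that("proteins with nonstandard residues are skipped with a warning", {
  prots <- c(P1 = "ACDEFGHIKLMNPQRSTVWY", P2 = "ACDEFGHIXLMNPQRSTVWY")
  vars <- data.frame(protein_id = c("P1", "P2"), position = c(5, 5),
                     ref_aa = c("F", "F"), alt_aa = c("W", "W"),
                     coverage = c(10, 10), tpm = c(1, 1))
  expect_warning(lps <- build_long_peptides(prots, vars), "nonstandard")
  expect_length(lps, 1)
  expect_equal(lps[[1]]$protein_id, "P1")
})

test_that("candidate enumeration matches brute-force mutation-covering k-mers", {
  prot <- make_protein(200)
  v <- list(protein_id = "P1", position = 100,
            ref_aa = substr(prot, 100, 100), alt_aa = "W")
  lp <- build_long_peptide(prot, v, flank = 15)

  cand9 <- enumerate_candidates(lp, lengths = 9)
  expect_equal(nrow(cand9), 9)
  cand_all <- enumerate_candidates(lp, lengths = 8:11)
  expect_equal(nrow(cand_all), 8 + 9 + 10 + 11)

  for (k in 8:11) {
    got <- enumerate_candidates(lp, lengths = k)$sequence
    expect_equal(got, oracle_covering_kmers(lp$sequence, lp$mutation_offset, k))
  }

  # every candidate is a substring containing the mutated residue, and its
  # WT counterpart differs at exactly one position
  for (i in seq_len(nrow(cand_all))) {
    expect_true(grepl(cand_all$sequence[i], lp$sequence, fixed = TRUE))
    mm <- sum(strsplit(cand_all$sequence[i], "")[[1]] !=
                strsplit(cand_all$wt_counterpart[i], "")[[1]])
    expect_equal(mm, 1)
    expect_equal(substr(cand_all$sequence[i], cand_all$mutation_pos[i],
                        cand_all$mutation_pos[i]), "W")
  }
})

test_that("terminal variants yield min(k, distance-to-terminus + 1) candidates", {
  prot <- make_protein(100)
  set.seed(71)
  for (pos in c(1, 2, 5, 50, 96, 100)) {
    v <- list(protein_id = "P1", position = pos,
              ref_aa = substr(prot, pos, pos), alt_aa = "W")
    lp <- build_long_peptide(prot, v, flank = 15)
    for (k in c(8, 9, 11)) {
      n_expect <- length(oracle_covering_kmers(lp$sequence,
                                               lp$mutation_offset, k))
      expect_equal(nrow(enumerate_candidates(lp, lengths = k)), n_expect)
      if (pos == 50) expect_equal(n_expect, k)  # interior: exactly k
      if (pos == 1) expect_equal(n_expect, 1)   # terminus: window start only
    }
  }
  # a window shorter than every requested length yields an empty table
  tiny <- make_protein(6)
  v <- list(protein_id = "P1", position = 3, ref_aa = substr(tiny, 3, 3),
            alt_aa = "W")
  lp <- build_long_peptide(tiny, v)
  expect_equal(nrow(enumerate_candidates(lp, lengths = 8:11)), 0)
})

test_that("search database round-trips through FASTA byte-exactly", {
  cfg <- sim_config(seed = 11)
  prots <- gen_proteome(cfg)
  vars <- gen_variants(prots, cfg)
  lps <- build_long_peptides(prots, vars)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_search_database(prots, lps, path)

  db <- read_search_database(path)
  expect_equal(db$proteome, prots)
  expect_length(db$long_peptides, length(lps))
  expect_equal(vapply(db$long_peptides, function(x) x$sequence, character(1)),
               vapply(lps, function(x) x$sequence, character(1)))
  expect_equal(vapply(db$long_peptides, function(x) x$mutation_offset,
                      integer(1)),
               vapply(lps, function(x) x$mutation_offset, integer(1)))

  # duplicate long peptides from distinct variants keep distinct records
  lp_dup <- c(lps[1], lps[1])
  lp_dup[[2]]$protein_id <- lps[[2]]$protein_id  # fake distinct provenance
  path2 <- withr::local_tempfile(fileext = ".fasta")
  prots2 <- prots
  write_proteome(prots, path2)
  hdrs <- names(read_proteome(path2))
  expect_equal(hdrs, names(prots))
  path3 <- withr::local_tempfile(fileext = ".fasta")
  write_search_database(prots, c(lps[1], lps[1]), path3)
  n_records <- sum(startsWith(readLines(path3), ">"))
  expect_equal(n_records, length(prots) + 2)

  # empty long-peptide list: database identical to the reference
  path4 <- withr::local_tempfile(fileext = ".fasta")
  write_search_database(prots, list(), path4)
  expect_equal(read_proteome(path4), prots)
})
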