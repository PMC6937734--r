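test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(digest_protein("AAAA", 0)$peptide, "AAAA")
  # K before P is suppressed, R cleaves
  got <- digest_protein("AKPRG", 0)
  expect_equal(got$peptide, c("AKPR", "G"))
  expect_equal(got$start, c(1L, 5L))
  expect_equal(got$end, c(4L, 5L))
  expect_equal(got$prev_aa, c("-", "R"))
  expect_equal(got$next_aa, c("G", "-"))
  # missed cleavages: all cleavage-site subsets up to 1 missed site
  expect_setequal(digest_protein("AKRG", 1)$peptide, c("AK", "R", "G", "AKR", "RG"))
  expect_setequal(digest_protein("AKRG", 0)$peptide, c("AK", "R", "G"))
})

test_that("identical sequences align with zero variants", {
  aln <- align_to_reference("MKVLAQ", "MKVLAQ")
  vc <- variant_count(aln)
  expect_equal(vc$n_variants, 0)
  expect_equal(vc$percent_divergence, 0)
})

test_that("variant counting separates substitutions, deletions, insertion events", {
  # single substitution
  expect_equal(variant_count(align_to_reference("MRVL", "MKVL"))$n_variants, 1)
  # one 2-residue insertion run counts once
  ref <- strrep("MKVLAQDIGV", 4)
  ins <- paste0(substr(ref, 1, 20), "WW", substr(ref, 21, 40))
  vc <- variant_count(align_to_reference(ins, ref))
  expect_equal(vc$n_insertion_events, 1)
  expect_equal(vc$n_variants, 1)
  # 3 substitutions + 1 deleted reference residue = 4
  mutated <- ref
  for (p in c(5, 15, 25)) substr(mutated, p, p) <- "W"
  mutated <- paste0(substr(mutated, 1, 34), substr(mutated, 36, 40))
  vc2 <- variant_count(align_to_reference(mutated, ref))
  expect_equal(vc2$n_substitutions, 3)
  expect_equal(vc2$n_deleted_positions, 1)
  expect_equal(vc2$n_variants, 4)
})

test_that("variant count equals Hamming distance on indel-free pairs", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      ref <- random_peptide(50)
      loc <- strsplit(ref, "")[[1]]
      k <- sample(0:5, 1)
      pos <- sample(50, k)
      for (p in pos) loc[p] <- sample(setdiff(names(retroproteo:::AA_MONO), loc[p]), 1)
      loc <- paste(loc, collapse = "")
      vc <- variant_count(align_to_reference(loc, ref))
      expect_equal(vc$n_variants, oracle_hamming(loc, ref))
      expect_equal(vc$n_variants, k)
    }
  })
})

test_that("per-position identity matches the generator's mutation ledger", {
  fam <- simulate_locus_family(n_loci = 12, length = 150, mutation_rate = 0.03,
                               indel_rate = 0, seed = 31)
  ident <- per_position_identity(fam$loci, fam$consensus)
  expect_equal(nrow(ident), 150)
  counts <- table(factor(fam$ledger$position, levels = 1:150))
  expect_equal(ident$pct_identity, 100 * (12 - as.numeric(counts)) / 12)

  # all loci identical to the reference -> 100 everywhere
  fam0 <- simulate_locus_family(n_loci = 4, length = 80, mutation_rate = 0,
                                indel_rate = 0, seed = 1)
  expect_true(all(per_position_identity(fam0$loci, fam0$consensus)$pct_identity == 100))

  # 1 of 4 loci substituted at one position -> 75 there
  loci <- fam0$loci
  p <- 40L
  old <- substr(loci$protein[1], p, p)
  substr(loci$protein[1], p, p) <- if (old == "W") "Y" else "W"
  ident4 <- per_position_identity(loci, fam0$consensus)
  expect_equal(ident4$pct_identity[p], 75)
  expect_true(all(ident4$pct_identity[-p] == 100))
})

test_that("the five mAb epitopes have the reported lengths and locate by substring", {
  epis <- l1_epitopes()
  expect_setequal(epis$name, c("MT5", "MT9", "MT11", "MT49", "MT69"))
  expect_equal(range(nchar(epis$sequence)), c(6L, 14L))
})

test_that("epitope scan counts planted mismatches, including the V990M polymorphism", {
  # build a reference where the MT5 window QDIGVGKD starts at position 986,
  # placing the polymorphic valine at position 990
  withr::with_seed(78, {
    ref <- paste0(random_peptide(985), "QDIGVGKD", random_peptide(30))
  })
  expect_equal(substr(ref, 990, 990), "V")
  l1hs <- ref
  l1pa2 <- ref
  substr(l1pa2, 990, 990) <- "M"  # the ancestral methionine allele
  loci <- tibble::tibble(locus_id = c("hs_1", "pa2_1"), protein = c(l1hs, l1pa2))
  scan <- epitope_scan(l1_epitopes()[l1_epitopes()$name == "MT5", ], loci, ref)
  expect_equal(scan$n_mismatch[scan$locus_id == "hs_1"], 0)
  expect_equal(scan$n_mismatch[scan$locus_id == "pa2_1"], 1)
  frac <- epitope_match_fraction(scan)
  expect_equal(frac$match_fraction, 0.5)
})

test_that("epitope scan on an unmutated family reports full conservation", {
  fam <- simulate_locus_family(n_loci = 6, length = 120, mutation_rate = 0,
                               indel_rate = 0, seed = 3)
  epis <- tibble::tibble(name = "win", sequence = substr(fam$consensus, 50, 57),
                         reference_start = 50L)
  scan <- epitope_scan(epis, fam$loci, fam$consensus)
  expect_true(all(scan$match))
  expect_equal(epitope_match_fraction(scan)$match_fraction, 1.0)
})

test_that("epitope scan errors when the epitope cannot be located", {
  loci <- tibble::tibble(locus_id = "x", protein = "MKVLAQ")
  epis <- tibble::tibble(name = "nowhere", sequence = "WWWW",
                         reference_start = NA_integer_)
  expect_error(epitope_scan(epis, loci, "MKVLAQ"), class = "retroproteo_epitope_error")
})

test_that("amino-acid positions map to 1-based codon spans", {
  expect_equal(aa_to_nt(1), tibble::tibble(aa_position = 1L, nt_first = 1L, nt_last = 3L))
  expect_equal(aa_to_nt(990)$nt_first, 2968L)
  expect_equal(aa_to_nt(100)$nt_first, 298L)
  expect_equal(aa_to_nt(100)$nt_last, 300L)
  expect_error(aa_to_nt(0), ">= 1")
})

test_that("orthogonalization keeps uniquely supported loci and picks divergent representatives", {
  fam <- simulate_locus_family(n_loci = 4, length = 100, mutation_rate = 0.05,
                               indel_rate = 0, seed = 13)
  # each peptide unique to one locus: exactly those loci are retained
  support <- tibble::tibble(peptide = c("pep1", "pep2"),
                            locus_id = c("locus_001", "locus_003"))
  got <- orthogonalize_loci(support, fam$loci, fam$consensus)
  expect_equal(got$retained, c("locus_001", "locus_003"))
  expect_equal(got$peptide_map$representative, c("locus_001", "locus_003"))

  # one shared peptide, neither supporter retained by rule (a):
  # the more divergent locus wins
  div <- purrr::map_dbl(fam$loci$protein, function(p)
    variant_count(align_to_reference(p, fam$consensus))$n_variants)
  names(div) <- fam$loci$locus_id
  d <- div[c("locus_002", "locus_004")]
  expected <- sort(names(d)[d == max(d)])[1]
  shared <- tibble::tibble(peptide = "pepS", locus_id = c("locus_002", "locus_004"))
  got2 <- orthogonalize_loci(shared, fam$loci, fam$consensus)
  expect_equal(got2$retained, expected)
})

test_that("orthogonalization matches the brute-force oracle on mixed fixtures", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n_loci <- sample(4:8, 1)
      fam <- simulate_locus_family(n_loci = n_loci, length = 80,
                                   mutation_rate = 0.06, indel_rate = 0,
                                   seed = 500 + rep)
      n_pep <- sample(5:9, 1)
      support <- purrr::map(seq_len(n_pep), function(i) {
        k <- sample(1:3, 1)
        tibble::tibble(peptide = sprintf("pep_%02d", i),
                       locus_id = sample(fam$loci$locus_id, k))
      }) |> dplyr::bind_rows()
      div <- purrr::map_dbl(fam$loci$protein, function(p)
        variant_count(align_to_reference(p, fam$consensus))$n_variants)
      names(div) <- fam$loci$locus_id
      got <- orthogonalize_loci(support, fam$loci, fam$consensus)
      expect_equal(got$retained, oracle_orthogonalize(support, div))

      # minimality: dropping any retained locus breaks coverage or uniqueness
      by_pep <- split(support$locus_id, support$peptide)
      uniq <- unlist(by_pep[lengths(purrr::map(by_pep, unique)) == 1])
      for (r in got$retained) {
        without <- setdiff(got$retained, r)
        covers <- all(purrr::map_lgl(by_pep, ~ any(.x %in% without)))
        expect_true(r %in% uniq || !covers)
      }
    }
  })
})

test_that("generated nucleotide sequences translate exactly to the proteins", {
  fam <- simulate_locus_family(n_loci = 6, length = 90, mutation_rate = 0.02,
                               indel_rate = 0.3, seed = 9)
  got <- as.character(Biostrings::translate(Biostrings::DNAStringSet(fam$loci$nucleotide)))
  expect_equal(unname(got), fam$loci$protein)
  cons <- as.character(Biostrings::translate(Biostrings::DNAString(fam$consensus_nt)))
  expect_equal(cons, fam$consensus)
})
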