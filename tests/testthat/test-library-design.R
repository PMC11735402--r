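test_that("SNV enumeration follows the 3L closed form", {
  expect_length(enumerate_snvs("A"), 3L)
  alts <- vapply(enumerate_snvs("A"), `[[`, character(1), "alt")
  expect_setequal(alts, c("C", "G", "T"))
  e9 <- enumerate_snvs("ACG")
  expect_length(e9, 9L)
  seqs <- vapply(e9, apply_edit, character(1), region_seq = "ACG")
  expect_length(unique(seqs), 9L)
  # random 50-mer: 150 edits, no sequence collisions
  s50 <- random_cds(17, seed = 8)
  s50 <- substring(s50, 1, 50)
  e150 <- enumerate_snvs(s50)
  expect_length(e150, 150L)
  expect_length(unique(vapply(e150, apply_edit, character(1),
                              region_seq = s50)), 150L)
})

test_that("minimal-Hamming codon exchange with lexicographic ties", {
  expect_equal(min_hamming_codon("CGC", "H"), "CAC")   # His: CAC dist 1
  expect_equal(min_hamming_codon("CTG", "I"), "ATA")   # ties ATA/ATC/ATT
  expect_equal(min_hamming_codon("GGA", "G"), "GGC")   # synonymous, dist 1
  expect_error(min_hamming_codon("ATG", "M"), "single-codon")
  expect_error(min_hamming_codon("TGG", "W"), "single-codon")
  # exhaustively: the result always encodes the target at minimal distance
  gc <- Biostrings::GENETIC_CODE
  withr::with_seed(1, {
    for (i in 1:30) {
      ref <- sample(names(gc), 1)
      target <- sample(setdiff(unique(unname(gc)), gc[[ref]]), 1)
      got <- min_hamming_codon(ref, target)
      cands <- setdiff(names(gc)[gc == target], ref)
      dists <- vapply(cands, function(c2)
        sum(strsplit(c2, "")[[1]] != strsplit(ref, "")[[1]]), integer(1))
      expect_equal(gc[[got]], target)
      expect_equal(sum(strsplit(got, "")[[1]] != strsplit(ref, "")[[1]]),
                   min(dists))
    }
  })
})

test_that("amino-acid enumeration completes each codon to 19 missense + stop", {
  # Lys codon AAA: SNVs reach Q,E,*,T,R,I,N (+ synonymous AAG)
  m <- coding_model("ATGAAATGGTAA")   # M K W *
  edits <- enumerate_aa_substitutions(m, "E1")
  gc <- Biostrings::GENETIC_CODE
  # per-codon multi-nt target counts
  by_codon <- split(edits, vapply(edits, function(e) e$pos %/% 3L, integer(1)))
  # codon 2 (AAA, region pos 3-5): 19 - 6 missense + 0 extra nonsense,
  # synonymous covered by the AAG SNV
  aaa <- by_codon[["1"]]
  expect_length(aaa, 13L)
  targets <- vapply(aaa, function(e) {
    cod <- "AAA"
    substring(cod, e$pos %% 3L + 1L, e$pos %% 3L + nchar(e$alt)) <- e$alt
    gc[[cod]]
  }, character(1))
  expect_false("*" %in% targets)   # TAA reachable by SNV
  expect_setequal(targets, setdiff(unique(unname(gc)),
                                   c("K", "Q", "E", "*", "T", "R", "I", "N")))
  # Trp codon TGG: no synonymous codon exists -> no synonymous entry
  tgg <- by_codon[["2"]]
  t_tgg <- vapply(tgg, function(e) {
    cod <- "TGG"
    substring(cod, e$pos %% 3L + 1L, e$pos %% 3L + nchar(e$alt)) <- e$alt
    gc[[cod]]
  }, character(1))
  expect_false("W" %in% t_tgg)

  # union of SNV + multi-nt coverage: every internal codon reaches all
  # 19 missense targets plus stop
  cds <- random_cds(10, seed = 21)
  m2 <- coding_model(cds)
  lib <- build_library(m2, insertions = FALSE, deletions = FALSE)
  rec <- lib$records[lib$records$coding_class %in%
                       c("missense", "nonsense"), ]
  cover <- table(rec$codon_index,
                 substring(rec$protein_change,
                           nchar(rec$protein_change),
                           nchar(rec$protein_change)))
  per_codon <- rowSums(cover > 0)
  # all codons except those whose WT aa limits targets: 19 missense + stop
  expect_true(all(per_codon == 20L))
})

test_that("indel enumeration obeys closed forms and dedups as expected", {
  # "A": 4 insertions, 1 deletion
  e <- enumerate_indels("A", max_del = 1)
  kinds <- vapply(e, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "insertion"), 4L)
  expect_equal(sum(kinds == "deletion"), 1L)
  ins_seqs <- vapply(e[kinds == "insertion"], apply_edit, character(1),
                     region_seq = "A")
  expect_setequal(ins_seqs, c("AA", "CA", "GA", "TA"))
  # "AC" insertions: 8 raw, 7 distinct (AAC arises twice)
  e2 <- enumerate_indels("AC", max_del = 1)
  ins2 <- vapply(e2[vapply(e2, `[[`, character(1), "kind") == "insertion"],
                 apply_edit, character(1), region_seq = "AC")
  expect_length(ins2, 8L)
  expect_length(unique(ins2), 7L)
  expect_equal(sum(ins2 == "AAC"), 2L)
  # "ACGT" deletions sizes 1-3: 9 raw, 9 distinct
  e3 <- enumerate_indels("ACGT", max_del = 3)
  del3 <- vapply(e3[vapply(e3, `[[`, character(1), "kind") == "deletion"],
                 apply_edit, character(1), region_seq = "ACGT")
  expect_length(del3, 9L)
  expect_setequal(del3, c("CGT", "AGT", "ACT", "ACG", "GT", "AT", "AC",
                          "T", "A"))
  # closed forms on a 60-mer: 4L insertions, 3L-3 deletions
  s <- substring(random_cds(20, seed = 4), 1, 60)
  e4 <- enumerate_indels(s)
  k4 <- vapply(e4, `[[`, character(1), "kind")
  expect_equal(sum(k4 == "insertion"), 240L)
  expect_equal(sum(k4 == "deletion"), 177L)
})

test_that("built library matches an independent brute-force enumerator", {
  cds <- random_cds(20, seed = 13)   # 60-nt fully coding region
  m <- coding_model(cds)
  lib <- build_library(m)
  expected <- oracle_library_sequences(m, "E1")
  expect_setequal(lib$records$sequence, expected)
  expect_false(cds %in% lib$records$sequence)
  expect_false(anyDuplicated(lib$records$sequence) > 0)
})

test_that("library minimum pairwise Hamming distance is 1", {
  cds <- random_cds(20, seed = 17)
  lib <- build_library(coding_model(cds))
  expect_equal(library_min_hamming(lib), 1)
})

test_that("dedup is idempotent and order-independent in its sequence set", {
  cds <- random_cds(15, seed = 19)
  m <- coding_model(cds)
  lib1 <- build_library(m)
  lib2 <- build_library(m)
  expect_identical(lib1$records$sequence, lib2$records$sequence)
  # switching off substitution enumerations must not change the indel
  # sequence set minus substitution-attributed overlaps
  lib_ind <- build_library(m, snvs = FALSE, aa_subs = FALSE)
  expect_true(all(lib_ind$records$sequence %in%
                    c(lib1$records$sequence)))
})

test_that("dedup precedence annotates shared sequences as substitutions first", {
  cds <- random_cds(15, seed = 23)
  m <- coding_model(cds)
  lib <- build_library(m)
  # any sequence reachable as both SNV and something else must be a
  # substitution record; equal-kind duplicates resolve to the 5'-most pos
  lens <- nchar(lib$records$sequence)
  same_len <- lib$records[lens == nchar(cds), ]
  expect_true(all(same_len$kind == "substitution"))
})

test_that("motif silencing removes BbsI sites without touching the protein", {
  # no site: unchanged
  m0 <- coding_model("ATGGATCGCTGGAAATAA")
  expect_identical(silence_motif(m0)$sequence, m0$sequence)

  # coding occurrence: GAA GAC spans codons 2-3 of ATG GAA GAC ...
  m1 <- coding_model("ATGGAAGACCTGAAATAA")
  s1 <- silence_motif(m1)
  expect_length(find_motif_public(s1$sequence, "GAAGAC"), 0L)
  expect_length(find_motif_public(s1$sequence, "GTCTTC"), 0L)
  expect_identical(s1$wt_protein, m1$wt_protein)

  # reverse-complement occurrence in coding sequence
  m2 <- coding_model("ATGGTCTTCCTGAAATAA")
  s2 <- silence_motif(m2)
  expect_length(find_motif_public(s2$sequence, "GAAGAC"), 0L)
  expect_length(find_motif_public(s2$sequence, "GTCTTC"), 0L)
  expect_identical(s2$wt_protein, m2$wt_protein)

  # intronic occurrence: removed by a single intronic base change
  seq3 <- paste0("ATGAAA", "GT", "GAAGACTT", "AG", "TGGTAA")
  m3 <- transcript_model(seq3, rbind(c(0, 6), c(18, 24)), cds_start = 0,
                         flank_len = 3)
  s3 <- silence_motif(m3)
  expect_length(find_motif_public(s3$sequence, "GAAGAC"), 0L)
  expect_identical(s3$wt_protein, m3$wt_protein)
  # splice dinucleotides untouched
  expect_equal(substring(s3$sequence, 7, 8), "GT")
  expect_equal(substring(s3$sequence, 17, 18), "AG")
})

test_that("library TSV/FASTA round trip preserves records", {
  cds <- random_cds(12, seed = 29)
  m <- coding_model(cds, constant_len = 0L)
  lib <- build_library(m)
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  write_library(lib, tsv = tsv, fasta = fa)
  lib2 <- read_library(tsv, wt_sequences = lib$wt_sequences)
  expect_equal(lib2$records$variant_id, lib$records$variant_id)
  expect_equal(lib2$records$sequence, lib$records$sequence)
  fasta <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(fasta), nrow(lib$records))
  expect_equal(unname(as.character(fasta)), lib$records$sequence)
})
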