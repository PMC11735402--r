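# Shared fixtures and independent oracles for the test suite.

# Single-exon model whose variable region is the whole (coding) sequence.
coding_model <- function(cds, flank_len = 0L, constant_len = 0L) {
  transcript_model(cds, cbind(0L, nchar(cds)), cds_start = 0L,
                   flank_len = flank_len, constant_len = constant_len)
}

# Random in-frame coding sequence without premature stops.
random_cds <- function(n_codons, seed) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  withr::with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""))
}

# Brute-force re-translation oracle: spliced protein of an edited model
# sequence, built by naive string surgery independent of annotate_edit.
oracle_protein <- function(model, region, edit) {
  r <- model$regions[model$regions$region == region, ]
  wt_region <- substring(model$sequence, r$var_start + 1L, r$var_end)
  ed_region <- apply_edit(edit, wt_region)
  full <- paste0(substring(model$sequence, 1L, r$var_start), ed_region,
                 substring(model$sequence, r$var_end + 1L))
  # shift every exon boundary lying strictly downstream of the edit start;
  # valid for exon-interior edits (callers restrict oracle use to those)
  shift <- nchar(ed_region) - nchar(wt_region)
  gpos <- r$var_start + edit$pos
  exons <- model$exons
  exons[exons > gpos] <- exons[exons > gpos] + shift
  spliced <- paste(substring(full, exons[, 1L] + 1L, exons[, 2L]),
                   collapse = "")
  cds <- substring(spliced, model$cds_start + 1L)
  cds <- substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  paste(Biostrings::GENETIC_CODE[
    substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))],
    collapse = "")
}

# Independent brute-force library enumerator: the set of distinct non-WT
# sequences reachable by the four enumerations, built with plain string ops.
oracle_library_sequences <- function(model, region) {
  r <- model$regions[model$regions$region == region, ]
  wt <- substring(model$sequence, r$var_start + 1L, r$var_end)
  L <- nchar(wt)
  gc <- Biostrings::GENETIC_CODE
  seqs <- character(0)
  # SNVs
  for (i in seq_len(L)) for (b in c("A", "C", "G", "T")) {
    s <- wt; substring(s, i, i) <- b
    if (s != wt) seqs <- c(seqs, s)
  }
  # whole-codon exchanges for every aa + stop target not reachable by SNV
  for (k in seq_along(model$wt_protein)) {
    sp0 <- model$cds_start + (k - 1L) * 3L
    # global 0-based codon start assuming single-exon coding fixtures
    off <- 0L; g0 <- NA
    for (i in seq_len(nrow(model$exons))) {
      len <- model$exons[i, 2L] - model$exons[i, 1L]
      if (sp0 >= off && sp0 + 3L <= off + len) {
        g0 <- model$exons[i, 1L] + (sp0 - off)
        if (g0 < r$exon_start || g0 + 3L > r$exon_end) g0 <- NA
        break
      }
      off <- off + len
    }
    if (is.na(g0)) next
    p <- g0 - r$var_start  # 0-based within region
    ref_codon <- substring(wt, p + 1L, p + 3L)
    reach <- character(0)
    for (i in 1:3) for (b in c("A", "C", "G", "T")) {
      cod <- ref_codon; substring(cod, i, i) <- b
      if (cod != ref_codon) reach <- c(reach, gc[[cod]])
    }
    for (target in unique(unname(gc))) {
      if (target == gc[[ref_codon]]) {
        if (gc[[ref_codon]] %in% reach || sum(gc == target) < 2L) next
      } else if (target %in% reach) next
      cands <- sort(setdiff(names(gc)[gc == target], ref_codon))
      d <- vapply(cands, function(c2)
        sum(strsplit(c2, "")[[1]] != strsplit(ref_codon, "")[[1]]),
        integer(1))
      alt <- cands[which.min(d)]
      s <- paste0(substring(wt, 1L, p), alt, substring(wt, p + 4L))
      seqs <- c(seqs, s)
    }
  }
  # insertions before each position
  for (i in 0:(L - 1L)) for (b in c("A", "C", "G", "T")) {
    seqs <- c(seqs, paste0(substring(wt, 1L, i), b, substring(wt, i + 1L)))
  }
  # deletions of 1-3 nt
  for (s_ in 1:3) for (i in 0:(L - s_)) {
    seqs <- c(seqs, paste0(substring(wt, 1L, i), substring(wt, i + s_ + 1L)))
  }
  setdiff(unique(seqs), wt)
}

# Plain-string motif finder (independent of the package internals).
find_motif_public <- function(seq, motif) {
  k <- nchar(motif); n <- nchar(seq)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(seq, starts, starts + k - 1L) == motif]
}

# Hash-map read-counting oracle.
oracle_count <- function(reads, sequences) {
  env <- new.env(hash = TRUE)
  for (s in sequences) assign(s, 0L, envir = env)
  unmatched <- 0L
  for (r in reads) {
    if (exists(r, envir = env, inherits = FALSE)) {
      assign(r, get(r, envir = env) + 1L, envir = env)
    } else {
      unmatched <- unmatched + 1L
    }
  }
  list(counts = vapply(sequences, function(s) get(s, envir = env),
                       integer(1)),
       unmatched = unmatched)
}

# Minimal PDB writer for synthetic structure fixtures.
# atoms: data.frame(chain, resno, resid, name, x, y, z, elem)
write_synthetic_pdb <- function(atoms, path, models = 1L) {
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1L) lines <- c(lines, sprintf("MODEL %8d", m))
    for (i in seq_len(nrow(atoms))) {
      a <- atoms[i, ]
      # second model shifted so tests can confirm only model 1 is read
      dx <- if (m > 1L) 100 else 0
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, a$name, a$resid, a$chain, a$resno, a$x + dx, a$y, a$z, a$elem))
    }
    if (models > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
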