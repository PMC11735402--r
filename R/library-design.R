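#' Silently remove a restriction motif from a transcript model
#'
#' Golden-Gate cloning requires the target sequence to be free of the cloning
#' enzyme's recognition site. Every occurrence of \code{motif} or its reverse
#' complement is removed: occurrences overlapping coding sequence by a
#' synonymous codon exchange (codons scanned 5' to 3', alternative codons in
#' alphabetical order, first change that removes the occurrence without
#' creating a new one wins); purely intronic occurrences by a single-base
#' change (positions 5' to 3', bases alphabetical), never touching a splice
#' dinucleotide.
#'
#' @param model An \code{sge_transcript}.
#' @param motif Recognition sequence (default BbsI, \code{GAAGAC}).
#' @param max_iter Safety bound on the removal loop.
#' @return A new \code{sge_transcript} with identical protein sequence and no
#'   occurrence of the motif on either strand.
#' @export
silence_motif <- function(model, motif = "GAAGAC", max_iter = 100L) {
  check_dna(motif, "motif")
  if (nchar(motif) < 4L) stop("motif must be at least 4 nt", call. = FALSE)
  seq <- model$sequence
  for (iter in seq_len(max_iter)) {
    occ <- motif_occurrences(seq, motif)
    if (nrow(occ) == 0L) break
    seq <- remove_one_occurrence(seq, occ[1L, ], motif, model)
  }
  if (nrow(motif_occurrences(seq, motif)) > 0L) {
    stop("failed to silence all motif occurrences", call. = FALSE)
  }
  out <- transcript_model(seq, model$exons, model$cds_start,
                          model$codon_offset, model$flank_len,
                          model$constant_len, model$name)
  if (!identical(out$wt_protein, model$wt_protein)) {
    stop("internal error: silencing altered the protein", call. = FALSE)
  }
  out
}

# All occurrences of motif / its reverse complement (1-based starts).
motif_occurrences <- function(seq, motif) {
  rc <- revcomp(motif)
  pats <- unique(c(motif, rc))
  hits <- unlist(lapply(pats, function(p) find_motif(seq, p)))
  occ <- data.frame(start = if (is.null(hits)) integer(0) else hits,
                    len = rep(nchar(motif), length(hits)))
  occ[order(occ$start), , drop = FALSE]
}

remove_one_occurrence <- function(seq, occ, motif, model) {
  mask <- exonic_mask(model)
  span <- occ$start:(occ$start + occ$len - 1L)      # 1-based positions
  n0 <- nrow(motif_occurrences(seq, motif))

  # --- coding route: synonymous codon exchange ----------------------------
  exonic_pos <- span[mask[span]]
  gc <- genetic_code()
  for (g in exonic_pos) {
    k <- codon_of_global_pos(model, g - 1L)
    if (is.na(k)) next
    # global span of codon k (requires all three bases in one exon)
    cod_span <- codon_global_span(model, k)
    if (is.null(cod_span)) next
    ref_codon <- substring(seq, cod_span[1L], cod_span[3L])
    syn <- sort(names(gc)[gc == gc[[ref_codon]]])
    syn <- setdiff(syn, ref_codon)
    for (alt in syn) {
      cand <- paste0(substring(seq, 1L, cod_span[1L] - 1L), alt,
                     substring(seq, cod_span[3L] + 1L))
      if (occurrence_removed(cand, seq, occ, motif, n0)) return(cand)
    }
  }

  # --- intronic route: single-base change ---------------------------------
  intronic_pos <- span[!mask[span]]
  forbidden <- splice_dinucleotide_positions(model)
  for (g in setdiff(intronic_pos, forbidden)) {
    cur <- substring(seq, g, g)
    for (b in setdiff(BASES, cur)) {
      cand <- paste0(substring(seq, 1L, g - 1L), b, substring(seq, g + 1L))
      if (occurrence_removed(cand, seq, occ, motif, n0)) return(cand)
    }
  }
  stop("unsilenceable motif occurrence at position ", occ$start, call. = FALSE)
}

occurrence_removed <- function(cand, seq, occ, motif, n0) {
  occ_new <- motif_occurrences(cand, motif)
  gone <- !any(occ_new$start == occ$start &
                 substring(cand, occ$start, occ$start + occ$len - 1L) %in%
                   c(motif, revcomp(motif)))
  gone && nrow(occ_new) < n0
}

# 1-based global positions of the first/last two bases of every intron.
splice_dinucleotide_positions <- function(model) {
  if (nrow(model$exons) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(model$exons) - 1L)) {
    istart <- model$exons[i, 2L]        # 0-based first intron base
    iend <- model$exons[i + 1L, 1L]
    out <- c(out, istart + 1L, istart + 2L, iend - 1L, iend)
  }
  out
}

# 1-based global positions (start, mid, end) of CDS codon k when the codon
# lies fully inside a single exon, else NULL.
codon_global_span <- function(model, k) {
  sp0 <- model$cds_start + (k - 1L) * 3L  # spliced 0-based start
  off <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1L]; e <- model$exons[i, 2L]
    len <- e - s
    if (sp0 >= off && sp0 + 3L <= off + len) {
      g0 <- s + (sp0 - off)               # 0-based
      return(c(g0 + 1L, g0 + 2L, g0 + 3L))
    }
    off <- off + len
  }
  NULL
}

#' Enumerate all single-nucleotide substitutions of a region
#'
#' @param region_seq Variable-region sequence.
#' @return List of \code{sge_edit}s, 3 per position (every other base).
#' @export
enumerate_snvs <- function(region_seq) {
  L <- nchar(region_seq)
  if (L == 0L) return(list())
  out <- vector("list", 3L * L)
  j <- 0L
  for (i in seq_len(L)) {
    ref <- substring(region_seq, i, i)
    for (alt in setdiff(BASES, ref)) {
      j <- j + 1L
      out[[j]] <- edit_spec("substitution", i - 1L, ref, alt)
    }
  }
  out
}

#' Minimal-Hamming codon exchange
#'
#' Returns the codon encoding \code{target_aa} with the smallest Hamming
#' distance to \code{ref_codon}; ties are broken by the tie rule
#' (default: lexicographically smallest codon).
#'
#' @param ref_codon Reference 3-mer.
#' @param target_aa One-letter amino acid code, or \code{"*"} for stop.
#' @param tie_rule Currently only \code{"lexicographic"}.
#' @return A 3-mer different from \code{ref_codon}.
#' @export
min_hamming_codon <- function(ref_codon, target_aa,
                              tie_rule = "lexicographic") {
  tie_rule <- match.arg(tie_rule, "lexicographic")
  gc <- genetic_code()
  cands <- sort(names(gc)[gc == target_aa])
  cands <- setdiff(cands, ref_codon)
  if (length(cands) == 0L) {
    stop("no alternative codon encodes ", target_aa,
         " (single-codon amino acid)", call. = FALSE)
  }
  d <- vapply(cands, hamming, integer(1), a = ref_codon)
  cands[which(d == min(d))][1L]   # candidates already sorted
}

#' Enumerate multi-nucleotide codon substitutions for full amino-acid coverage
#'
#' For every codon lying fully inside the exon of \code{region}, finds the
#' amino-acid (and stop) targets that no single-nucleotide substitution can
#' reach and adds one 2- or 3-nt substitution per missing target, chosen by
#' \code{\link{min_hamming_codon}}. Together with the SNV set this covers all
#' 19 missense targets plus stop at each fully-internal codon; a synonymous
#' target is also added when the reference amino acid has an alternative
#' codon that is not SNV-reachable (methionine and tryptophan, being
#' single-codon amino acids, get no synonymous entry).
#'
#' @param model An \code{sge_transcript}.
#' @param region Region id or index.
#' @param include_synonymous Add non-SNV-reachable synonymous exchanges.
#' @return List of \code{sge_edit}s (substitutions trimmed to the differing
#'   span within the codon).
#' @export
enumerate_aa_substitutions <- function(model, region,
                                       include_synonymous = TRUE) {
  r <- region_row(model, region)
  gc <- genetic_code()
  targets_all <- sort(unique(unname(gc)))   # 20 amino acids + '*'
  out <- list()
  for (k in region_codons(model, region)) {
    cod_span <- codon_global_span(model, k)
    ref_codon <- substring(model$sequence, cod_span[1L], cod_span[3L])
    ref_aa <- gc[[ref_codon]]
    reachable <- snv_reachable_aas(ref_codon, gc)
    for (target in targets_all) {
      if (target == ref_aa) {
        if (!include_synonymous) next
        if (ref_aa %in% reachable) next           # synonymous SNV exists
        if (sum(gc == ref_aa) < 2L) next          # Met/Trp: impossible
      } else if (target %in% reachable) {
        next
      }
      alt_codon <- min_hamming_codon(ref_codon, target)
      out[[length(out) + 1L]] <-
        codon_substitution_edit(ref_codon, alt_codon,
                                cod_span[1L] - 1L - r$var_start)
    }
  }
  out
}

# Amino acids reachable from ref_codon by one nucleotide substitution
# (reference amino acid included only if a synonymous SNV exists).
snv_reachable_aas <- function(ref_codon, gc = genetic_code()) {
  aas <- character(0)
  for (i in 1:3) {
    ref <- substring(ref_codon, i, i)
    for (b in setdiff(BASES, ref)) {
      cod <- ref_codon
      substring(cod, i, i) <- b
      aas <- c(aas, gc[[cod]])
    }
  }
  unique(aas)
}

# Substitution edit for a whole-codon exchange, trimmed to the span between
# the first and last differing base. codon_pos0: 0-based region position of
# the codon's first base.
codon_substitution_edit <- function(ref_codon, alt_codon, codon_pos0) {
  diff <- which(utf8ToInt(ref_codon) != utf8ToInt(alt_codon))
  i <- diff[1L]; j <- diff[length(diff)]
  edit_spec("substitution", codon_pos0 + i - 1L,
            substring(ref_codon, i, j), substring(alt_codon, i, j))
}

# 1-based CDS codon indices fully inside the exon of `region`.
region_codons <- function(model, region) {
  r <- region_row(model, region)
  n_codons <- length(model$wt_protein)
  keep <- integer(0)
  for (k in seq_len(n_codons)) {
    span <- codon_global_span(model, k)
    if (!is.null(span) &&
        span[1L] - 1L >= r$exon_start && span[3L] <= r$exon_end) {
      keep <- c(keep, k)
    }
  }
  keep
}

#' Enumerate single-base insertions and 1-3 nt deletions
#'
#' Insertions place each of the four bases before every position of the
#' variable region (4L raw edits); deletions remove 1 to \code{max_del}
#' consecutive bases at every admissible start. All indels are left-aligned;
#' duplicates by resulting sequence are collapsed later in
#' \code{\link{build_library}}.
#'
#' @param region_seq Variable-region sequence.
#' @param max_del Maximum deletion size.
#' @return List of \code{sge_edit}s.
#' @export
enumerate_indels <- function(region_seq, max_del = 3L) {
  L <- nchar(region_seq)
  if (L == 0L) return(list())
  out <- list()
  for (i in 0:(L - 1L)) {
    for (b in BASES) {
      out[[length(out) + 1L]] <-
        left_align_edit(edit_spec("insertion", i, "", b), region_seq)
    }
  }
  for (s in seq_len(min(max_del, L))) {
    for (i in 0:(L - s)) {
      ref <- substring(region_seq, i + 1L, i + s)
      out[[length(out) + 1L]] <-
        left_align_edit(edit_spec("deletion", i, ref, ""), region_seq)
    }
  }
  out
}

#' Build the full saturation-mutagenesis library
#'
#' Applies the active enumerations to every variable region of the model,
#' computes the mutated variable-region sequence of each edit, removes the
#' wild-type sequence, deduplicates by resulting sequence (precedence:
#' substitution > deletion > insertion, then 5'-most position, then
#' alphabetical alternate allele) and annotates every kept record via
#' \code{\link{annotate_edit}}.
#'
#' @param model An \code{sge_transcript} (run \code{\link{silence_motif}}
#'   first if the construct is cloned with a type IIS enzyme).
#' @param snvs,aa_subs,insertions,deletions Enumeration switches.
#' @param max_del Maximum deletion size.
#' @param include_synonymous Forward to
#'   \code{\link{enumerate_aa_substitutions}}.
#' @return An object of class \code{sge_library}: list with \code{records}
#'   (one row per variant), \code{wt_sequences} (region -> wild-type variable
#'   region) and \code{config}.
#' @export
build_library <- function(model, snvs = TRUE, aa_subs = TRUE,
                          insertions = TRUE, deletions = TRUE,
                          max_del = 3L, include_synonymous = TRUE) {
  config <- list(snvs = snvs, aa_subs = aa_subs, insertions = insertions,
                 deletions = deletions, max_del = max_del,
                 include_synonymous = include_synonymous)
  wt_sequences <- vapply(model$regions$region, variable_region,
                         character(1), model = model)
  all_rows <- list()
  for (region in model$regions$region) {
    wt <- wt_sequences[[region]]
    if (nchar(wt) < max_del) {
      warning("region ", region, " too short for enumeration", call. = FALSE)
      next
    }
    edits <- list()
    if (snvs) edits <- c(edits, enumerate_snvs(wt))
    if (aa_subs) {
      edits <- c(edits, enumerate_aa_substitutions(model, region,
                                                   include_synonymous))
    }
    if (insertions || deletions) {
      ind <- enumerate_indels(wt, max_del)
      kinds <- vapply(ind, `[[`, character(1), "kind")
      if (!insertions) ind <- ind[kinds != "insertion"]
      if (!deletions) ind <- ind[kinds != "deletion"]
      edits <- c(edits, ind)
    }
    if (length(edits) == 0L) next
    df <- data.frame(
      region = region,
      kind = vapply(edits, `[[`, character(1), "kind"),
      pos = vapply(edits, `[[`, integer(1), "pos"),
      ref = vapply(edits, `[[`, character(1), "ref"),
      alt = vapply(edits, `[[`, character(1), "alt"),
      stringsAsFactors = FALSE
    )
    df$sequence <- vapply(edits, apply_edit, character(1), region_seq = wt)
    df <- df[df$sequence != wt & nchar(df$sequence) > 0L, , drop = FALSE]
    # dedup precedence: substitution > deletion > insertion, 5'-most, then
    # alphabetical alt
    prec <- match(df$kind, c("substitution", "deletion", "insertion"))
    df <- df[order(prec, df$pos, df$alt), , drop = FALSE]
    df <- df[!duplicated(df$sequence), , drop = FALSE]
    all_rows[[region]] <- df
  }
  records <- do.call(rbind, all_rows)
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty library", call. = FALSE)
  }
  rownames(records) <- NULL

  ann <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    e <- edit_spec(records$kind[i], records$pos[i],
                   records$ref[i], records$alt[i])
    ann[[i]] <- annotate_edit(e, model, records$region[i])
  }
  records <- cbind(records, do.call(rbind, ann))
  records$hamming_to_wt <- NA_integer_
  subs <- records$kind == "substitution"
  records$hamming_to_wt[subs] <- mapply(hamming, records$ref[subs],
                                        records$alt[subs], USE.NAMES = FALSE)
  records$variant_id <- sprintf(
    "%s:%s:%d:%s>%s", records$region,
    c(substitution = "sub", deletion = "del",
      insertion = "ins")[records$kind],
    records$pos + 1L,
    ifelse(records$ref == "", "-", records$ref),
    ifelse(records$alt == "", "-", records$alt)
  )
  records <- records[, c("variant_id", setdiff(names(records), "variant_id"))]
  structure(list(records = records, wt_sequences = as.list(wt_sequences),
                 config = config, model_name = model$name),
            class = "sge_library")
}

#' @export
print.sge_library <- function(x, ...) {
  cat(sprintf("<sge_library> %d variants across %d region(s)\n",
              nrow(x$records), length(x$wt_sequences)))
  print(table(x$records$coding_class))
  invisible(x)
}

#' Minimum pairwise Hamming distance of a library
#'
#' Computed per region over all pairs of distinct equal-length sequences
#' (sequences of different length are not comparable under the Hamming
#' metric). A well-formed exhaustive library attains 1: two substitutions at
#' the same position differ at exactly that position.
#'
#' @param library An \code{sge_library}.
#' @return Integer (or \code{Inf} when no comparable pair exists).
#' @export
library_min_hamming <- function(library) {
  best <- Inf
  for (region in names(library$wt_sequences)) {
    seqs <- library$records$sequence[library$records$region == region]
    best <- min(best, min_pairwise_hamming(seqs))
    if (best == 1) return(1)
  }
  best
}

#' Write the library as annotation TSV and FASTA
#'
#' @param library An \code{sge_library}.
#' @param tsv,fasta Output paths (either may be \code{NULL}).
#' @param model Optional \code{sge_transcript}; when given, FASTA records are
#'   full oligonucleotides with the constant frames prepended/appended.
#' @export
write_library <- function(library, tsv = NULL, fasta = NULL, model = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(library$records, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta)) {
    seqs <- library$records$sequence
    if (!is.null(model)) {
      fr <- lapply(library$records$region, constant_frames, model = model)
      seqs <- paste0(vapply(fr, `[[`, character(1), "flank5"), seqs,
                     vapply(fr, `[[`, character(1), "flank3"))
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- library$records$variant_id
    Biostrings::writeXStringSet(x, fasta)
  }
  invisible(library)
}

#' Read a library annotation TSV written by \code{\link{write_library}}
#' @param tsv Path.
#' @param wt_sequences Named list/vector of wild-type variable-region
#'   sequences per region (needed for exact-match counting).
#' @export
read_library <- function(tsv, wt_sequences = NULL) {
  records <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  structure(list(records = records,
                 wt_sequences = as.list(wt_sequences),
                 config = list(), model_name = NA_character_),
            class = "sge_library")
}
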