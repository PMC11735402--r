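#' Build a transcript / mini-gene model
#'
#' Represents the mutagenesis target: a contiguous stretch of genomic sequence
#' in transcript-strand orientation containing one or more exons with their
#' flanking intron sequence. Each exon defines one *variable region* (the exon
#' plus \code{flank_len} intronic nucleotides on each side) framed by constant
#' regions of \code{constant_len} nucleotides that stay identical across all
#' synthetic oligonucleotides.
#'
#' All coordinates are 0-based, half-open. The spliced CDS is the
#' concatenation of the exon sequences starting at spliced offset
#' \code{cds_start}; \code{codon_offset} gives the protein position of the
#' first complete codon so that reported residue numbers match full-length
#' protein numbering (e.g. 126 for a p53 DNA-binding-domain construct starting
#' in exon 5).
#'
#' @param sequence Uppercase A/C/G/T string, transcript-strand orientation.
#' @param exons Two-column matrix (or list of length-2 vectors) of 0-based
#'   half-open \code{[start, end)} exon intervals on \code{sequence}.
#' @param cds_start Offset of the first codon base in *spliced* coordinates.
#' @param codon_offset Protein position of the first complete codon.
#' @param flank_len Intronic flank length included in each variable region.
#' @param constant_len Length of the constant frames outside each variable
#'   region.
#' @param name Model identifier.
#' @return An object of class \code{sge_transcript}.
#' @examples
#' m <- transcript_model("ATGAAATAA", cbind(0, 9), cds_start = 0)
#' spliced_cds(m)
#' @export
transcript_model <- function(sequence, exons, cds_start,
                             codon_offset = 1L, flank_len = 12L,
                             constant_len = 13L, name = "transcript") {
  check_dna(sequence)
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(exons), ncol = 2L)
  if (nrow(exons) == 0L) stop("at least one exon is required", call. = FALSE)
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  n <- nchar(sequence)
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] > n) ||
      any(exons[, 2L] <= exons[, 1L])) {
    stop("exon intervals out of range or empty", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("exon intervals overlap", call. = FALSE)
  }
  cds_start <- as.integer(cds_start)
  spliced_len <- sum(exons[, 2L] - exons[, 1L])
  if (cds_start < 0L || spliced_len - cds_start < 3L) {
    stop("spliced CDS must contain at least one codon", call. = FALSE)
  }

  # Canonical splice dinucleotide check (GT...AG) on internal introns.
  if (nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      istart <- exons[i, 2L]
      iend <- exons[i + 1L, 1L]
      donor <- substring(sequence, istart + 1L, istart + 2L)
      acceptor <- substring(sequence, iend - 1L, iend)
      if (donor != "GT" || acceptor != "AG") {
        warning(sprintf("intron %d is not GT..AG (%s..%s)", i, donor, acceptor),
                call. = FALSE)
      }
    }
  }

  # Variable regions: exon +/- flank, clipped to the sequence and to the
  # midpoint of short introns so regions never overlap.
  nr <- nrow(exons)
  vs <- pmax(exons[, 1L] - flank_len, 0L)
  ve <- pmin(exons[, 2L] + flank_len, n)
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) {
      if (ve[i] > vs[i + 1L]) {
        mid <- (exons[i, 2L] + exons[i + 1L, 1L]) %/% 2L
        ve[i] <- mid
        vs[i + 1L] <- mid
      }
    }
  }
  regions <- data.frame(
    region = paste0("E", seq_len(nr)),
    exon_start = exons[, 1L], exon_end = exons[, 2L],
    var_start = as.integer(vs), var_end = as.integer(ve),
    const_start = as.integer(pmax(vs - constant_len, 0L)),
    const_end = as.integer(pmin(ve + constant_len, n)),
    stringsAsFactors = FALSE
  )

  model <- structure(
    list(
      name = name, sequence = sequence, exons = exons,
      cds_start = cds_start, codon_offset = as.integer(codon_offset),
      flank_len = as.integer(flank_len),
      constant_len = as.integer(constant_len),
      regions = regions
    ),
    class = "sge_transcript"
  )
  model$wt_protein <- translate_nt(spliced_cds(model))
  model
}

#' @export
print.sge_transcript <- function(x, ...) {
  cat(sprintf("<sge_transcript> %s: %d nt, %d exon(s), CDS %d nt (codons %d-%d)\n",
              x$name, nchar(x$sequence), nrow(x$exons),
              3L * length(x$wt_protein), x$codon_offset,
              x$codon_offset + length(x$wt_protein) - 1L))
  invisible(x)
}

# Logical vector: is each position of `sequence` exonic?
exonic_mask <- function(model) {
  mask <- rep(FALSE, nchar(model$sequence))
  for (i in seq_len(nrow(model$exons))) {
    mask[(model$exons[i, 1L] + 1L):model$exons[i, 2L]] <- TRUE
  }
  mask
}

#' Spliced transcript and CDS
#'
#' \code{splice} concatenates the exon sequences; \code{spliced_cds} drops the
#' leading \code{cds_start} spliced bases and any trailing partial codon.
#' @param model An \code{sge_transcript}.
#' @return A nucleotide string.
#' @export
splice <- function(model) {
  paste(substring(model$sequence, model$exons[, 1L] + 1L, model$exons[, 2L]),
        collapse = "")
}

#' @rdname splice
#' @export
spliced_cds <- function(model) {
  s <- splice(model)
  cds <- substring(s, model$cds_start + 1L)
  substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
}

#' Variable-region sequence of one region
#' @param model An \code{sge_transcript}.
#' @param region Region id (e.g. \code{"E1"}) or index.
#' @export
variable_region <- function(model, region) {
  r <- region_row(model, region)
  substring(model$sequence, r$var_start + 1L, r$var_end)
}

#' Constant frames around one variable region
#' @inheritParams variable_region
#' @return List with elements \code{flank5} and \code{flank3}.
#' @export
constant_frames <- function(model, region) {
  r <- region_row(model, region)
  list(
    flank5 = substring(model$sequence, r$const_start + 1L, r$var_start),
    flank3 = substring(model$sequence, r$var_end + 1L, r$const_end)
  )
}

region_row <- function(model, region) {
  if (is.numeric(region)) {
    i <- as.integer(region)
  } else {
    i <- match(region, model$regions$region)
  }
  if (is.na(i) || i < 1L || i > nrow(model$regions)) {
    stop("unknown region: ", region, call. = FALSE)
  }
  model$regions[i, , drop = FALSE]
}

#' Construct an edit
#'
#' An edit is a substitution, insertion or deletion expressed in 0-based
#' coordinates of a variable region. Substitutions carry equal-length
#' \code{ref}/\code{alt} spans of 1-3 nt (with \code{ref != alt}); insertions
#' carry a single \code{alt} base inserted *before* \code{pos}; deletions
#' carry a 1-3 nt \code{ref} span. Indels should be left-aligned (see
#' \code{\link{left_align_edit}}).
#'
#' @param kind One of \code{"substitution"}, \code{"insertion"},
#'   \code{"deletion"}.
#' @param pos 0-based position within the variable region.
#' @param ref Reference allele (empty for insertions).
#' @param alt Alternate allele (empty for deletions).
#' @export
edit_spec <- function(kind, pos, ref = "", alt = "") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  pos <- as.integer(pos)
  if (pos < 0L) stop("pos must be >= 0", call. = FALSE)
  if (kind == "substitution") {
    if (nchar(ref) != nchar(alt) || !nchar(ref) %in% 1:3 || ref == alt) {
      stop("substitution needs equal-length ref/alt of 1-3 nt, ref != alt",
           call. = FALSE)
    }
  } else if (kind == "insertion") {
    if (nchar(ref) != 0L || nchar(alt) != 1L) {
      stop("insertion needs empty ref and a single alt base", call. = FALSE)
    }
  } else {
    if (nchar(alt) != 0L || !nchar(ref) %in% 1:3) {
      stop("deletion needs empty alt and a 1-3 nt ref", call. = FALSE)
    }
  }
  structure(list(kind = kind, pos = pos, ref = ref, alt = alt),
            class = "sge_edit")
}

#' Left-align an indel within its region sequence (VCF-style)
#'
#' Homopolymer-ambiguous indels are shifted 5' as far as possible so that every
#' resulting sequence has one canonical edit representation. Substitutions are
#' returned unchanged.
#' @param edit An \code{sge_edit}.
#' @param region_seq The wild-type variable-region sequence the edit applies
#'   to.
#' @export
left_align_edit <- function(edit, region_seq) {
  if (edit$kind == "substitution") return(edit)
  chars <- strsplit(region_seq, "")[[1]]
  pos <- edit$pos
  if (edit$kind == "deletion") {
    len <- nchar(edit$ref)
    # deleting [pos, pos+len) == deleting [pos-1, pos-1+len) iff
    # seq[pos-1] == seq[pos+len-1] (0-based)
    while (pos > 0L && chars[pos] == chars[pos + len]) pos <- pos - 1L
    edit$ref <- substring(region_seq, pos + 1L, pos + len)
  } else {
    while (pos > 0L && chars[pos] == edit$alt) pos <- pos - 1L
  }
  edit$pos <- pos
  edit
}

#' Apply an edit to a sequence
#' @inheritParams left_align_edit
#' @return The edited sequence.
#' @export
apply_edit <- function(edit, region_seq) {
  pos <- edit$pos
  L <- nchar(region_seq)
  if (edit$kind == "insertion") {
    if (pos > L) stop("edit outside region", call. = FALSE)
    return(paste0(substring(region_seq, 1L, pos), edit$alt,
                  substring(region_seq, pos + 1L)))
  }
  len <- nchar(edit$ref)
  if (pos + len > L) stop("edit outside region", call. = FALSE)
  obs <- substring(region_seq, pos + 1L, pos + len)
  if (obs != edit$ref) {
    stop(sprintf("ref mismatch at pos %d: expected %s, found %s",
                 pos, edit$ref, obs), call. = FALSE)
  }
  paste0(substring(region_seq, 1L, pos),
         if (edit$kind == "substitution") edit$alt else "",
         substring(region_seq, pos + len + 1L))
}

#' Annotate the consequence of an edit
#'
#' Applies the edit to the full model sequence, re-splices and re-translates,
#' and classifies the variant into the screen's taxonomy: coding classes
#' \code{synonymous}, \code{missense}, \code{nonsense}, \code{frameshift},
#' \code{inframe_indel}, \code{intronic}, \code{splice_dinucleotide}; and
#' nucleotide classes \code{sub1_Ts}/\code{sub1_Tv} (transition/transversion),
#' \code{sub2}, \code{sub3}, \code{ins}, \code{del_if}/\code{del_fs}
#' (in-frame/frameshift) and \code{intronic}.
#'
#' Disruption of an invariant splice dinucleotide (first/last two intron
#' bases) takes precedence over coding classification; edits spanning an
#' exon/intron boundary are classified by their exonic effect and flagged via
#' \code{boundary = TRUE}. \code{introduces_ptc} reports whether translation
#' of the edited spliced sequence terminates strictly before the wild-type
#' stop.
#'
#' @param edit An \code{sge_edit} in variable-region coordinates.
#' @param model An \code{sge_transcript}.
#' @param region Region id or index.
#' @return A one-row \code{data.frame} with columns \code{coding_class},
#'   \code{nt_class}, \code{protein_change}, \code{codon_index},
#'   \code{introduces_ptc}, \code{boundary}.
#' @export
annotate_edit <- function(edit, model, region) {
  r <- region_row(model, region)
  L <- r$var_end - r$var_start
  span_len <- if (edit$kind == "insertion") 0L else nchar(edit$ref)
  if (edit$pos + span_len > L || (edit$kind == "insertion" && edit$pos >= L)) {
    stop("edit outside region", call. = FALSE)
  }
  gs <- r$var_start + edit$pos            # 0-based global start
  ge <- gs + span_len                     # half-open end
  mask <- exonic_mask(model)

  # --- splice dinucleotide check ------------------------------------------
  splice_hit <- FALSE
  if (nrow(model$exons) > 1L) {
    for (i in seq_len(nrow(model$exons) - 1L)) {
      istart <- model$exons[i, 2L]        # first intron base (0-based)
      iend <- model$exons[i + 1L, 1L]     # one past last intron base
      dinucs <- c(istart, istart + 1L, iend - 2L, iend - 1L)
      if (span_len > 0L && any(dinucs >= gs & dinucs < ge)) splice_hit <- TRUE
      # insertion between the two bases of a dinucleotide breaks it
      if (edit$kind == "insertion" &&
          (gs == istart + 1L || gs == iend - 1L)) splice_hit <- TRUE
    }
  }

  # --- exonic overlap ------------------------------------------------------
  if (edit$kind == "insertion") {
    # inserted base inherits the status of the base it is inserted before
    exonic_span <- mask[gs + 1L]
    exonic_net <- if (exonic_span) 1L else 0L
    touches_exon <- exonic_span
    touches_intron <- !exonic_span
  } else {
    span_mask <- mask[(gs + 1L):ge]
    touches_exon <- any(span_mask)
    touches_intron <- any(!span_mask)
    exonic_net <- if (edit$kind == "deletion") -sum(span_mask) else 0L
  }
  boundary <- touches_exon && touches_intron
  # anchor for codon-level reporting: first exonic base touched by the edit
  g_anchor <- if (edit$kind == "insertion") gs else
    if (touches_exon) gs + which(span_mask)[1L] - 1L else gs

  if (!touches_exon && !splice_hit) {
    return(consequence_row("intronic", "intronic", NA_character_,
                           NA_integer_, FALSE, boundary))
  }

  # nt class by edit kind / size
  nt_class <- if (!touches_exon) {
    "intronic"
  } else if (edit$kind == "substitution") {
    ndiff <- hamming(edit$ref, edit$alt)
    if (ndiff == 1L) {
      i <- which(utf8ToInt(edit$ref) != utf8ToInt(edit$alt))[1]
      a <- substring(edit$ref, i, i); b <- substring(edit$alt, i, i)
      if ((a %in% PURINES) == (b %in% PURINES)) "sub1_Ts" else "sub1_Tv"
    } else if (ndiff == 2L) "sub2" else "sub3"
  } else if (edit$kind == "insertion") {
    "ins"
  } else {
    if ((-exonic_net) %% 3L == 0L) "del_if" else "del_fs"
  }

  # --- re-splice and translate the edited sequence -------------------------
  ed <- edited_cds(model, edit, gs, ge, mask)
  wt_aa <- model$wt_protein
  ed_aa <- ed$protein
  wt_stop <- stop_index(wt_aa)
  ed_stop <- stop_index(ed_aa)
  introduces_ptc <- is.finite(ed_stop) && ed_stop < wt_stop

  if (splice_hit) {
    cls <- "splice_dinucleotide"
    # splicing disruption is not modelled at sequence level; PTC unknown
    return(consequence_row(cls, nt_class, NA_character_, NA_integer_,
                           FALSE, boundary))
  }

  if (edit$kind == "substitution") {
    ncmp <- min(length(wt_aa), length(ed_aa))
    diffs <- which(wt_aa[seq_len(ncmp)] != ed_aa[seq_len(ncmp)])
    diffs <- diffs[diffs <= min(wt_stop, ncmp)]  # ignore changes past WT stop
    if (length(diffs) == 0L) {
      k <- codon_of_global_pos(model, g_anchor)
      return(consequence_row("synonymous", nt_class, "=",
                             protein_pos(model, k), FALSE, boundary))
    }
    k <- diffs[1L]
    pp <- protein_pos(model, k)
    chg <- paste0(wt_aa[k], pp, ed_aa[k])
    cls <- if (ed_aa[k] == "*") "nonsense" else "missense"
    return(consequence_row(cls, nt_class, chg, pp, introduces_ptc, boundary))
  }

  # indel
  if (exonic_net %% 3L != 0L) {
    k <- codon_of_global_pos(model, g_anchor)
    pp <- protein_pos(model, k)
    chg <- if (is.na(pp)) NA_character_ else paste0(wt_aa[k], pp, "fs")
    return(consequence_row("frameshift", nt_class, chg, pp,
                           introduces_ptc, boundary))
  }
  k <- codon_of_global_pos(model, g_anchor)
  pp <- protein_pos(model, k)
  suffix <- if (edit$kind == "deletion") "del" else "ins"
  chg <- if (is.na(pp)) NA_character_ else paste0(wt_aa[k], pp, suffix)
  consequence_row("inframe_indel", nt_class, chg, pp, introduces_ptc, boundary)
}

consequence_row <- function(coding_class, nt_class, protein_change,
                            codon_index, introduces_ptc, boundary) {
  data.frame(coding_class = coding_class, nt_class = nt_class,
             protein_change = protein_change, codon_index = codon_index,
             introduces_ptc = introduces_ptc, boundary = boundary,
             stringsAsFactors = FALSE)
}

stop_index <- function(aa) {
  i <- which(aa == "*")
  if (length(i) == 0L) Inf else i[1L]
}

# Protein position (full-protein numbering) of CDS codon k (1-based), NA if
# out of range.
protein_pos <- function(model, k) {
  if (is.na(k) || k < 1L) return(NA_integer_)
  model$codon_offset + as.integer(k) - 1L
}

# 1-based CDS codon index containing global position g (0-based); NA when g is
# intronic or upstream of the CDS.
codon_of_global_pos <- function(model, g) {
  sp <- global_to_spliced(model, g)
  if (is.na(sp) || sp < model$cds_start) return(NA_integer_)
  as.integer((sp - model$cds_start) %/% 3L) + 1L
}

# Spliced coordinate (0-based) of global position g, NA if intronic.
global_to_spliced <- function(model, g) {
  off <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1L]; e <- model$exons[i, 2L]
    if (g >= s && g < e) return(off + (g - s))
    off <- off + (e - s)
  }
  NA_integer_
}

# Edited spliced CDS + translation. The edit touches a single region; exon
# boundaries downstream of an indel shift with the indel, which is handled by
# editing per-base annotation vectors.
edited_cds <- function(model, edit, gs, ge, mask) {
  chars <- strsplit(model$sequence, "")[[1]]
  if (edit$kind == "substitution") {
    chars[(gs + 1L):ge] <- strsplit(edit$alt, "")[[1]]
  } else if (edit$kind == "deletion") {
    keep <- rep(TRUE, length(chars))
    keep[(gs + 1L):ge] <- FALSE
    chars <- chars[keep]
    mask <- mask[keep]
  } else {
    ins_exonic <- mask[gs + 1L]
    chars <- append(chars, edit$alt, after = gs)
    mask <- append(mask, ins_exonic, after = gs)
  }
  spliced <- paste(chars[mask], collapse = "")
  cds <- substring(spliced, model$cds_start + 1L)
  cds <- substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  list(cds = cds, protein = if (nchar(cds) >= 3L) translate_nt(cds)
                            else character(0))
}

#' Read/write a transcript model (FASTA + YAML sidecar)
#'
#' The sequence is stored as single-record FASTA and the exon intervals,
#' CDS offset, codon offset and flank/constant lengths in a YAML sidecar.
#' @param model An \code{sge_transcript}.
#' @param fasta,yaml File paths.
#' @export
write_transcript_model <- function(model, fasta, yaml) {
  seqs <- Biostrings::DNAStringSet(model$sequence)
  names(seqs) <- model$name
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- list(
    name = model$name,
    exons = lapply(seq_len(nrow(model$exons)),
                   function(i) as.integer(model$exons[i, ])),
    cds_start = model$cds_start, codon_offset = model$codon_offset,
    flank_len = model$flank_len, constant_len = model$constant_len
  )
  yaml::write_yaml(meta, yaml)
  invisible(model)
}

#' @rdname write_transcript_model
#' @export
read_transcript_model <- function(fasta, yaml) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- yaml::read_yaml(yaml)
  transcript_model(
    sequence = as.character(seqs[[1L]]),
    exons = do.call(rbind, meta$exons),
    cds_start = meta$cds_start, codon_offset = meta$codon_offset,
    flank_len = meta$flank_len, constant_len = meta$constant_len,
    name = meta$name %||% names(seqs)[1L]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
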