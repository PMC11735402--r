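#' Trim a merged amplicon read to its variable region
#'
#' A read is expected to be \code{flank5 + variable region + flank3}. Both
#' constant frames are matched by anchored Hamming comparison at the read
#' ends; reads whose frames exceed \code{max_flank_mismatch} mismatches are
#' rejected. Matching is exact on the interior: sequencing-error rescue is
#' deliberately not attempted because library sequences can differ by a single
#' nucleotide, so any mismatch tolerance would mis-assign reads between
#' adjacent variants.
#'
#' @param read Read sequence (merged, adapter-free).
#' @param flank5,flank3 Constant frames.
#' @param max_flank_mismatch Allowed mismatches per frame.
#' @return List with \code{ok} (logical), \code{interior} (string or
#'   \code{NA}) and \code{reason} (\code{"ok"} or \code{"flank_fail"}).
#' @export
trim_to_variable_region <- function(read, flank5, flank3,
                                    max_flank_mismatch = 0L) {
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  if (n5 == 0L || n3 == 0L) stop("flanks must be non-empty", call. = FALSE)
  if (nchar(read) < n5 + n3) {
    return(list(ok = FALSE, interior = NA_character_, reason = "flank_fail"))
  }
  m5 <- hamming(substring(read, 1L, n5), flank5)
  m3 <- hamming(substring(read, nchar(read) - n3 + 1L), flank3)
  if (m5 > max_flank_mismatch || m3 > max_flank_mismatch) {
    return(list(ok = FALSE, interior = NA_character_, reason = "flank_fail"))
  }
  list(ok = TRUE,
       interior = substring(read, n5 + 1L, nchar(read) - n3),
       reason = "ok")
}

#' Count exact-matching reads against a variant library
#'
#' Each read (already trimmed to the variable region) increments the count of
#' exactly one library variant iff its sequence matches that variant exactly.
#' Reads equal to the wild-type variable region are tallied separately and
#' discarded; anything else is counted as unmatched.
#'
#' @param reads Character vector of variable-region sequences.
#' @param library An \code{sge_library} with a wild-type sequence for
#'   \code{region}.
#' @param region Region id.
#' @return List with \code{counts} (named integer vector over the region's
#'   variant ids) and \code{stats} (reads_in, matched, wt_discarded,
#'   unmatched, flank_fail).
#' @export
count_reads <- function(reads, library, region) {
  rec <- library$records[library$records$region == region, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no library variants for region ", region,
                            call. = FALSE)
  if (anyDuplicated(rec$sequence)) {
    stop("library sequences are not unique within region ", region,
         call. = FALSE)
  }
  wt <- library$wt_sequences[[region]]
  counts <- integer(nrow(rec))
  names(counts) <- rec$variant_id
  idx <- match(reads, rec$sequence)
  hit <- !is.na(idx)
  if (any(hit)) {
    tab <- tabulate(idx[hit], nbins = nrow(rec))
    counts[] <- tab
  }
  n_wt <- if (is.null(wt)) 0L else sum(!hit & reads == wt)
  stats <- c(reads_in = length(reads), matched = sum(hit),
             wt_discarded = n_wt,
             unmatched = length(reads) - sum(hit) - n_wt,
             flank_fail = 0L)
  list(counts = counts, stats = stats)
}

#' Count a FASTQ file of merged reads for one sample
#'
#' Convenience wrapper: reads (optionally gzipped) FASTQ with
#' \pkg{Biostrings}, trims the constant frames and counts exact matches.
#' Base qualities are ignored; overlap-merged reads are assumed to be
#' error-corrected upstream.
#'
#' @param fastq Path to a FASTQ file.
#' @inheritParams count_reads
#' @param flank5,flank3 Constant frames around the variable region.
#' @param max_flank_mismatch Allowed mismatches per frame.
#' @export
count_fastq <- function(fastq, library, region, flank5, flank3,
                        max_flank_mismatch = 0L) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  long_enough <- nchar(reads) >= n5 + n3
  ok <- long_enough
  if (any(long_enough)) {
    r <- reads[long_enough]
    m5 <- mapply(function(x) hamming(substring(x, 1L, n5), flank5),
                 r, USE.NAMES = FALSE)
    m3 <- mapply(function(x)
      hamming(substring(x, nchar(x) - n3 + 1L), flank3),
      r, USE.NAMES = FALSE)
    ok[long_enough] <- m5 <= max_flank_mismatch & m3 <= max_flank_mismatch
  }
  interiors <- substring(reads[ok], n5 + 1L, nchar(reads[ok]) - n3)
  res <- count_reads(interiors, library, region)
  res$stats["flank_fail"] <- sum(!ok)
  res$stats["reads_in"] <- length(reads)
  res$stats["unmatched"] <- res$stats["reads_in"] - res$stats["matched"] -
    res$stats["wt_discarded"] - res$stats["flank_fail"]
  res
}

#' Relative variant abundances of one sample
#'
#' Divides each matched read count by the total number of matched reads.
#' @param counts Non-negative integer vector (one sample column).
#' @return Named numeric vector summing to 1.
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("degenerate sample: all counts zero", call. = FALSE)
  counts / total
}

#' Assemble a count matrix with sample metadata
#'
#' @param counts Integer matrix, variants x samples (rownames = variant ids,
#'   colnames = sample ids).
#' @param samples \code{data.frame} with one row per column of \code{counts}
#'   and columns \code{sample}, \code{condition} (e.g. \code{"control"},
#'   \code{"treated"}), \code{replicate}, \code{material} (\code{"DNA"} or
#'   \code{"mRNA"}).
#' @param stats Optional per-sample read-accounting matrix.
#' @return An object of class \code{sge_counts}.
#' @export
count_matrix <- function(counts, samples, stats = NULL) {
  counts <- as.matrix(counts)
  if (nrow(samples) != ncol(counts)) {
    stop("samples must describe each column of counts", call. = FALSE)
  }
  need <- c("sample", "condition", "replicate", "material")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples, stats = stats),
            class = "sge_counts")
}

#' @export
print.sge_counts <- function(x, ...) {
  cat(sprintf("<sge_counts> %d variants x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples)
  invisible(x)
}

#' Write/read count tables as TSV
#' @param x An \code{sge_counts}.
#' @param counts_tsv,samples_tsv Paths.
#' @export
write_counts <- function(x, counts_tsv, samples_tsv = NULL) {
  df <- data.frame(variant_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_tsv)) {
    utils::write.table(x$samples, samples_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_tsv, samples_tsv) {
  df <- utils::read.delim(counts_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  samples <- utils::read.delim(samples_tsv, stringsAsFactors = FALSE)
  count_matrix(m, samples)
}
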