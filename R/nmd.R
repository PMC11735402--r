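#' Nonsense-mediated decay detection from paired mRNA/DNA counts
#'
#' Compares each variant's abundance in the transcript pool (cDNA sequencing)
#' with its abundance in the genomic DNA of the same cell library. Variants
#' whose transcripts are degraded by NMD are depleted at the mRNA level;
#' the log2 fold change
#' \code{log2(median mRNA abundance) - log2(median DNA abundance)}
#' (medians over replicates, pseudocounted frequencies as in scoring) is
#' compared against a threshold. Variants with a mean raw cDNA read count
#' below \code{min_mean_cdna_count} carry too little signal and are marked
#' not evaluable.
#'
#' @param dna,mrna Count matrices (variants x replicates) sharing rownames,
#'   or \code{sge_counts} objects (all columns used).
#' @param pseudocount Pseudocount applied to raw counts when computing
#'   per-replicate abundances.
#' @param min_mean_cdna_count Minimum mean raw cDNA count for evaluability.
#' @param threshold NMD classification threshold on the log2 fold change.
#' @return \code{data.frame} per variant: \code{dna_abundance},
#'   \code{mrna_abundance} (medians over replicates),
#'   \code{log2fc_mrna_dna}, \code{mean_cdna_count}, \code{evaluable},
#'   \code{nmd_positive} (\code{NA} when not evaluable).
#' @export
nmd_log2fc <- function(dna, mrna, pseudocount = 0.5,
                       min_mean_cdna_count = 5, threshold = -2) {
  if (inherits(dna, "sge_counts")) dna <- dna$counts
  if (inherits(mrna, "sge_counts")) mrna <- mrna$counts
  dna <- as.matrix(dna); mrna <- as.matrix(mrna)
  common <- intersect(rownames(dna), rownames(mrna))
  if (length(common) == 0L) stop("no shared variants between DNA and mRNA",
                                 call. = FALSE)
  dna <- dna[common, , drop = FALSE]
  mrna <- mrna[common, , drop = FALSE]

  ab <- function(m) {
    f <- sweep(m + pseudocount, 2L, colSums(m) + pseudocount, "/")
    apply(f, 1L, stats::median)
  }
  dna_ab <- ab(dna)
  mrna_ab <- ab(mrna)
  lfc <- log2(mrna_ab) - log2(dna_ab)
  mean_cdna <- rowMeans(mrna)
  evaluable <- mean_cdna >= min_mean_cdna_count
  nmd <- ifelse(evaluable, classify_nmd(lfc, threshold), NA)
  data.frame(
    variant_id = common,
    dna_abundance = dna_ab, mrna_abundance = mrna_ab,
    log2fc_mrna_dna = lfc, mean_cdna_count = mean_cdna,
    evaluable = evaluable, nmd_positive = nmd,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify NMD status from a log2 fold change
#'
#' Strict inequality: a variant is NMD-positive iff its mRNA/DNA log2 fold
#' change is strictly below the threshold; boundary equality is negative.
#'
#' @param log2fc Numeric vector.
#' @param threshold Cutoff (default -2, i.e. a 4-fold mRNA depletion).
#' @return Logical vector.
#' @export
classify_nmd <- function(log2fc, threshold = -2) {
  log2fc < threshold
}
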