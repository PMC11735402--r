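#' Enrichment scores (log2 fold change of variant abundance)
#'
#' \code{ES = log2 f_treated - log2 f_control}. When raw counts are supplied,
#' frequencies are computed as \code{(c + pseudocount) / (N + pseudocount)}
#' with \code{N} the total matched reads of the sample, which keeps
#' zero-count variants finite. In pure-frequency mode a zero control
#' frequency yields \code{NA} (undefined score) and a warning.
#'
#' @param treated,control Either relative-abundance vectors (frequency mode)
#'   or raw count vectors when \code{from_counts = TRUE}. Must share the same
#'   variant universe (names).
#' @param pseudocount Added to raw counts (and totals); ignored in frequency
#'   mode.
#' @param from_counts Interpret inputs as raw counts.
#' @return Named numeric vector of enrichment scores.
#' @export
enrichment_scores <- function(treated, control, pseudocount = 0.5,
                              from_counts = TRUE) {
  if (length(treated) != length(control)) {
    stop("treated and control must share the variant universe", call. = FALSE)
  }
  if (from_counts) {
    ft <- (treated + pseudocount) / (sum(treated) + pseudocount)
    fc <- (control + pseudocount) / (sum(control) + pseudocount)
  } else {
    ft <- treated
    fc <- control
    if (any(fc == 0)) {
      warning("zero control frequency without pseudocount: score undefined",
              call. = FALSE)
      fc[fc == 0] <- NA_real_
    }
  }
  es <- log2(ft) - log2(fc)
  names(es) <- names(treated)
  es
}

#' Relative fitness score (RFS) transformation
#'
#' Control-anchored affine rescaling of enrichment scores:
#' \deqn{RFS(ES) = \frac{ES - \tilde{x}_{non}}{\tilde{x}_{non} -
#'   \tilde{x}_{syn}} \times 2 + 1}
#' where \eqn{\tilde{x}_{non}} and \eqn{\tilde{x}_{syn}} are the medians of
#' the nonsense and synonymous control scores. By construction the nonsense
#' median maps exactly to +1 and the synonymous median exactly to -1, making
#' scores comparable across libraries and screens regardless of their LOF /
#' WT-like composition.
#'
#' @param es Named numeric vector of enrichment scores.
#' @param nonsense_ids,synonymous_ids Names of the control variants (must be
#'   present in \code{es}).
#' @return Named numeric vector of RFS values.
#' @export
rfs_transform <- function(es, nonsense_ids, synonymous_ids) {
  m_non <- stats::median(es[nonsense_ids], na.rm = TRUE)
  m_syn <- stats::median(es[synonymous_ids], na.rm = TRUE)
  if (!is.finite(m_non) || !is.finite(m_syn)) {
    stop("control sets must be non-empty with finite scores", call. = FALSE)
  }
  if (m_non == m_syn) {
    stop("degenerate controls: nonsense and synonymous medians are equal",
         call. = FALSE)
  }
  (es - m_non) / (m_non - m_syn) * 2 + 1
}

#' Aggregate per-replicate RFS values
#'
#' @param rfs Matrix, variants x replicates (a vector is treated as a single
#'   replicate).
#' @return \code{data.frame} with \code{rfs_median} (elementwise median) and
#'   \code{rfs_mad} (raw median absolute deviation, constant = 1).
#' @export
aggregate_replicates <- function(rfs) {
  if (is.null(dim(rfs))) rfs <- matrix(rfs, ncol = 1L,
                                       dimnames = list(names(rfs), NULL))
  med <- apply(rfs, 1L, stats::median, na.rm = TRUE)
  mad <- apply(rfs, 1L, stats::mad, constant = 1, na.rm = TRUE)
  data.frame(rfs_median = med, rfs_mad = mad, row.names = rownames(rfs))
}

#' Count-based log-ratio score with standard error
#'
#' The log-ratio estimator used for per-variant significance testing:
#' \code{score = log2((c1+p)/N1) - log2((c0+p)/N0)} with a Poisson-derived
#' standard error \code{SE = (1/ln 2) * sqrt(1/(c1+p) + 1/(c0+p))}
#' (pseudocount \code{p}, default 0.5).
#'
#' @param c0,c1 Control / treated raw counts (vectors allowed).
#' @param N0,N1 Library-size totals of the two samples.
#' @param pseudocount Pseudocount.
#' @return \code{data.frame} with columns \code{score} and \code{se}.
#' @export
count_score_with_se <- function(c0, N0, c1, N1, pseudocount = 0.5) {
  if (any(N0 <= 0) || any(N1 <= 0)) stop("totals must be positive",
                                         call. = FALSE)
  score <- log2((c1 + pseudocount) / N1) - log2((c0 + pseudocount) / N0)
  se <- sqrt(1 / (c1 + pseudocount) + 1 / (c0 + pseudocount)) / log(2)
  data.frame(score = score, se = se, row.names = names(c0))
}

#' One-sided z-test against the synonymous null
#'
#' Tests, per variant, the null hypothesis that its score is equal to or
#' lower than the weighted mean of the synonymous variants. The synonymous
#' mean is inverse-variance weighted,
#' \eqn{\mu = \sum s_i/SE_i^2 / \sum 1/SE_i^2} with squared standard error
#' \eqn{SE_\mu^2 = 1/\sum 1/SE_i^2}; the statistic is
#' \eqn{z = (s_v - \mu) / \sqrt{SE_v^2 + SE_\mu^2}} with an upper-tail
#' standard-normal p value (scores above the synonymous population flag
#' candidate loss of function). P values are Benjamini-Hochberg adjusted over
#' all tested variants.
#'
#' @param scores,ses Named numeric vectors (same variants).
#' @param synonymous_ids Names of the synonymous control variants.
#' @return \code{data.frame} with columns \code{z}, \code{p}, \code{q}.
#' @export
syn_null_ztest <- function(scores, ses, synonymous_ids) {
  syn <- intersect(synonymous_ids, names(scores))
  if (length(syn) == 0L) stop("synonymous set is empty", call. = FALSE)
  if (any(ses <= 0, na.rm = TRUE)) {
    stop("degenerate weights: zero or negative SE", call. = FALSE)
  }
  w <- 1 / ses[syn]^2
  mu <- sum(scores[syn] * w) / sum(w)
  se_mu2 <- 1 / sum(w)
  z <- (scores - mu) / sqrt(ses^2 + se_mu2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(z = z, p = p, q = q, row.names = names(scores))
}

#' Score a screen end-to-end
#'
#' Runs the full per-variant scoring pipeline on a count matrix:
#' per-replicate enrichment scores (treated vs control DNA), per-exon RFS
#' normalization anchored on that exon's nonsense and synonymous variants,
#' replicate aggregation to \code{rfs_median}, a combined count-based
#' log-ratio score (per-replicate scores pooled by inverse-variance
#' weighting, then RFS-transformed per exon with its SE rescaled by the same
#' affine slope), and the one-sided synonymous-null z-test with BH
#' correction.
#'
#' @param counts An \code{sge_counts} with paired control/treated DNA samples
#'   per replicate.
#' @param library An \code{sge_library} annotating each variant.
#' @param treated,control Condition labels in \code{counts$samples}.
#' @param pseudocount Pseudocount for both score families.
#' @param min_control_count Variants whose mean control count falls below
#'   this value are flagged (\code{low_input}), not dropped.
#' @return A \code{data.frame} (one row per variant): per-replicate ES and
#'   RFS, \code{rfs_median}, \code{rfs_mad}, combined \code{score} and
#'   \code{se} (RFS scale), \code{z}, \code{p}, \code{q}, annotation columns.
#' @export
score_screen <- function(counts, library, treated = "treated",
                         control = "control", pseudocount = 0.5,
                         min_control_count = 0) {
  rec <- library$records
  m <- counts$counts
  rec <- rec[match(rownames(m), rec$variant_id), , drop = FALSE]
  if (anyNA(rec$variant_id)) {
    stop("count matrix contains variants absent from the library",
         call. = FALSE)
  }
  s <- counts$samples
  dna <- s[s$material == "DNA", , drop = FALSE]
  reps <- sort(unique(dna$replicate))
  regions <- unique(rec$region)
  non_ids <- rec$variant_id[rec$coding_class == "nonsense"]
  syn_ids <- rec$variant_id[rec$coding_class == "synonymous"]

  es_mat <- rfs_mat <- matrix(
    NA_real_, nrow(m), length(reps),
    dimnames = list(rownames(m), paste0("rep", reps))
  )
  score_mat <- se_mat <- es_mat
  ctrl_counts <- matrix(NA_real_, nrow(m), length(reps))
  for (j in seq_along(reps)) {
    r <- reps[j]
    cc <- m[, dna$sample[dna$condition == control & dna$replicate == r]]
    ct <- m[, dna$sample[dna$condition == treated & dna$replicate == r]]
    if (is.matrix(cc) || is.matrix(ct)) {
      stop("expected exactly one control and one treated DNA sample per ",
           "replicate", call. = FALSE)
    }
    ctrl_counts[, j] <- cc
    es <- enrichment_scores(ct, cc, pseudocount)
    es_mat[, j] <- es
    cs <- count_score_with_se(cc, sum(cc), ct, sum(ct), pseudocount)
    score_mat[, j] <- cs$score
    se_mat[, j] <- cs$se
    for (reg in regions) {
      in_reg <- rec$region == reg
      rfs_mat[in_reg, j] <- rfs_transform(
        es[in_reg],
        intersect(non_ids, rec$variant_id[in_reg]),
        intersect(syn_ids, rec$variant_id[in_reg])
      )
    }
  }

  agg <- aggregate_replicates(rfs_mat)

  # combined count score: fixed-effect inverse-variance pooling
  w <- 1 / se_mat^2
  comb_score <- rowSums(score_mat * w) / rowSums(w)
  comb_se <- sqrt(1 / rowSums(w))
  names(comb_score) <- names(comb_se) <- rownames(m)

  # transform pooled scores to the RFS scale per exon; SE scales by |slope|
  t_score <- comb_score
  t_se <- comb_se
  for (reg in regions) {
    in_reg <- rec$region == reg
    non_r <- intersect(non_ids, rec$variant_id[in_reg])
    syn_r <- intersect(syn_ids, rec$variant_id[in_reg])
    t_score[in_reg] <- rfs_transform(comb_score[in_reg], non_r, syn_r)
    slope <- 2 / abs(stats::median(comb_score[non_r]) -
                       stats::median(comb_score[syn_r]))
    t_se[in_reg] <- comb_se[in_reg] * slope
  }
  zt <- syn_null_ztest(t_score, t_se, syn_ids)

  out <- data.frame(
    variant_id = rec$variant_id, region = rec$region,
    coding_class = rec$coding_class, nt_class = rec$nt_class,
    protein_change = rec$protein_change, codon_index = rec$codon_index,
    es_mat, rfs_mat,
    rfs_median = agg$rfs_median, rfs_mad = agg$rfs_mad,
    score = t_score, se = t_se, z = zt$z, p = zt$p, q = zt$q,
    low_input = rowMeans(ctrl_counts) < min_control_count,
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE
  )
  colnames(out)[7:(6 + length(reps))] <- paste0("es_rep", reps)
  colnames(out)[(7 + length(reps)):(6 + 2 * length(reps))] <-
    paste0("rfs_rep", reps)
  out
}
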