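#' Binary functional classification from RFS
#'
#' A variant is called functionally abnormal when its median relative fitness
#' score is strictly positive (scores above 0 sit closer to the nonsense
#' anchor at +1 than to the synonymous anchor at -1).
#'
#' @param rfs Numeric vector of RFS medians.
#' @param threshold Decision boundary (strict \code{>}).
#' @return Character vector, \code{"abnormal"} / \code{"normal"}.
#' @export
classify_function <- function(rfs, threshold = 0) {
  ifelse(rfs > threshold, "abnormal", "normal")
}

#' Confusion table and derived metrics against a clinical truth set
#'
#' @param truth Named character vector, values \code{"pathogenic"} /
#'   \code{"benign"} (e.g. ClinVar-derived labels).
#' @param predicted Named character vector, values \code{"abnormal"} /
#'   \code{"normal"} (from \code{\link{classify_function}}). Only variants
#'   present in both are evaluated.
#' @return List with \code{confusion} (tp, fn, fp, tn), \code{precision},
#'   \code{recall}, \code{f1} (each \code{NA} when its denominator is zero).
#' @export
confusion_metrics <- function(truth, predicted) {
  common <- intersect(names(truth), names(predicted))
  if (length(common) == 0L) stop("no overlap between truth and predictions",
                                 call. = FALSE)
  t <- truth[common]; p <- predicted[common]
  tp <- sum(t == "pathogenic" & p == "abnormal")
  fn <- sum(t == "pathogenic" & p == "normal")
  fp <- sum(t == "benign" & p == "abnormal")
  tn <- sum(t == "benign" & p == "normal")
  confusion_from_counts(tp, fn, fp, tn)
}

#' @rdname confusion_metrics
#' @param tp,fn,fp,tn Confusion cells given directly.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
       precision = precision, recall = recall, f1 = f1)
}

#' Precision-recall and ROC curves with trapezoidal AUCs
#'
#' Sweeps every unique score as a decision threshold (predict positive when
#' \code{score >= threshold}), grouping tied scores into a single step so
#' that ties cannot inflate the AUC. Curve areas are computed by the
#' trapezoidal rule; the ROC curve is anchored at (0,0) and (1,1), the PR
#' curve starts at recall 0 with the precision of its first threshold point.
#'
#' @param truth Named vector, \code{"pathogenic"} / \code{"benign"}.
#' @param scores Named numeric vector (higher = more pathogenic).
#' @return List with \code{roc} / \code{pr} curve \code{data.frame}s and
#'   \code{roc_auc}, \code{pr_auc}.
#' @export
pr_roc <- function(truth, scores) {
  common <- intersect(names(truth), names(scores))
  t <- truth[common]
  s <- scores[common]
  keep <- is.finite(s)
  t <- t[keep]; s <- s[keep]
  pos <- t == "pathogenic"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in the truth set", call. = FALSE)
  }
  o <- order(s, decreasing = TRUE)
  s_o <- s[o]; pos_o <- pos[o]
  cum_tp <- cumsum(pos_o); cum_fp <- cumsum(!pos_o)
  last_idx <- cumsum(rle(s_o)$lengths)  # tied scores form one step
  thr <- s_o[last_idx]
  tp <- cum_tp[last_idx]; fp <- cum_fp[last_idx]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  precision <- tp / (tp + fp)

  roc <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pr <- data.frame(threshold = c(Inf, thr),
                   recall = c(0, tpr), precision = c(precision[1], precision))
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)
  list(roc = roc, pr = pr,
       roc_auc = trap(roc$fpr, roc$tpr),
       pr_auc = trap(pr$recall, pr$precision))
}

#' Odds of pathogenicity (OddsPath) from a functional-assay confusion table
#'
#' Implements the truth-set calibration of functional evidence used for
#' ACMG/AMP variant interpretation. With prior pathogenic proportion
#' \code{P1 = (TP+FN)/(TP+FN+FP+TN)} and posterior proportions
#' \code{P2 = TP/(TP+FP)} (among variants classified abnormal) and
#' \code{P2' = FN/(FN+TN)} (among variants classified normal):
#' \deqn{OddsPath = \frac{P2 (1 - P1)}{(1 - P2) P1}}
#' evaluated at \code{P2} for pathogenic (PS3) and at \code{P2'} for benign
#' (BS3) evidence. A zero misclassification cell makes the corresponding
#' odds infinite; \code{correction = TRUE} adds 0.5 to every cell first.
#'
#' Strength labels follow the published OddsPath evidence thresholds
#' (supporting 2.08, moderate 4.33, strong 18.7, very strong 350, with
#' reciprocal bounds on the benign side); the table is configurable.
#'
#' @param tp,fn,fp,tn Confusion cells (pathogenic = positive class,
#'   abnormal = positive prediction).
#' @param correction Apply a 0.5 continuity correction to all cells.
#' @param thresholds Named vector of ascending pathogenic-side odds cutoffs.
#' @return List with \code{ps3}, \code{bs3} (numeric odds) and
#'   \code{ps3_strength}, \code{bs3_strength} labels.
#' @export
oddspath <- function(tp, fn, fp, tn, correction = FALSE,
                     thresholds = c(supporting = 2.08, moderate = 4.33,
                                    strong = 18.7, very_strong = 350)) {
  if (tp + fn + fp + tn <= 0) stop("empty confusion table", call. = FALSE)
  if (correction) {
    tp <- tp + 0.5; fn <- fn + 0.5; fp <- fp + 0.5; tn <- tn + 0.5
  }
  p1 <- (tp + fn) / (tp + fn + fp + tn)
  odds <- function(p2) {
    if (p2 == 1) return(Inf)
    (p2 * (1 - p1)) / ((1 - p2) * p1)
  }
  ps3 <- odds(tp / (tp + fp))
  bs3 <- odds(fn / (fn + tn))
  strength <- function(x, side) {
    if (side == "benign") x <- 1 / x
    lev <- names(thresholds)[x > thresholds]
    if (length(lev) == 0L) "none" else lev[length(lev)]
  }
  list(ps3 = ps3, bs3 = bs3,
       ps3_strength = strength(ps3, "pathogenic"),
       bs3_strength = strength(bs3, "benign"))
}

#' Z-prime factor separating positive and negative controls
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} -
#'   \mu_{neg}|}}
#' with sample means and standard deviations; values above 0.5 indicate an
#' excellent assay window between loss-of-function (nonsense) and neutral
#' (synonymous) controls.
#'
#' @param pos_scores,neg_scores Numeric vectors, each of length >= 2.
#' @export
z_prime <- function(pos_scores, neg_scores) {
  if (length(pos_scores) < 2L || length(neg_scores) < 2L) {
    stop("need at least two scores per control set", call. = FALSE)
  }
  mu_p <- mean(pos_scores); mu_n <- mean(neg_scores)
  if (mu_p == mu_n) stop("control means are equal: Z' undefined",
                         call. = FALSE)
  1 - 3 * (stats::sd(pos_scores) + stats::sd(neg_scores)) / abs(mu_p - mu_n)
}

#' Rescale an external screen to the RFS scale and assign quadrants
#'
#' Applies the control-anchored affine rescaling (nonsense median to +1,
#' synonymous median to -1) to an external score vector, then labels each
#' shared variant by its quadrant in the (this screen, external screen)
#' plane split at 0/0: strictly positive = LOF side. \code{"LR"}
#' (lower-right) marks variants called LOF here but WT-like externally.
#'
#' @param external_scores Named numeric vector from the external screen.
#' @param nonsense_ids,synonymous_ids Control ids present in the external
#'   table.
#' @param reference_rfs Optional named RFS vector of this screen; when given,
#'   quadrant labels are returned for the shared variants.
#' @return List with \code{rescaled} and, when \code{reference_rfs} is
#'   given, \code{quadrants} (named character vector: LL/LR/UL/UR).
#' @export
rescale_external_screen <- function(external_scores, nonsense_ids,
                                    synonymous_ids, reference_rfs = NULL) {
  nonsense_ids <- intersect(nonsense_ids, names(external_scores))
  synonymous_ids <- intersect(synonymous_ids, names(external_scores))
  if (length(nonsense_ids) == 0L || length(synonymous_ids) == 0L) {
    stop("control variants missing from the external screen", call. = FALSE)
  }
  rescaled <- rfs_transform(external_scores, nonsense_ids, synonymous_ids)
  out <- list(rescaled = rescaled)
  if (!is.null(reference_rfs)) {
    common <- intersect(names(reference_rfs), names(rescaled))
    x <- reference_rfs[common]   # this screen
    y <- rescaled[common]        # external screen
    out$quadrants <- stats::setNames(
      paste0(ifelse(y > 0, "U", "L"), ifelse(x > 0, "R", "L")), common)
  }
  out
}

#' Trinucleotide substitution channel of an SNV
#'
#' Maps a single-nucleotide substitution with its plus-strand trinucleotide
#' context to the standard pyrimidine-centred 96-channel notation
#' (e.g. \code{"T[C>T]G"}): when the mutated base is a purine, context and
#' alleles are reverse-complemented first.
#'
#' @param context Plus-strand trinucleotide centred on the mutated base.
#' @param alt Alternate base (plus strand).
#' @return Channel string, or \code{NA} for invalid input.
#' @export
sbs_channel <- function(context, alt) {
  mapply(function(ctx, a) {
    if (is.na(ctx) || is.na(a) || nchar(ctx) != 3L) return(NA_character_)
    ref <- substring(ctx, 2L, 2L)
    if (ref == a) return(NA_character_)
    if (ref %in% PURINES) {
      ctx <- revcomp(ctx)
      a <- revcomp(a)
      ref <- substring(ctx, 2L, 2L)
    }
    sprintf("%s[%s>%s]%s", substring(ctx, 1L, 1L), ref, a,
            substring(ctx, 3L, 3L))
  }, context, alt, USE.NAMES = FALSE)
}

#' Per-variant mutational probability from averaged SBS signatures
#'
#' Averages a set of COSMIC-style single-base-substitution signatures,
#' weighted by their prevalence, into one 96-channel profile (SBSmean) and
#' looks up each single-nucleotide variant's channel probability. Non-SNV
#' variants and SNVs without full trinucleotide context return \code{NA}.
#'
#' @param channels Character vector of 96-channel strings (from
#'   \code{\link{sbs_channel}}; \code{NA} for not-applicable variants).
#' @param signatures Numeric matrix, 96 channels (rownames) x signatures.
#' @param weights Non-negative per-signature weights (prevalence).
#' @return Numeric vector of probabilities.
#' @export
sbs_mean_probability <- function(channels, signatures, weights) {
  signatures <- as.matrix(signatures)
  if (length(weights) != ncol(signatures)) {
    stop("one weight per signature required", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  sbs_mean <- as.vector(signatures %*% weights) / sum(weights)
  names(sbs_mean) <- rownames(signatures)
  unname(sbs_mean[channels])
}

#' Trinucleotide channels for a variant library
#'
#' Extracts the plus-strand trinucleotide context of every single-nucleotide
#' substitution in the library from the model sequence and maps it to its
#' 96-channel label. Multi-nucleotide and indel variants, and SNVs at the
#' ends of the model sequence, yield \code{NA}.
#'
#' @param library An \code{sge_library}.
#' @param model The \code{sge_transcript} the library was designed on.
#' @return Character vector aligned with \code{library$records}.
#' @export
variant_sbs_channels <- function(library, model) {
  rec <- library$records
  n <- nchar(model$sequence)
  out <- rep(NA_character_, nrow(rec))
  snv <- rec$kind == "substitution" & nchar(rec$ref) == 1L
  rows <- which(snv)
  for (i in rows) {
    r <- region_row(model, rec$region[i])
    g <- r$var_start + rec$pos[i] + 1L   # 1-based global position
    if (g <= 1L || g >= n) next
    ctx <- substring(model$sequence, g - 1L, g + 1L)
    out[i] <- sbs_channel(ctx, rec$alt[i])
  }
  out
}

#' Spearman correlation with t-approximation p value
#'
#' Rank correlation \eqn{\rho} with the two-tailed p value from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Full evaluation report for a screen against a truth set
#'
#' Combines \code{\link{classify_function}}, \code{\link{confusion_metrics}},
#' \code{\link{pr_roc}}, \code{\link{oddspath}} and \code{\link{z_prime}}.
#'
#' @param scores Named RFS-median vector.
#' @param truth Named truth vector (\code{"pathogenic"}/\code{"benign"}).
#' @param nonsense_ids,synonymous_ids Control ids for the Z' factor.
#' @param threshold Functional-abnormality cutoff.
#' @return List: confusion metrics, AUCs, OddsPath, Z'.
#' @export
evaluate_screen <- function(scores, truth, nonsense_ids = NULL,
                            synonymous_ids = NULL, threshold = 0) {
  pred <- classify_function(scores, threshold)
  names(pred) <- names(scores)
  cm <- confusion_metrics(truth, pred)
  curves <- pr_roc(truth, scores)
  op <- oddspath(cm$confusion["tp"], cm$confusion["fn"],
                 cm$confusion["fp"], cm$confusion["tn"])
  zp <- if (!is.null(nonsense_ids) && !is.null(synonymous_ids)) {
    z_prime(scores[intersect(nonsense_ids, names(scores))],
            scores[intersect(synonymous_ids, names(scores))])
  } else NA_real_
  c(cm, list(roc_auc = curves$roc_auc, pr_auc = curves$pr_auc,
             oddspath = op, z_prime = zp))
}
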