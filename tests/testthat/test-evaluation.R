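test_that("functional classification uses a strict positive-RFS rule", {
  expect_equal(classify_function(c(0.8, -0.9, 0)),
               c("abnormal", "normal", "normal"))
})

test_that("confusion metrics reproduce the clinical truth-set figures", {
  # 398 of 401 pathogenic called abnormal, 248 of 253 benign called normal
  cm <- confusion_from_counts(tp = 398, fn = 3, fp = 5, tn = 248)
  expect_equal(cm$precision, 0.988, tolerance = 5e-4)
  expect_equal(cm$recall, 0.993, tolerance = 5e-4)
  expect_equal(cm$f1, 0.990, tolerance = 5e-4)
  # perfect classifier
  perfect <- confusion_from_counts(10, 0, 0, 10)
  expect_equal(unname(c(perfect$precision, perfect$recall, perfect$f1)),
               c(1, 1, 1))
  # no predicted positives: precision undefined (NA), recall 0
  none <- confusion_from_counts(0, 5, 0, 5)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  # label-based path agrees with count-based path
  truth <- c(p1 = "pathogenic", p2 = "pathogenic", b1 = "benign")
  pred <- c(p1 = "abnormal", p2 = "normal", b1 = "normal")
  cm2 <- confusion_metrics(truth, pred)
  expect_equal(unname(cm2$confusion), c(1, 1, 0, 1))
})

test_that("OddsPath reproduces the published calibration values", {
  op <- oddspath(tp = 398, fn = 3, fp = 5, tn = 248)
  expect_equal(signif(op$ps3, 3), 50.2)
  expect_equal(signif(op$bs3, 2), 0.0076)
  expect_equal(op$ps3_strength, "strong")
  expect_equal(op$bs3_strength, "strong")
  # uninformative classifier: P2 == P1 -> odds 1
  op1 <- oddspath(tp = 50, fn = 50, fp = 50, tn = 50)
  expect_equal(op1$ps3, 1)
  expect_equal(op1$bs3, 1)
  # zero misclassification: infinite without correction, finite with
  op_inf <- oddspath(tp = 100, fn = 10, fp = 0, tn = 100)
  expect_true(is.infinite(op_inf$ps3))
  op_corr <- oddspath(tp = 100, fn = 10, fp = 0, tn = 100,
                      correction = TRUE)
  expect_true(is.finite(op_corr$ps3))
  # monotonicity: more TP at fixed totals increases PS3
  expect_gt(oddspath(399, 2, 5, 248)$ps3, oddspath(398, 3, 5, 248)$ps3)
  expect_lt(oddspath(398, 3, 5, 249)$bs3, oddspath(398, 3, 5, 248)$bs3)
})

test_that("PR/ROC curves agree with a brute-force threshold oracle", {
  brute <- function(truth, scores) {
    thr <- sort(unique(scores), decreasing = TRUE)
    pts <- t(vapply(thr, function(t0) {
      pred <- scores >= t0
      tp <- sum(pred & truth == "pathogenic")
      fp <- sum(pred & truth == "benign")
      c(fpr = fp / sum(truth == "benign"),
        tpr = tp / sum(truth == "pathogenic"),
        prec = tp / (tp + fp))
    }, numeric(3)))
    pts
  }
  # hand-checkable 4-point example with a tie
  truth <- c(a = "pathogenic", b = "pathogenic", c = "benign", d = "benign")
  scores <- c(a = 3, b = 1, c = 1, d = 0)
  res <- pr_roc(truth, scores)
  pts <- brute(truth, scores)
  expect_equal(res$roc$fpr, c(0, pts[, "fpr"], 1))
  expect_equal(res$roc$tpr, c(0, pts[, "tpr"], 1))
  expect_equal(res$pr$precision[-1], unname(pts[, "prec"]))
  # by hand: ROC points (0,0),(0,.5),(.5,1),(1,1) -> .375 + .5 = .875
  expect_equal(res$roc_auc, 0.875)

  # random larger instances vs oracle points
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 20
      truth <- setNames(sample(c("pathogenic", "benign"), n, replace = TRUE,
                               prob = c(0.6, 0.4)), paste0("v", 1:n))
      if (length(unique(truth)) < 2) next
      scores <- setNames(round(rnorm(n), 1), names(truth))
      res <- pr_roc(truth, scores)
      pts <- brute(truth, scores)
      expect_equal(res$roc$fpr[-c(1, nrow(res$roc))], unname(pts[, "fpr"]))
      expect_equal(res$roc$tpr[-c(1, nrow(res$roc))], unname(pts[, "tpr"]))
    }
  })

  # perfectly separated scores
  truth <- setNames(rep(c("pathogenic", "benign"), each = 10),
                    paste0("v", 1:20))
  scores <- setNames(c(rnorm(10, 10), rnorm(10, -10)), names(truth))
  res <- pr_roc(truth, scores)
  expect_equal(res$roc_auc, 1)
  expect_equal(res$pr_auc, 1)

  # label-independent scores: ROC-AUC ~ 0.5
  withr::with_seed(29, {
    n <- 4000
    truth <- setNames(sample(c("pathogenic", "benign"), n, replace = TRUE),
                      paste0("v", 1:n))
    scores <- setNames(rnorm(n), names(truth))
    expect_equal(pr_roc(truth, scores)$roc_auc, 0.5, tolerance = 0.05)
  })
  expect_error(pr_roc(setNames(rep("benign", 3), letters[1:3]),
                      setNames(1:3, letters[1:3])), "both classes")
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    n <- 300
    truth <- setNames(sample(c("pathogenic", "benign"), n, replace = TRUE),
                      paste0("v", 1:n))
    scores <- setNames(rnorm(n) + (truth == "pathogenic"), names(truth))
    mine <- pr_roc(truth, scores)$roc_auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(truth, c("benign", "pathogenic")),
      predictor = scores, quiet = TRUE, direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-10)
  })
})

test_that("Z' factor formula and limits", {
  withr::with_seed(5, {
    pos <- rnorm(200, 1, 0.1); neg <- rnorm(200, -1, 0.1)
    zp <- z_prime(pos, neg)
    expect_equal(zp, 1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)),
                 tolerance = 1e-12)
    expect_equal(zp, 0.7, tolerance = 0.05)
  })
  # vanishing spread: Z' -> 1
  expect_gt(z_prime(c(1, 1 + 1e-9, 1 - 1e-9), c(-1, -1 + 1e-9, -1 - 1e-9)),
            0.999)
  expect_error(z_prime(c(1, 1), c(1, 1)), "equal")
})

test_that("external screens rescale onto the RFS scale with quadrant labels", {
  withr::with_seed(7, {
    ext <- c(rnorm(20, 5, 0.5), rnorm(20, -3, 0.5), rnorm(30, 1, 2))
    names(ext) <- paste0("v", seq_along(ext))
    non <- names(ext)[1:20]; syn <- names(ext)[21:40]
    res <- rescale_external_screen(ext, non, syn)
    expect_equal(median(res$rescaled[non]), 1, tolerance = 1e-12)
    expect_equal(median(res$rescaled[syn]), -1, tolerance = 1e-12)
  })
  # quadrant semantics: x = this screen, y = external
  ref <- c(a = 0.5, b = -0.5, c = 0.5, d = -0.5, e = 0)
  ext <- c(a = -0.3, b = -0.3, c = 0.3, d = 0.3, e = 0,
           n1 = 2, n2 = 2.2, s1 = -2, s2 = -2.2)
  res <- rescale_external_screen(ext, c("n1", "n2"), c("s1", "s2"),
                                 reference_rfs = ref)
  expect_equal(unname(res$quadrants["a"]), "LR")  # LOF here, WT-like there
  expect_equal(unname(res$quadrants["b"]), "LL")
  expect_equal(unname(res$quadrants["c"]), "UR")
  expect_equal(unname(res$quadrants["d"]), "UL")
  expect_equal(unname(res$quadrants["e"]), "LL")  # strict-positive rule
  expect_error(rescale_external_screen(ext[1:2], "n1", "s1"), "missing")
})

test_that("trinucleotide channels map to the pyrimidine strand", {
  expect_equal(sbs_channel("ACA", "T"), "A[C>T]A")
  # purine reference: reverse complement first; G>A at TGC -> G[C>T]A
  expect_equal(sbs_channel("TGC", "A"), "G[C>T]A")
  expect_true(is.na(sbs_channel("AAA", "A")))   # ref == alt
  expect_true(is.na(sbs_channel(NA, "A")))
  # full channel space: 96 distinct channels from all context/alt combos
  ctx <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                         c("C", "T"), function(a, b)
                                           paste0(a, b))),
                         c("A", "C", "G", "T"), paste0))
  chans <- unlist(lapply(ctx, function(cx) {
    ref <- substring(cx, 2, 2)
    vapply(setdiff(c("A", "C", "G", "T"), ref), sbs_channel,
           character(1), context = cx)
  }))
  expect_equal(length(unique(chans)), 96L)
})

test_that("signature averaging is prevalence-weighted per channel", {
  sig <- cbind(s1 = c(0.1, 0.9), s2 = c(0.2, 0.8))
  rownames(sig) <- c("A[C>T]A", "A[C>G]A")
  # single signature, weight 1
  expect_equal(sbs_mean_probability("A[C>T]A", sig[, 1, drop = FALSE], 1),
               0.1)
  # weighted mean 0.75/0.25
  expect_equal(sbs_mean_probability("A[C>T]A", sig, c(0.75, 0.25)), 0.125)
  expect_true(is.na(sbs_mean_probability(NA_character_, sig, c(1, 1))))
  expect_error(sbs_mean_probability("A[C>T]A", sig, c(-1, 2)),
               "non-negative")
})

test_that("library SNVs get correct genomic trinucleotide contexts", {
  m <- coding_model("ATGGATCGCTGGAAATAA")
  lib <- build_library(m, aa_subs = FALSE, insertions = FALSE,
                       deletions = FALSE)
  ch <- variant_sbs_channels(lib, m)
  rec <- lib$records
  # check one pyrimidine-reference SNV explicitly: position 5 (0-based 4),
  # context "GAT"... ref A is purine: channel via reverse complement
  i <- which(rec$pos == 4L & rec$alt == "G")
  expect_equal(ch[i], sbs_channel("GAT", "G"))
  # first and last sequence positions have no context
  expect_true(all(is.na(ch[rec$pos == 0L])))
  expect_true(all(is.na(ch[rec$pos == nchar("ATGGATCGCTGGAAATAA") - 1L])))
  # all interior SNVs get a channel
  interior <- rec$pos > 0L & rec$pos < 17L
  expect_false(anyNA(ch[interior]))
})

test_that("Spearman correlation with t-approximation p value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, x)$p, 0)
  expect_equal(correlate(x, rev(x))$rho, -1)
  # hand-ranked 5-point example
  y <- c(10, 30, 20, 50, 40)   # ranks 1,3,2,5,4
  res <- correlate(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)))
  tstat <- res$rho * sqrt(3 / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)
  # agreement with stats::cor.test rho
  withr::with_seed(3, {
    a <- rnorm(50); b <- a + rnorm(50)
    expect_equal(correlate(a, b)$rho,
                 unname(cor.test(a, b, method = "spearman")$estimate))
  })
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("simulated screens separate classes well enough for clinical use", {
  cfg <- sim_config(seed = 43, n_exons = 2, exon_len = 45, intron_len = 30)
  sim <- simulate_experiment(cfg)
  st <- score_screen(sim$dna, sim$library)
  scores <- setNames(st$rfs_median, st$variant_id)
  truth_lof <- setNames(ifelse(sim$truth$true_lof, "pathogenic", "benign"),
                        sim$truth$variant_id)
  ev <- evaluate_screen(
    scores, truth_lof,
    nonsense_ids = st$variant_id[st$coding_class == "nonsense"],
    synonymous_ids = st$variant_id[st$coding_class == "synonymous"])
  expect_gte(ev$f1, 0.98)
  expect_gte(ev$roc_auc, 0.95)
  expect_gt(ev$z_prime, 0.5)
})
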