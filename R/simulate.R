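#' Simulation configuration for a synthetic SGE screen
#'
#' Bundles every tunable of the simulator. Defaults emulate the study
#' conditions of a saturation-genome-editing scan of a multi-exon region:
#' coverage of about 500 reads per variant, three biological replicates,
#' variant fitness anchored at +1 (nonsense/frameshift) and -1
#' (synonymous/intronic) with a bimodal missense mixture, and ~30-fold mRNA
#' depletion of premature-termination-codon (PTC) variants.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_exons,exon_len,intron_len Mini-gene geometry (nt). The total
#'   exonic length must be divisible by 3.
#' @param flank_len,constant_len Variable-region flank and constant-frame
#'   lengths (nt).
#' @param depth Expected reads per variant and sample.
#' @param replicates Number of biological replicates.
#' @param selection_strength Exponential-growth differential g >= 0: the
#'   expected treated abundance of a variant with fitness f is proportional
#'   to its control abundance times \code{2^(g*f)}.
#' @param fitness_lof,fitness_wt Means of the loss-of-function and wild-type
#'   fitness anchors.
#' @param sd_control SD of nonsense/frameshift/synonymous/intronic fitness.
#' @param sd_missense SD of the missense mixture components.
#' @param missense_lof_weight Mixture weight of the missense LOF component.
#' @param fitness_inframe Mean fitness of in-frame indels (single amino acid
#'   insertions/deletions impair the domain almost as much as truncation).
#' @param nmd_fold Fold-depletion of PTC variants at the mRNA level.
#' @param dispersion Dirichlet concentration per variant for the initial
#'   abundance draw (larger = more even clone sizes).
#' @return List of class \code{sge_sim_config}.
#' @export
sim_config <- function(seed = 1L, n_exons = 2L, exon_len = 45L,
                       intron_len = 30L, flank_len = 12L, constant_len = 13L,
                       depth = 500, replicates = 3L,
                       selection_strength = 2, fitness_lof = 1,
                       fitness_wt = -1, sd_control = 0.15,
                       sd_missense = 0.3, missense_lof_weight = 0.55,
                       fitness_inframe = 0.8, nmd_fold = 30,
                       dispersion = 50) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (missense_lof_weight < 0 || missense_lof_weight > 1) {
    stop("missense_lof_weight must lie in [0, 1]", call. = FALSE)
  }
  if ((n_exons * exon_len) %% 3L != 0L) {
    stop("total exonic length must be divisible by 3", call. = FALSE)
  }
  if (exon_len < 9L || intron_len < 6L) {
    stop("exon_len >= 9 and intron_len >= 6 required", call. = FALSE)
  }
  structure(as.list(environment()), class = "sge_sim_config")
}

#' Generate a random mini-gene
#'
#' Random coding sequence (no premature stop codons in the wild-type frame)
#' split into \code{n_exons} exons joined by GT..AG introns, with intronic
#' padding on both ends so that every exon has full flanks. Reproducible
#' from the config seed.
#'
#' @param config An \code{sge_sim_config}.
#' @return An \code{sge_transcript}.
#' @export
make_minigene <- function(config) {
  with_seed(config$seed, {
    n_codons <- (config$n_exons * config$exon_len) %/% 3L
    gc <- genetic_code()
    sense <- names(gc)[gc != "*"]
    cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    rand_nt <- function(n) paste(sample(BASES, n, replace = TRUE),
                                 collapse = "")
    pad5 <- rand_nt(config$intron_len)
    pad3 <- rand_nt(config$intron_len)
    pieces <- character(0)
    exons <- matrix(0L, config$n_exons, 2L)
    pos <- nchar(pad5)
    pieces <- pad5
    for (i in seq_len(config$n_exons)) {
      ex <- substring(cds, (i - 1L) * config$exon_len + 1L,
                      i * config$exon_len)
      exons[i, ] <- c(pos, pos + config$exon_len)
      pieces <- c(pieces, ex)
      pos <- pos + config$exon_len
      if (i < config$n_exons) {
        intr <- paste0("GT", rand_nt(config$intron_len - 4L), "AG")
        pieces <- c(pieces, intr)
        pos <- pos + nchar(intr)
      }
    }
    pieces <- c(pieces, pad3)
    transcript_model(paste(pieces, collapse = ""), exons, cds_start = 0L,
                     codon_offset = 1L, flank_len = config$flank_len,
                     constant_len = config$constant_len,
                     name = sprintf("minigene_seed%d", config$seed))
  })
}

#' Assign ground-truth fitness to a variant library
#'
#' Draws per-variant true fitness by consequence class: nonsense, frameshift
#' and splice-dinucleotide variants around the LOF anchor (+1),
#' synonymous and intronic variants around the WT anchor (-1), in-frame
#' indels near the LOF anchor, and missense variants from a two-component
#' LOF/WT-like mixture. True NMD status is the variant's
#' \code{introduces_ptc} flag (splice-site variants trigger NMD through
#' unmodelled splicing changes and are deliberately left out of the PTC
#' truth).
#'
#' @param library An \code{sge_library}.
#' @param config An \code{sge_sim_config}.
#' @return \code{data.frame}: \code{variant_id}, \code{true_fitness},
#'   \code{true_class}, \code{true_lof}, \code{true_nmd}.
#' @export
assign_true_fitness <- function(library, config) {
  rec <- library$records
  n <- nrow(rec)
  with_seed(config$seed + 1L, {
    fit <- numeric(n)
    lof <- logical(n)
    cls <- rec$coding_class
    hi <- cls %in% c("nonsense", "frameshift", "splice_dinucleotide")
    lo <- cls %in% c("synonymous", "intronic")
    mi <- cls == "missense"
    fi <- cls == "inframe_indel"
    fit[hi] <- stats::rnorm(sum(hi), config$fitness_lof, config$sd_control)
    fit[lo] <- stats::rnorm(sum(lo), config$fitness_wt, config$sd_control)
    fit[fi] <- stats::rnorm(sum(fi), config$fitness_inframe,
                            config$sd_missense)
    is_lof_mis <- stats::runif(sum(mi)) < config$missense_lof_weight
    fit[mi] <- stats::rnorm(sum(mi),
                            ifelse(is_lof_mis, config$fitness_lof,
                                   config$fitness_wt),
                            config$sd_missense)
    lof[hi | fi] <- TRUE
    lof[mi] <- is_lof_mis
    data.frame(variant_id = rec$variant_id, true_fitness = fit,
               true_class = cls, true_lof = lof,
               true_nmd = rec$introduces_ptc,
               stringsAsFactors = FALSE)
  })
}

# One multinomial sample column at the configured depth.
multinom_column <- function(prob, total) {
  as.integer(stats::rmultinom(1L, size = total, prob = prob))
}

#' Simulate replicate DNA count tables under selection
#'
#' Per replicate, initial abundances are drawn from a symmetric Dirichlet
#' (concentration \code{dispersion} per variant, emulating clone-size
#' variation after editing); the control sample is a multinomial draw of
#' \code{depth * n_variants} reads at those abundances, the treated sample a
#' multinomial draw at abundances reweighted by \code{2^(g * fitness)} and
#' renormalized. This makes the expected enrichment score linear in fitness,
#' matching the affine RFS construction.
#'
#' @param library An \code{sge_library}.
#' @param truth Output of \code{\link{assign_true_fitness}}.
#' @param config An \code{sge_sim_config}.
#' @return An \code{sge_counts} with \code{2 * replicates} DNA samples.
#' @export
simulate_screen <- function(library, truth, config) {
  rec <- library$records
  n <- nrow(rec)
  fit <- truth$true_fitness[match(rec$variant_id, truth$variant_id)]
  total <- round(config$depth * n)
  cols <- list()
  samples <- list()
  for (r in seq_len(config$replicates)) {
    with_seed(config$seed + 100L + r, {
      f0 <- stats::rgamma(n, shape = config$dispersion)
      f0 <- f0 / sum(f0)
      f1 <- f0 * 2^(config$selection_strength * fit)
      f1 <- f1 / sum(f1)
      cols[[paste0("ctrl_", r)]] <- multinom_column(f0, total)
      cols[[paste0("trt_", r)]] <- multinom_column(f1, total)
    })
    samples[[length(samples) + 1L]] <-
      data.frame(sample = paste0("ctrl_", r), condition = "control",
                 replicate = r, material = "DNA")
    samples[[length(samples) + 1L]] <-
      data.frame(sample = paste0("trt_", r), condition = "treated",
                 replicate = r, material = "DNA")
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rec$variant_id
  count_matrix(m, do.call(rbind, samples))
}

#' Simulate mRNA count tables with NMD depletion
#'
#' For each DNA sample (column), the expected mRNA abundance of every PTC
#' variant is its DNA abundance divided by \code{nmd_fold}; abundances are
#' renormalized and sequenced as a multinomial draw of \code{depth *
#' n_variants} reads. With \code{nmd_fold = 1} the mRNA expectation equals
#' the DNA abundances.
#'
#' @param dna_counts An \code{sge_counts} (typically the control DNA
#'   samples).
#' @param truth Output of \code{\link{assign_true_fitness}} (uses
#'   \code{true_nmd}).
#' @param config An \code{sge_sim_config}; \code{depth} sets the mRNA
#'   sequencing depth.
#' @return An \code{sge_counts} of matching dimensions, material
#'   \code{"mRNA"}.
#' @export
simulate_mrna <- function(dna_counts, truth, config) {
  m <- dna_counts$counts
  ptc <- truth$true_nmd[match(rownames(m), truth$variant_id)]
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  total <- round(config$depth * nrow(m))
  for (j in seq_len(ncol(m))) {
    with_seed(config$seed + 200L + j, {
      f <- m[, j] / sum(m[, j])
      f <- f * ifelse(ptc, 1 / config$nmd_fold, 1)
      f <- f / sum(f)
      out[, j] <- multinom_column(f, total)
    })
  }
  samples <- dna_counts$samples
  samples$material <- "mRNA"
  samples$sample <- paste0(samples$sample, "_rna")
  colnames(out) <- samples$sample
  count_matrix(out, samples)
}

#' Emit simulated reads for one sample as FASTQ
#'
#' Reads are \code{flank5 + variant sequence + flank3}, each repeated
#' according to its count, plus optional wild-type reads, with a uniform
#' per-base substitution error (default 0, so exact-match counting recovers
#' the counts losslessly).
#'
#' @param library An \code{sge_library}.
#' @param model The design \code{sge_transcript} (provides constant frames).
#' @param region Region id.
#' @param counts Named count vector over the region's variant ids.
#' @param path Output FASTQ path.
#' @param wt_reads Number of wild-type reads to interleave.
#' @param error_rate Per-base substitution probability.
#' @param seed Seed for error injection and shuffling.
#' @export
simulate_reads <- function(library, model, region, counts, path,
                           wt_reads = 0L, error_rate = 0, seed = 1L) {
  rec <- library$records[library$records$region == region, , drop = FALSE]
  counts <- counts[rec$variant_id]
  fr <- constant_frames(model, region)
  seqs <- rep(rec$sequence, counts)
  if (wt_reads > 0L) {
    seqs <- c(seqs, rep(library$wt_sequences[[region]], wt_reads))
  }
  with_seed(seed, {
    seqs <- sample(seqs)
    reads <- paste0(fr$flank5, seqs, fr$flank3)
    if (error_rate > 0) {
      reads <- vapply(reads, function(x) {
        ch <- strsplit(x, "")[[1]]
        hit <- stats::runif(length(ch)) < error_rate
        ch[hit] <- sample(BASES, sum(hit), replace = TRUE)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("read%06d", seq_along(reads))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(
        vapply(nchar(reads), function(n)
          paste(rep("I", n), collapse = ""), character(1)))
    )
  })
  invisible(path)
}

#' Run a complete simulated screen
#'
#' Design, ground truth, DNA and mRNA count simulation in one call:
#' builds the mini-gene and library, assigns true fitness, simulates
#' replicate control/treated DNA counts and matched mRNA counts.
#'
#' @param config An \code{sge_sim_config}.
#' @param snvs,aa_subs,insertions,deletions Library switches forwarded to
#'   \code{\link{build_library}}.
#' @return List: \code{model}, \code{library}, \code{truth},
#'   \code{dna} (\code{sge_counts}), \code{mrna} (\code{sge_counts},
#'   matched to the control DNA samples).
#' @export
simulate_experiment <- function(config, snvs = TRUE, aa_subs = TRUE,
                                insertions = TRUE, deletions = TRUE) {
  model <- make_minigene(config)
  library <- build_library(model, snvs = snvs, aa_subs = aa_subs,
                           insertions = insertions, deletions = deletions)
  truth <- assign_true_fitness(library, config)
  dna <- simulate_screen(library, truth, config)
  ctrl <- dna$samples$condition == "control"
  dna_ctrl <- count_matrix(dna$counts[, ctrl, drop = FALSE],
                           dna$samples[ctrl, , drop = FALSE])
  mrna <- simulate_mrna(dna_ctrl, truth, config)
  list(model = model, library = library, truth = truth,
       dna = dna, mrna = mrna)
}
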