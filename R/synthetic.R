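## Seeded generators: annotated transcriptomes with planted half-life
## determinants, and multi-study half-life compendia with batch structure.
## Everything is a pure function of (spec, seed).

#' Specification of the synthetic transcriptome generator
#'
#' Defaults describe a compact transcriptome whose mRNAs (median ~850 nt)
#' fit the scaled-down 1,024-nt encoder: region lengths are log-normal,
#' exon counts Poisson, and the latent half-life is an additive function
#' of ORF exon-junction density (stabilizing), codon usage (a fixed
#' 61-codon weight vector), and destabilizing 3'UTR motifs: the AU-rich
#' element core \code{UAUUUAU} with a U-shaped positional weight peaking
#' at the 3'UTR termini, and the Pumilio-binding element
#' \code{UGUAAAUA}. Codon weights are drawn once from a fixed internal
#' seed so they are study constants, not per-run randomness.
#'
#' @param n_genes Number of genes.
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog Log-normal
#'   length parameters (nt).
#' @param codons_meanlog,codons_sdlog Log-normal parameters of the codon
#'   count (ORF length / 3).
#' @param exon_lambda Poisson mean of the extra exon count (exons = 1 +
#'   Poisson).
#' @param intron_meanlog,intron_sdlog Log-normal intron lengths for the
#'   emitted gene models.
#' @param junction_coef Latent shift per ORF-internal junction per kb of
#'   ORF.
#' @param codon_weight_sd Spread of the fixed codon weight vector (latent
#'   shift per unit codon frequency).
#' @param motifs List of motif effects: each a list with \code{kmer},
#'   \code{effect} (latent shift per occurrence at full positional
#'   weight), \code{posweight} (function of the region percentile in
#'   [0,1], returning weights in [0,1]), \code{plant_prob} and
#'   \code{max_copies} (planting intensity in the 3'UTR).
#' @param noise_sd Residual latent noise.
#' @return List of class \code{"generative_spec"}.
#' @export
generativeSpec <- function(n_genes = 3000L,
                           utr5_meanlog = log(100), utr5_sdlog = 0.35,
                           codons_meanlog = log(150), codons_sdlog = 0.30,
                           utr3_meanlog = log(300), utr3_sdlog = 0.45,
                           exon_lambda = 4, intron_meanlog = log(200),
                           intron_sdlog = 0.5, junction_coef = 0.08,
                           codon_weight_sd = 3,
                           motifs = NULL, noise_sd = 0.2) {
  if (is.null(motifs))
    motifs <- list(
      ARE = list(kmer = "UAUUUAU", effect = -0.4,
                 posweight = function(p) 0.25 + 0.75 * (2 * abs(p - 0.5))^2,
                 plant_prob = 0.5, max_copies = 3L),
      PUF = list(kmer = "UGUAAAUA", effect = -0.3,
                 posweight = function(p) 0.25 + 0.75 * (2 * abs(p - 0.5))^2,
                 plant_prob = 0.3, max_copies = 2L))
  codon_weights <- .withSeed(42L, {
    cods <- apply(expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1,
                  paste0, collapse = "")
    cods <- setdiff(cods, .STOP_CODONS)
    stats::setNames(stats::rnorm(61, sd = codon_weight_sd), cods)
  })
  structure(list(n_genes = as.integer(n_genes),
                 utr5_meanlog = utr5_meanlog, utr5_sdlog = utr5_sdlog,
                 codons_meanlog = codons_meanlog,
                 codons_sdlog = codons_sdlog,
                 utr3_meanlog = utr3_meanlog, utr3_sdlog = utr3_sdlog,
                 exon_lambda = exon_lambda,
                 intron_meanlog = intron_meanlog,
                 intron_sdlog = intron_sdlog,
                 junction_coef = junction_coef,
                 codon_weights = codon_weights, motifs = motifs,
                 noise_sd = noise_sd),
            class = "generative_spec")
}

#' Generate a synthetic annotated transcriptome
#'
#' Random sequences with sampled region lengths (ORF forced to a multiple
#' of 3, AUG start and stop codon placed, no internal in-frame stops),
#' exon junctions sampled uniformly over the spliced length, and planted
#' 3'UTR motifs. Optionally emits matching GTF + FASTA fixtures (a
#' one-chromosome-per-gene genome with introns re-inserted; half the
#' genes on the minus strand) so the real ingestion path can be
#' exercised.
#'
#' @param spec A \code{\link{generativeSpec}}.
#' @param seed Integer seed.
#' @param out_dir If non-NULL, writes \code{transcriptome.fa} and
#'   \code{transcriptome.gtf} here.
#' @return List with \code{ts} (a \linkS4class{TranscriptSet}),
#'   \code{fasta}/\code{gtf} paths (or NULL), and \code{gene_bodies}
#'   (a \linkS4class{GRanges} of gene spans for peak counting).
#' @export
genTranscriptome <- function(spec = generativeSpec(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(inherits(spec, "generative_spec"))
  n <- spec$n_genes
  non_stop <- names(spec$codon_weights)
  .withSeed(seed, {
    u5 <- pmax(10L, as.integer(round(stats::rlnorm(n, spec$utr5_meanlog,
                                                   spec$utr5_sdlog))))
    nc <- pmax(35L, as.integer(round(stats::rlnorm(n, spec$codons_meanlog,
                                                   spec$codons_sdlog))))
    u3 <- pmax(30L, as.integer(round(stats::rlnorm(n, spec$utr3_meanlog,
                                                   spec$utr3_sdlog))))
    seqs <- character(n); jx <- vector("list", n)
    introns <- vector("list", n)
    for (g in seq_len(n)) {
      orf <- paste0("AUG",
                    paste(sample(non_stop, nc[g] - 2L, replace = TRUE),
                          collapse = ""),
                    sample(.STOP_CODONS, 1L))
      utr5 <- paste(sample(.BASES, u5[g], replace = TRUE), collapse = "")
      utr3c <- sample(.BASES, u3[g], replace = TRUE)
      ## plant destabilizing motifs in the 3'UTR
      for (mt in spec$motifs) {
        if (stats::runif(1) < mt$plant_prob) {
          k <- nchar(mt$kmer)
          if (u3[g] > k + 2L) {
            copies <- sample.int(mt$max_copies, 1L)
            starts <- sample.int(u3[g] - k, copies)
            for (s in starts)
              utr3c[s:(s + k - 1L)] <- strsplit(mt$kmer, "")[[1]]
          }
        }
      }
      seqs[g] <- paste0(utr5, orf, paste(utr3c, collapse = ""))
      L <- nchar(seqs[g])
      n_ex <- 1L + stats::rpois(1, spec$exon_lambda)
      if (n_ex > 1L) {
        j <- sort(sample.int(L - 1L, min(n_ex - 1L, L - 2L)))
        jx[[g]] <- j
        introns[[g]] <- pmax(30L, as.integer(round(
          stats::rlnorm(length(j), spec$intron_meanlog,
                        spec$intron_sdlog))))
      } else {
        jx[[g]] <- integer()
        introns[[g]] <- integer()
      }
    }
    ids <- sprintf("g%04d", seq_len(n))
    strand <- rep(c("+", "-"), length.out = n)
    ts <- TranscriptSet(
      seq = stats::setNames(seqs, sprintf("t%04d", seq_len(n))),
      geneId = ids, utr5Len = u5, orfLen = 3L * nc, utr3Len = u3,
      junctions = jx,
      intronLenTotal = vapply(introns, sum, numeric(1)))

    fasta <- gtf <- NULL
    gene_bodies <- NULL
    flank <- 25L
    chrom_seqs <- character(n)
    gtf_lines <- character(0)
    gene_start <- integer(n); gene_end <- integer(n)
    if (!is.null(out_dir)) for (g in seq_len(n)) {
      L <- nchar(seqs[g]); j <- jx[[g]]
      ex_start_sp <- c(0L, j); ex_end_sp <- c(j, L)   # 0-based half-open
      w <- ex_end_sp - ex_start_sp
      il <- introns[[g]]
      ## pre-mRNA (plus-strand sense) with introns re-inserted
      pieces <- character(0)
      gpos <- flank  # 0-based genomic cursor after the 5' flank
      ex_gstart <- integer(length(w)); ex_gend <- integer(length(w))
      sseq <- seqs[g]
      for (e in seq_along(w)) {
        ex_gstart[e] <- gpos + 1L                      # 1-based closed
        ex_gend[e] <- gpos + w[e]
        pieces <- c(pieces, substr(sseq, ex_start_sp[e] + 1L, ex_end_sp[e]))
        gpos <- gpos + w[e]
        if (e < length(w)) {
          pieces <- c(pieces,
                      paste(sample(.BASES, il[e], replace = TRUE),
                            collapse = ""))
          gpos <- gpos + il[e]
        }
      }
      pre <- paste0(paste(sample(.BASES, flank, replace = TRUE),
                          collapse = ""),
                    paste(pieces, collapse = ""),
                    paste(sample(.BASES, flank, replace = TRUE),
                          collapse = ""))
      chrom_len <- nchar(pre)
      ## ORF interval on the spliced sequence, mapped to genomic pieces
      orf_sp <- c(u5[g], u5[g] + 3L * nc[g])           # 0-based half-open
      cds <- list()
      for (e in seq_along(w)) {
        lo <- max(ex_start_sp[e], orf_sp[1])
        hi <- min(ex_end_sp[e], orf_sp[2])
        if (lo < hi)
          cds[[length(cds) + 1L]] <-
            c(ex_gstart[e] + (lo - ex_start_sp[e]),
              ex_gstart[e] + (hi - ex_start_sp[e]) - 1L)
      }
      if (strand[g] == "-") {
        pre <- as.character(Biostrings::reverseComplement(
          Biostrings::RNAString(pre)))
        flip <- function(ab) c(chrom_len - ab[2] + 1L,
                               chrom_len - ab[1] + 1L)
        tmp <- lapply(seq_along(w), function(e)
          flip(c(ex_gstart[e], ex_gend[e])))
        ex_gstart <- vapply(tmp, `[`, integer(1), 1)
        ex_gend <- vapply(tmp, `[`, integer(1), 2)
        cds <- lapply(cds, flip)
      }
      chrom <- sprintf("chr_%s", ids[g])
      chrom_seqs[g] <- chartr("Uu", "Tt", pre)
      attr_ <- sprintf('gene_id "%s"; transcript_id "t%04d";', ids[g], g)
      for (e in seq_along(w))
        gtf_lines <- c(gtf_lines,
                       paste(chrom, "synthetic", "exon", ex_gstart[e],
                             ex_gend[e], ".", strand[g], ".", attr_,
                             sep = "\t"))
      for (cc in cds)
        gtf_lines <- c(gtf_lines,
                       paste(chrom, "synthetic", "CDS", cc[1], cc[2], ".",
                             strand[g], "0", attr_, sep = "\t"))
      gene_start[g] <- min(ex_gstart); gene_end[g] <- max(ex_gend)
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fasta <- file.path(out_dir, "transcriptome.fa")
      gtf <- file.path(out_dir, "transcriptome.gtf")
      dna <- Biostrings::DNAStringSet(chrom_seqs)
      names(dna) <- sprintf("chr_%s", ids)
      Biostrings::writeXStringSet(dna, fasta)
      writeLines(gtf_lines, gtf)
      gene_bodies <- GenomicRanges::GRanges(
        seqnames = sprintf("chr_%s", ids),
        ranges = IRanges::IRanges(start = gene_start, end = gene_end),
        strand = strand)
      names(gene_bodies) <- ids
    }
    list(ts = ts, fasta = fasta, gtf = gtf, gene_bodies = gene_bodies)
  })
}

#' Latent half-lives with a full effect ledger
#'
#' The latent (log-scale, arbitrary units) half-life of each gene is the
#' sum of: \code{junction_coef} times the ORF-internal junction density
#' (junctions per kb of ORF); the codon term (fixed weight vector dotted
#' with the gene's codon frequencies); every motif occurrence found in
#' the 3'UTR, weighted by its positional weight at the occurrence start
#' percentile; and Gaussian noise. The ledger records each contribution
#' so the construction can be verified exactly.
#'
#' @param ts A \linkS4class{TranscriptSet} (typically from
#'   \code{\link{genTranscriptome}}).
#' @param spec The \code{\link{generativeSpec}} used to build it.
#' @param seed Integer seed (noise draw).
#' @return List with \code{latent} (named numeric) and \code{ledger}
#'   (data.frame of per-gene terms: junction, codon, one column per
#'   motif, noise).
#' @export
genLatentHalflives <- function(ts, spec = generativeSpec(), seed = 1L) {
  lens <- regionLengths(ts)
  nj <- vapply(seq_len(length(ts)), function(i) {
    j <- ts@junctions[[i]]
    sum(j > lens[i, "utr5"] & j < lens[i, "utr5"] + lens[i, "orf"])
  }, numeric(1))
  junction_term <- spec$junction_coef * nj / (lens[, "orf"] / 1000)
  freq <- codonFrequencies(ts)
  w <- spec$codon_weights[sub("codon_", "", colnames(freq))]
  codon_term <- drop(freq %*% w)
  utr3 <- as.character(regionSeq(ts, "utr3"))
  motif_terms <- vapply(names(spec$motifs), function(nm) {
    mt <- spec$motifs[[nm]]
    vapply(seq_along(utr3), function(i) {
      hits <- gregexpr(mt$kmer, utr3[i], fixed = TRUE)[[1]]
      if (hits[1] == -1L) return(0)
      pct <- (hits - 1) / nchar(utr3[i])
      sum(mt$effect * mt$posweight(pct))
    }, numeric(1))
  }, numeric(length(ts)))
  if (is.null(dim(motif_terms)))
    motif_terms <- matrix(motif_terms, nrow = length(ts),
                          dimnames = list(NULL, names(spec$motifs)))
  noise <- .withSeed(seed, stats::rnorm(length(ts), sd = spec$noise_sd))
  latent <- junction_term + codon_term + rowSums(motif_terms) + noise
  names(latent) <- geneIds(ts)
  ledger <- data.frame(gene_id = geneIds(ts), junction = junction_term,
                       codon = codon_term, motif_terms, noise = noise,
                       latent = latent, row.names = NULL)
  list(latent = latent, ledger = ledger)
}

#' Specification of the synthetic multi-study compendium
#'
#' Defaults reproduce the standard validation conditions: 20 samples from
#' 10 studies (2 replicates each), half pulse-labeling and half
#' transcriptional-shutoff, four cell types, per-sample observation noise
#' sd 0.5, 30\% missingness, gene-wise study batch effects, a gene-wise
#' method-class bias (emulating method-dependent measurement bias such as
#' length-dependent labeling), gene-wise cell-type effects, and a mild
#' monotone per-sample distortion \code{a*x + b*x^3}. Two samples are
#' deposited as degradation rates and some in minutes, exercising the
#' unit handling.
#'
#' @param n_samples Number of samples.
#' @param n_studies Number of studies (replicates are distributed
#'   round-robin).
#' @param noise_sd Per-sample measurement noise (latent scale).
#' @param missing_rate Fraction of cells missing.
#' @param missing_length_coef Optional dependence of missingness on
#'   transcript length (0 disables).
#' @param study_sd Gene-wise per-study batch effect sd.
#' @param method_class_sd Gene-wise method-class bias sd.
#' @param celltype_sd Gene-wise cell-type effect sd.
#' @param distortion_a,distortion_b Ranges (length-2) of the monotone
#'   distortion coefficients.
#' @param n_rate_samples Samples deposited as degradation rates.
#' @param minute_fraction Fraction of half-life samples in minutes.
#' @return List of class \code{"compendium_spec"}.
#' @export
compendiumSpec <- function(n_samples = 20L, n_studies = 10L,
                           noise_sd = 0.5, missing_rate = 0.3,
                           missing_length_coef = 0, study_sd = 0.12,
                           method_class_sd = 0.08, celltype_sd = 0.08,
                           distortion_a = c(0.85, 1.25),
                           distortion_b = c(0, 0.03),
                           n_rate_samples = 2L, minute_fraction = 0.25) {
  structure(as.list(environment()), class = "compendium_spec")
}

#' Generate a synthetic multi-study half-life matrix
#'
#' Each sample observes \code{distortion(latent + study effect +
#' method-class bias + cell-type effect + noise)}, mapped onto a raw
#' half-life scale (hours = \code{10^(0.3*y + 0.8)}), with cells dropped
#' per the missingness model and per-sample units / degradation-rate
#' flags assigned to exercise the preprocessing.
#'
#' @param latents Named numeric latent half-lives (see
#'   \code{\link{genLatentHalflives}}).
#' @param cspec A \code{\link{compendiumSpec}}.
#' @param seed Integer seed.
#' @param lengths Optional named transcript lengths (required when
#'   \code{missing_length_coef != 0}).
#' @return List with \code{values} (raw gene-by-sample matrix with NAs),
#'   \code{meta} (sample metadata), and \code{truth} (per-sample
#'   parameters and the latent vector).
#' @export
genCompendiumMatrix <- function(latents, cspec = compendiumSpec(),
                                seed = 1L, lengths = NULL) {
  stopifnot(inherits(cspec, "compendium_spec"))
  n_g <- length(latents); n_s <- cspec$n_samples
  genes <- names(latents)
  .withSeed(seed, {
    study <- sprintf("study%02d", rep_len(seq_len(cspec$n_studies), n_s))
    study <- sort(study)
    cls_of_study <- rep_len(c("pulse_labeling", "transcriptional_shutoff"),
                            cspec$n_studies)
    names(cls_of_study) <- sprintf("study%02d", seq_len(cspec$n_studies))
    method_class <- cls_of_study[study]
    method <- ifelse(method_class == "pulse_labeling", "4sU", "ActD")
    cells <- c("HeLa", "K562", "HEK293", "mESC")
    cell_of_study <- sample(cells, cspec$n_studies, replace = TRUE)
    names(cell_of_study) <- names(cls_of_study)
    cell_type <- cell_of_study[study]
    is_rate <- rep(FALSE, n_s)
    if (cspec$n_rate_samples > 0)
      is_rate[sample.int(n_s, cspec$n_rate_samples)] <- TRUE
    unit <- ifelse(is_rate, NA_character_,
                   ifelse(stats::runif(n_s) < cspec$minute_fraction,
                          "minutes", "hours"))
    study_eff <- matrix(stats::rnorm(n_g * cspec$n_studies,
                                     sd = cspec$study_sd),
                        n_g, cspec$n_studies,
                        dimnames = list(genes, names(cls_of_study)))
    class_eff <- matrix(stats::rnorm(n_g * 2, sd = cspec$method_class_sd),
                        n_g, 2,
                        dimnames = list(genes,
                                        c("pulse_labeling",
                                          "transcriptional_shutoff")))
    ct_eff <- matrix(stats::rnorm(n_g * length(cells),
                                  sd = cspec$celltype_sd),
                     n_g, length(cells), dimnames = list(genes, cells))
    a <- stats::runif(n_s, cspec$distortion_a[1], cspec$distortion_a[2])
    b <- stats::runif(n_s, cspec$distortion_b[1], cspec$distortion_b[2])
    vals <- matrix(NA_real_, n_g, n_s,
                   dimnames = list(genes, sprintf("s%02d", seq_len(n_s))))
    miss_p <- rep(cspec$missing_rate, n_g)
    if (cspec$missing_length_coef != 0) {
      if (is.null(lengths)) stop("lengths required for length-dependent missingness")
      z <- as.numeric(scale(lengths[genes]))
      miss_p <- pmin(0.95, pmax(0.02,
                                cspec$missing_rate +
                                  cspec$missing_length_coef * z))
    }
    for (j in seq_len(n_s)) {
      y <- latents + study_eff[, study[j]] + class_eff[, method_class[j]] +
        ct_eff[, cell_type[j]] +
        stats::rnorm(n_g, sd = cspec$noise_sd)
      y <- a[j] * y + b[j] * y^3
      hl_hours <- 10^(0.3 * y + 0.8)
      v <- if (is_rate[j]) log(2) / hl_hours
           else if (identical(unit[j], "minutes")) hl_hours * 60
           else hl_hours
      drop_ <- stats::runif(n_g) < miss_p
      v[drop_] <- NA_real_
      vals[, j] <- v
    }
    meta <- data.frame(sample_id = colnames(vals), study = study,
                       species = "human", cell_type = cell_type,
                       method = method, method_class = method_class,
                       unit = unit, is_degradation_rate = is_rate,
                       stringsAsFactors = FALSE)
    list(values = vals, meta = meta,
         truth = list(latent = latents, distortion_a = a,
                      distortion_b = b, study_effect_sd = cspec$study_sd,
                      class_effect = class_eff))
  })
}
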