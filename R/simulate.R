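# Synthetic locus, cohort, methylation landscape, expression and bisulfite
# reads with full ground truth. The generator emulates the statistical
# structure of an ~8 kb candidate locus: two CpG islands flanking the TSS
# (the second with a tri-modal internal density), a CpG-poor intronic
# enhancer carrying an excess of polymorphic CpGs, a ~30-individual cohort
# with two linked haplotypes ("HI"/"LO") differing in enhancer CpG count,
# feature-structured distance-correlated methylation, expression generated
# under one of three mechanistic models, and directional bisulfite reads with
# imperfect conversion.

#' Default synthetic locus parameters
#'
#' @return Named list of generator parameters; see [generate_locus()].
#' @export
synth_locus_params <- function() {
  list(
    length = 8000L, tss = 2880L,
    island1 = c(2300L, 2699L),
    island2_blocks = list(c(3050L, 3429L), c(3530L, 3909L), c(4010L, 4349L)),
    exon1 = c(2880L, 4250L), intron = c(4251L, 7600L),
    enhancer = c(5500L, 6285L),
    promoter_gc = 0.30, promoter_cpgs = 4L,
    n_enhancer_cpgs = 12L,
    n_polycpg = 30L, n_enhancer_polycpg = 7L, n_island_polycpg = 3L,
    n_multiallelic = 1L, n_other_snps = 10L,
    # six-class variant spectrum favouring the deamination classes
    spectrum_weights = c("CpG/CpA" = 0.45, "CpG/CpC" = 0.03,
                         "CpG/CpT" = 0.07, "CpG/ApG" = 0.07,
                         "CpG/GpG" = 0.03, "CpG/TpG" = 0.35),
    island_cpg_every = 10L, block_cpg_every = 8L, spacer_cpg_every = 60L,
    background_gc = 0.38, background_cpg_keep = 0.5
  )
}

rand_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# GC-balanced stretch with CpGs planted at a regular spacing; accidental
# CpGs are stripped so the planted spacing controls the density profile
island_chars <- function(len, cpg_every) {
  chars <- rand_seq(len, 0.5)
  at <- seq(2L, len - 2L, by = cpg_every)
  chars[at] <- "C"; chars[at + 1L] <- "G"
  repeat {
    cg <- which(chars[-len] == "C" & chars[-1] == "G")
    bad <- setdiff(cg, at)
    if (!length(bad)) break
    chars[bad] <- sample(c("A", "T"), length(bad), replace = TRUE)
  }
  chars
}

#' Generate a synthetic locus with known truth
#'
#' Builds the reference sequence (CpG-suppressed background, two planted CpG
#' islands, a CpG-poor enhancer with a fixed number of CpG sites), places
#' polymorphic CpGs with the six-class variant spectrum and an excess inside
#' the enhancer, adds non-CpG SNPs including the defining set of the
#' high-expression haplotype, and returns a validated `locus_ref` together
#' with the generating truth.
#'
#' @param params Parameter list from [synth_locus_params()].
#' @param seed Integer seed.
#' @return List with `locus` (a `locus_ref`) and `truth` (islands, enhancer,
#'   focal polyCpG, defining SNPs, HI-haplotype delta sites, drawn classes).
#' @export
generate_locus <- function(params = synth_locus_params(), seed = 1L) {
  set.seed(seed)
  p <- params
  chars <- rand_seq(p$length, p$background_gc)
  # suppress background CpGs (deamination-style C->T), one pass
  cg <- which(chars[-p$length] == "C" & chars[-1] == "G")
  drop <- cg[stats::runif(length(cg)) > p$background_cpg_keep]
  chars[drop] <- "T"
  isl2 <- range(unlist(p$island2_blocks))
  if (p$island1[2] >= isl2[1]) stop("island intervals overlap")
  # island 1
  i1 <- p$island1
  chars[i1[1]:i1[2]] <- island_chars(i1[2] - i1[1] + 1L, p$island_cpg_every)
  # island 2: dense blocks separated by sparser spacers (local density minima)
  prev_end <- NULL
  for (blk in p$island2_blocks) {
    chars[blk[1]:blk[2]] <- island_chars(blk[2] - blk[1] + 1L,
                                         p$block_cpg_every)
    if (!is.null(prev_end) && blk[1] > prev_end + 1L)
      chars[(prev_end + 1L):(blk[1] - 1L)] <-
        island_chars(blk[1] - prev_end - 1L, p$spacer_cpg_every)
    prev_end <- blk[2]
  }
  # inter-island gap: AT-rich so islands stay separable, a few CpGs kept
  gap <- c(i1[2] + 1L, isl2[1] - 1L)
  gap_len <- gap[2] - gap[1] + 1L
  gap_chars <- rand_seq(gap_len, p$promoter_gc)
  cg <- which(gap_chars[-gap_len] == "C" & gap_chars[-1] == "G")
  gap_chars[cg] <- "T"
  at <- round(seq(5L, gap_len - 5L, length.out = p$promoter_cpgs))
  gap_chars[at] <- "C"; gap_chars[at + 1L] <- "G"
  chars[gap[1]:gap[2]] <- gap_chars
  # enhancer: CpG-poor, with exactly n_enhancer_cpgs planted sites
  en <- p$enhancer
  en_len <- en[2] - en[1] + 1L
  en_chars <- rand_seq(en_len, 0.40)
  cg <- which(en_chars[-en_len] == "C" & en_chars[-1] == "G")
  en_chars[cg] <- "T"
  slots <- round(seq(5L, en_len - 5L, length.out = p$n_enhancer_cpgs)) +
    sample(-2:2, p$n_enhancer_cpgs, replace = TRUE)
  en_chars[slots] <- "C"; en_chars[slots + 1L] <- "G"
  chars[en[1]:en[2]] <- en_chars

  sequence <- chars_seq(chars)
  cg_all <- which(chars[-p$length] == "C" & chars[-1] == "G")
  in_iv <- function(x, iv) x >= iv[1] & x <= iv[2]
  cg_enh <- cg_all[in_iv(cg_all, en)]
  cg_isl <- cg_all[in_iv(cg_all, i1) | in_iv(cg_all, isl2)]
  cg_rest <- setdiff(cg_all, c(cg_enh, cg_isl))

  n_rest <- p$n_polycpg - p$n_enhancer_polycpg - p$n_island_polycpg
  if (length(cg_enh) < p$n_enhancer_polycpg ||
      length(cg_isl) < p$n_island_polycpg || length(cg_rest) < n_rest)
    stop("not enough CpG sites to place the requested polyCpGs")
  pick_from <- function(x, n) sort(x[sample.int(length(x), n)])
  picks <- c(pick_from(cg_enh, p$n_enhancer_polycpg),
             pick_from(cg_isl, p$n_island_polycpg),
             pick_from(cg_rest, n_rest))
  classes <- sample(names(p$spectrum_weights), length(picks), replace = TRUE,
                    prob = p$spectrum_weights)
  # class determines which base of the dinucleotide the SNP hits and its alt
  class_snp <- function(cls, cpos) {
    switch(cls,
           "CpG/CpA" = c(cpos + 1L, "A"), "CpG/CpC" = c(cpos + 1L, "C"),
           "CpG/CpT" = c(cpos + 1L, "T"), "CpG/ApG" = c(cpos, "A"),
           "CpG/GpG" = c(cpos, "G"), "CpG/TpG" = c(cpos, "T"))
  }
  snp_pos <- integer(); snp_alt <- character()
  for (k in seq_along(picks)) {
    cp <- picks[k]
    info <- class_snp(classes[k], cp)
    pos <- as.integer(info[1]); alt <- info[2]
    # avoid alts that would create a second CpG with a neighbouring base;
    # the realized class follows the adjusted alt
    if (alt == "C" && pos + 1L <= p$length && chars[pos + 1L] == "G") alt <- "T"
    if (alt == "G" && pos - 1L >= 1L && chars[pos - 1L] == "C") alt <- "A"
    if (alt != info[2])
      classes[k] <- if (pos == cp) paste0("CpG/", alt, "pG")
                    else paste0("CpG/Cp", alt)
    snp_pos <- c(snp_pos, pos); snp_alt <- c(snp_alt, alt)
  }
  # one multi-allelic polyCpG: give an extra alt to a non-enhancer site
  if (p$n_multiallelic > 0L) {
    cand <- which(!in_iv(picks, en))
    for (k in utils::head(cand, p$n_multiallelic)) {
      extra <- setdiff(c("A", "C", "G", "T"),
                       c(chars[snp_pos[k]], snp_alt[k], "C", "G"))
      snp_alt[k] <- paste(c(snp_alt[k], extra[1]), collapse = ",")
      classes[k] <- "multi-allelic"
    }
  }
  focal_idx <- ceiling(p$n_enhancer_polycpg / 2)
  focal_cp <- picks[focal_idx]
  delta_idx <- unique(c(focal_idx,
                        utils::head(setdiff(seq_len(p$n_enhancer_polycpg),
                                            focal_idx), 3L)))
  delta_cps <- picks[delta_idx]

  # non-CpG SNPs (incl. three defining SNPs linked to the HI haplotype)
  forbidden <- unique(c(cg_all, cg_all + 1L, snp_pos))
  safe_alt <- function(pos) {
    cand <- setdiff(c("A", "T"), chars[pos])  # A/T never creates a CpG
    cand[1]
  }
  other_pos <- integer()
  while (length(other_pos) < p$n_other_snps) {
    q <- sample(p$length - 2L, 1L) + 1L
    if (q %in% forbidden || q %in% other_pos) next
    other_pos <- c(other_pos, q)
  }
  other_pos <- sort(other_pos)
  defining_other <- other_pos[round(seq(1, length(other_pos), length.out = 3))]

  snps <- data.frame(
    pos = c(snp_pos, other_pos),
    ref = chars[c(snp_pos, other_pos)],
    alt = c(snp_alt, vapply(other_pos, safe_alt, "")),
    stringsAsFactors = FALSE)
  snps <- snps[order(snps$pos), , drop = FALSE]

  locus <- load_locus(sequence, snps,
                      annotations = list(tss = p$tss, exon1 = p$exon1,
                                         intron = p$intron,
                                         enhancer = p$enhancer),
                      id = "synthetic_locus")
  truth <- list(
    island1 = i1, island2 = isl2, island2_blocks = p$island2_blocks,
    enhancer = en,
    polycpg_positions = picks, polycpg_classes = classes,
    focal_polycpg = focal_cp,
    focal_snp = snp_pos[focal_idx],
    defining_snps = sort(c(snp_pos[focal_idx], defining_other)),
    hi_delta_sites = sort(delta_cps),
    seed = seed)
  list(locus = locus, truth = truth)
}

#' Generate a synthetic cohort of diploid individuals
#'
#' Draws two haplotypes per individual with the high-expression ("HI")
#' haplotype at frequency `hi_freq` (Hardy-Weinberg genotype mix in
#' expectation). HI haplotypes carry the non-CpG allele at the configured
#' enhancer delta sites (hence fewer enhancer CpGs) and the alternate allele
#' at the defining SNPs, each with probability `linkage`; all other variant
#' sites segregate independently with per-site minor-allele frequencies drawn
#' uniformly.
#'
#' @param sim Output of [generate_locus()].
#' @param n_individuals Cohort size (default 30).
#' @param hi_freq HI haplotype frequency (default 1/6).
#' @param linkage Probability a haplotype carries its full defining set
#'   (default 0.9, applied per non-focal defining site).
#' @param maf_range Range minor-allele frequencies for unlinked variants are
#'   drawn from (default 0.05-0.4).
#' @param seed Integer seed.
#' @return List with `individuals`, `haplotype` (n-by-2 matrix of
#'   `"HI"`/`"LO"`), `alleles` (list of two character matrices, individuals by
#'   SNPs, of carried bases), `genotype_truth` (data frame `individual`,
#'   `c_position`, `cpg_alleles`), `hi_count`, `enhancer_cpg_count` and
#'   per-individual haplotype sequences accessor data.
#' @export
generate_cohort <- function(sim, n_individuals = 30L, hi_freq = 1 / 6,
                            linkage = 0.9, maf_range = c(0.05, 0.4),
                            seed = 1L) {
  set.seed(seed)
  locus <- sim$locus; truth <- sim$truth
  snps <- locus$snps
  n_snp <- nrow(snps)
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  hap <- matrix(sample(c("HI", "LO"), 2L * n_individuals, replace = TRUE,
                       prob = c(hi_freq, 1 - hi_freq)),
                nrow = n_individuals, ncol = 2L,
                dimnames = list(inds, NULL))
  first_alt <- vapply(strsplit(snps$alt, ","), `[`, "", 1L)
  poly <- locus$cpg[locus$cpg$status == "polymorphic", , drop = FALSE]
  delta_snps <- poly$snp_position[poly$c_position %in% truth$hi_delta_sites]
  maf <- stats::runif(n_snp, maf_range[1], maf_range[2])
  alleles <- lapply(1:2, function(a) {
    m <- matrix(NA_character_, n_individuals, n_snp,
                dimnames = list(inds, as.character(snps$pos)))
    for (j in seq_len(n_snp)) {
      pos <- snps$pos[j]
      if (pos == truth$focal_snp) {
        # the focal polyCpG defines the haplotype: HI lacks the CpG
        m[, j] <- ifelse(hap[, a] == "HI", first_alt[j], snps$ref[j])
      } else if (pos %in% c(truth$defining_snps, delta_snps)) {
        linked <- stats::runif(n_individuals) < linkage
        on_hi <- hap[, a] == "HI"
        m[, j] <- ifelse(on_hi == linked, first_alt[j], snps$ref[j])
      } else {
        m[, j] <- ifelse(stats::runif(n_individuals) < maf[j],
                         first_alt[j], snps$ref[j])
      }
    }
    m
  })
  # CpG-allele count per individual at each polymorphic site
  has_cpg <- function(a, cp, sp) {
    # allele matrix a; site has CpG when the carried base keeps C at cp, G at cp+1
    ref_c <- substring(locus$sequence, cp, cp)
    ref_g <- substring(locus$sequence, cp + 1L, cp + 1L)
    b <- a[, as.character(sp)]
    at_c <- sp == cp
    if (at_c) b == "C" & ref_g == "G" else ref_c == "C" & b == "G"
  }
  gt <- do.call(rbind, lapply(seq_len(nrow(poly)), function(k) {
    cp <- poly$c_position[k]; sp <- poly$snp_position[k]
    n_cpg <- has_cpg(alleles[[1]], cp, sp) + has_cpg(alleles[[2]], cp, sp)
    data.frame(individual = inds, c_position = cp,
               cpg_alleles = as.integer(n_cpg), stringsAsFactors = FALSE)
  }))
  en <- truth$enhancer
  hap_seq <- function(i, a) {
    chars <- seq_chars(locus$sequence)
    chars[snps$pos] <- alleles[[a]][i, ]
    chars_seq(chars)
  }
  enh_count <- vapply(seq_len(n_individuals), function(i) {
    mean(vapply(1:2, function(a) {
      s <- seq_chars(substr(hap_seq(i, a), en[1], en[2]))
      sum(s[-length(s)] == "C" & s[-1] == "G")
    }, numeric(1)))
  }, numeric(1))
  list(individuals = inds, haplotype = hap, alleles = alleles,
       genotype_truth = gt,
       hi_count = stats::setNames(rowSums(hap == "HI"), inds),
       enhancer_cpg_count = stats::setNames(enh_count, inds),
       hap_seq = hap_seq, seed = seed)
}

default_feature_levels <- function() {
  list(
    means = c(CpGi.1 = 0.075, Promoter = 0.018, CpGi.2 = 0.20,
              CpGi.2a = 0.012, CpGi.2b = 0.051, CpGi.2c = 0.446,
              Intron = 0.716, Enhancer = 0.725, shore = 0.716, other = 0.50),
    sds = c(CpGi.1 = 0.10, Promoter = 0.006, CpGi.2 = 0.15,
            CpGi.2a = 0.013, CpGi.2b = 0.064, CpGi.2c = 0.266,
            Intron = 0.188, Enhancer = 0.17, shore = 0.188, other = 0.20))
}

#' Simulate the per-allele methylation landscape
#'
#' Draws, per individual, a latent Gaussian field over the catalogued CpG
#' sites with covariance `exp(-d / corr_length)` and maps it through a
#' logistic link centred at the feature-level means, giving bounded,
#' distance-correlated methylation probabilities. Enhancer sites on HI
#' haplotypes are shifted down by `genotype_effect` (the feature mean
#' describes the common LO background). Alleles lacking the CpG at a
#' polymorphic site get `NA` (nothing to methylate).
#'
#' @param cohort Output of [generate_cohort()].
#' @param sim Output of [generate_locus()].
#' @param feature_map A `feature_map` covering the locus.
#' @param corr_length Correlation length of the latent field in bp
#'   (default 500).
#' @param genotype_effect Downward shift of enhancer methylation on HI
#'   alleles, probability scale (default 0.2).
#' @param feature_levels List with `means` and `sds` per feature name
#'   (defaults mirror a low-methylation island/promoter, an intermediate
#'   distal island compartment and a highly methylated intron and enhancer).
#' @param seed Integer seed.
#' @return List with `sites`, `features`, `p_allele` (individuals x 2 x
#'   sites array), `has_cpg` (same shape, logical), `total` and `per_cpg`
#'   (individuals x sites matrices of the implied total and per-CpG-allele
#'   methylation), and the parameters.
#' @export
simulate_methylation <- function(cohort, sim, feature_map,
                                 corr_length = 500, genotype_effect = 0.2,
                                 feature_levels = default_feature_levels(),
                                 seed = 1L) {
  set.seed(seed)
  locus <- sim$locus
  sites <- locus$cpg$c_position
  n_sites <- length(sites)
  feat <- feature_of(feature_map, sites)
  feat[is.na(feat)] <- "other"
  mu <- feature_levels$means[feat]
  sdv <- feature_levels$sds[feat]
  mu[is.na(mu)] <- 0.5; sdv[is.na(sdv)] <- 0.2
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  s_logit <- pmin(sdv / (mu * (1 - mu)), 3)
  D <- abs(outer(sites, sites, "-"))
  Sig <- exp(-D / corr_length)
  L <- chol(Sig + diag(1e-8, n_sites))
  inds <- cohort$individuals
  n_ind <- length(inds)
  in_enh <- sites >= sim$truth$enhancer[1] & sites <= sim$truth$enhancer[2]

  poly <- locus$cpg[locus$cpg$status == "polymorphic", , drop = FALSE]
  site_is_poly <- sites %in% poly$c_position
  cpg_here <- function(i, a) {
    ok <- rep(TRUE, n_sites)
    for (k in seq_len(nrow(poly))) {
      cp <- poly$c_position[k]; sp <- poly$snp_position[k]
      b <- cohort$alleles[[a]][i, as.character(sp)]
      keep <- if (!is.na(sp) && sp == cp) {
        b == "C" && substring(locus$sequence, cp + 1L, cp + 1L) == "G"
      } else {
        substring(locus$sequence, cp, cp) == "C" && b == "G"
      }
      ok[sites == cp] <- keep
    }
    ok
  }

  p_allele <- array(NA_real_, c(n_ind, 2L, n_sites),
                    dimnames = list(inds, NULL, as.character(sites)))
  has_cpg <- array(TRUE, c(n_ind, 2L, n_sites),
                   dimnames = dimnames(p_allele))
  for (i in seq_len(n_ind)) {
    z <- drop(crossprod(L, stats::rnorm(n_sites)))
    p_base <- stats::plogis(stats::qlogis(mu) + s_logit * z)
    for (a in 1:2) {
      p <- p_base
      if (cohort$haplotype[i, a] == "HI")
        p[in_enh] <- pmax(p[in_enh] - genotype_effect, 0)
      hc <- cpg_here(i, a)
      p[!hc] <- NA_real_
      p_allele[i, a, ] <- p
      has_cpg[i, a, ] <- hc
    }
  }
  h1 <- has_cpg[, 1, ]; h2 <- has_cpg[, 2, ]
  p1 <- ifelse(h1, p_allele[, 1, ], 0)
  p2 <- ifelse(h2, p_allele[, 2, ], 0)
  n_cpg <- h1 + h2
  total <- (p1 + p2) / 2
  per_cpg <- ifelse(n_cpg > 0, (p1 + p2) / n_cpg, NA_real_)
  list(sites = sites, features = feat, p_allele = p_allele,
       has_cpg = has_cpg, total = total, per_cpg = per_cpg,
       corr_length = corr_length, genotype_effect = genotype_effect,
       feature_levels = feature_levels, seed = seed)
}

#' Simulate expression under one of three polyCpG mechanisms
#'
#' The three generative regimes correspond to the mechanistic alternatives
#' for how a polymorphic CpG can shape expression: `density` -- expression
#' follows total enhancer methylation (methyl-binding-domain recruitment
#' scales with overall methylation); `tf_genotype` -- expression follows the
#' CpG-allele count at the focal polyCpG (a transcription factor recognizes
#' one allele); `tf_meth_sensitive` -- expression follows the fraction of
#' methylated CpG alleles at the focal site (a methylation-sensitive factor
#' binds only the CpG allele).
#'
#' @param cohort Output of [generate_cohort()].
#' @param meth_truth Output of [simulate_methylation()].
#' @param sim Output of [generate_locus()].
#' @param model One of `"density"`, `"tf_genotype"`, `"tf_meth_sensitive"`.
#' @param beta Effect size (default strong negative per regime: -6000,
#'   -1500, -5000 respectively, in expression units per predictor unit).
#' @param sigma Noise standard deviation (default 300, which together with
#'   the default `beta` gives a strong-effect regime, signal-to-noise
#'   roughly 2-3).
#' @param baseline Baseline expression (default 5670 dpm/mg TE).
#' @param seed Integer seed.
#' @return List with `expression` (named vector), `model`, `predictor`
#'   (the true predictor values) and the parameters.
#' @export
simulate_expression <- function(cohort, meth_truth, sim,
                                model = c("density", "tf_genotype",
                                          "tf_meth_sensitive"),
                                beta = NULL, sigma = 300, baseline = 5670,
                                seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  sites <- meth_truth$sites
  in_enh <- sites >= sim$truth$enhancer[1] & sites <= sim$truth$enhancer[2]
  focal <- as.character(sim$truth$focal_polycpg)
  if (is.null(beta))
    beta <- switch(model, density = -6000, tf_genotype = -1500,
                   tf_meth_sensitive = -5000)
  x <- switch(model,
    density = rowMeans(meth_truth$total[, in_enh, drop = FALSE]),
    tf_genotype = meth_truth$has_cpg[, 1, focal] +
      meth_truth$has_cpg[, 2, focal],
    tf_meth_sensitive = {
      v <- meth_truth$per_cpg[, focal]
      v[is.na(v)] <- 0  # no CpG allele: the factor never binds
      v
    })
  e <- baseline + beta * x + stats::rnorm(length(x), 0, sigma)
  e <- pmax(e, 0)
  names(e) <- cohort$individuals
  list(expression = e, model = model, predictor = x, beta = beta,
       sigma = sigma, baseline = baseline, seed = seed)
}

#' Binomial read-count measurement of a simulated methylation landscape
#'
#' Measures the simulated per-site total methylation at a given sequencing
#' depth by drawing methylated read counts binomially, yielding a
#' `meth_matrix` and a genotype table with the same shapes the read pipeline
#' produces. This is the fast measurement model used for statistical
#' calibration studies; the full FASTQ path (reads, trimming, alignment,
#' extraction) is exercised by [simulate_reads()].
#'
#' @param meth_truth Output of [simulate_methylation()].
#' @param cohort Output of [generate_cohort()].
#' @param sim Output of [generate_locus()].
#' @param coverage Reads per site per individual (default 100).
#' @param seed Integer seed.
#' @return List with `meth` (a `meth_matrix`) and `genotypes` (data frame
#'   `individual`, `c_position`, `genotype` from the cohort truth).
#' @export
simulate_counts <- function(meth_truth, cohort, sim, coverage = 100L,
                            seed = 1L) {
  set.seed(seed)
  total <- meth_truth$total  # individuals x sites
  n <- length(total)
  m <- matrix(stats::rbinom(n, coverage, as.vector(total)), nrow(total))
  meth <- t(m)  # sites x individuals
  unmeth <- coverage - meth
  dn <- list(site = as.character(meth_truth$sites),
             individual = cohort$individuals)
  dimnames(meth) <- dimnames(unmeth) <- dn
  mm <- structure(list(meth = meth, unmeth = unmeth,
                       fraction = meth / coverage,
                       sites = sim$locus$cpg,
                       individuals = cohort$individuals),
                  class = "meth_matrix")
  gt <- cohort$genotype_truth
  names(gt)[names(gt) == "cpg_alleles"] <- "genotype"
  list(meth = mm, genotypes = gt)
}

default_amplicons <- function(target = c(2700L, 6285L), n = 5L) {
  cuts <- round(seq(target[1], target[2] + 1L, length.out = n + 1L))
  data.frame(start = cuts[-(n + 1L)], end = cuts[-1L] - 1L)
}

#' Simulate directional paired-end bisulfite reads
#'
#' For each fragment: an individual's allele, a strand (original-top or
#' original-bottom, equiprobable) and a start within the amplicon are drawn;
#' each CpG on the fragment draws its methylation state from the allele's
#' probability; bisulfite chemistry converts unmethylated cytosines of the
#' strand of origin to thymine with probability `conversion` (methylated
#' cytosines are protected; all non-CpG cytosines are unmethylated);
#' uniform sequencing errors are added; the two mates read the fragment ends
#' in opposite orientations.
#'
#' @param cohort Output of [generate_cohort()].
#' @param meth_truth Output of [simulate_methylation()].
#' @param sim Output of [generate_locus()].
#' @param coverage Expected per-site read-pair depth per individual
#'   (default 100).
#' @param read_length Read length in bp (default 130).
#' @param fragment_range Fragment length range in bp (default 260-380).
#' @param conversion Bisulfite conversion efficiency (default 0.97).
#' @param error_rate Per-base sequencing error rate (default 0.001).
#' @param amplicons Data frame `start`, `end`; defaults to five amplicons
#'   tiling the 3.6 kb target from upstream of the TSS into the enhancer.
#' @param individuals Subset of cohort individuals to sequence (default all).
#' @param seed Integer seed.
#' @return List with `reads` (read data frame with `individual`) and
#'   `truth` (per-fragment data frame: `id`, `individual`, `allele`,
#'   `strand`, `start`, `end`; plus `conversion`).
#' @export
simulate_reads <- function(cohort, meth_truth, sim, coverage = 100L,
                           read_length = 130L, fragment_range = c(260L, 380L),
                           conversion = 0.97, error_rate = 0.001,
                           amplicons = NULL, individuals = NULL, seed = 1L) {
  set.seed(seed)
  locus <- sim$locus
  if (is.null(amplicons)) amplicons <- default_amplicons()
  if (is.null(individuals)) individuals <- cohort$individuals
  sites <- meth_truth$sites
  bases_pool <- c("A", "C", "G", "T")
  frag_rows <- list(); read_rows <- list()
  k <- 0L
  for (ind in individuals) {
    i <- match(ind, cohort$individuals)
    hapc <- lapply(1:2, function(a) seq_chars(cohort$hap_seq(i, a)))
    for (amp in seq_len(nrow(amplicons))) {
      a_s <- amplicons$start[amp]; a_e <- amplicons$end[amp]
      amp_len <- a_e - a_s + 1L
      n_frag <- max(1L, round(coverage * amp_len / (2 * read_length)))
      for (f in seq_len(n_frag)) {
        k <- k + 1L
        allele <- sample(1:2, 1L)
        strand <- sample(c("OT", "OB"), 1L)
        flen <- min(sample(fragment_range[1]:fragment_range[2], 1L), amp_len)
        fs <- a_s + sample.int(amp_len - flen + 1L, 1L) - 1L
        fe <- fs + flen - 1L
        chars <- hapc[[allele]][fs:fe]
        n <- length(chars)
        # CpG positions on this allele within the fragment
        cg_rel <- which(chars[-n] == "C" & chars[-1] == "G")
        cg_abs <- cg_rel + fs - 1L
        pm <- meth_truth$p_allele[i, allele, match(cg_abs, sites)]
        pm[is.na(pm)] <- 0  # uncatalogued CpG (none expected): unmethylated
        methylated <- stats::runif(length(cg_rel)) < pm
        if (strand == "OT") {
          cs <- which(chars == "C")
          protected <- cg_rel[methylated]
          conv <- setdiff(cs, protected)
          conv <- conv[stats::runif(length(conv)) < conversion]
          chars[conv] <- "T"
        } else {
          gs <- which(chars == "G")
          protected <- cg_rel[methylated] + 1L
          conv <- setdiff(gs, protected)
          conv <- conv[stats::runif(length(conv)) < conversion]
          chars[conv] <- "A"
        }
        fseq <- chars_seq(chars)
        L <- min(read_length, n)
        head_seq <- substr(fseq, 1L, L)
        tail_rc <- revcomp(substr(fseq, n - L + 1L, n))
        m1 <- if (strand == "OT") head_seq else tail_rc
        m2 <- if (strand == "OT") tail_rc else head_seq
        add_err <- function(s) {
          ch <- seq_chars(s)
          hit <- which(stats::runif(length(ch)) < error_rate)
          for (h in hit)
            ch[h] <- sample(setdiff(bases_pool, ch[h]), 1L)
          chars_seq(ch)
        }
        m1 <- add_err(m1); m2 <- add_err(m2)
        id <- sprintf("frag%06d_ind=%s", k, ind)
        q <- strrep("I", L)
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          id = id, mate = c(1L, 2L), bases = c(m1, m2), quals = q,
          individual = ind, stringsAsFactors = FALSE)
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          id = id, individual = ind, allele = allele, strand = strand,
          start = fs, end = fe, stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, read_rows)
  truth <- do.call(rbind, frag_rows)
  rownames(reads) <- rownames(truth) <- NULL
  list(reads = reads, truth = truth, conversion = conversion, seed = seed)
}
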