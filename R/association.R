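# Expression-association and polyCpG-distribution statistics: median split of
# expression, per-site and per-feature differential methylation, genotype
# tests, the three polyCpG measures against expression, the variant-spectrum
# and distribution tests, and PWM allele-affinity comparison.

#' Split individuals at the median expression value
#'
#' Individuals strictly above the median go to the high-expression group,
#' strictly below to the low-expression group; exact ties at the median are
#' assigned alternately, in sorted-identifier order, to whichever group is
#' smaller, so that group sizes differ by at most one.
#'
#' @param expression Named numeric vector of expression values (one per
#'   individual).
#' @return List with `threshold` (the median) and `groups`, a named character
#'   vector of `"high"`/`"low"` assignments.
#' @export
median_split <- function(expression) {
  stopifnot(length(expression) >= 4L, !is.null(names(expression)))
  if (length(unique(expression)) == 1L)
    stop("all expression values equal: degenerate split")
  med <- stats::median(expression)
  grp <- rep(NA_character_, length(expression))
  names(grp) <- names(expression)
  grp[expression > med] <- "high"
  grp[expression < med] <- "low"
  ties <- sort(names(expression)[expression == med])
  for (id in ties) {
    n_high <- sum(grp == "high", na.rm = TRUE)
    n_low <- sum(grp == "low", na.rm = TRUE)
    grp[id] <- if (n_high <= n_low) "high" else "low"
  }
  list(threshold = med, groups = grp)
}

welch_site <- function(hi, lo) {
  hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
  if (length(hi) < 2L || length(lo) < 2L)
    return(c(diff = NA_real_, t = NA_real_, p = NA_real_))
  d <- mean(hi) - mean(lo)
  if (stats::sd(hi) == 0 && stats::sd(lo) == 0)
    return(c(diff = d, t = 0, p = 1))  # zero variance in both groups
  tt <- tryCatch(stats::t.test(hi, lo), error = function(e) NULL)
  if (is.null(tt)) return(c(diff = d, t = 0, p = 1))
  c(diff = d, t = unname(tt$statistic), p = tt$p.value)
}

#' Per-site differential methylation between expression groups
#'
#' Two-sided Welch t-test of methylation fractions between high- and
#' low-expression individuals at every CpG site, with Benjamini-Hochberg
#' adjustment across all tested sites. Sites constant in both groups get
#' p = 1 by convention.
#'
#' @param meth A `meth_matrix`.
#' @param split A split from [median_split()].
#' @return Data frame `c_position`, `mean_diff` (high minus low), `t`, `p`,
#'   `p_adj`.
#' @export
site_differential <- function(meth, split) {
  stopifnot(inherits(meth, "meth_matrix"))
  grp <- split$groups[meth$individuals]
  hi <- meth$fraction[, grp == "high", drop = FALSE]
  lo <- meth$fraction[, grp == "low", drop = FALSE]
  res <- t(vapply(seq_len(nrow(meth$fraction)), function(i) {
    welch_site(hi[i, ], lo[i, ])
  }, numeric(3)))
  out <- data.frame(c_position = meth$sites$c_position,
                    mean_diff = res[, "diff"], t = res[, "t"], p = res[, "p"])
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-feature methylation tests
#'
#' For each gene feature, computes every individual's feature mean (the
#' unweighted mean of the fractions at the feature's CpG sites), then runs a
#' Welch t-test between expression groups and a Pearson correlation of the
#' feature mean with expression.
#'
#' @param meth A `meth_matrix`.
#' @param feature_map A `feature_map` from [partition_features()].
#' @param split A split from [median_split()] (optional, `NULL` skips the
#'   group test).
#' @param expression Named numeric vector of expression values.
#' @return Data frame with one row per feature: `feature`, `n_sites`,
#'   `mean_high`, `mean_low`, `t`, `p_t`, `r`, `p_r`; plus the
#'   individuals-by-features matrix of feature means as attribute
#'   `feature_means`.
#' @export
feature_tests <- function(meth, feature_map, split = NULL, expression = NULL) {
  stopifnot(inherits(meth, "meth_matrix"))
  feat <- feature_of(feature_map, meth$sites$c_position)
  feats <- unique(feat[!is.na(feat)])
  fm <- sapply(feats, function(f) {
    colMeans(meth$fraction[feat %in% f, , drop = FALSE], na.rm = TRUE)
  })
  rownames(fm) <- meth$individuals
  rows <- lapply(feats, function(f) {
    v <- fm[, f]
    if (all(is.na(v))) {
      warning("feature ", f, " has no covered sites; skipped")
      return(NULL)
    }
    row <- data.frame(feature = f, n_sites = sum(feat %in% f),
                      mean_high = NA_real_, mean_low = NA_real_,
                      t = NA_real_, p_t = NA_real_,
                      r = NA_real_, p_r = NA_real_)
    if (!is.null(split)) {
      grp <- split$groups[meth$individuals]
      w <- welch_site(v[grp == "high"], v[grp == "low"])
      row$mean_high <- mean(v[grp == "high"], na.rm = TRUE)
      row$mean_low <- mean(v[grp == "low"], na.rm = TRUE)
      row$t <- w["t"]; row$p_t <- w["p"]
    }
    if (!is.null(expression)) {
      e <- expression[meth$individuals]
      if (stats::sd(v, na.rm = TRUE) > 0) {
        ct <- stats::cor.test(v, e)
        row$r <- unname(ct$estimate); row$p_r <- ct$p.value
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "feature_means") <- fm
  out
}

#' Genotype association tests
#'
#' One-way ANOVA of expression on genotype group (number of high-expression
#' haplotypes, 0/1/2) and tie-corrected Kendall rank correlation (tau-b) of
#' the per-individual enhancer CpG count with the genotype score.
#'
#' @param scores Named integer vector: number of high-expression ("HI")
#'   alleles per individual (0, 1 or 2).
#' @param expression Named numeric vector of expression values.
#' @param enhancer_cpg_counts Optional named integer vector of enhancer CpG
#'   counts per individual for the Kendall test.
#' @return List with `anova_F`, `anova_p`, `kendall_tau`, `kendall_p`.
#' @export
genotype_tests <- function(scores, expression, enhancer_cpg_counts = NULL) {
  ids <- intersect(names(scores), names(expression))
  g <- factor(scores[ids])
  out <- list(anova_F = NA_real_, anova_p = NA_real_,
              kendall_tau = NA_real_, kendall_p = NA_real_)
  if (nlevels(g) >= 2L) {
    fit <- stats::aov(expression[ids] ~ g)
    s <- summary(fit)[[1]]
    out$anova_F <- s$`F value`[1]
    out$anova_p <- s$`Pr(>F)`[1]
  }
  if (!is.null(enhancer_cpg_counts)) {
    ids2 <- intersect(names(scores), names(enhancer_cpg_counts))
    ct <- suppressWarnings(
      stats::cor.test(enhancer_cpg_counts[ids2], as.numeric(scores[ids2]),
                      method = "kendall"))
    out$kendall_tau <- unname(ct$estimate)
    out$kendall_p <- ct$p.value
  }
  out
}

#' Compare the three polyCpG measures as predictors of expression
#'
#' For every polymorphic CpG, Pearson correlation (with two-sided p) of
#' expression with each of `total_meth`, `genotype` and `meth_per_cpg`, and
#' per site the predictor with the largest absolute correlation. The winning
#' predictor points to the mechanism by which the site could drive
#' expression: overall methylation density, sequence-specific transcription
#' factor binding, or methylation-sensitive binding of the CpG allele.
#'
#' @param measures Data frame from [polycpg_measures()].
#' @param expression Named numeric vector of expression values.
#' @param min_n Minimum individuals with a defined predictor (default 5).
#' @return List with `results` (one row per site and predictor: `c_position`,
#'   `predictor`, `r`, `p`, `n`) and `top` (per site, the winning predictor).
#' @export
polycpg_model_comparison <- function(measures, expression, min_n = 5L) {
  preds <- c("total_meth", "genotype", "meth_per_cpg")
  rows <- list()
  for (cp in unique(measures$c_position)) {
    sub <- measures[measures$c_position == cp, , drop = FALSE]
    e <- expression[sub$individual]
    for (pr in preds) {
      x <- as.numeric(sub[[pr]])
      ok <- !is.na(x) & !is.na(e)
      r <- p <- NA_real_
      if (sum(ok) >= min_n && stats::sd(x[ok]) > 0 && stats::sd(e[ok]) > 0) {
        ct <- stats::cor.test(x[ok], e[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(c_position = cp, predictor = pr, r = r, p = p, n = sum(ok))
    }
  }
  res <- do.call(rbind, rows)
  top <- do.call(rbind, lapply(split(res, res$c_position), function(d) {
    if (all(is.na(d$r))) return(data.frame(c_position = d$c_position[1],
                                           predictor = NA_character_,
                                           r = NA_real_))
    w <- which.max(abs(d$r))
    data.frame(c_position = d$c_position[1], predictor = d$predictor[w],
               r = d$r[w])
  }))
  rownames(top) <- NULL
  list(results = res, top = top)
}

#' PolyCpG variant-spectrum test
#'
#' Counts bi-allelic polymorphic CpGs in each of the six possible variant
#' classes (CpG/CpA, CpG/CpC, CpG/CpT, CpG/ApG, CpG/GpG, CpG/TpG) and tests
#' the observed spectrum against the neutral expectation that every class is
#' equally likely (chi-square goodness of fit, df = 5). Deamination of
#' methylated cytosine predicts an excess of the CpA and TpG classes.
#'
#' @param catalogue CpG catalogue data frame (from [catalogue_cpgs()] or a
#'   `locus_ref$cpg`).
#' @return List with `counts` (named length-6 vector), `n_biallelic`,
#'   `chi_square`, `df`, `p`.
#' @export
spectrum_test <- function(catalogue) {
  classes <- c("CpG/CpA", "CpG/CpC", "CpG/CpT",
               "CpG/ApG", "CpG/GpG", "CpG/TpG")
  cls <- catalogue$variant_class
  cls <- cls[!is.na(cls) & cls != "multi-allelic"]
  if (!length(cls)) stop("no bi-allelic polymorphic CpGs in catalogue")
  counts <- table(factor(cls, levels = classes))
  ct <- suppressWarnings(stats::chisq.test(as.integer(counts),
                                           p = rep(1 / 6, 6)))
  list(counts = stats::setNames(as.integer(counts), classes),
       n_biallelic = length(cls),
       chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-by-two Fisher's exact test for polyCpG distribution
#'
#' Exact two-sided Fisher test on a 2x2 contingency table, used to compare
#' polyCpG rates between a focal region and the rest of the locus (polyCpGs
#' vs fixed CpGs, or polyCpGs vs non-polyCpG nucleotides). The two-sided
#' p-value sums all tables whose point hypergeometric probability does not
#' exceed the observed table's.
#'
#' @param poly_in,other_in Counts inside the focal region.
#' @param poly_out,other_out Counts outside it.
#' @return List with `table`, `odds_ratio`, `p_two_sided`, and the two group
#'   proportions `prop_in`, `prop_out`.
#' @export
distribution_fisher <- function(poly_in, other_in, poly_out, other_out) {
  poly_in <- as.vector(poly_in); other_in <- as.vector(other_in)
  poly_out <- as.vector(poly_out); other_out <- as.vector(other_out)
  tab <- matrix(c(poly_in, poly_out, other_in, other_out), nrow = 2,
                dimnames = list(region = c("in", "out"),
                                class = c("poly", "other")))
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table needs non-negative entries and positive margins")
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_two_sided = ft$p.value,
       prop_in = poly_in / (poly_in + other_in),
       prop_out = poly_out / (poly_out + other_out))
}
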