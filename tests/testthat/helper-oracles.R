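# Independent brute-force oracles used to validate the implementation.
# These deliberately use the most direct (slow) formulation of each
# computation, not the package's own code paths.

# Enumerate every haplotype over the SNP alleles and scan each for CG
# dinucleotides; a site is fixed when CG on every haplotype, polymorphic when
# CG on some but not all.
oracle_catalogue <- function(sequence, snps) {
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  if (nrow(snps) == 0L) {
    cg <- which(chars[-len] == "C" & chars[-1] == "G")
    return(data.frame(c_position = cg, status = rep("fixed", length(cg))))
  }
  alt_list <- strsplit(snps$alt, ",")
  allele_sets <- lapply(seq_len(nrow(snps)),
                        function(j) c(snps$ref[j], alt_list[[j]]))
  combos <- expand.grid(allele_sets, stringsAsFactors = FALSE)
  cg_sets <- lapply(seq_len(nrow(combos)), function(k) {
    h <- chars
    h[snps$pos] <- unlist(combos[k, ])
    which(h[-len] == "C" & h[-1] == "G")
  })
  all_pos <- sort(unique(unlist(cg_sets)))
  in_all <- vapply(all_pos, function(p) {
    all(vapply(cg_sets, function(s) p %in% s, logical(1)))
  }, logical(1))
  data.frame(c_position = all_pos,
             status = ifelse(in_all, "fixed", "polymorphic"))
}

# Direct substring counting at every offset.
oracle_window_counts <- function(sequence, window) {
  len <- nchar(sequence)
  vapply(seq_len(len - window + 1L), function(s) {
    win <- substr(sequence, s, s + window - 1L)
    cnt <- 0L
    for (i in seq_len(window - 1L))
      if (substr(win, i, i + 1L) == "CG") cnt <- cnt + 1L
    cnt
  }, integer(1))
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    cand <- vapply(k:n, function(j) n * p[ord[j]] / j, numeric(1))
    adj[ord[k]] <- min(1, min(cand))
  }
  adj
}

# One-way ANOVA F from raw sums of squares.
oracle_anova_f <- function(y, g) {
  g <- as.factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  k <- nlevels(g); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher p.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Chi-square goodness of fit against uniform class probabilities.
oracle_chisq_uniform <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

# A small analysis-ready synthetic world shared across tests (built once).
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_locus(seed = 11L)
      isl <- predict_islands(sim$locus$sequence)
      prof <- cpg_density_profile(sim$locus$sequence)
      comp <- subdivide_island(isl[2, ], prof)
      fm <- partition_features(sim$locus, isl, comp)
      cohort <- generate_cohort(sim, seed = 12L)
      mt <- simulate_methylation(cohort, sim, fm, seed = 13L)
      cache <<- list(sim = sim, islands = isl, profile = prof,
                     compartments = comp, features = fm,
                     cohort = cohort, meth_truth = mt)
    }
    cache
  }
})
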