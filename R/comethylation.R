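# Pairwise co-methylation, its decay with genomic distance within and between
# gene features, and cross-platform concordance, with permutation-based
# significance throughout. Permutation p-values use the conservative add-one
# form p = (1 + #{null >= observed}) / (n_perm + 1).

#' Pairwise co-methylation matrix
#'
#' Pearson correlation of methylation fractions between every pair of CpG
#' sites across individuals, using pairwise-complete observations. Cells with
#' fewer than `min_individuals` complete pairs, and sites with no variation,
#' are `NA`.
#'
#' @param meth A `meth_matrix`, or a numeric matrix of fractions with sites in
#'   rows and individuals in columns.
#' @param min_individuals Minimum complete pairs per cell (default 5).
#' @return List with `r` (sites-by-sites correlation matrix) and `n_pairs`
#'   (complete pairs per cell).
#' @export
comethylation_matrix <- function(meth, min_individuals = 5L) {
  x <- if (inherits(meth, "meth_matrix")) meth$fraction else meth
  x <- t(x)  # individuals in rows for cor()
  n_pairs <- crossprod(!is.na(x))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[n_pairs < min_individuals] <- NA_real_
  list(r = r, n_pairs = n_pairs)
}

pair_table <- function(r, positions, features) {
  p <- ncol(r)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(
    site_i = idx[, 1], site_j = idx[, 2],
    r = r[idx],
    distance = abs(positions[idx[, 2]] - positions[idx[, 1]]),
    same_feature = features[idx[, 1]] == features[idx[, 2]])
}

decay_coefs <- function(tab) {
  fit <- stats::lm(r ~ distance * same_feature, data = tab)
  cf <- stats::coef(fit)
  c(slope_distance = unname(cf["distance"]),
    same_feature_effect = unname(cf["same_featureTRUE"]),
    interaction = unname(cf["distance:same_featureTRUE"]))
}

#' Distance decay of co-methylation within and between features
#'
#' Ordinary least squares of pairwise co-methylation on pair distance, a
#' same-feature indicator and their interaction. Significance is assessed by
#' permutation: the site positions (and their feature labels) are shuffled
#' across the columns of the fixed correlation matrix, which destroys the
#' distance structure while preserving the empirical correlation
#' distribution; two-sided add-one p-values are reported per coefficient.
#'
#' @param comat Output of [comethylation_matrix()] (or a bare correlation
#'   matrix).
#' @param positions Integer vector of site positions (1-based).
#' @param features Character vector of feature labels per site.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return List with `coefficients`, `p_perm`, `n_perm`, `seed`, `n_pairs`
#'   and the tidy `pairs` table.
#' @export
distance_decay <- function(comat, positions, features, n_perm = 1000L,
                           seed = 1L) {
  r <- if (is.list(comat)) comat$r else comat
  stopifnot(length(positions) == ncol(r), length(features) == ncol(r))
  tab <- pair_table(r, positions, features)
  tab <- tab[!is.na(tab$r), , drop = FALSE]
  strata <- table(tab$same_feature)
  if (length(strata) < 2L || any(strata < 10L))
    warning("fewer than 10 site pairs in a stratum; interaction may be unstable")
  obs <- decay_coefs(tab)
  p <- ncol(r)
  exceed <- c(0L, 0L, 0L)
  valid <- c(0L, 0L, 0L)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(p)
    ptab <- pair_table(r, positions[perm], features[perm])
    ptab <- ptab[!is.na(ptab$r), , drop = FALSE]
    pc <- tryCatch(decay_coefs(ptab), error = function(e) rep(NA_real_, 3))
    ok <- !is.na(pc) & !is.na(obs)
    valid <- valid + ok
    exceed <- exceed + (ok & abs(pc) >= abs(obs))
  }
  p_perm <- ifelse(is.na(obs), NA_real_, (1 + exceed) / (valid + 1))
  names(p_perm) <- names(obs)
  list(coefficients = obs, p_perm = p_perm, n_perm = n_perm, seed = seed,
       n_pairs = nrow(tab), pairs = tab)
}

#' Cross-platform concordance by permutation
#'
#' Pearson correlation between two methylation matrices over their shared
#' (individual, site) pairs, with a null distribution built by randomly
#' reassigning the individuals of the second matrix.
#'
#' @param meth_a,meth_b `meth_matrix` objects or numeric matrices (sites in
#'   rows, individuals in columns) sharing row and column names.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return List with `r_observed`, `p_perm`, `n_perm`, `seed`, `n_shared`.
#' @export
concordance_test <- function(meth_a, meth_b, n_perm = 1000L, seed = 1L) {
  a <- if (inherits(meth_a, "meth_matrix")) meth_a$fraction else meth_a
  b <- if (inherits(meth_b, "meth_matrix")) meth_b$fraction else meth_b
  sites <- intersect(rownames(a), rownames(b))
  inds <- intersect(colnames(a), colnames(b))
  if (length(inds) < 3L) stop("need at least 3 shared individuals")
  if (!length(sites)) stop("no shared sites")
  a <- a[sites, inds, drop = FALSE]
  b <- b[sites, inds, drop = FALSE]
  r_obs <- stats::cor(as.vector(a), as.vector(b),
                      use = "pairwise.complete.obs")
  set.seed(seed)
  r_null <- replicate(n_perm, {
    stats::cor(as.vector(a), as.vector(b[, sample(ncol(b)), drop = FALSE]),
               use = "pairwise.complete.obs")
  })
  list(r_observed = r_obs,
       p_perm = (1 + sum(r_null >= r_obs, na.rm = TRUE)) / (n_perm + 1),
       n_perm = n_perm, seed = seed,
       n_shared = length(inds) * length(sites))
}
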