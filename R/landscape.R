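#' Sliding-window CpG density profile
#'
#' Counts CpG dinucleotides, G+C fraction and the observed/expected CpG ratio
#' in sliding windows across a sequence. The observed/expected ratio in a
#' window of length L is `N_CpG * L / (N_C * N_G)`, the classical measure of
#' CpG depletion relative to base composition; it is defined as 0 when the
#' window contains no C or no G.
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param window Window size in bp (default 300).
#' @param step Step between window starts in bp (default 1).
#' @return Data frame with one row per window: `start` (1-based window start),
#'   `cpg` (CpG count fully inside the window), `gc` (G+C fraction) and
#'   `obs_exp`.
#' @export
cpg_density_profile <- function(sequence, window = 300L, step = 1L) {
  len <- nchar(sequence)
  if (len < window) stop("sequence (", len, " bp) shorter than window")
  chars <- seq_chars(sequence)
  is_c <- chars == "C"
  is_g <- chars == "G"
  cg_at <- c(is_c[-len] & is_g[-1], FALSE)  # CpG starting at each position
  cum_c <- c(0L, cumsum(is_c)); cum_g <- c(0L, cumsum(is_g))
  cum_cg <- c(0L, cumsum(cg_at))
  starts <- seq.int(1L, len - window + 1L, by = step)
  ends <- starts + window - 1L
  rng <- function(cs, a, b) cs[b + 1L] - cs[a]
  n_c <- rng(cum_c, starts, ends)
  n_g <- rng(cum_g, starts, ends)
  n_cg <- rng(cum_cg, starts, ends - 1L)  # CpG must lie fully inside
  obs_exp <- ifelse(n_c * n_g > 0, n_cg * window / (n_c * n_g), 0)
  data.frame(start = starts, cpg = n_cg, gc = (n_c + n_g) / window,
             obs_exp = obs_exp)
}

#' Predict CpG islands
#'
#' Scans the sequence with a sliding window and merges maximal runs of window
#' starts whose windows exceed both the G+C and observed/expected thresholds.
#' A merged run's island spans from the first passing window's start to the
#' last passing window's end; islands not longer than `min_length` are
#' discarded. These are the traditional island criteria (length > 200 bp,
#' GC > 50%, Obs/Exp CpG > 0.60).
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param window Window size in bp (default 300).
#' @param min_length Minimum island length in bp (default 200).
#' @param min_gc Minimum G+C fraction (default 0.5, exclusive).
#' @param min_obs_exp Minimum observed/expected CpG ratio (default 0.6,
#'   exclusive).
#' @param step Step between window starts (default 1).
#' @return Data frame `start`, `end`, `length` of islands in 5'-to-3' order
#'   (zero rows when none pass).
#' @export
predict_islands <- function(sequence, window = 300L, min_length = 200L,
                            min_gc = 0.5, min_obs_exp = 0.6, step = 1L) {
  prof <- cpg_density_profile(sequence, window, step)
  pass <- prof$gc > min_gc & prof$obs_exp > min_obs_exp
  if (!any(pass))
    return(data.frame(start = integer(), end = integer(), length = integer()))
  starts <- prof$start[pass]
  # merge passing windows whose intervals overlap or touch
  brk <- c(TRUE, diff(starts) > window)
  run <- cumsum(brk)
  isl <- do.call(rbind, lapply(split(starts, run), function(s) {
    data.frame(start = min(s), end = max(s) + window - 1L)
  }))
  isl$length <- isl$end - isl$start + 1L
  isl <- isl[isl$length > min_length, , drop = FALSE]
  isl <- isl[order(isl$start), , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

#' Subdivide a CpG island at local density minima
#'
#' Smooths the within-island CpG-count curve with a centred moving average
#' and splits the island at internal local minima, so that heterogeneous
#' islands (e.g. one with a tri-modal density) are broken into contiguous
#' compartments. Only prominent minima split: a candidate must sit below the
#' smaller of the flanking maxima by at least `min_prominence` of the curve's
#' range, and minima closer than one window apart are collapsed to the
#' lowest. Plateau minima are split at the plateau midpoint. `k` accepted
#' minima give `k + 1` compartments that tile the island exactly.
#'
#' @param island One-row data frame (or list) with `start` and `end`.
#' @param profile Density profile from [cpg_density_profile()] covering the
#'   island (window starts inside it).
#' @param smoothing_halfwidth Half-width of the moving average in profile
#'   steps (default 25).
#' @param window Window size the profile was computed with (default 300).
#' @param min_prominence Minimum prominence of a splitting minimum, as a
#'   fraction of the within-island density range (default 0.25).
#' @return Data frame `start`, `end` of compartments in order. Islands
#'   shorter than three windows are returned unsplit.
#' @export
subdivide_island <- function(island, profile, smoothing_halfwidth = 25L,
                             window = 300L, min_prominence = 0.25) {
  start <- island$start[1]; end <- island$end[1]
  keep <- profile$start >= start & profile$start <= end - window + 1L
  y <- profile$cpg[keep]
  xs <- profile$start[keep]
  if (end - start + 1L < 3L * window || length(y) < 3L)
    return(data.frame(start = start, end = end))
  # centred moving average, shrinking at the edges
  h <- smoothing_halfwidth
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  rng <- diff(range(sm))
  if (rng == 0) return(data.frame(start = start, end = end))
  # internal strict local minima on the run-length-compressed curve
  r <- rle(sm)
  nr <- length(r$values)
  if (nr < 3L) return(data.frame(start = start, end = end))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  cand <- integer()
  for (j in 2:(nr - 1L)) {
    if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
      cand <- c(cand, (starts_idx[j] + ends_idx[j]) %/% 2L)
  }
  if (!length(cand)) return(data.frame(start = start, end = end))
  prom <- vapply(cand, function(m) {
    min(max(sm[1:m]), max(sm[m:n])) - sm[m]
  }, numeric(1))
  cand <- cand[prom >= min_prominence * rng]
  # collapse minima within one window of each other, keeping the lowest
  cand <- cand[order(sm[cand])]
  kept <- integer()
  for (m in cand) {
    if (!length(kept) || all(abs(xs[m] - xs[kept]) >= window))
      kept <- c(kept, m)
  }
  if (!length(kept)) return(data.frame(start = start, end = end))
  splits <- sort(xs[kept] + window %/% 2L)
  splits <- splits[splits > start & splits <= end]
  if (!length(splits)) return(data.frame(start = start, end = end))
  bounds <- c(start, splits, end + 1L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L] - 1L)
}

#' Partition a locus into named gene features
#'
#' Assembles the named, non-overlapping feature map used to stratify
#' methylation analyses: the first island becomes `CpGi.1`, the inter-island
#' gap containing the TSS becomes `Promoter`, compartments of the second
#' island become `CpGi.2a`, `CpGi.2b`, ..., the segment from the second island
#' to the enhancer becomes `Intron`, the supplied enhancer interval becomes
#' `Enhancer`, island flanks up to `shore_flank` bp not otherwise labelled
#' become `shore`, and everything else `other`. Overlaps are resolved by
#' priority: islands/compartments > Promoter > Enhancer > Intron > shore >
#' other.
#'
#' @param locus A `locus_ref` (used for length and TSS).
#' @param islands Data frame `start`, `end` from [predict_islands()].
#' @param compartments Optional data frame `start`, `end` of second-island
#'   compartments from [subdivide_island()]; when `NULL` the second island is
#'   labelled `CpGi.2` unsplit.
#' @param enhancer Optional 1-based interval `c(start, end)`; defaults to the
#'   locus annotation `enhancer` when present. The enhancer is an input (e.g.
#'   from H3K4me1 ChIP-seq), never computed.
#' @param shore_flank Shore width in bp (default 2000).
#' @param target Optional interval restricting the map (e.g. the sequencing
#'   target); defaults to the whole locus.
#' @return A `feature_map`: data frame `name`, `start`, `end`, pairwise
#'   disjoint and jointly covering `target`.
#' @export
partition_features <- function(locus, islands, compartments = NULL,
                               enhancer = NULL, shore_flank = 2000L,
                               target = NULL) {
  len <- locus$length
  enhancer <- enhancer %||% locus$annotations$enhancer
  target <- target %||% c(1L, len)
  target <- check_interval(target, len, "target")
  lab <- rep("other", len)
  paint <- function(iv, name) {
    if (is.null(iv)) return(invisible())
    s <- max(1L, as.integer(iv[1])); e <- min(len, as.integer(iv[2]))
    if (s <= e) lab[s:e] <<- name
    invisible()
  }
  n_isl <- nrow(islands)
  # lowest priority first; later paints win
  for (i in seq_len(n_isl)) {   # shores
    paint(c(islands$start[i] - shore_flank, islands$start[i] - 1L), "shore")
    paint(c(islands$end[i] + 1L, islands$end[i] + shore_flank), "shore")
  }
  if (n_isl >= 2L && !is.null(enhancer))
    paint(c(islands$end[2] + 1L, enhancer[1] - 1L), "Intron")
  if (!is.null(enhancer)) {
    for (i in seq_len(n_isl)) {
      if (enhancer[1] <= islands$end[i] && enhancer[2] >= islands$start[i])
        stop("enhancer interval overlaps a CpG island")
    }
    paint(enhancer, "Enhancer")
  }
  if (n_isl >= 2L && !is.na(locus$tss) &&
      locus$tss > islands$end[1] && locus$tss < islands$start[2])
    paint(c(islands$end[1] + 1L, islands$start[2] - 1L), "Promoter")
  if (n_isl >= 1L) paint(unlist(islands[1, c("start", "end")]), "CpGi.1")
  if (n_isl >= 2L) {
    if (is.null(compartments)) {
      paint(unlist(islands[2, c("start", "end")]), "CpGi.2")
    } else {
      for (i in seq_len(nrow(compartments)))
        paint(unlist(compartments[i, c("start", "end")]),
              paste0("CpGi.2", letters[i]))
    }
  }
  if (n_isl > 2L) for (i in 3:n_isl)
    paint(unlist(islands[i, c("start", "end")]), paste0("CpGi.", i))
  lab <- lab[target[1]:target[2]]
  r <- rle(lab)
  ends <- cumsum(r$lengths) + target[1] - 1L
  fm <- data.frame(name = r$values,
                   start = ends - r$lengths + 1L,
                   end = ends, stringsAsFactors = FALSE)
  class(fm) <- c("feature_map", "data.frame")
  fm
}

#' Map positions to features
#'
#' @param feature_map A `feature_map` from [partition_features()].
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of feature names (`NA` outside the map).
#' @export
feature_of <- function(feature_map, positions) {
  idx <- vapply(positions, function(p) {
    h <- which(feature_map$start <= p & feature_map$end >= p)
    if (length(h)) h[1] else NA_integer_
  }, integer(1))
  feature_map$name[idx]
}
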