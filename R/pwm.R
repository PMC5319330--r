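#' Compare PWM binding affinity between two alleles
#'
#' Scores a set of position weight matrices against the two allele sequences
#' of a short window (e.g. 20 bp centred on a polymorphic CpG). Count
#' matrices are converted to log-odds with a pseudocount against a background
#' base distribution; each motif's affinity per allele is the best log-odds
#' score over both strands and all placements. Motifs are ranked by the
#' absolute allele difference in best score, the signature of
#' sequence-specific transcription factor binding at the polymorphism.
#'
#' @param pwms Named list of 4-by-w numeric matrices (rows A, C, G, T;
#'   JASPAR-style counts or probabilities).
#' @param window_a,window_b Allele sequences of equal length.
#' @param background Background base probabilities (default uniform).
#' @param pseudocount Added to each count before normalization (default 0.1).
#' @param p_values Optional named numeric vector of motif-level p-values to
#'   carry through Benjamini-Hochberg adjustment.
#' @return Data frame, one row per scored motif, ordered by decreasing
#'   `|score_a - score_b|`: `motif`, `score_a`, `score_b`, `difference`, and
#'   `p_adj` when `p_values` was supplied. Motifs longer than the window are
#'   skipped with a warning.
#' @export
pwm_allele_affinity <- function(pwms, window_a, window_b,
                                background = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                                pseudocount = 0.1, p_values = NULL) {
  stopifnot(nchar(window_a) == nchar(window_b))
  if (is.null(names(pwms)))
    names(pwms) <- paste0("motif", seq_along(pwms))
  rows <- lapply(names(pwms), function(nm) {
    pwm <- as.matrix(pwms[[nm]])
    if (nrow(pwm) != 4L) stop("PWM '", nm, "' must have 4 rows (A,C,G,T)")
    rownames(pwm) <- c("A", "C", "G", "T")
    if (ncol(pwm) > nchar(window_a)) {
      warning("motif ", nm, " (", ncol(pwm),
              " bp) longer than window; skipped")
      return(NULL)
    }
    prob <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
    lods <- log2(prob / background[rownames(prob)])
    sa <- best_pwm_score(lods, toupper(window_a))
    sb <- best_pwm_score(lods, toupper(window_b))
    data.frame(motif = nm, score_a = sa, score_b = sb, difference = sa - sb)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (!is.null(p_values))
    out$p_adj <- stats::p.adjust(p_values[out$motif], method = "BH")
  out <- out[order(-abs(out$difference)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

best_pwm_score <- function(lods, window) {
  w <- ncol(lods)
  score_strand <- function(s) {
    ri <- match(seq_chars(s), rownames(lods))
    n <- length(ri)
    best <- -Inf
    for (o in 0:(n - w)) {
      idx <- ri[(o + 1):(o + w)]
      if (anyNA(idx)) next  # ambiguous base: placement skipped
      sc <- sum(lods[cbind(idx, seq_len(w))])
      if (sc > best) best <- sc
    }
    best
  }
  max(score_strand(window), score_strand(revcomp(window)))
}
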