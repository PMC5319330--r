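# Read processing: trimming, bisulfite-aware ungapped alignment against the
# ambiguity reference, methylation extraction, genotype calling at polymorphic
# CpGs, and the allele-normalized methylation measures.
#
# Reads are held in a data frame with columns `id` (fragment identifier,
# shared by a pair), `mate` (1 or 2), `bases`, `quals` (Phred+33 string) and
# optionally `individual`.

DEFAULT_ADAPTER <- "AGATCGGAAGAGC"  # Illumina TruSeq/Nextflex adapter stem

#' Trim paired bisulfite reads
#'
#' Applies the amplicon-sequencing trimming chain: 3' bases below the quality
#' threshold are removed, 3' adapter contamination is clipped (full matches
#' anywhere, or a terminal overlap of at least `min_overlap` bases with the
#' adapter prefix), reads are then shortened to `max_len` bases, and reads
#' falling below `min_len` are dropped together with their mate when
#' `drop_orphans` is set.
#'
#' @param reads Read data frame (see module description).
#' @param max_len Maximum retained read length in bp (default 130).
#' @param min_phred Quality threshold for 3' trimming (default 20).
#' @param min_len Minimum read length in bp after trimming (default 16).
#' @param adapter 3' adapter sequence (set `NULL` to skip adapter clipping).
#' @param min_overlap Minimum terminal adapter overlap (default 5).
#' @param drop_orphans Drop a read whose mate was removed (default `TRUE`).
#' @return Trimmed read data frame.
#' @export
trim_reads <- function(reads, max_len = 130L, min_phred = 20L, min_len = 16L,
                       adapter = DEFAULT_ADAPTER, min_overlap = 5L,
                       drop_orphans = TRUE) {
  stopifnot(min_len <= max_len)
  if (!nrow(reads)) return(reads)
  if (anyDuplicated(paste(reads$id, reads$mate)))
    stop("duplicate (id, mate) records: mate counts do not match up")
  bases <- reads$bases; quals <- reads$quals
  n <- length(bases)
  for (i in seq_len(n)) {
    b <- bases[i]; q <- phred_to_int(quals[i])
    # 3' quality trim: drop the trailing run of bases below threshold
    keep <- length(q)
    while (keep > 0L && q[keep] < min_phred) keep <- keep - 1L
    b <- substr(b, 1L, keep)
    # adapter clip
    if (!is.null(adapter) && nchar(b)) {
      hit <- regexpr(adapter, b, fixed = TRUE)
      if (hit > 0L) {
        b <- substr(b, 1L, hit - 1L)
      } else {
        nb <- nchar(b)
        max_ov <- min(nchar(adapter) - 1L, nb)
        for (k in max_ov:min_overlap) {
          if (k < min_overlap) break
          if (substr(b, nb - k + 1L, nb) == substr(adapter, 1L, k)) {
            b <- substr(b, 1L, nb - k)
            break
          }
        }
      }
    }
    keep <- min(nchar(b), max_len)
    bases[i] <- substr(b, 1L, keep)
    quals[i] <- substr(quals[i], 1L, keep)
  }
  reads$bases <- bases; reads$quals <- quals
  ok <- nchar(bases) >= min_len
  if (drop_orphans) {
    ok_frag <- tapply(ok, reads$id, all)
    ok <- ok & ok_frag[reads$id]
  }
  out <- reads[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

encode_mask <- function(sequence) {
  chars <- seq_chars(sequence)
  m <- vapply(chars, function(ch) {
    b <- BASE_BITS[ch]
    if (!is.na(b)) return(unname(b))
    iupac_mask(ch)
  }, integer(1), USE.NAMES = FALSE)
  as.integer(m)
}

conversion_frames <- function(ambiguity_reference) {
  m <- encode_mask(ambiguity_reference)
  list(
    # original-top frame: an unmethylated reference C may read as T
    OT = as.integer(bitwOr(m, ifelse(bitwAnd(m, BASE_BITS[["C"]]) > 0,
                                     BASE_BITS[["T"]], 0L))),
    # original-bottom frame seen in top orientation: reference G may read as A
    OB = as.integer(bitwOr(m, ifelse(bitwAnd(m, BASE_BITS[["G"]]) > 0,
                                     BASE_BITS[["A"]], 0L)))
  )
}

#' Align bisulfite reads to the ambiguity reference
#'
#' Ungapped, bisulfite-aware alignment at amplicon scale. Each read is scanned
#' across the reference in the two conversion frames of a directional library:
#' original-top (read C may appear as T where the reference has C) and
#' original-bottom (read in top orientation, G may appear as A). IUPAC
#' ambiguity codes in the reference match any of their bases before
#' conversion. A read maps only if a single best placement exists with at most
#' `max_mismatch` mismatches; ties within or across frames leave it unmapped.
#' Mate 2 of a pair is sequenced in the opposite orientation and is
#' reverse-complemented into top orientation before frame selection.
#'
#' @param reads Read data frame (`id`, `mate`, `bases`, optionally
#'   `individual`).
#' @param ambiguity_reference Character scalar from
#'   [build_bisulfite_reference()].
#' @param max_mismatch Maximum mismatches per read (default 3).
#' @return Data frame of aligned reads: `id`, `mate`, `individual`, `strand`
#'   (`OT`/`OB`), `start`, `end` (1-based on the reference), `mismatches`,
#'   `seq` (read bases in top-strand orientation). Unmapped reads are counted
#'   in the `unmapped` attribute.
#' @export
align_bisulfite <- function(reads, ambiguity_reference, max_mismatch = 3L) {
  frames <- conversion_frames(ambiguity_reference)
  n <- nrow(reads)
  ind <- if ("individual" %in% names(reads)) reads$individual else
    rep(NA_character_, n)
  res <- vector("list", n)
  unmapped <- 0L
  for (i in seq_len(n)) {
    fwd <- toupper(reads$bases[i])
    if (!nchar(fwd)) { unmapped <- unmapped + 1L; next }
    rev <- revcomp(fwd)
    mate <- if ("mate" %in% names(reads)) reads$mate[i] else 1L
    # top-orientation candidate per frame: mate 1 reads the strand of origin,
    # mate 2 its complement
    cand <- if (mate == 1L) list(OT = fwd, OB = rev) else
      list(OT = rev, OB = fwd)
    hit_ot <- scan_read(encode_mask(cand$OT), frames$OT, max_mismatch)
    hit_ob <- scan_read(encode_mask(cand$OB), frames$OB, max_mismatch)
    mm <- c(hit_ot[2], hit_ob[2]); mm[mm < 0] <- NA
    if (all(is.na(mm))) { unmapped <- unmapped + 1L; next }
    pick <- which(mm == min(mm, na.rm = TRUE))
    if (length(pick) > 1L) { unmapped <- unmapped + 1L; next }  # frame tie
    hit <- if (pick == 1L) hit_ot else hit_ob
    if (hit[3] > 1L) { unmapped <- unmapped + 1L; next }        # placement tie
    strand <- c("OT", "OB")[pick]
    seq_top <- cand[[strand]]
    res[[i]] <- data.frame(
      id = reads$id[i], mate = mate, individual = ind[i], strand = strand,
      start = hit[1] + 1L, end = hit[1] + nchar(seq_top),
      mismatches = hit[2], seq = seq_top, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(id = character(), mate = integer(),
                      individual = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), seq = character())
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

# Long-format per-base observations from alignments, with mate-overlap
# deduplication (each reference position counted once per fragment, mate 1
# wins). Returns a list of parallel vectors.
alignment_observations <- function(alignments) {
  if (!nrow(alignments))
    return(list(pos = integer(), base = character(), ind = character(),
                strand = character()))
  nvec <- nchar(alignments$seq)
  pos <- sequence(nvec) + rep(alignments$start - 1L, nvec)
  base <- unlist(strsplit(alignments$seq, "", fixed = TRUE), use.names = FALSE)
  ind <- rep(alignments$individual, nvec)
  strand <- rep(alignments$strand, nvec)
  frag <- rep(alignments$id, nvec)
  mate <- rep(alignments$mate, nvec)
  m1 <- alignments[alignments$mate == 1L, , drop = FALSE]
  if (nrow(m1)) {
    j <- match(frag, m1$id)
    drop <- mate == 2L & !is.na(j) &
      pos >= m1$start[j] & pos <= m1$end[j]
    if (any(drop)) {
      pos <- pos[!drop]; base <- base[!drop]; ind <- ind[!drop]
      strand <- strand[!drop]
    }
  }
  list(pos = pos, base = base, ind = ind, strand = strand)
}

count_votes <- function(obs, sel, positions, meth_base, unmeth_base,
                        individuals) {
  site <- match(obs$pos, positions)
  use <- sel & !is.na(site)
  f_site <- factor(site[use], levels = seq_along(positions))
  f_ind <- factor(obs$ind[use], levels = individuals)
  b <- obs$base[use]
  list(meth = unclass(table(f_site[b == meth_base], f_ind[b == meth_base])),
       unmeth = unclass(table(f_site[b == unmeth_base],
                              f_ind[b == unmeth_base])))
}

#' Extract per-CpG methylation and conversion statistics
#'
#' Tallies methylation calls at every catalogued CpG site: on original-top
#' fragments the C of the dinucleotide votes (C = methylated, T =
#' unmethylated), on original-bottom fragments the G votes (G = methylated,
#' A = unmethylated); any other base is ignored. Cytosines outside CpG context
#' accumulate CHH and CHG counts, and since non-CpG methylation is essentially
#' absent from the assayed tissue, apparent non-CpG methylation estimates
#' bisulfite conversion failure: `conversion = 1 - mean non-CpG methylation`.
#' Overlapping mate bases are counted once per fragment.
#'
#' @param alignments Alignment data frame from [align_bisulfite()].
#' @param locus A `locus_ref`; supplies the CpG catalogue, SNP positions and
#'   sequence context.
#' @param individuals Optional character vector fixing the individual order.
#' @return A list with `meth`: a `meth_matrix` (fields `meth`, `unmeth`,
#'   `fraction` as sites-by-individuals matrices, `sites`, `individuals`), and
#'   `conversion`: list with overall `chh_rate`, `chg_rate`,
#'   `conversion_estimate` and a `per_individual` data frame.
#' @export
extract_methylation <- function(alignments, locus, individuals = NULL) {
  stopifnot(inherits(locus, "locus_ref"))
  if (is.null(individuals))
    individuals <- sort(unique(alignments$individual))
  if (!length(individuals)) individuals <- NA_character_
  obs <- alignment_observations(alignments)
  cpg <- locus$cpg
  c_pos <- cpg$c_position
  g_pos <- c_pos + 1L
  chars <- seq_chars(locus$sequence)
  len <- locus$length
  snp_pos <- locus$snps$pos
  excl <- unique(c(c_pos, g_pos, snp_pos))
  # non-CpG cytosines on the top strand; context is the two downstream bases,
  # skipped when a SNP makes the context ambiguous
  top_c <- setdiff(which(chars == "C"), excl)
  top_c <- top_c[top_c <= len - 2L & !(top_c + 1L) %in% snp_pos &
                   !(top_c + 2L) %in% snp_pos]
  top_ctx <- ifelse(chars[top_c + 2L] == "G", "CHG", "CHH")
  # non-CpG cytosines on the bottom strand sit at top-strand Gs; their
  # downstream context runs towards lower top coordinates
  bot_c <- setdiff(which(chars == "G"), excl)
  bot_c <- bot_c[bot_c >= 3L & !(bot_c - 1L) %in% snp_pos &
                   !(bot_c - 2L) %in% snp_pos]
  bot_ctx <- ifelse(chars[bot_c - 2L] == "C", "CHG", "CHH")

  is_ot <- obs$strand == "OT"
  v_ot <- count_votes(obs, is_ot, c_pos, "C", "T", individuals)
  v_ob <- count_votes(obs, !is_ot, g_pos, "G", "A", individuals)
  meth <- v_ot$meth + v_ob$meth
  unmeth <- v_ot$unmeth + v_ob$unmeth
  cov <- meth + unmeth
  fraction <- ifelse(cov > 0, meth / cov, NA_real_)
  dimnames(meth) <- dimnames(unmeth) <- dimnames(fraction) <-
    list(site = as.character(c_pos), individual = individuals)

  nc_ot <- count_votes(obs, is_ot, top_c, "C", "T", individuals)
  nc_ob <- count_votes(obs, !is_ot, bot_c, "G", "A", individuals)
  ctx_rate <- function(ctx_label) {
    m <- sum(nc_ot$meth[top_ctx == ctx_label, , drop = FALSE]) +
      sum(nc_ob$meth[bot_ctx == ctx_label, , drop = FALSE])
    u <- sum(nc_ot$unmeth[top_ctx == ctx_label, , drop = FALSE]) +
      sum(nc_ob$unmeth[bot_ctx == ctx_label, , drop = FALSE])
    if (m + u > 0) m / (m + u) else NA_real_
  }
  per_ind_m <- colSums(nc_ot$meth) + colSums(nc_ob$meth)
  per_ind_u <- colSums(nc_ot$unmeth) + colSums(nc_ob$unmeth)
  per_ind <- data.frame(
    individual = individuals,
    non_cpg_obs = per_ind_m + per_ind_u,
    non_cpg_meth = ifelse(per_ind_m + per_ind_u > 0,
                          per_ind_m / (per_ind_m + per_ind_u), NA_real_))
  per_ind$conversion <- 1 - per_ind$non_cpg_meth
  tot_m <- sum(per_ind_m); tot_u <- sum(per_ind_u)
  conversion <- list(
    chh_rate = ctx_rate("CHH"), chg_rate = ctx_rate("CHG"),
    non_cpg_observations = tot_m + tot_u,
    conversion_estimate = if (tot_m + tot_u > 0)
      1 - tot_m / (tot_m + tot_u) else NA_real_,
    per_individual = per_ind)

  mm <- structure(list(meth = meth, unmeth = unmeth, fraction = fraction,
                       sites = cpg, individuals = individuals),
                  class = "meth_matrix")
  list(meth = mm, conversion = conversion)
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d CpG sites x %d individuals; mean fraction %.3f\n",
              nrow(x$fraction), ncol(x$fraction),
              mean(x$fraction, na.rm = TRUE)))
  invisible(x)
}

#' Call genotypes at polymorphic CpGs
#'
#' Genotype at a polyCpG is the number of CpG-bearing alleles an individual
#' carries (0, 1 or 2). Only the conversion-safe strand is used: when the SNP
#' sits at the C of the dinucleotide, original-bottom fragments are read (the
#' complementary G is untouched by C-to-T conversion), and when it sits at the
#' G, original-top fragments are read. The CpG-allele read fraction `f` maps
#' to genotype 2 when `f > 1 - het_band`, 0 when `f < het_band`, 1 when
#' `|f - 0.5| <= het_halfwidth`, and `NA` (unknown) otherwise or when coverage
#' is below `min_cov`.
#'
#' @param alignments Alignment data frame from [align_bisulfite()].
#' @param locus A `locus_ref`.
#' @param min_cov Minimum informative coverage (default 10).
#' @param het_band Homozygote band width (default 0.10).
#' @param het_halfwidth Half-width of the heterozygote band around 0.5
#'   (default 0.15).
#' @param individuals Optional character vector fixing individual order.
#' @return Data frame `individual`, `c_position`, `coverage`, `cpg_reads`,
#'   `cpg_fraction`, `genotype`.
#' @export
call_genotypes <- function(alignments, locus, min_cov = 10L, het_band = 0.10,
                           het_halfwidth = 0.15, individuals = NULL) {
  stopifnot(inherits(locus, "locus_ref"))
  if (is.null(individuals))
    individuals <- sort(unique(alignments$individual))
  poly <- locus$cpg[locus$cpg$status == "polymorphic", , drop = FALSE]
  obs <- alignment_observations(alignments)
  out <- lapply(seq_len(nrow(poly)), function(k) {
    sp <- poly$snp_position[k]; cp <- poly$c_position[k]
    at_c <- !is.na(sp) && sp == cp
    use_strand <- if (at_c) "OB" else "OT"
    vote_pos <- if (at_c) cp else cp + 1L
    cpg_base <- if (at_c) "C" else "G"
    sel <- obs$strand == use_strand & obs$pos == vote_pos
    f_ind <- factor(obs$ind[sel], levels = individuals)
    covg <- as.integer(table(f_ind))
    cpg_n <- as.integer(table(f_ind[obs$base[sel] == cpg_base]))
    f <- ifelse(covg > 0, cpg_n / covg, NA_real_)
    geno <- rep(NA_integer_, length(covg))
    geno[!is.na(f) & f > 1 - het_band] <- 2L
    geno[!is.na(f) & f < het_band] <- 0L
    geno[!is.na(f) & abs(f - 0.5) <= het_halfwidth] <- 1L
    geno[covg < min_cov] <- NA_integer_
    data.frame(individual = individuals, c_position = cp, coverage = covg,
               cpg_reads = cpg_n, cpg_fraction = f, genotype = geno,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Allele-normalized polyCpG methylation measures
#'
#' For each (individual, polymorphic CpG) pair computes the three measures
#' compared in the association analysis: `total_meth`, the fraction of all
#' covering reads that carry a methylated CpG regardless of genotype;
#' `genotype`, the number of CpG-bearing alleles (0/1/2); and `meth_per_cpg`,
#' methylation normalized per CpG allele -- equal to `total_meth` for CpG
#' homozygotes, twice `total_meth` for heterozygotes (clipped at 1 with a
#' warning, since sampling noise can push it above), and `NA` when no CpG
#' allele is present or the genotype is unknown.
#'
#' @param meth A `meth_matrix` from [extract_methylation()].
#' @param genotypes Genotype data frame from [call_genotypes()] (or columns
#'   `individual`, `c_position`, `genotype`).
#' @return Data frame `individual`, `c_position`, `total_meth`, `genotype`,
#'   `meth_per_cpg`, `clipped`.
#' @export
polycpg_measures <- function(meth, genotypes) {
  stopifnot(inherits(meth, "meth_matrix"))
  key <- paste(genotypes$individual, genotypes$c_position)
  poly <- meth$sites[meth$sites$status == "polymorphic", , drop = FALSE]
  rows <- lapply(poly$c_position, function(cp) {
    tm <- meth$fraction[as.character(cp), ]
    g <- genotypes$genotype[match(paste(meth$individuals, cp), key)]
    mpc <- rep(NA_real_, length(tm))
    mpc[!is.na(g) & g == 2L] <- tm[!is.na(g) & g == 2L]
    mpc[!is.na(g) & g == 1L] <- 2 * tm[!is.na(g) & g == 1L]
    clipped <- !is.na(mpc) & mpc > 1
    mpc[clipped] <- 1
    data.frame(individual = meth$individuals, c_position = cp,
               total_meth = unname(tm), genotype = g,
               meth_per_cpg = unname(mpc), clipped = unname(clipped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$clipped))
    warning(sum(out$clipped),
            " heterozygote per-CpG methylation value(s) clipped at 1")
  rownames(out) <- NULL
  out
}
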