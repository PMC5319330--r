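#' Build a validated locus reference
#'
#' Reads a single-record FASTA, a VCF-like SNP table and a set of locus
#' annotations, derives the catalogue of fixed and polymorphic CpG sites, and
#' returns the object every other stage of the pipeline works from. A
#' polymorphic CpG (polyCpG) is a SNP at the C or the G of a CpG dinucleotide,
#' so that one allele carries a methylatable CpG and the other does not.
#'
#' @param fasta Path to a single-record FASTA file, or a plain character
#'   sequence over A/C/G/T (convenient for simulated loci).
#' @param snp_table Path to a tab-separated table with columns
#'   `CHROM`, `POS` (1-based), `REF`, `ALT` (comma-separated single bases), or
#'   a data frame with columns `pos`, `ref`, `alt` (`alt` a character vector of
#'   comma-separated alternates). `NULL` for a locus without known variants.
#' @param annotations Named list (or path to a YAML file) with entries `tss`
#'   (single 1-based position) and optionally `exon1`, `intron`, `enhancer`
#'   (1-based inclusive intervals as length-2 vectors).
#' @param carrier_counts Optional data frame (`pos`, `carriers`) giving, per
#'   SNP, the number of cohort individuals carrying the minor allele. When
#'   supplied, SNPs with fewer than `min_carriers` carriers are dropped from
#'   the catalogue; variants seen in a single individual are too rare to be
#'   informative for association.
#' @param min_carriers Minimum carrier count applied when `carrier_counts` is
#'   given (default 2).
#' @param id Sequence identifier; defaults to the FASTA header.
#'
#' @return An object of class `locus_ref`: a list with elements `id`,
#'   `sequence`, `length`, `snps` (data frame `pos`, `ref`, `alt`), `cpg`
#'   (the CpG catalogue, see [catalogue_cpgs()]), `tss` and `annotations`.
#' @export
load_locus <- function(fasta, snp_table = NULL, annotations = NULL,
                       carrier_counts = NULL, min_carriers = 2L, id = NULL) {
  if (file.exists(fasta)) {
    rec <- Biostrings::readDNAStringSet(fasta)
    if (length(rec) != 1L)
      stop("FASTA must contain exactly one record, found ", length(rec))
    sequence <- toupper(as.character(rec[[1]]))
    if (is.null(id)) id <- names(rec)[1]
  } else {
    sequence <- toupper(fasta)
    if (is.null(id)) id <- "locus"
  }
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence must contain only A/C/G/T")
  len <- nchar(sequence)

  snps <- if (is.null(snp_table)) {
    data.frame(pos = integer(), ref = character(), alt = character())
  } else if (is.character(snp_table)) {
    read_snp_table(snp_table)
  } else {
    normalize_snp_frame(snp_table)
  }
  if (anyDuplicated(snps$pos))
    stop("duplicate SNP positions: ",
         paste(snps$pos[duplicated(snps$pos)], collapse = ", "))
  if (nrow(snps)) {
    if (any(snps$pos < 1 | snps$pos > len))
      stop("SNP positions outside [1, ", len, "]")
    ref_at <- substring(sequence, snps$pos, snps$pos)
    bad <- which(ref_at != snps$ref)
    if (length(bad))
      stop(sprintf("SNP REF mismatch at position %d: table says %s, sequence has %s",
                   snps$pos[bad[1]], snps$ref[bad[1]], ref_at[bad[1]]))
    alt_list <- strsplit(snps$alt, ",", fixed = TRUE)
    if (any(mapply(function(r, a) r %in% a, snps$ref, alt_list)))
      stop("ALT alleles must be disjoint from REF")
    if (any(vapply(alt_list, function(a) any(!a %in% c("A", "C", "G", "T")) ||
                     length(a) < 1 || length(a) > 2, logical(1))))
      stop("ALT must list 1-2 single bases per SNP")
  }
  if (!is.null(carrier_counts) && nrow(snps)) {
    keep <- rep(TRUE, nrow(snps))
    m <- match(snps$pos, carrier_counts$pos)
    keep[!is.na(m)] <- carrier_counts$carriers[m[!is.na(m)]] >= min_carriers
    snps <- snps[keep, , drop = FALSE]
  }
  snps <- snps[order(snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  ann <- parse_annotations(annotations, len)

  structure(list(
    id = id, sequence = sequence, length = len, snps = snps,
    cpg = catalogue_cpgs(sequence, snps),
    tss = ann$tss, annotations = ann$intervals
  ), class = "locus_ref")
}

read_snp_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("pos", "ref", "alt") %in% names(tab)))
    stop("SNP table needs columns CHROM, POS, REF, ALT: ", path)
  normalize_snp_frame(tab)
}

normalize_snp_frame <- function(tab) {
  data.frame(pos = as.integer(tab$pos),
             ref = toupper(as.character(tab$ref)),
             alt = toupper(gsub(" ", "", as.character(tab$alt))),
             stringsAsFactors = FALSE)
}

parse_annotations <- function(annotations, len) {
  if (is.null(annotations)) return(list(tss = NA_integer_, intervals = list()))
  if (is.character(annotations)) annotations <- yaml::read_yaml(annotations)
  tss <- annotations$tss %||% NA_integer_
  if (!is.na(tss) && (tss < 1 || tss > len))
    stop("tss outside [1, ", len, "]")
  nm <- setdiff(names(annotations), "tss")
  intervals <- lapply(nm, function(k) check_interval(unlist(annotations[[k]]), len, k))
  names(intervals) <- nm
  list(tss = as.integer(tss), intervals = intervals)
}

#' Derive the CpG catalogue of a locus
#'
#' Scans every dinucleotide of the reference, taking SNP alleles into account,
#' and reports all positions where some allele combination yields a CpG. Sites
#' with no overlapping SNP are `fixed`; sites where a SNP toggles the CpG are
#' `polymorphic` and carry a variant class named after the non-CpG
#' dinucleotide (e.g. `CpG/TpG` for a C/T SNP at the C).
#'
#' @param sequence Reference sequence (character scalar, A/C/G/T).
#' @param snps Data frame `pos`, `ref`, `alt` as in [load_locus()].
#' @return Data frame with columns `c_position` (1-based position of the C),
#'   `status` (`fixed`/`polymorphic`), `variant_class` (`NA` for fixed sites;
#'   one of the six dinucleotide classes or `multi-allelic`), and
#'   `snp_position`.
#' @export
catalogue_cpgs <- function(sequence, snps = NULL) {
  chars <- seq_chars(sequence)
  len <- length(chars)
  if (is.null(snps)) snps <- data.frame(pos = integer(), ref = character(),
                                        alt = character())
  alt_list <- strsplit(snps$alt, ",", fixed = TRUE)
  allowed <- function(i) {
    j <- match(i, snps$pos)
    if (is.na(j)) chars[i] else c(snps$ref[j], alt_list[[j]])
  }
  # candidate positions: reference C, or any position a SNP could turn into
  # the C or G of a CpG
  cand <- sort(unique(c(which(chars[-len] == "C"),
                        snps$pos[snps$pos < len], snps$pos - 1L)))
  cand <- cand[cand >= 1 & cand < len]
  out <- lapply(cand, function(i) {
    set_c <- allowed(i); set_g <- allowed(i + 1L)
    if (!("C" %in% set_c) || !("G" %in% set_g)) return(NULL)
    snp_c <- i %in% snps$pos
    snp_g <- (i + 1L) %in% snps$pos
    if (!snp_c && !snp_g) {
      return(data.frame(c_position = i, status = "fixed",
                        variant_class = NA_character_,
                        snp_position = NA_integer_))
    }
    if (snp_c && snp_g) {
      # SNPs at both bases of one dinucleotide: outside the six-class spectrum
      return(data.frame(c_position = i, status = "polymorphic",
                        variant_class = "multi-allelic",
                        snp_position = i))
    }
    sp <- if (snp_c) i else i + 1L
    j <- match(sp, snps$pos)
    alts <- alt_list[[j]]
    if (length(alts) > 1L) {
      cls <- "multi-allelic"
    } else {
      ref_d <- chars_seq(chars[c(i, i + 1L)])
      alt_ch <- chars[c(i, i + 1L)]
      alt_ch[sp - i + 1L] <- alts
      cls <- classify_polycpg_variant(ref_d, chars_seq(alt_ch))
    }
    data.frame(c_position = i, status = "polymorphic",
               variant_class = cls, snp_position = sp)
  })
  out <- do.call(rbind, c(out, list(
    data.frame(c_position = integer(), status = character(),
               variant_class = character(), snp_position = integer()))))
  out <- out[order(out$c_position), , drop = FALSE]
  # a SNP serving as the G of one CpG and the C of the next is catalogued
  # against both sites; note it, since the ambiguity reference must then pick
  # one CpG allele for that base
  dup <- stats::na.omit(out$snp_position[duplicated(out$snp_position)])
  if (length(dup))
    message("SNP(s) at ", paste(unique(dup), collapse = ", "),
            " overlap two CpG sites; both sites catalogued as polymorphic")
  rownames(out) <- NULL
  out
}

#' Classify a polymorphic CpG variant
#'
#' Given the two dinucleotide alleles of a bi-allelic polyCpG (exactly one of
#' which is `CG`), returns the class named by the non-CpG dinucleotide with
#' orientation preserved: a difference at the second base gives `CpG/Cp*`, at
#' the first base `CpG/*pG`.
#'
#' @param ref_dinucleotide,alt_dinucleotide Two-base character scalars.
#' @return One of `"CpG/CpA"`, `"CpG/CpC"`, `"CpG/CpT"`, `"CpG/ApG"`,
#'   `"CpG/GpG"`, `"CpG/TpG"`.
#' @export
classify_polycpg_variant <- function(ref_dinucleotide, alt_dinucleotide) {
  a <- toupper(ref_dinucleotide); b <- toupper(alt_dinucleotide)
  stopifnot(nchar(a) == 2L, nchar(b) == 2L)
  is_cg <- c(a, b) == "CG"
  if (sum(is_cg) != 1L)
    stop("exactly one of the two dinucleotides must be CG (got ",
         a, ", ", b, ")")
  d <- if (is_cg[1]) b else a
  diff_at <- which(seq_chars(a) != seq_chars(b))
  if (length(diff_at) != 1L)
    stop("dinucleotides must differ at exactly one base (got ", a, ", ", b, ")")
  paste0("CpG/", substr(d, 1, 1), "p", substr(d, 2, 2))
}

#' Build the bisulfite-aware ambiguity reference
#'
#' Returns a copy of the reference in which every SNP that is part of a CpG
#' dinucleotide is written as its CpG allele (C at the C, G at the G), while
#' every other SNP is replaced by the IUPAC code covering its ref and alt
#' alleles. Aligning converted reads against this reference measures
#' methylation at both fixed and polymorphic CpGs without allelic bias.
#'
#' @param locus A `locus_ref` from [load_locus()].
#' @return Character scalar over the IUPAC alphabet, same length as the
#'   reference.
#' @export
build_bisulfite_reference <- function(locus) {
  stopifnot(inherits(locus, "locus_ref"))
  chars <- seq_chars(locus$sequence)
  snps <- locus$snps
  if (!nrow(snps)) return(locus$sequence)
  cpg <- locus$cpg
  poly <- cpg[cpg$status == "polymorphic", , drop = FALSE]
  alt_list <- strsplit(snps$alt, ",", fixed = TRUE)
  for (j in seq_len(nrow(snps))) {
    p <- snps$pos[j]
    as_c <- any(poly$snp_position == p & poly$c_position == p, na.rm = TRUE)
    as_g <- any(poly$snp_position == p & poly$c_position == p - 1L, na.rm = TRUE)
    if (as_c && as_g) {
      # one base cannot be both the C of one CpG and the G of the previous;
      # keep the C allele of the downstream site
      warning("SNP at ", p, " is the G of one CpG and the C of the next; ",
              "ambiguity reference keeps the C allele")
      chars[p] <- "C"
    } else if (as_c) {
      chars[p] <- "C"
    } else if (as_g) {
      chars[p] <- "G"
    } else {
      chars[p] <- iupac_code_for(c(snps$ref[j], alt_list[[j]]))
    }
  }
  chars_seq(chars)
}

#' @export
print.locus_ref <- function(x, ...) {
  cat(sprintf("<locus_ref> %s: %d bp, %d SNPs, %d CpG sites (%d fixed, %d polymorphic)\n",
              x$id, x$length, nrow(x$snps), nrow(x$cpg),
              sum(x$cpg$status == "fixed"), sum(x$cpg$status == "polymorphic")))
  if (!is.na(x$tss)) cat("  TSS at", x$tss, "\n")
  for (nm in names(x$annotations))
    cat(sprintf("  %s: [%d, %d]\n", nm, x$annotations[[nm]][1],
                x$annotations[[nm]][2]))
  invisible(x)
}
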