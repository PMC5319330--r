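make_read <- function(id, mate, bases, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(bases))
  data.frame(id = id, mate = mate, bases = bases, quals = quals,
             stringsAsFactors = FALSE)
}

test_that("trimming applies quality, adapter, length and pairing rules", {
  empty <- make_read(character(), integer(), character())
  expect_equal(nrow(trim_reads(empty)), 0L)

  # long high-quality read is shortened to 130 bp
  r <- rbind(make_read("f1", 1L, strrep("ACGT", 70), strrep("D", 280)),
             make_read("f1", 2L, strrep("ACGT", 70), strrep("D", 280)))
  tr <- trim_reads(r, adapter = NULL)
  expect_true(all(nchar(tr$bases) == 130L))
  expect_true(all(nchar(tr$quals) == 130L))

  # low-quality 3' tail removed; if the rest is too short the pair is dropped
  r <- rbind(make_read("f1", 1L, strrep("A", 30),
                       paste0(strrep("I", 10), strrep("#", 20))),
             make_read("f1", 2L, strrep("C", 30)))
  tr <- trim_reads(r, adapter = NULL)
  expect_equal(nrow(tr), 0L)  # 10 bp survivor < 16 bp drags its mate along
  tr_keep <- trim_reads(r, adapter = NULL, drop_orphans = FALSE)
  expect_equal(tr_keep$mate, 2L)

  # adapter removed by terminal overlap match
  payload <- strrep("ACGT", 10)
  r <- rbind(make_read("f1", 1L, paste0(payload, "AGATCGGAAGAGC")),
             make_read("f1", 2L, payload))
  tr <- trim_reads(r)
  expect_equal(tr$bases[tr$mate == 1L], payload)

  # duplicate mate records are a pairing error
  r <- rbind(make_read("f1", 1L, "ACGTACGTACGTACGTACGT"),
             make_read("f1", 1L, "ACGTACGTACGTACGTACGT"))
  expect_error(trim_reads(r), "mate counts")
})

test_that("bisulfite alignment handles conversion frames and ambiguity codes", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  sub <- substr(ref, 101, 180)

  # unconverted read maps at its true offset in the C->T frame
  al <- align_bisulfite(make_read("r1", 1L, sub), ref)
  expect_equal(al$start, 101L)
  expect_equal(al$strand, "OT")
  expect_equal(al$mismatches, 0L)

  # fully converted read (all C->T) still maps with zero mismatches
  conv <- chartr("C", "T", sub)
  al <- align_bisulfite(make_read("r1", 1L, conv), ref)
  expect_equal(al$start, 101L)
  expect_equal(al$mismatches, 0L)

  # bottom-strand read: G->A conversion seen in top orientation, as mate 1
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("G", "A", sub))))
  al <- align_bisulfite(make_read("r1", 1L, rc), ref)
  expect_equal(al$start, 101L)
  expect_equal(al$strand, "OB")

  # IUPAC codes in the reference match both alleles
  amb <- paste0(substr(ref, 1, 120), "W", substr(ref, 122, 600))
  readA <- paste0(substr(sub, 1, 20), "A", substr(sub, 22, 80))
  readT <- paste0(substr(sub, 1, 20), "T", substr(sub, 22, 80))
  for (rd in c(readA, readT)) {
    al <- align_bisulfite(make_read("r1", 1L, chartr("C", "T", rd)), amb)
    expect_equal(al$start, 101L)
    expect_equal(al$mismatches, 0L)
  }

  # ambiguous placement leaves the read unmapped
  rep_ref <- strrep("ACGTACGTAA", 20)
  al <- align_bisulfite(make_read("r1", 1L, substr(rep_ref, 1, 30)), rep_ref)
  expect_equal(nrow(al), 0L)
  expect_gt(attr(al, "unmapped"), 0L)
})

test_that("alignment agrees with Biostrings matchPattern as cross-check", {
  set.seed(8)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  # independent route: matchPattern of the C->T-converted read against the
  # C->Y-converted reference with ambiguity-aware subject matching
  ref_ot <- chartr("C", "Y", ref)
  subj <- Biostrings::DNAString(ref_ot)
  for (i in 1:20) {
    o <- sample(1800, 1)
    rd <- chartr("C", "T", substr(ref, o, o + 99))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(rd), subj,
                                     max.mismatch = 0,
                                     fixed = c(pattern = TRUE, subject = FALSE))
    al <- align_bisulfite(make_read("r", 1L, rd), ref, max_mismatch = 0)
    if (length(hits) == 1L) {
      expect_equal(al$start, Biostrings::start(hits)[1])
    } else {
      expect_equal(nrow(al), 0L)
    }
  }
})

constructed_alignments <- function() {
  # reference with one CpG at 3-4 and non-CpG cytosines elsewhere
  ref <- "AACGTCATCAAT"
  loc <- load_locus(ref)
  # 3 methylated (C at 3), 7 unmethylated (T at 3) OT reads, full length
  reads <- c(rep("AACGTTATTAAT", 3), rep("AATGTTATTAAT", 7))
  al <- data.frame(id = paste0("f", 1:10), mate = 1L, individual = "i1",
                   strand = "OT", start = 1L, end = 12L, mismatches = 0L,
                   seq = reads, stringsAsFactors = FALSE)
  list(locus = loc, alignments = al)
}

test_that("methylation extraction computes fractions and conversion rates", {
  w <- constructed_alignments()
  out <- extract_methylation(w$alignments, w$locus)
  expect_equal(unname(out$meth$fraction[1, 1]), 0.30)
  expect_equal(unname(out$meth$meth[1, 1] + out$meth$unmeth[1, 1]), 10)
  # all non-CpG cytosines read T: perfect conversion
  expect_equal(out$conversion$chh_rate, 0)
  expect_equal(out$conversion$conversion_estimate, 1)

  # zero coverage is NA, not zero
  al2 <- w$alignments[0, ]
  out2 <- extract_methylation(al2, w$locus, individuals = "i1")
  expect_true(all(is.na(out2$meth$fraction)))
})

test_that("overlapping mate bases are counted once per fragment", {
  ref <- "AACGTCATCAAT"
  loc <- load_locus(ref)
  al <- data.frame(id = c("f1", "f1"), mate = c(1L, 2L), individual = "i1",
                   strand = "OT", start = c(1L, 1L), end = c(12L, 12L),
                   mismatches = 0L, seq = rep("AACGTTATTAAT", 2),
                   stringsAsFactors = FALSE)
  out <- extract_methylation(al, loc)
  expect_equal(unname(out$meth$meth[1, 1]), 1L)  # not 2
})

test_that("strand mirroring leaves fraction estimates unchanged", {
  ref <- "AACGTCATCAAT"
  loc <- load_locus(ref)
  ot <- data.frame(id = paste0("f", 1:4), mate = 1L, individual = "i1",
                   strand = "OT", start = 1L, end = 12L, mismatches = 0L,
                   seq = c("AACGTTATTAAT", "AACGTTATTAAT",
                           "AATGTTATTAAT", "AATGTTATTAAT"),
                   stringsAsFactors = FALSE)
  # same molecules observed from the bottom strand: G (meth) / A (unmeth)
  ob <- data.frame(id = paste0("g", 1:4), mate = 1L, individual = "i1",
                   strand = "OB", start = 1L, end = 12L, mismatches = 0L,
                   seq = c("AACGTCATCAAT", "AACGTCATCAAT",
                           "AACATCATCAAT", "AACATCATCAAT"),
                   stringsAsFactors = FALSE)
  f_ot <- extract_methylation(ot, loc)$meth$fraction[1, 1]
  f_both <- extract_methylation(rbind(ot, ob), loc)$meth$fraction[1, 1]
  expect_equal(unname(f_ot), 0.5)
  expect_equal(unname(f_both), 0.5)
})

test_that("genotype calls follow the banding rules", {
  # polyCpG with SNP at the C (C/T): genotyping uses OB reads at the C
  loc <- load_locus("AACGTCATCAAT", data.frame(pos = 3L, ref = "C", alt = "T"))
  mk <- function(n_c, n_t, ind = "i1") {
    seqs <- c(rep("AACGTCATCAAT", n_c), rep("AATGTCATCAAT", n_t))
    data.frame(id = paste0("f", seq_along(seqs)), mate = 1L, individual = ind,
               strand = "OB", start = 1L, end = 12L, mismatches = 0L,
               seq = seqs, stringsAsFactors = FALSE)
  }
  gt <- call_genotypes(mk(40, 0), loc)
  expect_equal(gt$genotype, 2L)
  gt <- call_genotypes(mk(21, 19), loc)  # f = 0.525, inside the het band
  expect_equal(gt$genotype, 1L)
  gt <- call_genotypes(mk(0, 40), loc)
  expect_equal(gt$genotype, 0L)
  gt <- call_genotypes(mk(3, 2), loc)    # below min_cov
  expect_true(is.na(gt$genotype))
  gt <- call_genotypes(mk(28, 12), loc)  # f = 0.7: between bands, unknown
  expect_true(is.na(gt$genotype))
})

test_that("per-CpG measures follow the heterozygote doubling rule", {
  w <- constructed_alignments()
  meth <- extract_methylation(w$alignments, w$locus)$meth
  # make the catalogued site polymorphic for the measure computation
  meth$sites$status <- "polymorphic"
  gt <- data.frame(individual = "i1", c_position = 3L, genotype = 1L)
  m <- polycpg_measures(meth, gt)
  expect_equal(m$total_meth, 0.30)
  expect_equal(m$meth_per_cpg, 0.60)

  gt$genotype <- 2L
  expect_equal(polycpg_measures(meth, gt)$meth_per_cpg, 0.30)
  gt$genotype <- 0L
  expect_true(is.na(polycpg_measures(meth, gt)$meth_per_cpg))
  gt$genotype <- NA_integer_
  expect_true(is.na(polycpg_measures(meth, gt)$meth_per_cpg))

  # clipping at 1 for noisy heterozygotes
  meth$fraction[1, 1] <- 0.6
  gt$genotype <- 1L
  expect_warning(m <- polycpg_measures(meth, gt), "clipped")
  expect_equal(m$meth_per_cpg, 1)
})
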