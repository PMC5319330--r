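# Shared sequence helpers. Sequences are plain upper-case character scalars
# over A/C/G/T (IUPAC codes where stated); coordinates are 1-based inclusive
# in every user-facing structure.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base -> bit encoding used by the alignment kernel (A=1, C=2, G=4, T=8)
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  hit <- vapply(names(IUPAC_SETS), function(k) {
    identical(sort(IUPAC_SETS[[k]]), bases)
  }, logical(1))
  names(IUPAC_SETS)[hit][1]
}

iupac_mask <- function(code) {
  set <- IUPAC_SETS[[toupper(code)]]
  if (is.null(set)) return(0L)  # N handled above; anything else matches nothing
  sum(BASE_BITS[set])
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

chars_seq <- function(chars) paste(chars, collapse = "")

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

subseq_chr <- function(sequence, start, end) substr(sequence, start, end)

phred_to_int <- function(quals) utf8ToInt(quals) - 33L

int_to_phred <- function(q) intToUtf8(q + 33L)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

check_interval <- function(x, len, what) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      x[1] < 1 || x[2] > len) {
    stop(sprintf("annotation '%s' must be a 1-based interval within [1, %d]",
                 what, len), call. = FALSE)
  }
  as.integer(x)
}
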