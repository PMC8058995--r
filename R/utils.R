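#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist coef cor cutree hclust lm median model.matrix
#'   p.adjust pf phyper rgamma rmultinom rnorm rpois sd setNames var
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised over plain character vectors; `N` is passed through.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param len sequence length (single value).
#' @return character vector of `n` uniform-random DNA sequences.
#' @export
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, "")
}

#' Number of mismatching positions between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Phred+33 helpers ------------------------------------------------------

phred_to_string <- function(q) {
  vapply(q, function(qq) intToUtf8(pmin(pmax(qq, 0), 41) + 33L), "")
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

# substring presence of `needle` in any of `haystacks` (character vector),
# fixed matching
any_substring <- function(needle, haystacks) {
  any(grepl(needle, haystacks, fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x surprise
sample1 <- function(v) v[sample.int(length(v), 1L)]

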