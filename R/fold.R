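# Interface to the ViennaRNA command-line tools. Folding is delegated to
# RNAfold; everything measured *on* the resulting structure (stem pairs,
# bulges, mature-region errors) is implemented in hairpin.R.

vienna_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

#' Fold sequences into minimum-free-energy secondary structures
#'
#' Batch interface to ViennaRNA's `RNAfold`. DNA input is folded as its RNA
#' transcript (RNAfold reads T as U).
#'
#' @param seqs character vector of nucleotide sequences.
#' @param ids optional sequence identifiers (default `seq1..seqN`).
#' @param temperature folding temperature in degrees Celsius (default 37).
#' @return a data.frame with columns `id`, `sequence`, `structure`
#'   (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_sequences <- function(seqs, ids = NULL, temperature = 37) {
  if (length(seqs) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      structure = character(), mfe = numeric()))
  }
  if (!vienna_available()) {
    stop("RNAfold not found on PATH; ViennaRNA is required for folding")
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", ids, "\n", seqs), fa)
  out <- system2("RNAfold", c("--noPS", "-T", format(temperature)),
                 stdin = fa, stdout = TRUE, stderr = FALSE)
  parse_rnafold_output(out)
}

parse_rnafold_output <- function(lines) {
  hdr <- grep("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- lines[hdr + 1L]
  res <- lines[hdr + 2L]
  m <- regmatches(res, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", res))
  mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  structure <- sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", res)
  data.frame(id = ids, sequence = seqs, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Free energy of a given structure (RNAeval)
#'
#' Recomputes the energy of a fixed secondary structure for a sequence,
#' independently of the fold search.
#'
#' @inheritParams fold_sequences
#' @param structures dot-bracket strings, one per sequence.
#' @return numeric vector of energies in kcal/mol.
#' @export
eval_structure_energy <- function(seqs, structures, temperature = 37) {
  stopifnot(length(seqs) == length(structures))
  if (length(seqs) == 0) return(numeric())
  inp <- tempfile(fileext = ".txt")
  on.exit(unlink(inp), add = TRUE)
  writeLines(as.vector(rbind(seqs, structures)), inp)
  out <- system2("RNAeval", c("-T", format(temperature)),
                 stdin = inp, stdout = TRUE, stderr = FALSE)
  res <- grep("[().]+\\s+\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
  m <- regmatches(res, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", res))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector `pt` with `pt[i]` = partner of position i, 0 if
#'   unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pt
}
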