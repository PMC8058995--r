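# Readers/writers for the pipeline's on-disk formats: FASTA/FASTQ via
# Biostrings, tab-separated truth/annotation/count tables via base R.

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a simulated library to FASTQ (Phred+33)
#' @param lib data.frame with `id`, `sequence`, `quality`.
#' @param path output file.
#' @export
write_fastq <- function(lib, path) {
  x <- Biostrings::DNAStringSet(lib$sequence)
  names(x) <- lib$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(lib$quality))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path input file.
#' @return data.frame `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a reference bundle's files to a directory
#'
#' FASTA for the transcriptome, precursors (with `family=` and `mature=`
#' attributes in the header), matures and contaminants; TSV for annotation,
#' profiles and truth tables.
#'
#' @param ref a `ReferenceBundle`.
#' @param dir output directory (created if missing).
#' @export
write_bundle <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ref$transcriptome, file.path(dir, "transcriptome.fa"))
  prec <- setNames(ref$precursors$sequence,
                   sprintf("%s family=%s mature=%d-%d", ref$precursors$id,
                           ref$precursors$family, ref$precursors$mature_start,
                           ref$precursors$mature_end))
  write_fasta(prec, file.path(dir, "precursors.fa"))
  write_fasta(setNames(ref$mature_catalogue$sequence,
                       ref$mature_catalogue$name),
              file.path(dir, "matures.fa"))
  write_fasta(setNames(ref$ncrna$sequence, ref$ncrna$id),
              file.path(dir, "ncrna.fa"))
  write_fasta(setNames(ref$repeats$sequence, ref$repeats$id),
              file.path(dir, "repeats.fa"))
  write_tsv(ref$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(ref$profiles, file.path(dir, "profiles.tsv"))
  for (nm in names(ref$truth)) {
    write_tsv(ref$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  invisible(dir)
}
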