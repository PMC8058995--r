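# Raw-read triage: adapter trimming, poly-N/quality/length filtering,
# ncRNA/repeat annotation, tag collapsing and Table-1-style library stats.
#
# Every read receives exactly one annotation class; class totals always sum
# to the raw read total (asserted in preprocess_libraries).

#' Filtering parameters for small-RNA read triage
#'
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len length gates for valid tags (nt).
#' @param max_N_fraction poly-N threshold: inserts with a higher N fraction
#'   are junk.
#' @param min_mean_quality minimum mean Phred score of the insert.
#' @param adapter_min_overlap minimum adapter-prefix overlap for trimming.
#' @return a `filter_params` list.
#' @export
filter_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                          min_len = 18, max_len = 25,
                          max_N_fraction = 0.10, min_mean_quality = 20,
                          adapter_min_overlap = 6) {
  stopifnot(min_len <= max_len, adapter_min_overlap >= 1,
            nchar(adapter) >= adapter_min_overlap)
  structure(list(adapter = adapter, min_len = min_len, max_len = max_len,
                 max_N_fraction = max_N_fraction,
                 min_mean_quality = min_mean_quality,
                 adapter_min_overlap = adapter_min_overlap),
            class = "filter_params")
}

# all strings within hamming distance 1 of x
one_mismatch_set <- function(x) {
  ch <- strsplit(x, "")[[1]]
  out <- x
  for (i in seq_along(ch)) {
    for (b in c("A", "C", "G", "T", "N")) {
      if (b != ch[i]) {
        y <- ch; y[i] <- b
        out <- c(out, paste(y, collapse = ""))
      }
    }
  }
  out
}

#' Trim the 3' adapter from reads
#'
#' The insert ends at the leftmost position where an adapter prefix of at
#' least `adapter_min_overlap` nt matches with at most one mismatch
#' (including partial adapter overlap at the read's 3' end). Reads whose
#' adapter starts at position 1 have no insert (`adapter_only`); reads with
#' no adapter match are kept untrimmed.
#'
#' @param seqs character vector of read sequences.
#' @param params a [filter_params()] object.
#' @return data.frame `insert`, `trim_pos` (NA if untrimmed), `status`
#'   (`trimmed` / `adapter_only` / `untrimmed`).
#' @export
trim_adapter <- function(seqs, params = filter_params()) {
  A <- nchar(params$adapter)
  n <- length(seqs)
  len <- nchar(seqs)
  trim_pos <- rep(NA_integer_, n)
  # pattern sets per overlap length (adapter prefix +- one mismatch)
  ovls <- params$adapter_min_overlap:A
  pats <- lapply(ovls, function(o) {
    one_mismatch_set(substr(params$adapter, 1, o))
  })
  names(pats) <- as.character(ovls)
  maxlen <- max(len, 0)
  for (s in seq_len(max(maxlen - params$adapter_min_overlap + 1, 0))) {
    open <- which(is.na(trim_pos) & len - s + 1 >= params$adapter_min_overlap)
    if (length(open) == 0) break
    o <- pmin(len[open] - s + 1L, A)
    sub <- substr(seqs[open], s, s + o - 1L)
    for (oo in unique(o)) {
      idx <- open[o == oo]
      hit <- sub[o == oo] %in% pats[[as.character(oo)]]
      trim_pos[idx[hit]] <- s
    }
  }
  status <- ifelse(is.na(trim_pos), "untrimmed",
                   ifelse(trim_pos == 1L, "adapter_only", "trimmed"))
  insert <- ifelse(is.na(trim_pos), seqs, substr(seqs, 1, trim_pos - 1L))
  data.frame(insert = insert, trim_pos = trim_pos, status = status,
             stringsAsFactors = FALSE)
}

mean_phred <- function(quals, k) {
  vapply(seq_along(quals), function(i) {
    if (k[i] <= 0) return(NA_real_)
    mean(utf8ToInt(substr(quals[i], 1, k[i])) - 33L)
  }, numeric(1))
}

#' Filter trimmed reads into annotation classes
#'
#' Applies, in order: adapter-only, poly-N junk (N fraction above
#' `max_N_fraction`), low mean quality, and the 18-25 nt length gates.
#' Surviving reads are `valid` candidates for ncRNA annotation.
#'
#' @param seqs raw read sequences.
#' @param quals Phred+33 quality strings (same length as `seqs`).
#' @param params a [filter_params()] object.
#' @return data.frame `insert`, `label` with one label per read.
#' @export
filter_reads <- function(seqs, quals, params = filter_params()) {
  tr <- trim_adapter(seqs, params)
  ins <- tr$insert
  k <- nchar(ins)
  n_frac <- ifelse(k > 0,
                   vapply(gregexpr("N", ins, fixed = TRUE), function(m) {
                     sum(m > 0)
                   }, numeric(1)) / pmax(k, 1), 0)
  mq <- mean_phred(quals, k)
  label <- rep("valid", length(seqs))
  label[k > params$max_len] <- "too_long"
  label[k < params$min_len] <- "too_short"
  label[!is.na(mq) & mq < params$min_mean_quality] <- "low_quality"
  label[n_frac > params$max_N_fraction] <- "junk"
  label[tr$status == "adapter_only"] <- "adapter_only"
  data.frame(insert = ins, label = label, stringsAsFactors = FALSE)
}

NCRNA_PRECEDENCE <- c("rRNA", "tRNA", "snoRNA", "snRNA", "other_ncRNA")

#' Annotate tags against ncRNA and repeat references
#'
#' A tag matching a reference as an exact substring on either strand gets
#' that reference's class, with precedence rRNA > tRNA > snoRNA > snRNA >
#' other ncRNA, then repeats; unmatched tags stay `valid`.
#'
#' @param tags character vector of tag sequences.
#' @param ncrna data.frame with `class` and `sequence` (classes among
#'   rRNA/tRNA/snoRNA/snRNA/other_ncRNA).
#' @param repeats data.frame with `sequence`, or NULL.
#' @return character vector of annotations, one per tag.
#' @export
annotate_ncrna <- function(tags, ncrna, repeats = NULL) {
  hay <- lapply(NCRNA_PRECEDENCE, function(cl) {
    s <- ncrna$sequence[ncrna$class == cl]
    if (length(s) == 0) return("")
    paste(c(s, revcomp(s)), collapse = "#")
  })
  names(hay) <- NCRNA_PRECEDENCE
  rep_hay <- if (!is.null(repeats) && nrow(repeats) > 0) {
    paste(c(repeats$sequence, revcomp(repeats$sequence)), collapse = "#")
  } else ""
  vapply(tags, function(tg) {
    for (cl in NCRNA_PRECEDENCE) {
      if (nzchar(hay[[cl]]) && grepl(tg, hay[[cl]], fixed = TRUE)) return(cl)
    }
    if (nzchar(rep_hay) && grepl(tg, rep_hay, fixed = TRUE)) return("repeat")
    "valid"
  }, "", USE.NAMES = FALSE)
}

#' Collapse reads into unique tags with per-library counts
#'
#' @param reads_by_library named list, one character vector of kept insert
#'   sequences per library.
#' @return data.frame: `sequence`, one count column per library, `total`.
#' @export
collapse_unique <- function(reads_by_library) {
  stopifnot(is.list(reads_by_library))
  all_seq <- sort(unique(unlist(reads_by_library, use.names = FALSE)))
  if (length(all_seq) == 0) {
    out <- data.frame(sequence = character(), stringsAsFactors = FALSE)
    for (nm in names(reads_by_library)) out[[nm]] <- integer(0)
    out$total <- integer(0)
    return(out)
  }
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (nm in names(reads_by_library)) {
    tb <- table(factor(reads_by_library[[nm]], levels = all_seq))
    out[[nm]] <- as.integer(tb)
  }
  out$total <- rowSums(out[, names(reads_by_library), drop = FALSE])
  stopifnot(sum(out$total) == length(unlist(reads_by_library,
                                            use.names = FALSE)))
  out
}

#' Length distribution of valid tags
#'
#' @param tags collapsed tag data.frame ([collapse_unique()] output, with an
#'   `annotation` column if only valid tags should be counted).
#' @param min_len,max_len length range of the table.
#' @return data.frame `length`, `total`, `unique`.
#' @export
length_distribution <- function(tags, min_len = 18, max_len = 25) {
  if ("annotation" %in% names(tags)) tags <- tags[tags$annotation == "valid", ]
  L <- nchar(tags$sequence)
  lens <- min_len:max_len
  data.frame(length = lens,
             total = vapply(lens, function(l) sum(tags$total[L == l]), 1),
             unique = vapply(lens, function(l) sum(L == l), 1L))
}

#' Preprocess a set of raw libraries into annotated unique tags
#'
#' Full triage driver: trims and filters each library, collapses kept reads
#' to unique tags with per-library counts, annotates tags against ncRNA and
#' repeat references, and assembles per-library statistics in the shape of a
#' high-throughput sequencing summary table (raw reads; adapter/length
#' filter; junk; low quality; Rfam classes; repeats; valid reads), each as
#' total and unique counts.
#'
#' @param libraries named list of data.frames with `sequence` and `quality`.
#' @param ncrna,repeats reference data.frames (see [annotate_ncrna()]).
#' @param params a [filter_params()] object.
#' @return list with `tags` (collapsed count matrix + `annotation`),
#'   `stats` (long data.frame: library, class, total, unique) and `params`.
#' @export
preprocess_libraries <- function(libraries, ncrna = NULL, repeats = NULL,
                                 params = filter_params()) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  filt <- lapply(libraries, function(lib) {
    filter_reads(lib$sequence, lib$quality, params)
  })
  kept <- lapply(filt, function(f) f$insert[f$label == "valid"])
  tags <- collapse_unique(kept)
  tags$annotation <- if (nrow(tags) > 0 && !is.null(ncrna)) {
    annotate_ncrna(tags$sequence, ncrna, repeats)
  } else rep("valid", nrow(tags))

  lib_names <- names(libraries)
  stats <- list()
  for (nm in lib_names) {
    lab <- filt[[nm]]$label
    ins <- filt[[nm]]$insert
    ann <- tags$annotation[match(ins, tags$sequence)]
    cls <- ifelse(lab == "valid", ann, lab)
    raw <- data.frame(library = nm, class = "raw_reads",
                      total = length(lab),
                      unique = length(unique(libraries[[nm]]$sequence)))
    per <- do.call(rbind, lapply(unique(cls), function(cl) {
      data.frame(library = nm, class = cl, total = sum(cls == cl),
                 unique = length(unique(ins[cls == cl])))
    }))
    adt <- data.frame(library = nm, class = "adt_length_filter",
                      total = sum(cls %in% c("adapter_only", "too_short",
                                             "too_long")),
                      unique = length(unique(ins[cls %in% c(
                        "adapter_only", "too_short", "too_long")])))
    rfam <- data.frame(library = nm, class = "rfam_total",
                       total = sum(cls %in% NCRNA_PRECEDENCE),
                       unique = length(unique(ins[cls %in% NCRNA_PRECEDENCE])))
    stats[[nm]] <- rbind(raw, per, adt, rfam)
    # partition check: every read in exactly one class
    base_cls <- setdiff(unique(cls), c("adt_length_filter", "rfam_total"))
    stopifnot(sum(per$total[per$class %in% base_cls]) == length(lab))
  }
  stats <- do.call(rbind, stats)
  rownames(stats) <- NULL
  list(tags = tags, stats = stats, params = params)
}
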