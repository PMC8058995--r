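# Known/conserved miRNA identification (3-group classification against the
# precursor catalogue and the transcriptome) and novel miRNA prediction via
# candidate excision + hairpin-criteria evaluation.

#' Map valid tags to catalogue precursors
#'
#' A tag matches a precursor when it occurs as an exact substring starting
#' within `window` nt of the annotated mature start.
#'
#' @param tags character vector of valid tag sequences.
#' @param precursors data.frame with `id`, `sequence`, `mature_start`,
#'   `mature_end`, `family`, `name`.
#' @param window allowed offset (nt) from the annotated mature start.
#' @return data.frame `tag`, `precursor`, `name`, `family`, `offset` (tag
#'   start minus mature start); multi-mapping tags yield one row per hit.
#' @export
map_to_precursors <- function(tags, precursors, window = 4) {
  hits <- list()
  for (i in seq_len(nrow(precursors))) {
    ps <- precursors$sequence[i]
    ms <- precursors$mature_start[i]
    for (tg in tags) {
      m <- gregexpr(tg, ps, fixed = TRUE)[[1]]
      m <- m[m > 0]
      m <- m[abs(m - ms) <= window]
      if (length(m) > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          tag = tg, precursor = precursors$id[i],
          name = precursors$name[i], family = precursors$family[i],
          offset = m[1] - ms, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(tag = character(), precursor = character(),
                      name = character(), family = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Classify catalogue-matched miRNAs into groups 1-3
#'
#' Group 1: the tag and its catalogue precursor both occur in the
#' transcriptome (known miRNAs). Group 2: the tag occurs in the
#' transcriptome but its precursor does not. Group 3: neither does, though
#' the tag hits a catalogue precursor (conserved miRNAs). Matching is exact
#' substring on the sense strand.
#'
#' @param matches output of [map_to_precursors()].
#' @param precursors precursor data.frame (same ids as in `matches`).
#' @param transcriptome named character vector of transcript sequences.
#' @return `matches` with a `group` column (1, 2 or 3).
#' @export
classify_groups <- function(matches, precursors, transcriptome) {
  if (nrow(matches) == 0) {
    matches$group <- integer(0)
    return(matches)
  }
  hay <- paste(transcriptome, collapse = "#")
  tag_in_tx <- vapply(matches$tag, grepl, logical(1), x = hay, fixed = TRUE,
                      USE.NAMES = FALSE)
  prec_seq <- precursors$sequence[match(matches$precursor, precursors$id)]
  prec_in_tx <- vapply(prec_seq, grepl, logical(1), x = hay, fixed = TRUE,
                       USE.NAMES = FALSE)
  matches$group <- ifelse(tag_in_tx & prec_in_tx, 1L,
                          ifelse(tag_in_tx, 2L, 3L))
  matches
}

#' Family membership table
#'
#' Known miRNAs keep their catalogue family; novel records are numbered
#' `miRn1, miRn2, ...` in input order.
#'
#' @param records data.frame with `name` and `family` (NA for novel).
#' @return data.frame `family`, `members`, sorted by descending size.
#' @export
assign_families <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(family = character(), members = integer()))
  }
  fam <- records$family
  novel <- is.na(fam) | fam == ""
  fam[novel] <- paste0("miRn", seq_len(sum(novel)))
  tb <- sort(table(fam), decreasing = TRUE)
  data.frame(family = names(tb), members = as.integer(tb),
             stringsAsFactors = FALSE)
}

#' Excise candidate precursor loci around unannotated tags
#'
#' Each transcriptome hit of an unannotated valid tag is extended by
#' `window` nt on both sides (clipped at transcript ends) to form a
#' candidate precursor region; overlapping candidates on the same
#' transcript are merged, keeping the most abundant tag as the putative
#' mature.
#'
#' @param tags data.frame with `sequence` and `total` (abundance), or a
#'   character vector (abundance 1 each).
#' @param transcriptome named character vector.
#' @param window flank (nt) excised on each side of the tag.
#' @return data.frame `id`, `transcript`, `start`, `end`, `sequence`,
#'   `mature_start`, `mature_end` (candidate-relative), `mature_tag`.
#' @export
find_novel_candidates <- function(tags, transcriptome, window = 150) {
  if (is.character(tags)) {
    tags <- data.frame(sequence = tags, total = 1L, stringsAsFactors = FALSE)
  }
  if (nrow(tags) == 0) {
    return(data.frame(id = character(), transcript = character(),
                      start = integer(), end = integer(),
                      sequence = character(), mature_start = integer(),
                      mature_end = integer(), mature_tag = character()))
  }
  hits <- list()
  for (t in names(transcriptome)) {
    ts <- transcriptome[[t]]
    for (i in seq_len(nrow(tags))) {
      m <- gregexpr(tags$sequence[i], ts, fixed = TRUE)[[1]]
      m <- m[m > 0]
      for (pos in m) {
        hits[[length(hits) + 1]] <- data.frame(
          transcript = t, tag = tags$sequence[i], tag_start = pos,
          tag_end = pos + nchar(tags$sequence[i]) - 1L,
          abundance = tags$total[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(find_novel_candidates(character(0), transcriptome, window))
  }
  hits <- do.call(rbind, hits)
  out <- list()
  for (t in unique(hits$transcript)) {
    h <- hits[hits$transcript == t, ]
    L <- nchar(transcriptome[[t]])
    ir <- IRanges::IRanges(start = pmax(1L, h$tag_start - window),
                           end = pmin(L, h$tag_end + window))
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(IRanges::IRanges(h$tag_start, h$tag_end), red)
    for (j in seq_along(red)) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      best <- members[which.max(h$abundance[members])]
      st <- IRanges::start(red)[j]; en <- IRanges::end(red)[j]
      out[[length(out) + 1]] <- data.frame(
        transcript = t, start = st, end = en,
        sequence = substr(transcriptome[[t]], st, en),
        mature_start = h$tag_start[best] - st + 1L,
        mature_end = h$tag_end[best] - st + 1L,
        mature_tag = h$tag[best], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- cbind(id = sprintf("cand%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Catalogue novel miRNAs from hairpin evaluations
#'
#' Passing candidates become novel miRNA records named `miRn1, miRn2, ...`
#' (duplicated loci collapsed); the summary reports mature length, hairpin
#' length and MFE extremes of the accepted set.
#'
#' @param evaluations output of [evaluate_hairpin()] with `mature_tag`,
#'   `transcript`, `start` columns carried through (as produced on
#'   [find_novel_candidates()] output).
#' @return list `records` (novel miRNA table) and `summary`.
#' @export
catalogue_novel <- function(evaluations) {
  ev <- evaluations[evaluations$pass, , drop = FALSE]
  if ("transcript" %in% names(ev) && nrow(ev) > 0) {
    ev <- ev[!duplicated(paste(ev$transcript, ev$start)), , drop = FALSE]
  }
  if (nrow(ev) == 0) {
    return(list(records = data.frame(name = character(), mature = character(),
                                     precursor_id = character(),
                                     mfe = numeric()),
                summary = list(n = 0L, mature_len_range = c(NA, NA),
                               hairpin_len_range = c(NA, NA),
                               mfe_range = c(NA, NA))))
  }
  mature <- if ("mature_tag" %in% names(ev)) ev$mature_tag else
    substr(ev$sequence, ev$mature_start, ev$mature_end)
  records <- data.frame(name = paste0("miRn", seq_len(nrow(ev))),
                        mature = mature,
                        precursor_id = as.character(ev$id),
                        hairpin_length = ev$hairpin_length,
                        mfe = ev$mfe, stringsAsFactors = FALSE)
  if ("transcript" %in% names(ev)) {
    records$transcript <- ev$transcript
    records$start <- ev$start
  }
  list(records = records,
       summary = list(n = nrow(records),
                      mature_len_range = range(nchar(mature)),
                      hairpin_len_range = range(ev$hairpin_length),
                      mfe_range = range(ev$mfe)))
}

#' Identify known miRNAs and predict novel ones from collapsed tags
#'
#' Driver for the cataloguing stage: maps valid tags to the precursor
#' catalogue, classifies groups, then subjects unannotated tags to candidate
#' excision and hairpin evaluation.
#'
#' @param tags collapsed tag table ([preprocess_libraries()] `$tags`).
#' @param precursors catalogue precursor data.frame.
#' @param transcriptome named character vector.
#' @param criteria [hairpin_criteria()].
#' @param window mature-start window for catalogue matching.
#' @param flank candidate excision flank.
#' @param min_novel_abundance minimum summed tag count for a novel candidate.
#' @return list `known` (matches with groups), `families`, `candidates`,
#'   `evaluations`, `novel` ([catalogue_novel()] output).
#' @export
identify_mirnas <- function(tags, precursors, transcriptome,
                            criteria = hairpin_criteria(), window = 4,
                            flank = 150, min_novel_abundance = 1) {
  valid <- tags[tags$annotation == "valid", , drop = FALSE]
  matches <- map_to_precursors(valid$sequence, precursors, window = window)
  known <- classify_groups(matches, precursors, transcriptome)
  fam <- assign_families(unique(known[, c("name", "family")]))

  rest <- valid[!(valid$sequence %in% known$tag) &
                  valid$total >= min_novel_abundance, , drop = FALSE]
  cands <- find_novel_candidates(rest, transcriptome, window = flank)
  evals <- if (nrow(cands) > 0) {
    cbind(evaluate_hairpin(cands[, c("id", "sequence", "mature_start",
                                     "mature_end")], criteria,
                           refine = TRUE),
          cands[, c("transcript", "start", "end", "mature_tag")])
  } else cands
  novel <- catalogue_novel(evals)
  list(known = known, families = fam, candidates = cands,
       evaluations = evals, novel = novel)
}
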