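# Degradome (PARE) analysis: map tag 5' ends onto transcripts, predict
# miRNA binding sites with the classic plant penalty scheme, validate
# cleavage opposite miRNA position 10 and classify sites into categories
# 0-4 by signal abundance relative to the transcript's tag profile.

# pairing cost between a miRNA base and a target (transcript) base, DNA
# alphabet: 0 Watson-Crick, 0.5 G:U wobble (miRNA G : target T, miRNA T :
# target G), 1 otherwise
PAIR_COST <- local({
  bases <- c("A", "C", "G", "T")
  m <- matrix(1, 4, 4, dimnames = list(bases, bases))
  m["A", "T"] <- 0; m["T", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "T"] <- 0.5; m["T", "G"] <- 0.5
  m
})

position_multiplier <- function(i) ifelse(i >= 2 & i <= 13, 2, 1)

#' Map degradome tags onto transcript 5'-end profiles
#'
#' Each tag's 5' end increments the profile at every exact sense-strand
#' match start (whole-count mode) or at 1/n per locus (fractional mode).
#'
#' @param tags character vector of tag sequences.
#' @param transcriptome named character vector.
#' @param mode `"whole"` (count once per locus) or `"fractional"`.
#' @return list `profiles` (named list of per-position count vectors) and
#'   `unmapped` (number of tags without a match).
#' @export
map_degradome <- function(tags, transcriptome, mode = c("whole", "fractional")) {
  mode <- match.arg(mode)
  profiles <- lapply(transcriptome, function(s) numeric(nchar(s)))
  unmapped <- 0L
  tb <- table(tags)
  for (tg in names(tb)) {
    cnt <- as.integer(tb[[tg]])
    locs <- list()
    for (t in names(transcriptome)) {
      m <- gregexpr(tg, transcriptome[[t]], fixed = TRUE)[[1]]
      m <- m[m > 0]
      if (length(m) > 0) locs[[t]] <- m
    }
    n_loc <- sum(lengths(locs))
    if (n_loc == 0) {
      unmapped <- unmapped + cnt
      next
    }
    w <- if (mode == "whole") cnt else cnt / n_loc
    for (t in names(locs)) {
      for (pos in locs[[t]]) {
        profiles[[t]][pos] <- profiles[[t]][pos] + w
      }
    }
  }
  list(profiles = profiles, unmapped = unmapped)
}

#' Score a miRNA:target duplex
#'
#' Penalty = mismatches x 1 + G:U wobbles x 0.5 + single-nucleotide gaps x 1,
#' each doubled at miRNA positions 2-13 (counting from the miRNA 5' end).
#' The site is the transcript subsequence given 5'->3'; the duplex is
#' antiparallel, so miRNA position 1 pairs with the site's 3' end. At most
#' `max_gaps` single-nucleotide gaps are allowed (plant miRNA:target
#' duplexes tolerate a lone bulged nucleotide, not register shifts), handled
#' by a gap-budgeted dynamic program over the (miRNA, reversed site)
#' alignment.
#'
#' @param mirna miRNA sequence (5'->3', DNA or RNA alphabet).
#' @param site transcript site sequence (5'->3').
#' @param max_gaps maximum number of gaps in the duplex (default 1).
#' @return minimal penalty (half-integer).
#' @export
score_duplex <- function(mirna, site, max_gaps = 1) {
  mir <- chartr("Uu", "Tt", toupper(mirna))
  st <- chartr("Uu", "Tt", toupper(site))
  a <- strsplit(mir, "")[[1]]
  b <- rev(strsplit(st, "")[[1]])      # align antiparallel
  m <- length(a); n <- length(b)
  if (abs(m - n) > max_gaps) return(Inf)
  mult <- position_multiplier(seq_len(m))
  # D[i+1, j+1, g+1]: best penalty aligning a[1..i] to b[1..j] with g gaps
  D <- array(Inf, c(m + 1, n + 1, max_gaps + 1))
  D[1, 1, 1] <- 0
  for (g in 0:max_gaps) {
    # leading gaps (charged at the adjacent miRNA position)
    for (i in seq_len(min(g, m))) {
      D[i + 1, 1, g + 1] <- if (i == g) sum(mult[seq_len(i)]) else Inf
    }
    if (g > 0 && g <= n) {
      D[1, g + 1, g + 1] <- g * position_multiplier(1)
    }
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        pc <- PAIR_COST[a[i], b[j]] * mult[i]
        best <- D[i, j, g + 1] + pc
        if (g > 0) {
          best <- min(best,
                      D[i, j + 1, g] + 1 * mult[i],
                      D[i + 1, j, g] + 1 * mult[min(i + 1, m)])
        }
        D[i + 1, j + 1, g + 1] <- min(D[i + 1, j + 1, g + 1], best)
      }
    }
  }
  min(D[m + 1, n + 1, ])
}

# vectorised ungapped penalty over all site start positions of a transcript;
# returns numeric vector over starts 1..L-m+1
ungapped_scan <- function(mirna, transcript) {
  mir <- chartr("Uu", "Tt", toupper(mirna))
  tx <- chartr("Uu", "Tt", toupper(transcript))
  a <- strsplit(mir, "")[[1]]
  b <- strsplit(tx, "")[[1]]
  m <- length(a); L <- length(b)
  if (L < m) return(numeric(0))
  n_start <- L - m + 1
  bi <- match(b, DNA_BASES)
  total <- numeric(n_start)
  for (i in seq_len(m)) {
    # miRNA position i pairs with transcript position s + m - i
    cost <- PAIR_COST[a[i], ]
    ci <- cost[bi[(m - i + 1):(m - i + n_start)]]
    ci[is.na(ci)] <- 1
    total <- total + ci * position_multiplier(i)
  }
  total
}

#' Predict miRNA binding sites on a transcript
#'
#' Scans every position with the vectorized ungapped scorer, then refines
#' near-threshold windows with the gapped dynamic program (site length
#' within one nt of the miRNA length), reporting sites with penalty <=
#' `threshold`.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcript transcript sequence.
#' @param threshold maximum penalty (default 4).
#' @param refine_margin extra penalty margin for the ungapped screen below
#'   which gapped refinement is attempted.
#' @return data.frame `start`, `end`, `score` (best alignment per site).
#' @export
predict_sites <- function(mirna, transcript, threshold = 4,
                          refine_margin = 8) {
  m <- nchar(mirna)
  u <- ungapped_scan(mirna, transcript)
  if (length(u) == 0) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  cand <- which(u <= threshold + refine_margin)
  out <- list()
  L <- nchar(transcript)
  for (s in cand) {
    best <- u[s]; best_end <- s + m - 1L
    if (u[s] > threshold) {
      for (n_site in c(m - 1L, m, m + 1L)) {
        en <- s + n_site - 1L
        if (en > L) next
        sc <- score_duplex(mirna, substr(transcript, s, en))
        if (sc < best) { best <- sc; best_end <- en }
      }
    }
    if (best <= threshold) {
      out[[length(out) + 1]] <- data.frame(start = s, end = best_end,
                                           score = best)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  res <- do.call(rbind, out)
  # collapse overlapping reports of the same site: keep best-scoring start
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1) {
    for (i in 2:nrow(res)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (res$start[i] - res$start[prev] < 3) {
        if (res$score[i] < res$score[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a cleavage position into degradome categories 0-4
#'
#' Category 4: exactly one tag at the position. Category 0: the count is
#' the transcript's unique maximum. Category 1: equal to a maximum attained
#' at more than one position. Category 2: above the median of nonzero
#' positions but below the maximum. Category 3: more than one tag, at or
#' below the nonzero median.
#'
#' @param position 1-based transcript coordinate.
#' @param profile per-position tag count vector.
#' @return integer category, or NA if the position has no tag support.
#' @export
classify_category <- function(position, profile) {
  cnt <- profile[position]
  if (is.na(cnt) || cnt < 1) return(NA_integer_)
  if (cnt == 1) return(4L)
  mx <- max(profile)
  med <- median(profile[profile > 0])
  if (cnt == mx) {
    if (sum(profile == mx) == 1) return(0L) else return(1L)
  }
  if (cnt > med) return(2L)
  3L
}

#' Call validated cleavage targets
#'
#' For each predicted duplex the expected cleavage position is the
#' transcript nucleotide opposite miRNA position 10; a site is validated if
#' degradome tags support a position within `window` nt of it (the
#' best-supported position in the window, ties to the closer coordinate).
#'
#' @param alignments data.frame with `mirna`, `transcript`, `start`, `end`,
#'   `score` (site coordinates on the transcript).
#' @param profiles named list of per-position tag counts ([map_degradome()]).
#' @param window evidence half-window (nt, default 1).
#' @return data.frame of validated sites with `cleavage_pos`, `count`,
#'   `category`.
#' @export
call_targets <- function(alignments, profiles, window = 1) {
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    t <- alignments$transcript[i]
    prof <- profiles[[t]]
    if (is.null(prof)) next
    n_site <- alignments$end[i] - alignments$start[i] + 1L
    expected <- alignments$start[i] + n_site - 10L
    win <- max(1L, expected - window):min(length(prof), expected + window)
    cnts <- prof[win]
    if (all(cnts < 1)) next
    best <- win[order(-cnts, abs(win - expected), win)][1]
    out[[length(out) + 1]] <- data.frame(
      mirna = alignments$mirna[i], transcript = t,
      site_start = alignments$start[i], site_end = alignments$end[i],
      score = alignments$score[i], cleavage_pos = best,
      count = prof[best],
      category = classify_category(best, prof),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      score = numeric(), cleavage_pos = integer(),
                      count = numeric(), category = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' T-plot table for one transcript
#'
#' @param profile per-position tag count vector.
#' @param sites validated site table ([call_targets()] rows for this
#'   transcript).
#' @return data.frame `position`, `count`, `site` flag (TRUE at called
#'   cleavage positions).
#' @export
tplot_data <- function(profile, sites = NULL) {
  if (length(profile) == 0) {
    return(data.frame(position = integer(), count = numeric(),
                      site = logical()))
  }
  flag <- logical(length(profile))
  if (!is.null(sites) && nrow(sites) > 0) flag[sites$cleavage_pos] <- TRUE
  data.frame(position = seq_along(profile), count = profile, site = flag)
}

#' Degradome target identification driver
#'
#' Predicts binding sites of each miRNA on each transcript and validates
#' them against the degradome profiles.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcriptome named character vector.
#' @param profiles [map_degradome()] profiles.
#' @param threshold duplex penalty threshold.
#' @param window cleavage evidence half-window.
#' @return validated site table ([call_targets()] output).
#' @export
degradome_targets <- function(mirnas, transcriptome, profiles, threshold = 4,
                              window = 1) {
  aln <- list()
  for (mn in names(mirnas)) {
    for (t in names(transcriptome)) {
      s <- predict_sites(mirnas[[mn]], transcriptome[[t]], threshold)
      if (nrow(s) > 0) {
        aln[[length(aln) + 1]] <- cbind(mirna = mn, transcript = t, s)
      }
    }
  }
  if (length(aln) == 0) {
    return(call_targets(data.frame(mirna = character(),
                                   transcript = character(),
                                   start = integer(), end = integer(),
                                   score = numeric()), profiles, window))
  }
  call_targets(do.call(rbind, aln), profiles, window)
}
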