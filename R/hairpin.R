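# Hairpin-criteria evaluation for novel miRNA prediction.
#
# A candidate precursor is folded (RNAfold MFE structure) and the helix that
# carries the mature miRNA is measured: number of stem base pairs, largest
# contiguous unpaired run (bulge) in the stem and inside the mature region,
# unpaired mature positions ("errors"), and the largest asymmetry of any
# internal loop touching the mature region ("biased errors"). The criteria
# thresholds mirror the classic plant novel-miRNA filter: single stem bulge
# <= 12 nt, mature-region bulge <= 4 nt, >= 16 stem base pairs, <= 2 mature
# errors, <= 2 biased errors per bulge.

#' Thresholds for the novel-miRNA hairpin filter
#'
#' @param max_stem_bulge largest allowed contiguous unpaired run (nt) in a
#'   single stem bulge/internal loop.
#' @param max_mature_bulge largest allowed unpaired run inside the mature
#'   region.
#' @param min_stem_pairs minimum number of base pairs in the stem carrying
#'   the mature.
#' @param max_mature_errors maximum unpaired mature positions.
#' @param max_biased_errors maximum asymmetric unpaired nucleotides within a
#'   single internal loop overlapping the mature region.
#' @param max_span stems are traced outward from the terminal loop only while
#'   the enclosing pair spans no more than this many nt, so that long-range
#'   pairings of flanking sequence in an excised candidate window are not
#'   mistaken for precursor stem (default 250 nt, comfortably above plant
#'   pre-miRNA sizes).
#' @return a list of thresholds, class `hairpin_criteria`.
#' @export
hairpin_criteria <- function(max_stem_bulge = 12, max_mature_bulge = 4,
                             min_stem_pairs = 16, max_mature_errors = 2,
                             max_biased_errors = 2, max_span = 250) {
  stopifnot(max_stem_bulge >= 0, max_mature_bulge >= 0, min_stem_pairs >= 0,
            max_mature_errors >= 0, max_biased_errors >= 0)
  structure(list(max_stem_bulge = max_stem_bulge,
                 max_mature_bulge = max_mature_bulge,
                 min_stem_pairs = min_stem_pairs,
                 max_mature_errors = max_mature_errors,
                 max_biased_errors = max_biased_errors,
                 max_span = max_span),
            class = "hairpin_criteria")
}

# Nesting tree of a pair table: for every pair (keyed by its opening
# position) its parent pair and children pairs.
pair_tree <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  parent <- integer(n)          # parent[i] = opening pos of enclosing pair
  children <- vector("list", n)
  stack <- integer(0)
  pt <- integer(n)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
      par <- if (length(stack)) stack[length(stack)] else 0L
      parent[j] <- par
      if (par > 0) children[[par]] <- c(children[[par]], j)
    }
  }
  # root-level pairs
  roots <- which(pt > seq_len(n) & parent == 0L)
  list(pt = pt, parent = parent, children = children, roots = roots)
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Measure the mature-bearing hairpin of a folded candidate
#'
#' Locates the helix whose base pairs involve the mature interval, traces it
#' inward to its terminal loop and outward while pairs remain directly
#' nested (stopping at multiloop branches and at `max_span`), and reports
#' the stem/bulge/error statistics the novel-miRNA criteria are applied to.
#'
#' @param structure dot-bracket string from the MFE fold.
#' @param mature_start,mature_end 1-based inclusive mature interval.
#' @param max_span see [hairpin_criteria()].
#' @return a list with `stem_pairs`, `stem_bulge`, `mature_bulge`,
#'   `mature_errors`, `biased_errors`, `spans_loop`, `hairpin_start`,
#'   `hairpin_end`, `hairpin_length`.
#' @export
measure_hairpin <- function(structure, mature_start, mature_end,
                            max_span = 250) {
  n <- nchar(structure)
  stopifnot(mature_start >= 1, mature_end <= n, mature_start <= mature_end)
  tree <- pair_tree(structure)
  pt <- tree$pt
  mat <- mature_start:mature_end

  out <- list(stem_pairs = 0L, stem_bulge = 0L,
              mature_bulge = longest_run(pt[mat] == 0L),
              mature_errors = sum(pt[mat] == 0L),
              biased_errors = 0L, spans_loop = FALSE,
              hairpin_start = NA_integer_, hairpin_end = NA_integer_,
              hairpin_length = NA_integer_)

  # mature folding back on itself means it crosses the terminal loop
  out$spans_loop <- any(pt[mat] %in% mat & pt[mat] != 0L)

  paired_mat <- mat[pt[mat] > 0L]
  if (length(paired_mat) == 0L || out$spans_loop) return(out)

  # opening positions of pairs that involve the mature
  open_of <- function(i) if (pt[i] > i) i else pt[i]
  mature_opens <- vapply(paired_mat, open_of, 1L)
  # the pair whose open is most frequent = helix carrying most mature pairs
  tab <- table(mature_opens)
  start_open <- as.integer(names(tab)[which.max(tab)])

  # walk inward to the terminal loop (or a multiloop branch)
  cur <- start_open
  repeat {
    kids <- tree$children[[cur]]
    kids <- kids[kids > 0]
    if (length(kids) != 1L) break
    cur <- kids[[1]]
  }
  innermost <- cur

  # walk outward while directly nested (parent has this pair as only child)
  cur <- innermost
  path <- innermost
  repeat {
    par <- tree$parent[cur]
    if (par == 0L) break
    kids <- tree$children[[par]]
    if (length(kids[kids > 0]) != 1L) break
    if (pt[par] - par + 1L > max_span) break
    cur <- par
    path <- c(par, path)
  }

  # path holds opening positions, outermost first
  i_open <- path
  j_close <- pt[path]
  out$stem_pairs <- length(path)
  out$hairpin_start <- i_open[1]
  out$hairpin_end <- j_close[1]
  out$hairpin_length <- j_close[1] - i_open[1] + 1L

  if (length(path) >= 2L) {
    g5 <- i_open[-1] - i_open[-length(path)] - 1L
    g3 <- j_close[-length(path)] - j_close[-1] - 1L
    runs <- pmax(g5, g3)
    out$stem_bulge <- max(0L, runs)
    # internal loops whose unpaired run overlaps the mature region
    bias <- abs(g5 - g3)
    touches <- vapply(seq_along(g5), function(k) {
      r5 <- if (g5[k] > 0) (i_open[k] + 1L):(i_open[k + 1L] - 1L) else integer(0)
      r3 <- if (g3[k] > 0) (j_close[k + 1L] + 1L):(j_close[k] - 1L) else integer(0)
      any(c(r5, r3) %in% mat)
    }, logical(1))
    if (any(touches)) out$biased_errors <- max(bias[touches])
  }
  out
}

#' Evaluate candidate precursors against the hairpin criteria
#'
#' Folds each candidate at its minimum free energy and applies the
#' novel-miRNA stem-loop criteria around the given mature interval.
#'
#' @param candidates data.frame with columns `id`, `sequence`,
#'   `mature_start`, `mature_end` (1-based, inclusive, on the candidate).
#' @param criteria a [hairpin_criteria()] object.
#' @param temperature folding temperature (deg C).
#' @param refine if TRUE, candidates excised from wide transcript windows
#'   are evaluated in two stages: the mature-bearing helix traced in the
#'   first fold is excised with a `refine_pad` nt pad and refolded in
#'   isolation, and the verdict is taken from that refold. This removes
#'   artifacts of flanking sequence pairing into (or away from) the
#'   precursor stem, the usual practice when precursors are excised from
#'   longer transcripts.
#' @param refine_pad pad (nt) around the traced hairpin for refinement.
#' @return data.frame, one row per candidate: measured values, per-criterion
#'   pass flags, `mfe`, `structure`, overall `pass`, and a `reason` string
#'   for failures.
#' @export
evaluate_hairpin <- function(candidates, criteria = hairpin_criteria(),
                             temperature = 37, refine = FALSE,
                             refine_pad = 10) {
  stopifnot(all(c("id", "sequence", "mature_start", "mature_end") %in%
                  names(candidates)))
  if (nrow(candidates) == 0) {
    return(cbind(candidates,
                 data.frame(structure = character(), mfe = numeric())))
  }
  mlen <- candidates$mature_end - candidates$mature_start + 1L
  too_short <- nchar(candidates$sequence) < mlen + 3L

  folded <- fold_sequences(candidates$sequence,
                           ids = as.character(candidates$id),
                           temperature = temperature)
  res <- lapply(seq_len(nrow(candidates)), function(k) {
    if (too_short[k]) {
      m <- list(stem_pairs = 0L, stem_bulge = 0L, mature_bulge = 0L,
                mature_errors = NA_integer_, biased_errors = 0L,
                spans_loop = FALSE, hairpin_start = NA, hairpin_end = NA,
                hairpin_length = NA)
    } else {
      m <- measure_hairpin(folded$structure[k], candidates$mature_start[k],
                           candidates$mature_end[k],
                           max_span = criteria$max_span)
    }
    as.data.frame(m)
  })
  res <- do.call(rbind, res)
  ev <- cbind(candidates[, c("id", "sequence", "mature_start", "mature_end")],
              res,
              structure = folded$structure, mfe = folded$mfe)

  if (refine) {
    refit <- which(!too_short & is.finite(res$hairpin_start) &
                     (res$hairpin_start > 1 |
                        res$hairpin_end < nchar(candidates$sequence)))
    if (length(refit) > 0) {
      st <- pmax(1L, pmin(res$hairpin_start[refit],
                          candidates$mature_start[refit]) - refine_pad)
      en <- pmin(nchar(candidates$sequence[refit]),
                 pmax(res$hairpin_end[refit],
                      candidates$mature_end[refit]) + refine_pad)
      sub <- data.frame(
        id = candidates$id[refit],
        sequence = substr(candidates$sequence[refit], st, en),
        mature_start = candidates$mature_start[refit] - st + 1L,
        mature_end = candidates$mature_end[refit] - st + 1L)
      ev2 <- evaluate_hairpin(sub, criteria, temperature, refine = FALSE)
      # the refined row describes the excised hairpin: sequence, structure
      # and coordinates are all relative to the excised region, whose start
      # within the original candidate is recorded in `refine_offset`
      meas <- c("sequence", "mature_start", "mature_end", "stem_pairs",
                "stem_bulge", "mature_bulge", "mature_errors",
                "biased_errors", "spans_loop", "hairpin_start",
                "hairpin_end", "hairpin_length", "structure", "mfe")
      ev$refine_offset <- NA_integer_
      ev[refit, meas] <- ev2[, meas]
      ev$refine_offset[refit] <- st
    }
  }

  ev$stem_bulge_ok <- ev$stem_bulge <= criteria$max_stem_bulge
  ev$mature_bulge_ok <- ev$mature_bulge <= criteria$max_mature_bulge
  ev$stem_pairs_ok <- ev$stem_pairs >= criteria$min_stem_pairs
  ev$mature_errors_ok <- !is.na(ev$mature_errors) &
    ev$mature_errors <= criteria$max_mature_errors
  ev$biased_errors_ok <- ev$biased_errors <= criteria$max_biased_errors
  ev$in_stem_ok <- !ev$spans_loop
  ev$pass <- ev$stem_bulge_ok & ev$mature_bulge_ok & ev$stem_pairs_ok &
    ev$mature_errors_ok & ev$biased_errors_ok & ev$in_stem_ok &
    !too_short
  ev$reason <- ifelse(too_short, "candidate shorter than mature + loop",
               ifelse(ev$pass, "",
               ifelse(!ev$in_stem_ok, "mature spans terminal loop",
               ifelse(!ev$stem_pairs_ok, "stem pairs < minimum",
               ifelse(!ev$stem_bulge_ok, "stem bulge too large",
               ifelse(!ev$mature_bulge_ok, "mature bulge too large",
               ifelse(!ev$mature_errors_ok, "too many mature errors",
                      "biased errors too large")))))))
  rownames(ev) <- NULL
  ev
}
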