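# Construction of synthetic pre-miRNA hairpins. A precursor is designed as
# 5' arm + short A/C loop + reverse complement of the arm, with the mature
# embedded in the 5' arm. Decoys carry one targeted defect. Every design is
# verified with the package's own hairpin evaluator (the same filter the
# pipeline applies) and redrawn until the designed verdict holds, so the
# truth tables are guaranteed consistent with the evaluator.

design_one_hairpin <- function(mature_len = 24, arm_len = NULL,
                               loop_len = NULL,
                               violation = c("none", "stem_bulge",
                                             "mature_errors", "mature_bulge")) {
  violation <- match.arg(violation)
  if (is.null(arm_len)) arm_len <- sample1(38:60)
  if (is.null(loop_len)) loop_len <- sample1(8:12)
  arm5 <- paste(sample(DNA_BASES, arm_len, replace = TRUE), collapse = "")
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  # keep the mature clear of the arm ends so designed defects stay local;
  # the stem-bulge decoy additionally needs room for its insertion anchor
  m_range <- 3:(arm_len - mature_len - 2)
  if (violation == "stem_bulge") {
    m_range <- m_range[m_range >= 9 | m_range <= arm_len - mature_len - 7]
  }
  m_off <- sample1(m_range)
  mature <- substr(arm5, m_off, m_off + mature_len - 1)
  arm3 <- revcomp(arm5)

  # index in arm3 pairing with arm5 position i
  pair_idx <- function(i) arm_len - i + 1L

  if (violation == "stem_bulge") {
    # 13-nt unpaired insertion in the 3' arm, opposite a point outside the
    # mature region, between the mature's pairing block and the loop or end
    # keep >= 6 bp of stem outside the bulge so it cannot become a dangling
    # end, and stay clear of the mature block
    lo <- if (m_off - 2 >= 7) 7:(m_off - 2) else integer(0)
    hi <- if (m_off + mature_len + 1 <= arm_len - 6) {
      (m_off + mature_len + 1):(arm_len - 6)
    } else integer(0)
    anchor <- sample1(c(lo, hi))
    at <- pair_idx(anchor)
    ins <- paste(sample(c("A", "C"), 13, replace = TRUE), collapse = "")
    arm3 <- paste0(substr(arm3, 1, at), ins, substr(arm3, at + 1, arm_len))
  } else if (violation == "mature_errors") {
    # three isolated mismatches opposite mature positions (symmetric 1x1
    # internal loops: errors = 3, no bulge, no bias)
    pos <- m_off + c(4, 10, 16)
    for (p in pos) {
      b <- substr(arm5, p, p)
      bad <- switch(b, A = c("A", "C", "G"), C = c("A", "C"),
                    G = c("A", "G"), T = c("C", "T"))
      q <- pair_idx(p)
      substr(arm3, q, q) <- sample1(bad)
    }
  } else if (violation == "mature_bulge") {
    # delete the 5 bases pairing the mature's middle: 5-nt unpaired run in
    # the mature region (which necessarily also exceeds the error count)
    mid <- m_off + floor(mature_len / 2) - 2L
    q <- pair_idx(mid + 4L)          # arm3 block runs antiparallel
    arm3 <- paste0(substr(arm3, 1, q - 1), substr(arm3, q + 5, nchar(arm3)))
  }

  seq <- paste0(arm5, loop, arm3)
  list(sequence = seq, mature_start = m_off,
       mature_end = m_off + mature_len - 1L, mature = mature,
       violation = violation)
}

# verdict the design must show under the evaluator
design_ok <- function(ev, violation) {
  if (violation == "none") return(ev$pass)
  if (ev$pass) return(FALSE)
  switch(violation,
    stem_bulge = !ev$stem_bulge_ok & ev$mature_bulge_ok & ev$stem_pairs_ok &
      ev$mature_errors_ok & ev$biased_errors_ok & ev$in_stem_ok,
    mature_errors = !ev$mature_errors_ok & ev$stem_bulge_ok &
      ev$mature_bulge_ok & ev$stem_pairs_ok & ev$in_stem_ok,
    # a 5-nt mature bulge unavoidably unpairs >2 mature positions and forms
    # a 5x0 asymmetric loop, so the error/bias counts cascade with it
    mature_bulge = !ev$mature_bulge_ok & ev$stem_bulge_ok & ev$stem_pairs_ok &
      ev$in_stem_ok)
}

#' Design a verified set of hairpin precursors
#'
#' Draws stem-loop precursors (and optionally decoys with one targeted
#' criterion violation each), folds them, and keeps only designs whose
#' evaluator verdict matches the design intent; failed draws are replaced.
#'
#' @param violations character vector, one entry per requested hairpin:
#'   `"none"` for a criteria-satisfying precursor or one of `"stem_bulge"`,
#'   `"mature_errors"`, `"mature_bulge"`.
#' @param mature_lens mature lengths, recycled over hairpins.
#' @param criteria evaluator thresholds ([hairpin_criteria()]).
#' @param max_rounds redraw rounds before giving up.
#' @return data.frame: `id`, `sequence`, `mature_start`, `mature_end`,
#'   `mature`, `violation`, `expected_pass`, plus the evaluator columns.
#' @export
design_hairpin_set <- function(violations, mature_lens = 24,
                               criteria = hairpin_criteria(),
                               max_rounds = 30) {
  n <- length(violations)
  mature_lens <- rep_len(mature_lens, n)
  done <- vector("list", n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (length(todo) == 0) break
    drafts <- lapply(todo, function(k) {
      design_one_hairpin(mature_len = mature_lens[k],
                         violation = violations[k])
    })
    cand <- data.frame(
      id = as.character(todo),
      sequence = vapply(drafts, `[[`, "", "sequence"),
      mature_start = as.integer(vapply(drafts, function(d) d$mature_start, numeric(1))),
      mature_end = as.integer(vapply(drafts, function(d) d$mature_end, numeric(1))))
    ev <- evaluate_hairpin(cand, criteria)
    keep <- vapply(seq_along(todo), function(i) {
      design_ok(ev[i, ], violations[todo[i]])
    }, logical(1))
    for (i in which(keep)) {
      k <- todo[i]
      row <- cbind(ev[i, ], mature = drafts[[i]]$mature,
                   violation = violations[k],
                   expected_pass = violations[k] == "none")
      done[[k]] <- row
    }
    todo <- todo[!keep]
  }
  if (length(todo) > 0) {
    stop("could not design ", length(todo),
         " hairpin(s) with the requested property in ", max_rounds, " rounds")
  }
  out <- do.call(rbind, done)
  rownames(out) <- NULL
  out
}
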