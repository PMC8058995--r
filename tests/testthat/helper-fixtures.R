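# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# a small reference bundle + libraries used across module tests
small_config <- function(...) {
  sim_config(seed = 101, n_transcripts = 60, n_known_mirnas = 20,
             n_novel_mirnas = 6, n_decoy_mirnas = 6, n_contaminant_refs = 6,
             library_depth = 3000, n_target_pairs = 8, ...)
}

small_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_reference(small_config())
  }
  .fixture_cache$bundle
}

# zero-noise configuration: deterministic counts, no junk/contaminants
clean_config <- function(...) {
  sim_config(seed = 202, n_transcripts = 120, n_known_mirnas = 40,
             n_novel_mirnas = 6, n_decoy_mirnas = 6, n_contaminant_refs = 4,
             library_depth = 5000, n_target_pairs = 8,
             junk_fraction = 0, contaminant_fraction = 0,
             lowqual_fraction = 0, adapter_only_fraction = 0,
             count_model = "exact", ...)
}

clean_pipeline <- function() {
  if (is.null(.fixture_cache$clean_pipe)) {
    .fixture_cache$clean_pipe <- run_pipeline(clean_config(), seed = 202)
  }
  .fixture_cache$clean_pipe
}

# brute-force duplex scorer: enumerate all alignments of the miRNA against
# the reversed site with up to `max_gaps` gaps on either strand
brute_force_duplex <- function(mirna, site, max_gaps = 1) {
  pair_cost <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
    gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
    ifelse(wc, 0, ifelse(gu, 0.5, 1))
  }
  mult <- function(i) ifelse(i >= 2 & i <= 13, 2, 1)
  a <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  b <- rev(strsplit(chartr("Uu", "Tt", toupper(site)), "")[[1]])
  best <- Inf
  rec <- function(i, j, acc, gaps) {
    if (acc >= best) return()
    if (i > length(a) && j > length(b)) {
      best <<- min(best, acc)
      return()
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, acc + pair_cost(a[i], b[j]) * mult(i), gaps)
    }
    if (gaps < max_gaps) {
      if (i <= length(a)) rec(i + 1, j, acc + 1 * mult(i), gaps + 1)
      if (j <= length(b)) rec(i, j + 1, acc + 1 * mult(min(i, length(a))),
                              gaps + 1)
    }
  }
  rec(1, 1, 0, 0)
  best
}

# independent category oracle: literal restatement of the abundance-tier
# definitions, evaluated without shortcuts
oracle_category <- function(position, profile) {
  cnt <- profile[position]
  if (cnt < 1) return(NA_integer_)
  if (cnt == 1) return(4L)
  mx <- max(profile)
  n_at_max <- sum(profile == mx)
  nonzero <- sort(profile[profile > 0])
  med <- median(nonzero)
  if (cnt == mx && n_at_max == 1) return(0L)
  if (cnt == mx && n_at_max > 1) return(1L)
  if (cnt < mx && cnt > med) return(2L)
  3L
}
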