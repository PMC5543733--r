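# Independent brute-force oracles. Deliberately naive double loops, kept
# separate from the package implementations they check.

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Windowed weighted mean anchored at the window's ceiling(w/2)-th residue.
oracle_window_mean <- function(residues, lookup, window, weights = NULL) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  if (is.null(weights)) weights <- rep(1, window)
  weights <- weights / sum(weights)
  out <- rep(NA_real_, L)
  for (start in seq_len(L - window + 1)) {
    acc <- 0
    for (k in seq_len(window)) {
      acc <- acc + lookup[[chars[start + k - 1]]] * weights[k]
    }
    out[start + ceiling(window / 2) - 1] <- acc
  }
  out
}

# Hexapeptide product over 0.37^6, anchored at the window's first residue.
oracle_surface <- function(residues, lookup) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  out <- rep(NA_real_, L)
  for (start in seq_len(L - 5)) {
    p <- 1
    for (k in 0:5) p <- p * lookup[[chars[start + k]]]
    out[start] <- p / 0.37^6
  }
  out
}

# Per-state GOR offset sums as a plain triple loop over an info table kept
# in long form.
oracle_gor_scores <- function(residues, info_tbl) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  states <- c("H", "E", "T", "C")
  scores <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, states))
  for (i in seq_len(L)) {
    for (d in -8:8) {
      j <- i + d
      if (j < 1 || j > L) next
      for (s in states) {
        v <- info_tbl$info[info_tbl$state == s &
                             info_tbl$residue == chars[j] &
                             info_tbl$offset == d]
        scores[i, s] <- scores[i, s] + v
      }
    }
  }
  scores
}

# Threshold-scan discretization.
oracle_discretize <- function(values, thresholds, levels) {
  vapply(values, function(v) {
    if (is.na(v)) return(NA_real_)
    idx <- 1
    for (t in thresholds) if (v >= t) idx <- idx + 1
    levels[idx]
  }, numeric(1))
}

# Maximal runs of TRUE, then gap merging, as explicit index scans.
oracle_runs <- function(ok, gap_merge = 0) {
  runs <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) <= 1) return(runs)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= gap_merge) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  merged
}

# Per-column conservation tally.
oracle_column_identity <- function(column_chars, gap_policy) {
  nongap <- column_chars[column_chars != "-"]
  if (length(nongap) == 0) {
    return(if (gap_policy == "exclude") NA_real_ else 0)
  }
  counts <- table(nongap)
  denom <- if (gap_policy == "exclude") length(nongap) else length(column_chars)
  max(counts) / denom
}

# Brute-force enumeration of IUPAC expansions by recursive descent.
oracle_expand <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(bases), "")[[1]]
  acc <- ""
  for (ch in chars) {
    opts <- strsplit(map[[ch]], "")[[1]]
    acc <- as.vector(vapply(acc, function(a) paste0(a, opts),
                            character(length(opts))))
  }
  sort(acc)
}

scan_for <- function(sim, config = default_config()) {
  predict_epitopes(sim$seq, config)
}

rank1 <- function(scan) {
  cand <- scan$candidates
  cand[!is.na(cand$rank) & cand$rank == 1, ]
}
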