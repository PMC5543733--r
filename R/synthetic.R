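#' Specification for a synthetic protein with planted segments
#'
#' Describes the generator's study conditions: overall length, background
#' residue distribution, and the planted segments. Two segment kinds are
#' supported, chosen to separate the predictor tracks by construction:
#' `"epitope-like"` segments draw from the hydrophilic / turn-forming
#' vocabulary R K D E N Q S T G P, `"buried-helix"` segments from the
#' hydrophobic / helix-forming vocabulary A L I V F M W. A segment with
#' `start = NA` is placed uniformly at random (without overlap) when the
#' protein is generated.
#'
#' @param length Protein length (default 200, in the 150-250 range typical
#'   of the gamma-type phospholipase A2 inhibitor family this emulates).
#' @param segments List of `list(kind, start, length)` entries; default one
#'   epitope-like 20-mer and one buried-helix 15-mer at random positions.
#' @param background `"uniform"` (default) or `"swissprot"`, or a named
#'   frequency vector over the 20 residues summing to 1.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(length = 200L,
                       segments = list(
                         list(kind = "epitope-like", start = NA, length = 20L),
                         list(kind = "buried-helix", start = NA, length = 15L)
                       ),
                       background = "uniform") {
  freqs <- aa_background(background)
  for (s in segments) {
    stopifnot(s$kind %in% c("epitope-like", "buried-helix"), s$length >= 1)
    if (!is.na(s$start) && (s$start < 1 || s$start + s$length - 1 > length)) {
      abort("planted segment outside sequence bounds",
            class = "epitopr_error_synth_spec")
    }
  }
  fixed <- purrr::keep(segments, ~ !is.na(.x$start))
  if (length(fixed) > 1) {
    iv <- purrr::map(fixed, ~ c(.x$start, .x$start + .x$length - 1L))
    for (i in seq_along(iv)) for (j in seq_len(i - 1)) {
      if (iv[[i]][1] <= iv[[j]][2] && iv[[i]][2] >= iv[[j]][1]) {
        abort("planted segments overlap", class = "epitopr_error_synth_spec")
      }
    }
  }
  structure(list(length = as.integer(length), segments = segments,
                 background = freqs),
            class = "synth_spec")
}

#' Background residue distributions
#'
#' `"uniform"` (1/20 each; the default so tests do not silently depend on
#' an external composition table) or `"swissprot"`, an approximate
#' database-wide composition.
#'
#' @param which Distribution name or a named frequency vector.
#' @return Named numeric over the 20 canonical residues, summing to 1.
#' @export
aa_background <- function(which = "uniform") {
  if (is.numeric(which)) {
    stopifnot(setequal(names(which), AA20), abs(sum(which) - 1) < 1e-6,
              all(which >= 0))
    return(which[AA20])
  }
  freqs <- switch(which,
    uniform = setNames(rep(1 / 20, 20), AA20),
    swissprot = c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38,
                  Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
                  L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
                  S = 6.65, T = 5.36, W = 1.10, Y = 2.92,
                  V = 6.85)[AA20] / 100,
    abort(paste0("unknown background '", which, "'"),
          class = "epitopr_error_synth_spec")
  )
  freqs / sum(freqs)
}

#' Generate a synthetic protein with planted ground truth
#'
#' Background residues are drawn i.i.d. from the spec's background
#' distribution; planted segments are overwritten with draws from their
#' kind's residue vocabulary. The result is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @param id Record identifier for the generated protein.
#' @return List with `seq` (one-row protein tibble) and `truth` (tibble
#'   `kind`, `start`, `end`, `length` of the planted segments).
#' @export
generate_protein <- function(spec, seed, id = "synthetic") {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    L <- spec$length
    chars <- sample(AA20, L, replace = TRUE, prob = spec$background)
    placed <- purrr::keep(spec$segments, ~ !is.na(.x$start)) |>
      purrr::map(~ c(.x$start, .x$start + .x$length - 1L))
    truth <- list()
    for (s in spec$segments) {
      if (is.na(s$start)) {
        start <- place_segment(L, s$length, placed)
      } else {
        start <- s$start
      }
      end <- start + s$length - 1L
      placed[[length(placed) + 1L]] <- c(start, end)
      vocab <- if (s$kind == "epitope-like") EPITOPE_RESIDUES else BURIED_RESIDUES
      chars[start:end] <- sample(vocab, s$length, replace = TRUE)
      truth[[length(truth) + 1L]] <- tibble(
        kind = s$kind, start = as.integer(start), end = as.integer(end),
        length = as.integer(s$length)
      )
    }
    list(seq = protein(paste(chars, collapse = ""), id = id),
         truth = bind_rows(truth))
  })
}

# Uniform placement without overlap against already-placed intervals,
# by rejection; deterministic under the active RNG stream.
place_segment <- function(L, len, placed) {
  if (len > L) {
    abort("segment longer than sequence", class = "epitopr_error_synth_spec")
  }
  for (try in 1:1000) {
    start <- sample.int(L - len + 1L, 1L)
    end <- start + len - 1L
    clash <- any(vapply(placed, function(iv) start <= iv[2] && end >= iv[1],
                        logical(1)))
    if (!clash) return(start)
  }
  abort("could not place non-overlapping segments",
        class = "epitopr_error_synth_spec")
}

#' Generate a synthetic multiple alignment with known structure
#'
#' A root sequence is sampled from the uniform residue distribution; each
#' of `n_seqs` rows is an i.i.d. per-column mutated copy (with probability
#' `mutation_rate` a column's residue is resampled uniformly from all 20,
#' so it may coincide with the original). At each declared discordant
#' column, every group instead receives its own fixed residue, distinct
#' across groups and exempt from mutation — the planted analogue of a
#' group-diagnostic substitution. Pure function of its arguments and
#' `seed`.
#'
#' @param n_seqs Number of rows (>= 2).
#' @param ncols Number of alignment columns.
#' @param groups Named character vector (names become record ids) or
#'   `NULL` for an automatic even split into groups "A" and "B".
#' @param discordant_columns Integer columns to plant group-diagnostic
#'   residues at.
#' @param mutation_rate Per-column substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `aln` (gapped-protein style tibble; no gaps are
#'   generated), `groups` (named vector), and `truth` (list: `root`,
#'   `discordant` tibble of `column`, `group`, `residue`).
#' @export
generate_alignment <- function(n_seqs = 10L, ncols = 120L, groups = NULL,
                               discordant_columns = integer(0),
                               mutation_rate = 0, seed = 1L) {
  if (mutation_rate < 0 || mutation_rate >= 1) {
    abort("mutation_rate must be in [0, 1)", class = "epitopr_error_synth_spec")
  }
  if (length(discordant_columns) > 0 &&
      (min(discordant_columns) < 1 || max(discordant_columns) > ncols)) {
    abort("discordant columns outside alignment",
          class = "epitopr_error_synth_spec")
  }
  if (is.null(groups)) {
    ids <- sprintf("seq%02d", seq_len(n_seqs))
    groups <- setNames(ifelse(seq_len(n_seqs) <= ceiling(n_seqs / 2), "A", "B"),
                       ids)
  }
  ids <- names(groups)
  stopifnot(length(ids) == n_seqs)
  levels <- sort(unique(unname(groups)))
  with_seed(seed, {
    root <- sample(AA20, ncols, replace = TRUE)
    disc <- list()
    disc_res <- list()
    for (j in discordant_columns) {
      res <- sample(AA20, length(levels), replace = FALSE)
      disc_res[[as.character(j)]] <- setNames(res, levels)
      disc[[length(disc) + 1L]] <- tibble(column = as.integer(j),
                                          group = levels, residue = res)
    }
    rows <- purrr::map_chr(ids, function(id) {
      chars <- root
      if (mutation_rate > 0) {
        hit <- stats::runif(ncols) < mutation_rate
        chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
      }
      for (j in discordant_columns) {
        chars[j] <- disc_res[[as.character(j)]][[groups[[id]]]]
      }
      paste(chars, collapse = "")
    })
    list(
      aln = tibble(id = ids, residues = rows, length = nchar(rows)),
      groups = groups,
      truth = list(root = paste(root, collapse = ""),
                   discordant = bind_rows(disc))
    )
  })
}

#' Expected pairwise identity under the alignment mutation model
#'
#' Two rows match at a non-discordant column when neither mutated, or the
#' mutated draw(s) coincide: `(1 - r)^2 + (1 - (1 - r)^2) / A` with
#' alphabet size `A = 20`.
#'
#' @param rate Per-column mutation rate.
#' @param alphabet_size Residue alphabet size (default 20).
#' @return Expected identity in `[0, 1]`.
#' @export
expected_pairwise_identity <- function(rate, alphabet_size = 20) {
  keep2 <- (1 - rate)^2
  keep2 + (1 - keep2) / alphabet_size
}

#' Mean observed pairwise identity of an alignment
#'
#' Arithmetic mean, over all unordered row pairs, of the fraction of
#' columns with identical residues (gap-free alignments).
#'
#' @param aln Alignment tibble.
#' @return Mean pairwise identity in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(aln) {
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p) mean(mat[p[1], ] == mat[p[2], ])))
}

# Evaluate code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
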