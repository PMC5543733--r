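#' Chou-Fasman secondary-structure assignment
#'
#' Classical nucleation-extension assignment over the four states H
#' (alpha-helix), E (beta-sheet), T (beta-turn), C (random coil):
#'
#' * Helix nucleates wherever at least 4 of 6 consecutive residues have
#'   helix propensity above `helix_former_cutoff`; each nucleus extends in
#'   both directions while the running tetrapeptide mean propensity stays at
#'   or above `extension_floor`.
#' * Strand nucleates wherever at least 3 of 5 consecutive residues exceed
#'   `strand_former_cutoff`, and extends analogously.
#' * Helix/strand overlaps are resolved per overlapping run by the larger of
#'   regional mean helix vs strand propensity; exact ties go to the softer
#'   state in the package-wide tie-break order T, C, E, H.
#' * A beta-turn is called at position i when the tetrapeptide bend
#'   probability `f(i) f(i+1) f(i+2) f(i+3)` exceeds
#'   `turn_tetrapeptide_cutoff`, the mean turn propensity over the
#'   tetrapeptide exceeds 1.00, and it also exceeds the tetrapeptide's mean
#'   helix and strand propensities; the four positions are assigned T,
#'   overriding helix/strand.
#' * Everything else is coil.
#'
#' All cutoffs are parameters (classical published defaults), not
#' hard-coded behavior.
#'
#' @param seqs Protein records tibble (`id`, `residues`), length >= 6.
#' @param params Parameter table as from [cf_params()].
#' @param helix_former_cutoff,strand_former_cutoff Propensity a residue must
#'   exceed to count as a former (defaults 1.03, 1.05).
#' @param turn_tetrapeptide_cutoff Bend-probability cutoff (default 7.5e-5).
#' @param extension_floor Running tetrapeptide mean below which extension
#'   stops (default 1.00).
#' @return Tibble with columns `sequence_id`, `position`, `state`
#'   (factor-free character in H/E/T/C), `method = "chou-fasman"`.
#' @export
chou_fasman <- function(seqs, params = cf_params(),
                        helix_former_cutoff = 1.03,
                        strand_former_cutoff = 1.05,
                        turn_tetrapeptide_cutoff = 7.5e-5,
                        extension_floor = 1.00) {
  if (min(seqs$length) < 6) {
    abort("Chou-Fasman needs sequences of length >= 6",
          class = "epitopr_error_short_sequence")
  }
  pa_l <- setNames(params$p_helix, params$residue)
  pb_l <- setNames(params$p_strand, params$residue)
  pt_l <- setNames(params$p_turn, params$residue)
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    chars <- strsplit(res, "")[[1]]
    L <- length(chars)
    pa <- unname(pa_l[chars]); pb <- unname(pb_l[chars]); pt <- unname(pt_l[chars])

    helix <- nucleate_extend(pa, helix_former_cutoff, win = 6L, need = 4L,
                             floor = extension_floor)
    strand <- nucleate_extend(pb, strand_former_cutoff, win = 5L, need = 3L,
                              floor = extension_floor)

    state <- rep("C", L)
    state[helix] <- "H"
    state[strand & !helix] <- "E"
    # overlapping runs: regional mean propensity decides; ties soften to E
    both <- helix & strand
    for (run in runs_of(both)) {
      idx <- run[1]:run[2]
      ma <- mean(pa[idx]); mb <- mean(pb[idx])
      state[idx] <- if (ma > mb) "H" else "E"
    }

    tp <- turn_probability(chars, params)
    for (i in seq_len(L - 3L)) {
      idx <- i:(i + 3L)
      mt <- mean(pt[idx])
      if (tp[i] > turn_tetrapeptide_cutoff && mt > 1.00 &&
          mt > mean(pa[idx]) && mt > mean(pb[idx])) {
        state[idx] <- "T"
      }
    }
    tibble(sequence_id = id, position = seq_len(L), state = state,
           method = "chou-fasman")
  }) |>
    bind_rows()
}

# Union of all nucleation windows (>= `need` formers among `win` consecutive
# residues), each maximal seeded run then extended outward while the
# tetrapeptide mean at the growing edge stays >= floor (window shrunk at the
# sequence ends). Returns a logical vector. Scan order cannot matter: the
# seed set is a union and extension is per maximal run.
nucleate_extend <- function(p, cutoff, win, need, floor) {
  L <- length(p)
  seeded <- rep(FALSE, L)
  former <- p > cutoff
  if (L >= win) {
    cs <- cumsum(c(0L, former))
    for (i in seq_len(L - win + 1L)) {
      if (cs[i + win] - cs[i] >= need) seeded[i:(i + win - 1L)] <- TRUE
    }
  }
  out <- seeded
  for (run in runs_of(seeded)) {
    j <- run[2]
    while (j < L && mean(p[max(1L, j + 1L - 3L):(j + 1L)]) >= floor) {
      j <- j + 1L
      out[j] <- TRUE
    }
    j <- run[1]
    while (j > 1L && mean(p[(j - 1L):min(L, j - 1L + 3L)]) >= floor) {
      j <- j - 1L
      out[j] <- TRUE
    }
  }
  out
}

# Maximal runs of TRUE in a logical vector, as a list of c(start, end).
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], c)
}

turn_probability <- function(chars, params) {
  f1 <- setNames(params$f1, params$residue)
  f2 <- setNames(params$f2, params$residue)
  f3 <- setNames(params$f3, params$residue)
  f4 <- setNames(params$f4, params$residue)
  L <- length(chars)
  if (L < 4L) return(numeric(0))
  i <- seq_len(L - 3L)
  unname(f1[chars[i]] * f2[chars[i + 1L]] * f3[chars[i + 2L]] * f4[chars[i + 3L]])
}

#' Tetrapeptide turn-probability track
#'
#' The bend statistic behind the Chou-Fasman turn call: at position i, the
#' product of the four positional bend frequencies
#' `f1(i) f2(i+1) f3(i+2) f4(i+3)`. Defined for positions 1..L-3.
#'
#' @inheritParams chou_fasman
#' @return Tibble with `sequence_id`, `position`, `p_turn`, `defined`.
#' @export
turn_propensity <- function(seqs, params = cf_params()) {
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    chars <- strsplit(res, "")[[1]]
    L <- length(chars)
    tp <- turn_probability(chars, params)
    tibble(sequence_id = id, position = seq_len(L),
           p_turn = c(tp, rep(NA_real_, min(L, 3L))),
           defined = c(rep(TRUE, length(tp)), rep(FALSE, min(L, 3L))))
  }) |>
    bind_rows()
}

#' GOR-style secondary-structure assignment
#'
#' Directional-information predictor: each state's score at position i is
#' the sum, over neighbor offsets -8..+8 that fall inside the sequence, of
#' the information value contributed by the residue at that offset, minus
#' the state's decision constant; the assigned state is the argmax, with
#' exact ties resolved by the declared tie-break order (default T, C, E, H —
#' softer states first, so a position is only called rigid unambiguously).
#'
#' @inheritParams chou_fasman
#' @param table Directional-information table as from [gor_info()]
#'   (columns `state`, `residue`, `offset`, `info`; must be total over
#'   4 states x 20 residues x offsets -8..8).
#' @param decision_constants Named numeric (H, E, T, C), default all 0.
#' @param tie_break Character permutation of H/E/T/C.
#' @return Tibble with `sequence_id`, `position`, `state`,
#'   `method = "garnier-robson"`, plus one score column per state.
#' @export
garnier_robson <- function(seqs, table = gor_info(),
                           decision_constants = c(H = 0, E = 0, T = 0, C = 0),
                           tie_break = c("T", "C", "E", "H")) {
  stopifnot(setequal(tie_break, c("H", "E", "T", "C")))
  arr <- gor_table_array(table)
  dc <- decision_constants[tie_break]
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    chars <- strsplit(res, "")[[1]]
    L <- length(chars)
    ri <- match(chars, AA20)
    scores <- matrix(0, nrow = L, ncol = 4L,
                     dimnames = list(NULL, tie_break))
    for (d in -8:8) {
      src <- seq_len(L) + d
      ok <- src >= 1L & src <= L
      for (s in tie_break) {
        scores[ok, s] <- scores[ok, s] + arr[s, , as.character(d)][ri[src[ok]]]
      }
    }
    scores <- sweep(scores, 2L, dc, "-")
    state <- tie_break[max.col(scores, ties.method = "first")]
    out <- tibble(sequence_id = id, position = seq_len(L), state = state,
                  method = "garnier-robson")
    st_order <- c("H", "E", "T", "C")
    for (s in st_order) out[[paste0("score_", s)]] <- scores[, s]
    out
  }) |>
    bind_rows()
}

# state x residue x offset array, validated total.
gor_table_array <- function(table) {
  states <- c("H", "E", "T", "C")
  arr <- array(NA_real_, dim = c(4L, 20L, 17L),
               dimnames = list(states, AA20, as.character(-8:8)))
  arr[cbind(match(table$state, states), match(table$residue, AA20),
            match(table$offset, -8:8))] <- table$info
  if (anyNA(arr)) {
    abort("information table is missing state/residue/offset entries",
          class = "epitopr_error_gor_table")
  }
  arr
}

#' Consensus of two secondary-structure tracks
#'
#' Where the two methods agree, the agreed state; where they disagree, the
#' softer of the two states in the fixed order T > C > E > H (softest
#' first). A position is therefore only called rigid (H or E) when both
#' methods call it rigid — a deliberately epitope-permissive consensus,
#' since downstream selection only penalizes rigid fractions.
#'
#' @param cf,gr Structure-track tibbles (`sequence_id`, `position`,
#'   `state`) over the same sequences.
#' @return Tibble `sequence_id`, `position`, `state`, `method = "consensus"`.
#' @export
consensus_track <- function(cf, gr) {
  a <- dplyr::select(cf, "sequence_id", "position", cf_state = "state")
  b <- dplyr::select(gr, "sequence_id", "position", gr_state = "state")
  if (nrow(a) != nrow(b)) {
    abort("track length mismatch", class = "epitopr_error_track_mismatch")
  }
  j <- dplyr::inner_join(a, b, by = c("sequence_id", "position"))
  if (nrow(j) != nrow(a)) {
    abort("tracks cover different sequences/positions",
          class = "epitopr_error_track_mismatch")
  }
  soft <- c(T = 1L, C = 2L, E = 3L, H = 4L)
  j |>
    mutate(
      state = dplyr::if_else(soft[.data$cf_state] <= soft[.data$gr_state],
                             .data$cf_state, .data$gr_state),
      method = "consensus"
    ) |>
    select("sequence_id", "position", "state", "method")
}
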