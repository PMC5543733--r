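#' Selection criteria for epitope nomination
#'
#' Bundles every numeric threshold the selection stage consumes. The
#' published criteria behind them are qualitative (at least eight residues;
#' turn/coil rather than rigid helix/sheet structure; good hydrophilicity,
#' accessibility, flexibility and antigenicity; avoid active-site
#' segments), so each has an explicit numeric default here and is echoed in
#' every report.
#'
#' @param min_length Minimum candidate length (default 8).
#' @param ai_threshold Antigenic-index seed threshold for segment
#'   extraction.
#' @param hydrophilicity_min Hydrophilicity seed threshold (windowed
#'   Hopp-Woods units).
#' @param surface_min Minimum mean surface probability (1 = random
#'   expectation).
#' @param flexibility_min Minimum mean flexibility index (1 = average).
#' @param max_rigid_fraction Maximum tolerated fraction of rigid (H or E)
#'   consensus states within a candidate.
#' @param gap_merge Runs separated by at most this many positions are
#'   merged.
#' @param forbidden_regions List of `c(start, end)` 1-based inclusive
#'   intervals (e.g. active peptides) that no passed candidate may overlap.
#'   Empty by default: active-site avoidance is a design consideration to
#'   opt into, not an always-on step.
#' @param rank_weights Nonnegative weights for the composite ranking score
#'   over (ai, hydrophilicity, surface, flexibility); default equal.
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_length = 8L,
                               ai_threshold = 0.15,
                               hydrophilicity_min = 0.25,
                               surface_min = 1.0,
                               flexibility_min = 1.0,
                               max_rigid_fraction = 0.3,
                               gap_merge = 2L,
                               forbidden_regions = list(),
                               rank_weights = c(ai = 1, hydrophilicity = 1,
                                                surface = 1, flexibility = 1)) {
  if (min_length < 1) {
    abort("min_length must be >= 1", class = "epitopr_error_criteria")
  }
  if (max_rigid_fraction < 0 || max_rigid_fraction > 1) {
    abort("max_rigid_fraction must be in [0, 1]",
          class = "epitopr_error_criteria")
  }
  for (fr in forbidden_regions) {
    if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 1) {
      abort("forbidden_regions entries must be c(start, end), start <= end",
            class = "epitopr_error_criteria")
    }
  }
  structure(
    list(min_length = as.integer(min_length), ai_threshold = ai_threshold,
         hydrophilicity_min = hydrophilicity_min, surface_min = surface_min,
         flexibility_min = flexibility_min,
         max_rigid_fraction = max_rigid_fraction,
         gap_merge = as.integer(gap_merge),
         forbidden_regions = forbidden_regions,
         rank_weights = rank_weights),
    class = "selection_criteria"
  )
}

#' Extract maximal candidate segments from the antigenic-index track
#'
#' Returns every maximal run of consecutive positions where the antigenic
#' index is at least `ai_threshold` and the hydrophilicity profile is at
#' least `hydrophilicity_min` (both defined); adjacent runs separated by at
#' most `gap_merge` positions are merged. Candidates are unfiltered: every
#' run, however short, is reported and flagged later.
#'
#' @param ai Antigenic-index track from [antigenic_index()].
#' @param hydro Hydrophilicity profile over the same sequences.
#' @param seqs Protein records tibble (for the peptide strings).
#' @param criteria A [selection_criteria()] object.
#' @return Candidate tibble: `sequence_id`, `start`, `end`, `length`,
#'   `peptide`, `mean_ai`, `mean_hydrophilicity`.
#' @export
extract_segments <- function(ai, hydro, seqs, criteria = selection_criteria()) {
  if (!inherits(criteria, "selection_criteria")) {
    abort("criteria must come from selection_criteria()",
          class = "epitopr_error_criteria")
  }
  purrr::map(unique(ai$sequence_id), function(sid) {
    a <- dplyr::filter(ai, .data$sequence_id == sid) |> arrange(.data$position)
    h <- dplyr::filter(hydro, .data$sequence_id == sid) |> arrange(.data$position)
    res <- seqs$residues[match(sid, seqs$id)]
    ok <- a$defined & h$defined &
      !is.na(a$ai) & a$ai >= criteria$ai_threshold &
      !is.na(h$value) & h$value >= criteria$hydrophilicity_min
    segs <- merge_runs(runs_of(ok), criteria$gap_merge)
    purrr::map(segs, function(run) {
      idx <- run[1]:run[2]
      tibble(
        sequence_id = sid,
        start = as.integer(run[1]), end = as.integer(run[2]),
        length = as.integer(run[2] - run[1] + 1L),
        peptide = substr(res, run[1], run[2]),
        mean_ai = mean(a$ai[idx], na.rm = TRUE),
        mean_hydrophilicity = mean(h$value[idx], na.rm = TRUE)
      )
    }) |> bind_rows()
  }) |>
    bind_rows() -> out
  if (nrow(out) == 0) {
    out <- tibble(sequence_id = character(), start = integer(),
                  end = integer(), length = integer(), peptide = character(),
                  mean_ai = numeric(), mean_hydrophilicity = numeric())
  }
  out
}

merge_runs <- function(runs, gap_merge) {
  if (length(runs) <= 1) return(runs)
  out <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- out[[length(out)]]
    if (r[1] - last[2] - 1L <= gap_merge) {
      out[[length(out)]] <- c(last[1], r[2])
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Apply the multi-criterion epitope filter
#'
#' Each candidate is tested in a fixed, reportable order —
#' `overlaps_forbidden`, `too_short`, `rigid_structure`, `low_surface`,
#' `low_hydrophilicity`, `low_flexibility` — and the first failed test names
#' the single `rejection_reason` (mirroring the narrative reasons used to
#' discard candidates: segments too short to be effective epitopes, a
#' hydrophilic segment hidden from the surface, a rigid alpha-helix that
#' would hinder antibody interaction). The full per-criterion boolean
#' vector is retained alongside.
#'
#' @param candidates Candidate tibble from [extract_segments()].
#' @param structure Consensus structure track ([consensus_track()]).
#' @param surface,flex Surface-probability and flexibility profiles.
#' @param criteria A [selection_criteria()] object.
#' @return The candidate tibble with `mean_surface`, `mean_flexibility`,
#'   `rigid_fraction`, per-criterion `ok_*` flags, `passed`, and
#'   `rejection_reason`.
#' @export
filter_candidates <- function(candidates, structure, surface, flex,
                              criteria = selection_criteria()) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, mean_surface = numeric(0),
                  mean_flexibility = numeric(0), rigid_fraction = numeric(0),
                  ok_forbidden = logical(0), ok_length = logical(0),
                  ok_rigid = logical(0), ok_surface = logical(0),
                  ok_hydrophilicity = logical(0), ok_flexibility = logical(0),
                  passed = logical(0), rejection_reason = character(0)))
  }
  rows <- purrr::pmap(candidates, function(sequence_id, start, end, ...) {
    st <- dplyr::filter(structure, .data$sequence_id == !!sequence_id,
                        .data$position >= start, .data$position <= end)
    su <- dplyr::filter(surface, .data$sequence_id == !!sequence_id,
                        .data$position >= start, .data$position <= end,
                        .data$defined)
    fl <- dplyr::filter(flex, .data$sequence_id == !!sequence_id,
                        .data$position >= start, .data$position <= end,
                        .data$defined)
    tibble(
      mean_surface = mean(su$value),
      mean_flexibility = mean(fl$value),
      rigid_fraction = mean(st$state %in% c("H", "E"))
    )
  }) |> bind_rows()
  out <- dplyr::bind_cols(candidates, rows)
  overlaps_forbidden <- vapply(seq_len(nrow(out)), function(i) {
    any(vapply(criteria$forbidden_regions, function(fr) {
      out$start[i] <= fr[2] && out$end[i] >= fr[1]
    }, logical(1)))
  }, logical(1))
  out <- out |>
    mutate(
      ok_forbidden = !overlaps_forbidden,
      ok_length = .data$length >= criteria$min_length,
      ok_rigid = .data$rigid_fraction <= criteria$max_rigid_fraction,
      ok_surface = .data$mean_surface >= criteria$surface_min,
      ok_hydrophilicity = .data$mean_hydrophilicity >= criteria$hydrophilicity_min,
      ok_flexibility = .data$mean_flexibility >= criteria$flexibility_min
    )
  reason_order <- c(overlaps_forbidden = "ok_forbidden",
                    too_short = "ok_length",
                    rigid_structure = "ok_rigid",
                    low_surface = "ok_surface",
                    low_hydrophilicity = "ok_hydrophilicity",
                    low_flexibility = "ok_flexibility")
  reasons <- vapply(seq_len(nrow(out)), function(i) {
    failed <- names(reason_order)[!unlist(out[i, reason_order])]
    if (length(failed) == 0) "none" else failed[1]
  }, character(1))
  out |>
    mutate(rejection_reason = reasons, passed = reasons == "none")
}

#' Rank passed candidates by a composite criterion score
#'
#' Each passed candidate's criterion means (antigenic index,
#' hydrophilicity, surface, flexibility) are z-scored across the passed
#' cohort and combined by a weighted sum (equal weights by default). Ties
#' break toward the longer candidate, then the smaller start position.
#' Failed candidates keep `rank = NA`.
#'
#' @param candidates Flagged candidate tibble from [filter_candidates()].
#' @param criteria A [selection_criteria()] object (supplies
#'   `rank_weights`).
#' @return The candidate tibble with `composite_score` and `rank`, sorted
#'   passed-first by rank.
#' @export
rank_candidates <- function(candidates, criteria = selection_criteria()) {
  w <- criteria$rank_weights
  stopifnot(setequal(names(w), c("ai", "hydrophilicity", "surface", "flexibility")),
            all(w >= 0))
  if (nrow(candidates) == 0) {
    return(mutate(candidates, composite_score = numeric(0), rank = integer(0)))
  }
  zscore <- function(x) {
    if (length(x) < 2 || sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / sd(x)
  }
  passed <- dplyr::filter(candidates, .data$passed)
  if (nrow(passed) > 0) {
    z <- w[["ai"]] * zscore(passed$mean_ai) +
      w[["hydrophilicity"]] * zscore(passed$mean_hydrophilicity) +
      w[["surface"]] * zscore(passed$mean_surface) +
      w[["flexibility"]] * zscore(passed$mean_flexibility)
    passed$composite_score <- z / sum(w)
    ord <- order(-passed$composite_score, -passed$length, passed$start)
    passed$rank <- NA_integer_
    passed$rank[ord] <- seq_len(nrow(passed))
  } else {
    passed <- mutate(passed, composite_score = numeric(0), rank = integer(0))
  }
  failed <- dplyr::filter(candidates, !.data$passed) |>
    mutate(composite_score = NA_real_, rank = NA_integer_)
  bind_rows(passed, failed) |>
    arrange(is.na(.data$rank), .data$rank, .data$sequence_id, .data$start)
}

#' Terminal-cysteine conjugation note
#'
#' Carrier-protein coupling chemistry (maleimide-activated KLH/BSA) needs a
#' free thiol, so a candidate peptide that already begins or ends with
#' cysteine is conjugation-ready; otherwise a terminal Cys would have to be
#' added. Annotation only — never affects pass/fail.
#'
#' @param peptide Character vector of peptides.
#' @return Character vector: `"conjugation-ready (N-terminal Cys)"`,
#'   `"conjugation-ready (C-terminal Cys)"`, or
#'   `"requires added terminal Cys"`.
#' @export
#' @examples
#' terminal_cys_note("CPVLRLSNRTHEANRNDLIKVA")
terminal_cys_note <- function(peptide) {
  first <- substr(peptide, 1, 1) == "C"
  last <- substr(peptide, nchar(peptide), nchar(peptide)) == "C"
  dplyr::case_when(
    first ~ "conjugation-ready (N-terminal Cys)",
    last ~ "conjugation-ready (C-terminal Cys)",
    TRUE ~ "requires added terminal Cys"
  )
}

#' Jaccard index of two 1-based inclusive intervals
#'
#' @param a,b Intervals as `c(start, end)`.
#' @return Intersection length over union length (0 when disjoint).
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}
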