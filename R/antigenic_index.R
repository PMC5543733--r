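#' Discretize a continuous profile onto bounded score levels
#'
#' The composite antigenic index combines components on a common bounded
#' score set rather than raw scales. A profile value `v` receives
#' `levels[1]` when `v < thresholds[1]`, `levels[j + 1]` when
#' `thresholds[j] <= v < thresholds[j + 1]`, and the top level when
#' `v >= thresholds[k]`. Masked positions stay masked.
#'
#' @param profile Long profile tibble ([windowed_profile()] and friends).
#' @param thresholds Strictly increasing numeric vector.
#' @param levels Score levels, one more than `thresholds`; default the
#'   bounded set `-0.6, -0.3, -0.1, 0, 0.1, 0.3, 0.6`.
#' @return Tibble `sequence_id`, `position`, `score`, `defined`.
#' @export
discretize_profile <- function(profile, thresholds,
                               levels = c(-0.6, -0.3, -0.1, 0, 0.1, 0.3, 0.6)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing",
          class = "epitopr_error_thresholds")
  }
  if (length(levels) != length(thresholds) + 1L) {
    abort("need exactly one more score level than thresholds",
          class = "epitopr_error_thresholds")
  }
  profile |>
    mutate(score = dplyr::if_else(
      .data$defined,
      levels[findInterval(.data$value, thresholds) + 1L],
      NA_real_
    )) |>
    select("sequence_id", "position", "score", "defined")
}

#' Map a secondary-structure track onto score levels
#'
#' Direct state-to-score mapping for the two structure components of the
#' antigenic index: flexible states (T, C) score high, rigid states (H, E)
#' low.
#'
#' @param track Structure-track tibble (`sequence_id`, `position`, `state`).
#' @param state_scores Named numeric over H, E, T, C; default
#'   `H = -0.6, E = -0.3, C = 0.3, T = 0.6`.
#' @return Tibble `sequence_id`, `position`, `score`, `defined` (always
#'   TRUE: structure tracks are total).
#' @export
discretize_structure <- function(track,
                                 state_scores = c(H = -0.6, E = -0.3,
                                                  C = 0.3, T = 0.6)) {
  if (!all(c("H", "E", "T", "C") %in% names(state_scores))) {
    abort("state_scores must cover H, E, T, C",
          class = "epitopr_error_thresholds")
  }
  track |>
    mutate(score = unname(state_scores[.data$state]), defined = TRUE) |>
    select("sequence_id", "position", "score", "defined")
}

#' Composite antigenic index
#'
#' Weighted sum of the five discretized component tracks — hydrophilicity,
#' surface probability, flexibility, and the two secondary-structure tracks
#' — in the spirit of the classical composite antigenicity construction.
#' Weights must be nonnegative and sum to 1, so the index is a convex
#' combination bounded by the component score levels. A position is masked
#' whenever any component is masked there.
#'
#' @param components Named list of five discretized tracks (from
#'   [discretize_profile()] / [discretize_structure()]) with names
#'   `hydrophilicity`, `surface`, `flexibility`, `cf_structure`,
#'   `gr_structure`, all over the same sequences.
#' @param weights Named nonnegative numeric over the same five names,
#'   summing to 1. Default `0.3, 0.15, 0.15, 0.2, 0.2`.
#' @return Tibble with `sequence_id`, `position`, `ai`, `defined`, and one
#'   `score_*` column per component.
#' @export
antigenic_index <- function(components, weights = default_ai_weights()) {
  comp_names <- c("hydrophilicity", "surface", "flexibility",
                  "cf_structure", "gr_structure")
  if (!setequal(names(components), comp_names)) {
    abort(paste("components must be named:", paste(comp_names, collapse = ", ")),
          class = "epitopr_error_components")
  }
  weights <- weights[comp_names]
  if (anyNA(weights) || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("weights must be nonnegative over the five components and sum to 1",
          class = "epitopr_error_weights")
  }
  n <- vapply(components, nrow, integer(1))
  if (length(unique(n)) != 1) {
    abort("component tracks have different lengths",
          class = "epitopr_error_track_mismatch")
  }
  joined <- purrr::reduce(comp_names, .init = NULL, function(acc, nm) {
    tr <- components[[nm]] |>
      dplyr::rename_with(~ paste0(., "_", nm), c("score", "defined"))
    if (is.null(acc)) tr else
      dplyr::inner_join(acc, tr, by = c("sequence_id", "position"))
  })
  if (nrow(joined) != n[[1]]) {
    abort("component tracks cover different sequences/positions",
          class = "epitopr_error_track_mismatch")
  }
  score_cols <- paste0("score_", comp_names)
  def_cols <- paste0("defined_", comp_names)
  sc <- as.matrix(joined[score_cols])
  def <- Reduce(`&`, joined[def_cols])
  ai <- as.numeric(sc %*% weights)
  ai[!def] <- NA_real_
  out <- tibble(
    sequence_id = joined$sequence_id,
    position = joined$position,
    ai = ai,
    defined = def
  )
  out[score_cols] <- joined[score_cols]
  out
}

#' @rdname antigenic_index
#' @export
default_ai_weights <- function() {
  c(hydrophilicity = 0.3, surface = 0.15, flexibility = 0.15,
    cf_structure = 0.2, gr_structure = 0.2)
}
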