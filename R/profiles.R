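#' Sliding-window propensity profile
#'
#' Computes a per-residue profile by averaging a residue scale over a
#' sliding window. The window value is assigned to the center residue
#' (position `ceiling(window / 2)` within the window). Positions where the
#' full window does not fit are masked (`defined = FALSE`, `value = NA`)
#' under the default edge policy; `edge_policy = "shrink"` instead averages
#' over the in-bounds part of the window, for display parity with
#' full-length profile plots.
#'
#' @param seqs Tibble of protein records (columns `id`, `residues`), as from
#'   [read_fasta()] or [protein()].
#' @param scale A scale tibble from [aa_scale()], or a scale name.
#' @param window Window width, a positive integer no longer than the
#'   shortest sequence. Odd widths center exactly; even widths anchor
#'   center-left.
#' @param edge_policy `"mask"` (default) or `"shrink"`.
#' @param method Label stored in the `method` column; defaults to the scale
#'   name.
#' @return A long tibble with columns `sequence_id`, `position` (1-based),
#'   `method`, `value`, `defined`.
#' @export
#' @examples
#' windowed_profile(protein("GGGGGGG"), aa_scale("hopp-woods"), window = 7)
windowed_profile <- function(seqs, scale, window = 7,
                             edge_policy = c("mask", "shrink"),
                             method = NULL) {
  edge_policy <- match.arg(edge_policy)
  if (is.character(scale)) scale <- aa_scale(scale)
  lookup <- scale_lookup(scale)
  method <- method %||% attr(scale, "scale_name") %||% "windowed"
  check_window(window, min(seqs$length))
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    v <- lookup[strsplit(res, "")[[1]]]
    win_mean_profile(id, method, v, window, rep(1, window), edge_policy)
  }) |>
    bind_rows()
}

#' Hydrophilicity profile
#'
#' Sliding-window hydrophilicity with the Hopp-Woods scale by default
#' (window 7). `"kyte-doolittle"` may be selected instead; its hydropathy
#' values are negated on the fly so that high always means hydrophilic,
#' whichever scale is active.
#'
#' @inheritParams windowed_profile
#' @param scale `"hopp-woods"` (default) or `"kyte-doolittle"`.
#' @return Long profile tibble (see [windowed_profile()]); `method` is
#'   `"hydrophilicity"`.
#' @export
hydrophilicity_profile <- function(seqs, scale = "hopp-woods", window = 7,
                                   edge_policy = c("mask", "shrink")) {
  tbl <- aa_scale(scale)
  if (identical(attr(tbl, "scale_name"), "kyte-doolittle")) {
    tbl$value <- -tbl$value
  }
  windowed_profile(seqs, tbl, window, edge_policy, method = "hydrophilicity")
}

#' Emini surface-probability profile
#'
#' For every hexapeptide window, the product of the six fractional surface
#' probabilities divided by the random expectation `0.37^6`. Values above 1
#' indicate above-random surface exposure. The even window cannot center on
#' a residue: the value is anchored to the first residue of the hexapeptide
#' by default (`anchor = "first"`), or to the center-left residue (third of
#' six) with `anchor = "center-left"`; the anchoring convention is explicit
#' because the one used by the legacy desktop implementations is
#' undocumented.
#'
#' @inheritParams windowed_profile
#' @param scale Scale with `combine_mode` product-ratio; default
#'   `"emini-surface"`.
#' @param anchor `"first"` or `"center-left"`.
#' @return Long profile tibble; `method` is `"surface"`.
#' @export
surface_probability_profile <- function(seqs, scale = "emini-surface",
                                        anchor = c("first", "center-left")) {
  anchor <- match.arg(anchor)
  if (is.character(scale)) scale <- aa_scale(scale)
  if (!identical(attr(scale, "combine_mode"), "product-ratio")) {
    abort("surface probability needs a product-ratio scale",
          class = "epitopr_error_scale_mode")
  }
  if (min(seqs$length) < 6) {
    abort("sequence shorter than the hexapeptide window (6)",
          class = "epitopr_error_short_sequence")
  }
  lookup <- scale_lookup(scale)
  anchor_off <- if (anchor == "first") 0L else 2L
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    v <- unname(lookup[strsplit(res, "")[[1]]])
    L <- length(v)
    starts <- seq_len(L - 5L)
    wins <- vapply(starts, function(i) prod(v[i:(i + 5L)]) / 0.37^6, numeric(1))
    value <- rep(NA_real_, L)
    value[starts + anchor_off] <- wins
    tibble(sequence_id = id, position = seq_len(L), method = "surface",
           value = value, defined = !is.na(value))
  }) |>
    bind_rows()
}

#' Karplus-Schulz flexibility profile
#'
#' Weighted sliding-window mean of per-residue flexibility indices with a
#' symmetric, center-peaked weight vector (default
#' `0.25, 0.4375, 0.625, 1, 0.625, 0.4375, 0.25`, renormalized to sum 1).
#' With equal weights this reduces exactly to [windowed_profile()].
#'
#' @inheritParams windowed_profile
#' @param window Odd window width, default 7.
#' @param weights Numeric weight vector of length `window`; renormalized.
#' @return Long profile tibble; `method` is `"flexibility"`.
#' @export
flexibility_profile <- function(seqs, scale = "karplus-schulz", window = 7,
                                weights = NULL,
                                edge_policy = c("mask", "shrink")) {
  edge_policy <- match.arg(edge_policy)
  if (is.character(scale)) scale <- aa_scale(scale)
  if (window %% 2 == 0) {
    abort("flexibility window must be odd", class = "epitopr_error_window")
  }
  check_window(window, min(seqs$length))
  weights <- weights %||% default_flex_weights(window)
  if (length(weights) != window || any(weights < 0) || sum(weights) == 0) {
    abort("weights must be nonnegative, length equal to window",
          class = "epitopr_error_weights")
  }
  lookup <- scale_lookup(scale)
  purrr::map2(seqs$id, seqs$residues, function(id, res) {
    v <- lookup[strsplit(res, "")[[1]]]
    win_mean_profile(id, "flexibility", v, window, weights, edge_policy)
  }) |>
    bind_rows()
}

default_flex_weights <- function(window = 7) {
  if (window == 7) {
    c(0.25, 0.4375, 0.625, 1, 0.625, 0.4375, 0.25)
  } else {
    half <- (window - 1) / 2
    1 - abs(seq(-half, half)) / (half + 1)
  }
}

# Shared windowed (weighted-)mean kernel. Anchors each window's value at its
# ceiling(w/2)-th residue; "shrink" renormalizes over the in-bounds part.
win_mean_profile <- function(id, method, v, window, weights, edge_policy) {
  v <- unname(v)
  L <- length(v)
  w <- as.integer(window)
  wts <- weights / sum(weights)
  anchor_off <- as.integer(ceiling(w / 2)) - 1L
  value <- rep(NA_real_, L)
  defined <- rep(FALSE, L)
  starts <- seq_len(L - w + 1L)
  full <- vapply(starts, function(i) sum(v[i:(i + w - 1L)] * wts), numeric(1))
  value[starts + anchor_off] <- full
  defined[starts + anchor_off] <- TRUE
  if (edge_policy == "shrink") {
    for (p in which(!defined)) {
      lo <- max(1L, p - anchor_off)
      hi <- min(L, p + (w - 1L - anchor_off))
      wk <- weights[(lo - (p - anchor_off) + 1L):(hi - (p - anchor_off) + 1L)]
      value[p] <- sum(v[lo:hi] * wk / sum(wk))
    }
    defined <- rep(TRUE, L)
  }
  tibble(sequence_id = id, position = seq_len(L), method = method,
         value = value, defined = defined)
}

check_window <- function(window, min_len) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != as.integer(window)) {
    abort("window must be a positive integer", class = "epitopr_error_window")
  }
  if (window > min_len) {
    abort(sprintf("window (%d) longer than shortest sequence (%d)",
                  as.integer(window), as.integer(min_len)),
          class = "epitopr_error_window")
  }
  invisible(TRUE)
}
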