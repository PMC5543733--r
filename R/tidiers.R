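#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an epitope scan into its candidate table
#'
#' @param x An `epitope_scan` from [predict_epitopes()].
#' @param ... Unused.
#' @return The ranked candidate tibble (one row per candidate segment).
#' @export
tidy.epitope_scan <- function(x, ...) {
  x$candidates
}

#' One-row summary of an epitope scan
#'
#' @inheritParams tidy.epitope_scan
#' @return Tibble with `n_sequences`, `n_candidates`, `n_passed`,
#'   `top_peptide`, `top_start`, `top_end`, `top_score`.
#' @export
glance.epitope_scan <- function(x, ...) {
  top <- dplyr::filter(x$candidates, !is.na(.data$rank), .data$rank == 1L)
  tibble(
    n_sequences = nrow(x$seqs),
    n_candidates = nrow(x$candidates),
    n_passed = sum(x$candidates$passed),
    top_peptide = if (nrow(top)) top$peptide[1] else NA_character_,
    top_start = if (nrow(top)) top$start[1] else NA_integer_,
    top_end = if (nrow(top)) top$end[1] else NA_integer_,
    top_score = if (nrow(top)) top$composite_score[1] else NA_real_
  )
}

#' @export
print.epitope_scan <- function(x, ...) {
  g <- glance(x)
  cat("<epitope_scan> ", g$n_sequences, " sequence(s), ",
      g$n_candidates, " candidate(s), ", g$n_passed, " passed\n", sep = "")
  if (!is.na(g$top_peptide)) {
    cat("rank 1: ", g$top_start, "-", g$top_end, " ", g$top_peptide, "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy a conservation report into its per-column table
#'
#' @param x A `conservation_report` from [region_conservation()].
#' @param ... Unused.
#' @return Tibble of per-column identities and variability flags.
#' @export
tidy.conservation_report <- function(x, ...) {
  x$columns
}

#' One-row summary of a conservation report
#'
#' @inheritParams tidy.conservation_report
#' @return Tibble with the region bounds, gap policy, mean identity and
#'   variable-column count.
#' @export
glance.conservation_report <- function(x, ...) {
  tibble(
    region_start = x$region[1], region_end = x$region[2],
    gap_policy = x$gap_policy,
    mean_identity = x$mean_identity,
    n_variable = nrow(x$variable_positions)
  )
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("<conservation_report> columns ", x$region[1], "-", x$region[2],
      " (gap policy: ", x$gap_policy, ")\n",
      "mean identity ", formatC(x$mean_identity, digits = 4, format = "f"),
      "; ", nrow(x$variable_positions), " variable column(s)\n", sep = "")
  invisible(x)
}

#' Stacked track plot of an epitope scan
#'
#' One facet per predictor track (hydrophilicity, surface probability,
#' flexibility, antigenic index) with the two structure tracks drawn as
#' state strips underneath, and passed candidates shaded — the customary
#' multi-panel view of a composite epitope prediction.
#'
#' @param object An `epitope_scan`.
#' @param sequence_id Which sequence to plot (default: the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitope_scan <- function(object, sequence_id = NULL, ...) {
  sid <- sequence_id %||% object$seqs$id[1]
  tt <- track_table(object) |>
    dplyr::filter(.data$sequence_id == sid)
  numeric_tracks <- tt |>
    dplyr::filter(.data$method %in% c("hydrophilicity", "surface",
                                      "flexibility", "antigenic-index")) |>
    mutate(method = factor(.data$method,
                           levels = c("antigenic-index", "hydrophilicity",
                                      "surface", "flexibility")))
  cand <- object$candidates |>
    dplyr::filter(.data$sequence_id == sid, .data$passed)
  p <- ggplot2::ggplot(numeric_tracks,
                       ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$method), scales = "free_y") +
    ggplot2::labs(x = "residue position", y = NULL, title = sid) +
    ggplot2::theme_minimal()
  if (nrow(cand) > 0) {
    p <- p + ggplot2::geom_rect(
      data = cand,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}

#' @rdname autoplot.epitope_scan
#' @param x An `epitope_scan`.
#' @method plot epitope_scan
#' @export
plot.epitope_scan <- function(x, ...) print(autoplot(x, ...))

#' Structure-state strip plot
#'
#' Tile strip of the per-residue states of the Chou-Fasman, GOR-style and
#' consensus tracks of a scan.
#'
#' @inheritParams autoplot.epitope_scan
#' @param scan An `epitope_scan`.
#' @return A ggplot object.
#' @export
plot_structure <- function(scan, sequence_id = NULL) {
  sid <- sequence_id %||% scan$seqs$id[1]
  tt <- track_table(scan) |>
    dplyr::filter(.data$sequence_id == sid,
                  .data$method %in% c("chou-fasman", "garnier-robson",
                                      "consensus"))
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$position, y = .data$method,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(H = "#d62728", E = "#ff7f0e",
                                          T = "#2ca02c", C = "#bdbdbd")) +
    ggplot2::labs(x = "residue position", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
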