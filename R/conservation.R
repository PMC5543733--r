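#' Per-column conservation of an epitope window in a multiple alignment
#'
#' For every alignment column in `region`, the identity is the count of the
#' modal (most frequent) non-gap residue divided by a denominator set by
#' the gap policy: the number of non-gap residues (`"exclude"`, default) or
#' the number of rows (`"count-as-mismatch"`). Modal ties break
#' alphabetically, deterministically. Columns whose identity falls below
#' `variable_threshold` (default 1.0: any substitution) are flagged
#' variable; when `groups` are supplied, each variable position is
#' annotated with the per-group modal residues, the contrast used to spot
#' group-diagnostic substitutions (e.g. venomous vs non-venomous snakes at
#' epitope positions).
#'
#' @param aln Alignment tibble from `read_fasta(..., "gapped-protein")`
#'   (>= 2 records, equal gapped lengths).
#' @param region `c(start, end)` 1-based inclusive column interval.
#' @param gap_policy `"exclude"` or `"count-as-mismatch"`. Under
#'   `"exclude"` an all-gap column has no defined identity (`NA`) and is
#'   dropped from the region mean.
#' @param variable_threshold Identity below which a column is variable.
#' @param groups Optional grouping: named character vector (names = record
#'   ids) or tibble with columns `id`, `group`.
#' @return A `conservation_report`: list with `region`, `gap_policy`,
#'   `columns` (tibble: `column`, `modal_residue`, `modal_count`, `n_eff`,
#'   `identity`, `variable`), `mean_identity`, and `variable_positions`
#'   (with per-group modal residues when groups are given).
#' @export
region_conservation <- function(aln, region,
                                gap_policy = c("exclude", "count-as-mismatch"),
                                variable_threshold = 1.0,
                                groups = NULL) {
  gap_policy <- match.arg(gap_policy)
  check_alignment(aln)
  region <- check_region(region, aln$length[1])
  mat <- alignment_matrix(aln)
  cols <- purrr::map(region[1]:region[2], function(j) {
    column_identity(mat[, j], gap_policy, j)
  }) |>
    bind_rows() |>
    mutate(variable = !is.na(.data$identity) &
             .data$identity < variable_threshold)
  variable_positions <- dplyr::filter(cols, .data$variable) |>
    select("column", "modal_residue", "identity")
  if (!is.null(groups)) {
    gc <- group_contrast(aln, region, groups)
    variable_positions <- left_join(variable_positions,
                                    gc$columns, by = "column")
  }
  structure(
    list(
      region = region,
      gap_policy = gap_policy,
      variable_threshold = variable_threshold,
      columns = cols,
      mean_identity = mean(cols$identity, na.rm = TRUE),
      variable_positions = variable_positions
    ),
    class = "conservation_report"
  )
}

column_identity <- function(chars, gap_policy, j) {
  nongap <- chars[chars != "-"]
  n_rows <- length(chars)
  if (length(nongap) == 0) {
    return(tibble(column = j, modal_residue = NA_character_,
                  modal_count = 0L, n_eff = 0L,
                  identity = if (gap_policy == "exclude") NA_real_ else 0))
  }
  counts <- table(nongap)
  modal <- sort(names(counts)[counts == max(counts)])[1] # alphabetical tie-break
  denom <- if (gap_policy == "exclude") length(nongap) else n_rows
  tibble(column = j, modal_residue = modal,
         modal_count = as.integer(max(counts)), n_eff = as.integer(denom),
         identity = as.integer(max(counts)) / denom)
}

#' Per-group modal residues and discordant columns
#'
#' For each alignment column in `region`, the modal non-gap residue within
#' each declared group (ties alphabetical). A column is discordant when at
#' least two groups have a defined modal residue and they are not all the
#' same — the signature of a group-diagnostic substitution.
#'
#' @inheritParams region_conservation
#' @param groups Grouping for every record: named character vector or
#'   tibble (`id`, `group`); >= 2 distinct groups required.
#' @return List with `columns` (tibble: `column`, `discordant`, one
#'   `modal_<group>` column per group) and `discordant_columns` (integer
#'   vector).
#' @export
group_contrast <- function(aln, region, groups) {
  check_alignment(aln)
  region <- check_region(region, aln$length[1])
  grp <- normalize_groups(groups, aln$id)
  mat <- alignment_matrix(aln)
  levels <- sort(unique(grp))
  long <- purrr::map(region[1]:region[2], function(j) {
    purrr::map(levels, function(g) {
      chars <- mat[grp == g, j]
      nongap <- chars[chars != "-"]
      modal <- if (length(nongap) == 0) NA_character_ else {
        counts <- table(nongap)
        sort(names(counts)[counts == max(counts)])[1]
      }
      tibble(column = j, group = g, modal = modal)
    }) |> bind_rows()
  }) |> bind_rows()
  disc <- long |>
    group_by(.data$column) |>
    summarise(discordant = {
      m <- .data$modal[!is.na(.data$modal)]
      length(m) >= 2 && dplyr::n_distinct(m) > 1
    }, .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "group",
                             values_from = "modal",
                             names_prefix = "modal_") |>
    left_join(disc, by = "column")
  list(columns = wide,
       discordant_columns = disc$column[disc$discordant])
}

normalize_groups <- function(groups, ids) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("id", "group") %in% names(groups)))
    groups <- setNames(as.character(groups$group), groups$id)
  }
  if (is.null(names(groups)) || !all(ids %in% names(groups))) {
    abort("every alignment record needs a group label",
          class = "epitopr_error_missing_groups")
  }
  g <- unname(groups[ids])
  if (dplyr::n_distinct(g) < 2) {
    abort("group contrast needs >= 2 distinct groups",
          class = "epitopr_error_missing_groups")
  }
  g
}

#' Read a two-column group map
#'
#' Plain-text TSV `id<TAB>group`, optional header line `id group`.
#'
#' @param path File path.
#' @return Named character vector (names = record ids).
#' @export
read_groups <- function(path) {
  tbl <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tbl) < 2) {
    abort("group map needs two columns: id, group",
          class = "epitopr_error_missing_groups")
  }
  if (identical(tolower(tbl[1, 1]), "id")) tbl <- tbl[-1, , drop = FALSE]
  setNames(as.character(tbl[[2]]), tbl[[1]])
}

#' Map an ungapped sequence region onto alignment columns
#'
#' Projects a 1-based inclusive interval on the ungapped residues of one
#' alignment record onto the gapped column coordinates of the alignment —
#' needed to read epitope positions (stated on the protein) off alignment
#' figures.
#'
#' @inheritParams region_conservation
#' @param seq_id Record identifier in the alignment.
#' @param seq_region `c(start, end)` on the ungapped sequence.
#' @return Tibble with `position` (ungapped) and `column` (alignment),
#'   one row per residue; the spanned column interval is
#'   `range(out$column)`.
#' @export
map_epitope_to_alignment <- function(aln, seq_id, seq_region) {
  check_alignment(aln)
  row <- match(seq_id, aln$id)
  if (is.na(row)) {
    abort(paste0("sequence '", seq_id, "' not in alignment"),
          class = "epitopr_error_missing_record")
  }
  chars <- strsplit(aln$residues[row], "")[[1]]
  nongap_cols <- which(chars != "-")
  ungapped_len <- length(nongap_cols)
  if (seq_region[1] < 1 || seq_region[2] > ungapped_len ||
      seq_region[1] > seq_region[2]) {
    abort(sprintf("region %d-%d outside ungapped length %d",
                  seq_region[1], seq_region[2], ungapped_len),
          class = "epitopr_error_region")
  }
  pos <- seq_region[1]:seq_region[2]
  tibble(position = as.integer(pos), column = as.integer(nongap_cols[pos]))
}

#' Map alignment columns back to ungapped positions
#'
#' Inverse of [map_epitope_to_alignment()] on non-gap columns; gap columns
#' of the record map to `NA`.
#'
#' @inheritParams map_epitope_to_alignment
#' @param columns Integer vector of alignment columns.
#' @return Tibble with `column` and `position` (`NA` where the record has
#'   a gap).
#' @export
map_alignment_to_seq <- function(aln, seq_id, columns) {
  check_alignment(aln)
  row <- match(seq_id, aln$id)
  if (is.na(row)) {
    abort(paste0("sequence '", seq_id, "' not in alignment"),
          class = "epitopr_error_missing_record")
  }
  chars <- strsplit(aln$residues[row], "")[[1]]
  if (any(columns < 1 | columns > length(chars))) {
    abort("column outside alignment", class = "epitopr_error_region")
  }
  cum <- cumsum(chars != "-")
  tibble(column = as.integer(columns),
         position = ifelse(chars[columns] == "-", NA_integer_,
                           as.integer(cum[columns])))
}

#' Project an epitope onto a single unaligned homolog
#'
#' When no multiple alignment is available, a global (Needleman-Wunsch)
#' pairwise alignment of the query against one homolog locates the
#' homolog's segment corresponding to a query region. Scoring defaults:
#' match 1, mismatch -1, gap -2 per position. This is deliberately simple
#' glue — conservation statistics over many sequences should use a real
#' multiple alignment.
#'
#' @param query,homolog One-row protein tibbles ([protein()]).
#' @param seq_region `c(start, end)` on the query.
#' @param match,mismatch,gap Alignment scores.
#' @return List with `region` (`c(start, end)` on the homolog),
#'   `homolog_peptide`, `query_peptide`, and `identity` (fraction of
#'   region positions with identical residues).
#' @export
project_epitope <- function(query, homolog, seq_region,
                            match = 1, mismatch = -1, gap = -2) {
  mat <- matrix(mismatch, 20L, 20L, dimnames = list(AA20, AA20))
  diag(mat) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query$residues[1]),
    Biostrings::AAString(homolog$residues[1]),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = abs(gap),
    type = "global"
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- spos <- 0L
  hits <- integer(0)
  matches <- 0L
  covered <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qpos <- qpos + 1L
    if (sa[k] != "-") spos <- spos + 1L
    if (qa[k] != "-" && qpos >= seq_region[1] && qpos <= seq_region[2]) {
      covered <- covered + 1L
      if (sa[k] != "-") {
        hits <- c(hits, spos)
        if (qa[k] == sa[k]) matches <- matches + 1L
      }
    }
  }
  if (length(hits) == 0) {
    return(list(region = c(NA_integer_, NA_integer_),
                homolog_peptide = "", query_peptide = "",
                identity = 0))
  }
  region <- c(min(hits), max(hits))
  list(
    region = region,
    homolog_peptide = substr(homolog$residues[1], region[1], region[2]),
    query_peptide = substr(query$residues[1], seq_region[1], seq_region[2]),
    identity = matches / covered
  )
}

check_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "residues", "length") %in% names(aln)))
  if (nrow(aln) < 2) {
    abort("alignment needs >= 2 records", class = "epitopr_error_alignment")
  }
  if (dplyr::n_distinct(aln$length) != 1) {
    abort("alignment records have unequal lengths",
          class = "epitopr_error_unequal_lengths")
  }
  invisible(TRUE)
}

check_region <- function(region, ncols) {
  if (length(region) != 2 || anyNA(region) || region[1] > region[2]) {
    abort("region must be c(start, end) with start <= end",
          class = "epitopr_error_region")
  }
  if (region[1] < 1 || region[2] > ncols) {
    abort(sprintf("region %d-%d outside alignment columns 1-%d",
                  region[1], region[2], ncols),
          class = "epitopr_error_region")
  }
  as.integer(region)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$residues, ""))
}
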