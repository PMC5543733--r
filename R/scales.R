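#' Residue propensity scales
#'
#' The per-residue parameter tables behind every predictor track ship as
#' versioned plain-text files (two columns, `#` citation header) under
#' `inst/extdata/scales/`, so the exact numbers a run used are inspectable
#' and pinned by checksum. `aa_scale()` loads one by name.
#'
#' Available scales: `"hopp-woods"` (hydrophilicity), `"kyte-doolittle"`
#' (hydropathy; negate for hydrophilicity), `"emini-surface"` (fractional
#' surface probability, random expectation 0.37), `"karplus-schulz"`
#' (flexibility index, 1.0 = average).
#'
#' @param name Scale name (see above).
#' @return Tibble with columns `residue`, `value` covering the 20 canonical
#'   residues, with attributes `scale_name` and `combine_mode`.
#' @export
#' @examples
#' aa_scale("hopp-woods")
aa_scale <- function(name) {
  file <- scale_registry()[[name]]
  if (is.null(file)) {
    abort(paste0("unknown scale '", name, "'; see list_scales()"),
          class = "epitopr_error_unknown_scale")
  }
  path <- epitopr_file("scales", file)
  hdr <- read_scale_header(path)
  tbl <- as_tibble(utils::read.delim(path, comment.char = "#",
                                     stringsAsFactors = FALSE))
  stopifnot(setequal(tbl$residue, AA20), !anyDuplicated(tbl$residue))
  attr(tbl, "scale_name") <- hdr[["name"]] %||% name
  attr(tbl, "combine_mode") <- hdr[["combine_mode"]]
  attr(tbl, "source") <- hdr[["source"]]
  tbl
}

scale_registry <- function() {
  list(
    "hopp-woods" = "hopp_woods.tsv",
    "kyte-doolittle" = "kyte_doolittle.tsv",
    "emini-surface" = "emini_surface.tsv",
    "karplus-schulz" = "karplus_schulz.tsv"
  )
}

#' @rdname aa_scale
#' @export
list_scales <- function() names(scale_registry())

read_scale_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[stringr::str_starts(lines, "#")]
  kv <- stringr::str_match(lines, "^#\\s*([a-z_]+):\\s*(.*)$")
  kv <- kv[!is.na(kv[, 2]), , drop = FALSE]
  setNames(as.list(stringr::str_trim(kv[, 3])), kv[, 2])
}

# Named numeric lookup vector for a scale tibble.
scale_lookup <- function(scale_tbl) {
  setNames(scale_tbl$value, scale_tbl$residue)
}

#' Chou-Fasman conformational parameters
#'
#' Loads the packaged table of helix / strand / turn propensities and the
#' four positional bend frequencies `f1..f4` (tetrapeptide positions i..i+3).
#'
#' @return Tibble with columns `residue`, `p_helix`, `p_strand`, `p_turn`,
#'   `f1`, `f2`, `f3`, `f4`.
#' @export
cf_params <- function() {
  tbl <- as_tibble(utils::read.delim(epitopr_file("scales", "chou_fasman.tsv"),
                                     comment.char = "#", stringsAsFactors = FALSE))
  stopifnot(setequal(tbl$residue, AA20))
  tbl
}

#' GOR-style directional information table
#'
#' Loads the packaged directional-information table consumed by
#' [garnier_robson()]: for each state (H, E, T, C), residue, and neighbor
#' offset in -8..+8, the information contributed to that state by that
#' residue at that offset. The packaged table is a constructed
#' (synthetic-provenance, see its file header) parameter set; any table in
#' the same format can be substituted via the `table` argument of
#' [garnier_robson()].
#'
#' @return Tibble with columns `state`, `residue`, `offset`, `info`.
#' @export
gor_info <- function() {
  tbl <- as_tibble(utils::read.delim(
    epitopr_file("scales", "gor_info_synthetic.tsv"),
    comment.char = "#", stringsAsFactors = FALSE))
  stopifnot(
    setequal(tbl$state, c("H", "E", "T", "C")),
    setequal(tbl$offset, -8:8),
    nrow(tbl) == 4 * 20 * 17
  )
  tbl
}

#' Checksums of the packaged parameter files
#'
#' md5 of every shipped scale / parameter file, used to pin the exact
#' parameterization in run manifests and tests.
#'
#' @return Named character vector of md5 digests, keyed by file name.
#' @export
scale_checksums <- function() {
  dir <- epitopr_file("scales")
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  setNames(unname(tools::md5sum(files)), basename(files))
}
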