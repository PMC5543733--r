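#' Read sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA into a tibble, normalizes residues to
#' uppercase, and validates the alphabet. Coordinates throughout the package
#' are 1-based inclusive, matching the superscript numbering convention used
#' for epitope positions (e.g. a 151-172 span is 22 residues).
#'
#' Only the 20 canonical one-letter amino-acid codes are accepted for
#' proteins; ambiguity codes (`B`, `Z`, `X`, `U`) are rejected rather than
#' imputed, because every downstream propensity-scale lookup needs a
#' canonical residue. Under `alphabet = "gapped-protein"` the gap character
#' `-` is additionally permitted and all records must have equal length (an
#' alignment).
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"protein"`, `"nucleotide"`, `"gapped-protein"`.
#' @return A tibble with columns `id`, `residues`, `length`, one row per
#'   record. For `"gapped-protein"`, `length` is the gapped (column) length.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acdef"), fa)
#' read_fasta(fa)
read_fasta <- function(path, alphabet = c("protein", "nucleotide", "gapped-protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "epitopr_error_io")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)),
            class = "epitopr_error_malformed_fasta")
    }
  )
  ids <- stringr::str_trim(names(set))
  # keep only the first whitespace-delimited token as the record id
  ids <- stringr::str_split_i(ids, "\\s+", 1)
  if (any(is.na(ids) | ids == "")) {
    abort("FASTA record with empty header", class = "epitopr_error_malformed_header")
  }
  res <- unname(toupper(as.character(set)))
  # tolerate stray whitespace inside record bodies
  res <- gsub("[ \t\r]", "", res)
  if (any(nchar(res) == 0)) {
    abort(paste0("blank FASTA record: ", ids[nchar(res) == 0][1]),
          class = "epitopr_error_blank_record")
  }
  for (k in seq_along(ids)) validate_alphabet(ids[k], res[k], alphabet)
  out <- tibble(id = ids, residues = res, length = nchar(res))
  if (alphabet == "gapped-protein" && dplyr::n_distinct(out$length) > 1) {
    abort("gapped-protein records have unequal lengths; not an alignment",
          class = "epitopr_error_unequal_lengths")
  }
  out
}

validate_alphabet <- function(id, residues, alphabet) {
  allowed <- switch(alphabet,
    "protein" = AA20,
    "gapped-protein" = c(AA20, "-"),
    "nucleotide" = names(Biostrings::IUPAC_CODE_MAP)
  )
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0) {
    abort(
      sprintf("illegal %s character '%s' at position %d in record '%s'",
              alphabet, chars[bad[1]], bad[1], id),
      class = "epitopr_error_illegal_character",
      position = bad[1], residue = chars[bad[1]]
    )
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `residues` (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Build a single-record protein tibble from a residue string
#'
#' Convenience constructor for interactive use and tests; applies the same
#' normalization and validation as [read_fasta()].
#'
#' @param residues Residue string (one-letter codes; lowercase accepted).
#' @param id Record identifier.
#' @return One-row tibble with `id`, `residues`, `length`.
#' @export
protein <- function(residues, id = "seq1") {
  residues <- toupper(residues)
  if (!is.character(id) || length(id) != 1 || is.na(id) || id == "") {
    abort("id must be a non-empty string", class = "epitopr_error_malformed_header")
  }
  if (nchar(residues) == 0) {
    abort("empty residue string", class = "epitopr_error_blank_record")
  }
  validate_alphabet(id, residues, "protein")
  tibble(id = id, residues = residues, length = nchar(residues))
}

# ---- IUPAC-degenerate primers ------------------------------------------------

iupac_expansions <- function(code) {
  m <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(m)) {
    abort(paste0("invalid IUPAC nucleotide code: ", code),
          class = "epitopr_error_invalid_iupac")
  }
  strsplit(m[[code]], "")[[1]]
}

#' Degeneracy of an IUPAC primer
#'
#' Product of the per-position IUPAC code set sizes, i.e. the number of
#' distinct concrete primers the degenerate string encodes (R = A/G, M = A/C,
#' W = A/T, and the rest of the IUPAC code set).
#'
#' @param bases Primer string over IUPAC nucleotide codes.
#' @return Positive integer.
#' @export
#' @examples
#' primer_degeneracy("CRCTCATGTAMWTTTGTCACAA") # 2 * 2 * 2 = 8
primer_degeneracy <- function(bases) {
  chars <- strsplit(toupper(bases), "")[[1]]
  prod(vapply(chars, function(ch) length(iupac_expansions(ch)), integer(1)))
}

#' Expand an IUPAC-degenerate primer into concrete sequences
#'
#' Returns every Cartesian-product expansion of the degenerate positions,
#' lexicographically sorted; the count always equals [primer_degeneracy()].
#'
#' @inheritParams primer_degeneracy
#' @return Character vector of concrete A/C/G/T primers, sorted.
#' @export
#' @examples
#' expand_primer("AR") # "AA" "AG"
expand_primer <- function(bases) {
  chars <- strsplit(toupper(bases), "")[[1]]
  if (length(chars) == 0) {
    abort("empty primer", class = "epitopr_error_invalid_iupac")
  }
  sets <- lapply(chars, iupac_expansions)
  out <- Reduce(function(acc, s) {
    as.vector(t(outer(acc, s, paste0)))
  }, sets, accumulate = FALSE, init = "")
  sort(out)
}

#' Read a plain-text primer list
#'
#' One primer per line; either the bare sequence or `id<TAB>sequence`.
#' Blank lines and `#` comments are skipped.
#'
#' @param path Path to the primer list.
#' @return Tibble with columns `id`, `bases`, `degeneracy`.
#' @export
read_primers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  parts <- stringr::str_split(lines, "\t")
  ids <- purrr::map2_chr(parts, seq_along(parts), function(p, i) {
    if (length(p) >= 2) p[[1]] else paste0("primer", i)
  })
  bases <- toupper(purrr::map_chr(parts, function(p) p[[length(p)]]))
  tibble(
    id = ids,
    bases = bases,
    degeneracy = purrr::map_int(bases, function(b) as.integer(primer_degeneracy(b)))
  )
}

#' Match primer expansions against a nucleotide sequence
#'
#' Utility that reports every exact occurrence of any concrete expansion of a
#' degenerate primer (forward strand) in a target nucleotide string.
#'
#' @inheritParams primer_degeneracy
#' @param target Nucleotide string (A/C/G/T).
#' @return Tibble with columns `expansion`, `start`, `end` (1-based
#'   inclusive); zero rows when nothing matches.
#' @export
match_primer <- function(bases, target) {
  target <- toupper(target)
  hits <- purrr::map(expand_primer(bases), function(p) {
    loc <- stringr::str_locate_all(target, stringr::fixed(p))[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble(expansion = p, start = as.integer(loc[, 1]),
           end = as.integer(loc[, 2]))
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(expansion = character(), start = integer(), end = integer())
  }
  out
}
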