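#' Pipeline configuration
#'
#' The whole pipeline is parameterized by one declarative configuration:
#' scale choices, window sizes, discretization bins, antigenic-index
#' weights, selection criteria, and conservation options.
#' `default_config()` loads the packaged defaults
#' (`inst/extdata/config/default_config.yaml`); `load_config(path)` reads a
#' user YAML and fills every unset field from the defaults, so a partial
#' override file is enough.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return Nested configuration list.
#' @export
default_config <- function() {
  yaml::read_yaml(epitopr_file("config", "default_config.yaml"))
}

#' @rdname default_config
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

# SelectionCriteria view of a config.
criteria_from_config <- function(cfg) {
  s <- cfg$selection
  rw <- unlist(s$rank_weights)
  if (is.null(names(rw)) || !setequal(names(rw),
                                      c("ai", "hydrophilicity", "surface", "flexibility"))) {
    rw <- setNames(rw, c("ai", "hydrophilicity", "surface", "flexibility"))
  }
  selection_criteria(
    min_length = s$min_length,
    ai_threshold = s$ai_threshold,
    hydrophilicity_min = s$hydrophilicity_min,
    surface_min = s$surface_min,
    flexibility_min = s$flexibility_min,
    max_rigid_fraction = s$max_rigid_fraction,
    gap_merge = s$gap_merge,
    forbidden_regions = lapply(s$forbidden_regions, unlist),
    rank_weights = rw
  )
}

#' Compute every per-residue predictor track
#'
#' Runs the five component predictors (hydrophilicity, surface
#' probability, flexibility, Chou-Fasman and GOR-style structure), the
#' consensus structure track, the discretized components, and the
#' composite antigenic index, under one configuration.
#'
#' @param seqs Protein records tibble.
#' @param config Configuration list (see [default_config()]).
#' @return Named list of tracks: `hydrophilicity`, `surface`,
#'   `flexibility` (profiles), `cf`, `gr`, `consensus` (structure tracks),
#'   and `ai` (antigenic-index tibble with component scores).
#' @export
compute_tracks <- function(seqs, config = default_config()) {
  p <- config$profiles
  a <- config$antigenic_index
  ss <- config$secstruct
  min_needed <- max(p$hydrophilicity_window, p$flexibility_window, 6L)
  if (min(seqs$length) < min_needed) {
    abort(sprintf("sequence shorter than the minimum analyzable length (%d)",
                  min_needed),
          class = "epitopr_error_short_sequence")
  }
  hydro <- hydrophilicity_profile(seqs, scale = p$hydrophilicity_scale,
                                  window = p$hydrophilicity_window,
                                  edge_policy = p$edge_policy)
  surf <- surface_probability_profile(seqs, anchor = p$surface_anchor)
  flex <- flexibility_profile(seqs, window = p$flexibility_window,
                              weights = unlist(p$flexibility_weights),
                              edge_policy = p$edge_policy)
  cf <- chou_fasman(seqs,
                    helix_former_cutoff = ss$helix_former_cutoff,
                    strand_former_cutoff = ss$strand_former_cutoff,
                    turn_tetrapeptide_cutoff = ss$turn_tetrapeptide_cutoff,
                    extension_floor = ss$extension_floor)
  gr <- garnier_robson(seqs, tie_break = unlist(ss$tie_break))
  cons <- consensus_track(cf, gr)
  levels <- unlist(a$score_levels)
  st_scores <- unlist(a$structure_scores)
  ai <- antigenic_index(
    components = list(
      hydrophilicity = discretize_profile(hydro,
                                          unlist(a$hydrophilicity_thresholds),
                                          levels),
      surface = discretize_profile(surf, unlist(a$surface_thresholds), levels),
      flexibility = discretize_profile(flex,
                                       unlist(a$flexibility_thresholds), levels),
      cf_structure = discretize_structure(cf, st_scores),
      gr_structure = discretize_structure(gr, st_scores)
    ),
    weights = unlist(a$weights)
  )
  list(hydrophilicity = hydro, surface = surf, flexibility = flex,
       cf = cf, gr = gr, consensus = cons, ai = ai)
}

#' Predict linear B-cell epitopes on protein sequences
#'
#' End-to-end prediction: compute the predictor tracks and antigenic
#' index, extract maximal high-index hydrophilic segments, apply the
#' multi-criterion filter, rank what passes, and annotate
#' conjugation-readiness. The pipeline is fully deterministic given the
#' sequences and configuration.
#'
#' @inheritParams compute_tracks
#' @return An `epitope_scan` object: list with `seqs`, `config`,
#'   `criteria`, `tracks` (see [compute_tracks()]), and `candidates` (the
#'   ranked candidate tibble; zero rows is a valid result).
#' @export
#' @examples
#' sim <- generate_protein(synth_spec(), seed = 42)
#' scan <- predict_epitopes(sim$seq)
#' tidy(scan)
predict_epitopes <- function(seqs, config = default_config()) {
  criteria <- criteria_from_config(config)
  tracks <- compute_tracks(seqs, config)
  cand <- extract_segments(tracks$ai, tracks$hydrophilicity, seqs, criteria) |>
    filter_candidates(tracks$consensus, tracks$surface, tracks$flexibility,
                      criteria) |>
    rank_candidates(criteria) |>
    mutate(cys_note = terminal_cys_note(.data$peptide))
  structure(
    list(seqs = seqs, config = config, criteria = criteria,
         tracks = tracks, candidates = cand),
    class = "epitope_scan"
  )
}

#' Long per-position track table of an epitope scan
#'
#' Binds every profile and structure track of a scan into one long tibble
#' (`sequence_id`, `position`, `method`, `value`, `state`, `defined`) —
#' the TSV export format.
#'
#' @param scan An `epitope_scan`.
#' @return Long tibble.
#' @export
track_table <- function(scan) {
  stopifnot(inherits(scan, "epitope_scan"))
  tr <- scan$tracks
  profs <- bind_rows(tr$hydrophilicity, tr$surface, tr$flexibility) |>
    mutate(state = NA_character_)
  structs <- bind_rows(tr$cf |> select("sequence_id", "position", "state", "method"),
                       tr$gr |> select("sequence_id", "position", "state", "method"),
                       tr$consensus) |>
    mutate(value = NA_real_, defined = TRUE)
  ai <- tr$ai |>
    mutate(method = "antigenic-index", state = NA_character_) |>
    select("sequence_id", "position", "method", value = "ai", "state", "defined")
  bind_rows(profs, structs, ai) |>
    arrange(.data$sequence_id, .data$method, .data$position)
}

#' Run the prediction pipeline and write its reports
#'
#' File-level entry point behind the `predict` subcommand: reads a protein
#' FASTA, runs [predict_epitopes()], and writes `candidates.tsv`,
#' `candidates.json`, `tracks.tsv`, and `manifest.json` (configuration
#' echo, parameter-file checksums, package version, seed) into `out_dir`.
#' Outputs are byte-stable for fixed inputs and configuration. A run with
#' zero passing candidates still succeeds: an empty result is a result.
#'
#' @param fasta Path to a protein FASTA file.
#' @param config Path to a YAML config, a config list, or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (the prediction itself is
#'   deterministic).
#' @return The `epitope_scan`, invisibly.
#' @export
run_predict <- function(fasta, config = NULL, out_dir = ".", seed = NULL) {
  cfg <- if (is.list(config)) utils::modifyList(default_config(), config)
         else load_config(config)
  seqs <- read_fasta(fasta, "protein")
  scan <- predict_epitopes(seqs, cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(scan$candidates, file.path(out_dir, "candidates.tsv"))
  readr::write_tsv(track_table(scan), file.path(out_dir, "tracks.tsv"))
  jsonlite::write_json(
    list(candidates = scan$candidates,
         criteria = unclass(scan$criteria)),
    file.path(out_dir, "candidates.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  write_manifest(out_dir, cfg, seed)
  invisible(scan)
}

#' Run the conservation analysis and write its reports
#'
#' File-level entry point behind the `conserve` subcommand: reads a
#' pre-aligned multi-FASTA, scores per-column conservation over `region`,
#' optionally contrasts declared groups, and writes `conservation.tsv`,
#' `conservation.json`, and `manifest.json` into `out_dir`.
#'
#' @param aln_fasta Path to an aligned (gapped) multi-FASTA.
#' @param region `c(start, end)` alignment-column interval.
#' @param groups Optional path to a two-column `id<TAB>group` file, or a
#'   named vector.
#' @param config As in [run_predict()].
#' @param out_dir Output directory.
#' @return The `conservation_report`, invisibly.
#' @export
run_conserve <- function(aln_fasta, region, groups = NULL, config = NULL,
                         out_dir = ".") {
  cfg <- if (is.list(config)) utils::modifyList(default_config(), config)
         else load_config(config)
  aln <- read_fasta(aln_fasta, "gapped-protein")
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    groups <- read_groups(groups)
  }
  rep <- region_conservation(
    aln, region,
    gap_policy = cfg$conservation$gap_policy,
    variable_threshold = cfg$conservation$variable_identity_threshold,
    groups = groups
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(rep$columns, file.path(out_dir, "conservation.tsv"))
  jsonlite::write_json(
    list(region = rep$region, gap_policy = rep$gap_policy,
         mean_identity = rep$mean_identity,
         variable_positions = rep$variable_positions),
    file.path(out_dir, "conservation.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  write_manifest(out_dir, cfg, seed = NULL)
  invisible(rep)
}

#' Generate and write a synthetic dataset
#'
#' Entry point behind the `simulate` subcommand: generates a synthetic
#' protein (and optionally an alignment) and writes FASTA plus a
#' ground-truth JSON sidecar.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return List with the generated protein and truth, invisibly.
#' @export
run_simulate <- function(spec = synth_spec(), seed = 1L, out_dir = ".") {
  sim <- generate_protein(spec, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$seq, file.path(out_dir, "synthetic.fasta"))
  jsonlite::write_json(
    list(seed = seed, length = spec$length, truth = sim$truth),
    file.path(out_dir, "synthetic_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(sim)
}

write_manifest <- function(out_dir, cfg, seed) {
  jsonlite::write_json(
    list(
      package = "epitopr",
      version = as.character(utils::packageVersion("epitopr")),
      seed = seed,
      scale_checksums = as.list(scale_checksums()),
      config = cfg
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(NULL)
}
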