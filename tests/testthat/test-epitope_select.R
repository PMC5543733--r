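mk_ai <- function(values, id = "s") {
  tibble::tibble(sequence_id = id, position = seq_along(values),
                 ai = values, defined = !is.na(values))
}

mk_prof <- function(values, method, id = "s") {
  tibble::tibble(sequence_id = id, position = seq_along(values),
                 method = method, value = values, defined = !is.na(values))
}

mk_states <- function(states, id = "s") {
  tibble::tibble(sequence_id = id, position = seq_along(states),
                 state = states, method = "consensus")
}

const_seq <- function(n, id = "s") protein(strrep("K", n), id = id)

test_that("segment extraction returns maximal qualifying runs", {
  crit <- selection_criteria(ai_threshold = 0.2, hydrophilicity_min = 0,
                             gap_merge = 0)
  # constant high track: one segment spanning all defined positions
  ai <- mk_ai(rep(0.5, 20))
  hy <- mk_prof(rep(1, 20), "hydrophilicity")
  seg <- extract_segments(ai, hy, const_seq(20), crit)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(1L, 20L))

  # isolated high position: one length-1 segment
  v <- rep(-1, 20); v[10] <- 0.5
  seg <- extract_segments(mk_ai(v), hy, const_seq(20), crit)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end, seg$length), c(10L, 10L, 1L))

  # two planted high runs separated by a low valley: boundaries match the
  # brute-force run finder
  v <- rep(-1, 60); v[11:25] <- 0.6; v[40:52] <- 0.7
  seg <- extract_segments(mk_ai(v), mk_prof(rep(1, 60), "hydrophilicity"),
                          const_seq(60), crit)
  want <- oracle_runs(v >= 0.2, gap_merge = 0)
  expect_equal(nrow(seg), 2L)
  expect_equal(purrr::map2(seg$start, seg$end, c), want)
  expect_equal(seg$peptide, c(strrep("K", 15), strrep("K", 13)))
})

test_that("run extraction matches the oracle under random tracks and gap merging", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(30:120, 1)
    gap <- sample(0:3, 1)
    crit <- selection_criteria(ai_threshold = 0, hydrophilicity_min = 0,
                               gap_merge = gap)
    ai_v <- stats::runif(n, -1, 1)
    hy_v <- stats::runif(n, -1, 1)
    seg <- extract_segments(mk_ai(ai_v), mk_prof(hy_v, "hydrophilicity"),
                            const_seq(n), crit)
    want <- oracle_runs(ai_v >= 0 & hy_v >= 0, gap_merge = gap)
    expect_equal(purrr::map2(seg$start, seg$end, c), want)
  }
})

test_that("candidate means are computed over the segment and per-criterion flags set", {
  crit <- selection_criteria(ai_threshold = 0, hydrophilicity_min = 0,
                             surface_min = 1, flexibility_min = 1,
                             min_length = 8)
  ai_v <- rep(0.5, 30)
  hy_v <- rep(1.2, 30)
  su_v <- rep(2.0, 30)
  fl_v <- rep(1.05, 30)
  seg <- extract_segments(mk_ai(ai_v), mk_prof(hy_v, "hydrophilicity"),
                          const_seq(30), crit)
  out <- filter_candidates(seg, mk_states(rep("C", 30)),
                           mk_prof(su_v, "surface"),
                           mk_prof(fl_v, "flexibility"), crit)
  expect_true(out$passed)
  expect_equal(out$rejection_reason, "none")
  expect_equal(out$mean_surface, 2.0)
  expect_equal(out$mean_flexibility, 1.05)
  expect_equal(out$rigid_fraction, 0)
})

test_that("the three narrative failure modes get exactly their enumerated reasons", {
  crit <- selection_criteria(ai_threshold = 0, hydrophilicity_min = 0,
                             min_length = 8, surface_min = 1,
                             flexibility_min = 1, max_rigid_fraction = 0.3)
  n <- 40
  hy <- mk_prof(rep(1.5, n), "hydrophilicity")
  fl <- mk_prof(rep(1.05, n), "flexibility")

  # a six-residue candidate with min_length 8 -> too_short
  v <- rep(-1, n); v[10:15] <- 0.5
  seg <- extract_segments(mk_ai(v), hy, const_seq(n), crit)
  out <- filter_candidates(seg, mk_states(rep("C", n)),
                           mk_prof(rep(5, n), "surface"), fl, crit)
  expect_equal(out$rejection_reason, "too_short")
  expect_false(out$passed)

  # good hydrophilicity/flexibility/index but buried -> low_surface
  v <- rep(-1, n); v[10:25] <- 0.5
  seg <- extract_segments(mk_ai(v), hy, const_seq(n), crit)
  out <- filter_candidates(seg, mk_states(rep("C", n)),
                           mk_prof(rep(0.2, n), "surface"), fl, crit)
  expect_equal(out$rejection_reason, "low_surface")

  # majority-helix segment -> rigid_structure
  states <- rep("C", n); states[10:25] <- "H"
  out <- filter_candidates(seg, mk_states(states),
                           mk_prof(rep(5, n), "surface"), fl, crit)
  expect_equal(out$rejection_reason, "rigid_structure")
})

test_that("the first failed test in the fixed order names the reason", {
  crit <- selection_criteria(ai_threshold = 0, hydrophilicity_min = 0,
                             min_length = 8,
                             forbidden_regions = list(c(12, 14)))
  n <- 30
  v <- rep(-1, n); v[10:15] <- 0.5 # six residues AND overlapping forbidden
  seg <- extract_segments(mk_ai(v), mk_prof(rep(1.5, n), "hydrophilicity"),
                          const_seq(n), crit)
  out <- filter_candidates(seg, mk_states(rep("H", n)),
                           mk_prof(rep(0.1, n), "surface"),
                           mk_prof(rep(0.5, n), "flexibility"), crit)
  # fails every test; forbidden-region overlap is reported first
  expect_equal(out$rejection_reason, "overlaps_forbidden")
  expect_false(any(out$ok_forbidden, out$ok_length, out$ok_rigid,
                   out$ok_surface, out$ok_flexibility))
})

test_that("ranking: singleton gets rank 1; exact ties break by length then start", {
  base <- tibble::tibble(
    sequence_id = "s", start = c(10L, 40L, 70L), end = c(21L, 47L, 81L),
    length = c(12L, 8L, 12L), peptide = "X",
    mean_ai = 0.4, mean_hydrophilicity = 1, mean_surface = 2,
    mean_flexibility = 1.02, rigid_fraction = 0,
    ok_forbidden = TRUE, ok_length = TRUE, ok_rigid = TRUE,
    ok_surface = TRUE, ok_hydrophilicity = TRUE, ok_flexibility = TRUE,
    passed = TRUE, rejection_reason = "none"
  )
  r <- rank_candidates(base[1, ])
  expect_equal(r$rank, 1L)

  r <- rank_candidates(base)
  # identical means: all composite scores equal; longer first, then smaller start
  expect_equal(r$start[order(r$rank)], c(10L, 70L, 40L))
})

test_that("a candidate dominating every criterion is rank 1 under any nonnegative weights", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 5
    cand <- tibble::tibble(
      sequence_id = "s",
      start = seq(1, by = 30, length.out = n),
      end = seq(20, by = 30, length.out = n),
      length = 20L, peptide = "X",
      mean_ai = stats::runif(n, 0, 0.4),
      mean_hydrophilicity = stats::runif(n, 0, 1),
      mean_surface = stats::runif(n, 1, 4),
      mean_flexibility = stats::runif(n, 1, 1.05),
      rigid_fraction = 0,
      ok_forbidden = TRUE, ok_length = TRUE, ok_rigid = TRUE,
      ok_surface = TRUE, ok_hydrophilicity = TRUE, ok_flexibility = TRUE,
      passed = TRUE, rejection_reason = "none"
    )
    dom <- sample(n, 1)
    cand$mean_ai[dom] <- 0.6
    cand$mean_hydrophilicity[dom] <- 2
    cand$mean_surface[dom] <- 6
    cand$mean_flexibility[dom] <- 1.1
    w <- stats::runif(4, 0.1, 2)
    names(w) <- c("ai", "hydrophilicity", "surface", "flexibility")
    r <- rank_candidates(cand, selection_criteria(rank_weights = w))
    expect_equal(r$start[r$rank == 1 & !is.na(r$rank)], cand$start[dom])
  }
})

test_that("selection is deterministic and passed candidates respect the hard rules", {
  for (s in c(3, 14, 27)) {
    sim <- generate_protein(synth_spec(), seed = s)
    cfg <- default_config()
    cfg$selection$forbidden_regions <- list(c(87, 96))
    a <- predict_epitopes(sim$seq, cfg)
    b <- predict_epitopes(sim$seq, cfg)
    expect_identical(a$candidates, b$candidates)
    passed <- dplyr::filter(a$candidates, passed)
    expect_true(all(passed$length >= 8))
    expect_true(all(passed$end < 87 | passed$start > 96))
    expect_true(all(!is.na(passed$rank)) &&
                  !anyDuplicated(passed$rank))
  }
})

test_that("terminal cysteine annotation flags conjugation readiness", {
  expect_equal(terminal_cys_note("CPVLRLSNRTHEANRNDLIKVA"),
               "conjugation-ready (N-terminal Cys)")
  expect_equal(terminal_cys_note("PVLR"), "requires added terminal Cys")
  expect_equal(terminal_cys_note("PVLC"), "conjugation-ready (C-terminal Cys)")
})

test_that("interval Jaccard behaves on overlap, containment and disjoint cases", {
  expect_equal(interval_jaccard(c(1, 10), c(1, 10)), 1)
  expect_equal(interval_jaccard(c(1, 10), c(11, 20)), 0)
  expect_equal(interval_jaccard(c(1, 10), c(6, 15)), 5 / 15)
})
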