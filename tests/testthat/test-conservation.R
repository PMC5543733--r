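mk_aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = paste0("s", seq_along(seqs)), residues = seqs,
                 length = nchar(seqs))
}

test_that("identical ungapped sequences give identity 1 everywhere", {
  aln <- mk_aln("ACDEFG", "ACDEFG", "ACDEFG")
  rep <- region_conservation(aln, c(1, 6))
  expect_equal(rep$columns$identity, rep(1, 6))
  expect_equal(rep$mean_identity, 1)
  expect_equal(nrow(rep$variable_positions), 0L)
})

test_that("a single substitution yields 0.75 identity among four sequences", {
  aln <- mk_aln("ACDEFG", "ACDEFG", "ACDEFG", "ACREFG")
  rep <- region_conservation(aln, c(1, 6))
  expect_equal(rep$columns$identity, c(1, 1, 0.75, 1, 1, 1))
  expect_equal(rep$variable_positions$column, 3L)
  expect_equal(rep$variable_positions$modal_residue, "D")
})

test_that("gap policy changes the denominator as declared", {
  aln <- mk_aln("A", "A", "-", "A")
  excl <- region_conservation(aln, c(1, 1), gap_policy = "exclude")
  expect_equal(excl$columns$identity, 1.0)
  mism <- region_conservation(aln, c(1, 1), gap_policy = "count-as-mismatch")
  expect_equal(mism$columns$identity, 0.75)
})

test_that("modal ties break alphabetically and bad regions are named failures", {
  aln <- mk_aln("AC", "AC", "TC", "TC")
  rep <- region_conservation(aln, c(1, 2))
  expect_equal(rep$columns$modal_residue[1], "A")
  expect_error(region_conservation(aln, c(0, 2)),
               class = "epitopr_error_region")
  expect_error(region_conservation(aln, c(2, 1)),
               class = "epitopr_error_region")
  expect_error(region_conservation(mk_aln("AC"), c(1, 2)),
               class = "epitopr_error_alignment")
})

test_that("conservation equals the brute-force per-column tally on random alignments", {
  set.seed(91)
  for (rep_i in 1:5) {
    n <- sample(3:20, 1)
    ncol <- sample(50:300, 1)
    rows <- vapply(seq_len(n), function(i) {
      chars <- sample(c(aa_alphabet(), "-"), ncol, replace = TRUE,
                      prob = c(rep(0.95 / 20, 20), 0.05))
      paste(chars, collapse = "")
    }, character(1))
    aln <- tibble::tibble(id = paste0("r", seq_len(n)), residues = rows,
                          length = ncol)
    region <- sort(sample(ncol, 2))
    for (gp in c("exclude", "count-as-mismatch")) {
      got <- region_conservation(aln, region, gap_policy = gp)
      mat <- do.call(rbind, strsplit(rows, ""))
      want <- vapply(region[1]:region[2], function(j) {
        oracle_column_identity(mat[, j], gp)
      }, numeric(1))
      expect_equal(got$columns$identity, want, tolerance = 1e-9)
      expect_equal(got$mean_identity, mean(want, na.rm = TRUE),
                   tolerance = 1e-9)
    }
  }
})

test_that("mean identity is invariant under row and in-region column permutation", {
  set.seed(17)
  aln <- generate_alignment(n_seqs = 8, ncols = 60, mutation_rate = 0.1,
                           seed = 5)$aln
  region <- c(11, 40)
  base <- region_conservation(aln, region)$mean_identity
  shuffled_rows <- aln[sample(nrow(aln)), ]
  expect_equal(region_conservation(shuffled_rows, region)$mean_identity, base)
  mat <- do.call(rbind, strsplit(aln$residues, ""))
  cols <- region[1]:region[2]
  mat[, cols] <- mat[, sample(cols)]
  perm <- aln
  perm$residues <- apply(mat, 1, paste, collapse = "")
  expect_equal(region_conservation(perm, region)$mean_identity, base)
})

test_that("group contrast finds exactly the discordant columns", {
  # venomous-vs-non-venomous style pattern: groups fixed at two columns
  aln <- mk_aln("ASDEFG", "ASDEFG", "ARDEFN", "ARDEFN")
  groups <- c(s1 = "venomous", s2 = "venomous",
              s3 = "non-venomous", s4 = "non-venomous")
  gc <- group_contrast(aln, c(1, 6), groups)
  expect_equal(gc$discordant_columns, c(2L, 6L))
  expect_equal(gc$columns$`modal_venomous`[gc$columns$column == 2], "S")
  expect_equal(gc$columns$`modal_non-venomous`[gc$columns$column == 2], "R")

  # identical groups: no contrast
  gc <- group_contrast(aln[c(1, 2, 1, 2), ] |>
                         dplyr::mutate(id = paste0("s", 1:4)),
                       c(1, 6), groups)
  expect_equal(length(gc$discordant_columns), 0L)

  # within-group modal tie broken alphabetically
  aln2 <- mk_aln("A", "T", "G", "G")
  gc <- group_contrast(aln2, c(1, 1),
                       c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"))
  expect_equal(gc$columns$modal_g1, "A")

  expect_error(group_contrast(aln, c(1, 6), c(s1 = "a", s2 = "a")),
               class = "epitopr_error_missing_groups")
})

test_that("epitope positions project onto alignment columns through gaps", {
  aln <- mk_aln("ACDEFG", "A--CDE")
  # ungapped record: identity mapping
  m <- map_epitope_to_alignment(aln, "s1", c(2, 4))
  expect_equal(m$column, 2:4)
  # two gaps before the region shift the columns by two
  m <- map_epitope_to_alignment(aln, "s2", c(2, 4))
  expect_equal(m$column, 4:6)
  # boundary: region ending at the record's last residue
  m <- map_epitope_to_alignment(aln, "s2", c(4, 4))
  expect_equal(m$column, 6L)
  expect_error(map_epitope_to_alignment(aln, "s2", c(1, 5)),
               class = "epitopr_error_region")
  expect_error(map_epitope_to_alignment(aln, "nope", c(1, 2)),
               class = "epitopr_error_missing_record")
})

test_that("column-to-sequence mapping inverts the projection on non-gap columns", {
  set.seed(23)
  for (rep_i in 1:10) {
    chars <- sample(c(aa_alphabet(), "-"), 40, replace = TRUE,
                    prob = c(rep(0.9 / 20, 20), 0.1))
    other <- paste(sample(aa_alphabet(), 40, replace = TRUE), collapse = "")
    aln <- tibble::tibble(id = c("q", "o"),
                          residues = c(paste(chars, collapse = ""), other),
                          length = 40L)
    ungapped <- sum(chars != "-")
    if (ungapped < 3) next
    region <- sort(sample(ungapped, 2))
    m <- map_epitope_to_alignment(aln, "q", region)
    back <- map_alignment_to_seq(aln, "q", m$column)
    expect_equal(back$position, m$position)
  }
})

test_that("pairwise projection locates a shared epitope in an unaligned homolog", {
  core <- "CPVLRLSNRTHEANRNDLIKVA"
  # equal-length flanks: the cores align without gaps
  q <- protein(paste0(random_protein(12, seed = 1), core,
                      random_protein(20, seed = 2)), id = "q")
  h <- protein(paste0(random_protein(12, seed = 3), core,
                      random_protein(20, seed = 4)), id = "h")
  pr <- project_epitope(q, h, c(13, 34))
  expect_equal(pr$region, c(13, 34))
  expect_equal(pr$homolog_peptide, core)
  expect_equal(pr$identity, 1)

  # a two-residue shorter homolog prefix: the shared core is still found
  h2 <- protein(paste0(random_protein(10, seed = 3), core,
                       random_protein(20, seed = 4)), id = "h2")
  pr2 <- project_epitope(q, h2, c(13, 34))
  expect_equal(pr2$homolog_peptide, core)
  expect_equal(pr2$region, c(11, 32))
})
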