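test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("MAGIC")$sequence, "MAGIC")
  expect_equal(tryptic_digest("AKPRGR")$sequence, c("AKPR", "GR"))
  expect_setequal(tryptic_digest("MKR", max_missed = 1)$sequence,
                  oracle_digest("MKR", 1))
})

test_that("digestion agrees with the exhaustive substring oracle", {
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(names(residue_masses), sample(5:30, 1), replace = TRUE),
                 collapse = "")
    for (mm in 0:2) {
      expect_setequal(unique(tryptic_digest(seq, mm)$sequence),
                      unique(oracle_digest(seq, mm)))
    }
  }
})

test_that("fully cleaved products concatenate to the input sequence", {
  set.seed(7)
  for (i in 1:10) {
    seq <- paste(sample(names(residue_masses), 40, replace = TRUE), collapse = "")
    d <- tryptic_digest(seq, 0)
    expect_identical(paste(d$sequence, collapse = ""), seq)
    expect_true(all(d$missed_cleavages == 0))
  }
})

test_that("invalid residues are rejected with their position", {
  expect_error(tryptic_digest("AXK"), "position 2")
  expect_error(peptide_monoisotopic_mass(""), "non-empty")
  expect_error(peptide_monoisotopic_mass("GZ"), "'Z'")
})

test_that("monoisotopic masses match residue + water sums", {
  expect_equal(peptide_monoisotopic_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(peptide_monoisotopic_mass("GG"), 132.05349, tolerance = 1e-4)
  # additivity: mass(AB) = mass(A) + mass(B) - water
  expect_equal(peptide_monoisotopic_mass("PEPTIDE") +
                 peptide_monoisotopic_mass("K") - 18.010565,
               peptide_monoisotopic_mass("PEPTIDEK"), tolerance = 1e-9)
})

test_that("observable-peptide counting is distinct-in-window", {
  peps <- data.frame(sequence = c("A1", "A2", "A3"),
                     monoisotopic_mass = c(500, 1500, 7000))
  expect_equal(count_observable(peps, 798, 5997), 1L)
  expect_equal(count_observable(character(0)), 0L)
  dup <- data.frame(sequence = c("AAK", "AAK"), monoisotopic_mass = c(1000, 1000))
  expect_equal(count_observable(dup, 798, 5997), 1L)
  expect_error(count_observable(dup, 10, 5), "mass_min < mass_max")
})

test_that("emPAI is 10^(observed/observable) - 1", {
  expect_equal(compute_empai(0, 10)$empai, 0)
  expect_equal(compute_empai(10, 10)$empai, 9)
  expect_equal(compute_empai(2, 10)$empai, 0.5849, tolerance = 1e-4)
  expect_error(compute_empai(2, 0), "positive")
  expect_error(compute_empai(-1, 10), "non-negative")
  # strictly increasing in n_observed
  e <- compute_empai(0:12, 12)$empai
  expect_true(all(diff(e) > 0))
  expect_equal(e[1], 0)
})

test_that("affinity scores are max-normalised with forced full-affinity targets", {
  expect_equal(affinity_from_empai(c(A = 2, B = 1)), c(A = 1, B = 0.5))
  aff <- affinity_from_empai(c(A = 2), "COMMD1")
  expect_equal(aff, c(A = 1, COMMD1 = 1))
  # scale invariance
  x <- c(a = 0.3, b = 1.7, c = 0.04)
  expect_equal(affinity_from_empai(x), affinity_from_empai(13.7 * x))
  expect_error(affinity_from_empai(numeric()), "empty")
  expect_error(affinity_from_empai(c(A = -1)), "positive")
})

test_that("reference target-table emPAI column normalises against its maximum", {
  tab <- cigb552_tables()$targets
  emp <- setNames(tab$empai, tab$gene)
  aff <- affinity_from_empai(emp)
  expect_equal(max(aff), 1)
  expect_equal(names(which.max(aff)), "MYL12A")   # column maximum 2.45
  expect_equal(unname(aff["ACTN1"]), 1.76 / 2.45, tolerance = 1e-12)
})
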