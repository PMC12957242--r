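# Frozen oracle values: hand sums of IUPAC principal-isotope masses
# (H 1.0078250319, C 12, N 14.0030740, O 15.9949146, Na 22.9897693).

test_that("parse_formula reads counts and charge from the grammar", {
  f <- parse_formula("C4H4O4")
  expect_equal(f$counts, c(C = 4L, H = 4L, O = 4L))
  expect_equal(f$charge, 0L)

  expect_equal(parse_formula("H")$counts, c(H = 1L))

  cation <- parse_formula("C14H22NO4+")
  expect_equal(cation$counts, c(C = 14L, H = 22L, N = 1L, O = 4L))
  expect_equal(cation$charge, 1L)

  # unicode minus accepted for anions
  expect_equal(parse_formula("CHO2−")$charge, -1L)
})

test_that("parse_formula rejects malformed input with positional errors", {
  expect_error(parse_formula("C4H4O0"), "count of zero")
  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula("C4h4"), "position 3")
  expect_error(parse_formula("+"), "charge sign")
})

test_that("formulas round-trip through format_formula", {
  set.seed(1)
  elements <- c("C", "H", "N", "O", "Na", "S", "Cl")
  for (i in 1:25) {
    n_elt <- sample(1:5, 1)
    counts <- stats::setNames(sample(1:40, n_elt), sample(elements, n_elt))
    charge <- sample(c(-1L, 0L, 1L), 1)
    f <- structure(list(counts = counts, charge = charge),
                   class = "mol_formula")
    g <- parse_formula(format_formula(f))
    expect_equal(g$counts[sort(names(counts))],
                 vapply(sort(names(counts)), function(e) counts[[e]],
                        integer(1)))
    expect_equal(g$charge, charge)
  }
})

test_that("monoisotopic_mass sums principal-isotope masses", {
  empty <- structure(list(counts = integer(0), charge = 0L),
                     class = "mol_formula")
  expect_equal(monoisotopic_mass(empty), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C4H4O4"), 116.0110, tolerance = 1e-4)
})

test_that("monoisotopic_mass is additive over element-wise sums", {
  set.seed(2)
  for (i in 1:20) {
    a <- stats::setNames(sample(0:9, 4), c("C", "H", "N", "O"))
    b <- stats::setNames(sample(0:9, 4), c("C", "H", "N", "O"))
    mk <- function(cnt) {
      cnt <- cnt[cnt > 0]
      structure(list(counts = cnt, charge = 0L), class = "mol_formula")
    }
    expect_equal(monoisotopic_mass(mk(a)) + monoisotopic_mass(mk(b)),
                 monoisotopic_mass(mk(a + b)), tolerance = 1e-9)
  }
})

test_that("adduct_mz applies the electron-corrected adduct deltas", {
  expect_equal(adduct_mz("C4H4O4", "[M-H]-"), 115.0037)
  expect_equal(adduct_mz("C16H22O8", "[M+Na]+"), 365.1207)
  expect_equal(adduct_mz("C19H28NO5+", "[M]+"), 350.1962)
  expect_equal(adduct_mz("C15H26O9", "[2M-H]-"), 699.3081)
  # dimer consistency: [2M-H]- = M + [M-H]- exactly (unrounded)
  M <- monoisotopic_mass("C15H26O9")
  expect_equal(adduct_mz("C15H26O9", "[2M-H]-", digits = NULL),
               M + adduct_mz("C15H26O9", "[M-H]-", digits = NULL))
})

test_that("adduct_mz enforces polarity/charge consistency", {
  expect_error(adduct_mz("C4H4O4", "[M+K]+"), "unsupported adduct")
  expect_error(adduct_mz("C14H22NO4+", "[M+H]+"), "intrinsic cation")
  expect_error(adduct_mz("C4H4O4", "[M]+"), "requires an intrinsic cation")
})

test_that("ppm_error matches direct formula evaluation", {
  expect_equal(ppm_error(268.1040, 268.1040), 0)
  expect_equal(ppm_error(115.0045, 115.0037), 6.96, tolerance = 0.05)
  expect_equal(ppm_error(419.1665, 419.1676), -2.62, tolerance = 0.05)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("match_peaks picks the lowest-|ppm| candidate, ties by RT then id", {
  # two records straddling one peak; brute-force the winner
  db <- data.frame(id = 1:2, name = c("a", "b"),
                   formula = c("C4H4O4", "C4H4O4"),
                   adduct = c("[M-H]-", "[M-H]-"),
                   rt_min = c(1.00, 1.05), class = "Org")
  calc <- adduct_mz("C4H4O4", "[M-H]-", digits = NULL)
  peak <- data.frame(mz = calc * (1 + 2e-6), rt_min = 1.01)
  ann <- match_peaks(peak, db)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$id, 1L)  # equal ppm, closer RT

  # out of tolerance on mass
  far <- data.frame(mz = calc * (1 + 20e-6), rt_min = 1.0)
  expect_equal(nrow(match_peaks(far, db, ppm_tol = 10)), 0L)
  # empty database is an empty result, not an error
  expect_equal(nrow(match_peaks(peak, db[0, ])), 0L)
})

test_that("annotation count is monotone in both tolerances", {
  db <- cr_compounds()
  set.seed(3)
  peaks <- data.frame(mz = db$detected_mz * (1 + runif(56, -8e-6, 8e-6)),
                      rt_min = db$rt_min + runif(56, -0.3, 0.3))
  n_prev <- -1L
  for (tol in c(2, 5, 10, 20)) {
    n <- nrow(match_peaks(peaks, db, ppm_tol = tol, rt_tol = 0.2))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  n_prev <- -1L
  for (rt in c(0.05, 0.1, 0.2, 0.5)) {
    n <- nrow(match_peaks(peaks, db, ppm_tol = 10, rt_tol = rt))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("neutral losses annotate precursor-fragment differences", {
  expect_equal(neutral_loss_annotate(581.2203, 419.1664), "glycosyl")
  expect_equal(neutral_loss_annotate(419.1664, 257.1152), "glycosyl")
  expect_true(is.na(neutral_loss_annotate(100.0, 50.0)))
  expect_error(neutral_loss_annotate(100, 100), "below precursor")
})
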