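test_that("hydrocarbon formulas and masses follow CnH(2n+2-2d)", {
  # worked cases: (cn, db, H, nominal mass)
  cases <- list(c(39, 2, 76, 544), c(26, 0, 54, 366), c(27, 2, 52, 376),
                c(1, 0, 4, 16), c(32, 1, 64, 448))
  for (cs in cases) {
    sp <- hc_species(cs[1], cs[2])
    f <- neutral_formula(sp)
    expect_identical(unname(f[["C"]]), as.integer(cs[1]))
    expect_identical(unname(f[["H"]]), as.integer(cs[3]))
    expect_equal(neutral_mass(sp, "nominal"), cs[4])
    expect_lt(abs(neutral_mass(sp, "monoisotopic") - cs[4]), 1)
  }
})

test_that("invalid CN:DB combinations are rejected with the violated bound", {
  expect_error(hc_species(0, 0), "carbon_number")
  expect_error(hc_species(10, 5), "floor\\(\\(CN - 1\\)/2\\)")
  expect_error(hc_species(32, 1, geometry = c("cis", "cis")), "one entry per")
  expect_error(hc_species(32, 1, geometry = "sideways"), "geometry")
})

test_that("protonated-molecule m/z reproduces the diene ion series", {
  expect_equal(ion_mz(hc_species(39, 2), "[M+H]+"), 545)
  expect_equal(ion_mz(hc_species(41, 2), "[M+H]+"), 573)
  expect_equal(ion_mz(hc_species(43, 2), "[M+H]+"), 601)
  expect_equal(ion_mz(hc_species(32, 1), "[M+C4H9]+"), 505)  # 448 + 57
})

test_that("adduct registry carries the seven APCI channels", {
  reg <- adduct_registry()
  expect_setequal(reg$nominal_offset, c(-1, 1, 0, 39, 57, 85, 93))
  expect_true(all(abs(reg$monoisotopic_offset - reg$nominal_offset) < 0.5))
  expect_equal(unname(adduct_offset("[M+C3H3]+")[["monoisotopic"]]),
               39.0229, tolerance = 1e-4)
  expect_equal(unname(adduct_offset("[M+C7H9]+")[["monoisotopic"]]),
               93.0699, tolerance = 1e-4)
  # nominal-offset aliases and unicode minus both resolve
  expect_equal(unname(adduct_offset("[M+39]+")[["nominal"]]), 39)
  expect_equal(unname(adduct_offset("[M−H]+")[["nominal"]]), -1)
  expect_error(adduct_offset("[M+Na]+"), "unknown adduct")
})

test_that("mass additivity holds exactly on both scales", {
  reg <- adduct_registry()
  for (cn in c(20, 33, 47, 63)) for (db in 0:3) {
    sp <- hc_species(cn, db)
    for (a in reg$name) {
      off <- adduct_offset(a, reg)
      expect_identical(ion_mz(sp, a, "nominal"),
                       neutral_mass(sp, "nominal") + off[["nominal"]])
      expect_identical(ion_mz(sp, a, "monoisotopic"),
                       neutral_mass(sp, "monoisotopic") +
                         off[["monoisotopic"]])
    }
  }
})

test_that("alkane [M-H]+ and alkene [M+H]+ share an ion formula for all CN", {
  for (cn in 20:70) {
    expect_identical(ion_mz(hc_species(cn, 0), "[M-H]+", "nominal"),
                     ion_mz(hc_species(cn, 1), "[M+H]+", "nominal"))
    expect_equal(ion_mz(hc_species(cn, 0), "[M-H]+", "monoisotopic"),
                 ion_mz(hc_species(cn, 1), "[M+H]+", "monoisotopic"),
                 tolerance = 1e-9)
  }
})

test_that("neutral mass is monotone in CN and drops 2 Da per double bond", {
  m_cn <- vapply(20:60, function(cn) neutral_mass(hc_species(cn, 1)),
                 numeric(1))
  expect_true(all(diff(m_cn) > 0))
  for (db in 0:2)
    expect_equal(neutral_mass(hc_species(41, db)) -
                   neutral_mass(hc_species(41, db + 1)), 2)
})

test_that("isotope patterns match a full-convolution oracle", {
  # oracle: complete binomial pmf convolution, a separate code path from
  # the truncated summation used by the implementation
  oracle_ratio <- function(nC, nH, k) {
    pc <- dbinom(0:nC, nC, 0.0107)
    ph <- dbinom(0:nH, nH, 0.000115)
    full <- convolve(pc, rev(ph), type = "open")
    full[k + 1] / full[1]
  }
  p39 <- isotope_pattern(c(C = 39, H = 76), 3)
  expect_equal(p39$intensity[2], oracle_ratio(39, 76, 1), tolerance = 1e-9)
  expect_equal(p39$intensity[3], oracle_ratio(39, 76, 2), tolerance = 1e-9)
  expect_lt(abs(p39$intensity[2] - 0.426), 0.005)
  expect_lt(abs(isotope_pattern(c(C = 1, H = 4), 2)$intensity[2] - 0.0112),
            2e-4)
  p1 <- isotope_pattern(c(C = 0, H = 2), 1)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$intensity, 1)
  expect_error(isotope_pattern(c(C = 0, H = 0), 2), "empty formula")
  # structural invariants: base peak 1, non-negative, ~1.0034 Da spacing
  expect_true(all(p39$intensity >= 0))
  expect_true(all(abs(diff(p39$mz) - 1.0034) < 1e-3))
})

test_that("first-order M+1 approximation holds within 2% up to C70", {
  for (cn in seq(10, 70, by = 10)) {
    f <- neutral_formula(hc_species(cn, 0))
    r <- isotope_pattern(f, 2)$intensity[2]
    approx1 <- f[["C"]] * 0.0107 + f[["H"]] * 0.000115
    expect_lt(abs(r - approx1) / approx1, 0.02)
  }
})

test_that("candidates_for_mz matches brute-force enumeration", {
  reg <- adduct_registry()
  brute <- function(mz, tol, cn_range, db_range) {
    hits <- list()
    for (cn in cn_range[1]:cn_range[2]) for (db in db_range[1]:db_range[2]) {
      if (db > (cn - 1) %/% 2) next
      h <- 2 * cn + 2 - 2 * db
      for (j in seq_len(nrow(reg))) {
        m <- cn * 12 + h + reg$nominal_offset[j]
        if (abs(mz - m) <= tol)
          hits[[length(hits) + 1]] <- c(cn, db, j)
      }
    }
    hits
  }
  set.seed(42)
  for (q in seq_len(100)) {
    mz <- round(runif(1, 300, 900))
    got <- candidates_for_mz(mz, 0.3, registry = adduct_registry(),
                             cn_range = c(20, 70), db_range = c(0, 6),
                             scale = "nominal")
    want <- brute(mz, 0.3, c(20, 70), c(0, 6))
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      want_keys <- sort(vapply(want, function(w)
        paste(w[1], w[2], reg$name[w[3]]), character(1)))
      got_keys <- sort(paste(got$carbon_number, got$double_bonds,
                             got$adduct))
      expect_identical(got_keys, want_keys)
    }
  }
})

test_that("candidate lookup resolves worked examples and degeneracy", {
  hit <- candidates_for_mz(545, 0.3, adducts = "[M+H]+",
                           cn_range = c(20, 70), db_range = c(0, 6))
  expect_true(any(hit$carbon_number == 39 & hit$double_bonds == 2))
  both <- candidates_for_mz(421, 0.3, adducts = c("[M-H]+", "[M+H]+"),
                            cn_range = c(25, 35), db_range = c(0, 3))
  expect_true(any(both$carbon_number == 30 & both$double_bonds == 0 &
                    both$adduct == "[M-H]+"))
  expect_true(any(both$carbon_number == 30 & both$double_bonds == 1 &
                    both$adduct == "[M+H]+"))
  expect_identical(nrow(candidates_for_mz(545, 1e-4, adducts = character(0))),
                   0L)
  # deterministic ranking: ties broken by fewer double bonds then lower CN
  expect_lte(both$double_bonds[1], both$double_bonds[2])
})

test_that("CN:DB labels parse including geometry prefixes", {
  sp <- parse_cn_db("13c-C32:1")
  expect_identical(sp$carbon_number, 32L)
  expect_identical(sp$geometry, "cis")
  expect_identical(parse_cn_db("41:2")$double_bonds, 2L)
  expect_error(parse_cn_db("banana"), "cannot parse")
})

test_that("adduct registry round-trips through its config file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_adduct_registry(adduct_registry(), f)
  back <- read_adduct_registry(f)
  expect_equal(back$monoisotopic_offset,
               adduct_registry()$monoisotopic_offset, tolerance = 1e-9)
  extra <- data.frame(name = "[M+C2H5]+", delta_C = 2L, delta_H = 5L,
                      charge = 1L, source_solvent = "custom")
  reg2 <- adduct_registry(extra = extra)
  expect_equal(reg2$nominal_offset[reg2$name == "[M+C2H5]+"], 29)
})
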