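test_that("summed-ion chromatograms peak at the true retention time", {
  run <- single_species_run(32, 1)
  sp <- hc_species(32, 1, geometry = "cis")
  eic <- extract_eic(run, sp)
  apex <- eic$rt[which.max(eic$intensity)]
  rt_true <- run$ground_truth$rt_true[1]
  scan_period <- median(diff(run$rt))
  expect_lt(abs(apex - rt_true), scan_period + 1e-9)
  # a species 10 Da away shares no channel: all-zero trace
  far <- extract_eic(run, hc_species(33, 1))
  expect_true(all(far$intensity == 0))
  expect_error(extract_eic(run, sp, adducts = character(0)), "empty")
})

test_that("the alkane/alkene degeneracy shows up in the EIC and is resolved by windows", {
  comp <- data.frame(cn = c(30, 30), db = c(0, 1),
                     geometry = c("", "cis"),
                     abundance_pct = c(100, 100),
                     class_share_pct = c(50, 50))
  run <- clean_run(comp)
  gt <- run$ground_truth
  eic0 <- extract_eic(run, hc_species(30, 0))
  # secondary bump at the monoene Rt through the shared CnH2n+1+ formula
  rt1 <- gt$rt_true[gt$db == 1]
  i1 <- which.min(abs(eic0$rt - rt1))
  expect_gt(eic0$intensity[i1], 0)
  # the pipeline never calls DB=1 inside the saturated window or vice versa
  ann <- annotate_run(run)
  a <- ann$annotations
  w <- ann$windows
  sat_end <- w$end[w$db == 0]
  expect_true(all(a$apex_rt[a$db == 0] < sat_end))
  expect_true(all(a$apex_rt[a$db == 1] >= sat_end))
  expect_identical(sort(paste(a$cn, a$db)), c("30 0", "30 1"))
})

test_that("peak detection integrates Gaussians to their known area", {
  rt <- seq(0, 10, by = 1 / 120)
  expect_identical(nrow(detect_peaks(data.frame(rt = rt, intensity = 0 * rt))),
                   0L)
  tr <- gaussian_trace(rt, mu = 5, sigma = 0.1, area = 42)
  pk <- detect_peaks(tr)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$area, 42, tolerance = 0.01)
  expect_lt(pk$left_rt, pk$apex_rt); expect_gt(pk$right_rt, pk$apex_rt)
  # reported area equals brute-force trapezoid integration over the bounds
  seg <- rt >= pk$left_rt & rt <= pk$right_rt
  y <- tr$intensity[seg]; t <- rt[seg]
  brute <- sum((y[-length(y)] + y[-1]) / 2 * diff(t))
  expect_identical(pk$area, brute)
  expect_error(detect_peaks(tr[1:2, ]), "at least 3")
})

test_that("two Gaussians four sigma apart resolve with a boundary between", {
  rt <- seq(0, 10, by = 1 / 120)
  tr <- data.frame(rt = rt, intensity =
                     10 * dnorm(rt, 4.8, 0.1) + 8 * dnorm(rt, 5.2, 0.1))
  pk <- detect_peaks(tr)
  expect_identical(nrow(pk), 2L)
  expect_gt(pk$left_rt[2], pk$apex_rt[1])
  expect_lt(pk$right_rt[1], pk$apex_rt[2])
  expect_equal(sum(pk$area), 18, tolerance = 0.05)
})

test_that("valley merging fuses noise shoulders but keeps real pairs", {
  rt <- seq(0, 4, by = 1 / 120)
  # one peak with a 5% dimple near the top: a single chromatographic peak
  y <- 10 * dnorm(rt, 2, 0.1)
  dip <- which.min(abs(rt - 2.02))
  y[dip] <- y[dip] * 0.95
  pk <- detect_peaks(data.frame(rt = rt, intensity = y))
  expect_identical(nrow(pk), 1L)
})

test_that("averaged spectra reflect the class adduct chemistry", {
  run <- clean_run(tiny_composition())
  gt <- run$ground_truth
  # saturated cluster: base peak is the [M-H]+ ion
  rt0 <- gt$rt_true[gt$db == 0]
  sp0 <- average_spectrum(run, c(rt0 - 0.05, rt0 + 0.05))
  expect_equal(sp0$mz[which.max(sp0$intensity)],
               ion_mz(hc_species(30, 0), "[M-H]+", "monoisotopic"),
               tolerance = 0.01)
  # triene eluting at high %toluene: [M+H]+, [M]+. and the +93 adduct
  rt3 <- gt$rt_true[gt$db == 3]
  sp3 <- average_spectrum(run, c(rt3 - 0.2, rt3 + 0.2))
  for (a in c("[M+H]+", "[M]+.", "[M+C7H9]+")) {
    target <- ion_mz(hc_species(43, 3), a, "monoisotopic")
    expect_true(any(abs(sp3$mz - target) < 0.01 & sp3$intensity > 0),
                info = a)
  }
  # single-scan window returns the scan unchanged
  i <- which.min(abs(run$rt - rt0))
  one <- average_spectrum(run, c(run$rt[i], run$rt[i]))
  scan_rows <- run$centroids[run$centroids$scan == i, ]
  expect_identical(nrow(one), nrow(scan_rows))
  expect_equal(sum(one$intensity), sum(scan_rows$intensity),
               tolerance = 1e-9)
  expect_error(average_spectrum(run, c(-5, -4)), "overlap")
})

test_that("class windows center on apexes with midpoint boundaries", {
  w <- calibrate_class_windows(model = retention_model(), run_end = 140)
  expect_true(w$start[w$db == 0] == 0)
  expect_true(w$start[w$db == 1] < 22.9 && w$end[w$db == 1] > 22.9)
  expect_true(w$start[w$db == 0] < 6.5 && w$end[w$db == 0] > 6.5)
  expect_true(all(w$end[-4] == w$start[-1]))   # ordered, non-overlapping
  # midpoint rule on a custom two-class model
  ca <- data.frame(system = "X", temperature_c = 20, db_class = 0:1,
                   apex_min = c(10, 20))
  m2 <- retention_model(class_apex = ca)
  w2 <- calibrate_class_windows(model = m2, system = "X", temperature = 20,
                                run_end = 40)
  expect_equal(w2$end[1], 15)
  expect_error(calibrate_class_windows(model = retention_model(),
                                       system = "I", temperature = 15),
               "strictly increasing")
})

test_that("species assignment reads CN and class from spectrum plus window", {
  run <- single_species_run(41, 2)
  w <- calibrate_class_windows(run)
  eic <- extract_eic(run, hc_species(41, 2))
  pk <- detect_peaks(eic)
  ann <- assign_species(pk[1, ], run, w)
  expect_identical(ann$cn, 41L)
  expect_identical(ann$db, 2L)
  expect_true(ann$assigned)
  expect_match(ann$matched_adducts, "\\[M\\+H\\]\\+")

  # CnH2n+1+ base ion inside the saturated window: alkane call, never CN:1
  run0 <- single_species_run(30, 0)
  w0 <- calibrate_class_windows(run0)
  eic0 <- extract_eic(run0, hc_species(30, 0))
  pk0 <- detect_peaks(eic0)
  ann0 <- assign_species(pk0[1, ], run0, w0)
  expect_identical(ann0$cn, 30L)
  expect_identical(ann0$db, 0L)

  # a peak with no matching ion is flagged unassigned
  fake <- structure(list(
    rt = run0$rt,
    centroids = data.table::data.table(
      scan = seq_along(run0$rt), mz = 250.0,
      intensity = rep(100, length(run0$rt))),
    ground_truth = data.frame(), metadata = run0$metadata),
    class = "synthetic_run")
  bogus <- data.frame(apex_rt = 5.5, left_rt = 5.3, right_rt = 5.7,
                      area = 1, height = 100)
  annx <- assign_species(bogus, fake, w0)
  expect_false(annx$assigned)
  expect_true(is.na(annx$cn))
  expect_error(assign_species(data.frame(apex_rt = 1e5, left_rt = 1,
                                         right_rt = 2, area = 1,
                                         height = 1), run0, w0),
               "no class window")
})

test_that("geometry is called from retention against the class boundary", {
  comp <- data.frame(cn = c(32, 32), db = 1,
                     geometry = c("trans", "cis"),
                     abundance_pct = c(50, 50), class_share_pct = 100)
  run <- clean_run(comp)
  ann <- annotate_run(run)
  a <- ann$annotations[order(ann$annotations$apex_rt), ]
  expect_identical(a$geometry, c("trans", "cis"))
  gt <- run$ground_truth
  expect_lt(gt$rt_true[gt$geometry == "trans"],
            gt$rt_true[gt$geometry == "cis"])

  b <- geometry_boundaries()
  expect_error(call_geometry(data.frame(db = 0, apex_rt = 6.5), b),
               "undefined for saturated")
  expect_identical(call_geometry(data.frame(db = 2, apex_rt = 80), b), "cis")
  expect_identical(call_geometry(data.frame(db = 2, apex_rt = 60), b),
                   "trans")
  # a class absent from the reference cannot be called
  expect_identical(call_geometry(data.frame(db = 3, apex_rt = 100),
                                 b[c("1", "2")]), "unknown")
})

test_that("allylic 13C shift separates cis from trans at the midpoint", {
  expect_identical(geometry_from_allylic_shift(27.20), "cis")
  expect_identical(geometry_from_allylic_shift(32.60), "trans")
  expect_identical(geometry_from_allylic_shift(29.9), "cis")
  expect_error(geometry_from_allylic_shift(45), "plausible")
  expect_error(geometry_from_allylic_shift(10), "plausible")
})

test_that("within-class relative areas always normalize to 100", {
  one_per_class <- data.frame(db = 0:3, area = c(5, 50, 500, 5000))
  q <- quantify_within_class(one_per_class)
  expect_equal(q$rel_area_pct, rep(100, 4))
  dienes <- data.frame(db = c(2, 2), area = c(3, 3))
  expect_equal(quantify_within_class(dienes)$rel_area_pct, c(50, 50))
  set.seed(1)
  rnd <- data.frame(db = sample(0:3, 40, replace = TRUE),
                    area = runif(40, 0.1, 10))
  qr <- quantify_within_class(rnd)
  sums <- tapply(qr$rel_area_pct, qr$db, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_error(quantify_within_class(data.frame(db = 0, area = 0)),
               "zero total area")
})
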