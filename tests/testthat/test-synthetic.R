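pk_ref <- pk_parameters(dose = 100, f = 1, ka = 1, ke = 0.1, v = 10)

test_that("parent profile obeys the one-compartment closed form", {
  p0 <- simulate_parent(pk_parameters(0, 1, 1, 0.1, 10), study_times)
  expect_true(all(p0$values == 0))
  p <- simulate_parent(pk_ref, study_times)
  expect_equal(p$values[1], 0)
  expect_true(all(p$values >= 0))
  # unimodal: differences change sign at most once
  dense <- simulate_parent(pk_ref, seq(0, 48, by = 0.05))
  signs <- sign(diff(dense$values))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)
  expect_error(pk_parameters(100, 1, 0.5, 0.5, 10), "differ")
})

test_that("dense trapezoid of the parent recovers F*D/(V*ke)", {
  auc <- trapezoid_auc(simulate_parent(pk_ref, seq(0, 200, by = 0.01)))$value
  expect_lt(abs(auc - 100) / 100 * 100, 0.5)  # F*D/(V*ke) = 100
})

test_that("metabolite formation respects mass balance", {
  spec <- metabolite_spec("p", "m", "glucuronidation", fraction = 0.3,
                          km = 0.7)
  grid <- seq(0, 400, by = 0.02)
  m <- simulate_metabolite(pk_ref, spec, grid)
  expect_equal(m$values[1], 0)
  expect_true(all(m$values >= 0))
  auc_m <- trapezoid_auc(m)$value
  auc_p <- trapezoid_auc(simulate_parent(pk_ref, grid))$value
  # AUC ratio = fraction * ke / km under linear kinetics
  expect_equal(auc_m / auc_p, 0.3 * 0.1 / 0.7, tolerance = 0.01)
  # zero formation fraction -> identically zero profile
  none <- simulate_metabolite(
    pk_ref, metabolite_spec("p", "m0", "sulfation", 0, 0.7), study_times)
  expect_true(all(none$values == 0))
})

test_that("degenerate rate equalities fall back to numerical integration", {
  # km == ke: Bateman denominators vanish; lsoda path must stay finite
  spec <- metabolite_spec("p", "m", "sulfation", fraction = 0.5, km = 0.1)
  grid <- seq(0, 400, by = 0.05)
  m <- simulate_metabolite(pk_ref, spec, grid)
  expect_false(anyNA(m$values))
  ratio <- trapezoid_auc(m)$value /
    trapezoid_auc(simulate_parent(pk_ref, grid))$value
  expect_equal(ratio, 0.5, tolerance = 0.01)  # fraction * ke/km, km = ke
  # km == ka likewise
  m2 <- simulate_metabolite(
    pk_ref, metabolite_spec("p", "m2", "sulfation", 0.5, 1), grid)
  expect_false(anyNA(m2$values))
})

test_that("assay noise is mean-preserving with the stated CV", {
  prof <- simulate_parent(pk_ref, study_times)
  clean <- apply_assay(prof, assay_model(cv = 0, lloq = 0), seed = 1)
  expect_equal(clean$values, 1000 * prof$values)
  # Monte-Carlo CV check at a fixed concentration
  const <- concentration_profile(seq_len(10000), rep(2, 10000))
  noisy <- apply_assay(const, assay_model(cv = 0.1, lloq = 0), seed = 2)
  expect_equal(stats::sd(noisy$values) / mean(noisy$values), 0.1,
               tolerance = 0.05)
  expect_equal(mean(noisy$values), 2000, tolerance = 0.01)
})

test_that("LLOQ censoring flags and zeroes, and draws are reproducible", {
  prof <- simulate_parent(pk_ref, study_times)
  censored <- apply_assay(prof, assay_model(cv = 0, lloq = 1e6), seed = 3)
  expect_true(all(censored$below_lloq))
  expect_true(all(censored$values == 0))
  a <- apply_assay(prof, assay_model(), seed = 11)
  b <- apply_assay(prof, assay_model(), seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, apply_assay(prof, assay_model(), seed = 12)$values))
  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(apply_assay(prof, assay_model(), seed = 5))
  expect_identical(runif(1), before)
  # internal-standard normalization switches the unit
  ratio <- apply_assay(prof, assay_model(cv = 0, lloq = 0, is_area = 500),
                       seed = 1)
  expect_equal(ratio$values, 1000 * prof$values / 500)
  expect_equal(ratio$unit_label, "area_ratio")
})

test_that("cohort simulation has the contracted shape and determinism", {
  tab <- simulate_cohort(c("human", "rat"), schedule = study_schedule,
                         replicates = 3, seed = 17)
  expect_s3_class(tab, "peak_area_matrix")
  expect_equal(nrow(tab), 2 * 10 * 3)
  expect_setequal(unique(tab$species), c("human", "rat"))
  expect_identical(
    tab,
    simulate_cohort(c("human", "rat"), schedule = study_schedule,
                    replicates = 3, seed = 17))
  expect_error(
    simulate_cohort("human",
                    panel = list(parents = list(), metabolites = list()),
                    schedule = study_schedule, seed = 1),
    "empty")
})

test_that("species pathway preferences swap the sulfate:glucuronide ratio", {
  assay0 <- assay_model(cv = 0, lloq = 0)
  tab <- simulate_cohort(c("human", "rat"), schedule = study_schedule,
                         assay = assay0, replicates = 1, seed = 5)
  ratio <- function(sp) {
    sulf <- sum(tab$area[tab$species == sp &
                           grepl("sulfate", tab$compound_id)])
    gluc <- sum(tab$area[tab$species == sp &
                           grepl("glucuronide", tab$compound_id)])
    sulf / gluc
  }
  expect_gt(ratio("human"), 1)  # sulfation-preferring settings
  expect_lt(ratio("rat"), 1)    # glucuronidation-preferring settings
})

test_that("noiseless cohorts satisfy the pooling identity end to end", {
  assay0 <- assay_model(cv = 0, lloq = 0)
  tab <- simulate_cohort("human", schedule = study_schedule, assay = assay0,
                         replicates = 1, seed = 5)
  profs <- aucpool:::panel_profiles(default_panel(), "human", study_times)
  for (cid in names(profs)) {
    serial_area <- concentration_profile(study_times,
                                         1000 * profs[[cid]]$values)
    trad <- trapezoid_auc(serial_area)$value
    pooled <- tab$area[tab$compound_id == cid] * 24
    expect_lt(abs(pooled - trad) / trad, 1e-10)
  }
})

test_that("mean pooled AUC over 200 noisy cohorts is unbiased within 2%", {
  prof <- simulate_parent(pk_ref, study_times)
  truth <- trapezoid_auc(prof)$value * 1000
  d <- pooling_volumes(study_schedule, 480, 0)
  assay <- assay_model(cv = 0.1, lloq = 0)
  means <- vapply(1:200, function(i) {
    mean(vapply(1:3, function(r) {
      noisy <- apply_assay(prof, assay, seed = i * 13 + r)
      pooled_auc(pool_concentration(noisy, d), study_schedule)$value
    }, 0))
  }, 0)
  expect_equal(mean(means), truth, tolerance = 0.02)
})

test_that("synthetic spectra carry Gaussian peaks of known area", {
  panel <- data.frame(compound_id = "c1", mz = 283.0248, rt_min = 5,
                      height = 1e6, sigma_min = 0.1)
  spectra <- synth_spectra(panel, seq(4, 6, by = 0.01))
  trace <- extract_eic(spectra, 283.0248, 5)
  area <- integrate_eic(trace, c(4, 6), "c1")$area
  expect_equal(area, 1e6 * 0.1 * sqrt(2 * pi), tolerance = 0.02)
  # empty panel -> spectra with zero centroids
  empty <- synth_spectra(panel[0, ], c(1, 2, 3))
  expect_length(empty, 3)
  expect_length(empty[[1]]$mz, 0)
  # near-coincident m/z targets trigger the overlap warning
  panel2 <- data.frame(compound_id = c("a", "b"),
                       mz = c(300, 300 * (1 + 8e-6)), rt_min = c(5, 5.5),
                       height = 1e5, sigma_min = 0.1)
  expect_warning(synth_spectra(panel2, seq(4, 6, 0.1), ppm_warn = 5),
                 "overlap")
})
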