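toy_matrix <- function(areas, species = "human", reps = 1) {
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(compound_id = names(areas), species = species, replicate = r,
               area = unname(areas))))
}

test_that("exposure ranking, spans and cumulative fractions are exact", {
  tab <- exposure_table(toy_matrix(c(A = 9, B = 1)),
                        sampling_schedule(c(0, 24)))
  expect_equal(tab$exposure, c(216, 24))
  expect_equal(tab$rank, c(1, 2))
  expect_equal(tab$cumulative_fraction, c(90, 100))
  single <- exposure_table(toy_matrix(c(only = 4)),
                           sampling_schedule(c(0, 12)))
  expect_equal(single$rank, 1)
  expect_equal(single$cumulative_fraction, 100)
  # replicate means feed the exposure
  tab3 <- exposure_table(toy_matrix(c(A = 2), reps = 3),
                         sampling_schedule(c(0, 10)))
  expect_equal(tab3$exposure, 20)
})

test_that("equal exposures are ranked by compound id and order is input-invariant", {
  m <- toy_matrix(c(zeta = 5, alpha = 5, mid = 7))
  tab <- exposure_table(m, sampling_schedule(c(0, 24)))
  expect_equal(tab$compound_id, c("mid", "alpha", "zeta"))
  shuffled <- m[c(3, 1, 2), ]
  expect_equal(exposure_table(shuffled, sampling_schedule(c(0, 24))),
               tab, ignore_attr = TRUE)
  expect_error(exposure_table(toy_matrix(c(A = 0, B = 0)),
                              sampling_schedule(c(0, 24))), "zero")
  expect_error(exposure_table(m[, -4], sampling_schedule(c(0, 24))),
               "area")
})

test_that("top-N cumulative fractions behave on both bases", {
  tab <- exposure_table(toy_matrix(c(a = 50, b = 30, c = 20)),
                        sampling_schedule(c(0, 1)))
  expect_equal(cumulative_fraction(tab, 2), 80)
  expect_equal(cumulative_fraction(tab, 3), 100)
  expect_equal(cumulative_fraction(tab, 1), 50)
  expect_equal(cumulative_fraction(tab, 2, basis = "count"), 200 / 3)
  expect_error(cumulative_fraction(tab, 0), "between")
  expect_error(cumulative_fraction(tab, 4), "between")
  # non-decreasing in top_n
  vals <- vapply(1:3, function(k) cumulative_fraction(tab, k), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("cross-species shares sum reference-set exposure", {
  tab <- exposure_table(toy_matrix(c(A = 30, B = 70)),
                        sampling_schedule(c(0, 1)))
  expect_equal(species_share("A", tab), 30)
  expect_equal(species_share(c("A", "B"), tab), 100)
  expect_equal(species_share(c("X", "Y"), tab), 0)  # disjoint set
  expect_equal(species_share("A", tab, basis = "count"), 50)
  expect_error(species_share(character(), tab), "non-empty")
  # multi-species tables require naming the species
  two <- exposure_table(rbind(toy_matrix(c(A = 1)),
                              toy_matrix(c(A = 2), species = "rat")),
                        sampling_schedule(c(0, 1)))
  expect_error(species_share("A", two), "several species")
  expect_equal(species_share("A", two, species = "rat"), 100)
})

test_that("time-percentage profiles normalize to 100 and are scale-free", {
  p <- percent_profile(concentration_profile(c(0, 1, 2), c(2, 6, 2)))
  expect_equal(p$values, c(20, 60, 20))
  expect_equal(sum(p$values), 100, tolerance = 1e-9)
  const <- percent_profile(concentration_profile(0:4, rep(3, 5)))
  expect_equal(const$values, rep(20, 5))
  big <- percent_profile(concentration_profile(c(0, 1, 2),
                                               1000 * c(2, 6, 2)))
  expect_equal(big$values, p$values)
  expect_error(percent_profile(concentration_profile(c(0, 1), c(0, 0))),
               "zero")
})

test_that("Pearson correlation matches the definitional oracle", {
  a <- concentration_profile(1:4, c(1, 2, 3, 5), "a")
  b <- concentration_profile(1:4, c(2, 4, 5, 9), "b")
  res <- correlate_profiles(a, b, normalize = FALSE)
  expect_equal(res$r, pearson_oracle(c(1, 2, 3, 5), c(2, 4, 5, 9)),
               tolerance = 1e-12)
  expect_equal(res$n, 4)
  # self-correlation and perfect anticorrelation
  expect_equal(correlate_profiles(a, a)$r, 1, tolerance = 1e-12)
  anti <- concentration_profile(1:4, 2 * mean(c(1, 2, 3, 5)) - c(1, 2, 3, 5),
                                "anti")
  expect_equal(correlate_profiles(a, anti, normalize = FALSE)$r, -1,
               tolerance = 1e-12)
  # symmetry, and the oracle over random seeded pairs
  set.seed(50)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- concentration_profile(1:n, runif(n, 0, 10), "x")
    y <- concentration_profile(1:n, runif(n, 0, 10), "y")
    rxy <- correlate_profiles(x, y, normalize = FALSE)
    expect_equal(rxy$r, pearson_oracle(x$values, y$values),
                 tolerance = 1e-10)
    expect_equal(rxy$r, correlate_profiles(y, x, normalize = FALSE)$r)
    expect_true(rxy$p >= 0 && rxy$p <= 1)
  }
  expect_error(correlate_profiles(
    concentration_profile(1:3, rep(2, 3)),
    concentration_profile(1:3, c(1, 2, 3))), "constant")
  expect_error(correlate_profiles(
    concentration_profile(1:2, 1:2), concentration_profile(1:2, 2:3)),
    "at least 3")
  # the p-value is the two-sided t transform of r
  r <- res$r; n <- res$n
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p, 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("correlations among compounds of one parent are positive in a noiseless cohort", {
  profs <- aucpool:::panel_profiles(default_panel(), "human", study_times)
  rhein_family <- profs[grep("rhein", names(profs))]
  ids <- names(rhein_family)
  for (i in seq_along(ids))
    for (j in seq_len(i - 1)) {
      r <- correlate_profiles(rhein_family[[ids[i]]],
                              rhein_family[[ids[j]]])$r
      expect_gt(r, 0)
    }
})

test_that("Q-marker selection applies the rank and correlation rules", {
  tab <- exposure_table(toy_matrix(c(a = 50, b = 30, c = 15, d = 4, e = 1)),
                        sampling_schedule(c(0, 24)),
                        reference_available = "a")
  mk_cor <- function(id, r, p) structure(
    list(compound_id = id, reference_id = "a", r = r, p = p, n = 12),
    class = "correlation_result")
  good <- lapply(c("b", "c", "d", "e"), mk_cor, r = 0.95, p = 1e-5)
  rep1 <- select_qmarker(tab, good, top_k = 5)
  expect_equal(rep1$candidate_id, "a")
  expect_true(rep1$pass)
  expect_true(all(rep1$companions$pass))
  # one weakly correlated companion is flagged, and only that one
  mixed <- c(lapply(c("b", "d", "e"), mk_cor, r = 0.95, p = 1e-5),
             list(mk_cor("c", 0.5, 1e-5)))
  rep2 <- select_qmarker(tab, mixed, top_k = 5)
  expect_false(rep2$pass)
  expect_equal(rep2$companions$compound_id[!rep2$companions$pass], "c")
  expect_match(rep2$reason, "c")
  # availability only at rank 3 -> the rank-3 compound is the candidate
  tab3 <- exposure_table(toy_matrix(c(a = 50, b = 30, c = 15, d = 4, e = 1)),
                         sampling_schedule(c(0, 24)),
                         reference_available = "c")
  mk_cor_c <- function(id, r, p) structure(
    list(compound_id = id, reference_id = "c", r = r, p = p, n = 12),
    class = "correlation_result")
  rep3 <- select_qmarker(
    tab3, lapply(c("a", "b", "d", "e"), mk_cor_c, r = 0.9, p = 1e-4),
    top_k = 5)
  expect_equal(rep3$candidate_id, "c")
  expect_equal(rep3$candidate_rank, 3)
  expect_true(rep3$pass)
  # no obtainable reference -> explicit null candidate with a reason
  rep4 <- select_qmarker(
    exposure_table(toy_matrix(c(a = 1, b = 2)),
                   sampling_schedule(c(0, 24))), list())
  expect_true(is.na(rep4$candidate_id))
  expect_false(rep4$pass)
  expect_match(rep4$reason, "reference")
  # missing correlation fails loudly
  rep5 <- select_qmarker(tab, good[1:3], top_k = 5)
  expect_false(rep5$pass)
  expect_match(rep5$reason, "missing correlation")
  expect_error(select_qmarker(tab, good, r_threshold = 1.2), "\\(0, 1\\)")
})
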