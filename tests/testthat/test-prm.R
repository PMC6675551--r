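test_that("heavy-label mass accounting counts label sites", {
  argR <- isotope_label("R")
  expect_equal(heavy_mass_shift("TGAARFDEF", argR), 10.008269)
  lysK <- isotope_label("K")
  expect_equal(heavy_mass_shift("AKAAKA", lysK), 2 * 8.014199)
  expect_error(heavy_mass_shift("TGAAGFDEF", argR), "no site|no 'R'")
  expect_error(isotope_label("R", mass_delta = -1), "positive")
})

test_that("fragment m/z matches the elemental-composition oracle", {
  expect_equal(fragment_mz("TGAARFDEF", "y", 1), 166.0863, tolerance = 1e-4)
  expect_equal(fragment_mz("TGAARFDEF", "b", 2), 159.0764, tolerance = 1e-4)
  set.seed(12)
  for (i in 1:50) {
    pep <- random_peptide(sample(8:12, 1))
    idx <- sample(nchar(pep) - 1, 1)
    z <- sample(1:2, 1)
    for (s in c("b", "y")) {
      expect_equal(fragment_mz(pep, s, idx, z),
                   oracle_fragment_mz(pep, s, idx, z), tolerance = 1e-5)
    }
  }
  expect_error(fragment_mz("TGAARFDEF", "y", 9), "index")
  expect_error(fragment_mz("TGAARFDEF", "y", 0), "index")
  expect_error(fragment_mz("TGAARFDEF", "y", 1, charge = 0), "charge")
})

test_that("b/y masses are additive to the precursor for random peptides", {
  set.seed(77)
  for (i in 1:500) {
    pep <- random_peptide(sample(8:15, 1))
    n <- nchar(pep)
    idx <- sample(n - 1, 1)
    b <- fragment_mz(pep, "b", idx, 1)
    y <- fragment_mz(pep, "y", n - idx, 1)
    # singly charged: mass(b_i) + mass(y_{n-i}) = precursor(1+) + proton
    expect_equal(b + y, oracle_precursor_mz(pep, 1) + 1.007276,
                 tolerance = 1e-4)
  }
})

test_that("heavy and light fragments differ by delta/charge iff the span holds the label", {
  label <- isotope_label("R")
  pep <- "TGAARFDEF"  # R at position 5
  for (z in 1:2) {
    for (idx in 1:8) {
      d_b <- fragment_mz(pep, "b", idx, z, label) - fragment_mz(pep, "b", idx, z)
      d_y <- fragment_mz(pep, "y", idx, z, label) - fragment_mz(pep, "y", idx, z)
      expect_equal(d_b, if (idx >= 5) label$mass_delta / z else 0,
                   tolerance = 1e-9)
      expect_equal(d_y, if (idx >= 5) label$mass_delta / z else 0,
                   tolerance = 1e-9)
    }
  }
  tab <- fragment_table(pep, label)
  expect_true(all((tab$mz_heavy > tab$mz_light) == tab$contains_label))
})

test_that("XIC extraction honors the 0.02 m/z window", {
  sig <- data.frame(time = c(1, 2, 3), mz = c(500.00, 500.00, 500.00),
                    intensity = c(5, 10, 5))
  xic <- extract_xic(sig, 500.00)
  expect_equal(xic$intensity, c(5, 10, 5))

  off <- data.frame(time = 1:3, mz = rep(500.03, 3), intensity = c(5, 10, 5))
  expect_equal(extract_xic(off, 500.00)$intensity, c(0, 0, 0))

  two <- data.frame(time = c(1, 1), mz = c(499.99, 500.01),
                    intensity = c(3, 4))
  expect_equal(extract_xic(two, 500.00)$intensity, 7)
  expect_error(extract_xic(two, 500, tol = 0), "positive")
})

test_that("identical traces validate; silent or shifted light channels do not", {
  cfg <- sim_config(seed = 21)
  tr <- gen_prm_traces("TGAARFDEF", cfg)
  rep1 <- coelution_score(tr$heavy, tr$heavy)  # channel vs itself
  expect_true(all(abs(rep1$fragment_correlations - 1) < 1e-12))
  expect_equal(rep1$verdict, "validated")
  expect_equal(rep1$apex_dt, 0)
  expect_equal(rep1$spectral_contrast, 1)

  silent <- tr$light
  silent$intensity <- 0
  w <- capture_warnings(rep2 <- coelution_score(silent, tr$heavy))
  expect_true(length(w) > 0 && all(grepl("degenerate", w)))
  expect_equal(rep2$verdict, "not_validated")

  shifted <- gen_prm_traces("TGAARFDEF",
                            sim_config(seed = 21,
                                       prm = list(apex_shift = 1.0,
                                                  noise_sd = 0)))
  rep3 <- coelution_score(shifted$light, shifted$heavy, max_apex_dt = 0.2)
  expect_gt(rep3$apex_dt, 0.2)
  expect_equal(rep3$verdict, "not_validated")
})

test_that("relaxing thresholds never flips a validated pair to not_validated", {
  set.seed(55)
  shifts <- c(0, stats::runif(19, 0, 0.3))  # include a clean co-eluting case
  verdicts <- t(vapply(seq_along(shifts), function(i) {
    cfg <- sim_config(seed = i,
                      prm = list(apex_shift = shifts[i],
                                 noise_sd = stats::runif(1, 0, 0.05)))
    tr <- gen_prm_traces("TGAARFDEF", cfg)
    c(strict = coelution_score(tr$light, tr$heavy, min_fragments = 4,
                               r_min = 0.95)$verdict,
      loose = coelution_score(tr$light, tr$heavy, min_fragments = 2,
                              r_min = 0.8)$verdict)
  }, character(2)))
  expect_true(any(verdicts[, "strict"] == "validated"))
  expect_false(any(verdicts[, "strict"] == "validated" &
                     verdicts[, "loose"] == "not_validated"))
})

test_that("light-contamination QC compares apexes at the stated threshold", {
  heavy <- data.frame(time = 1:5, intensity = c(0, 10, 100, 10, 0))
  none <- data.frame(time = 1:5, intensity = rep(0, 5))
  expect_equal(check_light_contamination(none, heavy), "pass")
  expect_equal(check_light_contamination(heavy, heavy), "fail")
  tiny <- data.frame(time = 1:5, intensity = c(0, 0.01, 0.1, 0.01, 0))
  expect_equal(check_light_contamination(tiny, heavy, threshold = 0.01),
               "pass")
  expect_error(check_light_contamination(none, none), "no signal")
})
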