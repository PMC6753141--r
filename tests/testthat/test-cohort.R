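test_that("subject sampling is deterministic and respects dispersion", {
  cfg <- cohort_config()
  t1 <- sample_subject(123, cfg)
  t2 <- sample_subject(123, cfg)
  expect_identical(t1, t2)
  expect_length(t1$fingers, 5)

  # zero dispersion collapses all subjects onto the medians
  cfg0 <- cohort_config(dispersion = 0)
  a <- sample_subject(1, cfg0)
  b <- sample_subject(999, cfg0)
  expect_identical(a, b)
  expect_equal(a$fingers[[1]]$epi$Rs, 300)

  # empirical CV of Rs across subjects matches the log-normal target
  cfg2 <- cohort_config(dispersion = 0.2)
  rs <- vapply(1:100, function(s) sample_subject(s, cfg2)$fingers[[1]]$epi$Rs,
               numeric(1))
  cv <- sd(rs) / mean(rs)
  expect_gt(cv, 0.15)
  expect_lt(cv, 0.25)
})

test_that("pair circuits share the parameters of shared fingers", {
  tmpl <- sample_subject(5)
  c12 <- pair_circuit_from_template(tmpl, 1, 2)
  c13 <- pair_circuit_from_template(tmpl, 1, 3)
  expect_identical(c12$z1, c13$z1)          # both start at finger 1's epidermis
  expect_identical(c12$z1, tmpl$fingers[[1]]$epi)
  expect_identical(c12$z4, tmpl$fingers[[2]]$epi)
  expect_error(pair_circuit_from_template(tmpl, 2, 2), "finger pair")
  expect_error(pair_circuit_from_template(tmpl, 0, 3), "finger pair")
})

test_that("pair circuit wiring matches its documented construction", {
  tmpl <- sample_subject(9)
  circ <- pair_circuit_from_template(tmpl, 2, 4)
  fa <- tmpl$fingers[[2]]
  fb <- tmpl$fingers[[4]]
  # interior dermis path: series resistances (+ body), series capacitances
  expect_equal(circ$z2$Rs, fa$dermis$Rs + fb$dermis$Rs + tmpl$body_resistance)
  expect_equal(circ$z2$Rp, fa$dermis$Rp + fb$dermis$Rp)
  expect_equal(circ$z2$Cp,
               fa$dermis$Cp * fb$dermis$Cp / (fa$dermis$Cp + fb$dermis$Cp))
  expect_equal(circ$z3$Rs, fa$sweat$Rs + fb$sweat$Rs)
})

test_that("symmetric template makes all 10 pair spectra identical", {
  tmpl <- sample_subject(1, cohort_config(dispersion = 0))
  fp <- finger_pairs()
  specs <- sapply(seq_len(nrow(fp)), function(p)
    pair_impedance(pair_circuit_from_template(tmpl, fp$a[p], fp$b[p])))
  expect_equal(max(apply(specs, 1, function(r) diff(range(r)))), 0)
})

test_that("session scale follows the inverse-temperature model", {
  expect_equal(session_scale(33, drift = 1, gamma = 0.02, t_ref = 33), 1)
  expect_equal(session_scale(20, drift = 1, gamma = 0), 1)  # switched off
  # closed form: 29 vs 37 degrees around t_ref 33 gives 1.08 vs 0.92
  expect_equal(session_scale(29, gamma = 0.02, t_ref = 33), 1.08)
  expect_equal(session_scale(37, gamma = 0.02, t_ref = 33), 0.92)
  expect_error(session_scale(30, gamma = -0.1), "gamma")
  expect_error(session_scale(1000, gamma = 0.02), "non-positive")
})

test_that("hotter sessions have lower impedance when gamma > 0", {
  ds <- generate_dataset(6, 4, 3, drift_sigma = 0, noise_sigma = 0,
                         gamma = 0.02, seed = 3)
  mean_z <- apply(ds$spectra, 1, mean)
  # within each subject, mean |Z| regresses on temperature with negative slope
  for (s in unique(ds$meta$subject_id)) {
    i <- ds$meta$subject_id == s
    expect_lt(coef(lm(mean_z[i] ~ ds$meta$temperature[i]))[2], 0)
  }
})

test_that("generated datasets are reproducible and correctly sized", {
  d1 <- small_dataset()
  d2 <- small_dataset()
  expect_identical(d1, d2)
  expect_identical(dim(d1$spectra), c(4L * 3L * 3L, 10L, 25L))
  d3 <- small_dataset(seed = 8)
  expect_false(identical(d1$spectra, d3$spectra))
  expect_error(generate_dataset(1, 3, 3), "n_subjects")
  expect_error(generate_dataset(4, 3, 3, noise_sigma = -1), "noise_sigma")
})

test_that("the study-scale geometry yields 2050 records of 250 values", {
  # structural count only; the full cohort is 41 subjects x 5 sessions x 10
  # placements, each record holding 10 pairs x 25 frequencies
  expect_equal(41 * 5 * 10, 2050)
  ds <- small_dataset()
  expect_equal(prod(dim(ds$spectra)[2:3]), 250)
})

test_that("noise-free repeats within a session are identical", {
  ds <- generate_dataset(3, 2, 4, noise_sigma = 0, seed = 11)
  for (s in unique(ds$meta$subject_id)) {
    for (ses in unique(ds$meta$session_id)) {
      i <- which(ds$meta$subject_id == s & ds$meta$session_id == ses)
      for (j in i[-1]) expect_equal(ds$spectra[j, , ], ds$spectra[i[1], , ])
    }
  }
})

test_that("session drift is common-mode: between-session spectral ratios are constant", {
  ds <- generate_dataset(3, 3, 2, noise_sigma = 0, drift_sigma = 0.3,
                         seed = 21)
  meta <- ds$meta
  for (s in unique(meta$subject_id)) {
    i1 <- which(meta$subject_id == s & meta$session_id == "D01")[1]
    i2 <- which(meta$subject_id == s & meta$session_id == "D02")[1]
    ratio <- ds$spectra[i2, , ] / ds$spectra[i1, , ]
    expect_lt(diff(range(ratio)), 1e-12)   # one constant across pairs & freqs
    expect_false(isTRUE(all.equal(ratio[1, 1], 1)))  # sessions actually move
  }
})

test_that("with drift active, raw log spectra vary across sessions but ratio features do not", {
  ds <- generate_dataset(3, 3, 2, noise_sigma = 0, drift_sigma = 0.3,
                         seed = 31)
  raw <- featurize(ds, "raw")
  ratio <- featurize(ds, "ratiometric")
  for (s in unique(ds$meta$subject_id)) {
    i <- ds$meta$subject_id == s
    expect_gt(mean(apply(log(raw[i, ]), 2, var)), 0)
    expect_equal(max(apply(ratio[i, ], 2, var)), 0, tolerance = 1e-20)
  }
})

test_that("drift heterogeneity breaks the common-mode premise", {
  ds <- generate_dataset(3, 3, 2, noise_sigma = 0, drift_sigma = 0.2,
                         drift_heterogeneity = 0.1, seed = 41)
  ratio <- featurize(ds, "ratiometric")
  i <- ds$meta$subject_id == "S01"
  expect_gt(max(apply(ratio[i, ], 2, var)), 0)   # no longer session-invariant
  expect_error(generate_dataset(3, 2, 2, drift_heterogeneity = -0.1),
               "drift_heterogeneity")
})
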