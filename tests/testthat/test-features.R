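test_that("there are exactly 10 canonical finger pairs from 5 fingers", {
  fp <- finger_pairs()
  expect_equal(nrow(fp), choose(5, 2))
  expect_true(all(fp$a < fp$b))
  expect_false(anyDuplicated(fp$label) > 0)
})

test_that("ratio_combination enforces the derangement invariants", {
  fp <- finger_pairs()
  expect_error(ratio_combination(fp$label, fp$label), "itself")
  expect_error(ratio_combination(fp$label[c(1, 1:9)], fp$label[c(2:10, 1)]),
               "exactly once")
  expect_error(ratio_combination(fp$label[1:5], fp$label[6:10]), "exactly 10")
  expect_error(ratio_combination(c(fp$label[1:9], "2-1"), fp$label[c(10, 1:9)]),
               "unknown pair")
  ok <- ratio_combination(fp$label, fp$label[c(2:10, 1)])
  expect_s3_class(ok, "ratio_combination")
})

test_that("the published combination set is the printed list and a single 10-cycle", {
  pc <- published_combination()
  expect_equal(pc$num[1], "1-2")
  expect_equal(pc$den[1], "4-5")
  expect_equal(pc$num, c("1-2", "1-3", "1-5", "1-4", "2-3",
                         "2-5", "2-4", "3-5", "3-4", "4-5"))
  expect_equal(pc$den, c("4-5", "1-2", "1-3", "1-5", "1-4",
                         "2-3", "2-5", "2-4", "3-5", "3-4"))
  # cycle decomposition of the induced permutation on canonical pair indices
  fp <- finger_pairs()
  sigma <- integer(10)
  sigma[match(pc$num, fp$label)] <- match(pc$den, fp$label)
  visited <- logical(10)
  cur <- 1L
  len <- 0L
  repeat {
    visited[cur] <- TRUE
    len <- len + 1L
    cur <- sigma[cur]
    if (cur == 1L) break
  }
  expect_equal(len, 10L)      # one orbit covers all pairs
  expect_true(all(visited))
})

test_that("45 candidate combinations exist and 10 are used", {
  expect_equal(choose(10, 2), 45)
  expect_equal(nrow(published_combination()), 10)
})

test_that("ratiometric transform divides spectra element-wise in declared order", {
  m <- toy_record(n_freq = 2)
  pc <- published_combination()
  v <- ratiometric_transform(m, pc)
  expect_length(v, 20)
  # first combination, both frequencies: pair(1,2)/pair(4,5)
  expect_equal(unname(v[1:2]), unname(m["1-2", ] / m["4-5", ]))
  # last combination: pair(4,5)/pair(3,4)
  expect_equal(unname(v[19:20]), unname(m["4-5", ] / m["3-4", ]))

  # identical spectra give all-ones
  m1 <- m
  m1[] <- rep(m1[1, ], each = 10)
  expect_equal(unname(ratiometric_transform(m1, pc)), rep(1, 20))

  # two-point toy: num (100, 80) over den (50, 40) is (2, 2)
  m2 <- m
  m2["1-2", ] <- c(100, 80)
  m2["4-5", ] <- c(50, 40)
  expect_equal(unname(ratiometric_transform(m2, pc)[1:2]), c(2, 2))
})

test_that("ratiometric features cancel common-mode scaling exactly", {
  m <- toy_record()
  pc <- published_combination()
  base <- ratiometric_transform(m, pc)
  for (s in c(3.7, 0.2, 151)) {
    expect_equal(ratiometric_transform(m * s, pc), base, tolerance = 1e-12)
  }
})

test_that("ratio features telescope to a unit product at every frequency", {
  m <- toy_record()
  for (combos in list(published_combination(),
                      ratio_combination(finger_pairs()$label,
                                        finger_pairs()$label[c(2:10, 1)]))) {
    v <- matrix(ratiometric_transform(m, combos), nrow = 10, byrow = TRUE)
    prods <- apply(v, 2, prod)
    expect_equal(prods, rep(1, 25), tolerance = 1e-9)
  }
})

test_that("raw features follow the canonical ordering", {
  m <- toy_record()
  v <- raw_features(m)
  expect_length(v, 250)
  expect_equal(unname(v[1]), unname(m["1-2", 1]))    # pair (1,2), 20 kHz
  expect_equal(unname(v[250]), unname(m["4-5", 25])) # pair (4,5), 500 kHz
  m3 <- m
  m3[] <- 100
  expect_equal(unname(raw_features(m3)), rep(100, 250))
  expect_error(raw_features(m[-1, ]), "all 10")
  expect_error(ratiometric_transform(-m), "> 0")
})

test_that("featurize produces one 250-element vector per record", {
  ds <- small_dataset()
  x <- featurize(ds, "ratiometric")
  expect_equal(dim(x), c(36L, 250L))
  expect_true(all(is.finite(x)) && all(x > 0))
  expect_equal(unname(x[3, ]),
               unname(ratiometric_transform(ds$spectra[3, , ])))
})

test_that("branch-and-bound selection equals exhaustive enumeration on small instances", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    cost <- outer(rnorm(n), rnorm(n), function(x, y) (x - y)^2)
    got <- zratio:::min_cost_derangement(cost)
    want <- zratio:::min_cost_derangement_bruteforce(cost)
    expect_equal(got$sigma, want$sigma)
    expect_equal(got$objective, want$objective, tolerance = 1e-12)
    expect_true(all(got$sigma != seq_len(n)))   # fixed-point free
  }
})

test_that("degenerate selection ties break to the lexicographically smallest derangement", {
  cost <- matrix(0, 5, 5)   # all assignments equal
  got <- zratio:::min_cost_derangement(cost)
  expect_equal(got$objective, 0)
  expect_equal(got$sigma, zratio:::all_derangements(5)[1, ])
  expect_equal(got$sigma, c(2L, 1L, 4L, 5L, 3L))
})

test_that("select_combinations returns a valid, optimal combination set", {
  ds <- small_dataset()
  sel <- select_combinations(ds)
  expect_s3_class(sel, "ratio_combination")
  expect_gte(attr(sel, "objective"), 0)
  # optimality against a direct exhaustive search over all 10-pair
  # derangements restricted to a random subsample is infeasible; instead
  # verify the objective is reproduced from the returned assignment
  m <- apply(log(ds$spectra), 2, mean)
  fp <- finger_pairs()
  sigma <- match(sel$den, fp$label)[match(fp$label, sel$num)]
  expect_equal(sum((m - m[sigma])^2), attr(sel, "objective"))
  expect_error(select_combinations(list()), "spectra_dataset")
})

test_that("selection prefers denominators with matching log-scale", {
  # construct a dataset-like object where pair p's magnitudes cluster at
  # distinct levels; pairs with equal levels should be matched together
  ds <- small_dataset()
  lv <- rep(c(1, 2, 3, 4, 5), each = 2)      # five matched level pairs
  ds$spectra[] <- 0
  for (p in 1:10) ds$spectra[, p, ] <- exp(lv[p])
  sel <- select_combinations(ds)
  expect_equal(attr(sel, "objective"), 0)
  fp <- finger_pairs()
  sigma <- match(sel$den, fp$label)[match(fp$label, sel$num)]
  expect_equal(lv[sigma], lv)   # every numerator got an equal-level denominator
})
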