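test_that("structures are deterministic walks with native-like geometry", {
  st1 <- generate_structure(60, seed = 5)
  st2 <- generate_structure(60, seed = 5)
  expect_identical(st1$record$coords, st2$record$coords)
  expect_false(identical(st1$record$coords,
                         generate_structure(60, seed = 6)$record$coords))
  # consecutive residues sit one virtual bond apart
  steps <- sqrt(rowSums(diff(st1$record$coords)^2))
  expect_equal(steps, rep(3.8, 59), tolerance = 1e-9)
  # non-adjacent residues respect the exclusion radius
  D <- as.matrix(dist(st1$record$coords))
  far <- D[abs(row(D) - col(D)) >= 2]
  expect_true(all(far >= 4.0 - 1e-9))
})

test_that("contact density lands in the sparse native band", {
  dens <- vapply(1:25, function(s) generate_structure(120, seed = s)$density,
                 numeric(1))
  expect_true(all(dens >= 0.01 & dens <= 0.05))
  expect_gt(mean(dens), 0.015)   # mean near the 2-3% native sparsity
  expect_lt(mean(dens), 0.035)
})

test_that("synthetic CM matrices span the oracle-to-noise range", {
  st <- cached("synth_struct_80", generate_structure(80, seed = 9))
  pairs <- enumerate_pairs(80, "all")
  truth <- st$cmap$contacts[pairs]

  oracle <- generate_cm_scores(st$cmap, rho = 1, seed = 1)
  s <- oracle$scores[pairs]
  # ranking by a rho = 1 matrix retrieves exactly the true contacts first
  expect_true(all(s[truth] == 1) && all(s[!truth] == 0))
  expect_identical(oracle$scores, t(oracle$scores))

  # rho = 0: top-L/5 precision matches the base rate in expectation
  k <- k_from_L(80, "L5")
  prec0 <- vapply(1:25, function(sd) {
    noise <- generate_cm_scores(st$cmap, rho = 0, seed = sd)$scores[pairs]
    100 * sum(truth[order(-noise)[1:k]]) / k
  }, numeric(1))
  base <- 100 * mean(truth)
  se <- sd(prec0) / sqrt(length(prec0))
  expect_lt(abs(mean(prec0) - base), 3 * se + 1e-9)

  # precision is monotone non-decreasing in rho over seed averages
  sweep <- vapply(c(0, 0.4, 0.8, 1), function(r) {
    mean(vapply(1:10, function(sd) {
      sc <- generate_cm_scores(st$cmap, rho = r, seed = sd)$scores[pairs]
      100 * sum(truth[order(-sc)[1:k]]) / k
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sweep) >= -1e-9))
})

test_that("restricted signal ranges leave other classes at noise level", {
  st <- cached("synth_struct_80", generate_structure(80, seed = 9))
  cm <- generate_cm_scores(st$cmap, rho = 1, seed = 2, signal_range = "long")
  lp <- enumerate_pairs(80, "long")
  sp <- enumerate_pairs(80, "short")
  expect_true(all(cm$scores[lp][st$cmap$contacts[lp]] == 1))
  expect_true(all(cm$scores[sp][st$cmap$contacts[sp]] < 1))
})

test_that("feature fixtures parse back through the format readers", {
  st <- cached("synth_struct_80", generate_structure(80, seed = 9))
  tg <- generate_target(80, seed = 9, rho = c(psicov = 0.7, ccmpred = 0.2),
                        informativeness = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_fixture_target(tg, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fixture_target(dir, tg$record$id)
  expect_identical(back$record$sequence, tg$record$sequence)
  expect_equal(back$record$coords, tg$record$coords, tolerance = 1e-3)
  expect_identical(back$cmap$contacts, tg$cmap$contacts)
  expect_equal(unname(back$pssm$scores), unname(tg$pssm$scores))
  expect_identical(back$ss, tg$ss)
  expect_identical(back$sa, tg$sa)
  expect_equal(back$cm$psicov$scores, tg$cm$psicov$scores, tolerance = 1e-4)
  expect_equal(dim(back$feature_table), dim(tg$feature_table))
})

test_that("target generation is fully deterministic in (parameters, seed)", {
  a <- generate_target(60, seed = 3, rho = c(x = 0.5), informativeness = 0.7)
  b <- generate_target(60, seed = 3, rho = c(x = 0.5), informativeness = 0.7)
  expect_identical(a$record$coords, b$record$coords)
  expect_identical(a$cm$x$scores, b$cm$x$scores)
  expect_identical(a$pssm$scores, b$pssm$scores)
  expect_identical(a$ss, b$ss)
  expect_identical(a$feature_table, b$feature_table)
})

test_that("planted informativeness is visible in the profile columns", {
  st <- cached("synth_struct_80", generate_structure(80, seed = 9))
  f1 <- generate_features(st$record, st$cmap, informativeness = 1, seed = 4)
  f0 <- generate_features(st$record, st$cmap, informativeness = 0, seed = 4)
  pairs <- enumerate_pairs(80, "all")
  con <- pairs[st$cmap$contacts[pairs], , drop = FALSE]
  cols <- 1L + (con[, 2] - con[, 1]) %% 20L
  planted <- f1$pssm$scores[cbind(con[, 1], cols)]
  null_ <- f0$pssm$scores[cbind(con[, 1], cols)]
  expect_gt(mean(planted) - mean(null_), 5)   # amp = 10 bump is visible
  expect_identical(f0$ss, f1$ss)              # plant only touches the profile
})
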