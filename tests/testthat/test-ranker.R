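test_that("relevance binning orders pairs by distance", {
  phi <- matrix(runif(8), 4, 2)
  g <- build_rank_examples("q", phi, c(5, 20, 13, 9))
  expect_s3_class(g, "rank_group")
  expect_gt(g$relevance[1], g$relevance[2])   # 5 A above 20 A
  expect_equal(g$relevance, c(5L, 1L, 3L, 4L))

  same <- build_rank_examples("q", phi, rep(10, 4))
  expect_equal(nrow(pairwise_differences(same)), 0)

  big <- build_rank_examples("q", matrix(runif(60), 30, 2), runif(30, 4, 30),
                             pair_cap = 12, seed = 9)
  expect_equal(nrow(big$phi), 12)
  big2 <- build_rank_examples("q", matrix(runif(60), 30, 2), runif(30, 4, 30),
                              pair_cap = 12, seed = 9)
  expect_equal(nrow(big2$phi), 12)
})

test_that("difference vectors enumerate ordered relevance pairs", {
  mk <- function(rel) structure(list(qid = "q",
                                     phi = matrix(seq_along(rel), ncol = 1),
                                     relevance = as.integer(rel)),
                                class = "rank_group")
  expect_equal(nrow(pairwise_differences(mk(c(3, 2, 1)))), 3)
  expect_equal(nrow(pairwise_differences(mk(c(2, 2, 1, 1, 1)))), 6)  # 2 x 3
  expect_equal(nrow(pairwise_differences(mk(1))), 0)
  # differences always point from higher to lower relevance
  d <- pairwise_differences(mk(c(2, 1)))
  expect_equal(as.numeric(d), 1 - 2)  # phi ordered by position here
  # never crosses query groups: list input is per-group concatenation
  two <- list(mk(c(2, 1)), mk(c(5, 4)))
  expect_equal(nrow(pairwise_differences(two)), 2)
})

test_that("the 1-D closed form w* = min(1, C n) is reproduced exactly", {
  for (n in c(1, 3, 10)) {
    d <- matrix(1, n, 1)
    for (C in c(0.01, 0.1, 2)) {
      m <- train_rank_svm(d, C = C, tol = 1e-12)
      expect_equal(m$w, min(1, C * n), tolerance = 1e-8)
    }
  }
})

test_that("separable 2-D toys satisfy the margin at large C", {
  m <- train_rank_svm(rbind(c(1, 0), c(0, 1)), C = 100, tol = 1e-12)
  expect_true(all(m$w >= 1 - 1e-6))
  expect_equal(m$w, c(1, 1), tolerance = 1e-6)
})

test_that("solver objective matches the quadprog dual oracle on toys", {
  skip_if_not_installed("quadprog")
  with_seed(31, {
    for (rep in 1:12) {
      n <- sample(3:30, 1)
      p <- sample(2:5, 1)
      X <- matrix(rnorm(n * p), n, p)
      C <- sample(c(0.05, 0.5, 2), 1)
      fit <- train_rank_svm(X, C = C, tol = 1e-12, max_iter = 200000L)
      oracle <- rank_svm_qp_oracle(X, C)
      expect_lt(abs(fit$objective - oracle$objective), 1e-6)
      # and neither beats the other as a minimizer
      expect_lt(fit$objective, oracle$objective + 1e-6)
      expect_lt(oracle$objective, fit$objective + 1e-6)
    }
  })
})

test_that("non-convergence is an error carrying the final objective", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(train_rank_svm(X, C = 10, tol = 1e-14, max_iter = 1L),
               "did not converge")
})

test_that("noiseless linear relevance is recovered with Kendall tau 1", {
  with_seed(17, {
    w_true <- c(0.8, 0.15, 0.05)
    for (q in 1:5) {
      phi <- matrix(runif(120), 40, 3)
      u <- as.numeric(phi %*% w_true)
      edges <- quantile(u, 1:3 / 4)
      # points hugging a bin edge make zero-margin constraints that no
      # finite-norm linear scorer can separate under a finite C
      keep <- apply(abs(outer(u, edges, "-")), 1, min) > 0.03
      phi <- phi[keep, , drop = FALSE]
      rel <- findInterval(u[keep], edges) + 1L
      n <- nrow(phi)
      expect_gte(n, 12)
      g <- structure(list(qid = paste0("q", q), phi = phi,
                          relevance = rel), class = "rank_group")
      m <- train_rank_svm(pairwise_differences(g), C = 50, tol = 1e-10,
                          max_iter = 200000L)
      s <- rank_score(m, phi)
      # every strictly-ordered relevance pair is ordered correctly:
      # Kendall tau over comparable pairs is exactly 1
      ok <- TRUE
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (rel[a] != rel[b]) {
          ok <- ok && (sign(s[a] - s[b]) == sign(rel[a] - rel[b]))
        }
      }
      expect_true(ok)
    }
  })
})

test_that("rank_score is the linear form with its documented edge cases", {
  m <- structure(list(w = c(1, 0, 0), C = 1, feature_names = NULL),
                 class = "rank_model")
  phi <- matrix(runif(30), 10, 3)
  expect_equal(rank_score(m, phi), phi[, 1])
  m0 <- structure(list(w = c(0, 0, 0), C = 1), class = "rank_model")
  expect_equal(rank_score(m0, phi), rep(0, 10))
  expect_error(rank_score(m, phi[, 1:2]), "mismatch")

  # positive scaling of features preserves the output order
  m2 <- structure(list(w = c(0.3, -0.2, 1.1), C = 1), class = "rank_model")
  s1 <- rank_score(m2, phi)
  s2 <- rank_score(m2, phi * 7.3)
  expect_equal(order(s1), order(s2))
})

test_that("C is selected by grouped cross-validation over the grid", {
  with_seed(23, {
    groups <- lapply(1:6, function(q) {
      phi <- matrix(runif(40), 20, 2)
      u <- phi %*% c(1, 0.1)
      rel <- as.integer(cut(u, quantile(u, 0:4 / 4), include.lowest = TRUE))
      structure(list(qid = paste0("q", q), phi = phi, relevance = rel),
                class = "rank_group")
    })
    cv <- cv_select_C(groups, C_grid = c(0.1, 1, 10), nfolds = 3, seed = 1)
    expect_true(cv$C %in% c(0.1, 1, 10))
    expect_length(cv$accuracy, 3)
    expect_true(all(cv$accuracy > 0.5))   # signal is learnable
    expect_equal(sort(unique(cv$folds)), 1:3)
  })
})

test_that("stage-1 assembly enforces the configured CM inputs", {
  with_seed(41, {
    st <- generate_structure(60, seed = 2)
    tg <- list(record = st$record, cmap = st$cmap,
               cm = list(psicov = generate_cm_scores(st$cmap, 0.5, 1)),
               feature_table = noise_table(60))
    s1 <- stage1_features(tg, NULL, "long", cm_names = "psicov")
    expect_equal(colnames(s1$phi), "psicov")
    expect_true(all(s1$phi >= 0 & s1$phi <= 1))
    expect_error(stage1_features(tg, NULL, "long", cm_names = c("psicov", "gremlin")),
                 "missing correlated-mutations input")
    expect_warning(
      s2 <- stage1_features(tg, NULL, "long", cm_names = c("psicov", "gremlin"),
                            allow_missing = TRUE),
      "set to 0")
    expect_equal(unname(s2$phi[, "gremlin"]), rep(0, nrow(s2$phi)))
  })
})

test_that("prediction lists from constant scores use the tie order", {
  with_seed(43, {
    st <- generate_structure(60, seed = 4)
    tg <- list(record = st$record, cmap = st$cmap,
               cm = list(psicov = structure(list(
                 scores = matrix(0.5, 60, 60), method_tag = "psicov"),
                 class = "cm_scores")))
    m <- structure(list(w = 1, C = 1, feature_names = "psicov"),
                   class = "rank_model")
    p <- predict_contacts(tg, NULL, m, "long")
    ep <- enumerate_pairs(60, "long")
    expect_equal(p$i, ep[, 1])
    expect_equal(p$j, ep[, 2])
    expect_true(all(p$score == 0.5))    # constant scores map to 0.5
  })
})
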