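test_that("list lengths follow the Top5 / floor(L/10) / floor(L/5) rules", {
  expect_equal(k_from_L(100, "L5"), 20)
  expect_equal(k_from_L(47, "L10"), 4)
  expect_equal(k_from_L(9, "L10"), 1)       # floor gives 0, clamped
  expect_equal(k_from_L(9, "top5"), 5)
  expect_equal(k_from_L(47, "L10", rounding = "ceiling"), 5)
  expect_equal(k_from_L(47, "L5", rounding = "round"), 9)
  # floor agrees with brute-force list slicing
  for (L in c(10, 47, 100, 333)) {
    expect_equal(k_from_L(L, "L5"), max(1, length(seq_len(L %/% 5))))
  }
})

test_that("precision_at_k is 100 * TP / k with the documented edge cases", {
  L <- 60
  pairs <- enumerate_pairs(L, "long")
  co <- matrix(FALSE, L, L)
  truth <- pairs[1:20, , drop = FALSE]
  co[truth] <- TRUE; co[truth[, c(2, 1)]] <- TRUE
  cmap <- structure(list(distances = ifelse(co, 5, 30), contacts = co,
                         threshold = 8, L = L), class = "contact_map")

  # top-20 list with 13 true contacts -> 65%
  sel <- rbind(truth[1:13, ], pairs[30:36, ])
  pl <- prediction_list("t", sel[, 1], sel[, 2], seq(1, 0.5, length.out = 20))
  expect_equal(precision_at_k(pl, cmap, "long", 20), 65.0)
  # top-5 with 3 true
  sel5 <- rbind(truth[1:3, ], pairs[40:41, ])
  pl5 <- prediction_list("t", sel5[, 1], sel5[, 2], c(9:5) / 10)
  expect_equal(precision_at_k(pl5, cmap, "long", 5), 60.0)
  # predictions identical to the contact set
  oracle <- prediction_list("t", truth[, 1], truth[, 2], rep(0.9, 20))
  expect_equal(precision_at_k(oracle, cmap, "long", 20), 100)
  # fewer predictions than k: denominator is what was taken
  expect_equal(precision_at_k(pl5, cmap, "long", 50), 60.0)

  # replacing a false positive by a true contact never lowers precision
  with_seed(3, {
    for (rep in 1:5) {
      n_true <- sample(3:10, 1)
      sel <- rbind(truth[seq_len(n_true), ], pairs[50:(59 - n_true), ])
      base <- prediction_list("t", sel[, 1], sel[, 2], runif(10))
      p0 <- precision_at_k(base, cmap, "long", 10)
      sel2 <- rbind(truth[seq_len(n_true + 1), ], pairs[50:(58 - n_true), ])
      better <- prediction_list("t", sel2[, 1], sel2[, 2], runif(10))
      expect_gte(precision_at_k(better, cmap, "long", 10), p0)
    }
  })
})

test_that("pairs outside the requested range class are not scored", {
  L <- 40
  co <- matrix(FALSE, L, L); co[1, 30] <- co[30, 1] <- TRUE
  cmap <- structure(list(distances = ifelse(co, 5, 30), contacts = co,
                         threshold = 8, L = L), class = "contact_map")
  pl <- prediction_list("t", c(1, 2), c(30, 10), c(0.3, 0.9))  # long + short
  expect_equal(precision_at_k(pl, cmap, "long", 1), 100)
  expect_equal(precision_at_k(pl, cmap, "short", 1), 0)
})

test_that("the paired t-test matches the textbook statistic", {
  a <- c(60, 70, 80, 55, 90); b <- c(50, 72, 78, 50, 85)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  got <- paired_t_test(a, b)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_equal(got$df, 4)

  expect_equal(paired_t_test(a, a)$p_value, 1.0)
  expect_warning(deg <- paired_t_test(a, a - 3), "zero variance")
  expect_equal(deg$p_value, 0)
  expect_error(paired_t_test(1, 2), "at least 2")
  # name matching restricts to shared targets
  expect_equal(paired_t_test(setNames(a, letters[1:5]),
                             setNames(b, letters[1:5]))$t, t_hand)
})

test_that("scatter tables partition targets around the diagonal", {
  a <- setNames(c(50, 60, 70), c("t1", "t2", "t3"))
  same <- scatter_report(a, a)
  expect_equal(unname(same$counts), c(0, 0, 3))
  b <- a; b["t2"] <- 65
  sc <- scatter_report(a, b)
  expect_equal(unname(sc$counts["above"]), 1)
  expect_equal(sum(sc$counts), 3)
  expect_error(scatter_report(a, setNames(1, "zz")), "share no targets")
})

test_that("reports macro-average per-target cells and filter short domains", {
  mk_cell <- function(p) data.frame(range = rep(c("short", "medium", "long"), each = 3),
                                    metric = rep(c("top5", "L10", "L5"), 3),
                                    k = 5, precision = p)
  per_target <- list(t1 = mk_cell(100), t2 = mk_cell(50), t3 = mk_cell(0))
  lens <- c(t1 = 100L, t2 = 80L, t3 = 40L)   # t3 too short to evaluate
  rep_ <- evaluation_report(per_target, lens)
  expect_equal(rep_$n_targets, 2)
  expect_true(all(rep_$aggregate$precision == 75))
  expect_error(evaluation_report(per_target, c(t1 = 10L, t2 = 20L, t3 = 30L)),
               "length > 50")
})

test_that("oracle predictions score 100% in every cell", {
  tg <- cached("eval_target", generate_target(70, seed = 12, rho = c(m = 0.5),
                                              informativeness = 0))
  preds <- list()
  for (rc in c("short", "medium", "long")) {
    p <- enumerate_pairs(70, rc)
    truth <- p[tg$cmap$contacts[p], , drop = FALSE]
    preds[[rc]] <- prediction_list(tg$record$id, truth[, 1], truth[, 2],
                                   rep(1, nrow(truth)), range_class = rc)
  }
  res <- evaluate_target(preds, tg$cmap)
  expect_true(all(res$precision == 100))
})
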