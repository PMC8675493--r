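scores_fixture <- function(n = 100, n_sig = 5, seed = 81, with_resid = TRUE,
                           nan_cells = 0) {
  set.seed(seed)
  m <- matrix(runif(n * n_sig), n, n_sig,
              dimnames = list(sprintf("c%03d", 1:n),
                              sprintf("s%02d", 1:n_sig)))
  if (nan_cells > 0) m[seq_len(nan_cells), 1] <- NaN
  res <- if (with_resid)
    matrix(rnorm(n * n_sig), n, n_sig, dimnames = dimnames(m)) else NULL
  structure(list(scaled = m, normalised = m - 0.5,
                 switch_points = setNames(runif(n_sig), colnames(m)),
                 residuals = res, sig_stats = NULL,
                 provenance = list(collection = "fixture")),
            class = "ScoreMatrix")
}

test_that("per-group statistics match a brute-force oracle to 1e-12", {
  sc <- scores_fixture(n = 100, n_sig = 5, nan_cells = 7)
  groups <- factor(rep(c("g1", "g2"), 50))
  tab <- signature_stats(sc, groups)
  or <- oracle_stats(sc$scaled, sc$residuals, sc$switch_points, groups)
  expect_equal(nrow(tab), 10L)
  for (col in c("switch_point", "mean", "median", "sd", "variance", "min",
                "max", "prop_nan", "residuals_mean")) {
    expect_equal(tab[[col]], or[[col]], tolerance = 1e-12, label = col)
  }
  expect_true(all(tab$min <= tab$median & tab$median <= tab$max))
  expect_error(signature_stats(sc, factor(rep("g1", 100),
                                          levels = c("g1", "empty"))),
               "empty")
})

test_that("constant columns and NaN counting behave in signature_stats", {
  sc <- scores_fixture(n = 10, n_sig = 2, seed = 82)
  sc$scaled[, 1] <- 0.4
  sc$scaled[1:2, 2] <- NaN
  tab <- signature_stats(sc, rep("all", 10))
  s1 <- tab[tab$signature == "s01", ]
  expect_equal(s1$sd, 0)
  expect_equal(s1$variance, 0)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$mean, s1$median)
  expect_equal(tab[tab$signature == "s02", "prop_nan"], 0.2)
})

test_that("4-squares corners follow the switch-point / residual-mean rule", {
  sc <- scores_fixture(n = 60, n_sig = 10, seed = 83)
  sc$switch_points[] <- c(0, 1, 0.5, runif(7, 0.3, 0.7))
  tab <- signature_stats(sc, rep("g", 60))
  # put signature 1 at the residual-mean maximum, 2 at the minimum,
  # 3 exactly at the median
  tab$residuals_mean <- rank(tab$residuals_mean)
  tab$residuals_mean[1] <- 100
  tab$residuals_mean[2] <- -100
  tab$residuals_mean[3] <- median(tab$residuals_mean[-(1:2)])
  fsq <- four_squares(tab, "g")
  expect_equal(fsq$quadrant[1], "bottom_right_most_sensitive")
  expect_equal(fsq$quadrant[2], "top_left_least_sensitive")
  expect_equal(fsq$quadrant[3], "unclassified")

  no_res <- signature_stats(scores_fixture(with_resid = FALSE),
                            rep("g", 100))
  expect_error(four_squares(no_res, "g"), "regress_out")
})

test_that("4-squares is invariant to cell order and group relabelling", {
  sc <- scores_fixture(n = 80, n_sig = 8, seed = 84)
  groups <- rep(c("a", "b"), 40)
  f1 <- four_squares(signature_stats(sc, groups), "a")
  # permute cells
  perm <- sample(80)
  sc2 <- sc
  sc2$scaled <- sc$scaled[perm, ]
  sc2$residuals <- sc$residuals[perm, ]
  f2 <- four_squares(signature_stats(sc2, groups[perm]), "a")
  expect_equal(f1$quadrant, f2$quadrant)
  # monotone relabelling of groups
  groups3 <- ifelse(groups == "a", "group_1", "group_2")
  f3 <- four_squares(signature_stats(sc, groups3), "group_1")
  expect_equal(f1$quadrant, f3$quadrant)
})

test_that("differential ranking finds a planted shift and orders by effect", {
  sc <- scores_fixture(n = 200, n_sig = 8, seed = 85)
  cond <- rep(c("A", "B"), 100)
  shift <- 3 * sd(sc$residuals[, 4])
  sc$residuals[cond == "A", 4] <- sc$residuals[cond == "A", 4] + shift
  rd <- rank_differential(sc, cond, n_perm = 500, seed = 6)
  expect_equal(rd$signature[1], "s04")
  expect_lt(rd$fdr[1], 0.05)
  expect_true(all(diff(abs(rd$effect)) <= 1e-12))
  expect_equal(rd$rank, seq_len(8))
  # effect sign: A minus B (second factor level is "B"? no: A < B, so
  # level 2 is "B"; effect is level-2 mean minus level-1 mean)
  expect_lt(rd$effect[1], 0)

  # constant column: zero effect, p = 1
  sc$residuals[, 2] <- 0.7
  rd2 <- rank_differential(sc, cond, n_perm = 200, seed = 7)
  row2 <- rd2[rd2$signature == "s02", ]
  expect_equal(row2$effect, 0)
  expect_equal(row2$p_value, 1)
  expect_warning(rank_differential(sc, cond, n_perm = 50, seed = 8),
                 "unstable")
})

test_that("null differential ranking stays quiet on permuted labels", {
  sc <- scores_fixture(n = 150, n_sig = 6, seed = 86)
  hits <- 0L
  for (r in 1:20) {
    set.seed(900 + r)
    cond <- sample(rep(c("A", "B"), 75))
    rd <- rank_differential(sc, cond, n_perm = 300, seed = r)
    if (any(rd$fdr < 0.05)) hits <- hits + 1L
  }
  # nominal false-call rate is <= 5% per replicate; 3 of 20 is the
  # one-sided binomial 98% bound
  expect_lte(hits, 3L)
})

test_that("correlation modules group duplicated and latent-shared signatures", {
  sc <- scores_fixture(n = 300, n_sig = 4, seed = 87)
  sc$scaled <- cbind(sc$scaled, dup = sc$scaled[, 1])
  cm <- correlation_modules(sc)
  expect_equal(cm$correlation["s01", "dup"], 1)
  expect_equal(cm$modules[["s01"]], cm$modules[["dup"]])

  # independent signatures stay apart at 1000 cells
  sc2 <- scores_fixture(n = 1000, n_sig = 2, seed = 88)
  cm2 <- correlation_modules(sc2)
  expect_lt(abs(cm2$correlation[1, 2]), 0.15)
  expect_true(cm2$modules[[1]] != cm2$modules[[2]])

  # three signatures sharing a latent factor form one module
  set.seed(89)
  n <- 400
  latent <- rnorm(n)
  m <- sapply(1:3, function(i) 0.9 * latent + sqrt(1 - 0.81) * rnorm(n))
  m <- cbind(m, matrix(rnorm(2 * n), n, 2))
  dimnames(m) <- list(sprintf("c%03d", 1:n), sprintf("s%02d", 1:5))
  sc3 <- scores_fixture(n = n, n_sig = 5, seed = 89)
  sc3$scaled <- m
  cm3 <- correlation_modules(sc3)
  expect_equal(length(unique(cm3$modules[1:3])), 1L)
  expect_false(cm3$modules[[4]] %in% cm3$modules[1:3])

  # constant columns are excluded with a warning
  sc4 <- scores_fixture(n = 50, n_sig = 3, seed = 90)
  sc4$scaled[, 2] <- 0.5
  expect_warning(cm4 <- correlation_modules(sc4), "constant")
  expect_false("s02" %in% rownames(cm4$correlation))
})
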