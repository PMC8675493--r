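test_that("continuous-design statistic matches a brute-force OLS oracle", {
  set.seed(101)
  n <- 50
  auc <- runif(n)
  X <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%04d", 1:1000)))
  X[, "g0001"] <- 5 * auc + rnorm(n, sd = 0.1)
  tab <- PharmacoTable(
    ExpressionMatrix(X),
    data.frame(sample = rownames(X), drug = "d", auc = auc))
  t_stat <- de_statistic(tab, "d", "continuous")
  expect_equal(names(which.max(t_stat)), "g0001")
  expect_equal(unname(rank(-t_stat)["g0001"]), 1)
  # brute-force per-gene lm oracle on a subset
  for (g in c("g0001", "g0002", "g0500")) {
    fit <- summary(lm(X[, g] ~ auc))
    expect_equal(unname(t_stat[g]), fit$coefficients["auc", "t value"],
                 tolerance = 1e-10)
  }
  # a constant gene gets statistic zero
  Xc <- X; Xc[, "g0002"] <- 3
  tab2 <- PharmacoTable(ExpressionMatrix(Xc),
                        data.frame(sample = rownames(X), drug = "d",
                                   auc = auc))
  expect_equal(unname(de_statistic(tab2, "d", "continuous")["g0002"]), 0)
})

test_that("contrast-design statistic approximates the two-sample t", {
  set.seed(102)
  n <- 40
  arm <- rep(c("control", "treated"), each = 20)
  X <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:50)))
  X[arm == "treated", "g01"] <- X[arm == "treated", "g01"] + 2
  tab <- PharmacoTable(ExpressionMatrix(X),
                       data.frame(sample = rownames(X), drug = "d", arm = arm))
  t_stat <- de_statistic(tab, "d", "contrast")
  oracle <- t.test(X[arm == "treated", "g01"], X[arm == "control", "g01"],
                   var.equal = TRUE)$statistic
  expect_equal(unname(t_stat["g01"]), unname(oracle), tolerance = 1e-10)
  expect_gt(t_stat["g01"], 0)  # positive = higher in treated
  expect_error(de_statistic(tab, "d", "continuous"), "auc")
})

test_that("confounder adjustment removes tissue-driven false positives", {
  sim <- simulate_pharmaco(n_samples = 60, n_genes = 300, n_drugs = 1,
                           effect = 0, tissue_offset = 10, seed = 7)
  adj <- de_statistic(sim$table, "drug01", "continuous")
  noconf <- PharmacoTable(sim$table$expression, sim$table$response)
  raw <- de_statistic(noconf, "drug01", "continuous")
  expect_gt(mean(abs(raw[sim$offset_genes])), 3)
  expect_lt(mean(abs(adj[sim$offset_genes])), 2)
})

test_that("null de_statistic |t|>2 rate matches the nominal level", {
  sim <- simulate_pharmaco(n_samples = 50, n_genes = 1000, n_drugs = 1,
                           effect = 0, seed = 19)
  t_stat <- de_statistic(sim$table, "drug01", "continuous")
  df <- 50 - 4  # intercept + auc + 2 tissue dummies
  nominal <- 2 * pt(-2, df)
  bt <- binom.test(sum(abs(t_stat) > 2), length(t_stat), p = nominal)
  expect_gt(bt$p.value, 0.01)
})

test_that("make_signature cuts top/bottom N with deterministic ties", {
  set.seed(103)
  stats <- setNames(rnorm(600), sprintf("g%03d", 1:600))
  sig <- make_signature(stats, "s", signature_build_config(n_top = 250))
  expect_length(sig$up_genes, 250)
  expect_length(sig$dn_genes, 250)
  expect_setequal(sig$up_genes, names(sort(stats, decreasing = TRUE))[1:250])
  # planted strong genes recovered exactly
  stats2 <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  planted <- sample(names(stats2), 10)
  stats2[planted] <- stats2[planted] + 50
  sig2 <- make_signature(stats2, "s2", signature_build_config(n_top = 10))
  expect_setequal(sig2$up_genes, planted)
  # degenerate: all equal -> lexicographic extremes, warning
  eq <- setNames(rep(1, 6), c("a", "b", "c", "d", "e", "f"))
  expect_warning(sig3 <- make_signature(eq, "tie",
                                        signature_build_config(n_top = 2)),
                 "lexicographic")
  expect_equal(sort(sig3$up_genes), c("a", "b"))
  expect_equal(sort(sig3$dn_genes), c("e", "f"))
  expect_error(make_signature(eq, "x", signature_build_config(n_top = 4)),
               ">= 8 genes")
})

test_that("negating the statistic swaps UP and DN sets", {
  set.seed(104)
  stats <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  cfg <- signature_build_config(n_top = 20)
  a <- make_signature(stats, "a", cfg)
  b <- make_signature(-stats, "b", cfg)
  expect_setequal(b$up_genes, a$dn_genes)
  expect_setequal(b$dn_genes, a$up_genes)
})

test_that("drug specificity rescaling and decile background arithmetic", {
  set.seed(105)
  n_types <- 4
  expr <- random_expr(20, 400, seed = 106)
  types <- rep(sprintf("t%d", 1:n_types), each = 5)
  sigs <- lapply(1:100, function(i) {
    g <- gene_ids(expr)[(4 * i - 3):(4 * i)]
    GeneSignature(sprintf("d%03d", i), up_genes = g[1:2], dn_genes = g[3:4])
  })
  coll <- SignatureCollection(sigs, "drugs")
  spec <- drug_specificity(coll, expr, types)
  expect_true(all(spec$dss >= 0 & spec$dss <= 1))
  expect_length(spec$decile_low, 10)   # ceiling(0.1 * 100)
  expect_length(spec$decile_high, 10)
  bg <- select_background(spec, coll)
  expect_length(bg, 20)
  expect_equal(signature_names(bg),
               intersect(signature_names(coll), signature_names(bg)))

  # the most discordant observed pattern anchors dss = 0
  expect_equal(min(spec$dss), 0)
  expect_error(drug_specificity(coll, expr, rep("t1", 20)), "2 cell-type")

  # constructed endpoints: flat pattern -> 1, extreme pattern -> 0
  m <- cbind(gflat = rep(1, 8), gvar = rep(c(0, 10), each = 4))
  rownames(m) <- sprintf("s%d", 1:8)
  two <- SignatureCollection(list(GeneSignature("flat", up_genes = "gflat"),
                                  GeneSignature("var", up_genes = "gvar")),
                             "two")
  sp2 <- drug_specificity(two, ExpressionMatrix(m),
                          rep(c("t1", "t2"), each = 4))
  expect_equal(unname(sp2$dss), c(1, 0))

  # 10-signature collection -> 2-signature background
  small <- SignatureCollection(sigs[1:10], "small")
  bg2 <- select_background(drug_specificity(small, expr, types), small)
  expect_length(bg2, 2)
  expect_error(select_background(spec, small), "not in collection")
})

test_that("planted resistance genes are recovered from pharmaco tables", {
  sim <- simulate_pharmaco(n_samples = 50, n_genes = 1000, n_drugs = 2,
                           effect = 5, n_planted = 10, seed = 23)
  for (drug in names(sim$planted)) {
    t_stat <- de_statistic(sim$table, drug, "continuous")
    sig <- make_signature(t_stat, drug, signature_build_config(n_top = 10))
    jac <- length(intersect(sig$up_genes, sim$planted[[drug]])) /
      length(union(sig$up_genes, sim$planted[[drug]]))
    expect_gte(jac, 0.9)
  }
})
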