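test_that("2x2 tables count per subfamily, exclude missing states, and partition the pool", {
  l1 <- data.frame(
    element_id = sprintf("e%02d", 1:11),
    subfamily = c(rep("A", 10), "F"),
    location_class = c(rep("intragenic_total", 3), rep("intergenic", 7),
                       "intragenic_partial"),
    featX = c("conserved", "conserved", "mutated",
              "conserved", "conserved", "conserved",
              "mutated", "mutated", "mutated", "mutated", NA),
    stringsAsFactors = FALSE)
  tab <- build_feature_tables(l1, "featX")
  A <- tab[tab$stratum == "A", ]
  expect_equal(c(A$a, A$b, A$c, A$d), c(2, 1, 3, 4))
  expect_false("F" %in% tab$stratum)  # F's only element has a missing state

  # two subfamilies partition into strata summing to the pooled table
  l1$featX[11] <- "conserved"
  tab2 <- build_feature_tables(l1, "featX")
  expect_equal(sum(tab2$a + tab2$b + tab2$c + tab2$d), 11)
  expect_error(build_feature_tables(l1, "no_such_feature"), "absent")
})

test_that("CMH statistic and MH odds ratio match closed forms", {
  one <- mh_test(data.frame(a = 20, b = 10, c = 10, d = 20))
  expect_equal(one$mh_or, 4.0)
  expect_equal(one$statistic, (59 / 60) * 20 / 3, tolerance = 1e-12)  # 6.5556
  expect_equal(one$n_strata_used, 1L)

  two <- mh_test(data.frame(a = c(20, 20), b = c(10, 10),
                            c = c(10, 10), d = c(20, 20)))
  expect_equal(two$mh_or, 4.0)
  expect_equal(two$statistic, 13.111, tolerance = 1e-3)

  # perfect independence: a_i = E_i in every stratum
  null <- mh_test(data.frame(a = c(10, 30), b = c(10, 30),
                             c = c(10, 30), d = c(10, 30)))
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
  expect_equal(null$mh_or, 1)
})

test_that("single-stratum CMH equals ((n-1)/n) * Pearson chi-square", {
  set.seed(5)
  for (i in 1:20) {
    cells <- rpois(4, 30) + 1
    m <- matrix(cells, 2, byrow = TRUE)
    pear <- suppressWarnings(chisq.test(m, correct = FALSE))$statistic
    n <- sum(cells)
    got <- mh_test(data.frame(a = cells[1], b = cells[2],
                              c = cells[3], d = cells[4]))
    expect_equal(got$statistic, unname(pear) * (n - 1) / n, tolerance = 1e-10)
  }
})

test_that("mh_test agrees with the stratified reference implementation", {
  set.seed(9)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    a <- rpois(K, 40) + 1; b <- rpois(K, 25) + 1
    cc <- rpois(K, 30) + 1; d <- rpois(K, 50) + 1
    arr <- array(rbind(a, cc, b, d), dim = c(2, 2, K))
    ref <- mantelhaen.test(arr, correct = FALSE)
    got <- mh_test(data.frame(a = a, b = b, c = cc, d = d))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$mh_or, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("MH OR is a convex combination of per-stratum ORs; degenerate strata drop", {
  set.seed(31)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    a <- rpois(K, 20) + 1; b <- rpois(K, 20) + 1
    cc <- rpois(K, 20) + 1; d <- rpois(K, 20) + 1
    ors <- a * d / (b * cc)
    got <- mh_test(data.frame(a = a, b = b, c = cc, d = d))
    expect_gte(got$mh_or, min(ors) - 1e-12)
    expect_lte(got$mh_or, max(ors) + 1e-12)
  }
  # a zero-margin stratum is uninformative and dropped
  strata <- data.frame(a = c(20, 0), b = c(10, 0), c = c(10, 5), d = c(20, 5))
  got <- mh_test(strata)
  expect_equal(got$n_strata_used, 1L)
  expect_equal(got$mh_or, 4.0)
  expect_error(mh_test(data.frame(a = 0, b = 0, c = 3, d = 4)),
               "no informative strata")
  inf <- mh_test(data.frame(a = 5, b = 0, c = 0, d = 5))
  expect_true(is.infinite(inf$mh_or))
  expect_true(inf$degenerate_or)
})

test_that("Welch test matches hand computation and is antisymmetric", {
  w <- welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$t, -1.0954, tolerance = 1e-3)
  expect_equal(w$df, 6, tolerance = 1e-9)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- rnorm(10); b <- rnorm(12, 1)
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)

  # equal n and equal variance: Welch equals pooled Student t
  x <- c(1, 2, 3, 4, 5); y <- x + 2.5
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(welch_test(x, y)$t, unname(pooled$statistic), tolerance = 1e-10)

  expect_error(welch_test(c(1, 1, 1), c(1, 1, 1)), "zero variance")
  expect_error(welch_test(1, c(1, 2, 3)), ">= 2")
})

test_that("feature screen emits one ordered row per manifest feature with directions", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_l1_table(cfg, simulate_genome(cfg))
  el <- sim$elements
  el$location_class <- sim$truth$true_class
  manifest <- feature_manifest(el)
  res <- run_feature_screen(el, manifest)
  expect_equal(nrow(res), 53L)  # 42 categorical + 11 quantitative
  expect_equal(res$feature, manifest$feature)
  expect_true(all(res$kind[res$or > 0 & !is.na(res$or)] == "categorical"))
  expect_true(all(res$status == "ok"))
  expect_setequal(unique(res$direction[res$kind == "categorical"]),
                  "conserved-enriched-intragenic")
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))

  # a broken feature fails its row, not the screen
  el$UTR5_promoter_motif <- NA_character_
  res2 <- run_feature_screen(el, manifest)
  expect_match(res2$status[res2$feature == "UTR5_promoter_motif"], "failed")
  expect_true(all(res2$status[-1] == "ok"))
})

test_that("Simpson-style confounding: MH follows stratum ORs, pooled table reverses", {
  strata <- data.frame(a = c(99, 100), b = c(1, 900),
                       c = c(900, 1), d = c(100, 99))
  per_stratum <- strata$a * strata$d / (strata$b * strata$c)
  expect_true(all(per_stratum > 1))
  mh <- mh_test(strata)
  expect_gt(mh$mh_or, 1)
  pooled_or <- sum(strata$a) * sum(strata$d) / (sum(strata$b) * sum(strata$c))
  expect_lt(pooled_or, 1)
  expect_equal(mh$mh_or, 11.0, tolerance = 1e-9)
})
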