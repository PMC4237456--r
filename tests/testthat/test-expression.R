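make_expr <- function(ref, stg, stages = c("1-cell", "2-cell")) {
  # one gene, R replicates per stage, values given per replicate
  vals <- matrix(c(ref, stg), nrow = 1,
                 dimnames = list("g1", NULL))
  expression_matrix(vals,
                    stage = rep(stages, c(length(ref), length(stg))),
                    replicate = c(seq_along(ref), seq_along(stg)))
}

test_that("paired t-test matches hand computation and handles degenerate genes", {
  # diffs 1.0, 1.2, 0.8: dbar = 1, s_d = 0.2, t = 8.660, df 2, p ~ 0.01307
  expr <- make_expr(c(0, 0, 0), c(1.0, 1.2, 0.8))
  de <- paired_de(expr, "2-cell", "1-cell")
  expect_equal(de$t, 8.660, tolerance = 1e-3)
  expect_equal(de$df, 2L)
  expect_equal(de$p, 0.01307, tolerance = 1e-3)
  expect_equal(de$call, "up")

  # alternating diffs: t = 0 => ns
  e2 <- make_expr(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(paired_de(e2, "2-cell", "1-cell")$call, "ns")

  # reference against itself: all diffs zero => ns, not degenerate-significant
  d0 <- paired_de(expr, "1-cell", "1-cell")
  expect_equal(d0$call, "ns")
  expect_equal(d0$p, 1)

  # zero-variance non-zero diff: forced significant with p = 0, flagged
  e3 <- make_expr(c(0, 0, 0), c(-2, -2, -2))
  d3 <- paired_de(e3, "2-cell", "1-cell")
  expect_equal(d3$p, 0)
  expect_equal(d3$call, "down")
  expect_true(d3$degenerate)

  # calls always agree in sign with the mean difference
  set.seed(12)
  vals <- matrix(rnorm(200 * 6), 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  expr6 <- expression_matrix(vals, rep(c("1-cell", "2-cell"), each = 3),
                             rep(1:3, 2))
  de6 <- paired_de(expr6, "2-cell")
  expect_true(all(de6$mean_diff[de6$call == "up"] > 0))
  expect_true(all(de6$mean_diff[de6$call == "down"] < 0))
  expect_true(all(de6$p[de6$call != "ns"] < 0.05))
})

test_that("association test reproduces hand-computed tables, ORs and Woolf CIs", {
  universe <- sprintf("g%03d", 1:40)
  l1 <- universe[1:20]
  called <- c(universe[1:10], universe[21:30])  # a=10 b=10 c=10 d=10
  at <- assoc_test(de_stub(universe, called), l1, "down")
  expect_equal(at$chi2, 0)
  expect_equal(at$p, 1)
  expect_equal(at$or, 1)
  expect_false(at$significant)

  # table (10,20,30,40)
  universe <- sprintf("g%03d", 1:100)
  l1 <- universe[1:30]
  called <- c(universe[1:10], universe[31:60])
  at2 <- assoc_test(de_stub(universe, called), l1, "down")
  expect_equal(c(at2$a, at2$b, at2$c, at2$d), c(10, 20, 30, 40))
  expect_equal(at2$or, 2 / 3, tolerance = 1e-4)
  expect_equal(at2$ci_low, 0.2725, tolerance = 1e-3)
  expect_equal(at2$ci_high, 1.6309, tolerance = 1e-3)

  # margins always reconstruct the universe and the L1 set
  expect_equal(at2$a + at2$b, 30)
  expect_equal(at2$a + at2$b + at2$c + at2$d, 100)

  # zero margin: degenerate, p = 1, flagged
  at3 <- assoc_test(de_stub(universe, character(0)), l1, "down")
  expect_true(at3$degenerate)
  expect_equal(at3$p, 1)
  expect_false(at3$significant)

  # zero cell: raw OR infinite, CI from Haldane-Anscombe adjustment, flagged
  called4 <- universe[1:10]  # all called genes host L1: c = 0
  at4 <- assoc_test(de_stub(universe, called4), l1, "down")
  expect_true(is.infinite(at4$or))
  expect_true(at4$ci_adjusted)
  expect_true(is.finite(at4$ci_low))
})

test_that("stage screen tests both directions per stage with exclusive calls", {
  cfg <- simulation_config(seed = 21, stages = c("1-cell", "2-cell", "4-cell"),
                           n_genes_expr = 400)
  genes <- sprintf("g%03d", 1:400)
  l1g <- genes[1:80]
  sim <- simulate_expression(cfg, genes, l1g)
  sc <- run_stage_screen(sim$expr, l1g)
  expect_equal(nrow(sc$assoc), 4L)  # 2 stages x up/down
  expect_setequal(sc$assoc$direction, c("up", "down"))
  for (st in c("2-cell", "4-cell")) {
    de <- sc$de[[st]]
    expect_length(intersect(sc$sets_up[[st]], sc$sets_down[[st]]), 0)
    rows <- sc$assoc[sc$assoc$stage == st, ]
    expect_equal(unique(rows$a + rows$b), length(intersect(l1g, de$gene_id)))
    expect_equal(unique(rows$a + rows$b + rows$c + rows$d), nrow(de))
  }
  # direction gene sets are L1-hosting called genes
  expect_true(all(sc$sets_down[["2-cell"]] %in% l1g))
  # single stage input: one row per direction
  sc1 <- run_stage_screen(sim$expr, l1g, stages = "2-cell")
  expect_equal(nrow(sc1$assoc), 2L)
})

test_that("set intersection over significant stages and Venn counts obey inclusion-exclusion", {
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"), s3 = c("C", "E"))
  res <- intersect_significant_sets(sets)
  expect_equal(res$common, "C")
  expect_equal(sum(res$regions$count), length(unique(unlist(sets))))

  one <- intersect_significant_sets(sets["s1"])
  expect_equal(one$common, c("A", "B", "C"))

  none <- intersect_significant_sets(sets, character(0))
  expect_equal(none$common, character(0))
  expect_match(none$status, "no significant")

  # region counts against a direct inclusion-exclusion oracle on random sets
  set.seed(77)
  for (i in 1:10) {
    rs <- list(a = sample(LETTERS, 8), b = sample(LETTERS, 12),
               c = sample(LETTERS, 5))
    vc <- venn_counts(rs)
    expect_equal(sum(vc$count), length(unique(unlist(rs))))
    abc <- vc$count[vc$region == "a&b&c"]
    expect_equal(if (length(abc)) abc else 0L,
                 length(Reduce(intersect, rs)))
    a_only <- vc$count[vc$region == "a"]
    expect_equal(if (length(a_only)) a_only else 0L,
                 length(setdiff(rs$a, union(rs$b, rs$c))))
  }
})

test_that("ortholog mapping emits qualifying pairs including one-to-many", {
  pairs <- data.frame(m = c("m1", "m1", "m2", "m3"),
                      h = c("h1", "h2", "h3", "h4"))
  res <- map_orthologs(c("m1", "m2"), c("h1", "h2"), pairs)
  expect_equal(nrow(res$pairs), 2L)
  expect_setequal(res$pairs$h, c("h1", "h2"))
  expect_equal(res$unmatched_set1, "m2")

  empty <- map_orthologs(c("m1"), c("h1"), pairs[0, ])
  expect_equal(nrow(empty$pairs), 0L)
})
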