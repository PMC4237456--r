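test_that("identical configurations give byte-identical bundles", {
  cfg <- tiny_config(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  simulate_bundle(tiny_config(seed = 43), d3)
  expect_false(identical(readLines(file.path(d1, "l1.tsv")),
                         readLines(file.path(d3, "l1.tsv"))))
})

test_that("genome simulation honours counts, naming and sizing constraints", {
  cfg <- simulation_config(seed = 1, n_autosomes = 2, chrom_length_bp = 5e5,
                           n_genes_per_chrom = 10, gene_span_bp = c(2000, 10000),
                           n_l1_per_chrom = 5, l1_length_bp = 1000)
  g <- simulate_genome(cfg)
  expect_equal(sort(g$chrom_sizes$chrom), sort(c("chr1", "chr2", "chrX", "chrY")))
  expect_equal(length(unique(g$genes$gene_id)), 40L)  # 10 per chromosome
  expect_true(all(g$genes$end > g$genes$start))
  spans <- gene_span(g$genes)
  sizes <- setNames(g$chrom_sizes$length, g$chrom_sizes$chrom)
  expect_true(all(spans$end <= sizes[spans$chrom]))

  # empty gene list still emits the chromosome table
  g0 <- simulate_genome(tiny_config(n_genes_per_chrom = 0L))
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(nrow(g0$chrom_sizes), 4L)

  # genes that cannot fit raise a sizing error
  expect_error(simulate_genome(
    simulation_config(seed = 1, n_autosomes = 1, chrom_length_bp = 10000,
                      gene_span_bp = c(2000, 50000))), "exceeds")
})

test_that("L1 simulation plants classes, subfamilies and features consistently", {
  cfg <- tiny_config(seed = 8)
  genome <- simulate_genome(cfg)
  sim <- simulate_l1_table(cfg, genome)
  el <- sim$elements
  expect_equal(nrow(el), 4 * 40)
  expect_true(all(el$subfamily %in% cfg$subfamily_labels))
  expect_equal(attr(el, "features")$feature,
               c(cfg$feature_names_categorical, cfg$feature_names_quantitative))

  # truth classes agree with the classifier run on the written table
  cls <- classify_location(el, gene_span(genome$genes))
  expect_equal(as.character(cls$location_class), sim$truth$true_class)

  # zero elements: header-only table
  none <- simulate_l1_table(tiny_config(n_l1_per_chrom = 0L), genome)
  expect_equal(nrow(none$elements), 0L)
  expect_equal(ncol(none$elements), 6L + 53L)
})

test_that("planted feature odds ratios are recovered and the null plants OR 1", {
  cfg <- simulation_config(seed = 101, n_autosomes = 4, chrom_length_bp = 2e6,
                           n_genes_per_chrom = 30, n_l1_per_chrom = 700,
                           feature_names_categorical = c("planted", "nullfeat"),
                           feature_names_quantitative = "quant",
                           p_conserved_intragenic = c(planted = 0.8, nullfeat = 0.5),
                           p_conserved_intergenic = c(planted = 0.5, nullfeat = 0.5),
                           quant_means_intragenic = 1, quant_means_intergenic = 0)
  genome <- simulate_genome(cfg)
  sim <- simulate_l1_table(cfg, genome)
  el <- sim$elements
  el$location_class <- sim$truth$true_class
  mh <- mh_test(build_feature_tables(el, "planted"))
  # planted OR (0.8/0.2)/(0.5/0.5) = 4; a single draw recovers it to well
  # within 0.5 log units (CI-coverage itself is checked over replicates)
  expect_lt(abs(log(mh$mh_or / 4.0)), 0.5)
  mh0 <- mh_test(build_feature_tables(el, "nullfeat"))
  expect_lt(abs(log(mh0$mh_or)), 0.35)
  wt <- welch_test(el$quant[el$location_class != "intergenic"],
                   el$quant[el$location_class == "intergenic"])
  expect_gt(wt$mean_intragenic, wt$mean_intergenic)
})

test_that("expression simulation: nulls, planted effects and validation", {
  genes <- sprintf("g%03d", 1:120)
  l1g <- genes[1:30]

  # pure null: no noise, no effect => every stage identical, no DE calls
  cfg0 <- tiny_config(noise_sd = 0, planted_down_effect = 0,
                      stages = c("1-cell", "2-cell"))
  sim0 <- simulate_expression(cfg0, genes, l1g)
  de0 <- paired_de(sim0$expr, "2-cell")
  expect_true(all(de0$call == "ns"))

  # strong planted effect with no noise: called exactly on the planted genes
  cfg1 <- tiny_config(noise_sd = 0, stages = c("1-cell", "2-cell"))
  sim1 <- simulate_expression(cfg1, genes, l1g)
  de1 <- paired_de(sim1$expr, "2-cell")
  planted <- sim1$truth$gene_id[sim1$truth$planted_down]
  expect_setequal(de1$gene_id[de1$call == "down"], planted)

  expect_error(simulate_expression(tiny_config(n_replicates = 1L), genes),
               "paired t-test")
  expect_error(simulate_expression(cfg0, genes, c("not_a_gene")), "subset")
  expect_error(simulate_expression(cfg0, character(0)), "non-empty")
  expect_error(simulation_config(p_down_given_l1 = 1.2), "probabilities")
})

test_that("equal planted down rates yield association odds near 1", {
  genes <- sprintf("g%04d", 1:2000)
  l1g <- genes[1:200]
  cfg <- simulation_config(seed = 55, stages = c("1-cell", "2-cell"),
                           p_down_given_l1 = 0.25, p_down_given_no_l1 = 0.25)
  sim <- simulate_expression(cfg, genes, l1g)
  at <- assoc_test(paired_de(sim$expr, "2-cell"), l1g, "down")
  expect_true(at$ci_low <= 1 && 1 <= at$ci_high)
})

test_that("ortholog pair simulation respects universes and one-to-many", {
  p <- simulate_ortholog_pairs(sprintf("m%02d", 1:30), sprintf("h%02d", 1:30),
                               n_pairs = 10, seed = 3, p_one_to_many = 0.5)
  expect_gte(nrow(p), 10)
  expect_true(all(p$gene_id_species1 %in% sprintf("m%02d", 1:30)))
  expect_true(all(p$gene_id_species2 %in% sprintf("h%02d", 1:30)))
  expect_false(anyDuplicated(p[, 1:2]) > 0)
})
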