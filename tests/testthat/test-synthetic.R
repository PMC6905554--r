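test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_genes = 100, seed = 42)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  c_ <- generate_expression(synthetic_config(n_genes = 100, seed = 43))
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("generator marginals match the configuration", {
  cfg <- synthetic_config(n_genes = 500, n_disease_samples = 30,
                          n_healthy_samples = 30, noise_sd = 0.8,
                          disease_gene_fraction = 0.1,
                          effect_size_delta = 2, seed = 7)
  sim <- generate_expression(cfg)
  vals <- sim$expr$values
  null_genes <- setdiff(sim$expr$gene_ids, sim$truth$disease_genes)
  # per-gene SD of null genes concentrates around noise_sd
  sds <- apply(vals[null_genes, ], 1, sd)
  se <- 0.8 / sqrt(2 * (60 - 1))
  expect_lt(abs(mean(sds) - 0.8), 3 * se)
  # planted genes show the requested |shift| in the disease group
  dis <- sim$expr$condition == "disease"
  shifts <- rowMeans(vals[sim$truth$disease_genes, dis]) -
    rowMeans(vals[sim$truth$disease_genes, !dis])
  expect_equal(mean(abs(shifts)), 2, tolerance = 0.1)
  # signs are mixed (two-sided planted effects)
  expect_gt(sum(shifts > 0), 0)
  expect_gt(sum(shifts < 0), 0)
})

test_that("contamination bookkeeping is exact and disjoint", {
  cfg <- synthetic_config(n_genes = 400, disease_gene_fraction = 0.25,
                          contamination_fraction = 0.3, seed = 5)
  truth <- generate_expression(cfg)$truth
  n_dis <- length(truth$disease_genes)
  expect_equal(length(truth$hidden_positives), round(0.3 * n_dis))
  expect_setequal(c(truth$labeled_positives, truth$hidden_positives),
                  truth$disease_genes)
  expect_length(intersect(truth$labeled_positives,
                          truth$hidden_positives), 0)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(disease_gene_fraction = 1.2),
               "disease_gene_fraction")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(contamination_fraction = 1),
               "contamination_fraction")
})

test_that("ground-truth metrics are exact on forced predictions", {
  sim <- generate_expression(synthetic_config(n_genes = 200, seed = 9))
  truth <- sim$truth
  ids <- sim$expr$gene_ids
  perfect <- setNames(ifelse(ids %in% truth$disease_genes,
                             "inlier", "outlier"), ids)
  gm <- ground_truth_metrics(perfect, truth)
  expect_equal(c(gm$precision, gm$recall, gm$f_measure), c(1, 1, 1))
  all_in <- setNames(rep("inlier", length(ids)), ids)
  gm2 <- ground_truth_metrics(all_in, truth)
  expect_equal(gm2$recall, 1)
  expect_equal(gm2$precision,
               length(truth$disease_genes) / length(ids))
  expect_error(ground_truth_metrics(unname(perfect), truth), "named")
})

test_that("truth sidecar files round-trip", {
  sim <- generate_expression(synthetic_config(n_genes = 50, seed = 2,
                                              contamination_fraction = 0.2))
  path <- tempfile(fileext = ".csv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_setequal(back$disease_genes, sim$truth$disease_genes)
  expect_setequal(back$hidden_positives, sim$truth$hidden_positives)
  expect_equal(unname(back$effects[names(sim$truth$effects)]),
               unname(sim$truth$effects))
})
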