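test_that("latent generator reproduces configured path coefficients", {
  # degenerate coefficient 1: child is an exact copy of the parent
  cfg <- sim_config(n_samples = 50, block_spec = c(A = 1, B = 1),
                    structural_edges = data.frame(from = "A", to = "B",
                                                  coef = 1.0),
                    seed = 4)
  sc <- simulate_latents(cfg)
  expect_equal(sc[, "B"], sc[, "A"], tolerance = 1e-12)

  # Monte-Carlo calibration: sample correlation converges to the coefficient
  cfg <- sim_config(n_samples = 100000, block_spec = c(A = 1, B = 1),
                    structural_edges = data.frame(from = "A", to = "B",
                                                  coef = 0.6),
                    seed = 1)
  sc <- simulate_latents(cfg)
  expect_lt(abs(cor(sc[, "A"], sc[, "B"]) - 0.6), 0.01)

  # disconnected exogenous latents are independent
  cfg <- sim_config(n_samples = 100000, block_spec = c(A = 1, B = 1),
                    structural_edges = data.frame(from = character(0),
                                                  to = character(0),
                                                  coef = numeric(0)),
                    seed = 2)
  sc <- simulate_latents(cfg)
  expect_lt(abs(cor(sc[, "A"], sc[, "B"])), 0.01)
})

test_that("every latent has unit population variance by construction", {
  ed <- default_structural_edges()
  cfg <- sim_config(n_samples = 200000, structural_edges = ed, seed = 8)
  sc <- simulate_latents(cfg)
  expect_true(all(abs(apply(sc, 2, var) - 1) < 0.02))
})

test_that("infeasible or cyclic structural models are rejected", {
  expect_error(
    sim_config(block_spec = c(A = 1, B = 1, C = 1),
               structural_edges = data.frame(
                 from = c("A", "B", "A"), to = c("B", "C", "C"),
                 coef = c(0.9, 0.9, 0.9))),
    "explained variance")
  expect_error(
    sim_config(block_spec = c(A = 1, B = 1),
               structural_edges = data.frame(from = c("A", "B"),
                                             to = c("B", "A"),
                                             coef = c(0.5, 0.5))),
    "DAG")
  expect_error(
    sim_config(structural_edges = data.frame(from = "ABA", to = "AO",
                                             coef = 1.2)),
    "coefficient")
})

test_that("indicators follow the reflective measurement model", {
  # loading 1, noise 0: indicator equals its latent
  cfg <- sim_config(n_samples = 40, block_spec = c(A = 1),
                    structural_edges = data.frame(from = character(0),
                                                  to = character(0),
                                                  coef = numeric(0)),
                    loadings = 1.0, seed = 5)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  expect_equal(unname(X$values["A_01", ]), unname(sc[, "A"]),
               tolerance = 1e-12)

  # product-of-loadings identity for two indicators of one latent
  cfg <- sim_config(n_samples = 100000, block_spec = c(A = 2),
                    structural_edges = data.frame(from = character(0),
                                                  to = character(0),
                                                  coef = numeric(0)),
                    loadings = list(A = c(0.9, 0.8)), seed = 6)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  expect_lt(abs(cor(X$values["A_01", ], X$values["A_02", ]) - 0.72), 0.01)

  # unit-variance choice of the noise sd
  expect_lt(abs(var(X$values["A_01", ]) - 1), 0.02)
})

test_that("generator is deterministic given the seed", {
  cfg <- sim_config(seed = 33)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$counts$values, d2$counts$values)
  expect_identical(d1$de_genes, d2$de_genes)
})

test_that("NB counts carry the configured timepoint effects", {
  # null configuration: no DE genes, group means equal in expectation
  cfg <- sim_config(n_genes = 300, de_fraction = 0, seed = 9)
  cs <- simulate_counts(cfg)
  expect_length(cs$de_genes, 0)
  ctrl <- cs$counts$design$timepoint == "0d"
  m0 <- mean(cs$counts$values[, ctrl])
  m1 <- mean(cs$counts$values[, !ctrl])
  expect_lt(abs(m1 / m0 - 1), 0.05)

  # Poisson limit: dispersion 0 gives variance ~ mean
  cfg <- sim_config(n_genes = 60, de_fraction = 0, count_dispersion = 0,
                    timepoints = c("0d", "4d"), replicates = 200, seed = 10)
  cs <- simulate_counts(cfg)
  v <- apply(cs$counts$values, 1, var)
  m <- rowMeans(cs$counts$values)
  expect_lt(abs(median(v / m) - 1), 0.2)

  # generative fold-change: treated mean ~ 2^2 * 100 = 400
  cfg <- sim_config(n_genes = 40, de_fraction = 1, de_log2fc = 2,
                    count_baseline_mean = 100,
                    timepoints = c("0d", "4d"), replicates = 500, seed = 11)
  cs <- simulate_counts(cfg)
  treated <- cs$counts$design$timepoint == "4d"
  expect_lt(abs(mean(cs$counts$values[, treated]) / 400 - 1), 0.05)
  expect_setequal(cs$de_genes, rownames(cs$counts$values))
})

test_that("full dataset wires counts, indicators and truth together", {
  cfg <- sim_config(n_genes = 200, seed = 12)
  ds <- simulate_dataset(cfg)
  expect_equal(ncol(ds$expression$values), 12)
  expect_true(all(ds$de_genes %in% rownames(ds$counts$values)))
  # indicator genes are embedded in the counts and flagged DE
  expect_true(all(rownames(ds$expression$values) %in%
                    rownames(ds$counts$values)))
  expect_true(all(rownames(ds$expression$values) %in% ds$de_genes))
  expect_setequal(ds$annotation$gene, rownames(ds$expression$values))
})

test_that("dataset TSV round-trip preserves values", {
  cfg <- sim_config(n_genes = 50, seed = 13)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  counts2 <- read_expression_tsv(paths[["counts"]], paths[["design"]],
                                 mode = "counts")
  expect_identical(counts2$values, ds$counts$values * 1.0)
  expr2 <- read_expression_tsv(paths[["expression"]], paths[["design"]],
                               mode = "log")
  expect_equal(expr2$values, ds$expression$values, tolerance = 1e-12)
  expect_identical(counts2$design$timepoint, ds$counts$design$timepoint)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(length(truth$paths), nrow(ds$true_paths))
})
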