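make_counts <- function(m, timepoints, replicates) {
  design <- data.frame(
    sample = colnames(m),
    timepoint = rep(timepoints, each = replicates),
    replicate = rep(seq_len(replicates), length(timepoints)))
  expression_matrix(m, design = design, mode = "counts")
}

test_that("size factors follow the median-of-ratios definition", {
  # sample2 = 2 * sample1: factors 1/sqrt(2) and sqrt(2)
  m <- matrix(c(10L, 20L, 40L, 20L, 40L, 80L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # identical samples: all factors 1
  m2 <- matrix(rep(c(5L, 9L, 14L), 3), 3, 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m2)), rep(1, 3), tolerance = 1e-12)

  # single gene, counts (4, 9): geometric mean 6
  m3 <- matrix(c(4L, 9L), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(size_factors(m3)), c(4 / 6, 9 / 6), tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0L, 5L), 1, 2,
                                   dimnames = list("g1", c("a", "b")))),
               "all-zero|positive")
})

test_that("method-of-moments dispersion matches its formula", {
  expect_equal(estimate_dispersion(c(10, 10, 10)), 1e-8)
  # mean 100, sample variance 1100 -> alpha = 0.1
  x <- c(100 - sqrt(1100), 100, 100 + sqrt(1100))
  expect_equal(estimate_dispersion(x), 0.1, tolerance = 1e-12)
  # Poisson data: alpha near the floor
  set.seed(1)
  x <- rpois(2000, 50)
  expect_lt(estimate_dispersion(x), 0.01)
  expect_warning(expect_true(is.na(estimate_dispersion(c(0, 0, 0)))),
                 "undefined")
  expect_error(estimate_dispersion(5), "2 samples")
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    if (i %% 3 == 0) p <- round(p, 1)  # force ties
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                       # never decreases p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("contrast test handles null, antisymmetry and recovery", {
  # identical groups: log2fc 0, p 1
  m <- matrix(rep(c(10L, 30L, 50L), 6), 3, 6,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  em <- make_counts(m, c("0d", "4d"), 3)
  res <- suppressMessages(test_contrast(em, "0d", "4d"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_true(all(res$fdr >= res$p_value))

  # swapping the groups negates log2fc and keeps p
  cfg <- sim_config(n_genes = 300, seed = 21)
  cs <- simulate_counts(cfg)
  a <- suppressMessages(test_contrast(cs$counts, "0d", "8d"))
  b <- suppressMessages(test_contrast(cs$counts, "8d", "0d"))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # recovery: median estimated log2fc of true DE genes near the truth
  cfgp <- sim_config(n_genes = 1000, de_fraction = 0.2, de_log2fc = 2,
                     count_dispersion = 0.05, count_baseline_mean = 100,
                     seed = 22)
  csp <- simulate_counts(cfgp)
  rp <- suppressMessages(test_contrast(csp$counts, "0d", "12d"))
  med <- median(rp$log2fc[rp$gene %in% csp$de_genes])
  expect_lt(abs(med - 2), 0.3)

  expect_error(test_contrast(cs$counts, "0d", "nope"), "replicates")
})

test_that("DEG screen applies both thresholds inclusively", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 1.0, 3.0, -2.0),
                    p_value = c(1e-4, 1e-4, 0.01, 1e-5),
                    fdr = c(0.005, 0.005, 0.02, 0.004))
  out <- screen_degs(res)
  expect_setequal(out$gene, c("a", "b", "d"))       # c fails the FDR gate
  expect_equal(out$direction[out$gene == "a"], "up")
  expect_equal(out$direction[out$gene == "d"], "down")
  expect_true("b" %in% out$gene)                    # |log2fc| = 1 passes
  expect_error(screen_degs(res, fdr_max = 0), "positive")
})

test_that("CRG intersection and Venn regions are consistent", {
  crg <- intersect_crgs(list(c1 = c("A", "B", "C"), c2 = c("B", "C", "D"),
                             c3 = c("B", "C", "E")))
  expect_setequal(crg$genes, c("B", "C"))
  expect_equal(unname(crg$venn[["111"]]), 2L)
  expect_equal(sum(crg$venn), 5L)  # |union|

  expect_length(intersect_crgs(list(a = c("A"), b = character(0)))$genes, 0)
  expect_error(intersect_crgs(list(c("A"))), "at least 2")

  # region sizes always sum to the union, and the CRG set is inside
  # every per-contrast set
  set.seed(7)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) {
      sample(paste0("g", 1:30), sample(5:25, 1))
    })
    names(sets) <- paste0("s", 1:3)
    crg <- intersect_crgs(sets)
    expect_equal(sum(crg$venn), length(unique(unlist(sets))))
    for (s in sets) expect_true(all(crg$genes %in% s) || length(crg$genes) == 0)
    expect_setequal(crg$genes, Reduce(intersect, sets))
  }
})

test_that("FPKM follows the standard formula and is depth-invariant", {
  m <- matrix(c(100L, 999900L, 50L, 1999950L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- expression_matrix(m, mode = "counts")
  f <- fpkm(em, c(g1 = 1000, g2 = 500))
  # count 100, length 1000 bp, total 1e6 -> FPKM 100
  expect_equal(f$values["g1", "s1"], 100, tolerance = 1e-12)
  # count 50, length 2000 bp, total 2e6 -> FPKM 12.5
  f2 <- fpkm(em, c(g1 = 2000, g2 = 500))
  expect_equal(f2$values["g1", "s2"], 12.5, tolerance = 1e-12)
  # doubling all counts in a sample leaves its FPKM unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2L
  f3 <- fpkm(expression_matrix(m2, mode = "counts"), c(g1 = 1000, g2 = 500))
  expect_equal(f3$values[, "s1"], f$values[, "s1"], tolerance = 1e-12)
  expect_error(fpkm(em, c(g1 = 0, g2 = 500)), "length")
})
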