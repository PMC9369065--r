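test_that("model construction enforces its structural invariants", {
  expect_error(path_model(list(A = "x", B = "x"),
                          data.frame(from = "A", to = "B")),
               "shared")
  expect_error(path_model(list(A = "x", B = "y"),
                          data.frame(from = c("A", "B"), to = c("B", "A"))),
               "DAG")
  expect_error(path_model(list(A = character(0), B = "y"),
                          data.frame(from = "A", to = "B")),
               "indicator")
  m <- path_model(list(A = c("x1", "x2"), B = "y"),
                  data.frame(from = "A", to = "B"), scheme = "centroid")
  expect_s3_class(m, "PathModel")
  expect_equal(m$scheme, "centroid")
})

test_that("model YAML round-trips", {
  m <- path_model(list(H = c("h1", "h2"), T = c("t1", "t2"), A = "a1"),
                  data.frame(from = c("H", "T"), to = c("T", "A")))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_path_model(m, f)
  m2 <- read_path_model(f)
  expect_equal(m2$latents, m$latents)
  expect_equal(m2$edges, m$edges)
  expect_equal(m2$scheme, "path")
})

test_that("perfect dependence gives unit path, R2 and loadings", {
  set.seed(1)
  x <- rnorm(30)
  d <- cbind(x1 = x, y1 = x)
  f <- fit_pls(d, bivariate_model())
  expect_equal(f$path_coefficients$estimate, 1, tolerance = 1e-10)
  expect_equal(unname(f$r_squared["Y"]), 1, tolerance = 1e-10)
  expect_equal(f$loadings$estimate, c(1, 1), tolerance = 1e-10)
})

test_that("bivariate and regression oracle equivalences hold", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(40)
    y <- runif(1, -0.9, 0.9) * x + rnorm(40)
    f <- fit_pls(cbind(x1 = x, y1 = y), bivariate_model())
    expect_equal(f$path_coefficients$estimate, cor(x, y), tolerance = 1e-10)
  }
  # multi-predecessor: standardized multiple OLS coefficients
  m <- path_model(list(A = "a", B = "b", Y = "y"),
                  data.frame(from = c("A", "B"), to = c("Y", "Y")))
  for (i in 1:10) {
    a <- rnorm(60)
    b <- 0.4 * a + rnorm(60)
    y <- 0.5 * a - 0.3 * b + rnorm(60)
    f <- fit_pls(cbind(a = a, b = b, y = y), m)
    ols <- unname(coef(lm(scale(y) ~ scale(a) + scale(b)))[2:3])
    expect_equal(f$path_coefficients$estimate, ols, tolerance = 1e-10)
    expect_equal(unname(f$r_squared["Y"]),
                 summary(lm(scale(y) ~ scale(a) + scale(b)))$r.squared,
                 tolerance = 1e-10)
  }
})

test_that("latent scores are standardized and AVE matches raw data", {
  cfg <- sim_config(n_samples = 120, seed = 14)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  f <- fit_pls(X, model_from_config(cfg))
  expect_true(f$converged)
  # mean 0, population variance 1 to 1e-8
  expect_true(all(abs(colMeans(f$scores)) < 1e-8))
  expect_true(all(abs(colMeans(f$scores^2) - 1) < 1e-8))
  # AVE identity recomputed independently from raw data correlations
  for (nm in names(f$model$latents)) {
    ind <- f$model$latents[[nm]]
    lam <- vapply(ind, function(g) cor(X$values[g, ], f$scores[, nm]),
                  numeric(1))
    expect_equal(unname(pls_ave(f, nm)), mean(lam^2), tolerance = 1e-10)
  }
  # sign orientation: every latent's loading sum is nonnegative
  sums <- tapply(f$loadings$estimate, f$loadings$latent, sum)
  expect_true(all(sums >= 0))
})

test_that("reliability metrics follow their closed forms", {
  fake <- structure(list(
    ave = c(A = 0.5, B = 1.0, C = 0.81),
    composite_reliability = c(A = 0.7805, B = 1, C = 0.927),
    loadings = data.frame(latent = c("A", "A", "B", "C", "C", "C"),
                          indicator = paste0("i", 1:6),
                          estimate = c(0.8, 0.6, 1, 0.9, 0.9, 0.9)),
    model = list(latents = list(A = c("i1", "i2"), B = "i3",
                                C = c("i4", "i5", "i6")))),
    class = "PLSFit")
  expect_equal(pls_ave(fake, "A"), 0.5)          # (0.64 + 0.36) / 2
  expect_equal(pls_ave(fake, "B"), 1.0)          # sole indicator
  expect_equal(pls_ave(fake, "C"), 0.81)
  expect_equal(composite_reliability(fake, "A"), 0.7805)
  rep <- validate_model(fake)
  expect_true(rep$pass[rep$latent == "A"])       # inclusive boundary at 0.5
  expect_true(all(rep$pass))
  fake$ave["A"] <- 0.25                          # loadings (0.5, 0.5)
  expect_false(validate_model(fake)$pass[1])
})

test_that("CR and AVE computed by fit_pls match direct evaluation", {
  cfg <- sim_config(n_samples = 150, seed = 15)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  f <- fit_pls(X, model_from_config(cfg))
  for (nm in names(f$ave)) {
    lam <- f$loadings$estimate[f$loadings$latent == nm]
    expect_equal(unname(f$ave[nm]), mean(lam^2), tolerance = 1e-12)
    expect_equal(unname(f$composite_reliability[nm]),
                 sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2)),
                 tolerance = 1e-12)
  }
})

test_that("path recovery against the generating truth", {
  ed <- default_structural_edges()
  ed$coef <- c(0.6, 0.5, 0.4, 0.3, 0.25, 0.3, 0.2)
  cfg <- sim_config(n_samples = 500, structural_edges = ed, loadings = 0.9,
                    seed = 16)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  f <- fit_pls(X, model_from_config(cfg))
  expect_true(all(abs(f$path_coefficients$estimate - ed$coef) < 0.1))
  expect_lt(mean(abs(f$path_coefficients$estimate - ed$coef)), 0.05)
})

test_that("inner weighting schemes agree on well-conditioned data", {
  ed <- default_structural_edges()
  cfg <- sim_config(n_samples = 400, structural_edges = ed, loadings = 0.85,
                    seed = 17)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  m <- model_from_config(cfg)
  est <- sapply(c("path", "centroid", "factorial"), function(s) {
    fit_pls(X, m, scheme = s)$path_coefficients$estimate
  })
  expect_lt(max(abs(est[, "path"] - est[, "centroid"])), 0.02)
  expect_lt(max(abs(est[, "path"] - est[, "factorial"])), 0.02)
})

test_that("degenerate inputs are rejected and low n warns", {
  m <- bivariate_model()
  d <- cbind(x1 = rep(1, 10), y1 = rnorm(10))
  expect_error(fit_pls(d, m), "constant")
  expect_error(fit_pls(cbind(x1 = rnorm(2), y1 = rnorm(2)), m), "3 samples")
  cfg <- sim_config(seed = 18)  # 12 samples, 29 indicators
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  expect_warning(fit_pls(X, model_from_config(cfg)), "low-n")
  expect_error(fit_pls(matrix(rnorm(20), 10, 2,
                              dimnames = list(NULL, c("x1", "zz"))), m),
               "missing")
})

test_that("DOT export draws one signed edge per structural edge", {
  cfg <- sim_config(n_samples = 100, seed = 19)
  sc <- simulate_latents(cfg)
  X <- simulate_indicators(sc, cfg)
  f <- fit_pls(X, model_from_config(cfg))
  dot <- withr::local_tempfile(fileext = ".dot")
  export_dot(f, dot)
  lines <- readLines(dot)
  edge_lines <- grep("->", lines, value = TRUE)
  expect_length(edge_lines, nrow(f$model$edges))
  expect_true(all(grepl("color=(red|blue)", edge_lines)))
})
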