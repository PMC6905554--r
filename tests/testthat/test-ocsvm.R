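test_that("two orthonormal points give the analytic solution", {
  m <- ocsvm(rbind(c(1, 0), c(0, 1)), kernel = "linear", nu = 0.5)
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(m$rho, 0.5, tolerance = 1e-9)
  # implied w = (0.5, 0.5): hand-evaluated scores
  expect_equal(predict(m, c(1, 1), type = "score"), 0.5,
               tolerance = 1e-9)
  expect_equal(predict(m, c(0, 0), type = "score"), -0.5,
               tolerance = 1e-9)
  expect_equal(predict(m, rbind(c(1, 1), c(0, 0))),
               c("inlier", "outlier"))
})

test_that("replicated single point sits exactly on the boundary", {
  x0 <- c(0.7, -0.2, 1.1)
  for (kern in list(kernel_spec("linear"), kernel_spec("rbf", 0.8))) {
    m <- ocsvm(matrix(rep(x0, 5), 5, byrow = TRUE), kern, nu = 0.3)
    expect_equal(predict(m, x0, type = "score"), 0, tolerance = 1e-9)
    expect_equal(predict(m, x0), "inlier")  # ties go to inlier
  }
})

test_that("score sign convention: zero and positive scores are inliers", {
  m <- ocsvm(gaussian_cloud(30, seed = 4), kernel_spec("rbf", 0.5),
             nu = 0.2)
  sc <- predict(m, gaussian_cloud(50, seed = 5), type = "score")
  lab <- predict(m, gaussian_cloud(50, seed = 5))
  expect_identical(lab, ifelse(sc >= 0, "inlier", "outlier"))
})

test_that("distant query points under RBF score -rho", {
  m <- ocsvm(gaussian_cloud(25, seed = 6), kernel_spec("rbf", 1),
             nu = 0.1)
  far <- matrix(c(1e4, 1e4), 1)
  expect_equal(predict(m, far, type = "score"), -m$rho,
               tolerance = 1e-12)
  expect_true(m$rho > 0)
  expect_equal(predict(m, far), "outlier")
})

test_that("KKT conditions hold at the solution", {
  for (seed in 1:5) {
    X <- gaussian_cloud(60, seed = seed)
    nu <- c(0.1, 0.2, 0.5)[seed %% 3 + 1]
    m <- ocsvm(X, kernel_spec("rbf", 0.5), nu = nu)
    u <- 1 / (nu * 60)
    sc <- m$training_scores
    btol <- 1e-7 * u
    margin <- m$alphas > btol & m$alphas < u - btol
    expect_true(all(abs(sc[margin]) < 1e-6))
    expect_true(all(sc[m$alphas >= u - btol] < 1e-6))
    expect_true(all(sc[m$alphas <= btol] > -1e-6))
    # slacks are the positive parts of the margin violations
    expect_equal(m$slacks, pmax(0, -sc), tolerance = 1e-9)
  }
})

test_that("nu bounds the outlier fraction and the SV fraction", {
  for (seed in 1:6) {
    for (nu in c(0.1, 0.3)) {
      X <- gaussian_cloud(80, seed = 10 + seed)
      m <- ocsvm(X, kernel_spec("rbf", 0.5), nu = nu)
      expect_lte(mean(m$training_scores < -1e-6), nu)
      expect_gte(length(m$sv_index) / 80, nu - 1e-9)
    }
  }
})

test_that("decision scores are invariant to training-row permutation", {
  X <- gaussian_cloud(40, seed = 20)
  q <- gaussian_cloud(30, seed = 21)
  m1 <- ocsvm(X, kernel_spec("rbf", 0.6), nu = 0.15)
  set.seed(22)
  m2 <- ocsvm(X[sample(40), ], kernel_spec("rbf", 0.6), nu = 0.15)
  expect_equal(predict(m1, q, type = "score"),
               predict(m2, q, type = "score"), tolerance = 1e-6)
})

test_that("labels agree with an independent libsvm one-class fit", {
  # e1071 wraps libsvm, whose one-class dual is ours scaled by nu*l:
  # predicted labels must coincide away from the decision boundary
  X <- gaussian_cloud(60, seed = 30)
  grid <- as.matrix(expand.grid(seq(-3, 3, length.out = 20),
                                seq(-3, 3, length.out = 20)))
  for (nu in c(0.1, 0.3)) {
    mine <- ocsvm(X, kernel_spec("rbf", 0.7), nu = nu)
    ref <- e1071::svm(X, type = "one-classification", kernel = "radial",
                      gamma = 0.7, nu = nu, scale = FALSE)
    agree <- mean(predict(ref, grid) == (predict(mine, grid) == "inlier"))
    expect_gte(agree, 0.99)
  }
})

test_that("invalid inputs produce clear errors", {
  X <- gaussian_cloud(5)
  expect_error(ocsvm(X, nu = 0), "nu")
  expect_error(ocsvm(X, nu = 1), "nu")
  expect_error(ocsvm(rbind(c(1, NA)), nu = 0.5), "finite")
  m <- ocsvm(X, nu = 0.5)
  expect_error(predict(m, gaussian_cloud(3, d = 4)), "features")
})

test_that("serialized models round-trip to identical scores", {
  X <- gaussian_cloud(30, seed = 40)
  q <- gaussian_cloud(20, seed = 41)
  m <- ocsvm(X, kernel_spec("rbf", 0.4), nu = 0.2)
  path <- tempfile(fileext = ".json")
  write_occ_model(m, path)
  m2 <- read_occ_model(path)
  expect_equal(predict(m2, q, type = "score"),
               predict(m, q, type = "score"), tolerance = 1e-12)

  s <- svdd(X, kernel_spec("rbf", 0.4), C = 0.2)
  write_occ_model(s, path)
  s2 <- read_occ_model(path)
  expect_equal(predict(s2, q, type = "score"),
               predict(s, q, type = "score"), tolerance = 1e-12)
})
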