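test_that("packaged descriptor and property tables load aligned", {
  tabs <- loadQsprTables()
  expect_equal(nrow(tabs$descriptors), 13L)
  expect_equal(ncol(tabs$descriptors), 9L)
  expect_equal(names(tabs$descriptors),
               c("AZI", "M1", "M2", "mM2", "H", "ReZG3", "SDD", "I", "F"))
  expect_equal(ncol(tabs$properties), 11L)
  expect_equal(tabs$properties["Anastrozole", "MW"], 293.4)
  expect_identical(rownames(tabs$descriptors), rownames(tabs$properties))
  expect_false(anyNA(tabs$descriptors))
  expect_false(anyNA(tabs$properties))

  # alignment by exact name join survives shuffled rows
  y <- setNames(tabs$properties$BP, rownames(tabs$properties))
  shuffle <- sample(names(y))
  fit1 <- qsprFit(tabs$descriptors, y, method = "ridge")
  fit2 <- qsprFit(tabs$descriptors, y[shuffle], method = "ridge")
  expect_equal(coef(fit1), coef(fit2))
})

test_that("ols recovers exact linear data and satisfies the normal equations", {
  X <- data.frame(x1 = c(1, 2, 3, 5, 8, 13))
  fit <- qsprFit(X, 2 * X$x1 + 3, method = "ols")
  expect_equal(unname(coef(fit)), 2)
  expect_equal(fit@intercept, 3)
  expect_equal(fitMetrics(fit, X, 2 * X$x1 + 3)$mse, 0)

  set.seed(7)
  Xf <- as.data.frame(matrix(rnorm(20 * 4), 20, 4,
                             dimnames = list(NULL, paste0("d", 1:4))))
  yf <- rnorm(20)
  fitf <- qsprFit(Xf, yf, method = "ols")
  resid <- yf - predict(fitf, Xf)
  expect_lt(max(abs(crossprod(cbind(1, as.matrix(Xf)), resid))), 1e-8)
})

test_that("rank-deficient designs get the minimum-norm solution with a warning", {
  set.seed(3)
  X <- as.data.frame(matrix(rnorm(4 * 6), 4, 6,
                            dimnames = list(NULL, paste0("d", 1:6))))
  y <- rnorm(4)
  expect_warning(fit <- qsprFit(X, y, method = "ols"),
                 class = "revent_rank_deficient")
  # interpolates (n - 1 <= rank) and is the minimal-norm interpolant
  expect_lt(max(abs(y - predict(fit, X))), 1e-8)
  pinvBeta <- drop(MASS::ginv(scale(as.matrix(X), scale = FALSE)) %*% (y - mean(y)))
  expect_equal(unname(coef(fit)), pinvBeta, tolerance = 1e-6)
})

test_that("ridge matches ols as lambda -> 0 and an independent optimizer", {
  set.seed(11)
  X <- as.data.frame(matrix(rnorm(50 * 3), 50, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  y <- drop(as.matrix(X) %*% c(1, -2, 0.5)) + rnorm(50, sd = 0.1)
  expect_equal(coef(qsprFit(X, y, method = "ridge", lambda = 1e-10)),
               coef(qsprFit(X, y, method = "ols")), tolerance = 1e-6)
  # independent oracle: minimize the penalized objective numerically
  lam <- 0.7
  fit <- qsprFit(X, y, method = "ridge", lambda = lam)
  Xs <- scale(as.matrix(X))
  obj <- function(par) {
    mean((y - par[1] - drop(Xs %*% par[-1]))^2) / 2 + lam * sum(par[-1]^2) / 2
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(fit) * attr(Xs, "scaled:scale")), opt$par[-1],
               tolerance = 1e-5)
})

test_that("lasso shrinks everything to zero at lambda_max and is sparse along a path", {
  set.seed(5)
  X <- as.data.frame(matrix(rnorm(40 * 5), 40, 5,
                            dimnames = list(NULL, paste0("d", 1:5))))
  y <- drop(as.matrix(X) %*% c(3, 0, 0, -1, 0)) + rnorm(40, sd = 0.2)
  lamMax <- lassoLambdaMax(X, y)
  fit <- qsprFit(X, y, method = "lasso", lambda = lamMax * 1.0001)
  expect_true(all(coef(fit) == 0))
  expect_equal(unique(predict(fit, X)), mean(y))

  nnz <- vapply(exp(seq(log(1e-4), log(lamMax * 1.1), length.out = 10)),
    function(l) sum(coef(qsprFit(X, y, method = "lasso", lambda = l)) != 0),
    numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("ridge coefficient norms shrink monotonically in lambda", {
  set.seed(13)
  X <- as.data.frame(matrix(rnorm(30 * 4), 30, 4,
                            dimnames = list(NULL, paste0("d", 1:4))))
  y <- rnorm(30)
  norms <- vapply(10^seq(-4, 2, length.out = 8),
    function(l) sqrt(sum(coef(qsprFit(X, y, method = "ridge", lambda = l))^2 *
                         apply(X, 2, stats::sd)^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("noiseless linear data is recovered by every linear family at tiny penalty", {
  set.seed(17)
  X <- as.data.frame(matrix(rnorm(60 * 3), 60, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  beta <- c(1, -2, 0.5)
  y <- drop(as.matrix(X) %*% beta) + 4
  for (m in c("ols", "ridge", "lasso", "enet")) {
    fit <- qsprFit(X, y, method = m, lambda = 1e-10)
    expect_lt(max(abs(coef(fit) - beta)), 1e-4)
    expect_lt(abs(fit@intercept - 4), 1e-4)
  }
})

test_that("noisy synthetic recovery lands within three standard errors", {
  set.seed(11)
  n <- 50
  X <- as.data.frame(matrix(rnorm(n * 3), n, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  beta <- c(1, -2, 0.5)
  y <- drop(as.matrix(X) %*% beta) + rnorm(n, sd = 0.1)
  fit <- qsprFit(X, y, method = "ols")
  # oracle: closed-form normal equations and their standard errors
  Z <- cbind(1, as.matrix(X))
  bHat <- drop(solve(crossprod(Z), crossprod(Z, y)))
  expect_equal(unname(c(fit@intercept, coef(fit))), unname(bHat), tolerance = 1e-8)
  s2 <- sum((y - Z %*% bHat)^2) / (n - ncol(Z))
  se <- sqrt(diag(solve(crossprod(Z))) * s2)[-1]
  expect_true(all(abs(coef(fit) - beta) <= 3 * se))
})

test_that("fit metrics match hand arithmetic and degenerate cases", {
  X <- data.frame(x = c(1, 2, 3))
  fit <- qsprFit(X, c(1, 2, 3), method = "ols")
  m <- fitMetrics(fit, X, c(1, 2, 3))
  expect_equal(unlist(m), c(pearson_r = 1, r_squared = 1, mse = 0))

  # hand dataset y = (1,2,3), yhat = (1,2,4): identity fit on x = (1,2,4)
  X2 <- data.frame(x = c(1, 2, 4))
  handFit <- new("QsprFit", method = "ols",
                 coefficients = c(x = 1), intercept = 0, hyper = list(),
                 center = c(x = 0), scale = c(x = 1), featureNames = "x",
                 model = NULL)
  expect_equal(predict(handFit, X2), c(1, 2, 4))
  m2 <- fitMetrics(handFit, X2, c(1, 2, 3))
  expect_equal(m2$mse, 1 / 3)
  expect_equal(m2$r_squared, 0.5)

  constFit <- new("QsprFit", method = "ols",
                  coefficients = c(x = 0), intercept = 2, hyper = list(),
                  center = c(x = 0), scale = c(x = 1), featureNames = "x",
                  model = NULL)
  expect_warning(m3 <- fitMetrics(constFit, X, c(1, 2, 3)),
                 class = "revent_constant_prediction")
  expect_equal(m3$pearson_r, 0)
  expect_equal(m3$r_squared, 0)
  expect_error(fitMetrics(fit, X[1, , drop = FALSE], 1),
               class = "revent_too_few_rows")
})

test_that("model comparison is deterministic and penalization costs in-sample fit", {
  X <- data.frame(x = c(1, 2, 4, 7, 11, 16))
  y <- 5 * X$x - 2
  tab <- compareModels(X, y, methods = c("ols", "ridge", "lasso", "enet", "svr"),
                       seed = 42)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$mse[tab$model == "ols"], 0)
  expect_gte(tab$mse[tab$model == "ridge"], tab$mse[tab$model == "ols"])
  tab2 <- compareModels(X, y, methods = c("ols", "ridge", "lasso", "enet", "svr"),
                        seed = 42)
  expect_identical(tab, tab2)
  empty <- compareModels(X, y, methods = character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("equation export renders the sparse parenthesized format", {
  fit <- new("QsprFit", method = "lasso",
             coefficients = c(E_ReZG3 = 165.787), intercept = 550.12,
             hyper = list(lambda = 0.1), center = c(E_ReZG3 = 0),
             scale = c(E_ReZG3 = 1), featureNames = "E_ReZG3", model = NULL)
  expect_equal(equationText(fit), "550.1200 + (165.7870) E_ReZG3")
  expect_equal(equationText(fit, response = "BP"),
               "BP = 550.1200 + (165.7870) E_ReZG3")

  allZero <- new("QsprFit", method = "lasso",
                 coefficients = c(a = 0, b = 0), intercept = 28.7,
                 hyper = list(), center = c(a = 0, b = 0),
                 scale = c(a = 1, b = 1), featureNames = c("a", "b"),
                 model = NULL)
  expect_equal(equationText(allZero), "28.7000")

  neg <- new("QsprFit", method = "lasso",
             coefficients = c(E_R1 = -360.6798, E_ReZG3 = 479.8992),
             intercept = 319.04, hyper = list(),
             center = c(E_R1 = 0, E_ReZG3 = 0),
             scale = c(E_R1 = 1, E_ReZG3 = 1),
             featureNames = c("E_R1", "E_ReZG3"), model = NULL)
  expect_equal(equationText(neg),
               "319.0400 + (-360.6798) E_R1 + (479.8992) E_ReZG3")

  X <- data.frame(x = rnorm(10)); y <- rnorm(10)
  svrFit <- qsprFit(X, y, method = "svr")
  expect_error(equationText(svrFit), class = "revent_no_linear_equation")
})

test_that("zero-variance descriptors are dropped with a warning", {
  X <- data.frame(x = c(1, 2, 3, 4), z = 1)
  y <- c(2, 4, 6, 8)
  expect_warning(fit <- qsprFit(X, y, method = "ridge", lambda = 1e-10),
                 class = "revent_zero_variance")
  expect_equal(names(coef(fit)), "x")
  expect_error(suppressWarnings(qsprFit(X, y, method = "ridge", lambda = -1)),
               class = "revent_bad_hyperparameters")
  expect_error(qsprFit(X, c(y, 1), method = "ols"),
               class = "revent_not_aligned")
})

test_that("leave-one-out tuning returns a grid minimum", {
  set.seed(23)
  X <- as.data.frame(matrix(rnorm(25 * 2), 25, 2,
                            dimnames = list(NULL, c("a", "b"))))
  y <- X$a - X$b + rnorm(25, sd = 0.5)
  res <- looTune(X, y, method = "ridge", grid = c(0.01, 1, 100))
  expect_equal(nrow(res$table), 3L)
  expect_true(res$best %in% res$table$grid)
  expect_equal(res$table$loo_mse[res$table$grid == res$best], min(res$table$loo_mse))
})
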