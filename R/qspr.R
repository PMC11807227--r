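# QSPR harness: descriptor table -> physicochemical property regression with
# five model families (ols, ridge, lasso, elastic net, epsilon-SVR),
# in-sample metrics, model-comparison tables, and sparse equation export.
#
# Conventions: penalized fits run on standardized descriptors and report
# coefficients back on the original scale. The penalty parameterization
# follows the glmnet objective (1/(2n)) RSS + lambda * (mix |b|_1 +
# (1-mix)/2 |b|_2^2), so lasso shrinks everything to zero exactly at
# lambda >= lassoLambdaMax(X, y).

#' Load the packaged drug descriptor and property tables
#'
#' Thirteen cancer drugs with nine reverse-degree descriptor columns
#' (AZI, M1, M2, mM2, H, ReZG3, SDD, I, F) and eleven physicochemical
#' property columns (BP, EoV, FP, MR, MV, P, MW, MM, TPSA, HAC, C:
#' boiling point, enthalpy of vaporization, flash point, molar
#' refractivity, molar volume, polarization, molecular weight, monoisotopic
#' mass, topological polar surface area, heavy-atom count, complexity).
#' The column "I" is interpreted as the inverse-sum-indeg index (the rezg2
#' weight on reverse degrees); see the vignette for this assumption and for
#' transcription caveats on individual cells.
#'
#' @return list with data.frames `descriptors` and `properties`, drug names
#'   as row names, aligned by exact name match
#' @export
loadQsprTables <- function() {
  dpath <- system.file("extdata", "drug_entropy_descriptors.csv",
                       package = "revent", mustWork = TRUE)
  ppath <- system.file("extdata", "drug_physical_properties.csv",
                       package = "revent", mustWork = TRUE)
  desc <- utils::read.csv(dpath, row.names = 1L, check.names = FALSE,
                          comment.char = "#")
  prop <- utils::read.csv(ppath, row.names = 1L, check.names = FALSE,
                          comment.char = "#")
  prop <- prop[rownames(desc), , drop = FALSE]
  list(descriptors = desc, properties = prop)
}

.alignXy <- function(X, y) {
  X <- as.data.frame(X)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X))) {
      .reventStop("not_aligned", "row labels of X and names of y do not match")
    }
    y <- y[rownames(X)]
  } else if (length(y) != nrow(X)) {
    .reventStop("not_aligned", "X and y have different numbers of rows")
  }
  if (anyNA(X) || anyNA(y)) .reventStop("not_aligned", "missing cells are not allowed")
  if (nrow(X) < 2L) .reventStop("too_few_rows", "need at least 2 rows")
  list(X = data.matrix(X), y = as.numeric(y))
}

# Drop zero-variance descriptors (they cannot be standardized), with a warning.
.dropConstant <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    .reventWarn("zero_variance",
      paste("dropping zero-variance descriptor(s):",
            paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  X
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  list(Xs = scale(X, center = ctr, scale = scl), center = ctr, scale = scl)
}

#' Smallest lasso penalty with an all-zero solution
#'
#' With the glmnet penalty convention used throughout this harness, the
#' lasso coefficient vector is exactly zero iff
#' `lambda >= max |x_j' (y - mean(y))| / n` over standardized descriptors.
#'
#' @param X descriptor table (rows observations).
#' @param y numeric response.
#' @return the critical penalty lambda_max
#' @export
lassoLambdaMax <- function(X, y) {
  al <- .alignXy(X, y)
  Xs <- .standardize(.dropConstant(al$X))$Xs
  max(abs(crossprod(Xs, al$y - mean(al$y)))) / length(al$y)
}

.newFit <- function(method, coefs, intercept, hyper, center, scale,
                    featureNames, model = NULL) {
  new("QsprFit", method = method, coefficients = coefs,
      intercept = intercept, hyper = hyper, center = center, scale = scale,
      featureNames = featureNames, model = model)
}

#' Fit a QSPR regression model
#'
#' Methods: `"ols"` ordinary least squares on the original scale (the
#' minimum-norm solution, with a rank-deficiency warning, when the design
#' is not full rank, e.g. fewer observations than descriptors); `"ridge"`
#' L2-penalized least squares on standardized descriptors, solved in closed
#' form; `"lasso"`/`"enet"` L1/(L1+L2)-penalized least squares on
#' standardized descriptors via glmnet coordinate descent (convergence
#' threshold 1e-12); `"svr"` epsilon-insensitive support vector regression
#' (radial kernel) on standardized descriptors. Linear-family coefficients
#' are reported on the original descriptor scale.
#'
#' @param X descriptor table (data.frame or matrix, rows = observations);
#'   row names, when present, are matched against `names(y)`.
#' @param y numeric response, optionally named.
#' @param method one of `"ols"`, `"ridge"`, `"lasso"`, `"enet"`, `"svr"`.
#' @param lambda penalty for ridge/lasso/enet (defaults 1.0, 0.1, 0.1).
#' @param mix elastic-net mixing in `[0, 1]` (1 = lasso; default 0.5).
#' @param cost,epsilon,gamma SVR hyperparameters (defaults 100, 0.1, 1/p).
#' @param seed integer seed for any stochastic component.
#' @return a [QsprFit-class]
#' @examples
#' X <- data.frame(x1 = 1:6)
#' fit <- qsprFit(X, 2 * X$x1 + 3, method = "ols")
#' coef(fit)   # x1 = 2
#' @export
qsprFit <- function(X, y, method = c("ols", "ridge", "lasso", "enet", "svr"),
                    lambda = NULL, mix = 0.5, cost = 100, epsilon = 0.1,
                    gamma = NULL, seed = 1L) {
  method <- match.arg(method)
  al <- .alignXy(X, y)
  Xm <- .dropConstant(al$X)
  y <- al$y
  n <- nrow(Xm)
  if (is.null(lambda)) lambda <- switch(method, ridge = 1.0, 0.1)
  if (lambda < 0 || mix < 0 || mix > 1 || cost <= 0 || epsilon < 0) {
    .reventStop("bad_hyperparameters", "need lambda >= 0, mix in [0,1], cost > 0, epsilon >= 0")
  }

  if (method == "ols") {
    # minimum-norm least squares via SVD pseudoinverse on centered data
    xc <- colMeans(Xm); yc <- mean(y)
    Xc <- sweep(Xm, 2L, xc)
    sv <- svd(Xc)
    tol <- max(dim(Xc)) * max(sv$d, 0) * .Machine$double.eps
    pos <- sv$d > tol
    if (sum(pos) < ncol(Xc)) {
      .reventWarn("rank_deficient",
        sprintf("design is rank-deficient (rank %d < %d descriptors); reporting the minimum-norm solution",
                sum(pos), ncol(Xc)))
    }
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y - yc)) / sv$d[pos])
    beta <- drop(beta)
    names(beta) <- colnames(Xm)
    return(.newFit("ols", beta, yc - sum(xc * beta), list(),
                   stats::setNames(rep(0, ncol(Xm)), colnames(Xm)),
                   stats::setNames(rep(1, ncol(Xm)), colnames(Xm)),
                   colnames(Xm)))
  }

  std <- .standardize(Xm)
  Xs <- std$Xs

  if (method == "ridge") {
    # glmnet-convention ridge: (X'X/n + lambda I) b = X'(y - ybar)/n
    A <- crossprod(Xs) / n + diag(lambda, ncol(Xs))
    bstd <- drop(solve(A, crossprod(Xs, y - mean(y)) / n))
    coefs <- bstd / std$scale
    names(coefs) <- colnames(Xm)
    return(.newFit("ridge", coefs, mean(y) - sum(std$center * coefs),
                   list(lambda = lambda), std$center, std$scale, colnames(Xm)))
  }

  if (method %in% c("lasso", "enet")) {
    aMix <- if (method == "lasso") 1 else mix
    if (ncol(Xs) == 1L) {
      # closed-form coordinate update for a single standardized predictor
      z <- drop(crossprod(Xs, y - mean(y))) / n
      denom <- drop(crossprod(Xs)) / n + lambda * (1 - aMix)
      bstd <- sign(z) * max(abs(z) - lambda * aMix, 0) / denom
    } else {
      path <- lambda * c(64, 16, 4, 2)     # warm-start path above the target
      gfit <- glmnet::glmnet(Xs, y, alpha = aMix, lambda = path,
                             standardize = FALSE, intercept = TRUE,
                             thresh = 1e-12, maxit = 1e7)
      cf <- glmnet::coef.glmnet(gfit, s = lambda, exact = TRUE, x = Xs, y = y,
                                alpha = aMix, standardize = FALSE,
                                intercept = TRUE, thresh = 1e-12, maxit = 1e7)
      bstd <- drop(cf)[-1L]
    }
    coefs <- bstd / std$scale
    names(coefs) <- colnames(Xm)
    return(.newFit(method, coefs, mean(y) - sum(std$center * coefs),
                   list(lambda = lambda, mix = aMix),
                   std$center, std$scale, colnames(Xm)))
  }

  # svr: radial-kernel epsilon regression on standardized descriptors
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  if (gamma <= 0) .reventStop("bad_hyperparameters", "gamma must be > 0")
  model <- .withSeed(seed,
    e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE))
  .newFit("svr", stats::setNames(numeric(0), character(0)), NA_real_,
          list(kernel = "radial", cost = cost, epsilon = epsilon,
               gamma = gamma),
          std$center, std$scale, colnames(Xm), model = model)
}

#' @describeIn qsprFit coefficients on the original descriptor scale
#' @param object a [QsprFit-class]
#' @param ... ignored.
#' @export
setMethod("coef", "QsprFit", function(object, ...) object@coefficients)

#' Predict from a fitted QSPR model
#'
#' @param object a [QsprFit-class]
#' @param newdata descriptor table with the model's descriptor columns.
#' @param ... ignored.
#' @return numeric vector of predictions
#' @export
setMethod("predict", "QsprFit", function(object, newdata, ...) {
  Xm <- data.matrix(as.data.frame(newdata)[, object@featureNames, drop = FALSE])
  if (object@method == "svr") {
    Xs <- scale(Xm, center = object@center, scale = object@scale)
    return(as.numeric(stats::predict(object@model, Xs)))
  }
  as.numeric(object@intercept + Xm %*% object@coefficients)
})

setMethod("show", "QsprFit", function(object) {
  cat(sprintf("QsprFit: method = %s, %d descriptor(s)\n",
              object@method, length(object@featureNames)))
  if (object@method != "svr") {
    cat(sprintf("  intercept %.6g; nonzero coefficients %d/%d\n",
                object@intercept, sum(object@coefficients != 0),
                length(object@coefficients)))
  }
})

#' In-sample fit metrics
#'
#' mse is the mean squared residual; r_squared is `1 - SSres/SStot`;
#' pearson_r is the correlation between predictions and observations,
#' reported as 0 (with a warning) when the predictions are constant.
#'
#' @param fit a [QsprFit-class]
#' @param X descriptor table.
#' @param y observed response.
#' @return one-row data.frame with columns `pearson_r`, `r_squared`, `mse`
#' @export
fitMetrics <- function(fit, X, y) {
  al <- .alignXy(X, y)
  pred <- predict(fit, as.data.frame(al$X))
  obs <- al$y
  mse <- mean((obs - pred)^2)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  if (stats::sd(pred) == 0) {
    .reventWarn("constant_prediction",
      "predictions are constant; Pearson r undefined, reported as 0")
    r <- 0
  } else {
    r <- stats::cor(pred, obs)
  }
  data.frame(pearson_r = r, r_squared = r2, mse = mse)
}

#' Compare regression model families on one property
#'
#' Fits each requested method and reports its in-sample metrics, one row
#' per method; deterministic for a fixed seed.
#'
#' @param X descriptor table.
#' @param y numeric response.
#' @param methods character vector of methods (subset of ols, ridge, lasso,
#'   enet, svr).
#' @param seed integer seed.
#' @param ... hyperparameters forwarded to [qsprFit()].
#' @return data.frame with columns `model`, `pearson_r`, `r_squared`, `mse`
#' @export
compareModels <- function(X, y,
                          methods = c("ols", "ridge", "lasso", "enet", "svr"),
                          seed = 1L, ...) {
  if (length(methods) == 0L) {
    return(data.frame(model = character(0), pearson_r = numeric(0),
                      r_squared = numeric(0), mse = numeric(0)))
  }
  rows <- lapply(methods, function(m) {
    fit <- suppressWarnings(qsprFit(X, y, method = m, seed = seed, ...))
    cbind(data.frame(model = m), suppressWarnings(fitMetrics(fit, X, y)))
  })
  do.call(rbind, rows)
}

#' Render a fitted linear model as an equation string
#'
#' Formats `intercept + (coef) NAME + ...` with each coefficient printed in
#' parentheses at the requested precision (negative ones as `(-c)`), and
#' exactly-zero coefficients omitted, matching the sparse-lasso equation
#' style. Nonlinear fits (radial-kernel svr) have no linear equation.
#'
#' @param fit a linear-family [QsprFit-class]
#' @param precision decimal places (default 4).
#' @param response optional response name rendered as `"RESP = ..."`.
#' @return a single string
#' @examples
#' X <- data.frame(E_ReZG3 = c(1, 2, 4, 5))
#' equationText(qsprFit(X, 3 + 2 * X$E_ReZG3, method = "ols"))
#' @export
equationText <- function(fit, precision = 4L, response = NULL) {
  stopifnot(is(fit, "QsprFit"))
  if (fit@method == "svr") {
    .reventStop("no_linear_equation",
      "svr with a radial kernel has no linear equation")
  }
  fmt <- function(x) formatC(x, format = "f", digits = precision)
  keep <- fit@coefficients != 0
  terms <- sprintf("(%s) %s", fmt(fit@coefficients[keep]),
                   names(fit@coefficients)[keep])
  rhs <- paste(c(fmt(fit@intercept), terms), collapse = " + ")
  if (is.null(response)) rhs else paste(response, "=", rhs)
}

#' Leave-one-out grid search for a penalty or cost
#'
#' Optional helper: evaluates leave-one-out mean squared error over a grid
#' of the method's main hyperparameter (lambda for ridge/lasso/enet, cost
#' for svr) and returns the grid with the winner.
#'
#' @param X descriptor table.
#' @param y numeric response.
#' @param method model family.
#' @param grid numeric grid; defaults to a log-spaced grid.
#' @param seed integer seed.
#' @param ... further hyperparameters for [qsprFit()].
#' @return list with `table` (grid, loo_mse) and `best` (grid value)
#' @export
looTune <- function(X, y, method = c("ridge", "lasso", "enet", "svr"),
                    grid = NULL, seed = 1L, ...) {
  method <- match.arg(method)
  al <- .alignXy(X, y)
  if (is.null(grid)) grid <- 10^seq(-3, 2, length.out = 11)
  looMse <- vapply(grid, function(g) {
    errs <- vapply(seq_len(nrow(al$X)), function(i) {
      args <- c(list(X = al$X[-i, , drop = FALSE], y = al$y[-i],
                     method = method, seed = seed), list(...))
      if (method == "svr") args$cost <- g else args$lambda <- g
      fit <- suppressWarnings(do.call(qsprFit, args))
      (al$y[i] - predict(fit, as.data.frame(al$X[i, , drop = FALSE])))^2
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(table = data.frame(grid = grid, loo_mse = looMse),
       best = grid[which.min(looMse)])
}
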