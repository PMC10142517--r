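test_that("split sizes follow largest-remainder rounding", {
  s218 <- makeSplit(218, seed = 1)
  expect_equal(lengths(s218), c(train = 152L, val = 33L, test = 33L))
  s20 <- makeSplit(20, seed = 1)
  expect_equal(lengths(s20), c(train = 14L, val = 3L, test = 3L))
  all218 <- sort(c(s218$train, s218$val, s218$test))
  expect_identical(all218, 1:218)
  expect_identical(makeSplit(218, seed = 7), makeSplit(218, seed = 7))
  expect_false(identical(makeSplit(218, seed = 7)$train,
                         makeSplit(218, seed = 8)$train))
  expect_error(makeSplit(3, seed = 1), "empty")
})

test_that("grouped splits keep all plans of a patient together", {
  groups <- rep(sprintf("pt%02d", 1:30), times = rep(c(2, 3, 5), 10))
  n <- length(groups)
  sp <- makeSplit(n, seed = 4, groupIds = groups)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(n))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    hits <- c(all(rows %in% sp$train), all(rows %in% sp$val),
              all(rows %in% sp$test))
    expect_equal(sum(hits), 1)
  }
})

test_that("min-max scalers map the training range onto [-1, 1]", {
  X <- cbind(c(0, 0.25, 0.5), c(2, 5, 8))
  y <- c(1, 3, 5)
  sc <- fitScalers(X, y)
  Xs <- ringdose:::scaleForward(sc$input, X)
  expect_equal(Xs[1, ], c(-1, -1))
  expect_equal(Xs[3, ], c(1, 1))
  expect_equal(Xs[2, 1], 0) # midpoint of [0, 0.5]
  ys <- ringdose:::scaleForward(sc$target, y)
  expect_equal(ringdose:::scaleInverse(sc$target, ys), y, tolerance = 1e-12)
  expect_warning(fitScalers(cbind(rep(2, 3), 1:3), 1:3), "constant")
})

test_that("forward pass reproduces a hand-computed one-unit network", {
  sc <- list(input = list(min = -1, max = 1), target = list(min = -1, max = 1))
  m <- new("NetworkModel", hiddenWeights = matrix(1, 1, 1), hiddenBias = 0,
           outputWeights = 2, outputBias = 0, inputScaler = sc$input,
           targetScaler = sc$target, trained = TRUE)
  expect_equal(nnForward(m, 0.5), 2 * tanh(0.5), tolerance = 1e-12)
  # all-zero weights: constant prediction equal to the unscaled output bias
  m0 <- new("NetworkModel", hiddenWeights = matrix(0, 3, 2),
            hiddenBias = rep(0, 3), outputWeights = rep(0, 3),
            outputBias = 0.25, inputScaler = list(min = c(0, 0), max = c(1, 1)),
            targetScaler = list(min = 2, max = 6), trained = TRUE)
  for (x in list(c(0, 1), c(0.3, 0.4), c(1, 0)))
    expect_equal(nnForward(m0, x), (0.25 + 1) / 2 * 4 + 2)
  expect_error(nnForward(m0, c(1, 2, 3)), "does not match")
})

test_that("prediction is invariant to raw feature units", {
  set.seed(15)
  X <- cbind(stats::runif(30), stats::runif(30) * 100)
  y <- X[, 1] + 0.01 * X[, 2]
  sc1 <- fitScalers(X, y)
  m1 <- initNetwork(sc1, 5, seed = 2)
  X2 <- X; X2[, 2] <- X2[, 2] / 1000 # change of units
  sc2 <- fitScalers(X2, y)
  m2 <- m1; m2@inputScaler <- sc2$input
  expect_equal(nnForward(m1, X), nnForward(m2, X2), tolerance = 1e-12)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(21)
  d <- 6; h <- 4; n <- 7
  sc <- fitScalers(matrix(stats::runif(20 * d), 20, d), stats::runif(20))
  m <- initNetwork(sc, h, seed = 33)
  Xs <- matrix(stats::runif(n * d, -1, 1), n, d)
  fw <- ringdose:::forwardScaled(m, Xs, jacobian = TRUE)
  th <- ringdose:::thetaFromModel(m)
  eps <- 1e-6
  Jnum <- matrix(0, n, length(th))
  for (k in seq_along(th)) {
    tp <- th; tp[k] <- tp[k] + eps
    tm <- th; tm[k] <- tm[k] - eps
    Jnum[, k] <-
      (ringdose:::forwardScaled(ringdose:::modelFromTheta(m, tp), Xs)$yhat -
         ringdose:::forwardScaled(ringdose:::modelFromTheta(m, tm), Xs)$yhat) /
      (2 * eps)
  }
  expect_lt(max(abs(fw$J - Jnum)) / max(abs(Jnum)), 1e-6)
})

test_that("LM drives a noiseless linear target to the least-squares fit", {
  set.seed(7)
  n <- 200
  X <- cbind(stats::runif(n), stats::runif(n))
  y <- 3 * X[, 1] - 2 * X[, 2] + 1
  sc <- fitScalers(X, y)
  m0 <- initNetwork(sc, 10, seed = 3)
  fit <- lmTrain(m0, X, y, config = trainingConfig(maxEpochs = 200, seed = 3))
  expect_lte(nrow(fit$history), 200)
  expect_true(all(diff(fit$history$train_mse) < 0)) # strict decrease
  pred <- nnForward(fit$model, X)
  expect_lt(mean((pred - y)^2), 1e-8)
  ols <- stats::fitted(stats::lm(y ~ X))
  expect_lt(sqrt(mean((pred - ols)^2)), 1e-4)
})

test_that("an already-converged gradient returns zero accepted epochs", {
  X <- matrix(seq(0, 1, length.out = 20), 20, 1)
  y <- rep(0.5, 20) # constant target maps to scaled 0 with zero gradient
  sc <- list(input = list(min = 0, max = 1), target = list(min = 0, max = 1))
  m <- new("NetworkModel", hiddenWeights = matrix(0, 2, 1),
           hiddenBias = c(0, 0), outputWeights = c(0, 0), outputBias = -0,
           inputScaler = sc$input, targetScaler = sc$target, trained = FALSE)
  fit <- lmTrain(m, X, y, config = trainingConfig())
  expect_equal(nrow(fit$history), 0)
})

test_that("large damping steps along the gradient, zero damping is Gauss-Newton", {
  set.seed(40)
  d <- 2; h <- 2; n <- 50
  X <- matrix(stats::runif(n * d), n, d)
  y <- stats::runif(n)
  sc <- fitScalers(X, y)
  m <- initNetwork(sc, h, seed = 11)
  Xs <- ringdose:::scaleForward(sc$input, X)
  ys <- ringdose:::scaleForward(sc$target, y)
  fw <- ringdose:::forwardScaled(m, Xs, jacobian = TRUE)
  e <- ys - fw$yhat
  p <- ncol(fw$J)
  stepAt <- function(mu) solve(crossprod(fw$J) + mu * diag(p),
                               crossprod(fw$J, e))
  gdir <- crossprod(fw$J, e)
  big <- stepAt(1e12)
  cosang <- sum(big * gdir) / sqrt(sum(big^2) * sum(gdir^2))
  expect_gt(cosang, 1 - 1e-9)
  gn <- solve(crossprod(fw$J), crossprod(fw$J, e))
  expect_equal(as.vector(stepAt(0)), as.vector(gn), tolerance = 1e-8)
})

test_that("restart protocol returns the best-validation run with a full log", {
  set.seed(31)
  n <- 120; d <- 4
  X <- matrix(stats::runif(n * d, -1, 1), n, d)
  y <- sin(2 * X[, 1]) + 0.5 * X[, 2] + stats::rnorm(n, 0, 0.05)
  sp <- makeSplit(n, seed = 2)
  cfg <- trainingConfig(nRestarts = 6, hiddenSize = 5, seed = 17,
                        maxEpochs = 150)
  fit <- trainWithRestarts(X, y, sp, cfg)
  expect_equal(nrow(fit$summary), 6)
  expect_true(all(c("restart", "seed", "epochs", "train_mse", "val_mse")
                  %in% names(fit$summary)))
  expect_equal(fit$best, which.min(fit$summary$val_mse))
  expect_lte(min(fit$summary$val_mse), fit$summary$val_mse[1])
  # a single restart reduces to one lmTrain call with that seed
  cfg1 <- trainingConfig(nRestarts = 1, hiddenSize = 5, seed = 17,
                         maxEpochs = 150)
  one <- trainWithRestarts(X, y, sp, cfg1)
  sc <- fitScalers(X[sp$train, ], y[sp$train])
  m0 <- initNetwork(sc, 5, one$summary$seed[1])
  direct <- lmTrain(m0, X[sp$train, ], y[sp$train], X[sp$val, ], y[sp$val],
                    cfg1)
  expect_equal(nnForward(one$model, X), nnForward(direct$model, X),
               tolerance = 1e-12)
})

test_that("ratio predictions combine with D90 into absolute dose", {
  sc <- list(input = list(min = rep(0, 16), max = rep(1, 16)),
             target = list(min = 0, max = 1))
  m <- initNetwork(sc, 4, seed = 5)
  m@trained <- TRUE
  dec <- new("SubOrganDecomposition", oarLabel = "rectum", ringWidthMm = 3,
             nRings = 5L, ringVolumesCc = rep(1, 5),
             normalizedVolumes = rep(0.02, 5), oarVolumeCc = 50,
             hrctvVolumeCc = 0.5, insideVolumeCc = 0, farVolumeCc = 45)
  out <- predictOarDose(m, dec, d90Gy = 7)
  expect_equal(out$d2cc_gy, out$ratio * 7)
  expect_equal(predictOarDose(m, dec)$ratio, out$ratio) # deterministic
  m@trained <- FALSE
  expect_error(predictOarDose(m, dec), "untrained")
})
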