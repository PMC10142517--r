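#' Levenberg-Marquardt training configuration
#'
#' Damping schedule, stopping rules and the restart protocol of the network
#' trainer. A training run accepts a step only when the training MSE
#' decreases; the damping factor mu is divided by `muDec` on acceptance and
#' multiplied by `muInc` on rejection, interpolating between Gauss-Newton
#' (small mu) and gradient descent (large mu).
#'
#' @param mu0 initial damping factor.
#' @param muInc,muDec damping multipliers on rejection / acceptance.
#' @param muMax run stops once mu exceeds this.
#' @param maxEpochs cap on accepted epochs.
#' @param maxValFail consecutive accepted epochs with non-improving
#'   validation MSE tolerated before early stopping.
#' @param minGrad stop when the MSE gradient norm falls below this.
#' @param nRestarts independent random initializations; the run with the
#'   lowest validation MSE wins.
#' @param hiddenSize hidden units (default 10).
#' @param seed base seed of the restart stream.
#' @return validated named list of class `TrainingConfig`.
#' @export
trainingConfig <- function(mu0 = 1e-3, muInc = 10, muDec = 0.1,
                           muMax = 1e10, maxEpochs = 1000L, maxValFail = 6L,
                           minGrad = 1e-7, nRestarts = 100L,
                           hiddenSize = 10L, seed = 1L) {
  cfg <- list(mu0 = mu0, muInc = muInc, muDec = muDec, muMax = muMax,
              maxEpochs = as.integer(maxEpochs),
              maxValFail = as.integer(maxValFail), minGrad = minGrad,
              nRestarts = as.integer(nRestarts),
              hiddenSize = as.integer(hiddenSize), seed = as.integer(seed))
  if (cfg$mu0 <= 0 || cfg$muInc <= 1 || cfg$muDec <= 0 || cfg$muDec >= 1)
    stop("need mu0 > 0 and muInc > 1 > muDec > 0")
  if (cfg$nRestarts < 1L) stop("nRestarts must be >= 1")
  if (cfg$hiddenSize < 1L) stop("hiddenSize must be >= 1")
  class(cfg) <- "TrainingConfig"
  cfg
}

#' Fit min-max scalers on the training block
#'
#' Per-variable affine maps sending the training (min, max) to (-1, +1),
#' applied without clipping outside the range. A constant variable maps to
#' the constant 0 (with a warning), never to a failure.
#'
#' @param features training feature matrix (n x d).
#' @param target training target vector.
#' @return list with elements `input` and `target`, each `list(min, max)`.
#' @export
fitScalers <- function(features, target) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("training block is empty")
  lo <- apply(features, 2, min)
  hi <- apply(features, 2, max)
  if (any(hi == lo))
    warning("constant feature(s) ", paste(which(hi == lo), collapse = ", "),
            " map to 0")
  tlo <- min(target); thi <- max(target)
  if (thi == tlo) warning("constant target maps to 0")
  list(input = list(min = lo, max = hi),
       target = list(min = tlo, max = thi))
}

scaleForward <- function(sc, x) {
  rng <- sc$max - sc$min
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, sc$min), 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
    out[, rng == 0] <- 0
    out
  } else {
    if (rng > 0) 2 * (x - sc$min) / rng - 1 else rep(0, length(x))
  }
}

scaleInverse <- function(sc, xs) {
  rng <- sc$max - sc$min
  if (all(rng == 0)) return(rep(sc$min, length(xs)))
  (xs + 1) / 2 * rng + sc$min
}

#' Initialize an untrained network
#'
#' One hidden tanh layer of `hiddenSize` units and a linear output; weights
#' drawn uniform(-0.5, 0.5) scaled by 1/sqrt(fan-in) under the given seed.
#'
#' @param scalers output of [fitScalers()].
#' @param hiddenSize hidden units.
#' @param seed RNG seed for the initialization.
#' @return an untrained [NetworkModel-class].
#' @export
initNetwork <- function(scalers, hiddenSize = 10L, seed = 1L) {
  d <- length(scalers$input$min)
  h <- as.integer(hiddenSize)
  set.seed(seed)
  new("NetworkModel",
      hiddenWeights = matrix(stats::runif(h * d, -0.5, 0.5) / sqrt(d), h, d),
      hiddenBias = stats::runif(h, -0.5, 0.5) / sqrt(d),
      outputWeights = stats::runif(h, -0.5, 0.5) / sqrt(h),
      outputBias = stats::runif(1, -0.5, 0.5) / sqrt(h),
      inputScaler = scalers$input, targetScaler = scalers$target,
      trained = FALSE)
}

thetaFromModel <- function(model) {
  c(as.vector(model@hiddenWeights), model@hiddenBias,
    model@outputWeights, model@outputBias)
}

modelFromTheta <- function(model, theta) {
  h <- hiddenSize(model); d <- inputSize(model)
  model@hiddenWeights <- matrix(theta[seq_len(h * d)], h, d)
  model@hiddenBias <- theta[h * d + seq_len(h)]
  model@outputWeights <- theta[h * d + h + seq_len(h)]
  model@outputBias <- theta[h * d + 2L * h + 1L]
  model
}

# Forward pass and Jacobian of the scaled-space prediction w.r.t. the
# packed parameter vector (column-major W1, b1, W2, b2).
forwardScaled <- function(model, Xs, jacobian = FALSE) {
  h <- hiddenSize(model); d <- inputSize(model)
  Z <- sweep(Xs %*% t(model@hiddenWeights), 2, model@hiddenBias, "+")
  A <- tanh(Z)
  yhat <- as.vector(A %*% model@outputWeights) + model@outputBias
  if (!jacobian) return(list(yhat = yhat))
  D <- sweep(1 - A^2, 2, model@outputWeights, "*") # n x h
  n <- nrow(Xs)
  J <- matrix(0, n, h * d + 2L * h + 1L)
  for (k in seq_len(d))
    J[, (k - 1L) * h + seq_len(h)] <- D * Xs[, k]
  J[, h * d + seq_len(h)] <- D
  J[, h * d + h + seq_len(h)] <- A
  J[, h * d + 2L * h + 1L] <- 1
  list(yhat = yhat, J = J)
}

#' Network forward pass on raw features
#'
#' Scales the inputs with the model's fitted min-max maps, evaluates the
#' tanh hidden layer and linear output, and maps the result back through the
#' inverse target scaling.
#'
#' @param model a [NetworkModel-class].
#' @param features numeric vector of length d, or an n x d matrix.
#' @return predicted target value(s) on the original scale.
#' @export
nnForward <- function(model, features) {
  stopifnot(is(model, "NetworkModel"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != inputSize(model))
    stop("feature length ", ncol(features), " does not match the model (",
         inputSize(model), ")")
  Xs <- scaleForward(model@inputScaler, as.matrix(features))
  ys <- forwardScaled(model, Xs)$yhat
  scaleInverse(model@targetScaler, ys)
}

#' Train a network with the Levenberg-Marquardt algorithm
#'
#' Full-batch damped Gauss-Newton on the scaled-space residuals: each
#' candidate step solves `(J'J + mu I) delta = J' e` and is accepted only if
#' the training MSE strictly decreases (then `mu <- mu * muDec`), otherwise
#' `mu <- mu * muInc` and the step is retried. Stops on `maxEpochs`,
#' `mu > muMax`, gradient norm below `minGrad`, or — when a validation set
#' is supplied — after `maxValFail` consecutive accepted epochs without a
#' validation improvement, returning the weights of the best validation
#' epoch.
#'
#' @param model an initialized [NetworkModel-class] (scalers fitted).
#' @param features,target training block (raw scale).
#' @param valFeatures,valTarget optional validation block.
#' @param config a [trainingConfig()].
#' @return list with `model` (trained) and `history` (one row per accepted
#'   epoch: epoch, mu, train_mse, val_mse, grad_norm; scaled space).
#' @export
lmTrain <- function(model, features, target, valFeatures = NULL,
                    valTarget = NULL, config = trainingConfig()) {
  stopifnot(is(model, "NetworkModel"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("training set is empty")
  if (ncol(features) != inputSize(model))
    stop("model dims do not match the data")
  Xs <- scaleForward(model@inputScaler, features)
  ys <- scaleForward(model@targetScaler, target)
  hasVal <- !is.null(valFeatures)
  if (hasVal) {
    Xv <- scaleForward(model@inputScaler, as.matrix(valFeatures))
    yv <- scaleForward(model@targetScaler, valTarget)
  }
  n <- nrow(Xs)
  theta <- thetaFromModel(model)
  p <- length(theta)
  valMse <- function(th) {
    m <- modelFromTheta(model, th)
    mean((yv - forwardScaled(m, Xv)$yhat)^2)
  }

  mu <- config$mu0
  fw <- forwardScaled(model, Xs, jacobian = TRUE)
  e <- ys - fw$yhat
  mse <- mean(e^2)
  bestVal <- if (hasVal) valMse(theta) else NA_real_
  bestTheta <- theta
  valFail <- 0L
  hist <- list()
  epoch <- 0L

  repeat {
    g <- 2 * crossprod(fw$J, e) / n
    gnorm <- sqrt(sum(g^2))
    if (gnorm < config$minGrad) break
    if (epoch >= config$maxEpochs) break
    JtJ <- crossprod(fw$J)
    Jte <- crossprod(fw$J, e)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + mu * diag(p), Jte),
        error = function(err) NULL)
      if (is.null(delta)) {
        mu <- mu * config$muInc
        if (mu > config$muMax)
          stop("LM normal matrix singular despite damping (mu = ", mu,
               ", epoch = ", epoch, ", grad = ", signif(gnorm, 4), ")")
        next
      }
      thetaNew <- theta + as.vector(delta)
      mNew <- modelFromTheta(model, thetaNew)
      fwNew <- forwardScaled(mNew, Xs, jacobian = TRUE)
      eNew <- ys - fwNew$yhat
      mseNew <- mean(eNew^2)
      if (is.finite(mseNew) && mseNew < mse) {
        theta <- thetaNew
        fw <- fwNew
        e <- eNew
        mse <- mseNew
        mu <- mu * config$muDec
        accepted <- TRUE
      } else {
        mu <- mu * config$muInc
        if (mu > config$muMax) break
      }
    }
    if (!accepted) break # damping exhausted without an acceptable step
    epoch <- epoch + 1L
    vm <- if (hasVal) valMse(theta) else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, mu = mu, train_mse = mse,
                                val_mse = vm, grad_norm = gnorm)
    if (hasVal) {
      if (vm < bestVal) {
        bestVal <- vm
        bestTheta <- theta
        valFail <- 0L
      } else {
        valFail <- valFail + 1L
        if (valFail >= config$maxValFail) break
      }
    } else {
      bestTheta <- theta
    }
  }

  out <- modelFromTheta(model, bestTheta)
  out@trained <- TRUE
  list(model = out,
       history = if (length(hist)) do.call(rbind, hist) else
         data.frame(epoch = integer(0), mu = numeric(0),
                    train_mse = numeric(0), val_mse = numeric(0),
                    grad_norm = numeric(0)))
}

#' Train with random restarts, keeping the best validation run
#'
#' Runs `config$nRestarts` independent initializations (seeded stream) of
#' [lmTrain()] and returns the run with the lowest validation MSE, together
#' with a per-restart summary — the multi-start best-result protocol used to
#' sidestep bad local minima of a single LM run.
#'
#' @param features,target full data (raw scale).
#' @param split a [makeSplit()] assignment over the rows.
#' @param config a [trainingConfig()].
#' @return list with `model`, `summary` (restart, seed, epochs, train_mse,
#'   val_mse) and `best` (winning restart index).
#' @export
trainWithRestarts <- function(features, target, split,
                              config = trainingConfig()) {
  features <- as.matrix(features)
  scalers <- fitScalers(features[split$train, , drop = FALSE],
                        target[split$train])
  rows <- vector("list", config$nRestarts)
  models <- vector("list", config$nRestarts)
  for (r in seq_len(config$nRestarts)) {
    seed_r <- as.integer((as.numeric(config$seed) + 99991 * r) %% 2147483647)
    fit <- tryCatch({
      m0 <- initNetwork(scalers, config$hiddenSize, seed_r)
      lmTrain(m0, features[split$train, , drop = FALSE], target[split$train],
              features[split$val, , drop = FALSE], target[split$val],
              config)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[r]] <- data.frame(restart = r, seed = seed_r, epochs = NA_integer_,
                              train_mse = NA_real_, val_mse = NA_real_)
      next
    }
    m <- fit$model
    Xv <- features[split$val, , drop = FALSE]
    vm <- mean((scaleForward(m@targetScaler, target[split$val]) -
                  forwardScaled(m, scaleForward(m@inputScaler, Xv))$yhat)^2)
    tm <- mean((scaleForward(m@targetScaler, target[split$train]) -
                  forwardScaled(m, scaleForward(
                    m@inputScaler, features[split$train, , drop = FALSE]))$yhat)^2)
    rows[[r]] <- data.frame(restart = r, seed = seed_r,
                            epochs = nrow(fit$history),
                            train_mse = tm, val_mse = vm)
    models[[r]] <- m
  }
  summary <- do.call(rbind, rows)
  if (all(is.na(summary$val_mse))) stop("all restarts failed")
  best <- which.min(summary$val_mse)
  list(model = models[[best]], summary = summary, best = best)
}

#' Train/validation/test split by largest-remainder rounding
#'
#' Uniform random permutation followed by largest-remainder allocation of
#' the rounded set sizes (70/15/15 by default). With `groupIds`, whole
#' groups (e.g. all fraction plans of one patient) are kept in a single set.
#'
#' @param n number of rows (>= 3).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed permutation seed.
#' @param groupIds optional vector of length `n`; rows sharing a value stay
#'   in the same set.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @examples
#' lengths(makeSplit(218, seed = 1)) # 152, 33, 33
#' @export
makeSplit <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                      groupIds = NULL) {
  if (n < 3L) stop("need n >= 3")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  sizes <- largestRemainder(n, fractions)
  if (any(sizes == 0L)) stop("a split set would be empty at n = ", n)
  set.seed(seed)
  if (is.null(groupIds)) {
    perm <- sample.int(n)
    idx <- split(perm, rep(c("train", "val", "test"), sizes))
    lapply(idx[c("train", "val", "test")], sort)
  } else {
    if (length(groupIds) != n) stop("groupIds must have length n")
    groups <- unique(groupIds)
    perm <- groups[sample.int(length(groups))]
    setName <- c("train", "val", "test")
    out <- list(train = integer(0), val = integer(0), test = integer(0))
    k <- 1L
    for (g in perm) {
      rows <- which(groupIds == g)
      out[[setName[k]]] <- c(out[[setName[k]]], rows)
      if (k < 3L && length(out[[setName[k]]]) >= sizes[k]) k <- k + 1L
    }
    if (any(lengths(out) == 0L))
      stop("grouped allocation left a set empty; too few groups")
    lapply(out, sort)
  }
}

largestRemainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Predict the D2cm3/D90 ratio (and absolute D2cm3) of one OAR
#'
#' Assembles the model feature vector from a ring decomposition (rings
#' zero-padded to the model's input length minus one, then the HR-CTV
#' volume) and runs the trained network; with `d90Gy` supplied the absolute
#' hot-spot dose `ratio * D90` is returned as well.
#'
#' @param model a trained [NetworkModel-class].
#' @param decomp a [SubOrganDecomposition-class].
#' @param hrctvVolumeCc HR-CTV volume; default taken from the decomposition.
#' @param d90Gy optional planned D90 (Gy).
#' @return list with `ratio` and, when `d90Gy` is given, `d2cc_gy`.
#' @export
predictOarDose <- function(model, decomp, hrctvVolumeCc = NULL,
                           d90Gy = NULL) {
  stopifnot(is(model, "NetworkModel"), is(decomp, "SubOrganDecomposition"))
  if (!isTrained(model)) stop("model is untrained")
  if (is.null(hrctvVolumeCc)) hrctvVolumeCc <- decomp@hrctvVolumeCc
  nRings <- inputSize(model) - 1L
  v <- numeric(nRings)
  v[seq_len(min(decomp@nRings, nRings))] <-
    decomp@normalizedVolumes[seq_len(min(decomp@nRings, nRings))]
  ratio <- nnForward(model, c(v, hrctvVolumeCc))
  out <- list(ratio = unname(ratio))
  if (!is.null(d90Gy)) out$d2cc_gy <- unname(ratio * d90Gy)
  out
}
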