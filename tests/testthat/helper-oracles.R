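# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: distances by exhaustive pairwise search,
# statistics by direct summation of the defining formulas.

# Min Euclidean distance (mm) from each query point to the nearest point of
# a set, by exhaustive chunked pairwise search.
bruteMinDist <- function(query, set, chunk = 2000L) {
  s2 <- rowSums(set^2)
  out <- numeric(nrow(query))
  for (start in seq(1, nrow(query), by = chunk)) {
    i <- start:min(start + chunk - 1L, nrow(query))
    q <- query[i, , drop = FALSE]
    cross <- q %*% t(set)
    d2 <- outer(rowSums(q^2), s2, "+") - 2 * cross
    out[i] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Min Euclidean distance (mm) from every voxel center to the nearest target
# voxel center; 0 inside the target.
bruteDistanceMap <- function(grid, mask) {
  ax <- gridAxes(grid)
  cen <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ins <- cen[as.vector(mask), , drop = FALSE]
  d <- numeric(nrow(cen))
  out <- which(!as.vector(mask))
  d[out] <- bruteMinDist(cen[out, , drop = FALSE], ins)
  array(d, dim = gridShape(grid))
}

directPearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

directPairedT <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tt <- m / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), n - 1))
}

directMse <- function(a, b) sum((a - b)^2) / length(a)

directDelta <- function(a, b) {
  d <- abs(a - b)
  m <- sum(d) / length(d)
  list(mean = m, sd = sqrt(sum((d - m)^2) / (length(d) - 1)))
}

# A random small phantom (target blob + an OAR region) for geometry oracles.
randomTinyPhantom <- function(seed, maxShape = 32L) {
  set.seed(seed)
  shape <- sample(16:maxShape, 3, replace = TRUE)
  spacing <- stats::runif(3, 0.8, 2.5)
  g <- voxelGrid(shape, spacing)
  ax <- gridAxes(g)
  semi <- stats::runif(3, 4, 10) * spacing
  hr <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+") <= 1
  if (!any(hr)) hr[shape[1] %/% 2, shape[2] %/% 2, shape[3] %/% 2] <- TRUE
  # OAR: random box not fully overlapping the target
  lo <- sapply(shape, function(s) sample.int(max(s - 6, 1), 1))
  hi <- pmin(lo + sample(3:8, 3, replace = TRUE), shape)
  oar <- array(FALSE, shape)
  oar[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  oar <- oar & !hr
  list(grid = g, hrctv = hr, oar = oar)
}

# Compact phantom parameters for fast unit tests (small grid, small organs).
tinyPhantomParams <- function(seed = 1L, ...) {
  phantomParams(shape = c(64L, 72L, 64L), spacing = c(2, 2, 2),
                hrctvSemiAxesMm = c(12, 18),
                bladderSemiXMm = c(16, 20), bladderSemiYMm = c(10, 14),
                bladderSemiZMm = c(16, 20),
                rectumRadiusMm = c(7, 9), rectumLengthMm = c(40, 55),
                sigmoidRadiusMm = c(6, 8), sigmoidArcRadiusMm = c(22, 30),
                sigmoidArcSpanDeg = c(90, 120),
                gapMm = c(1, 10), seed = seed, ...)
}
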