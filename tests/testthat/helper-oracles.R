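# Independent brute-force oracles, deliberately written from first
# principles and kept free of any package internals.

# linear-interpolation percentile between order statistics: h = (n-1)p + 1
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  (1 - (h - lo)) * x[lo] + (h - lo) * x[hi]
}

# textbook pooled-variance two-sample t
oraclePooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# brute-force per-point radial cell assignment on a lattice
oracleCellIndex <- function(xMm, yMm) {
  r <- sqrt(xMm^2 + yMm^2)
  if (r >= 3) return(0L)
  th <- atan2(yMm, xMm) * 180 / pi
  quad <- (floor((th + 45) / 90)) %% 4      # 0 nasal 1 sup 2 temp 3 inf
  if (r < 0.5) 1L else if (r < 1.5) 2L + quad else 6L + quad
}

# flat map helpers -----------------------------------------------------

coarseLattice <- function() macularLattice(6, 0.1)

flatMap <- function(value, id = "S", lattice = coarseLattice(),
                    layer = "TR", eye = "OD") {
  n <- nPoints(lattice)
  thicknessMap(matrix(value, n, n), subjectId = id, layer = layer,
               eye = eye, lattice = lattice)
}

# stack of flat maps, one constant per subject
flatStack <- function(valuesPerSubject, label = "g",
                      lattice = coarseLattice(), layer = "TR") {
  maps <- lapply(seq_along(valuesPerSubject), function(i)
    flatMap(valuesPerSubject[i], id = paste0(label, i), lattice = lattice,
            layer = layer))
  buildCohort(maps, groupLabel = label)
}

# stack built from explicit per-subject value matrices
matrixStack <- function(matrices, label = "g", lattice = coarseLattice(),
                        layer = "TR") {
  maps <- lapply(seq_along(matrices), function(i)
    thicknessMap(matrices[[i]], subjectId = paste0(label, i), layer = layer,
                 eye = "OD", lattice = lattice))
  buildCohort(maps, groupLabel = label)
}

# a DeviationResult constructed directly from a deviation field and a
# significance mask (bypassing cohorts) for constructive measurement tests
plantedDeviation <- function(d, sig, lattice = coarseLattice(),
                             comparison = "planted") {
  n <- nPoints(lattice)
  ref <- new("ReferenceModel", lattice = lattice,
             mean = matrix(300, n, n), p025 = matrix(280, n, n),
             p975 = matrix(320, n, n), n = matrix(10L, n, n))
  dev <- new("DeviationResult", lattice = lattice, d = d,
             colorIndex = encodeColor(d, matrix(300, n, n),
                                      matrix(280, n, n), matrix(320, n, n)),
             p = matrix(ifelse(sig, 0.001, 0.5), n, n),
             sig = sig, comparison = comparison)
  dev
}
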