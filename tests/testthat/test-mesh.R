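test_that("icosphere sizes follow N = 10 l^2 + 2 and sphere topology", {
  for (l in c(1, 2, 4)) {
    s <- buildIcosphere(l)
    n <- 10 * l^2 + 2
    expect_equal(nVertices(s), n)
    expect_equal(nTriangles(s), 2 * n - 4)
    expect_equal(nBonds(s), 3 * n - 6)
    expect_equal(eulerCharacteristic(s), 2)
    expect_equal(nrow(bondTable(s)), 3 * n - 6)
  }
  expect_equal(nVertices(buildIcosphere(24)), 5762)
})

test_that("icosphere winding is globally consistent and outward", {
  s <- buildIcosphere(3)
  # validity (checked on construction) covers winding; verify outwardness:
  # all face normals point away from the origin on a convex sphere
  v <- vertexPositions(s)
  f <- triangleIndices(s)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]
    b <- v[f[i, 2], ]
    ce <- v[f[i, 3], ]
    n <- c(
      (b - a)[2] * (ce - a)[3] - (b - a)[3] * (ce - a)[2],
      (b - a)[3] * (ce - a)[1] - (b - a)[1] * (ce - a)[3],
      (b - a)[1] * (ce - a)[2] - (b - a)[2] * (ce - a)[1]
    )
    expect_gt(sum(n * (a + b + ce)), 0)
  }
})

test_that("invalid triangulations are rejected", {
  s <- buildIcosphere(1)
  f <- triangleIndices(s)
  f[1, ] <- f[1, c(1, 3, 2)] # break winding consistency
  expect_error(
    triSurface(vertexPositions(s), f),
    "winding|directed"
  )
  expect_error(
    triSurface(vertexPositions(s), triangleIndices(s)[-1, , drop = FALSE]),
    "open|closed"
  )
})

test_that("random sigma assignment hits the rounded Lo count exactly", {
  set.seed(101)
  s <- buildIcosphere(4) # NT = 320
  expect_equal(nLoTriangles(assignSigmaRandom(s, 0.7)), 224)
  s20 <- buildIcosphere(1) # NT = 20
  expect_equal(nLoTriangles(assignSigmaRandom(s20, 0.5)), 10)
  all1 <- assignSigmaRandom(s20, 1)
  expect_equal(nLoTriangles(all1), 20)
  p <- modelParams(1, 1, 5, 1, "model2", 1)
  expect_equal(totalEnergy(all1, p)[["S0"]], 0)
  expect_error(assignSigmaRandom(s20, 1.3), "phi0")
})

test_that("every tetrahedron flip is rejected, icosahedron flips are legal", {
  tet <- regularTetrahedron()
  for (b in seq_len(nBonds(tet))) {
    expect_null(flipCandidate(tet, b, coin = 0.5))
  }
  ico <- buildIcosphere(1) # all vertices degree 5
  pr <- flipCandidate(ico, 1, coin = 0.5)
  expect_s4_class(pr, "FlipProposal")
  s2 <- applyFlip(ico, pr)
  deg <- tabulate(triangleIndices(s2), nbins = 12)
  # face incidences = coordination number; old endpoints drop to 4,
  # new-diagonal endpoints rise to 6
  expect_equal(sort(deg[c(pr@u, pr@v)]), c(4, 4))
  expect_equal(sort(deg[c(pr@p, pr@q)]), c(6, 6))
  expect_equal(nBonds(s2), 30)
  expect_equal(nTriangles(s2), 20)
})

test_that("flip sigma rule conserves the Lo count in all cases", {
  set.seed(7)
  s <- assignSigmaRandom(buildIcosphere(2), 0.5)
  bt <- bondTable(s)
  sameSeen <- FALSE
  diffSeen <- FALSE
  for (b in seq_len(nrow(bt))) {
    pr <- flipCandidate(s, b, coin = runif(1))
    if (is.null(pr)) next
    if (pr@oldSigma[1] == pr@oldSigma[2]) {
      sameSeen <- TRUE
      expect_equal(pr@newSigma, pr@oldSigma) # same labels stay the same
    } else {
      diffSeen <- TRUE
      expect_setequal(pr@newSigma, c(-1L, 1L)) # different stay different
    }
    expect_equal(nLoTriangles(applyFlip(s, pr)), nLoTriangles(s))
  }
  expect_true(sameSeen && diffSeen)
})

test_that("the random side choice of boundary flips follows the coin", {
  set.seed(8)
  s <- buildIcosphere(2)
  bt <- bondTable(s)
  b <- which(s@sigma[bt[, 3]] == s@sigma[bt[, 4]])[1]
  s@sigma[bt[b, 3]] <- -1L # make bond b a boundary bond
  lo <- flipCandidate(s, b, coin = 0.1)@newSigma
  hi <- flipCandidate(s, b, coin = 0.9)@newSigma
  expect_equal(lo, rev(hi)) # the two coin outcomes are label swaps
})

test_that("apply followed by revert is the identity", {
  set.seed(21)
  s <- randomSurface(2, 0.5)
  for (rep in 1:50) {
    b <- sample(nBonds(s), 1)
    pr <- flipCandidate(s, b)
    if (is.null(pr)) next
    s3 <- revertFlip(applyFlip(s, pr), pr)
    expect_identical(triangleIndices(s3), triangleIndices(s))
    expect_identical(sigmaLabels(s3), sigmaLabels(s))
    expect_identical(bondTable(s3), bondTable(s))
  }
})

test_that("random flip storms preserve every topological invariant", {
  set.seed(31)
  s <- assignSigmaRandom(buildIcosphere(3), 0.4)
  nto <- nLoTriangles(s)
  st <- flipStorm(s, 20000, checkEvery = 500) # errors on any violation
  expect_gt(st$applied, 0)
  out <- st$surface
  expect_equal(nVertices(out), nVertices(s))
  expect_equal(nTriangles(out), nTriangles(s))
  expect_equal(nLoTriangles(out), nto)
  expect_equal(eulerCharacteristic(out), 2)
  expect_true(validObject(out))
  deg <- tabulate(triangleIndices(out), nbins = nVertices(out))
  expect_true(all(deg >= 3))
})
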