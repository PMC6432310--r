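test_that("rho takes the value c on Lo and 1 on Ld triangles", {
  expect_equal(rhoFactor(1, 5), 5)
  expect_equal(rhoFactor(-1, 5), 1)
  expect_equal(rhoFactor(-1, 123.4), 1)
  expect_equal(rhoFactor(1, 1), 1) # c = 1 erases the phase distinction
  expect_error(rhoFactor(0, 5))
})

test_that("bond coefficients reproduce the closed forms for both c values", {
  for (c in c(5, 8.37)) {
    expect_equal(bondCoefficient(1, 1, c), (c + 1 / c) / 2)
    expect_equal(bondCoefficient(1, -1, c), (2 + c + 1 / c) / 4)
    expect_equal(bondCoefficient(-1, -1, c), 1)
  }
  # printed reference values: 2.6 / 1.8 / 1 at c = 5, 4.24 / 2.62 / 1 at 8.37
  expect_equal(round(bondCoefficient(1, 1, 5), 1), 2.6)
  expect_equal(round(bondCoefficient(1, -1, 5), 1), 1.8)
  expect_equal(round(bondCoefficient(1, 1, 8.37), 2), 4.24)
  expect_equal(round(bondCoefficient(1, -1, 8.37), 2), 2.62)
})

test_that("coefficients are symmetric under label swap and c <-> 1/c", {
  for (si in c(-1, 1)) {
    for (sj in c(-1, 1)) {
      expect_equal(
        bondCoefficient(si, sj, 3.7),
        bondCoefficient(sj, si, 3.7)
      )
      expect_equal(
        bondCoefficient(si, sj, 3.7),
        bondCoefficient(si, sj, 1 / 3.7)
      )
    }
  }
})

test_that("model 1 has unit tension but the model 2 bending coefficients", {
  expect_equal(bondCoefficient(1, 1, 8.37, "model1", "tension"), 1)
  expect_equal(bondCoefficient(1, -1, 8.37, "model1", "tension"), 1)
  expect_equal(
    bondCoefficient(1, 1, 8.37, "model1", "bending"),
    bondCoefficient(1, 1, 8.37, "model2", "bending")
  )
})

test_that("total energy matches the independent R oracle on random surfaces", {
  set.seed(11)
  for (variant in c("model1", "model2")) {
    p <- modelParams(0.3, 7, 5, 0.5, variant, 2)
    s <- randomSurface(2, 0.5)
    expect_equal(totalEnergy(s, p), energyOracle(s, p), tolerance = 1e-12)
  }
})

test_that("regular tetrahedron bending energy is 6 (1 + 1/3) = 8", {
  # adjacent face normals of a regular tetrahedron have dot product -1/3
  tet <- regularTetrahedron()
  p <- modelParams(0, 1, 1, 1, "model2", 1) # unit coefficients at c = 1
  expect_equal(totalEnergy(tet, p)[["S2"]], 8, tolerance = 1e-12)
})

test_that("S0 is twice the boundary-bond count, 6 for one minority triangle", {
  s <- buildIcosphere(1)
  s@sigma[5] <- -1L # one Ld triangle: 3 boundary bonds
  p <- modelParams(1, 1, 5, 0.95, "model2", 1)
  e <- totalEnergy(s, p)
  expect_equal(e[["S0"]], 6)
  expect_equal(e[["S0"]] / 2, domainComponents(s)$boundaryBonds)
  # uniform phase: no boundary
  expect_equal(totalEnergy(buildIcosphere(1), p)[["S0"]], 0)
})

test_that("S0/2 equals the boundary-bond count on random configurations", {
  set.seed(12)
  p <- modelParams(1, 1, 5, 0.5, "model2", 2)
  for (rep in 1:5) {
    s <- randomSurface(2, runif(1))
    expect_equal(
      totalEnergy(s, p)[["S0"]] / 2,
      domainComponents(s)$boundaryBonds
    )
  }
})

test_that("scaling r -> alpha r scales S1 by alpha^2, leaves S0 and S2 fixed", {
  set.seed(13)
  s <- randomSurface(2, 0.6)
  p <- modelParams(0.5, 10, 8.37, 0.6, "model2", 2)
  e1 <- totalEnergy(s, p)
  s2 <- s
  s2@vertices <- 1.7 * s@vertices
  e2 <- totalEnergy(s2, p)
  expect_equal(e2[["S1"]], 1.7^2 * e1[["S1"]], tolerance = 1e-12)
  expect_equal(e2[["S0"]], e1[["S0"]])
  expect_equal(e2[["S2"]], e1[["S2"]], tolerance = 1e-12)
})

test_that("with c = 1 the two model variants coincide on any surface", {
  set.seed(14)
  for (rep in 1:10) {
    s <- randomSurface(2, runif(1))
    p1 <- modelParams(0.4, 8, 1, 0.5, "model1", 2)
    p2 <- modelParams(0.4, 8, 1, 0.5, "model2", 2)
    expect_equal(totalEnergy(s, p1), totalEnergy(s, p2), tolerance = 1e-14)
  }
})

test_that("degenerate triangles are diagnosed", {
  s <- buildIcosphere(1)
  s@vertices[1, ] <- s@vertices[2, ] # collapses the triangles sharing 1-2
  p <- modelParams(1, 1, 5, 1, "model2", 1)
  expect_error(totalEnergy(s, p), "degenerate")
})

test_that("vertex-move delta matches full recompute; identity move is zero", {
  set.seed(15)
  s <- randomSurface(2, 0.5)
  p <- modelParams(0.5, 10, 8.37, 0.5, "model2", 2)
  expect_equal(deltaEnergyVertexMove(s, p, 3, s@vertices[3, ]), 0)
  for (rep in 1:50) {
    vid <- sample(nVertices(s), 1)
    np <- s@vertices[vid, ] + runif(3, -0.3, 0.3)
    dS <- deltaEnergyVertexMove(s, p, vid, np)
    s2 <- s
    s2@vertices[vid, ] <- np
    full <- totalEnergy(s2, p)[["total"]] - totalEnergy(s, p)[["total"]]
    expect_equal(dS, full, tolerance = 1e-9)
  }
})

test_that("flip delta matches full recompute and reversal sums to zero", {
  set.seed(16)
  s <- randomSurface(2, 0.5)
  p <- modelParams(0.5, 10, 8.37, 0.5, "model2", 2)
  for (rep in 1:50) {
    b <- sample(nBonds(s), 1)
    pr <- flipCandidate(s, b)
    if (is.null(pr)) next
    dS <- deltaEnergyFlip(s, p, pr)
    s2 <- applyFlip(s, pr)
    full <- totalEnergy(s2, p)[["total"]] - totalEnergy(s, p)[["total"]]
    expect_equal(dS, full, tolerance = 1e-9)
    # energy of apply + revert accumulates to zero
    back <- totalEnergy(revertFlip(s2, pr), p)[["total"]] -
      totalEnergy(s, p)[["total"]]
    expect_equal(back, 0, tolerance = 1e-9)
  }
})

test_that("a flip in a flat patch has no bending contribution", {
  # planar surface piece: pyramid flattened onto the plane z = 0 is not a
  # closed surface, so build a doubled square (two coincident-boundary
  # pyramids with apexes at +z and -z) and flip the flat-bottom diagonal:
  # here all relevant normals around the diagonal of the flat quad are
  # parallel only in the z->0 limit, so instead check the S2-free limit
  # via coefficients: a flip between coplanar triangles changes S2 by the
  # difference of kappa_ij terms with n_i . n_j = 1, which vanishes.
  set.seed(17)
  s <- buildIcosphere(2)
  bt <- bondTable(s)
  b <- 1
  # flatten the quadrilateral patch of bond b into its best-fit plane
  pr <- flipCandidate(s, b, coin = 0.5)
  quad <- c(pr@u, pr@v, pr@p, pr@q)
  x <- s@vertices[quad, ]
  ctr <- colMeans(x)
  dec <- svd(sweep(x, 2, ctr))
  x2 <- sweep(x, 2, ctr) %*% dec$v
  x2[, 3] <- 0 # project onto the plane
  s@vertices[quad, ] <- sweep(x2 %*% t(dec$v), 2, ctr, "+")
  p0 <- modelParams(0, 5, 1, 1, "model2", 2) # c = 1: equal coefficients
  pr <- flipCandidate(s, b, coin = 0.5)
  dS <- deltaEnergyFlip(s, p0, pr)
  s2 <- applyFlip(s, pr)
  dS2 <- totalEnergy(s2, p0)[["S2"]] - totalEnergy(s, p0)[["S2"]]
  expect_equal(dS2, 0, tolerance = 1e-9)
  # and the delta then reduces to the pure tension difference
  dS1 <- totalEnergy(s2, p0)[["S1"]] - totalEnergy(s, p0)[["S1"]]
  expect_equal(dS, dS1, tolerance = 1e-9)
})
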