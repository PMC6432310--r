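test_that("semi-axes of a sphere are three equal diameters", {
  s <- buildIcosphere(3, radius = 2)
  d <- semiAxes(s)
  expect_equal(unname(d), rep(4, 3), tolerance = 0.02)
  expect_true(d[["D1"]] >= d[["D2"]] && d[["D2"]] >= d[["D3"]])
})

test_that("prolate and oblate point clouds are told apart by D2", {
  s <- buildIcosphere(3)
  prolate <- s@vertices %*% diag(c(3, 1, 1))
  dp <- semiAxes(prolate)
  expect_gt(dp[["D1"]], 2 * dp[["D2"]])
  expect_equal(dp[["D2"]], dp[["D3"]], tolerance = 0.02)
  oblate <- s@vertices %*% diag(c(3, 3, 1))
  do <- semiAxes(oblate)
  expect_equal(do[["D1"]], do[["D2"]], tolerance = 0.02)
  expect_gt(do[["D2"]], 2 * do[["D3"]])
})

test_that("semi-axes are invariant under rigid rotation and translation", {
  set.seed(61)
  s <- randomSurface(2, 0.5)
  d0 <- semiAxes(s)
  theta <- 0.83
  rot <- matrix(c(
    cos(theta), -sin(theta), 0,
    sin(theta), cos(theta), 0,
    0, 0, 1
  ), 3, 3, byrow = TRUE) %*% matrix(c(
    1, 0, 0,
    0, cos(0.31), -sin(0.31),
    0, sin(0.31), cos(0.31)
  ), 3, 3, byrow = TRUE)
  moved <- sweep(s@vertices %*% rot, 2, c(5, -2, 11), "+")
  expect_equal(semiAxes(moved), d0, tolerance = 1e-9)
})

test_that("domain components and boundary counts are exact on fixtures", {
  s <- buildIcosphere(1)
  comp <- domainComponents(s)
  expect_equal(length(comp$lo), 1)
  expect_equal(length(comp$ld), 0)
  expect_equal(comp$boundaryBonds, 0)
  s@sigma[7] <- -1L
  comp <- domainComponents(s)
  expect_equal(comp$lo, 19)
  expect_equal(comp$ld, 1)
  expect_equal(comp$boundaryBonds, 3)
})

test_that("component sizes per phase sum to the phase triangle counts", {
  set.seed(62)
  for (rep in 1:5) {
    s <- assignSigmaRandom(buildIcosphere(3), runif(1, 0.2, 0.8))
    comp <- domainComponents(s)
    expect_equal(sum(comp$lo), nLoTriangles(s))
    expect_equal(sum(comp$ld), nLdTriangles(s))
  }
})

test_that("random labels give boundary fraction ~ 2 phi (1 - phi)", {
  set.seed(63)
  phi <- 0.5
  fracs <- replicate(20, {
    s <- assignSigmaRandom(buildIcosphere(8), phi)
    domainComponents(s)$boundaryFraction
  })
  expect_equal(mean(fracs), 2 * phi * (1 - phi), tolerance = 0.02)
})

test_that("morphology labels follow the component-count contract", {
  lab <- function(lo, ld, boundaryFraction = 0.1) {
    classifyMorphology(list(
      lo = lo, ld = ld, boundaryBonds = 10,
      boundaryFraction = boundaryFraction
    ))$label
  }
  expect_equal(lab(c(100, 80), 200), "two_circular")
  expect_equal(lab(150, c(100, 90)), "stripe")
  expect_equal(lab(180, 140), "one_circular")
  expect_equal(lab(c(60, 55, 50, 45), 300), "multi_circular_raft")
  expect_equal(lab(rep(2, 90), rep(2, 60)), "random")
})

test_that("a nearly pinched-off domain raises the budding flag", {
  # sphere with a bud: the polar cap is remapped onto a ball connected to
  # the body through a pinched neck, and labelled Lo
  s <- buildIcosphere(6, radius = 1)
  v0 <- s@vertices
  z <- v0[, 3]
  v <- v0
  band <- z > 0.35 & z < 0.6
  v[band, 1:2] <- v[band, 1:2] * 0.1 # the neck
  top <- z >= 0.6
  u <- cbind(v0[top, 1], v0[top, 2], v0[top, 3] - 0.55)
  u <- u / sqrt(rowSums(u^2))
  v[top, ] <- cbind(0.7 * u[, 1], 0.7 * u[, 2], 1.25 + 0.7 * u[, 3])
  s@vertices <- v
  loFaces <- apply(s@triangles, 1, function(tr) all(z[tr] > 0.45))
  s@sigma <- ifelse(loFaces, 1L, -1L)
  out <- classifyMorphology(domainComponents(s), surface = s)
  expect_equal(out$label, "budding_candidate")
  expect_gt(length(out$buddingComponents), 0)
  # the same labels on the un-deformed sphere are a plain circular domain
  s0 <- buildIcosphere(6, radius = 1)
  s0@sigma <- ifelse(loFaces, 1L, -1L)
  expect_equal(
    classifyMorphology(domainComponents(s0), surface = s0)$label,
    "one_circular"
  )
})

test_that("mean triangle areas: closed form on the icosahedron, NA cases", {
  s <- buildIcosphere(1)
  edge <- sqrt(sum((s@vertices[bondTable(s)[1, 1], ] -
    s@vertices[bondTable(s)[1, 2], ])^2))
  out <- meanTriangleAreas(s)
  expect_equal(out$ao, sqrt(3) / 4 * edge^2, tolerance = 1e-12)
  expect_true(is.na(out$ad))
  expect_equal(out$areaFractionLo, 1)
  s@sigma <- rep(-1L, 20)
  expect_equal(meanTriangleAreas(s)$areaFractionLo, 0)
})

test_that("model 1 keeps ao ~ ad while model 2 shrinks Lo triangles", {
  sch <- runSchedule(5000, 15000, measInterval = 250)
  r1 <- runSimulation(
    modelParams(0.2, 7, 5, 0.5, "model1", 4), sch,
    seed = 64
  )
  tr1 <- r1$trajectory
  expect_equal(mean(tr1$area_lo) / mean(tr1$area_ld), 1, tolerance = 0.15)
  # equal-tension symmetry: area fraction tracks phi0 in model 1
  expect_equal(mean(tr1$area_fraction_lo), 0.5, tolerance = 0.15)
  # the instantaneous per-phase means come from meanTriangleAreas
  a1 <- meanTriangleAreas(r1$surface)
  expect_equal(
    a1$areaFractionLo,
    tail(tr1$area_fraction_lo, 1),
    tolerance = 1e-9
  )
  r2 <- runSimulation(
    modelParams(0.2, 7, 8.37, 0.5, "model2", 4), sch,
    seed = 64
  )
  tr2 <- r2$trajectory
  expect_lt(mean(tr2$area_lo), 0.8 * mean(tr2$area_ld)) # Lo shrinks
  expect_lt(mean(tr2$area_fraction_lo), 0.4) # well below phi0
})
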