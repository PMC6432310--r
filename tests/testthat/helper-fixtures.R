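# Small fixture surfaces built in code.

# Regular tetrahedron centred at the origin (edge 2*sqrt(2)), outward winding.
regularTetrahedron <- function(sigma = NULL) {
  v <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  )
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  for (i in seq_len(4)) {
    a <- v[f[i, 1], ]
    b <- v[f[i, 2], ]
    ce <- v[f[i, 3], ]
    n <- c(
      (b - a)[2] * (ce - a)[3] - (b - a)[3] * (ce - a)[2],
      (b - a)[3] * (ce - a)[1] - (b - a)[1] * (ce - a)[3],
      (b - a)[1] * (ce - a)[2] - (b - a)[2] * (ce - a)[1]
    )
    if (sum(n * (a + b + ce)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  triSurface(v, f, sigma)
}

# Icosphere with jittered vertex positions and random labels: a generic
# non-symmetric valid surface.
randomSurface <- function(subdivision = 2, phi0 = 0.5, jitter = 0.05) {
  s <- buildIcosphere(subdivision)
  s@vertices <- s@vertices +
    matrix(runif(3 * nVertices(s), -jitter, jitter), ncol = 3)
  assignSigmaRandom(s, phi0)
}

# Independent (vectorized R) recomputation of the Hamiltonian, used as the
# oracle for the compiled energy path.
energyOracle <- function(surface, params) {
  v <- surface@vertices
  f <- surface@triangles
  sig <- surface@sigma
  bt <- bondTable(surface)
  normals <- t(apply(f, 1, function(tr) {
    a <- v[tr[1], ]
    n <- c(
      (v[tr[2], ] - a)[2] * (v[tr[3], ] - a)[3] -
        (v[tr[2], ] - a)[3] * (v[tr[3], ] - a)[2],
      (v[tr[2], ] - a)[3] * (v[tr[3], ] - a)[1] -
        (v[tr[2], ] - a)[1] * (v[tr[3], ] - a)[3],
      (v[tr[2], ] - a)[1] * (v[tr[3], ] - a)[2] -
        (v[tr[2], ] - a)[2] * (v[tr[3], ] - a)[1]
    )
    n / sqrt(sum(n^2))
  }))
  s1f <- sig[bt[, 3]]
  s2f <- sig[bt[, 4]]
  len2 <- rowSums((v[bt[, 1], ] - v[bt[, 2], ])^2)
  ndot <- rowSums(normals[bt[, 3], , drop = FALSE] *
    normals[bt[, 4], , drop = FALSE])
  s0 <- sum(1 - s1f * s2f)
  s1 <- sum(bondCoefficient(s1f, s2f, params@c, params@variant, "tension") *
    len2)
  s2 <- sum(bondCoefficient(s1f, s2f, params@c, params@variant, "bending") *
    (1 - ndot))
  c(
    S0 = s0, S1 = s1, S2 = s2,
    total = params@lambda * s0 + s1 + params@kappa * s2
  )
}
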