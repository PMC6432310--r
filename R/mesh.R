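#' Construct a TriSurface
#'
#' Builds and validates a closed triangulated surface from vertex
#' coordinates, triangle indices and per-triangle phase labels.
#'
#' @param vertices numeric N x 3 matrix of coordinates.
#' @param triangles NT x 3 matrix of 1-based vertex indices with consistent
#'   outward winding.
#' @param sigma integer vector of NT phase labels in \{+1, -1\}; defaults
#'   to all +1 (uniform Lo).
#' @return a validated [TriSurface-class].
#' @examples
#' ico <- buildIcosphere(1)
#' s <- triSurface(vertexPositions(ico), triangleIndices(ico))
#' @export
triSurface <- function(vertices, triangles, sigma = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (is.null(sigma)) sigma <- rep(1L, nrow(triangles))
  obj <- new("TriSurface",
    vertices = vertices, triangles = triangles,
    sigma = as.integer(sigma)
  )
  validObject(obj)
  obj
}

#' Build a subdivided icosahedral sphere
#'
#' Subdivides each edge of a regular icosahedron into \code{subdivision}
#' segments, triangulates each face with the matching barycentric grid,
#' projects all vertices onto the unit sphere and rescales.  The result
#' has \eqn{N = 10\ell^2 + 2} vertices, \eqn{N_T = 2N - 4} triangles and
#' \eqn{N_B = 3N - 6} bonds; subdivision 24 gives the production lattice
#' size N = 5762.  All triangles start in the Lo phase (+1); use
#' [assignSigmaRandom()] to set a random mixture at a fixed Lo fraction.
#'
#' The partition function of the model is scale invariant, so the starting
#' radius is physically immaterial; by default it is chosen so that the
#' mean bond length is \code{meanEdge}, close to the equilibrium bond
#' length implied by the identity \eqn{\langle S_1 \rangle / N = 3/2} at
#' unit surface tension.
#'
#' @param subdivision positive integer subdivision frequency \eqn{\ell}.
#' @param radius sphere radius; overrides \code{meanEdge} when given.
#' @param meanEdge target mean bond length used to pick the radius.
#' @return a [TriSurface-class].
#' @examples
#' ico <- buildIcosphere(2)
#' nVertices(ico) # 42
#' @export
buildIcosphere <- function(subdivision, radius = NULL, meanEdge = 0.7) {
  stopifnot(length(subdivision) == 1, subdivision >= 1)
  l <- as.integer(subdivision)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # enforce outward winding on the seed
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]
    b <- v[f[i, 2], ]
    ce <- v[f[i, 3], ]
    n <- crossProduct(b - a, ce - a)
    if (sum(n * (a + b + ce)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }

  if (l == 1) {
    verts <- v
    faces <- f
  } else {
    # global ids: 12 corners, then l-1 interior points per icosahedral edge
    # (ordered from the smaller corner id), then interior points per face
    em <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    em <- t(apply(em, 1, sort))
    em <- unique(em)
    edgeKey <- paste(em[, 1], em[, 2])
    edgeBase <- 12L + (seq_len(nrow(em)) - 1L) * (l - 1L)
    names(edgeBase) <- edgeKey

    nInterior <- (l - 1) * (l - 2) / 2
    faceBase <- 12L + nrow(em) * (l - 1L) +
      (seq_len(nrow(f)) - 1L) * as.integer(nInterior)

    nTotal <- 12L + nrow(em) * (l - 1L) + nrow(f) * as.integer(nInterior)
    verts <- matrix(NA_real_, nTotal, 3)
    verts[1:12, ] <- v

    # id of barycentric grid point (i, j) on face fc: P = a + i*(b-a)/l + j*(c-a)/l
    gridId <- function(fc, i, j) {
      a <- f[fc, 1]
      b <- f[fc, 2]
      ce <- f[fc, 3]
      k <- l - i - j
      if (k == l) {
        return(a)
      }
      if (i == l) {
        return(b)
      }
      if (j == l) {
        return(ce)
      }
      if (j == 0) { # edge a-b, parameter i
        return(edgePointId(a, b, i))
      }
      if (i == 0) { # edge a-c, parameter j
        return(edgePointId(a, ce, j))
      }
      if (k == 0) { # edge b-c, parameter j (from b toward c)
        return(edgePointId(b, ce, j))
      }
      faceBase[fc] + ((i + j - 2) * (i + j - 1)) %/% 2 + j
    }
    edgePointId <- function(a, b, t) {
      key <- paste(min(a, b), max(a, b))
      tt <- if (a < b) t else l - t
      edgeBase[[key]] + tt
    }

    faces <- matrix(NA_integer_, nrow(f) * l^2, 3)
    fr <- 0L
    for (fc in seq_len(nrow(f))) {
      a <- v[f[fc, 1], ]
      b <- v[f[fc, 2], ]
      ce <- v[f[fc, 3], ]
      ids <- matrix(NA_integer_, l + 1, l + 1)
      for (i in 0:l) {
        for (j in 0:(l - i)) {
          id <- gridId(fc, i, j)
          ids[i + 1, j + 1] <- id
          if (is.na(verts[id, 1])) {
            verts[id, ] <- a + i * (b - a) / l + j * (ce - a) / l
          }
        }
      }
      for (i in 0:(l - 1)) {
        for (j in 0:(l - 1 - i)) {
          fr <- fr + 1L
          faces[fr, ] <- c(ids[i + 1, j + 1], ids[i + 2, j + 1], ids[i + 1, j + 2])
          if (i + j <= l - 2) {
            fr <- fr + 1L
            faces[fr, ] <- c(ids[i + 2, j + 1], ids[i + 2, j + 2], ids[i + 1, j + 2])
          }
        }
      }
    }
    verts <- verts / sqrt(rowSums(verts^2))
  }

  if (is.null(radius)) {
    # scale so the mean bond length equals meanEdge
    b <- cpp_bonds(verts, storage.mode2int(faces), rep(1L, nrow(faces)))
    el <- sqrt(rowSums((verts[b[, 1], ] - verts[b[, 2], ])^2))
    radius <- meanEdge / mean(el)
  }
  triSurface(verts * radius, faces)
}

crossProduct <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Randomly assign phase labels at a fixed Lo fraction
#'
#' Labels exactly \code{round(phi0 * NT)} uniformly chosen triangles as Lo
#' (+1) and the rest as Ld (-1).  This is the random two-phase coexistence
#' configuration used as the initial state of every simulation; the Lo
#' count is subsequently conserved by the bond-flip update rule.
#'
#' @param surface a [TriSurface-class].
#' @param phi0 Lo fraction in [0, 1].
#' @return the surface with new \code{sigma}.
#' @examples
#' set.seed(1)
#' s <- assignSigmaRandom(buildIcosphere(2), 0.5)
#' sum(sigmaLabels(s) > 0) # 40 of 80
#' @export
assignSigmaRandom <- function(surface, phi0) {
  stopifnot(is(surface, "TriSurface"))
  if (phi0 < 0 || phi0 > 1) stop("phi0 must lie in [0, 1]")
  nt <- nrow(surface@triangles)
  nto <- round(phi0 * nt)
  sig <- rep(-1L, nt)
  sig[sample.int(nt, nto)] <- 1L
  surface@sigma <- sig
  surface
}

# ------------------------------------------------------------------ accessors

#' @rdname triSurface
#' @param x a \code{TriSurface}.
#' @export
nVertices <- function(x) nrow(x@vertices)

#' @rdname triSurface
#' @export
nTriangles <- function(x) nrow(x@triangles)

#' @rdname triSurface
#' @export
nBonds <- function(x) 3L * nrow(x@vertices) - 6L

#' @rdname triSurface
#' @export
nLoTriangles <- function(x) sum(x@sigma > 0)

#' @rdname triSurface
#' @export
nLdTriangles <- function(x) sum(x@sigma < 0)

#' @rdname triSurface
#' @export
vertexPositions <- function(x) x@vertices

#' @rdname triSurface
#' @export
triangleIndices <- function(x) x@triangles

#' @rdname triSurface
#' @export
sigmaLabels <- function(x) x@sigma

#' @rdname triSurface
#' @export
eulerCharacteristic <- function(x) {
  nVertices(x) - nBonds(x) + nTriangles(x)
}

#' Bond (edge) table of a surface
#'
#' Returns the canonical bond table: one row per undirected bond with its
#' two endpoints and the two incident triangles (\code{face1} contains the
#' directed edge u -> v, \code{face2} the reverse).  The ordering is a
#' pure function of the triangulation, so bond indices are stable across
#' calls and usable with [flipCandidate()].
#'
#' @param x a [TriSurface-class].
#' @return integer NB x 4 matrix with columns u, v, face1, face2.
#' @export
bondTable <- function(x) {
  cpp_bonds(x@vertices, x@triangles, x@sigma)
}

# ---------------------------------------------------------------- bond flips

#' Propose, apply and revert bond flips
#'
#' \code{flipCandidate} proposes replacing the shared diagonal of the two
#' triangles incident to \code{bond} with the opposite diagonal.  The flip
#' is rejected (\code{NULL}) when it is topologically illegal: the new
#' diagonal already exists as a bond, an endpoint of the old diagonal
#' would drop below coordination 3, or the two triangles share more than
#' one bond (as on the tetrahedron).  Phase labels follow the conserving
#' reassignment rule: two equal labels are kept; two different labels are
#' redistributed at random over the two new triangles, so the Lo count
#' never changes.
#'
#' \code{applyFlip} applies a proposal and returns the new surface;
#' \code{revertFlip} undoes it, restoring the triangulation and labels
#' exactly (triangle rows may be cyclically rotated, which leaves both
#' topology and winding unchanged).
#'
#' @param surface a [TriSurface-class].
#' @param bond canonical bond index (row of [bondTable()]).
#' @param coin optional uniform [0,1) draw deciding the random label side;
#'   drawn from the session RNG when missing.
#' @param proposal a [FlipProposal-class] returned by \code{flipCandidate}.
#' @return \code{flipCandidate}: a [FlipProposal-class] or \code{NULL};
#'   \code{applyFlip} / \code{revertFlip}: the updated surface.
#' @examples
#' set.seed(1)
#' ico <- buildIcosphere(1)
#' pr <- flipCandidate(ico, 1)
#' s2 <- applyFlip(ico, pr)
#' s3 <- revertFlip(s2, pr)
#' identical(bondTable(s3), bondTable(ico)) # TRUE
#' @export
flipCandidate <- function(surface, bond, coin = NULL) {
  stopifnot(is(surface, "TriSurface"))
  if (is.null(coin)) coin <- runif(1)
  res <- cpp_flip_candidate(
    surface@vertices, surface@triangles, surface@sigma,
    as.integer(bond), coin
  )
  if (!res$legal) {
    return(NULL)
  }
  new("FlipProposal",
    bond = as.integer(res$bond),
    u = as.integer(res$u), v = as.integer(res$v),
    p = as.integer(res$p), q = as.integer(res$q),
    face1 = as.integer(res$face1), face2 = as.integer(res$face2),
    oldFace1 = surface@triangles[res$face1, ],
    oldFace2 = surface@triangles[res$face2, ],
    oldSigma = as.integer(res$oldSigma),
    newSigma = as.integer(res$newSigma)
  )
}

#' @rdname flipCandidate
#' @export
applyFlip <- function(surface, proposal) {
  stopifnot(is(surface, "TriSurface"), is(proposal, "FlipProposal"))
  res <- cpp_apply_flip(
    surface@vertices, surface@triangles, surface@sigma,
    proposal@bond, proposal@newSigma
  )
  surface@triangles <- res$triangles
  surface@sigma <- res$sigma
  surface
}

#' @rdname flipCandidate
#' @export
revertFlip <- function(surface, proposal) {
  stopifnot(is(surface, "TriSurface"), is(proposal, "FlipProposal"))
  f1 <- proposal@face1
  f2 <- proposal@face2
  # the flipped surface must hold the new triangles {u,q,p} and {v,p,q}
  if (!setequal(
    surface@triangles[f1, ], c(proposal@u, proposal@q, proposal@p)
  ) || !setequal(
    surface@triangles[f2, ], c(proposal@v, proposal@p, proposal@q)
  )) {
    stop("proposal is inconsistent with this surface")
  }
  # a flip only touches these two triangle rows; restoring the stored
  # originals (and labels) is the exact inverse
  surface@triangles[f1, ] <- proposal@oldFace1
  surface@triangles[f2, ] <- proposal@oldFace2
  surface@sigma[f1] <- proposal@oldSigma[1]
  surface@sigma[f2] <- proposal@oldSigma[2]
  validObject(surface)
  surface
}

#' Random-flip topology stress test
#'
#' Attempts \code{nAttempts} uniformly random bond flips, applying every
#' topologically legal one (no Metropolis weighting), and verifies the
#' full set of surface invariants every \code{checkEvery} attempts:
#' sphere-topology counts, Euler characteristic, winding consistency,
#' manifoldness, vertex coordination and Lo-count conservation.  Errors on
#' the first violation.
#'
#' @param surface a [TriSurface-class].
#' @param nAttempts number of flip attempts.
#' @param checkEvery attempts between invariant checks.
#' @return list with the final surface and counters.
#' @export
flipStorm <- function(surface, nAttempts, checkEvery = 1000L) {
  stopifnot(is(surface, "TriSurface"))
  res <- cpp_flip_storm(
    surface@vertices, surface@triangles, surface@sigma,
    as.integer(nAttempts), as.integer(checkEvery)
  )
  surface@triangles <- res$triangles
  surface@sigma <- res$sigma
  list(
    surface = surface, attempted = res$attempted,
    applied = res$applied, checks = res$checks
  )
}
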