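#' Principal-axis extents of a surface
#'
#' Diagonalizes the second-moment (gyration) tensor of the vertex
#' positions about the centre of mass and returns the full extent
#' (max minus min vertex projection) along each principal axis, sorted
#' \eqn{D_1 \ge D_2 \ge D_3}.  Prolate (elongated) surfaces show
#' \eqn{D_1 > D_2 \simeq D_3}; oblate (flattened) surfaces show
#' \eqn{D_1 \simeq D_2 > D_3}, so the minor axis \eqn{D_2} discriminates
#' stripe (prolate) from two-circular (oblate) morphologies.  The result
#' is invariant under rigid rotations and translations.
#'
#' @param surface a [TriSurface-class] or an N x 3 coordinate matrix.
#' @return named numeric vector c(D1, D2, D3).
#' @examples
#' semiAxes(buildIcosphere(3)) # three nearly equal diameters
#' @export
semiAxes <- function(surface) {
  x <- if (is(surface, "TriSurface")) surface@vertices else as.matrix(surface)
  x <- sweep(x, 2, colMeans(x))
  g <- crossprod(x) / nrow(x)
  ev <- eigen(g, symmetric = TRUE)$vectors
  proj <- x %*% ev
  d <- sort(apply(proj, 2, max) - apply(proj, 2, min), decreasing = TRUE)
  c(D1 = d[1], D2 = d[2], D3 = d[3])
}

#' Connected phase domains of a surface
#'
#' Components of the graph whose nodes are triangles and whose edges join
#' bond-sharing triangles with equal phase label.  Returns the component
#' sizes per phase and the count of (Lo,Ld) domain-boundary bonds, which
#' is exactly \eqn{S_0 / 2}.
#'
#' @param surface a [TriSurface-class].
#' @return list with \code{lo} and \code{ld} (sorted component sizes,
#'   decreasing), \code{boundaryBonds} and \code{boundaryFraction}
#'   (boundary bonds / all bonds).
#' @examples
#' s <- buildIcosphere(1)
#' s@sigma[1] <- -1L
#' domainComponents(s) # one 19-triangle Lo component, one Ld singleton
#' @export
domainComponents <- function(surface) {
  stopifnot(is(surface, "TriSurface"))
  bt <- bondTable(surface)
  sig <- surface@sigma
  same <- sig[bt[, 3]] == sig[bt[, 4]]
  g <- igraph::graph_from_edgelist(bt[same, c(3, 4), drop = FALSE],
    directed = FALSE
  )
  g <- igraph::add_vertices(
    g,
    max(0L, nrow(surface@triangles) - igraph::vcount(g))
  )
  comp <- igraph::components(g)
  phase <- sig[vapply(
    seq_len(comp$no),
    function(k) which(comp$membership == k)[1], integer(1)
  )]
  list(
    lo = sort(comp$csize[phase > 0], decreasing = TRUE),
    ld = sort(comp$csize[phase < 0], decreasing = TRUE),
    boundaryBonds = sum(!same),
    boundaryFraction = mean(!same)
  )
}

#' Mean triangle areas per phase and the Lo area fraction
#'
#' Arithmetic mean triangle area in the Lo and Ld domains.  The Lo area
#' fraction is \eqn{N_{To} a_o / (N_{To} a_o + N_{Td} a_d)}: identical to
#' \eqn{\phi_0} when both phases share the same mean area (model 1, where
#' \eqn{\gamma_{ij} = 1} everywhere), but smaller than \eqn{\phi_0} in
#' model 2 with c > 1, where the larger Lo surface tension shrinks Lo
#' triangles.
#'
#' @param surface a [TriSurface-class].
#' @return list(ao, ad, areaFractionLo); a phase with no triangles
#'   reports \code{NA} for its mean area.
#' @export
meanTriangleAreas <- function(surface) {
  stopifnot(is(surface, "TriSurface"))
  v <- surface@vertices
  f <- surface@triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  lo <- surface@sigma > 0
  nto <- sum(lo)
  ntd <- sum(!lo)
  ao <- if (nto > 0) mean(area[lo]) else NA_real_
  ad <- if (ntd > 0) mean(area[!lo]) else NA_real_
  afrac <- if (nto == 0) {
    0
  } else if (ntd == 0) {
    1
  } else {
    nto * ao / (nto * ao + ntd * ad)
  }
  list(ao = ao, ad = ad, areaFractionLo = afrac)
}

#' Default morphology-classification thresholds
#'
#' The phase names of the model's phase diagrams (random, circular,
#' stripe, raft, budding) are defined by eye from snapshots in the
#' literature; this package operationalizes them with explicit,
#' configurable cutoffs on domain-component statistics.
#'
#' @param randomMinComponents more Lo components than this (with small
#'   mean size) classifies as random.
#' @param randomMeanSizeFrac "small mean size": mean Lo component size
#'   below this fraction of the Lo triangle count.
#' @param raftMaxComponents upper component count of the multi-circular
#'   raft label.
#' @param speckFrac components below this fraction of their phase's
#'   triangle count are ignored as specks when counting domains (single
#'   stray triangles do not turn two circular domains into "random").
#' @param buddingNeckRatio a large Lo component whose boundary length is
#'   below this multiple of the circumference of the equal-area disc is
#'   flagged as a budding candidate (narrow neck evidence).
#' @param buddingMinSizeFrac minimum component size (fraction of all
#'   triangles) for the budding flag.
#' @return named list of thresholds.
#' @export
morphologyThresholds <- function(randomMinComponents = 6L,
                                 randomMeanSizeFrac = 0.05,
                                 raftMaxComponents = 6L,
                                 speckFrac = 0.02,
                                 buddingNeckRatio = 0.7,
                                 buddingMinSizeFrac = 0.1) {
  list(
    randomMinComponents = randomMinComponents,
    randomMeanSizeFrac = randomMeanSizeFrac,
    raftMaxComponents = raftMaxComponents,
    speckFrac = speckFrac,
    buddingNeckRatio = buddingNeckRatio,
    buddingMinSizeFrac = buddingMinSizeFrac
  )
}

#' Classify the domain morphology of a configuration
#'
#' Maps domain-component statistics onto the categorical morphologies of
#' the two-component membrane phase diagrams:
#' \itemize{
#'   \item \code{one_circular}: exactly one Lo and one Ld component;
#'   \item \code{two_circular}: two Lo components on one connected Ld
#'     background (oblate, pancake-like surfaces);
#'   \item \code{stripe}: one Lo band separating two Ld caps (prolate
#'     surfaces);
#'   \item \code{multi_circular_raft}: 3-6 comparable compact Lo patches;
#'   \item \code{random}: many small Lo components — the unseparated
#'     two-phase coexistence state;
#'   \item \code{budding_candidate}: a large Lo component whose boundary
#'     is much shorter than the circumference of the equal-area disc,
#'     geometric evidence of a narrow neck (reported as evidence only;
#'     budded surfaces may self-intersect since the model has no
#'     self-avoidance).
#' }
#' The label is a pure function of the component statistics (plus bond
#' geometry when \code{surface} is supplied for the budding heuristic).
#'
#' @param components output of [domainComponents()].
#' @param thresholds output of [morphologyThresholds()].
#' @param surface optional [TriSurface-class] enabling the budding
#'   heuristic.
#' @return list(label, nLo, nLd, boundaryBonds, buddingComponents).
#' @examples
#' s <- buildIcosphere(1)
#' s@sigma[1] <- -1L
#' classifyMorphology(domainComponents(s))$label # "one_circular"
#' @export
classifyMorphology <- function(components, thresholds = morphologyThresholds(),
                               surface = NULL) {
  lo <- components$lo
  ld <- components$ld
  nto <- sum(lo)
  ntd <- sum(ld)
  th <- thresholds
  # stray specks (isolated triangles shed by large domains) do not count
  # toward the domain-number classification
  loEff <- lo[lo >= th$speckFrac * nto]
  ldEff <- ld[ld >= th$speckFrac * ntd]
  nLo <- length(loEff)
  nLd <- length(ldEff)

  budding <- integer(0)
  if (!is.null(surface) && nLo >= 1) {
    budding <- buddingComponents(surface, th)
  }

  label <- if (length(budding) > 0) {
    "budding_candidate"
  } else if (nLo == 1 && nLd == 1) {
    "one_circular"
  } else if (nLo == 2 && nLd == 1) {
    "two_circular"
  } else if (nLo == 1 && nLd == 2) {
    "stripe"
  } else if (nLo >= 3 && nLo <= th$raftMaxComponents &&
    mean(loEff) >= th$randomMeanSizeFrac * nto) {
    "multi_circular_raft"
  } else {
    "random"
  }
  list(
    label = label, nLo = length(lo), nLd = length(ld),
    nLoEffective = nLo, nLdEffective = nLd,
    boundaryBonds = components$boundaryBonds,
    buddingComponents = budding
  )
}

# Narrow-neck evidence: an Lo component is a budding candidate when its
# domain boundary is much shorter than the circumference of a flat disc of
# the same area (a nearly pinched-off spherical bud has boundary -> 0 at
# fixed area).
buddingComponents <- function(surface, th) {
  bt <- bondTable(surface)
  sig <- surface@sigma
  comp <- domainComponentMembership(surface)
  v <- surface@vertices
  f <- surface@triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  area <- 0.5 * sqrt(
    (a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
      (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
      (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2
  )
  blen <- sqrt(rowSums((v[bt[, 1], , drop = FALSE] -
    v[bt[, 2], , drop = FALSE])^2))
  boundary <- sig[bt[, 3]] != sig[bt[, 4]]
  loComps <- unique(comp[sig > 0])
  out <- integer(0)
  for (k in loComps) {
    inComp <- comp == k
    if (sum(inComp) < th$buddingMinSizeFrac * length(sig)) next
    compArea <- sum(area[inComp])
    onBoundary <- boundary & (inComp[bt[, 3]] | inComp[bt[, 4]])
    neck <- sum(blen[onBoundary])
    if (neck < th$buddingNeckRatio * 2 * sqrt(pi * compArea)) {
      out <- c(out, k)
    }
  }
  out
}

# per-triangle component id (same partition as domainComponents)
domainComponentMembership <- function(surface) {
  bt <- bondTable(surface)
  sig <- surface@sigma
  same <- sig[bt[, 3]] == sig[bt[, 4]]
  g <- igraph::graph_from_edgelist(bt[same, c(3, 4), drop = FALSE],
    directed = FALSE
  )
  g <- igraph::add_vertices(
    g,
    max(0L, nrow(surface@triangles) - igraph::vcount(g))
  )
  igraph::components(g)$membership
}
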