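#' Model parameter constructor
#'
#' Builds a validated [ModelParams-class].  The per-bond coefficients are
#' symmetric under \eqn{c \leftrightarrow 1/c}, so values of \code{c}
#' below 1 are canonicalized to \code{1/c}.
#'
#' @param lambda aggregation (line tension) coupling, >= 0.
#' @param kappa bending rigidity (units of 1/kT), > 0.
#' @param c Finsler metric ratio; canonicalized to c >= 1.
#' @param phi0 Lo triangle fraction in [0, 1].
#' @param variant \code{"model2"} (phase-dependent surface tension,
#'   gamma_ij = kappa_ij) or \code{"model1"} (gamma_ij = 1).
#' @param subdivision icosphere subdivision frequency.
#' @return a [ModelParams-class].
#' @examples
#' modelParams(0.2, 7, 5, 0.7, "model1", 8)
#' @export
modelParams <- function(lambda, kappa, c, phi0,
                        variant = c("model2", "model1"), subdivision = 4L) {
  variant <- match.arg(variant)
  if (c <= 0) stop("c must be positive")
  if (c < 1) c <- 1 / c
  obj <- new("ModelParams",
    lambda = as.numeric(lambda), kappa = as.numeric(kappa),
    c = as.numeric(c), phi0 = as.numeric(phi0), variant = variant,
    subdivision = as.integer(subdivision)
  )
  validObject(obj)
  obj
}

#' Finsler metric factor of a phase
#'
#' \eqn{\rho(\Delta) = c} on liquid-ordered triangles (sigma = +1) and 1
#' on liquid-disordered triangles (sigma = -1).  This single factor
#' generates the phase dependence of the effective surface tension and
#' bending rigidity.
#'
#' @param sigma phase label(s), +1 or -1 (vectorized).
#' @param c metric ratio parameter.
#' @return numeric vector of rho values.
#' @examples
#' rhoFactor(c(1, -1), 5) # 5 1
#' @export
rhoFactor <- function(sigma, c) {
  stopifnot(all(sigma %in% c(-1, 1)))
  ifelse(sigma > 0, c, 1)
}

#' Effective per-bond surface tension and bending rigidity
#'
#' For a bond shared by triangles with labels \code{sigmaI} and
#' \code{sigmaJ}, the bending coefficient is
#' \deqn{\kappa_{ij} = \tfrac14\left(\rho_i + 1/\rho_i + \rho_j +
#'   1/\rho_j\right),}
#' which takes the three closed forms \eqn{(c + c^{-1})/2} on (Lo,Lo)
#' bonds, \eqn{(2 + c + c^{-1})/4} on (Lo,Ld) domain-boundary bonds and 1
#' on (Ld,Ld) bonds.  The tension coefficient \eqn{\gamma_{ij}} equals
#' \eqn{\kappa_{ij}} in model 2 and is identically 1 in model 1.  Both are
#' invariant under swapping the two labels and under
#' \eqn{c \leftrightarrow 1/c}.
#'
#' @param sigmaI,sigmaJ labels (+1/-1) of the two incident triangles
#'   (vectorized).
#' @param c metric ratio parameter.
#' @param variant \code{"model2"} or \code{"model1"}.
#' @param which \code{"bending"} (kappa_ij) or \code{"tension"} (gamma_ij).
#' @return numeric coefficient(s).
#' @examples
#' bondCoefficient(1, 1, 8.37, "model2", "bending") # 4.2447
#' bondCoefficient(1, -1, 8.37, "model2", "bending") # 2.6224
#' bondCoefficient(-1, -1, 8.37, "model2", "bending") # 1
#' @export
bondCoefficient <- function(sigmaI, sigmaJ, c,
                            variant = c("model2", "model1"),
                            which = c("bending", "tension")) {
  variant <- match.arg(variant)
  which <- match.arg(which)
  if (which == "tension" && variant == "model1") {
    return(rep(1, length(sigmaI)))
  }
  ri <- rhoFactor(sigmaI, c)
  rj <- rhoFactor(sigmaJ, c)
  (ri + 1 / ri + rj + 1 / rj) / 4
}

#' Total energy of a surface
#'
#' Evaluates the Hamiltonian \eqn{S = \lambda S_0 + S_1 + \kappa S_2} by
#' summing over all bonds: \eqn{S_0 = \sum_{ij} (1 - \sigma_i \sigma_j)}
#' over the two triangles sharing each bond (so \eqn{S_0} equals twice the
#' number of (Lo,Ld) domain-boundary bonds), \eqn{S_1 = \sum_{ij}
#' \gamma_{ij} \ell_{ij}^2} with the Euclidean bond length, and
#' \eqn{S_2 = \sum_{ij} \kappa_{ij} (1 - n_i \cdot n_j)} with the unit
#' outward normals of the two incident triangles.
#'
#' @param surface a [TriSurface-class].
#' @param params a [ModelParams-class].
#' @return named numeric vector c(S0, S1, S2, total).  Errors on a
#'   degenerate (zero-area) triangle, whose normal is undefined.
#' @examples
#' s <- buildIcosphere(2)
#' totalEnergy(s, modelParams(0.5, 10, 8.37, 0.8))
#' @export
totalEnergy <- function(surface, params) {
  stopifnot(is(surface, "TriSurface"), is(params, "ModelParams"))
  cpp_total_energy(
    surface@vertices, surface@triangles, surface@sigma,
    params@lambda, params@kappa, params@c, variantCode(params)
  )
}

variantCode <- function(params) if (params@variant == "model1") 1L else 2L

#' Exact local energy difference of a vertex move
#'
#' Energy change of moving one vertex to \code{newPosition}, computed from
#' only the bonds and triangles in the star of the vertex: \eqn{S_1} terms
#' on incident bonds and \eqn{S_2} terms on every bond of a star triangle.
#' \eqn{S_0} cannot change under a vertex move.  Agrees with a full
#' before/after recomputation to floating precision; a move that would
#' create a degenerate triangle returns \code{Inf} (automatic rejection).
#'
#' @param surface a [TriSurface-class].
#' @param params a [ModelParams-class].
#' @param vertexId vertex index (1-based).
#' @param newPosition numeric length-3 coordinates.
#' @return scalar energy difference dS.
#' @export
deltaEnergyVertexMove <- function(surface, params, vertexId, newPosition) {
  stopifnot(is(surface, "TriSurface"), is(params, "ModelParams"))
  cpp_delta_vertex(
    surface@vertices, surface@triangles, surface@sigma,
    params@lambda, params@kappa, params@c, variantCode(params),
    as.integer(vertexId), as.numeric(newPosition)
  )
}

#' Exact local energy difference of a bond flip
#'
#' Energy change of a [flipCandidate()] proposal, evaluated on the
#' five-bond patch it touches (the flipped diagonal plus the four
#' quadrilateral boundary bonds): the diagonal's length and coefficients
#' change, the two new triangle normals change, and the sigma-adjacency
#' (\eqn{S_0}) terms of the patch change.  Agrees with a full before/after
#' recomputation to floating precision.
#'
#' @param surface a [TriSurface-class].
#' @param params a [ModelParams-class].
#' @param proposal a [FlipProposal-class].
#' @return scalar energy difference dS.
#' @export
deltaEnergyFlip <- function(surface, params, proposal) {
  stopifnot(
    is(surface, "TriSurface"), is(params, "ModelParams"),
    is(proposal, "FlipProposal")
  )
  cpp_delta_flip(
    surface@vertices, surface@triangles, surface@sigma,
    params@lambda, params@kappa, params@c, variantCode(params),
    proposal@bond, proposal@newSigma
  )
}
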