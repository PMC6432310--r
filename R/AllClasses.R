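#' Closed triangulated surface with per-triangle phase labels
#'
#' A closed orientable triangulation of sphere topology.  Triangles are
#' stored with consistent outward winding (counter-clockwise seen from
#' outside), and each triangle carries a phase label \code{sigma}: +1 for
#' the liquid-ordered (Lo) phase, -1 for the liquid-disordered (Ld) phase.
#' Validity enforces the sphere-topology identities \eqn{N_T = 2N - 4},
#' \eqn{N_B = 3N - 6}, the Euler characteristic \eqn{N - N_B + N_T = 2},
#' two incident triangles per bond, vertex coordination of at least 3 and
#' globally consistent winding.
#'
#' @slot vertices numeric N x 3 matrix of vertex coordinates (model units).
#' @slot triangles integer NT x 3 matrix of vertex indices, outward winding.
#' @slot sigma integer vector of NT phase labels, +1 (Lo) or -1 (Ld).
#'
#' @seealso [triSurface()], [buildIcosphere()], [bondTable()]
#' @export
setClass("TriSurface",
  representation(
    vertices = "matrix",
    triangles = "matrix",
    sigma = "integer"
  )
)

setValidity("TriSurface", function(object) {
  v <- object@vertices
  f <- object@triangles
  s <- object@sigma
  if (!is.numeric(v) || ncol(v) != 3) {
    return("vertices must be a numeric N x 3 matrix")
  }
  if (ncol(f) != 3) {
    return("triangles must be an NT x 3 index matrix")
  }
  if (length(s) != nrow(f)) {
    return("sigma must hold one label per triangle")
  }
  chk <- cpp_validate(v, storage.mode2int(f), s)
  if (!chk$ok) {
    return(chk$message)
  }
  TRUE
})

# integer coercion preserving dim
storage.mode2int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Model parameters of the two-component membrane Hamiltonian
#'
#' Collects the couplings of \eqn{S = \lambda S_0 + S_1 + \kappa S_2}
#' together with the Lo fraction, the model variant and the lattice
#' subdivision.  Temperature is fixed at \eqn{k_B T = 1}.  The coefficient
#' formulas are symmetric under \eqn{c \leftrightarrow 1/c}, so \code{c}
#' is canonicalized to \eqn{c \ge 1} on construction.
#'
#' @slot lambda aggregation (line tension) coupling, \eqn{\lambda \ge 0}.
#' @slot kappa bending rigidity in units of \eqn{1/k_B T}, \eqn{\kappa > 0}.
#' @slot c Finsler metric ratio between the Lo and Ld phases, \eqn{c \ge 1}.
#' @slot phi0 conserved Lo triangle fraction \eqn{N_{To}/N_T} in [0, 1].
#' @slot variant \code{"model1"} (\eqn{\gamma_{ij} = 1}) or \code{"model2"}
#'   (\eqn{\gamma_{ij} = \kappa_{ij}}).
#' @slot subdivision icosphere subdivision frequency (N = 10 l^2 + 2).
#'
#' @seealso [modelParams()], [bondCoefficient()]
#' @export
setClass("ModelParams",
  representation(
    lambda = "numeric",
    kappa = "numeric",
    c = "numeric",
    phi0 = "numeric",
    variant = "character",
    subdivision = "integer"
  )
)

setValidity("ModelParams", function(object) {
  if (length(object@lambda) != 1 || object@lambda < 0) {
    return("lambda must be a single value >= 0")
  }
  if (length(object@kappa) != 1 || object@kappa <= 0) {
    return("kappa must be a single value > 0")
  }
  if (length(object@c) != 1 || object@c < 1) {
    return("c must be a single value >= 1 (canonical form of c <-> 1/c)")
  }
  if (length(object@phi0) != 1 || object@phi0 < 0 || object@phi0 > 1) {
    return("phi0 must lie in [0, 1]")
  }
  if (!object@variant %in% c("model1", "model2")) {
    return("variant must be \"model1\" or \"model2\"")
  }
  if (length(object@subdivision) != 1 || object@subdivision < 1) {
    return("subdivision must be a positive integer")
  }
  TRUE
})

#' Monte Carlo run schedule
#'
#' Sweep counts and intervals of a simulation run.  One sweep is N
#' vertex-move attempts plus N bond-flip attempts.  The move radius is
#' tuned only during thermalization and frozen during measurement, so the
#' production phase satisfies detailed balance with fixed parameters.
#'
#' @slot thermSweeps thermalization sweeps (tuning active).
#' @slot measSweeps measurement sweeps (tuning frozen).
#' @slot measInterval sweeps between recorded observable rows.
#' @slot tuneInterval sweeps per move-radius tuning window.
#' @slot recomputeInterval sweeps between full energy recomputations that
#'   audit the incrementally accumulated energy.
#' @slot checkpointInterval sweeps between checkpoints (0 = none).
#'
#' @seealso [runSchedule()], [runSimulation()]
#' @export
setClass("RunSchedule",
  representation(
    thermSweeps = "integer",
    measSweeps = "integer",
    measInterval = "integer",
    tuneInterval = "integer",
    recomputeInterval = "integer",
    checkpointInterval = "integer"
  )
)

setValidity("RunSchedule", function(object) {
  if (object@thermSweeps < 0 || object@measSweeps < 0) {
    return("sweep counts must be non-negative")
  }
  if (object@measInterval < 1 || object@tuneInterval < 1) {
    return("intervals must be >= 1")
  }
  if (object@recomputeInterval < 0 || object@checkpointInterval < 0) {
    return("intervals must be >= 0")
  }
  TRUE
})

#' Bond-flip proposal
#'
#' Describes the replacement of the shared diagonal (u, v) of two adjacent
#' triangles by the opposite diagonal (p, q), together with the phase
#' labels proposed for the two new triangles.  Applying and then reverting
#' a proposal restores the triangulation exactly.
#'
#' @slot bond canonical bond index of the flipped diagonal.
#' @slot u,v endpoints of the old diagonal (vertex indices).
#' @slot p,q endpoints of the new diagonal.
#' @slot face1,face2 row indices of the two incident triangles.
#' @slot oldFace1,oldFace2 the original triangle rows (for exact revert).
#' @slot oldSigma labels of (face1, face2) before the flip.
#' @slot newSigma labels proposed for (face1, face2) after the flip.
#'
#' @seealso [flipCandidate()], [applyFlip()], [revertFlip()]
#' @export
setClass("FlipProposal",
  representation(
    bond = "integer",
    u = "integer", v = "integer", p = "integer", q = "integer",
    face1 = "integer", face2 = "integer",
    oldFace1 = "integer", oldFace2 = "integer",
    oldSigma = "integer",
    newSigma = "integer"
  )
)

#' Metropolis sampler state
#'
#' Bundles a surface with its model parameters, the current move radius,
#' the sweep counter, acceptance counters and the cached energy breakdown.
#' Used by the single-update operations [vertexMoveUpdate()],
#' [flipUpdate()], [sweepState()] and [tuneRadius()]; long runs go through
#' [runSimulation()], which keeps the whole loop in compiled code.
#'
#' @slot surface a [TriSurface-class].
#' @slot params a [ModelParams-class].
#' @slot moveRadius radius of the vertex-move proposal ball.
#' @slot sweeps completed sweeps.
#' @slot vertexAttempted,vertexAccepted vertex-move counters.
#' @slot flipAttempted,flipAccepted bond-flip counters.
#' @slot windowAttempted,windowAccepted vertex counters since last tuning.
#' @slot energy cached energy breakdown c(S0, S1, S2, total).
#'
#' @seealso [newMCState()]
#' @export
setClass("MCState",
  representation(
    surface = "TriSurface",
    params = "ModelParams",
    moveRadius = "numeric",
    sweeps = "numeric",
    vertexAttempted = "numeric",
    vertexAccepted = "numeric",
    flipAttempted = "numeric",
    flipAccepted = "numeric",
    windowAttempted = "numeric",
    windowAccepted = "numeric",
    energy = "numeric"
  )
)

#' @describeIn TriSurface-class compact summary of counts and phase split.
#' @param object a \code{TriSurface}.
#' @export
setMethod("show", "TriSurface", function(object) {
  n <- nrow(object@vertices)
  nt <- nrow(object@triangles)
  nto <- sum(object@sigma > 0)
  cat(sprintf(
    "TriSurface: %d vertices, %d triangles, %d bonds\n", n, nt, 3 * n - 6
  ))
  cat(sprintf(
    "  sigma: %d Lo (+1), %d Ld (-1); phi = %.3f\n", nto, nt - nto, nto / nt
  ))
  invisible(object)
})

#' @describeIn ModelParams-class one-line parameter summary.
#' @param object a \code{ModelParams}.
#' @export
setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    "ModelParams (%s): lambda = %g, kappa = %g, c = %g, phi0 = %g, subdivision = %d\n",
    object@variant, object@lambda, object@kappa, object@c, object@phi0,
    object@subdivision
  ))
  invisible(object)
})

#' @describeIn MCState-class summary of progress and acceptance.
#' @param object an \code{MCState}.
#' @export
setMethod("show", "MCState", function(object) {
  cat(sprintf(
    "MCState: %g sweeps, move radius %.4g\n", object@sweeps,
    object@moveRadius
  ))
  if (object@vertexAttempted > 0) {
    cat(sprintf(
      "  vertex acceptance %.3f (%g/%g), flip acceptance %.3f (%g/%g)\n",
      object@vertexAccepted / object@vertexAttempted,
      object@vertexAccepted, object@vertexAttempted,
      if (object@flipAttempted > 0) {
        object@flipAccepted / object@flipAttempted
      } else {
        NA_real_
      },
      object@flipAccepted, object@flipAttempted
    ))
  }
  cat(sprintf(
    "  energy: S0 = %.6g, S1 = %.6g, S2 = %.6g, total = %.6g\n",
    object@energy[["S0"]], object@energy[["S1"]], object@energy[["S2"]],
    object@energy[["total"]]
  ))
  invisible(object)
})
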