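#' Run schedule constructor
#'
#' One sweep is N vertex-move attempts plus N bond-flip attempts in random
#' interleaving, followed by recentering of the surface at the origin.
#' The move radius is auto-tuned toward 50% vertex acceptance during
#' thermalization only; it is frozen for the whole measurement phase.
#' Defaults split a run 25% thermalization / 75% measurement when only
#' \code{totalSweeps} is given.
#'
#' @param thermSweeps thermalization sweeps.
#' @param measSweeps measurement sweeps.
#' @param totalSweeps alternative to the two counts: split 25/75.
#' @param measInterval sweeps between recorded observable rows.
#' @param tuneInterval sweeps per tuning window.
#' @param recomputeInterval sweeps between full-energy audits of the
#'   incremental energy accumulation.
#' @param checkpointInterval sweeps between checkpoints (0 disables).
#' @return a [RunSchedule-class].
#' @examples
#' runSchedule(totalSweeps = 4000)
#' @export
runSchedule <- function(thermSweeps = NULL, measSweeps = NULL,
                        totalSweeps = NULL, measInterval = 10L,
                        tuneInterval = 100L, recomputeInterval = 10000L,
                        checkpointInterval = 0L) {
  if (is.null(thermSweeps) || is.null(measSweeps)) {
    if (is.null(totalSweeps)) {
      stop("give thermSweeps and measSweeps, or totalSweeps")
    }
    thermSweeps <- round(0.25 * totalSweeps)
    measSweeps <- totalSweeps - thermSweeps
  }
  obj <- new("RunSchedule",
    thermSweeps = as.integer(thermSweeps),
    measSweeps = as.integer(measSweeps),
    measInterval = as.integer(measInterval),
    tuneInterval = as.integer(tuneInterval),
    recomputeInterval = as.integer(recomputeInterval),
    checkpointInterval = as.integer(checkpointInterval)
  )
  validObject(obj)
  obj
}

#' Equilibrium bond-length estimate for a parameter set
#'
#' The scale invariance of the partition function fixes
#' \eqn{\langle S_1 \rangle / N = 3/2}, i.e. a mean per-bond
#' \eqn{\langle \gamma_{ij} \ell_{ij}^2 \rangle = 1.5 N / N_B}.  Using the
#' random-mixing average of \eqn{\gamma_{ij}} at the Lo fraction
#' \code{phi0} gives the bond length the equilibrated surface will adopt;
#' starting the lattice there removes the slow relaxation of the global
#' breathing mode from thermalization.
#'
#' @param params a [ModelParams-class].
#' @return estimated equilibrium mean bond length.
#' @export
equilibriumEdgeLength <- function(params) {
  n <- 10 * params@subdivision^2 + 2
  nb <- 3 * n - 6
  phi <- params@phi0
  gbar <- if (params@variant == "model1") {
    1
  } else {
    phi^2 * bondCoefficient(1, 1, params@c) +
      2 * phi * (1 - phi) * bondCoefficient(1, -1, params@c) +
      (1 - phi)^2 * bondCoefficient(-1, -1, params@c)
  }
  sqrt(1.5 * n / (nb * gbar))
}

#' Initialize a Metropolis sampler state
#'
#' @param surface a [TriSurface-class]; built from
#'   \code{params@subdivision} and labelled at \code{params@phi0} when
#'   missing.
#' @param params a [ModelParams-class].
#' @param moveRadius initial vertex-move proposal radius (tuned later).
#' @return an [MCState-class].
#' @export
newMCState <- function(params, surface = NULL, moveRadius = 0.17) {
  stopifnot(is(params, "ModelParams"))
  if (is.null(surface)) {
    surface <- assignSigmaRandom(
      buildIcosphere(params@subdivision,
        meanEdge = equilibriumEdgeLength(params)
      ),
      params@phi0
    )
  }
  new("MCState",
    surface = surface, params = params,
    moveRadius = as.numeric(moveRadius), sweeps = 0,
    vertexAttempted = 0, vertexAccepted = 0,
    flipAttempted = 0, flipAccepted = 0,
    windowAttempted = 0, windowAccepted = 0,
    energy = totalEnergy(surface, params)
  )
}

#' Single Metropolis updates
#'
#' \code{vertexMoveUpdate} proposes moving one uniformly chosen vertex by
#' a displacement uniform in the ball of radius \code{moveRadius} and
#' accepts with probability min(1, exp(-dS)) at kT = 1.
#' \code{flipUpdate} picks one uniformly random bond; a topologically
#' illegal flip counts as rejected, a legal one is Metropolis-accepted
#' with the exact local energy difference.  The Lo triangle count is
#' conserved in every case.  Both return the updated state and whether
#' the proposal was accepted.  These single-step entry points drive the
#' small-scale tests; production runs use [runSimulation()].
#'
#' @param state an [MCState-class].
#' @return list(state, accepted, dS).
#' @export
vertexMoveUpdate <- function(state) {
  stopifnot(is(state, "MCState"))
  s <- state@surface
  p <- state@params
  res <- cpp_vertex_update(
    s@vertices, s@triangles, s@sigma,
    p@lambda, p@kappa, p@c, variantCode(p), state@moveRadius
  )
  state@vertexAttempted <- state@vertexAttempted + 1
  state@windowAttempted <- state@windowAttempted + 1
  if (res$accepted) {
    state@surface@vertices <- res$vertices
    state@vertexAccepted <- state@vertexAccepted + 1
    state@windowAccepted <- state@windowAccepted + 1
    state@energy <- totalEnergy(state@surface, p)
  }
  list(state = state, accepted = res$accepted, dS = res$dS)
}

#' @rdname vertexMoveUpdate
#' @export
flipUpdate <- function(state) {
  stopifnot(is(state, "MCState"))
  s <- state@surface
  p <- state@params
  res <- cpp_flip_update(
    s@vertices, s@triangles, s@sigma,
    p@lambda, p@kappa, p@c, variantCode(p)
  )
  state@flipAttempted <- state@flipAttempted + 1
  if (res$accepted) {
    state@surface@triangles <- res$triangles
    state@surface@sigma <- res$sigma
    state@flipAccepted <- state@flipAccepted + 1
    state@energy <- totalEnergy(state@surface, p)
  }
  list(state = state, accepted = res$accepted, dS = res$dS)
}

#' Advance a sampler state by whole sweeps
#'
#' Performs \code{nSweeps} sweeps (N vertex updates and N flip attempts
#' each, randomly interleaved), recentering the surface at the origin
#' after every sweep.  Tuning and measurement are off; use
#' [runSimulation()] for scheduled runs.
#'
#' @param state an [MCState-class].
#' @param nSweeps number of sweeps.
#' @return the updated state.
#' @export
sweepState <- function(state, nSweeps = 1L) {
  stopifnot(is(state, "MCState"))
  s <- state@surface
  p <- state@params
  res <- cpp_run_chunk(
    s@vertices, s@triangles, s@sigma,
    p@lambda, p@kappa, p@c, variantCode(p),
    as.integer(nSweeps), as.integer(state@sweeps), state@moveRadius,
    FALSE, 1000000L, 0.5, FALSE, 1L, 0L
  )
  state@surface@vertices <- res$vertices
  state@surface@triangles <- res$triangles
  state@surface@sigma <- res$sigma
  state@sweeps <- state@sweeps + nSweeps
  state@vertexAttempted <- state@vertexAttempted + res$vertexAttempted
  state@vertexAccepted <- state@vertexAccepted + res$vertexAccepted
  state@windowAttempted <- state@windowAttempted + res$vertexAttempted
  state@windowAccepted <- state@windowAccepted + res$vertexAccepted
  state@flipAttempted <- state@flipAttempted + res$flipAttempted
  state@flipAccepted <- state@flipAccepted + res$flipAccepted
  state@energy <- res$energy
  state
}

#' Tune the vertex-move radius toward a target acceptance
#'
#' Multiplicative control step: the move radius is scaled by the ratio of
#' the acceptance measured since the last tuning call to the target,
#' clamped to [0.5, 1.5] per step.  High acceptance therefore grows the
#' radius and low acceptance shrinks it.  Intended for the thermalization
#' phase only; [runSimulation()] freezes the radius during measurement.
#'
#' @param state an [MCState-class].
#' @param target target acceptance fraction (default 0.5).
#' @return the state with updated \code{moveRadius} and a reset window.
#' @export
tuneRadius <- function(state, target = 0.5) {
  stopifnot(is(state, "MCState"))
  if (state@windowAttempted > 0) {
    acc <- state@windowAccepted / state@windowAttempted
    fac <- min(1.5, max(0.5, acc / target))
    state@moveRadius <- min(1e3, max(1e-8, state@moveRadius * fac))
    state@windowAttempted <- 0
    state@windowAccepted <- 0
  }
  state
}

#' Run a full simulation
#'
#' Builds the icosphere at \code{params@subdivision}, assigns random phase
#' labels at \code{params@phi0} (the random two-phase coexistence state),
#' thermalizes with move-radius tuning toward 50% vertex acceptance, then
#' freezes the radius and measures.  Returns the observable trajectory
#' (one row per \code{measInterval} sweeps of the measurement phase), the
#' final surface, production acceptance fractions and the
#' production-average \eqn{\langle S_1 \rangle / N}, which the scale
#' invariance of the partition function pins at 3/2 (finite-size value
#' \eqn{3(N-1)/(2N)}) for every parameter set — the strongest global
#' correctness check of the sampler.
#'
#' Runs are fully reproducible from (seed, parameters, schedule); with
#' \code{checkpointInterval > 0} and \code{checkpointPath} set, the run
#' writes resumable checkpoints whose continuation is identical to the
#' uninterrupted run.
#'
#' @param params a [ModelParams-class].
#' @param schedule a [RunSchedule-class].
#' @param seed optional integer seed (\code{set.seed} when given).
#' @param surface optional starting [TriSurface-class] (overrides the
#'   default construction).
#' @param moveRadius initial move radius before tuning.
#' @param checkpointPath file path for checkpoints (RDS).
#' @param resume path of a checkpoint to resume from.
#' @return list with elements \code{trajectory} (data.frame),
#'   \code{surface}, \code{moveRadius}, \code{acceptance} (named vector,
#'   production phase), \code{meanS1PerN}, \code{energy},
#'   \code{energyDrift}, \code{params}, \code{schedule}, \code{seed}.
#' @examples
#' \donttest{
#' p <- modelParams(0.5, 10, 8.37, 0.8, "model2", subdivision = 2)
#' r <- runSimulation(p, runSchedule(500, 1500), seed = 1)
#' r$meanS1PerN # ~ 3/2
#' }
#' @export
runSimulation <- function(params, schedule, seed = NULL, surface = NULL,
                          moveRadius = 0.17, checkpointPath = NULL,
                          resume = NULL) {
  stopifnot(is(params, "ModelParams"), is(schedule, "RunSchedule"))
  if (!is.null(resume)) {
    ck <- readCheckpoint(resume)
    assign(".Random.seed", ck$randomSeed, envir = globalenv())
    state <- ck$state
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(surface)) {
      surface <- assignSigmaRandom(
        buildIcosphere(params@subdivision,
          meanEdge = equilibriumEdgeLength(params)
        ),
        params@phi0
      )
    }
    state <- list(
      phase = "therm", doneInPhase = 0L,
      surface = surface, moveRadius = moveRadius,
      records = list(), sumS1 = 0, nMeas = 0L,
      prodVAtt = 0, prodVAcc = 0, prodFAtt = 0, prodFAcc = 0,
      maxDrift = 0, energy = NULL
    )
  }

  ckInt <- schedule@checkpointInterval
  phaseLen <- c(
    therm = schedule@thermSweeps,
    meas = schedule@measSweeps
  )

  repeat {
    remaining <- phaseLen[[state$phase]] - state$doneInPhase
    if (remaining <= 0) {
      if (state$phase == "therm") {
        state$phase <- "meas"
        state$doneInPhase <- 0L
        next
      }
      break
    }
    chunk <- if (ckInt > 0) min(remaining, ckInt) else remaining
    s <- state$surface
    offset <- if (state$phase == "therm") {
      state$doneInPhase
    } else {
      schedule@thermSweeps + state$doneInPhase
    }
    res <- cpp_run_chunk(
      s@vertices, s@triangles, s@sigma,
      params@lambda, params@kappa, params@c, variantCode(params),
      as.integer(chunk), as.integer(offset), state$moveRadius,
      state$phase == "therm", schedule@tuneInterval, 0.5,
      state$phase == "meas", schedule@measInterval,
      schedule@recomputeInterval
    )
    state$surface@vertices <- res$vertices
    state$surface@triangles <- res$triangles
    state$surface@sigma <- res$sigma
    state$moveRadius <- res$moveRadius
    state$doneInPhase <- state$doneInPhase + chunk
    state$maxDrift <- max(state$maxDrift, res$maxDrift)
    state$energy <- res$energy
    if (state$phase == "meas") {
      state$records[[length(state$records) + 1L]] <- res$records
      state$sumS1 <- state$sumS1 + res$sumS1perN
      state$nMeas <- state$nMeas + res$nMeasuredSweeps
      state$prodVAtt <- state$prodVAtt + res$vertexAttempted
      state$prodVAcc <- state$prodVAcc + res$vertexAccepted
      state$prodFAtt <- state$prodFAtt + res$flipAttempted
      state$prodFAcc <- state$prodFAcc + res$flipAccepted
    }
    if (ckInt > 0 && !is.null(checkpointPath)) {
      writeCheckpoint(checkpointPath, state, params, schedule, seed)
    }
  }

  trajectory <- as.data.frame(do.call(rbind, state$records))
  list(
    trajectory = trajectory,
    surface = state$surface,
    moveRadius = state$moveRadius,
    acceptance = c(
      vertex = if (state$prodVAtt > 0) state$prodVAcc / state$prodVAtt else NA,
      flip = if (state$prodFAtt > 0) state$prodFAcc / state$prodFAtt else NA
    ),
    meanS1PerN = if (state$nMeas > 0) state$sumS1 / state$nMeas else NA,
    energy = state$energy,
    energyDrift = state$maxDrift,
    params = params,
    schedule = schedule,
    seed = seed
  )
}

#' Checkpoint I/O
#'
#' Serializes the full resumable run state — surface, labels, move radius,
#' phase progress, accumulated statistics and the R RNG state — so that a
#' resumed run continues the identical random sequence.
#'
#' @param path checkpoint file path (RDS).
#' @param state,params,schedule,seed internal run state (see
#'   [runSimulation()]).
#' @return \code{readCheckpoint}: the stored list.
#' @keywords internal
#' @export
writeCheckpoint <- function(path, state, params, schedule, seed) {
  saveRDS(
    list(
      state = state, params = params, schedule = schedule, seed = seed,
      randomSeed = get(".Random.seed", envir = globalenv())
    ),
    path
  )
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  readRDS(path)
}
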