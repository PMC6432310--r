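#' Write and read surface snapshots (PLY / OFF)
#'
#' Writes a surface as ascii PLY (default) with the phase label stored as
#' a per-face integer property \code{sigma}, loadable by standard mesh
#' viewers, or as ascii OFF with the label appended as a per-face scalar
#' after the vertex indices.  \code{readSnapshot} accepts the same
#' dialects and round-trips vertices (to printed float precision),
#' triangles and labels exactly.
#'
#' @param surface a [TriSurface-class].
#' @param path output file.
#' @param format \code{"ply"} or \code{"off"} (inferred from the file
#'   extension when missing).
#' @return \code{writeSnapshot}: the path, invisibly;
#'   \code{readSnapshot}: a [TriSurface-class].
#' @examples
#' f <- tempfile(fileext = ".ply")
#' writeSnapshot(buildIcosphere(1), f)
#' s <- readSnapshot(f)
#' @export
writeSnapshot <- function(surface, path, format = NULL) {
  stopifnot(is(surface, "TriSurface"))
  if (is.null(format)) {
    format <- if (grepl("\\.off$", path, ignore.case = TRUE)) "off" else "ply"
  }
  format <- match.arg(format, c("ply", "off"))
  v <- surface@vertices
  f <- surface@triangles
  s <- surface@sigma
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c(
      "ply",
      "format ascii 1.0",
      "comment two-component membrane snapshot (sigma: +1 Lo, -1 Ld)",
      sprintf("element vertex %d", nrow(v)),
      "property double x",
      "property double y",
      "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "property int sigma",
      "end_header"
    ), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(
      sprintf("3 %d %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, s),
      con
    )
  } else {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(
      sprintf("3 %d %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, s),
      con
    )
  }
  invisible(path)
}

#' @rdname writeSnapshot
#' @export
readSnapshot <- function(path, format = NULL) {
  lines <- readLines(path)
  if (is.null(format)) {
    format <- if (identical(lines[1], "ply")) "ply" else "off"
  }
  if (format == "ply") {
    endHdr <- which(lines == "end_header")[1]
    if (is.na(endHdr)) stop("not an ascii PLY file: ", path)
    hdr <- lines[seq_len(endHdr)]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
      hdr,
      value = TRUE
    )))
    nf <- as.integer(sub("element face ", "", grep("^element face",
      hdr,
      value = TRUE
    )))
    body <- lines[-seq_len(endHdr)]
  } else {
    if (!identical(lines[1], "OFF")) stop("not an OFF file: ", path)
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]
    nf <- counts[2]
    body <- lines[-(1:2)]
  }
  vl <- body[seq_len(nv)]
  fl <- body[nv + seq_len(nf)]
  v <- matrix(
    as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
    nv, 3,
    byrow = TRUE
  )
  fm <- matrix(
    as.numeric(unlist(strsplit(trimws(fl), "\\s+"))),
    nf, 5,
    byrow = TRUE
  )
  if (any(fm[, 1] != 3)) stop("only triangular faces are supported")
  sig <- as.integer(fm[, 5])
  if (!all(sig %in% c(-1L, 1L))) {
    stop("per-face sigma property must be +1 or -1")
  }
  triSurface(v, fm[, 2:4] + 1, sig)
}

# ------------------------------------------------------------- configuration

configDefaults <- function() {
  list(
    lattice = list(subdivision = 4L, mean_edge = 0.7),
    model = list(
      variant = "model2", lambda = 0.5, kappa = 10, c = 8.37, phi0 = 0.8
    ),
    schedule = list(
      therm_sweeps = 1000L, meas_sweeps = 3000L, meas_interval = 10L,
      tune_interval = 100L, recompute_interval = 10000L,
      checkpoint_interval = 0L
    ),
    output = list(dir = "."),
    scan = NULL,
    seed = 1L
  )
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration with sections \code{lattice}, \code{model},
#' \code{schedule}, and optionally \code{scan} (grid axes \code{lambda},
#' \code{kappa}, \code{phi0} for phase-plane scans) and \code{output}.
#' Unknown keys and out-of-range values are rejected with a named
#' diagnostic; \code{c < 1} is canonicalized to \code{1/c}; all defaults
#' are filled in and returned.
#'
#' @param path YAML file.
#' @return list with \code{params} ([ModelParams-class]), \code{schedule}
#'   ([RunSchedule-class]), \code{seed}, \code{meanEdge}, \code{output},
#'   and \code{scan} (grid data.frame or NULL).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  def <- configDefaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in c("lattice", "model", "schedule", "output")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad) > 0) {
        stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
      }
      def[[sec]] <- modifyList(def[[sec]], cfg[[sec]])
    }
  }
  if (!is.null(cfg$seed)) def$seed <- cfg$seed
  if (!is.null(cfg$scan)) def$scan <- cfg$scan

  m <- def$model
  if (!m$variant %in% c("model1", "model2")) {
    stop("model.variant must be \"model1\" or \"model2\"")
  }
  if (m$phi0 < 0 || m$phi0 > 1) stop("model.phi0 must lie in [0, 1]")
  if (m$lambda < 0) stop("model.lambda must be >= 0")
  if (m$kappa <= 0) stop("model.kappa must be > 0")
  params <- modelParams(
    m$lambda, m$kappa, m$c, m$phi0, m$variant,
    def$lattice$subdivision
  )
  schedule <- runSchedule(
    thermSweeps = def$schedule$therm_sweeps,
    measSweeps = def$schedule$meas_sweeps,
    measInterval = def$schedule$meas_interval,
    tuneInterval = def$schedule$tune_interval,
    recomputeInterval = def$schedule$recompute_interval,
    checkpointInterval = def$schedule$checkpoint_interval
  )
  scan <- NULL
  if (!is.null(def$scan)) {
    axes <- def$scan
    badAxes <- setdiff(names(axes), c("lambda", "kappa", "phi0"))
    if (length(badAxes) > 0) {
      stop("scan axes must be among lambda, kappa, phi0; got: ",
        paste(badAxes, collapse = ", "))
    }
    scan <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  }
  list(
    params = params, schedule = schedule, seed = def$seed,
    meanEdge = def$lattice$mean_edge, output = def$output, scan = scan
  )
}

#' Write an observable trajectory as TSV
#'
#' One row per measurement, with provenance comment lines (parameters and
#' seed) at the top so every log is self-describing.
#'
#' @param trajectory data.frame from [runSimulation()].
#' @param path output file.
#' @param params a [ModelParams-class] (for the provenance header).
#' @param seed seed used (for the provenance header).
#' @return the path, invisibly.
#' @export
writeObservables <- function(trajectory, path, params = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf(
      "# variant=%s lambda=%g kappa=%g c=%g phi0=%g subdivision=%d",
      params@variant, params@lambda, params@kappa, params@c, params@phi0,
      params@subdivision
    ), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  suppressWarnings(write.table(trajectory, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  ))
  invisible(path)
}

#' Phase-plane scan
#'
#' Runs one seeded, independent simulation per grid point, aggregates the
#' measurement-phase means of the recorded observables and classifies the
#' final configuration's morphology — the table from which a phase
#' diagram is drawn.  When \code{outFile} exists, completed grid points
#' (matched on parameters) are skipped and the table is extended, so
#' interrupted scans can be resumed.
#'
#' @param grid data.frame with columns among \code{lambda}, \code{kappa},
#'   \code{phi0}; one run per row.  Missing columns fall back to
#'   \code{params}.
#' @param params baseline [ModelParams-class] supplying the fixed
#'   parameters.
#' @param schedule per-point [RunSchedule-class].
#' @param seed base seed; point i runs with seed + i.
#' @param outFile optional TSV path, written after every point.
#' @return data.frame: parameters, mean observables, morphology label,
#'   acceptance, seed and an \code{error} column (scan continues past
#'   per-point failures).
#' @examples
#' \donttest{
#' p <- modelParams(0.2, 7, 5, 0.5, "model1", subdivision = 2)
#' g <- expand.grid(lambda = c(0.03, 0.4), phi0 = c(0.3, 0.7))
#' tab <- runScan(g, p, runSchedule(200, 600), seed = 1)
#' }
#' @export
runScan <- function(grid, params, schedule, seed = 1L, outFile = NULL) {
  stopifnot(is.data.frame(grid), is(params, "ModelParams"))
  done <- NULL
  if (!is.null(outFile) && file.exists(outFile)) {
    done <- read.table(outFile, header = TRUE, sep = "\t")
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pt <- as.list(grid[i, , drop = FALSE])
    p <- modelParams(
      lambda = if (!is.null(pt$lambda)) pt$lambda else params@lambda,
      kappa = if (!is.null(pt$kappa)) pt$kappa else params@kappa,
      c = params@c,
      phi0 = if (!is.null(pt$phi0)) pt$phi0 else params@phi0,
      variant = params@variant,
      subdivision = params@subdivision
    )
    if (!is.null(done) && nrow(done) > 0) {
      hit <- abs(done$lambda - p@lambda) < 1e-12 &
        abs(done$kappa - p@kappa) < 1e-12 &
        abs(done$phi0 - p@phi0) < 1e-12
      if (any(hit)) {
        rows[[i]] <- done[which(hit)[1], , drop = FALSE]
        next
      }
    }
    rows[[i]] <- tryCatch(
      {
        run <- runSimulation(p, schedule, seed = seed + i)
        tr <- run$trajectory
        comp <- domainComponents(run$surface)
        morph <- classifyMorphology(comp, surface = run$surface)
        data.frame(
          lambda = p@lambda, kappa = p@kappa, c = p@c, phi0 = p@phi0,
          variant = p@variant, subdivision = p@subdivision,
          seed = seed + i,
          S1_per_N = mean(tr$S1_per_N),
          S2_per_NB = mean(tr$S2_per_NB),
          S0 = mean(tr$S0),
          boundary_bonds = mean(tr$boundary_bonds),
          n_lo_components = length(comp$lo),
          n_ld_components = length(comp$ld),
          D1 = mean(tr$D1), D2 = mean(tr$D2), D3 = mean(tr$D3),
          acc_vertex = run$acceptance[["vertex"]],
          morphology = morph$label,
          error = "",
          stringsAsFactors = FALSE
        )
      },
      error = function(e) {
        data.frame(
          lambda = p@lambda, kappa = p@kappa, c = p@c, phi0 = p@phi0,
          variant = p@variant, subdivision = p@subdivision,
          seed = seed + i,
          S1_per_N = NA, S2_per_NB = NA, S0 = NA, boundary_bonds = NA,
          n_lo_components = NA, n_ld_components = NA,
          D1 = NA, D2 = NA, D3 = NA, acc_vertex = NA,
          morphology = NA_character_, error = conditionMessage(e),
          stringsAsFactors = FALSE
        )
      }
    )
    if (!is.null(outFile)) {
      tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      write.table(tab, outFile,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
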