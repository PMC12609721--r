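#' @include AllClasses.R mesh-geometry.R
NULL

## internal TrajectoryLog builder with finiteness guard
makeTrajectoryLog <- function(records, snapshots = list(), meta = list()) {
  df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  if (is.null(df)) df <- data.frame(iteration = numeric(0))
  num <- vapply(df, is.numeric, logical(1))
  if (nrow(df) &&
      any(vapply(df[num], function(col) any(!is.finite(col)), logical(1))))
    stop("non-finite observable produced during the run; aborting")
  new("TrajectoryLog", data = df, snapshots = snapshots, meta = meta)
}

#' Contact area of a membrane with a plane
#'
#' Sum of the areas of faces all of whose vertices lie within
#' `proximityDelta` of the plane `z = planeZ`. This is the spreading
#' readout; its normalised variant (divide by the run's final value) is
#' what spreading curves report.
#'
#' @param mesh a [TriMesh-class].
#' @param planeZ plane height (um).
#' @param proximityDelta proximity threshold (um), > 0.
#' @return contact area (um^2).
#' @export
contactArea <- function(mesh, planeZ = 0, proximityDelta = 0.05) {
  stopifnot(is(mesh, "TriMesh"))
  if (proximityDelta <= 0) stop("proximityDelta must be > 0")
  close_ <- abs(mesh@vertices[, 3L] - planeZ) <= proximityDelta
  f <- mesh@faces
  inContact <- close_[f[, 1L]] & close_[f[, 2L]] & close_[f[, 3L]]
  if (!any(inContact)) return(0)
  sum(triangleAreas(mesh@vertices, f[inContact, , drop = FALSE]))
}

#' Peak membrane height above a reference plane
#'
#' @param mesh a [TriMesh-class].
#' @param referenceZ reference height (um).
#' @return maximum vertex z minus the reference (um).
#' @export
peakHeight <- function(mesh, referenceZ = 0) {
  stopifnot(is(mesh, "TriMesh"))
  max(mesh@vertices[, 3L]) - referenceZ
}

#' Export trajectory observables as CSV
#'
#' One row per iteration, stable column order; reading the file back
#' reproduces the numeric series exactly (within default read/write
#' precision of 15 significant digits).
#'
#' @param log a [TrajectoryLog-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportObservables <- function(log, path) {
  stopifnot(is(log, "TrajectoryLog"))
  df <- log@data
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  if (!nrow(df)) {
    writeLines(paste(names(df), collapse = ","), con)
    return(invisible(path))
  }
  utils::write.csv(format(df, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export mesh snapshots as numbered OBJ frames
#'
#' Writes one OBJ per snapshot, named `frame_<iteration>.obj` with the
#' iteration zero-padded, into `dir`.
#'
#' @param log a [TrajectoryLog-class] with snapshots.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
exportMeshFrames <- function(log, dir) {
  stopifnot(is(log, "TrajectoryLog"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  its <- as.integer(names(log@snapshots))
  width <- max(6L, nchar(max(c(its, 0L))))
  paths <- character(length(its))
  for (k in seq_along(its)) {
    paths[k] <- file.path(dir, sprintf("frame_%0*d.obj", width, its[k]))
    writeOBJ(log@snapshots[[k]], paths[k])
  }
  invisible(paths)
}

#' Estimate a diffusion coefficient from a 1D trajectory
#'
#' Least-squares slope of the ensemble mean-squared displacement against
#' time over the first quarter of the lag range, divided by 2 (a
#' one-dimensional walk), reported in nm^2/us. A coefficient of
#' determination for the MSD fit is attached so that ballistic or
#' drifting series (quadratic MSD) are flagged by a poor linear fit.
#'
#' @param series numeric vector (single trajectory) or a matrix with one
#'   replicate per column, positions in um per iteration.
#' @param dt iteration duration (us).
#' @return list with `D` (nm^2/us), `r2` of the MSD fit, and the `msd`
#'   data.frame (lag time us, msd nm^2).
#' @export
estimateDiffusion <- function(series, dt = 1) {
  m <- cbind(series)
  n <- nrow(m)
  if (n < 100L) stop("need at least 100 samples")
  maxLag <- max(2L, floor(n / 4))
  lags <- seq_len(maxLag)
  msd <- vapply(lags, function(L) {
    d <- m[(L + 1):n, , drop = FALSE] - m[1:(n - L), , drop = FALSE]
    mean(d^2)
  }, numeric(1)) * 1e6           # um^2 -> nm^2
  tt <- lags * dt                # us
  if (all(msd == 0))
    return(list(D = 0, r2 = 1,
                msd = data.frame(lag = tt, msd = msd)))
  fit <- stats::lm(msd ~ tt)
  D <- unname(stats::coef(fit)[2L]) / 2
  list(D = max(D, 0), r2 = summary(fit)$r.squared,
       msd = data.frame(lag = tt, msd = msd))
}

## rolling mean with window w (centered on trailing window), used to smooth
## noisy observable series before monotonicity checks
rollingMean <- function(x, w = 10L) {
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[-seq_len(w - 1L)]
}
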