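#' BOLD-like multivariate time series
#'
#' Container for a node-by-time matrix of signal values sampled at a fixed
#' repetition time (TR). Nodes are brain voxels, regions, or synthetic
#' units; columns are consecutive acquisitions.
#'
#' @param values numeric matrix, nodes in rows, time-points in columns.
#'   All entries must be finite and at least 2 nodes are required.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param node_ids optional character vector of node labels; defaults to
#'   the rownames of `values` or `"n1"`, `"n2"`, ...
#'
#' @return an object of class `bold_ts` with elements `values`,
#'   `tr_seconds` and `node_ids`.
#' @export
#' @examples
#' ts <- bold_ts(matrix(rnorm(40), nrow = 2), tr_seconds = 3)
#' n_timepoints(ts)
bold_ts <- function(values, tr_seconds, node_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L)
    stop("a bold_ts needs at least 2 nodes", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all signal values must be finite", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(values)))
  }
  if (length(node_ids) != nrow(values))
    stop("`node_ids` length must match the number of nodes", call. = FALSE)
  rownames(values) <- node_ids
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         node_ids = as.character(node_ids)),
    class = "bold_ts"
  )
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d nodes x %d time-points, TR = %g s (%.1f s total)\n",
              n_nodes(x), n_timepoints(x), x$tr_seconds,
              n_timepoints(x) * x$tr_seconds))
  invisible(x)
}

#' @rdname bold_ts
#' @param ts a `bold_ts` object.
#' @export
n_nodes <- function(ts) nrow(ts$values)

#' @rdname bold_ts
#' @export
n_timepoints <- function(ts) ncol(ts$values)

#' Discard initial acquisitions
#'
#' Removes the first `n_drop` volumes of a run, the usual guard against
#' T1-equilibration effects at the start of an EPI sequence (e.g. a
#' 124-volume run trimmed to 120 time-points).
#'
#' @param ts a [bold_ts] object.
#' @param n_drop number of leading time-points to discard (default 4).
#' @return the trimmed [bold_ts].
#' @export
drop_initial_volumes <- function(ts, n_drop = 4L) {
  stopifnot(inherits(ts, "bold_ts"))
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L || n_drop >= n_timepoints(ts))
    stop("`n_drop` must be in [0, T)", call. = FALSE)
  if (n_drop == 0L) return(ts)
  bold_ts(ts$values[, -seq_len(n_drop), drop = FALSE], ts$tr_seconds,
          ts$node_ids)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase
#' distortion) to every node series after mean removal. The conventional
#' resting-state band is 0.01-0.08 Hz.
#'
#' @param ts a [bold_ts] object.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 0.5 / tr_seconds` (the Nyquist frequency).
#' @param order Butterworth section order (default 2; the effective
#'   attenuation is doubled by the forward-backward pass).
#' @return the filtered [bold_ts]; same shape and node order.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 2L) {
  stopifnot(inherits(ts, "bold_ts"))
  nyq <- 0.5 / ts$tr_seconds
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz < 0 || low_hz >= high_hz || high_hz >= nyq)
    stop(sprintf(
      "invalid band [%g, %g] Hz: need 0 <= low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- ts$values - rowMeans(ts$values)
  filt <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  bold_ts(filt, ts$tr_seconds, ts$node_ids)
}

#' Read / write node-by-time TSV tables
#'
#' The on-disk layout is one row per node: a `node` column of labels
#' followed by one column per time-point. `write_timeseries()` also writes
#' a YAML sidecar (`<path>.yaml`) holding the repetition time and any
#' extra metadata, which `read_timeseries()` picks up automatically.
#'
#' @param ts a [bold_ts] object.
#' @param path file path of the TSV table.
#' @param metadata optional named list merged into the YAML sidecar.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a [bold_ts].
#' @export
write_timeseries <- function(ts, path, metadata = NULL) {
  stopifnot(inherits(ts, "bold_ts"))
  df <- data.frame(node = ts$node_ids, ts$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("node", paste0("t", seq_len(n_timepoints(ts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(tr_seconds = ts$tr_seconds, n_nodes = n_nodes(ts),
                 n_timepoints = n_timepoints(ts)), metadata)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr_seconds repetition time; required unless a YAML sidecar
#'   written by [write_timeseries()] sits next to `path`.
#' @export
read_timeseries <- function(path, tr_seconds = NULL) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"node" %in% colnames(df) || ncol(df) < 2L)
    stop(sprintf("malformed time-series table: %s (need a 'node' column plus time columns)",
                 path), call. = FALSE)
  side_path <- paste0(path, ".yaml")
  if (is.null(tr_seconds)) {
    if (!file.exists(side_path))
      stop(sprintf("no `tr_seconds` given and no sidecar found at %s",
                   side_path), call. = FALSE)
    tr_seconds <- yaml::read_yaml(side_path)$tr_seconds
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop(sprintf("malformed time-series table: %s (non-numeric values)", path),
         call. = FALSE)
  bold_ts(vals, tr_seconds, node_ids = as.character(df$node))
}

#' Extract node time series from a 4-D NIfTI volume
#'
#' Reduces a 4-D volume to a node-by-time matrix using a 3-D binary mask:
#' every nonzero mask voxel becomes one node, taken in column-major scan
#' order (x fastest, then y, then z). Voxel array coordinates are recorded
#' in the node ids (`"v<x>_<y>_<z>"`) and in the `voxels` attribute.
#'
#' @param volume_path path to a 4-D NIfTI image.
#' @param mask_path path to a 3-D NIfTI mask of matching spatial shape.
#' @param tr_seconds repetition time; if `NULL`, taken from the volume
#'   header.
#' @return a [bold_ts] with one node per mask voxel and an attribute
#'   `voxels` (matrix of array coordinates, one row per node).
#' @export
read_nifti_timeseries <- function(volume_path, mask_path, tr_seconds = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI input requires the RNifti package", call. = FALSE)
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  dv <- dim(vol); dm <- dim(msk)
  if (length(dv) != 4L)
    stop(sprintf("volume is not 4-D: %s", volume_path), call. = FALSE)
  if (length(dm) != 3L || !all(dv[1:3] == dm))
    stop(sprintf("mask shape does not match volume grid: %s vs %s",
                 mask_path, volume_path), call. = FALSE)
  sel <- which(msk != 0)             # column-major scan order
  if (length(sel) == 0L)
    stop(sprintf("mask selects zero voxels: %s", mask_path), call. = FALSE)
  coords <- arrayInd(sel, dm)
  nt <- dv[4L]
  flat <- matrix(as.numeric(vol), prod(dv[1:3]), nt)
  vals <- flat[sel, , drop = FALSE]
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(vol)[4L]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("could not infer TR from the NIfTI header; pass `tr_seconds`",
           call. = FALSE)
  }
  ids <- sprintf("v%d_%d_%d", coords[, 1L], coords[, 2L], coords[, 3L])
  out <- bold_ts(vals, tr_seconds, node_ids = ids)
  attr(out, "voxels") <- coords
  out
}
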