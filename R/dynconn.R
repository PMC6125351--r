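#' Sliding-window specification
#'
#' @param m window length in time-points (>= 3). With TR = 3 s the
#'   conventional 15-point window spans 45 s.
#' @param n sliding offset in time-points (>= 1); `n = 1` gives maximally
#'   overlapping windows and the smoothest network-state transitions.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(m = 15L, n = 1L) {
  m <- as.integer(m); n <- as.integer(n)
  if (is.na(m) || m < 3L) stop("window length `m` must be >= 3", call. = FALSE)
  if (is.na(n) || n < 1L) stop("window offset `n` must be >= 1", call. = FALSE)
  structure(list(m = m, n = n), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> m = %d time-points, offset n = %d\n", x$m, x$n))
  invisible(x)
}

#' Enumerate sliding-window intervals
#'
#' For a series of length `T`, window `i` covers the half-open, 0-based
#' interval `[(i-1)*n, (i-1)*n + m)`, for `i = 1 .. floor((T-m)/n) + 1`.
#' A 120-point series with `m = 15`, `n = 1` yields 106 windows.
#'
#' @param T series length in time-points.
#' @param spec a [window_spec].
#' @return integer matrix with columns `start` and `end` (0-based,
#'   half-open), one row per window.
#' @export
sliding_windows <- function(T, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  T <- as.integer(T)
  if (T < spec$m)
    stop(sprintf("series too short: T = %d < window length m = %d", T, spec$m),
         call. = FALSE)
  k <- (T - spec$m) %/% spec$n + 1L
  start <- (seq_len(k) - 1L) * spec$n
  cbind(start = start, end = start + spec$m)
}

#' Pearson correlation over one window
#'
#' Computes the node-by-node Pearson correlation matrix over a window
#' interval, with the diagonal set to zero (self-loops are meaningless for
#' walk counting and would dominate SFC matrix powers). A node whose
#' signal is constant inside the window has no defined correlation; its
#' row and column are zeroed and a warning is raised rather than aborting.
#'
#' @param ts a [bold_ts] object.
#' @param interval length-2 integer vector `c(start, end)`, 0-based and
#'   half-open, as produced by [sliding_windows()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
window_correlation <- function(ts, interval) {
  stopifnot(inherits(ts, "bold_ts"))
  start <- as.integer(interval[[1L]]); end <- as.integer(interval[[2L]])
  if (start < 0L || end > n_timepoints(ts) || end - start < 3L)
    stop("interval out of range or shorter than 3 time-points", call. = FALSE)
  seg <- ts$values[, (start + 1L):end, drop = FALSE]
  sds <- apply(seg, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  R <- matrix(0, nrow(seg), nrow(seg),
              dimnames = list(ts$node_ids, ts$node_ids))
  ok <- which(!flat)
  if (length(ok) >= 2L)
    R[ok, ok] <- stats::cor(t(seg[ok, , drop = FALSE]))
  if (any(flat)) {
    warning(sprintf("zero-variance node(s) in window [%d,%d): %s (rows/cols zeroed)",
                    start, end, paste(ts$node_ids[flat], collapse = ", ")),
            call. = FALSE)
  }
  diag(R) <- 0
  R
}

#' Fisher variance-stabilizing transformation
#'
#' Elementwise `z = atanh(r)`. Coefficients with `|r| >= 1 - 1e-7`
#' (numerically perfect correlations) are clipped to `1 - 1e-7` before the
#' transform so that downstream matrix powers stay finite; values beyond 1
#' by more than rounding tolerance are an error.
#'
#' @param R numeric matrix (or vector) of correlation coefficients.
#' @return matrix of Fisher-z values, same shape.
#' @export
fisher_z <- function(R) {
  if (any(abs(R) > 1 + 1e-8, na.rm = TRUE))
    stop("invalid correlation: |r| > 1", call. = FALSE)
  clip <- 1 - 1e-7
  atanh(pmin(pmax(R, -clip), clip))
}

new_dynconn_stack <- function(windows, spec, sign, tr_seconds, node_ids) {
  structure(list(windows = windows, spec = spec, sign = sign,
                 tr_seconds = tr_seconds, node_ids = node_ids),
            class = "dynconn_stack")
}

#' Dynamic connectivity stack
#'
#' Slides a window along a time series and computes, per window, the
#' Fisher-transformed Pearson correlation matrix between all node pairs.
#' The result is the ordered sequence of network snapshots that all
#' downstream analyses (SFC, topology transitions) consume.
#'
#' @param ts a [bold_ts] object.
#' @param spec a [window_spec]; the default is the 15-point window with
#'   offset 1.
#' @return an object of class `dynconn_stack`: a list with `windows`
#'   (node x node x window array of Fisher-z values, zero diagonal),
#'   `spec`, `sign` (`"full"`), `tr_seconds` and `node_ids`.
#' @seealso [sign_split()], [sfc_stack()], [transition_series()]
#' @export
dyn_connectivity <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "bold_ts"))
  iv <- sliding_windows(n_timepoints(ts), spec)
  n <- n_nodes(ts)
  arr <- array(0, dim = c(n, n, nrow(iv)),
               dimnames = list(ts$node_ids, ts$node_ids, NULL))
  for (w in seq_len(nrow(iv)))
    arr[, , w] <- fisher_z(window_correlation(ts, iv[w, ]))
  new_dynconn_stack(arr, spec, "full", ts$tr_seconds, ts$node_ids)
}

#' @export
print.dynconn_stack <- function(x, ...) {
  cat(sprintf("<dynconn_stack:%s> %d nodes, %d windows (m = %d, n = %d)\n",
              x$sign, length(x$node_ids), n_windows(x), x$spec$m, x$spec$n))
  invisible(x)
}

#' @rdname dyn_connectivity
#' @param stack a `dynconn_stack`.
#' @export
n_windows <- function(stack) dim(stack$windows)[3L]

#' Split a connectivity stack by correlation sign
#'
#' Separates every window matrix into its positive part (entries > 0,
#' zeros elsewhere) and its negative part (entries < 0, kept with their
#' negative values). The two parts sum back to the input exactly.
#'
#' @param stack a full-sign `dynconn_stack` from [dyn_connectivity()].
#' @return list with elements `positive` and `negative`, each a
#'   `dynconn_stack` of the corresponding sign.
#' @export
sign_split <- function(stack) {
  stopifnot(inherits(stack, "dynconn_stack"))
  if (!identical(stack$sign, "full"))
    stop("sign_split() expects a full-sign stack", call. = FALSE)
  pos <- stack$windows; pos[pos < 0] <- 0
  neg <- stack$windows; neg[neg > 0] <- 0
  list(
    positive = new_dynconn_stack(pos, stack$spec, "positive",
                                 stack$tr_seconds, stack$node_ids),
    negative = new_dynconn_stack(neg, stack$spec, "negative",
                                 stack$tr_seconds, stack$node_ids)
  )
}
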