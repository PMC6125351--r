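#' Stepwise functional connectivity matrices for one window
#'
#' Given the positive-connection weight matrix `A` of one window (zero
#' diagonal, non-negative entries), the step-`l` SFC matrix is defined
#' recursively: `A_1 = A` and `A_l = A_{l-1} %*% A` for `l >= 2`, so
#' `A_l(i, j)` accumulates the products of edge weights over every
#' length-`l` walk from `i` to `j`. Step 1 is excluded from the returned
#' stack: a directly connected pair cannot simultaneously carry a negative
#' correlation, so the analysis of negative strength versus positive path
#' length starts at step 2.
#'
#' Note the recursion counts weighted *walks* (revisits allowed), not
#' simple paths; the zero-diagonal convention limits self-loop inflation.
#' It is implemented exactly as defined.
#'
#' @param pos_window square numeric matrix of non-negative weights with
#'   zero diagonal (one window of the positive stack).
#' @param l_max largest step distance (default 7, where weighted SFC
#'   patterns are empirically stable).
#' @return numeric array `n x n x (l_max - 1)`, third dimension named
#'   `"2" ... as.character(l_max)`.
#' @export
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.5; A[2, 3] <- A[3, 2] <- 0.4
#' sfc_matrices(A)[1, 3, "2"]   # one 2-step walk: 0.5 * 0.4
sfc_matrices <- function(pos_window, l_max = 7L) {
  pos_window <- as.matrix(pos_window)
  l_max <- as.integer(l_max)
  if (l_max < 2L) stop("`l_max` must be >= 2", call. = FALSE)
  if (nrow(pos_window) != ncol(pos_window))
    stop("input must be square", call. = FALSE)
  if (any(pos_window < 0))
    stop("invalid input: negative entries in a positive-connection matrix",
         call. = FALSE)
  if (any(diag(pos_window) != 0))
    stop("invalid input: diagonal must be zero", call. = FALSE)
  n <- nrow(pos_window)
  steps <- 2:l_max
  out <- array(0, dim = c(n, n, length(steps)),
               dimnames = list(rownames(pos_window), colnames(pos_window),
                               as.character(steps)))
  Al <- pos_window
  for (l in steps) {
    Al <- Al %*% pos_window
    out[, , as.character(l)] <- Al
  }
  out
}

new_sfc_stack <- function(arr, steps, normalized, node_ids) {
  structure(list(values = arr, steps = steps, normalized = normalized,
                 node_ids = node_ids),
            class = "sfc_stack")
}

#' Stepwise functional connectivity across all windows
#'
#' Applies [sfc_matrices()] to every window of a positive connectivity
#' stack.
#'
#' @param pos_stack a positive-sign `dynconn_stack` from [sign_split()].
#' @param l_max largest step distance (default 7).
#' @return an object of class `sfc_stack`: `values` is a
#'   `n x n x steps x windows` array, `steps` the step distances
#'   (2..l_max), `normalized` a flag.
#' @export
sfc_stack <- function(pos_stack, l_max = 7L) {
  stopifnot(inherits(pos_stack, "dynconn_stack"))
  if (!identical(pos_stack$sign, "positive"))
    stop("sfc_stack() expects the positive stack", call. = FALSE)
  W <- n_windows(pos_stack)
  n <- length(pos_stack$node_ids)
  steps <- 2:as.integer(l_max)
  arr <- array(0, dim = c(n, n, length(steps), W),
               dimnames = list(pos_stack$node_ids, pos_stack$node_ids,
                               as.character(steps), NULL))
  for (w in seq_len(W))
    arr[, , , w] <- sfc_matrices(pos_stack$windows[, , w], l_max = l_max)
  new_sfc_stack(arr, steps, FALSE, pos_stack$node_ids)
}

#' @export
print.sfc_stack <- function(x, ...) {
  cat(sprintf("<sfc_stack%s> %d nodes, steps %d..%d, %d windows\n",
              if (x$normalized) ":normalized" else "",
              length(x$node_ids), min(x$steps), max(x$steps),
              dim(x$values)[4L]))
  invisible(x)
}

#' Min-max normalization of SFC matrices
#'
#' Rescales SFC values to `[0, 1]` -- each value minus the minimum,
#' divided by the range -- so that degrees become comparable across step
#' distances before the optimal-distance argmax. The default scope
#' rescales each (window, step) matrix over its off-diagonal entries,
#' because the argmax is taken within one window and the `c^l` scale
#' covariance of matrix powers would otherwise let long steps dominate or
#' vanish; `scope = "pooled"` instead pools the extrema across windows per
#' step. A constant matrix maps to all zeros.
#'
#' @param stack an un-normalized `sfc_stack`.
#' @param scope `"window"` (default) or `"pooled"`.
#' @return the normalized `sfc_stack`.
#' @export
normalize_sfc <- function(stack, scope = c("window", "pooled")) {
  stopifnot(inherits(stack, "sfc_stack"))
  scope <- match.arg(scope)
  if (stack$normalized)
    stop("stack is already normalized", call. = FALSE)
  arr <- stack$values
  n <- dim(arr)[1L]
  off <- !diag(TRUE, n)
  rescale <- function(M, lo, hi) {
    out <- matrix(0, n, n)
    if (hi > lo) out[off] <- (M[off] - lo) / (hi - lo)
    out
  }
  for (s in seq_along(stack$steps)) {
    if (scope == "pooled") {
      vals <- arr[, , s, , drop = FALSE]
      sel <- as.vector(array(off, dim = dim(vals)))
      lo <- min(vals[sel]); hi <- max(vals[sel])
      for (w in seq_len(dim(arr)[4L]))
        arr[, , s, w] <- rescale(arr[, , s, w], lo, hi)
    } else {
      for (w in seq_len(dim(arr)[4L])) {
        M <- arr[, , s, w]
        arr[, , s, w] <- rescale(M, min(M[off]), max(M[off]))
      }
    }
  }
  new_sfc_stack(arr, stack$steps, TRUE, stack$node_ids)
}

#' Optimal step distance per node pair
#'
#' For every pair and window, the optimal distance `OD(i, j)` is the step
#' `l` at which the normalized SFC value is maximal -- the network
#' geodesic proxy through positive connections. Ties break toward the
#' smallest step (the conservative, shortest-distance reading); pairs
#' whose values are zero at every step carry no walk information and are
#' missing (`NA`).
#'
#' @param stack a *normalized* `sfc_stack` (see [normalize_sfc()]).
#' @return an object of class `od_map`: `per_window` is a
#'   `n x n x windows` array of step distances (NA where undefined, NA
#'   diagonal), `time_avg` the across-window mean per pair, `steps` the
#'   step range.
#' @export
optimal_distance <- function(stack) {
  stopifnot(inherits(stack, "sfc_stack"))
  if (!stack$normalized)
    stop("optimal_distance() requires a normalized sfc_stack; call normalize_sfc() first",
         call. = FALSE)
  dm <- dim(stack$values)
  n <- dm[1L]; S <- dm[3L]; W <- dm[4L]
  od <- array(NA_real_, dim = c(n, n, W),
              dimnames = list(stack$node_ids, stack$node_ids, NULL))
  for (w in seq_len(W)) {
    vals <- matrix(stack$values[, , , w], n * n, S)   # pairs x steps
    any_pos <- rowSums(vals > 0) > 0L
    best <- max.col(vals, ties.method = "first")      # smallest step wins ties
    ow <- ifelse(any_pos, stack$steps[best], NA_real_)
    ow <- matrix(ow, n, n)
    ## matrix powers are symmetric in exact arithmetic but BLAS summation
    ## order can perturb near-ties; mirror the upper triangle
    ow[lower.tri(ow)] <- t(ow)[lower.tri(ow)]
    diag(ow) <- NA_real_
    od[, , w] <- ow
  }
  avg <- apply(od, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  structure(list(per_window = od, time_avg = avg, steps = stack$steps,
                 node_ids = stack$node_ids),
            class = "od_map")
}

#' @export
print.od_map <- function(x, ...) {
  cat(sprintf("<od_map> %d nodes, %d windows, steps %d..%d\n",
              length(x$node_ids), dim(x$per_window)[3L],
              min(x$steps), max(x$steps)))
  invisible(x)
}

#' Optimal distance versus negative correlation strength
#'
#' Relates each pair's average optimal step distance (over the windows
#' where it is defined) to its average negative correlation value (over
#' the windows where the pair is negative). Pairs are binned by the
#' rounded average optimal distance; the curve starts at step 2 because a
#' directly connected positive pair cannot carry a simultaneous negative
#' value. Dispersion is the standard deviation of the per-pair averages
#' within each bin.
#'
#' @param od an `od_map` from [optimal_distance()].
#' @param neg_stack the negative `dynconn_stack` from [sign_split()].
#' @param values `"r"` (default) reports negative values on the
#'   correlation scale (inverse Fisher transform applied); `"fisher"`
#'   keeps the Fisher-z scale.
#' @param include_positive_as_zero if `TRUE`, windows where the pair is
#'   not negative enter its average as zeros; the default averages only
#'   over windows where the pair is negative.
#' @return data.frame with columns `step_bin`, `mean_negative`,
#'   `sd_negative`, `n_pairs`, one row per occupied bin (class
#'   `od_negativity_curve`).
#' @export
od_negativity_curve <- function(od, neg_stack,
                                values = c("r", "fisher"),
                                include_positive_as_zero = FALSE) {
  stopifnot(inherits(od, "od_map"), inherits(neg_stack, "dynconn_stack"))
  values <- match.arg(values)
  if (!identical(neg_stack$sign, "negative"))
    stop("`neg_stack` must be the negative stack", call. = FALSE)
  dmo <- dim(od$per_window); dmn <- dim(neg_stack$windows)
  if (!all(dmo == dmn))
    stop(sprintf("shape mismatch: OD maps are %s, negative stack is %s",
                 paste(dmo, collapse = "x"), paste(dmn, collapse = "x")),
         call. = FALSE)
  n <- dmo[1L]
  neg <- neg_stack$windows
  if (values == "r") neg <- tanh(neg)
  pair_mean_neg <- apply(neg, c(1L, 2L), function(v) {
    isneg <- v < 0
    if (include_positive_as_zero) {
      if (length(v)) mean(pmin(v, 0)) else NA_real_
    } else {
      if (any(isneg)) mean(v[isneg]) else NA_real_
    }
  })
  ut <- upper.tri(matrix(0, n, n))
  od_avg <- od$time_avg[ut]
  neg_avg <- pair_mean_neg[ut]
  keep <- !is.na(od_avg) & !is.na(neg_avg)
  bins <- pmin(pmax(round(od_avg[keep]), min(od$steps)), max(od$steps))
  vals <- neg_avg[keep]
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    v <- vals[bins == b]
    data.frame(step_bin = b, mean_negative = mean(v),
               sd_negative = if (length(v) > 1L) stats::sd(v) else 0,
               n_pairs = length(v))
  }))
  if (is.null(out))
    out <- data.frame(step_bin = integer(), mean_negative = numeric(),
                      sd_negative = numeric(), n_pairs = integer())
  class(out) <- c("od_negativity_curve", "data.frame")
  out
}
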