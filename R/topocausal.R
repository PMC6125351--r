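#' Node-level topology transition series
#'
#' For each node `i` and each consecutive window pair `(t, t+1)`, the
#' Euclidean distance between the node's two network configurations (its
#' "star network", i.e. its row of the association matrix):
#' `D(i, t) = sqrt( sum_j (r_t(i, j) - r_{t+1}(i, j))^2 )` over `j != i`.
#' Small values mean the node's connectivity pattern resembles itself
#' across the two windows; large values mark a topological reconfiguration.
#' Distances are computed on the stack's stored values (Fisher-z by
#' default upstream); for the negative stack the stored negative values
#' are equivalent to magnitudes since differences are squared within one
#' sign class.
#'
#' @param stack a positive- or negative-sign `dynconn_stack` with at
#'   least 2 windows.
#' @return an object of class `transition_series`: a numeric
#'   `nodes x (windows - 1)` matrix with attributes `sign` and `spec`.
#' @export
transition_series <- function(stack) {
  stopifnot(inherits(stack, "dynconn_stack"))
  W <- n_windows(stack)
  if (W < 2L)
    stop("too few windows: need at least 2 to form a transition", call. = FALSE)
  d <- stack$windows[, , 2:W, drop = FALSE] -
       stack$windows[, , 1:(W - 1L), drop = FALSE]
  out <- sqrt(apply(d^2, c(1L, 3L), sum))   # diagonal differences are zero
  out <- matrix(out, nrow = dim(d)[1L], dimnames = list(stack$node_ids, NULL))
  structure(out, sign = stack$sign, spec = stack$spec,
            class = c("transition_series", "matrix", "array"))
}

#' Granger F-test between two series
#'
#' Tests whether past values of `x` improve the prediction of `y` beyond
#' `y`'s own past: the restricted model regresses `y(t)` on a constant and
#' its own `order` lags; the full model adds `x`'s `order` lags. The F
#' statistic compares the two nested fits with `(order, n_eff - 2*order -
#' 1)` degrees of freedom, where `n_eff = length(y) - order`. A
#' significant F supports "`x` Granger-causes `y`".
#'
#' Degenerate inputs (constant or collinear series, rank-deficient
#' designs) yield `F = 0`, `p = 1` and a warning instead of an error.
#'
#' @param x candidate cause series.
#' @param y effect series (same length).
#' @param order lag order `p >= 1` shared by both lag blocks.
#' @return list with `F`, `p`, `order`, `df1`, `df2`, `degenerate`.
#' @export
granger_f <- function(x, y, order) {
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  N <- length(y)
  df2 <- (N - order) - 2L * order - 1L
  if (df2 < 1L)
    stop(sprintf("series too short for order %d: need length > 3*order + 1",
                 order), call. = FALSE)
  idx <- (order + 1L):N
  ylags <- vapply(seq_len(order), function(k) y[idx - k], numeric(length(idx)))
  xlags <- vapply(seq_len(order), function(k) x[idx - k], numeric(length(idx)))
  yy <- y[idx]
  deg <- function() {
    warning("degenerate Granger regression (constant or collinear series); returning p = 1",
            call. = FALSE)
    list(F = 0, p = 1, order = order, df1 = order, df2 = df2,
         degenerate = TRUE)
  }
  Xr <- cbind(1, ylags)
  Xf <- cbind(1, ylags, xlags)
  if (qr(Xf)$rank < ncol(Xf)) return(deg())
  rss0 <- sum(stats::lm.fit(Xr, yy)$residuals^2)
  rss1 <- sum(stats::lm.fit(Xf, yy)$residuals^2)
  if (!is.finite(rss0) || !is.finite(rss1) || rss1 <= 0) {
    if (rss0 <= .Machine$double.eps * sum(yy^2)) return(deg())
    rss1 <- max(rss1, .Machine$double.eps * rss0)
  }
  Fstat <- ((rss0 - rss1) / order) / (rss1 / df2)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, order, df2, lower.tail = FALSE),
       order = order, df1 = order, df2 = df2, degenerate = FALSE)
}

#' Lag order selection by Bayesian information criterion
#'
#' Fits the full bivariate-lag regression (`y` on its own and `x`'s lags,
#' shared order `p = q`) for each candidate order `1 .. max_lag` over a
#' common estimation sample, and returns the order minimizing the BIC.
#' With `symmetric = TRUE` the criterion sums the BICs of both directional
#' full models, so the chosen lag is invariant to swapping `x` and `y`
#' (used by [causality_map()] to give both directional tests one shared
#' lag).
#'
#' @param x,y equal-length numeric series.
#' @param max_lag largest candidate order (default 5).
#' @param symmetric if `TRUE`, select the lag on both directions jointly.
#' @return the selected integer lag in `1 .. max_lag`.
#' @export
bic_lag <- function(x, y, max_lag = 5L, symmetric = FALSE) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("`max_lag` must be >= 1", call. = FALSE)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  N <- length(y)
  if (N <= 3L * max_lag + 3L)
    stop(sprintf("series too short for lag selection: need length > %d",
                 3L * max_lag + 3L), call. = FALSE)
  idx <- (max_lag + 1L):N            # common sample across candidate orders
  ne <- length(idx)
  bic_dir <- function(a, b, p) {     # full model: b on lags of b and a
    blags <- vapply(seq_len(p), function(k) b[idx - k], numeric(ne))
    alags <- vapply(seq_len(p), function(k) a[idx - k], numeric(ne))
    rss <- sum(stats::lm.fit(cbind(1, blags, alags), b[idx])$residuals^2)
    rss <- max(rss, .Machine$double.xmin)
    ne * log(rss / ne) + (2L * p + 1L) * log(ne)
  }
  scores <- vapply(seq_len(max_lag), function(p) {
    s <- bic_dir(x, y, p)
    if (symmetric) s <- s + bic_dir(y, x, p)
    s
  }, numeric(1L))
  which.min(scores)                  # ties break toward the smallest lag
}

#' Benjamini-Hochberg false discovery rate flags
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' reject the `k` smallest where `k` is the largest index with
#' `p_(k) <= k * q / m`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed and
#'   never rejected).
#' @param q target FDR level (default 0.05).
#' @return logical vector of rejection flags, same length as `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(logical(0L))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Granger analysis specification
#'
#' @param max_lag largest candidate lag order for [bic_lag()] (default 5).
#' @param alpha per-node significance level (default 0.05).
#' @param fdr_q Benjamini-Hochberg q-level across nodes (default 0.05).
#' @param clamp_quantile percentile used to normalize the F-difference
#'   scores for display (default 0.98: absolute differences are clamped at
#'   their 98th percentile and rescaled to `[-1, 1]`).
#' @return an object of class `granger_spec`.
#' @export
granger_spec <- function(max_lag = 5L, alpha = 0.05, fdr_q = 0.05,
                         clamp_quantile = 0.98) {
  stopifnot(max_lag >= 1L, alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1,
            clamp_quantile > 0, clamp_quantile <= 1)
  structure(list(max_lag = as.integer(max_lag), alpha = alpha, fdr_q = fdr_q,
                 clamp_quantile = clamp_quantile),
            class = "granger_spec")
}

#' Node-wise Granger causality between positive and negative transitions
#'
#' For every node, selects one shared lag (symmetric BIC over both
#' directional full models, candidates `1 .. max_lag`), then tests both
#' hypotheses: positive-explains-negative (`F_pn`: past positive
#' transitions improve prediction of negative transitions) and
#' negative-explains-positive (`F_np`). FDR flags are computed across
#' nodes separately per direction. The difference score is
#' `F_pn - F_np` after a percentile normalization: absolute differences
#' are clamped at their `clamp_quantile` percentile across nodes and
#' rescaled to `[-1, 1]`, so positive scores mark nodes where positive
#' topology changes dominate in predicting negative ones.
#'
#' A failure in one node (e.g. a degenerate flat series) flags that node
#' as missing rather than aborting the run.
#'
#' @param pos,neg `transition_series` for the positive and negative
#'   networks (matching node sets and lengths).
#' @param spec a [granger_spec].
#' @return data.frame of class `causality_map` with one row per node:
#'   `node`, `lag`, `F_pn`, `F_np`, `p_pn`, `p_np`, `sig_pn`, `sig_np`
#'   (alpha-level flags), `fdr_pn`, `fdr_np`, `diff_raw`, `diff_score`,
#'   `failed`.
#' @export
causality_map <- function(pos, neg, spec = granger_spec()) {
  stopifnot(inherits(pos, "transition_series"),
            inherits(neg, "transition_series"),
            inherits(spec, "granger_spec"))
  if (!all(dim(pos) == dim(neg)) ||
      !identical(rownames(pos), rownames(neg)))
    stop("positive and negative transition series must share node set and length",
         call. = FALSE)
  n <- nrow(pos)
  res <- lapply(seq_len(n), function(i) {
    tryCatch({
      x <- pos[i, ]; y <- neg[i, ]
      lag <- bic_lag(x, y, max_lag = spec$max_lag, symmetric = TRUE)
      pn <- granger_f(x, y, lag)    # positive explains negative
      np <- granger_f(y, x, lag)
      list(lag = lag, F_pn = pn$F, F_np = np$F, p_pn = pn$p, p_np = np$p,
           failed = pn$degenerate && np$degenerate)
    }, error = function(e) {
      warning(sprintf("node %s failed: %s", rownames(pos)[i],
                      conditionMessage(e)), call. = FALSE)
      list(lag = NA_integer_, F_pn = NA_real_, F_np = NA_real_,
           p_pn = NA_real_, p_np = NA_real_, failed = TRUE)
    })
  })
  get <- function(f) vapply(res, function(r) as.numeric(r[[f]]), numeric(1L))
  out <- data.frame(
    node = if (!is.null(rownames(pos))) rownames(pos)
           else paste0("n", seq_len(n)),
    lag = as.integer(get("lag")),
    F_pn = get("F_pn"), F_np = get("F_np"),
    p_pn = get("p_pn"), p_np = get("p_np"),
    stringsAsFactors = FALSE
  )
  out$sig_pn <- !is.na(out$p_pn) & out$p_pn < spec$alpha
  out$sig_np <- !is.na(out$p_np) & out$p_np < spec$alpha
  out$fdr_pn <- fdr_bh(out$p_pn, q = spec$fdr_q)
  out$fdr_np <- fdr_bh(out$p_np, q = spec$fdr_q)
  out$diff_raw <- out$F_pn - out$F_np
  cq <- stats::quantile(abs(out$diff_raw), probs = spec$clamp_quantile,
                        na.rm = TRUE, names = FALSE)
  out$diff_score <- if (!is.finite(cq) || cq == 0) {
    ifelse(is.na(out$diff_raw), NA_real_, 0)
  } else {
    pmin(pmax(out$diff_raw, -cq), cq) / cq
  }
  out$failed <- vapply(res, function(r) isTRUE(r$failed), logical(1L))
  class(out) <- c("causality_map", "data.frame")
  out
}
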