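#' Seeded VAR-style series pair for Granger testing
#'
#' Generates `x` as white noise and `y(t) = beta * x(t - lag) + e(t)` with
#' white noise `e`, then standardizes both series to zero mean and unit
#' variance. With `beta = 0` the pair is independent (null calibration
#' fixture); with `beta > 0`, `x` Granger-causes `y` at the given lag.
#'
#' @param n series length (>= 20).
#' @param beta cross coefficient (0 for the null).
#' @param lag causal lag in steps (>= 1).
#' @param noise_sd innovation standard deviation of `y` (>= 0).
#' @param seed integer seed; identical arguments reproduce the series
#'   bit for bit.
#' @return list with numeric vectors `x` and `y` of length `n`.
#' @export
gen_var_pair <- function(n, beta = 0, lag = 1L, noise_sd = 1, seed = 1L) {
  n <- as.integer(n); lag <- as.integer(lag)
  if (is.na(n) || n <= 0L || is.na(lag) || lag <= 0L || noise_sd < 0)
    stop("invalid config: need n > 0, lag > 0, noise_sd >= 0", call. = FALSE)
  if (n < 20L)
    stop("invalid config: n must be >= 20", call. = FALSE)
  if (n <= 3L * lag + 3L)
    stop("invalid config: n too short for the requested lag", call. = FALSE)
  rng <- local({ set.seed(as.integer(seed)); list(x = stats::rnorm(n),
                                                  e = stats::rnorm(n)) })
  x <- rng$x
  y <- noise_sd * rng$e
  y[(lag + 1L):n] <- y[(lag + 1L):n] + beta * x[1L:(n - lag)]
  std <- function(v) { v <- v - mean(v); s <- stats::sd(v)
                       if (s > 0) v / s else v }
  list(x = std(x), y = std(y))
}

#' Configuration for the phase-lag chain generator
#'
#' Describes a chain of positively coupled modules in which a common
#' oscillation propagates with a fixed per-hop delay, so that modules far
#' apart drift out of phase and eventually anti-correlate: negative
#' correlations arise purely from propagation lag and graph distance, not
#' from any opposing force.
#'
#' With a sinusoidal base at period `base_period_s`, the correlation
#' between nodes `d` modules apart (at zero noise) is exactly
#' `cos(2*pi*d*hop_lag_s / base_period_s)` -- the closed-form oracle the
#' generator is tested against.
#'
#' @param n_modules number of chain modules (>= 2).
#' @param nodes_per_module nodes per module (default 1; at zero noise,
#'   multiple nodes in one module are identical copies whose r = 1 edges
#'   saturate the Fisher transform, so single-node modules are the clean
#'   default for oracle work; use more nodes together with noise).
#' @param n_timepoints series length (must cover at least two base
#'   periods).
#' @param tr_seconds sampling interval in seconds.
#' @param base_period_s period of the dominant oscillation in seconds.
#' @param hop_lag_s propagation delay per module hop in seconds (>= 0).
#' @param noise_sd standard deviation of additive node noise, in signal
#'   units (the base oscillation has amplitude 1).
#' @param base `"sinusoid"` (default; admits the exact cosine oracle) or
#'   `"bandlimited"` (0.01-0.08 Hz filtered white noise, delayed per
#'   module by Fourier phase shift, for more realistic spectra).
#' @param seed integer seed.
#' @return an object of class `lag_chain_config`.
#' @export
lag_chain_config <- function(n_modules = 6L, nodes_per_module = 1L,
                             n_timepoints = 120L, tr_seconds = 3,
                             base_period_s = 30, hop_lag_s = 3,
                             noise_sd = 0.1, base = c("sinusoid", "bandlimited"),
                             seed = 1L) {
  base <- match.arg(base)
  n_modules <- as.integer(n_modules)
  nodes_per_module <- as.integer(nodes_per_module)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_modules) || n_modules < 2L)
    stop("invalid config: need at least 2 modules", call. = FALSE)
  if (nodes_per_module < 1L)
    stop("invalid config: nodes_per_module must be >= 1", call. = FALSE)
  if (hop_lag_s < 0 || base_period_s <= 0 || tr_seconds <= 0 || noise_sd < 0)
    stop("invalid config: need hop_lag_s >= 0, base_period_s > 0, tr_seconds > 0, noise_sd >= 0",
         call. = FALSE)
  if (n_timepoints < 2 * base_period_s / tr_seconds)
    stop("invalid config: series must cover at least two base periods",
         call. = FALSE)
  structure(list(n_modules = n_modules, nodes_per_module = nodes_per_module,
                 n_timepoints = n_timepoints, tr_seconds = tr_seconds,
                 base_period_s = base_period_s, hop_lag_s = hop_lag_s,
                 noise_sd = noise_sd, base = base, seed = as.integer(seed)),
            class = "lag_chain_config")
}

#' Generate a phase-lag chain time series
#'
#' Module `k` (k = 1..n_modules) carries the base oscillation delayed by
#' `(k - 1) * hop_lag_s` seconds; every node adds independent Gaussian
#' noise. See [lag_chain_config()] for the closed-form correlation
#' structure this generator plants.
#'
#' @param cfg a [lag_chain_config].
#' @return a [bold_ts] with attributes `modules` (integer module index
#'   per node) and `config`.
#' @export
gen_lag_chain <- function(cfg = lag_chain_config()) {
  stopifnot(inherits(cfg, "lag_chain_config"))
  set.seed(cfg$seed)
  K <- cfg$n_modules; npm <- cfg$nodes_per_module
  Tn <- cfg$n_timepoints
  tvec <- (seq_len(Tn) - 1L) * cfg$tr_seconds
  base_at <- if (cfg$base == "sinusoid") {
    function(delay) sin(2 * pi * (tvec - delay) / cfg$base_period_s)
  } else {
    w <- stats::rnorm(Tn)
    nyq <- 0.5 / cfg$tr_seconds
    bf <- signal::butter(2, c(0.01, min(0.08, 0.9 * nyq)) / nyq, type = "pass")
    b0 <- signal::filtfilt(bf, w)
    b0 <- b0 / stats::sd(b0)
    ft <- stats::fft(b0)
    freqs <- c(0:(Tn %/% 2), -((Tn - Tn %/% 2 - 1L):1)) / (Tn * cfg$tr_seconds)
    function(delay) {   # circular Fourier phase shift by `delay` seconds
      Re(stats::fft(ft * exp(-2i * pi * freqs * delay), inverse = TRUE)) / Tn
    }
  }
  modules <- rep(seq_len(K), each = npm)
  vals <- matrix(0, K * npm, Tn)
  for (k in seq_len(K)) {
    s <- base_at((k - 1L) * cfg$hop_lag_s)
    rows <- which(modules == k)
    vals[rows, ] <- matrix(s, length(rows), Tn, byrow = TRUE)
  }
  if (cfg$noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), sd = cfg$noise_sd),
                          nrow(vals), Tn)
  ids <- sprintf("m%02d_n%02d", modules,
                 as.integer(stats::ave(modules, modules, FUN = seq_along)))
  out <- bold_ts(vals, cfg$tr_seconds, node_ids = ids)
  attr(out, "modules") <- modules
  attr(out, "config") <- cfg
  out
}

#' Configuration for the follower (causality) generator
#'
#' Describes a piecewise-stationary signal in which the set of positively
#' coupled nodes is reshuffled across blocks while the anti-phase
#' (negative) structure mirrors the positive set of `follow_lag_blocks`
#' blocks earlier -- so reconfigurations of the positive network precede
#' reconfigurations of the negative network by a known lag. Within block
#' `b`, members of the positive set share a latent signal `u_b`; every
#' node also carries a second shared latent `w_b` whose sign (+1 for
#' members of the lag-`follow_lag_blocks`-old positive set, -1 otherwise)
#' creates genuine negative window correlations between the two sign
#' groups without any filtering artifacts.
#'
#' @param n_nodes number of nodes (>= 8).
#' @param n_blocks number of stationary blocks.
#' @param block_len_windows block length, counted in non-overlapping
#'   analysis windows of `window_len` time-points (default 1: each block
#'   is exactly one window, so every window-to-window transition straddles
#'   one block boundary and the transition series carries no deterministic
#'   within-block periodicity).
#' @param follow_lag_blocks lag, in blocks, by which the negative
#'   structure trails the positive structure (>= 1).
#' @param coupling_strength latent coupling amplitude in (0, 1].
#' @param noise_sd standard deviation of independent node noise.
#' @param reconfig_prob per-block probability that a node's positive-set
#'   membership flips (Markov persistence; 0.5 reproduces independent
#'   redraws, 0 freezes the couplings).
#' @param window_len length in time-points of the analysis window the
#'   blocks are sized for (default 15).
#' @param seed integer seed.
#' @return an object of class `follower_config`.
#' @export
follower_config <- function(n_nodes = 40L, n_blocks = 80L,
                            block_len_windows = 1L, follow_lag_blocks = 1L,
                            coupling_strength = 0.9, noise_sd = 0.3,
                            reconfig_prob = 0.3, window_len = 15L,
                            seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_blocks <- as.integer(n_blocks)
  block_len_windows <- as.integer(block_len_windows)
  follow_lag_blocks <- as.integer(follow_lag_blocks)
  window_len <- as.integer(window_len)
  if (is.na(n_nodes) || n_nodes < 8L)
    stop("invalid config: need at least 8 nodes", call. = FALSE)
  if (is.na(follow_lag_blocks) || follow_lag_blocks < 1L)
    stop("invalid config: follow_lag_blocks must be >= 1", call. = FALSE)
  if (is.na(n_blocks) || n_blocks < follow_lag_blocks + 2L)
    stop("invalid config: n_blocks must be >= follow_lag_blocks + 2",
         call. = FALSE)
  if (is.na(block_len_windows) || block_len_windows < 1L ||
      is.na(window_len) || window_len < 3L)
    stop("invalid config: blocks too short to estimate a window correlation (need block_len_windows >= 1 and window_len >= 3)",
         call. = FALSE)
  if (coupling_strength <= 0 || coupling_strength > 1)
    stop("invalid config: coupling_strength must lie in (0, 1]", call. = FALSE)
  if (noise_sd < 0 || reconfig_prob < 0 || reconfig_prob > 1)
    stop("invalid config: need noise_sd >= 0 and reconfig_prob in [0, 1]",
         call. = FALSE)
  structure(list(n_nodes = n_nodes, n_blocks = n_blocks,
                 block_len_windows = block_len_windows,
                 follow_lag_blocks = follow_lag_blocks,
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 reconfig_prob = reconfig_prob, window_len = window_len,
                 seed = as.integer(seed)),
            class = "follower_config")
}

#' Generate a follower time series with planted causal direction
#'
#' See [follower_config()] for the construction. The returned ground
#' truth names the planted causal direction (`"positive->negative"`), the
#' lag in blocks and in analysis windows, and the recommended window
#' specification (non-overlapping windows of `window_len` points, so the
#' planted lag maps onto `follow_lag_blocks * block_len_windows`
#' transition steps).
#'
#' @param cfg a [follower_config].
#' @return list of class `follower_sim` with elements `ts` (a [bold_ts])
#'   and `truth` (list: `direction`, `lag_blocks`, `lag_windows`,
#'   `window`, `membership` -- the node-by-block positive-set indicator).
#' @export
gen_follower <- function(cfg = follower_config()) {
  stopifnot(inherits(cfg, "follower_config"))
  set.seed(cfg$seed)
  L <- cfg$block_len_windows * cfg$window_len
  B <- cfg$n_blocks
  n <- cfg$n_nodes
  cc <- cfg$coupling_strength
  P <- matrix(0L, n, B)
  P[, 1L] <- stats::rbinom(n, 1L, 0.5)
  if (B > 1L) for (b in 2:B) {
    fl <- stats::rbinom(n, 1L, cfg$reconfig_prob)
    P[, b] <- ifelse(fl == 1L, 1L - P[, b - 1L], P[, b - 1L])
  }
  vals <- matrix(0, n, B * L)
  for (b in seq_len(B)) {
    idx <- ((b - 1L) * L + 1L):(b * L)
    u <- stats::rnorm(L)
    w <- stats::rnorm(L)
    src <- b - cfg$follow_lag_blocks
    S <- if (src >= 1L) ifelse(P[, src] == 1L, 1, -1)
         else sample(c(-1, 1), n, replace = TRUE)
    block <- cc * (P[, b] %o% u) + cc * (S %o% w)
    vals[, idx] <- block +
      matrix(stats::rnorm(n * L, sd = cfg$noise_sd), n, L)
  }
  ts <- bold_ts(vals, tr_seconds = 3, node_ids = paste0("n", seq_len(n)))
  truth <- list(
    direction = "positive->negative",
    lag_blocks = cfg$follow_lag_blocks,
    lag_windows = cfg$follow_lag_blocks * cfg$block_len_windows,
    window = window_spec(m = cfg$window_len, n = cfg$window_len),
    membership = P
  )
  structure(list(ts = ts, truth = truth, config = cfg),
            class = "follower_sim")
}

#' @export
print.follower_sim <- function(x, ...) {
  cat(sprintf("<follower_sim> %d nodes, %d blocks; planted %s at lag %d block(s) (%d window step(s))\n",
              x$config$n_nodes, x$config$n_blocks, x$truth$direction,
              x$truth$lag_blocks, x$truth$lag_windows))
  invisible(x)
}

#' Write a generated series with its ground-truth sidecar
#'
#' Writes the node-by-time TSV plus a YAML sidecar carrying the generator
#' configuration and (for the follower) the planted causal direction.
#'
#' @param sim a [bold_ts] (from [gen_lag_chain()]) or a `follower_sim`
#'   (from [gen_follower()]).
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_synth <- function(sim, path) {
  if (inherits(sim, "follower_sim")) {
    meta <- list(generator = "follower",
                 config = unclass(sim$config),
                 truth = list(direction = sim$truth$direction,
                              lag_blocks = sim$truth$lag_blocks,
                              lag_windows = sim$truth$lag_windows))
    write_timeseries(sim$ts, path, metadata = meta)
  } else if (inherits(sim, "bold_ts")) {
    cfg <- attr(sim, "config")
    meta <- list(generator = if (!is.null(cfg)) "lag_chain" else "unknown",
                 config = if (!is.null(cfg)) unclass(cfg) else NULL,
                 modules = as.integer(attr(sim, "modules")))
    write_timeseries(sim, path, metadata = meta)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}
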