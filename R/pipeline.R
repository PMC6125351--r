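#' Pipeline configuration
#'
#' Bundles and validates every tunable of the full analysis: windowing,
#' optional band-pass, SFC depth, and the Granger specification. Unknown
#' arguments are rejected rather than silently ignored.
#'
#' @param input a [bold_ts], or a path to a TSV table readable by
#'   [read_timeseries()], or a length-2 character vector
#'   `c(volume, mask)` of NIfTI paths.
#' @param tr_seconds repetition time, required when the input carries
#'   none.
#' @param window_m,window_n sliding-window length and offset in
#'   time-points (defaults 15 and 1).
#' @param band optional length-2 numeric `c(low_hz, high_hz)`; `NULL`
#'   (default) skips filtering (synthetic inputs are already
#'   band-limited).
#' @param l_max largest SFC step distance (default 7).
#' @param max_lag,alpha,fdr_q Granger test settings, see [granger_spec()].
#' @param out_dir output directory for [run_pipeline()]; `NULL` disables
#'   writing.
#' @param verbose print progress messages to standard error.
#' @param ... unknown options; any use is an error.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, tr_seconds = NULL,
                            window_m = 15L, window_n = 1L,
                            band = NULL, l_max = 7L,
                            max_lag = 5L, alpha = 0.05, fdr_q = 0.05,
                            out_dir = NULL, verbose = FALSE, ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown config option(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  if (!is.null(band) &&
      (!is.numeric(band) || length(band) != 2L || band[1L] >= band[2L]))
    stop("`band` must be c(low_hz, high_hz) with low < high", call. = FALSE)
  structure(list(input = input, tr_seconds = tr_seconds,
                 spec = window_spec(window_m, window_n), band = band,
                 l_max = as.integer(l_max),
                 granger = granger_spec(max_lag = max_lag, alpha = alpha,
                                        fdr_q = fdr_q),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

resolve_input <- function(cfg) {
  x <- cfg$input
  if (inherits(x, "bold_ts")) return(x)
  if (inherits(x, "follower_sim")) return(x$ts)
  if (is.character(x) && length(x) == 2L)
    return(read_nifti_timeseries(x[1L], x[2L], tr_seconds = cfg$tr_seconds))
  if (is.character(x) && length(x) == 1L)
    return(read_timeseries(x, tr_seconds = cfg$tr_seconds))
  stop("unrecognized input: pass a bold_ts, a TSV path, or c(volume, mask) NIfTI paths",
       call. = FALSE)
}

#' Run the full dynamic-topology pipeline
#'
#' Executes the whole analysis chain on one run: (optional band-pass) ->
#' sliding-window Fisher-z connectivity -> sign split -> (a) SFC over
#' positive connections, optimal step distances and the optimal-distance
#' versus negative-strength curve, and (b) node-level topology transition
#' series for both signs and the node-wise Granger causality map between
#' them. Identical input and configuration reproduce identical outputs.
#'
#' When `out_dir` is set, writes `od_negativity_curve.tsv`,
#' `causality_map.tsv`, `transitions_positive.tsv`,
#' `transitions_negative.tsv`, `od_time_avg.tsv`, a `config.yaml` echo,
#' and `summary.json` (window/transition counts, parameters, file
#' checksums).
#'
#' @param cfg a [pipeline_config].
#' @return invisibly, a list with elements `dyn` (full stack), `split`,
#'   `sfc` (normalized), `od`, `curve`, `trans_pos`, `trans_neg`, `cmap`,
#'   and `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  ts <- resolve_input(cfg)
  if (!is.null(cfg$band)) {
    say("band-pass %g-%g Hz", cfg$band[1L], cfg$band[2L])
    ts <- bandpass(ts, cfg$band[1L], cfg$band[2L])
  }
  say("windows: m = %d, n = %d over %d time-points",
      cfg$spec$m, cfg$spec$n, n_timepoints(ts))
  dyn <- dyn_connectivity(ts, cfg$spec)
  parts <- sign_split(dyn)
  say("%d windows; SFC steps 2..%d", n_windows(dyn), cfg$l_max)
  sfc <- normalize_sfc(sfc_stack(parts$positive, l_max = cfg$l_max))
  od <- optimal_distance(sfc)
  curve <- od_negativity_curve(od, parts$negative)
  tp <- transition_series(parts$positive)
  tn <- transition_series(parts$negative)
  cmap <- causality_map(tp, tn, cfg$granger)
  summary <- list(
    package_version = as.character(utils::packageVersion("dyntopo")),
    n_nodes = n_nodes(ts), n_timepoints = n_timepoints(ts),
    tr_seconds = ts$tr_seconds,
    window_m = cfg$spec$m, window_n = cfg$spec$n,
    n_windows = n_windows(dyn), n_transitions = ncol(tp),
    l_max = cfg$l_max, sfc_steps = length(2:cfg$l_max),
    granger = unclass(cfg$granger),
    band = cfg$band
  )
  out <- list(dyn = dyn, split = parts, sfc = sfc, od = od, curve = curve,
              trans_pos = tp, trans_neg = tn, cmap = cmap, summary = summary)
  if (!is.null(cfg$out_dir)) {
    paths <- write_outputs(out, cfg)
    out$summary$files <- paths$checksums
  }
  invisible(out)
}

write_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  wtsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- character(0)
  files <- c(files, wtsv(as.data.frame(out$curve), "od_negativity_curve.tsv"))
  files <- c(files, wtsv(as.data.frame(out$cmap), "causality_map.tsv"))
  tdf <- function(m) data.frame(node = rownames(m), unclass(m),
                                check.names = FALSE)
  files <- c(files, wtsv(tdf(out$trans_pos), "transitions_positive.tsv"))
  files <- c(files, wtsv(tdf(out$trans_neg), "transitions_negative.tsv"))
  oddf <- data.frame(node = rownames(out$od$time_avg), out$od$time_avg,
                     check.names = FALSE)
  files <- c(files, wtsv(oddf, "od_time_avg.tsv"))
  yaml::write_yaml(list(window_m = cfg$spec$m, window_n = cfg$spec$n,
                        band = cfg$band, l_max = cfg$l_max,
                        granger = unclass(cfg$granger)),
                   p("config.yaml"))
  files <- c(files, "config.yaml")
  sums <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  names(sums) <- files
  summary <- out$summary
  summary$files <- sums
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(files = files, checksums = sums)
}
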