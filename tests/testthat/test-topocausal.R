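make_stack <- function(arr, sign = "positive") {
  dyntopo:::new_dynconn_stack(arr, window_spec(15, 1), sign, 3,
                              paste0("n", seq_len(dim(arr)[1])))
}

test_that("transition series evaluates the Euclidean distance exactly", {
  ## identical consecutive matrices -> all-zero transitions
  M <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  arr <- array(rep(M, 3), c(2, 2, 3))
  tr <- transition_series(make_stack(arr))
  expect_equal(unname(unclass(tr)), matrix(0, 2, 2), ignore_attr = TRUE)
  ## a single edge changing by 0.3 moves only its two endpoints
  arr2 <- array(0, c(4, 4, 2))
  arr2[1, 2, 1] <- arr2[2, 1, 1] <- 0.5
  arr2[1, 2, 2] <- arr2[2, 1, 2] <- 0.8
  tr2 <- transition_series(make_stack(arr2))
  expect_equal(unname(unclass(tr2))[, 1], c(0.3, 0.3, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## 106 windows -> 105 transition columns
  arr3 <- array(rnorm(3 * 3 * 106), c(3, 3, 106))
  expect_equal(ncol(transition_series(make_stack(arr3))), 105)
  expect_error(transition_series(make_stack(array(0, c(2, 2, 1)))),
               "too few windows")
})

test_that("transition series commutes with node relabeling", {
  set.seed(18)
  ts <- bold_ts(matrix(rnorm(6 * 60), nrow = 6), tr_seconds = 1)
  pos <- sign_split(dyn_connectivity(ts, window_spec(10, 5)))$positive
  tr <- transition_series(pos)
  perm <- sample(6)
  ts_p <- bold_ts(ts$values[perm, ], 1)
  pos_p <- sign_split(dyn_connectivity(ts_p, window_spec(10, 5)))$positive
  tr_p <- transition_series(pos_p)
  expect_equal(unname(unclass(tr_p)), unname(unclass(tr))[perm, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("granger_f matches the independent lmtest oracle", {
  skip_if_not_installed("lmtest")
  set.seed(55)
  for (rep in 1:6) {
    n <- 105
    x <- rnorm(n)
    y <- 0.4 * c(rep(0, 2), x[1:(n - 2)]) + rnorm(n)
    ord <- sample(1:4, 1)
    mine <- granger_f(x, y, ord)
    or <- lmtest::grangertest(y ~ x, order = ord)
    expect_equal(mine$F, or$F[2], tolerance = 1e-8)
    expect_equal(mine$p, or$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("granger_f detects a deterministic lag and stays affine-invariant", {
  set.seed(2)
  n <- 105
  x <- rnorm(n)
  y <- c(0, x[1:(n - 1)]) + rnorm(n, sd = 1e-4)
  g <- granger_f(x, y, 1)
  expect_lt(g$p, 1e-6)
  ## affine transforms of either series leave F unchanged
  g2 <- granger_f(3.2 * x - 5, -1.4 * y + 2, 1)
  expect_equal(g2$F, g$F, tolerance = 1e-8)
  ## degenerate inputs give p = 1 with a warning, not an error
  expect_warning(gd <- granger_f(rep(1, n), rnorm(n), 1), "degenerate")
  expect_equal(gd$p, 1)
  expect_true(gd$degenerate)
  expect_error(granger_f(x, y[-1], 1), "equal length")
  expect_error(granger_f(x[1:6], y[1:6], 2), "too short")
})

test_that("BIC lag selection finds planted lags and penalizes extras", {
  set.seed(77)
  chosen1 <- replicate(60, {
    p <- gen_var_pair(105, beta = 0.9, lag = 1, noise_sd = 0.4,
                      seed = sample.int(1e6, 1))
    bic_lag(p$x, p$y, max_lag = 5)
  })
  expect_gt(mean(chosen1 == 1), 0.7)
  ## white noise: the penalty favours the smallest candidate
  chosen0 <- replicate(60, {
    bic_lag(rnorm(105), rnorm(105), max_lag = 5)
  })
  expect_equal(as.integer(names(which.max(table(chosen0)))), 1L)
  expect_true(all(chosen0 >= 1 & chosen0 <= 5))
  expect_error(bic_lag(rnorm(12), rnorm(12), max_lag = 5), "too short")
})

test_that("symmetric BIC lag is invariant to swapping the series", {
  set.seed(30)
  for (rep in 1:10) {
    x <- rnorm(80); y <- 0.5 * c(0, 0, x[1:78]) + rnorm(80)
    expect_identical(bic_lag(x, y, symmetric = TRUE),
                     bic_lag(y, x, symmetric = TRUE))
  }
})

test_that("fdr_bh reproduces the step-up rule and the brute-force search", {
  expect_equal(sum(fdr_bh(c(0.01, 0.02, 0.03, 0.2), q = 0.05)), 3)
  expect_false(any(fdr_bh(rep(1, 10), q = 0.05)))
  expect_true(all(fdr_bh(rep(0, 10), q = 0.05)))
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(88)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(fdr_bh(p, q), bh_brute_force(p, q))
  }
})

test_that("causality_map output is structured, antisymmetric and robust", {
  set.seed(123)
  sim <- gen_follower(follower_config(seed = 14))
  sp <- sign_split(dyn_connectivity(sim$ts, sim$truth$window))
  tp <- transition_series(sp$positive)
  tn <- transition_series(sp$negative)
  cm <- causality_map(tp, tn)
  expect_s3_class(cm, "causality_map")
  expect_equal(nrow(cm), n_nodes(sim$ts))
  ok <- !cm$failed
  expect_true(all(cm$F_pn[ok] >= 0) && all(cm$F_np[ok] >= 0))
  expect_true(all(cm$p_pn[ok] >= 0 & cm$p_pn[ok] <= 1))
  expect_true(all(cm$lag[ok] >= 1 & cm$lag[ok] <= 5))
  ## FDR flags imply the alpha-level flag at equal thresholds
  expect_true(all(cm$p_pn[cm$fdr_pn] <= 0.05 + 1e-12))
  ## swapping the inputs negates the difference scores exactly
  cm_sw <- causality_map(tn, tp)
  expect_equal(cm_sw$diff_raw, -cm$diff_raw, tolerance = 1e-10)
  expect_equal(cm_sw$diff_score, -cm$diff_score, tolerance = 1e-10)
  ## a flat node is flagged, the rest of the run survives
  tp_bad <- tp; tp_bad[3, ] <- 0
  tn_bad <- tn; tn_bad[3, ] <- 0
  suppressWarnings(cm_bad <- causality_map(tp_bad, tn_bad))
  expect_true(cm_bad$failed[3] || cm_bad$p_pn[3] == 1)
  expect_false(any(cm_bad$failed[-3]))
})

test_that("under the global null the FDR-flagged fraction stays near q", {
  set.seed(9)
  flagged <- replicate(20, {
    n_nodes <- 12; len <- 80
    tp <- matrix(rnorm(n_nodes * len), n_nodes)
    tn <- matrix(rnorm(n_nodes * len), n_nodes)
    rownames(tp) <- rownames(tn) <- paste0("n", 1:n_nodes)
    tp <- structure(tp, sign = "positive", spec = window_spec(),
                    class = c("transition_series", "matrix", "array"))
    tn <- structure(tn, sign = "negative", spec = window_spec(),
                    class = c("transition_series", "matrix", "array"))
    cm <- causality_map(tp, tn)
    mean(cm$fdr_pn)
  })
  expect_lt(mean(flagged), 0.05 + 0.05)
})

test_that("null Granger p-values are approximately uniform", {
  pvals <- vapply(1:400, function(s) {
    pair <- gen_var_pair(105, beta = 0, lag = 1, noise_sd = 1, seed = 5000 + s)
    granger_f(pair$x, pair$y, 1)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permuting block order destroys the planted causal direction", {
  frac_of <- function(ts, spec) {
    pr <- sign_split(dyn_connectivity(ts, spec))
    cm <- causality_map(transition_series(pr$positive),
                        transition_series(pr$negative))
    mean(cm$F_pn > cm$F_np, na.rm = TRUE)
  }
  set.seed(61)
  planted <- numeric(6); permuted <- numeric(6)
  for (s in 1:6) {
    sim <- gen_follower(follower_config(seed = 200 + s))
    L <- sim$config$block_len_windows * sim$config$window_len
    B <- sim$config$n_blocks
    perm <- sample(B)
    cols <- as.vector(vapply(perm, function(b) ((b - 1) * L + 1):(b * L),
                             integer(L)))
    shuf <- bold_ts(sim$ts$values[, cols], sim$ts$tr_seconds)
    planted[s] <- frac_of(sim$ts, sim$truth$window)
    permuted[s] <- frac_of(shuf, sim$truth$window)
  }
  expect_gt(mean(planted), mean(permuted))
  expect_gt(mean(planted), 0.5)
})
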