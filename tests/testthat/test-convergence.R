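test_that("half_life implements ln(2)/b and rejects non-positive rates", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(log(2) / 10), 10.0)
  expect_error(half_life(0), "b > 0")
  expect_error(half_life(-1), "b > 0")
})

test_that("noise-free exponentials are recovered to 1e-6 relative", {
  t <- 1:300
  for (par in list(c(a = 50, b = 0.1, c = -300), c(a = -20, b = 0.2, c = 100))) {
    y <- par["a"] * exp(-par["b"] * t) + par["c"]
    f <- fit_exponential(y, t)
    expect_equal(f$status, "fitted")
    expect_lt(abs(f$a - par["a"]) / abs(par["a"]), 1e-6)
    expect_lt(abs(f$b - par["b"]) / par["b"], 1e-6)
    expect_lt(abs(f$c - par["c"]) / abs(par["c"]), 1e-6)
    expect_equal(f$cutoff, 4 * log(2) / par["b"], tolerance = 1e-6,
                 ignore_attr = TRUE)
    # cross-check b: log|f(t) - c| is linear with slope -b (early frames,
    # before the transient underflows)
    tt <- 1:40
    sl <- coef(lm(log(abs(y[tt] - par["c"])) ~ tt))[["tt"]]
    expect_equal(f$b, -sl, tolerance = 1e-8)
  }
})

test_that("flat and pure-noise series are classified no_transient with cutoff 0", {
  f <- fit_exponential(rep(100, 50))
  expect_equal(f$status, "no_transient")
  expect_equal(f$cutoff, 0)
  set.seed(4)
  f2 <- fit_exponential(rnorm(400, mean = 250, sd = 1))
  expect_equal(f2$status, "no_transient")
  expect_equal(f2$cutoff, 0)
})

test_that("fit input preconditions are enforced", {
  expect_error(fit_exponential(1:5), "at least 8")
  expect_error(fit_exponential(c(1:20, NA)), "non-finite")
})

test_that("the cutoff is four half-lives and marks 93.75% completion", {
  y <- 50 * exp(-0.2 * (1:200)) + 10
  f <- fit_exponential(y, 1:200)
  expect_equal(convergence_cutoff(f), 4 * f$half_life)
  # half-life identity on the fitted curve: f(T1/2) - c = (f(0) - c)/2
  curve <- function(x) f$a * exp(-f$b * x) + f$c
  expect_equal(curve(f$half_life) - f$c, (curve(0) - f$c) / 2)
  # completed fraction of the transient at the cutoff
  frac <- (curve(0) - curve(f$cutoff)) / (curve(0) - f$c)
  expect_equal(frac, 0.9375)
  f_flat <- fit_exponential(rep(1, 20))
  expect_error(convergence_cutoff(f_flat), "fitted")
})

test_that("increasing decay rate strictly decreases half-life and cutoff", {
  bs <- c(0.05, 0.1, 0.2, 0.5, 1)
  hl <- half_life(bs)
  expect_true(all(diff(hl) < 0))
  cuts <- vapply(bs, function(b)
    fit_exponential(40 * exp(-b * (1:200)) + 5, 1:200)$cutoff, numeric(1))
  expect_true(all(diff(cuts) < 0))
})

test_that("cutoff aggregation uses per-cell means and the interpolated quantile", {
  mk <- function(cutoffs, joint = "J", axis = "x", mode = "M") {
    data.frame(joint = joint, axis = axis, mode = mode, cutoff = cutoffs,
               status = "fitted", run_id = seq_along(cutoffs))
  }
  # all cell means 55 -> overall 55
  fits <- rbind(mk(c(50, 60), "A"), mk(55, "B"), mk(c(55, 55), "C"))
  s <- aggregate_cutoffs(fits)
  expect_equal(s$overall_quantile_frame, 55L)

  # cell means 10..100: 85%-quantile with linear interpolation = 86.5 -> 87
  fits10 <- do.call(rbind, lapply(1:10, function(k)
    mk(k * 10, joint = paste0("J", k))))
  s10 <- aggregate_cutoffs(fits10)
  expect_equal(
    quantile(seq(10, 100, 10), 0.85, type = 7, names = FALSE), 86.5)
  expect_equal(s10$overall_quantile_frame, 87L)

  # single cell mean 12.3 -> ceiling
  expect_equal(aggregate_cutoffs(mk(12.3))$overall_quantile_frame, 13L)

  # order invariance, and invariance to duplicating every cell's fits with
  # identical values (cell means are over runs, so duplicates cancel)
  shuffled <- fits10[sample(nrow(fits10)), ]
  expect_equal(aggregate_cutoffs(shuffled)$overall_quantile_frame, 87L)
  dup <- rbind(fits10, fits10)
  expect_equal(aggregate_cutoffs(dup)$overall_quantile_frame, 87L)
})

test_that("failed fits are excluded and counted; all-failed errors", {
  fits <- data.frame(joint = "J", axis = "x", mode = "M",
                     cutoff = c(40, NA), status = c("fitted", "fit_failed"))
  s <- aggregate_cutoffs(fits, fps = 30)
  expect_equal(s$n_fit_failed, 1L)
  expect_equal(s$overall_quantile_frame, 40L)
  expect_equal(s$discard_frames, 60L)
  allbad <- data.frame(joint = "J", axis = "x", cutoff = NA,
                       status = "fit_failed")
  expect_error(aggregate_cutoffs(allbad), "all fits failed")
})

test_that("discard recommendation rounds up to the next full second", {
  expect_equal(recommend_discard(55, 30), 60L)
  expect_equal(recommend_discard(60, 30), 60L)
  expect_equal(recommend_discard(61, 30), 90L)
  expect_equal(recommend_discard(0, 30), 0L)
})

test_that("windowing keeps frames discard+1..last with original labels", {
  rs <- generate_runset(tiny_config(n_runs = 2, n_frames = 90, noise_sd = 0.1))
  w <- apply_window(rs, 60)
  expect_equal(w$frames, 61:90)
  expect_equal(n_frames(w), 30L)
  expect_equal(w$runs[[1]]$xyz[1, , "PELVIS"], rs$runs[[1]]$xyz[61, , "PELVIS"])
  expect_identical(apply_window(rs, 0), rs)
  expect_error(apply_window(rs, 90), "empties")
})

test_that("runset-wide transient fitting labels every run, joint and axis", {
  centers <- preset_skeleton_centers_test()
  jcs <- list(
    joint_gen_config("PELVIS", centers$PELVIS,
                     transient_amplitude = c(50, -30, 40),
                     transient_rate = rep(0.1, 3), noise_sd = rep(0.3, 3)),
    joint_gen_config("NECK", centers$NECK, noise_sd = rep(0.3, 3))
  )
  rs <- generate_runset(runset_gen_config(n_runs = 2, n_frames = 300, seed = 6,
                                          joint_configs = jcs,
                                          mode_label = "CUDA"))
  fits <- fit_runset_transients(rs)
  expect_equal(nrow(fits), 2 * 2 * 3)
  expect_setequal(unique(fits$mode), "CUDA")
  pel <- fits[fits$joint == "PELVIS", ]
  expect_true(all(pel$status == "fitted"))
  expect_equal(pel$b, rep(0.1, 6), tolerance = 0.1)
  expect_true(all(fits$cutoff[fits$joint == "NECK"] == 0))
})
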