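# exhaustive maxima definition used as a property-test oracle
brute_maxima <- function(a, eps) {
  n <- length(a)
  out <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && a[j + 1] == a[i]) j <- j + 1
    if ((i == 1 || a[i - 1] < a[i]) && (j == n || a[j + 1] < a[i])) {
      lmin <- if (i > 1) min(a[1:(i - 1)]) else NA
      rmin <- if (j < n) min(a[(j + 1):n]) else NA
      if (a[i] - max(lmin, rmin, na.rm = TRUE) >= eps) out <- c(out, i)
    }
    i <- j + 1
  }
  out
}

test_that("find_maxima matches the exhaustive definition on crafted and random profiles", {
  expect_equal(find_maxima(c(1, 2, 3, 2, 1), 0.1), 3L)
  expect_equal(find_maxima(rep(2, 6)), integer(0))
  expect_equal(find_maxima(c(1, 5, 1, 4, 1), 0.1), c(2L, 4L))
  expect_equal(find_maxima(c(5, 1, 1, 1, 1), 0.1), 1L)   # boundary peak
  expect_equal(find_maxima(c(1, 3, 3, 3, 1), 0.1), 2L)   # plateau -> first
  set.seed(101)
  for (k in 1:50) {
    a <- round(runif(sample(3:30, 1), 0, 5), 2)
    eps <- runif(1, 0, 0.5)
    expect_equal(find_maxima(a, eps), brute_maxima(a, eps))
  }
})

test_that("stability returns the exact leading eigenvalue for the decoupled decay system", {
  # with vanishing couplings the Jacobian is diagonal: -Kd on auxin rows,
  # -k2 (basal) on PIN rows; with k2 > Kd the leading eigenvalue is -Kd
  p <- tp_small(alpha = 0, D = 1e-300, K0 = 1e-300, k1 = 1e-300,
                Kd = 0.07, k2 = 0.3)
  st <- profile1d(rep(0, 5), rep(0, 5))
  expect_equal(stability(p, st), -p$Kd, tolerance = 1e-6)
})

test_that("the basic-set stationary profile at alpha = 1 is linearly stable and integration returns to it after a small kick", {
  p <- param_preset("basic")$transport
  ss <- steady_state_1d(p, N = 50)
  lead <- stability(p, ss$profile)
  expect_lt(lead, 0)
  kicked <- perturb_cell(ss$profile, which.max(ss$profile$a), 0.5)
  back <- integrate_1d(kicked, p, t_end = 3000, times = c(0, 3000))
  expect_equal(back$a[2, ], ss$profile$a, tolerance = 1e-4)
})

test_that("continuation reproduces independently computed steady states along a monotone branch", {
  p <- tp_small(alpha = 0.2)
  br <- continue_branch(p, "alpha", range = c(0.2, 1.2), N = 6,
                        ds0 = 0.05, ds_max = 0.2)
  expect_gt(nrow(br$points), 5)
  expect_true(all(abs(diff(br$points$param)) <= 0.25 + 1e-9))
  # two-method agreement at interior branch points
  for (k in round(seq(2, nrow(br$points) - 1, length.out = 4))) {
    pk <- p; pk$alpha <- br$points$param[k]
    ss <- steady_state_1d(pk, N = 6, init = br$profiles[[k]],
                          newton_only = TRUE)
    expect_true(ss$converged)
    expect_equal(ss$profile$a, br$profiles[[k]]$a, tolerance = 1e-6)
  }
})

test_that("branch solutions at a small-N fixed parameter agree with brute-force multistart", {
  p <- param_preset("basic")$transport
  N <- 4
  br <- continue_branch(p, "alpha", range = c(0.2, 1.6), N = N,
                        ds0 = 0.05, ds_max = 0.2, compute_stability = FALSE)
  n_br <- count_solutions_at(br, 1)
  # multistart Newton from random initial data (independent of the
  # continuation path)
  f <- function(x) {
    r <- build_rhs_1d(profile1d(pmax(x[1:N], 0), pmax(x[N + 1:N], 0)),
                      p)
    c(r$da, r$dPIN)
  }
  set.seed(202)
  sols <- list()
  for (k in 1:300) {
    x0 <- runif(2 * N, 0, 6)
    ns <- rootauxin:::newton_solve(f, x0, tol = 1e-9, maxit = 80,
                                   lower = rep(0, 2 * N))
    if (ns$converged) {
      new <- TRUE
      for (s in sols) if (max(abs(s - ns$x)) < 1e-5) { new <- FALSE; break }
      if (new) sols[[length(sols) + 1]] <- ns$x
    }
  }
  # the branch through the zero-data state knows at least one solution and
  # never more than the full multistart census
  expect_gte(n_br, 1)
  expect_lte(n_br, length(sols))
})

test_that("crossing counts follow branch geometry", {
  mk <- function(param) structure(
    list(param_name = "alpha",
         points = data.frame(param = param), folds = numeric(0)),
    class = "continuation_branch")
  expect_equal(count_solutions_at(mk(seq(0, 2, 0.1)), 1.05), 1)
  s_shape <- c(seq(0, 1.2, 0.1), seq(1.15, 0.8, -0.05), seq(0.85, 2, 0.1))
  expect_equal(count_solutions_at(mk(s_shape), 1.0), 3)
  expect_equal(count_solutions_at(mk(s_shape), 1.9), 1)
})

test_that("oscillation detection recovers amplitude and period of a synthetic signal and is silent at stable states", {
  times <- seq(0, 200, by = 0.1)
  period_true <- 17.3
  a <- outer(sin(2 * pi * times / period_true), c(2, 0.5, 0.1)) + 3
  traj <- structure(list(times = times, a = a,
                         PIN = matrix(0, length(times), 3)),
                    class = "trajectory1d")
  rep <- detect_oscillation(NULL, NULL, traj = traj)
  expect_true(rep$oscillating)
  expect_equal(rep$amplitude, c(4, 1, 0.2), tolerance = 1e-3)
  expect_equal(rep$period, period_true, tolerance = 0.01 * period_true)

  p <- tp_small(alpha = 0.5)
  ss <- steady_state_1d(p, N = 6, t_relax = 800)
  quiet <- detect_oscillation(p, ss$profile, t_transient = 50,
                              t_measure = 200, n_out = 400)
  expect_false(quiet$oscillating)
  expect_lt(max(quiet$amplitude), 1e-4)
})

test_that("perturbation tolerance matches a direct brute-force scan and honours the sentinel", {
  p <- param_preset("basic")$transport
  ss <- steady_state_1d(p, N = 50)
  base_max <- which.max(ss$profile$a)
  tol <- perturbation_tolerance(p, ss$profile, grid_max = 8, step = 0.5,
                                refine = 0.1, t_relax = 3000)
  expect_true(is.finite(tol$threshold))
  # brute force on a fine grid around the reported threshold
  shifts <- function(delta) {
    st <- perturb_cell(ss$profile, base_max, delta)
    tr <- integrate_1d(st, p, t_end = 3000, times = c(0, 3000))
    which.max(tr$a[2, ]) != base_max
  }
  expect_false(shifts(tol$threshold - 0.3))
  expect_true(shifts(tol$threshold + 0.3))
  # all-below-threshold grid returns the sentinel
  none <- perturbation_tolerance(p, ss$profile, grid_max = 0.5, step = 0.25,
                                 t_relax = 2000)
  expect_identical(none$threshold, Inf)
})

test_that("profile comparison: exact affine copies, known noise, and the bundled synthetic reference", {
  p <- param_preset("basic")$transport
  ss <- steady_state_1d(p, N = 50)
  m <- ss$profile
  exact <- compare_profile(m, 4.2 * m$a + 1.7)
  expect_equal(exact$rmse, 0, tolerance = 1e-9)
  expect_equal(exact$scale, 4.2, tolerance = 1e-9)
  expect_equal(exact$offset, 1.7, tolerance = 1e-8)
  set.seed(303)
  sigma <- 0.8
  noisy <- compare_profile(m, 3 * m$a + 2 + rnorm(50, 0, sigma))
  expect_equal(noisy$rmse, sigma, tolerance = 0.25 * sigma)
  ref <- read_digitized_profile(system.file("extdata",
                                            "dr5_profile_synthetic.tsv",
                                            package = "rootauxin"))
  expect_equal(names(ref), c("position", "intensity"))
  fit <- compare_profile(m, ref)
  # the line scan is an affine image of a same-class profile plus mild
  # densitometry noise, so the match is tight relative to the signal range
  expect_lt(fit$rmse, 0.05 * diff(range(ref$intensity)))
  expect_gt(fit$scale, 0)
})

test_that("coordinate descent solves separable problems exactly and recovers transport parameters from a synthetic profile", {
  quad <- function(x) (x["u"] - 2)^2 + 3 * (x["v"] + 1)^2
  fit <- coordinate_descent_fit(quad, c(u = 0, v = 0),
                                lower = c(u = -5, v = -5),
                                upper = c(u = 5, v = 5))
  expect_true(fit$converged)
  expect_equal(unname(fit$par), c(2, -1), tolerance = 1e-6)
  expect_lte(fit$cycles, 2)

  # parameter recovery: regenerate a steady profile and fit (Kd, K0)
  p_true <- tp_small(Kd = 0.12, K0 = 0.25)
  target <- steady_state_1d(p_true, N = 8, t_relax = 600)$profile$a
  objective <- function(x) {
    p <- tp_small(Kd = unname(x["Kd"]), K0 = unname(x["K0"]))
    ss <- steady_state_1d(p, N = 8, t_relax = 400)
    if (!ss$converged) return(1e6)
    sum((ss$profile$a - target)^2)
  }
  fit2 <- coordinate_descent_fit(objective, c(Kd = 0.2, K0 = 0.15),
                                 lower = c(Kd = 0.02, K0 = 0.05),
                                 upper = c(Kd = 0.5, K0 = 0.6),
                                 tol = 1e-9, max_cycles = 8,
                                 check_identifiability = FALSE,
                                 line_tol = 1e-4)
  expect_lt(abs(fit2$par["Kd"] - 0.12) / 0.12, 0.05)
  expect_lt(abs(fit2$par["K0"] - 0.25) / 0.25, 0.05)
})

test_that("a jointly rescalable parameter pair is reported as a flat direction, not as converged", {
  # k1 and K0 enter the stationary auxin profile only through their
  # product, a constructed degeneracy
  objective <- function(x) {
    prod_err <- (x["k1"] * x["K0"] - 0.1)^2
    unname(prod_err)
  }
  fit <- coordinate_descent_fit(objective, c(k1 = 0.8, K0 = 0.2),
                                lower = c(k1 = 0.2, K0 = 0.02),
                                upper = c(k1 = 2, K0 = 0.6))
  expect_false(fit$converged)
  expect_setequal(fit$flat, c("k1", "K0"))
  expect_lt(fit$value, 1e-10)
})
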