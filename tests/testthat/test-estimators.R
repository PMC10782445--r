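beta1 <- 1 / 0.008314462618 # temperature at which beta = 1 mol/kJ

test_that("single-pair Crooks-Bayes posterior is symmetric about the work value", {
  ws <- tiny_workset(2, -2, temperature = beta1)
  post <- crooks_bayes_posterior(ws)
  est <- crooks_bayes_estimate(post)
  expect_equal(est$delta_g, 2, tolerance = 1e-6)
  expect_equal(est$method, "cb")
  # density symmetric about 2 on the centred default grid
  expect_equal(post$density, rev(post$density), tolerance = 1e-9)
})

test_that("identical forward/backward multisets give a posterior mean of zero", {
  vals <- c(1.2, -0.7, 3.1, 0.4)
  ws <- tiny_workset(vals, vals, temperature = beta1)
  expect_equal(cb_estimate(ws)$delta_g, 0, tolerance = 1e-8)
  expect_equal(bar_estimate(ws)$delta_g, 0, tolerance = 1e-9)
})

test_that("posterior moments reproduce a discretized Gaussian's moments", {
  grid <- seq(-7, 13, length.out = 4001)
  post <- structure(
    list(grid = grid,
         density = stats::dnorm(grid, 3, 0.5) /
           pracma::trapz(grid, stats::dnorm(grid, 3, 0.5)),
         thermo = make_thermo(298), n_forward = 1L, n_backward = 1L),
    class = "cb_posterior")
  est <- crooks_bayes_estimate(post)
  expect_equal(est$delta_g, 3, tolerance = 1e-3)
  expect_equal(est$std_error, 0.5, tolerance = 1e-3)
})

test_that("estimators reject one-sided or unnormalized input", {
  ws <- workset(c(1, 2), numeric(0), make_thermo(298))
  expect_error(crooks_bayes_posterior(ws), "jarzynski",
               class = "redoxcb_unsupported_error")
  expect_error(bar_estimate(ws), class = "redoxcb_unsupported_error")
  bad_post <- structure(
    list(grid = seq(0, 1, length.out = 101), density = rep(2, 101),
         thermo = make_thermo(298), n_forward = 1L, n_backward = 1L),
    class = "cb_posterior")
  expect_error(crooks_bayes_estimate(bad_post), "normalized")
})

test_that("BAR solves the logistic balance on tiny sets (brute-force oracle)", {
  expect_equal(bar_estimate(tiny_workset(2, -2, temperature = beta1))$delta_g,
               2, tolerance = 1e-8)
  set.seed(17)
  for (i in 1:6) {
    nf <- sample(1:5, 1); nb <- sample(1:5, 1)
    fwd <- rnorm(nf, 4, 3); bwd <- rnorm(nb, -4, 3)
    ws <- tiny_workset(fwd, bwd)
    root <- bar_estimate(ws)$delta_g
    scan <- oracle_bar_scan(fwd, bwd, ws$thermo$beta, root - 1, root + 1,
                            resolution = 1e-4)
    expect_equal(root, scan, tolerance = 1e-4)
  }
})

test_that("CB posterior moments match brute-force grid integration on tiny sets", {
  set.seed(23)
  for (i in 1:5) {
    fwd <- rnorm(sample(2:5, 1), 5, 2)
    bwd <- rnorm(sample(2:5, 1), -5, 2)
    ws <- tiny_workset(fwd, bwd)
    est <- cb_estimate(ws)
    dense <- seq(est$delta_g - 12 * est$std_error,
                 est$delta_g + 12 * est$std_error, length.out = 20001)
    oracle <- oracle_cb_moments(fwd, bwd, ws$thermo$beta, dense)
    expect_equal(est$delta_g, oracle$mean,
                 tolerance = 1e-4 * max(1, abs(oracle$mean)))
    expect_equal(est$std_error, oracle$sd, tolerance = 1e-4 * oracle$sd)
  }
})

test_that("CB posterior mode and BAR root coincide for equal sample counts", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(3, 4, 500, seed = 9))
  post <- crooks_bayes_posterior(ws)
  mode <- post$grid[which.max(post$density)]
  expect_equal(mode, bar_estimate(ws)$delta_g,
               tolerance = 1.5 * (post$grid[2] - post$grid[1]))
})

test_that("Jarzynski/FEP uses log-sum-exp and respects the Jensen bound", {
  th <- make_thermo(beta1)
  expect_equal(jarzynski_estimate(5, th)$delta_g, 5)
  expect_equal(jarzynski_estimate(rep(3.3, 10), th)$delta_g, 3.3, tolerance = 1e-12)
  # hand computation: -ln((1 + e^-100)/2) at beta = 1
  expect_equal(jarzynski_estimate(c(0, 100), th)$delta_g,
               -log((1 + exp(-100)) / 2), tolerance = 1e-12)
  expect_equal(jarzynski_estimate(c(0, 100), th)$delta_g, 0.693147,
               tolerance = 1e-6)
  # huge work values must not overflow
  expect_true(is.finite(jarzynski_estimate(c(500, 900), make_thermo(298))$delta_g))
  expect_equal(jarzynski_estimate(1:3, th, method = "fep")$method, "fep")
  set.seed(31)
  for (i in 1:25) {
    v <- rnorm(sample(1:50, 1), rnorm(1, 0, 20), runif(1, 0, 30))
    expect_lte(jarzynski_estimate(v, make_thermo(298))$delta_g,
               mean(v) + 1e-10)
  }
  expect_error(jarzynski_estimate(numeric(0), th), class = "redoxcb_data_error")
})

test_that("linear response applies <W> - beta var/2", {
  th04 <- make_thermo(1 / (0.008314462618 * 0.4)) # beta = 0.4 mol/kJ
  expect_equal(th04$beta, 0.4, tolerance = 1e-12)
  v <- c(10 - sqrt(2), 10 + sqrt(2)) # mean 10, unbiased variance 4
  expect_equal(lr_estimate(v, th04)$delta_g, 10 - 0.4 * 4 / 2, tolerance = 1e-10)
  set.seed(8)
  x <- rnorm(100, 10, 2)
  expect_equal(lr_estimate(x, th04)$delta_g, mean(x) - 0.4 * var(x) / 2,
               tolerance = 1e-10)
  expect_equal(lr_estimate(rep(7, 5), th04)$delta_g, 7)
  expect_error(lr_estimate(3, th04), class = "redoxcb_data_error")
})

test_that("histogram crossing finds the equal-variance Gaussian midpoint", {
  set.seed(42)
  ws <- workset(rnorm(1e5, 6, 1), -rnorm(1e5, 4, 1), make_thermo(298), "x")
  est <- histogram_crossing(ws)
  expect_equal(est$delta_g, 5, tolerance = 0.05)
  expect_true(is.na(est$std_error))
  expect_equal(est$method, "crossing")
})

test_that("histogram crossing flags disjoint and degenerate inputs", {
  ws_disjoint <- workset(rep(10, 20) + seq(0, 1e-3, length.out = 20),
                         rep(10, 20) + seq(0, 1e-3, length.out = 20),
                         make_thermo(298))
  expect_error(histogram_crossing(ws_disjoint), "overlap",
               class = "redoxcb_data_error")
  set.seed(2)
  v <- rnorm(50)
  ws_same <- workset(v, -v, make_thermo(298))
  expect_error(histogram_crossing(ws_same), "degenerate",
               class = "redoxcb_data_error")
  expect_error(histogram_crossing(workset(rnorm(5), rnorm(5), make_thermo(298))),
               class = "redoxcb_parameter_error")
})

test_that("convergence curve tracks prefix subsets and matches the full fit", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(5, 3, 400, seed = 12))
  full <- cb_estimate(ws)
  cc <- convergence_curve(ws, c(400))
  expect_equal(nrow(cc), 1)
  expect_equal(cc$delta_g, full$delta_g, tolerance = 1e-9)
  cc5 <- convergence_curve(ws, c(50, 100, 200, 300, 400))
  expect_equal(nrow(cc5), 5)
  expect_warning(cct <- convergence_curve(ws, c(100, 1000)), "truncated")
  expect_equal(cct$mu, 100L)
  expect_error(convergence_curve(ws, c(200, 100)),
               class = "redoxcb_parameter_error")
})

test_that("direction swap maps two-sided estimates to their negation", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(4, 2, 600, seed = 21))
  sw <- workset(ws$backward, ws$forward, ws$thermo, ws$label)
  expect_equal(bar_estimate(sw)$delta_g, -bar_estimate(ws)$delta_g,
               tolerance = 1e-9)
  expect_equal(cb_estimate(sw)$delta_g, -cb_estimate(ws)$delta_g,
               tolerance = 1e-9)
  expect_equal(histogram_crossing(sw)$delta_g, -histogram_crossing(ws)$delta_g,
               tolerance = 1e-9)
})

test_that("translation covariance: shifting work by +c shifts estimates by +c", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(2, 3, 500, seed = 33))
  for (c_shift in c(-7.25, 13.5)) {
    shifted <- workset(ws$forward + c_shift, ws$backward - c_shift,
                       ws$thermo, ws$label)
    expect_equal(bar_estimate(shifted)$delta_g,
                 bar_estimate(ws)$delta_g + c_shift, tolerance = 1e-9)
    expect_equal(cb_estimate(shifted)$delta_g,
                 cb_estimate(ws)$delta_g + c_shift, tolerance = 1e-9)
  }
})

test_that("every generated posterior is trapezoid-normalized", {
  set.seed(44)
  for (i in 1:8) {
    ws <- generate_crooks_gaussian(
      synthetic_work_spec(rnorm(1, 0, 10), runif(1, 0.5, 10),
                          sample(2:300, 1), seed = i))
    post <- crooks_bayes_posterior(ws)
    expect_gte(length(post$grid), 101)
    expect_true(all(post$density >= 0))
    expect_equal(pracma::trapz(post$grid, post$density), 1, tolerance = 1e-6)
  }
})

test_that("unequal sample counts are handled through M = ln(nF/nR)", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(5, 2, 3000, seed = 55))
  uneq <- workset(ws$forward, ws$backward[1:1000], ws$thermo)
  est <- bar_estimate(uneq)
  expect_lt(abs(est$delta_g - 5), 3 * est$std_error)
  cb <- cb_estimate(uneq)
  expect_lt(abs(cb$delta_g - 5), 3 * cb$std_error)
})

test_that("posterior and estimate exports write readable records", {
  ws <- generate_crooks_gaussian(synthetic_work_spec(1, 1, 50, seed = 3))
  post <- crooks_bayes_posterior(ws)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_posterior(post, tsv)
  back <- read.delim(tsv)
  expect_equal(names(back), c("delta_g_kjmol", "density"))
  expect_equal(nrow(back), length(post$grid))
  js <- withr::local_tempfile(fileext = ".json")
  export_estimate(crooks_bayes_estimate(post), "sysA", js)
  rec <- jsonlite::read_json(js)
  expect_equal(rec$label, "sysA")
  expect_equal(rec$method, "cb")
  expect_equal(rec$n_forward, 50)
})
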