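test_that("K_T follows exactly from the compound-parameter ratio", {
  expect_equal(kt_from_compounds(458752, 1.667e-3), 128.8, tolerance = 1e-3)
  expect_equal(kt_from_compounds(7, 7), 1)
  expect_equal(kt_from_compounds(16 * 0.3, 0.3), 2)
  expect_error(kt_from_compounds(-1, 1), "> 0")
})

test_that("the solver recovers both real roots of the human system", {
  sol <- solve_tes(forward_compounds(human_params()))
  expect_s3_class(sol, "tes_solution")
  expect_length(sol$roots, 2)
  expect_equal(sol$k_t, 128.8, tolerance = 1e-9)

  r1 <- sol$roots[[1]]$params   # sorted by ascending K_R: generating triple
  r2 <- sol$roots[[2]]$params   # spurious mirror root
  expect_equal(r1$K_R, 1.6, tolerance = 1e-8)
  expect_equal(r1$L, 0.7e5, tolerance = 1e-8)
  expect_equal(sol$roots[[1]]$label, "physiological")
  expect_equal(r2$K_R, 22.1, tolerance = 0.5 / 22.1)
  expect_equal(r2$L, 1.8, tolerance = 0.1 / 1.8)
  expect_equal(sol$roots[[2]]$label, "non_physiological")
  # both roots satisfy all three equations and share K_T
  for (r in sol$roots) {
    expect_lt(max(r$residuals), 1e-8)
    expect_identical(r$params$K_T, sol$k_t)
  }
  expect_length(sol$all_quartic_roots, 4)
})

test_that("forward-generated systems round-trip through the solver", {
  set.seed(7)
  for (i in 1:40) {
    truth <- random_triple()
    sol <- solve_tes(forward_compounds(truth))
    expect_lte(length(sol$roots), 2)
    krs <- vapply(sol$roots, function(r) r$params$K_R, numeric(1))
    j <- which.min(abs(krs - truth$K_R))
    expect_equal(sol$roots[[j]]$params$K_R, truth$K_R, tolerance = 1e-6)
    expect_equal(sol$roots[[j]]$params$L, truth$L, tolerance = 1e-5)
    for (r in sol$roots) expect_lt(max(r$residuals), 1e-8)
  }
})

test_that("P50 = K_T factorizes the quartic to the single root K_R = P50", {
  # D = 0: pick lkr4 and p50 so that p50 equals the implied K_T
  lkr4 <- 2e5; p50 <- 60
  lc4 <- lkr4 / p50^4
  sol <- solve_tes(compound_params(lkr4, lc4, p50))
  expect_length(sol$roots, 1)
  expect_equal(sol$roots[[1]]$params$K_R, p50, tolerance = 1e-9)
  expect_equal(sol$roots[[1]]$params$L, lkr4 / p50^4, tolerance = 1e-9)
})

test_that("root classification separates the reported parameter regimes", {
  expect_equal(classify_root(mwc_params(7.0e4, 1.6, 1.6 / 0.0124)),
               "physiological")
  expect_equal(classify_root(mwc_params(1.8, 22.1, 22.1 / 0.171)),
               "non_physiological")
  expect_equal(classify_root(mwc_params(1e2 * (1 + 1e-9), 1, 1 / 0.049)),
               "physiological")
  expect_equal(classify_root(mwc_params(1e2, 1, 1 / 0.049)),
               "non_physiological")  # boundary: strict L > L_min
  expect_equal(classify_root(mwc_params(5, 1, 1 + 1e-9)), "degenerate")
  expect_equal(classify_root(mwc_params(50, 1, 100), L_min = 10),
               "physiological")
})

test_that("classification reproduces the reference-table labels", {
  tab <- mammal_hb_table()
  ph <- tab[!is.na(tab$kr_ph), ]
  expect_equal(nrow(ph), 17)
  for (i in seq_len(nrow(ph))) {
    expect_equal(classify_root(
      mwc_params(ph$l_ph_1e5[i] * 1e5, ph$kr_ph[i], ph$kt[i])),
      "physiological")
    expect_equal(classify_root(
      mwc_params(ph$l_np[i], ph$kr_np[i], ph$kt[i])),
      "non_physiological")
  }
})

test_that("error propagation is linear-absolute with a quadrature option", {
  expect_equal(propagate_errors(function(v) v[1], 5, 0.3), 0.3)
  expect_equal(propagate_errors(function(v) v[1] + v[2], c(1, 2), c(0.1, 0.2)),
               0.3, tolerance = 1e-8)
  # opposite-sign partials must not cancel
  expect_equal(propagate_errors(function(v) v[1] - v[2], c(1, 2), c(0.1, 0.2)),
               0.3, tolerance = 1e-8)
  expect_equal(
    propagate_errors(function(v) v[1] + v[2], c(1, 2), c(3, 4),
                     method = "quadrature"), 5, tolerance = 1e-8)
  expect_equal(propagate_errors(function(v) exp(v[1]), 1, 0), 0)
  expect_gte(propagate_errors(function(v) sin(v[1]) - v[2]^2, c(2, 3),
                              c(0.1, 0.1)), 0)
  expect_error(suppressWarnings(
    propagate_errors(function(v) log(v[1]), 0, 0.1)), "coordinate")
})

test_that("propagated K_T uncertainty matches a Monte-Carlo spread", {
  x <- c(458752, 1.667e-3)
  dx <- 0.01 * x
  f <- function(v) kt_from_compounds(v[1], v[2])
  lin <- propagate_errors(f, x, dx)
  set.seed(11)
  draws <- vapply(seq_len(1e5), function(i)
    f(x + stats::runif(2, -dx, dx)), numeric(1))
  spread <- (max(draws) - min(draws)) / 2
  expect_gt(lin / spread, 0.5)
  expect_lt(lin / spread, 2)
})

test_that("input uncertainties propagate to per-root parameter deltas", {
  truth <- human_params()
  cp0 <- forward_compounds(truth)
  cp <- compound_params(cp0$lkr4, cp0$lc4, cp0$p50,
                        d_lkr4 = 0.01 * cp0$lkr4, d_lc4 = 0.01 * cp0$lc4,
                        d_p50 = 0.1)
  sol <- solve_tes(cp)
  for (r in sol$roots) {
    expect_true(all(is.finite(r$uncertainties)))
    expect_true(all(r$uncertainties >= 0))
  }
  # K_T uncertainty must equal direct propagation through the identity
  expect_equal(sol$roots[[1]]$uncertainties[["dK_T"]],
               propagate_errors(function(v) kt_from_compounds(v[1], v[2]),
                                c(cp$lkr4, cp$lc4),
                                c(cp$d_lkr4, cp$d_lc4)),
               tolerance = 1e-6)
})

test_that("the parameter-table CSV interface round-trips", {
  tmp <- tempfile(fileext = ".csv")
  cp <- forward_compounds(human_params())
  utils::write.csv(data.frame(id = "human", lkr4 = cp$lkr4, lc4 = cp$lc4,
                              p50 = cp$p50), tmp, row.names = FALSE)
  res <- solve_tes_table(utils::read.csv(tmp))
  expect_equal(nrow(res), 2)
  expect_setequal(res$label, c("physiological", "non_physiological"))
  expect_true(all(c("id", "root_index", "L", "K_R", "K_T", "c", "nH",
                    "dL", "dK_R", "dK_T", "residual") %in% names(res)))
  expect_error(solve_tes_table(data.frame(id = 1, lkr4 = 1)), "lacks column")
})
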