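make_ds <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  labeled_dataset(matrix(runif(n * d), n, d), runif(n))
}

test_that("dispersion scores implement the robust median/MAD outlyingness", {
  ds <- dispersion_scores(c(0.2, 0.4, 0.6))
  expect_equal(ds$median_y, 0.4)
  expect_equal(ds$scores[2], 0)
  expect_equal(ds$mad_y, mad(c(0.2, 0.4, 0.6), constant = 1))

  ds <- dispersion_scores(c(0, 0.5, 1))
  expect_equal(ds$median_y, 0.5)
  expect_equal(ds$mad_y, 0.5)
  expect_equal(ds$scores[3], 1)

  ds <- dispersion_scores(rep(0.3, 5))
  expect_equal(ds$scores, rep(0, 5))
  expect_error(dispersion_scores(numeric(0)), "empty")
})

test_that("with rho = 0 the neighborhood is the kappa-nearest set", {
  d <- make_ds(15, seed = 2)
  cfg <- transductive_config(N = 4, rho = 0, kernel = kernel_spec("rbf", 1))
  sel <- select_neighborhood(d, d$X[1, ] + 0.01, cfg)
  expect_equal(sort(sel$sigma), sort(order(sel$kappa_row)[1:4]))
  expect_equal(sum(sel$omega), 4)
  expect_true(all(sel$omega[sel$sigma] == 1))
  expect_error(select_neighborhood(make_ds(3), c(0, 0, 0),
                                   transductive_config(N = 5)), "exceeds")
})

test_that("two-stage selection attains the exhaustive subset optimum", {
  for (i in 1:20) {
    set.seed(100 + i)
    L <- sample(6:12, 1)
    N <- sample(2:4, 1)
    d <- make_ds(L, d = 2, seed = 200 + i)
    z <- runif(2)
    for (rho in c(0, 0.5, 2)) {
      cfg <- transductive_config(
        N = N, rho = rho, kernel = kernel_spec("rbf", 1),
        pool_multiplier = ceiling(L / N)) # pool covers the whole set
      sel <- select_neighborhood(d, z, cfg)
      ex <- exhaustive_selection(sel$kappa_row, d$y,
                                 sort(sel$pool), N, rho)
      expect_equal(sel$objective_value, ex$value, tolerance = 1e-12)
    }
  }
})

test_that("a feature-identical mislabeled example is excluded when rho is large", {
  set.seed(31)
  X <- matrix(runif(20), 10, 2)
  y <- runif(10, 0.05, 0.15)
  X[4, ] <- c(0.5, 0.5)
  y[4] <- 0.9 # mislabeled, feature-identical to the test point
  d <- labeled_dataset(X, y)
  z <- c(0.5, 0.5)
  cfg_hi <- transductive_config(N = 3, rho = 5, kernel = kernel_spec("rbf", 1))
  cfg_lo <- transductive_config(N = 3, rho = 0, kernel = kernel_spec("rbf", 1))
  expect_false(4 %in% select_neighborhood(d, z, cfg_hi)$sigma)
  expect_true(4 %in% select_neighborhood(d, z, cfg_lo)$sigma)
})

test_that("selection is deterministic with lower-index tie breaking", {
  X <- matrix(0.5, 6, 2) # all points identical: kappa ties everywhere
  d <- labeled_dataset(X, rep(0.5, 6))
  cfg <- transductive_config(N = 3, rho = 1, kernel = kernel_spec("rbf", 1))
  sel <- select_neighborhood(d, c(0.5, 0.5), cfg)
  expect_equal(sel$sigma, 1:3)
})

test_that("weighted SVR with unit weights matches an inductive reference", {
  set.seed(41)
  for (i in 1:5) {
    L <- sample(10:20, 1)
    X <- matrix(rnorm(L * 3), L, 3)
    y <- runif(L)
    C <- sample(c(0.5, 1, 4), 1); eps <- sample(c(0.05, 0.1), 1)
    m <- fit_weighted_svr(X, y, C = C, epsilon = eps,
                          kernel = kernel_spec("rbf", 0.6), tol = 1e-10)
    ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      gamma = 0.6, cost = C, epsilon = eps, scale = FALSE,
                      tolerance = 1e-8)
    beta_ref <- numeric(L); beta_ref[ref$index] <- ref$coefs
    expect_lt(max(abs(m$beta - beta_ref)), 1e-5)
    expect_lt(max(abs(predict_svr(m, X) - predict(ref, X))), 1e-5)
  }
})

test_that("dual solution satisfies its constraints and KKT tolerance", {
  set.seed(42)
  for (i in 1:10) {
    L <- sample(8:25, 1)
    X <- matrix(rnorm(L * 2), L, 2)
    y <- runif(L)
    w <- sample(c(0, 1), L, replace = TRUE)
    if (all(w == 0)) w[1] <- 1
    m <- fit_weighted_svr(X, y, weights = w, C = 2, epsilon = 0.1,
                          kernel = kernel_spec("rbf", 1))
    expect_lt(abs(sum(m$beta)), 1e-8)
    expect_true(all(abs(m$beta) <= 2 * w + 1e-8))
    expect_true(all(m$beta[w == 0] == 0))
    expect_lt(m$kkt_gap, 1e-6)
  }
  expect_error(fit_weighted_svr(matrix(rnorm(10), 5), runif(5),
                                weights = rep(0, 5)), "all weights are zero")
})

test_that("flat labels give the constant predictor with empty support", {
  X <- matrix(rnorm(20), 10, 2)
  m <- fit_weighted_svr(X, rep(0.4, 10), C = 3, epsilon = 0.1)
  expect_length(m$support_indices, 0)
  expect_equal(predict_svr(m, X), rep(0.4, 10))
})

test_that("0/1-weighted fits reduce exactly to the plain fit on the subset", {
  set.seed(50)
  for (i in 1:50) {
    L <- sample(8:30, 1)
    d <- sample(2:4, 1)
    X <- matrix(rnorm(L * d), L, d)
    y <- runif(L)
    w <- sample(c(0, 1), L, replace = TRUE, prob = c(0.4, 0.6))
    if (sum(w) < 2) w[1:2] <- 1
    kern <- kernel_spec(sample(c("rbf", "linear"), 1), gamma = 0.7)
    mw <- fit_weighted_svr(X, y, weights = w, C = 1.5, epsilon = 0.08,
                           kernel = kern, tol = 1e-10)
    ms <- fit_weighted_svr(X[w == 1, , drop = FALSE], y[w == 1], C = 1.5,
                           epsilon = 0.08, kernel = kern, tol = 1e-10)
    expect_lt(max(abs(mw$beta[w == 1] - ms$beta)), 1e-6)
    Z <- matrix(rnorm(5 * d), 5, d)
    expect_lt(max(abs(predict_svr(mw, Z) - predict_svr(ms, Z))), 1e-8)
  }
})

test_that("prediction is the support-vector kernel expansion", {
  set.seed(60)
  X <- matrix(rnorm(24), 8, 3)
  y <- runif(8)
  kern <- kernel_spec("rbf", 0.9)
  m <- fit_weighted_svr(X, y, C = 1, epsilon = 0.05, kernel = kern)
  z <- rnorm(3)
  manual <- sum(vapply(seq_len(8), function(i) {
    m$beta[i] * brute_kernel(X[i, ], z, kern)
  }, numeric(1))) + m$b
  expect_equal(predict_svr(m, z), manual, tolerance = 1e-12)
  # free support vectors are reproduced within the tube
  free <- which(abs(m$beta) > 1e-8 & abs(m$beta) < 1 - 1e-8)
  for (i in free) {
    expect_lt(abs(predict_svr(m, X[i, ]) - y[i]), 0.05 + 1e-6)
  }
})

test_that("transductive prediction equals the plain SVR on the subset", {
  set.seed(70)
  d <- make_ds(25, d = 3, seed = 70)
  cfg <- transductive_config(N = 5, kernel = kernel_spec("rbf", 1))
  for (i in 1:5) {
    z <- runif(3)
    out <- predict_transductive(d, z, cfg)
    sig <- out$selection$sigma
    ms <- fit_weighted_svr(d$X[sig, , drop = FALSE], d$y[sig], C = cfg$C,
                           epsilon = cfg$epsilon, kernel = cfg$kernel)
    expect_lt(abs(out$yhat - predict_svr(ms, z)), 1e-8)
  }
})

test_that("shared-label neighborhoods predict that label", {
  set.seed(71)
  X <- matrix(runif(30), 15, 2)
  d <- labeled_dataset(X, rep(0.6, 15))
  cfg <- transductive_config(N = 5, kernel = kernel_spec("rbf", 1))
  out <- predict_transductive(d, runif(2), cfg)
  expect_lt(abs(out$yhat - 0.6), cfg$epsilon + 1e-8)
})

test_that("prediction is local: a far-away cluster cannot perturb it", {
  set.seed(72)
  A <- matrix(rnorm(40, mean = 0, sd = 0.05), 20, 2)
  B <- matrix(rnorm(40, mean = 5, sd = 0.05), 20, 2)
  d <- labeled_dataset(rbind(A, B),
                       c(rnorm(20, 0.2, 0.01), rnorm(20, 0.8, 0.01)))
  cfg <- transductive_config(N = 5, kernel = kernel_spec("rbf", 1))
  yh <- predict_transductive(d, c(0.01, -0.01), cfg)$yhat
  expect_lt(abs(yh - 0.2), 0.1)
})

test_that("raising rho never raises the worst dispersion inside sigma", {
  set.seed(80)
  for (i in 1:15) {
    d <- make_ds(20, d = 2, seed = 300 + i)
    z <- runif(2)
    worst <- vapply(c(0, 0.5, 1, 2, 5), function(rho) {
      cfg <- transductive_config(N = 4, rho = rho,
                                 kernel = kernel_spec("rbf", 1))
      sel <- select_neighborhood(d, z, cfg)
      max(sel$dispersion_terms[sel$sigma])
    }, numeric(1))
    expect_true(all(diff(worst) <= 1e-12))
  }
})

test_that("within-subject transduction does k-fold bookkeeping", {
  d <- normalize_dataset(gen_multisubject_features(1, 50, heterogeneity = 0,
                                                   noise_sd = 0.05, seed = 1))
  rep1 <- run_st_svr(d, "s01", transductive_config(), seed = 1)
  expect_equal(rep1$n_predictions, 50)
  rep2 <- run_st_svr(d, "s01", transductive_config(), seed = 1)
  expect_equal(rep1$yhat, rep2$yhat)
  expect_error(run_st_svr(d, "nope"), "no examples")
  expect_error(run_st_svr(normalize_dataset(
    gen_multisubject_features(1, 20, seed = 2)), "s01"), "too few")
})

test_that("a homogeneous low-noise subject is predicted accurately", {
  d <- normalize_dataset(gen_multisubject_features(1, 100, heterogeneity = 0,
                                                   noise_sd = 0.01, seed = 1))
  rep <- run_st_svr(d, "s01", transductive_config(), seed = 1)
  expect_lt(rep$mae, 0.05)
})

test_that("pooled transduction matches within-subject when subjects agree", {
  d2 <- sapply(1:5, function(s) {
    d <- normalize_dataset(gen_multisubject_features(3, 150, heterogeneity = 0,
                                                     noise_sd = 0.01, seed = s))
    abs(run_t_svr(d, "s01", seed = s)$mae - run_st_svr(d, "s01", seed = s)$mae)
  })
  expect_lt(max(d2), 0.02)
  expect_error(run_t_svr(normalize_dataset(
    gen_multisubject_features(1, 30, seed = 1)), "s01"), "multi-subject")
})

test_that("pooled transduction supplements an imbalanced subject", {
  res <- sapply(1:10, function(s) {
    d <- normalize_dataset(gen_multisubject_features(
      4, 30, heterogeneity = 0.2, imbalance = 0.7, seed = s))
    t_mae <- run_t_svr(d, "s01", seed = s)$mae
    idx <- which(d$subject_id == "s01")
    subj <- labeled_dataset(d$X[idx, ], d$y[idx], d$subject_id[idx])
    fold <- rep(seq_len(5), length.out = 30)
    yh <- numeric(30)
    for (f in 1:5) {
      tr <- labeled_dataset(subj$X[fold != f, ], subj$y[fold != f])
      m <- fit_baseline_esvr(tr, transductive_config())
      yh[fold == f] <- predict_svr(m, subj$X[fold == f, , drop = FALSE])
    }
    c(t = t_mae, e = mean(abs(subj$y - yh)))
  })
  expect_lt(mean(res["t", ]), mean(res["e", ]))
})

test_that("models and selections survive a JSON round trip", {
  set.seed(90)
  X <- matrix(rnorm(30), 10, 3)
  y <- runif(10)
  m <- fit_weighted_svr(X, y, C = 2, epsilon = 0.1,
                        kernel = kernel_spec("rbf", 0.5))
  path <- tempfile(fileext = ".json")
  svr_model_to_json(m, path)
  m2 <- svr_model_from_json(path)
  Z <- matrix(rnorm(15), 5, 3)
  expect_equal(predict_svr(m2, Z), predict_svr(m, Z), tolerance = 1e-12)

  d <- labeled_dataset(X, y)
  sel <- select_neighborhood(d, rnorm(3), transductive_config(
    N = 3, kernel = kernel_spec("rbf", 0.5)))
  js <- selection_to_json(sel)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$sigma, sel$sigma)
  expect_equal(back$objective_value, sel$objective_value)
})
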