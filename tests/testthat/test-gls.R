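# simulated squares with standardized-scale covariates for model tests
sim_squares <- function(n, seed = 1) {
  set.seed(seed)
  nx <- ceiling(sqrt(n))
  data.frame(square_id = sprintf("m%04d", seq_len(n)),
             x = (rep(seq_len(nx), length.out = n) - 0.5) * 1000,
             y = (rep(seq_len(nx), each = nx)[seq_len(n)] - 0.5) * 1000,
             dist_sea = rnorm(n), width = rnorm(n),
             shoreline = rnorm(n), land_area = rnorm(n))
}

sim_response <- function(squares, beta, sigma = 0.3, rho = NULL, nu = NULL,
                         seed = 2) {
  spec <- model_spec()
  X <- cbind(1, scale(squares$dist_sea), scale(squares$width),
             scale(squares$shoreline), scale(squares$land_area))
  Z <- X[, -1]
  for (pair in spec$interactions) {
    i <- match(pair, c("dist_sea", "width", "shoreline", "land_area"))
    X <- cbind(X, Z[, i[1]] * Z[, i[2]])
  }
  n <- nrow(squares)
  set.seed(seed)
  eps <- if (is.null(rho)) rnorm(n, 0, sigma) else {
    d <- as.matrix(dist(squares[, c("x", "y")]))
    C <- (1 - nu) * exp(-d / rho) + diag(nu, n)
    drop(crossprod(chol(C), rnorm(n))) * sigma
  }
  drop(X %*% beta) + eps
}

test_that("the generalist specification drops land_area x width", {
  spec <- model_spec("generalist", drop = list(c("land_area", "width")))
  labs <- vapply(spec$interactions, function(p) paste(sort(p), collapse = ":"),
                 character(1))
  expect_length(spec$interactions, 5)
  expect_false("land_area:width" %in% labs)
  expect_length(model_spec()$interactions, 6)
})

test_that("a pure-nugget fit reproduces OLS exactly", {
  sq <- sim_squares(80, seed = 5)
  beta <- c(0.5, 0.3, -0.2, 0.25, -0.3, rep(0.1, 6))
  y <- sim_response(sq, beta, sigma = 0.2)
  rt <- data.frame(total = exp(y) - 1)   # fit works on ln(S + 1)
  fit <- fit_spatial_gls(rt, sq, model_spec("total"), nu = 1)
  X <- skerrydiv:::build_design(sq, model_spec("total"))
  ols <- lm.fit(X, y)
  expect_lt(max(abs(fit$coefficients$estimate - ols$coefficients)), 1e-6)
  # Wald interval half-width is 1.96 SE
  expect_equal(fit$coefficients$hi95 - fit$coefficients$estimate,
               1.96 * fit$coefficients$se)
  # SEs match lm's unbiased-variance Wald errors
  lf <- lm(y ~ X - 1)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(lf)))),
               tolerance = 1e-8)
})

test_that("two observations with known covariance give the closed-form GLS mean", {
  sq <- data.frame(square_id = c("a", "b"), x = c(0, 1000), y = c(0, 0))
  rt <- data.frame(total = c(3, 8))
  spec <- structure(list(response = "total", covariates = character(),
                         interactions = list()), class = "model_spec")
  rho <- 2000; nu <- 0.25
  fit <- fit_spatial_gls(rt, sq, spec, rho = rho, nu = nu)
  y <- log(rt$total + 1)
  C <- (1 - nu) * exp(-as.matrix(dist(sq[, c("x", "y")])) / rho) + diag(nu, 2)
  Ci <- solve(C)
  expect_equal(fit$coefficients$estimate,
               drop(sum(Ci %*% y) / sum(Ci)), tolerance = 1e-10)
})

test_that("the profiled likelihood dominates the OLS submodel", {
  sq <- sim_squares(100, seed = 8)
  beta <- c(0.4, 0.3, -0.2, 0.2, -0.3, rep(0, 6))
  y <- sim_response(sq, beta, sigma = 0.3, rho = 3000, nu = 0.3, seed = 11)
  rt <- data.frame(total = exp(y) - 1)
  free <- fit_spatial_gls(rt, sq, model_spec("total"))
  ols <- fit_spatial_gls(rt, sq, model_spec("total"), nu = 1)
  expect_gte(free$loglik, ols$loglik - 1e-8)
  expect_lt(free$nu, 1)   # spatial signal present and detected
})

test_that("fit agrees with nlme's exponential-correlation GLS", {
  skip_if_not_installed("nlme")
  sq <- sim_squares(90, seed = 13)
  beta <- c(0.4, 0.3, -0.2, 0.2, -0.3, rep(0.05, 6))
  y <- sim_response(sq, beta, sigma = 0.3, rho = 2500, nu = 0.2, seed = 14)
  rt <- data.frame(total = exp(y) - 1)
  ours <- fit_spatial_gls(rt, sq, model_spec("total"))
  X <- skerrydiv:::build_design(sq, model_spec("total"))
  df <- as.data.frame(X[, -1])
  names(df) <- paste0("v", seq_len(ncol(df)))
  df$y <- y; df$px <- sq$x; df$py <- sq$y
  theirs <- nlme::gls(
    y ~ v1 + v2 + v3 + v4 + v5 + v6 + v7 + v8 + v9 + v10,
    data = df, method = "ML",
    correlation = nlme::corExp(form = ~ px + py, nugget = TRUE))
  expect_equal(ours$coefficients$estimate, unname(coef(theirs)),
               tolerance = 0.02)
  expect_equal(ours$loglik, as.numeric(logLik(theirs)), tolerance = 0.01)
})

test_that("degenerate designs are refused", {
  sq <- sim_squares(30, seed = 2)
  sq$width <- sq$dist_sea
  rt <- data.frame(total = rpois(30, 4))
  expect_error(fit_spatial_gls(rt, sq, model_spec("total")),
               class = "skerrydiv_singular_design")
  expect_error(fit_spatial_gls(rt[1:5, , drop = FALSE], sq[1:5, ],
                               model_spec("total")),
               class = "skerrydiv_underdetermined")
})

test_that("confidence intervals tighten as the sample grows", {
  w <- function(n) {
    sq <- sim_squares(n, seed = 3)
    beta <- c(0.4, 0.3, -0.2, 0.2, -0.3, rep(0, 6))
    y <- sim_response(sq, beta, sigma = 0.3, seed = 4)
    rt <- data.frame(total = exp(y) - 1)
    fit <- fit_spatial_gls(rt, sq, model_spec("total"), nu = 1)
    mean(fit$coefficients$hi95 - fit$coefficients$lo95)
  }
  w100 <- w(100); w400 <- w(400)
  expect_lt(w400, w100)
  # roughly 1/sqrt(n): the ratio should be near 0.5, well below 0.75
  expect_lt(w400 / w100, 0.75)
})
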