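mk_depth <- function(m) grid_create(as.matrix(m), 0, nrow(as.matrix(m)), 1)

test_that("GPS positions snap to the lowest-snow cell within the buffer", {
  m <- matrix(50, 9, 9)
  m[2, 8] <- 5                    # unique minimum towards the NE
  depth <- mk_depth(m)
  # buffer 0: the containing cell, no search
  s0 <- snap_position(4.5, 4.5, depth, buffer = 0)
  expect_equal(c(s0$row, s0$col), c(5, 5))
  # 5 m buffer from the center reaches the minimum at row 2, col 8
  s <- snap_position(4.5, 4.5, depth, buffer = 5)
  expect_equal(c(s$row, s$col), c(2, 8))
  expect_equal(s$depth, 5)

  # two equal minima: the nearer one wins
  m2 <- matrix(50, 9, 9); m2[5, 7] <- 5; m2[5, 9] <- 5
  s2 <- snap_position(4.5, 4.5, mk_depth(m2), buffer = 5)
  expect_equal(c(s2$row, s2$col), c(5, 7))
  # equidistant equal minima: row-major order breaks the tie
  m3 <- matrix(50, 9, 9); m3[3, 5] <- 5; m3[7, 5] <- 5
  s3 <- snap_position(4.5, 4.5, mk_depth(m3), buffer = 5)
  expect_equal(c(s3$row, s3$col), c(3, 5))
  expect_error(snap_position(4.5, 4.5, depth, buffer = -1), ">= 0")
})

test_that("standardization gives zero-mean unit-sd columns with exact back-transform", {
  d <- data.frame(used = c(1, 0, 1), SNOW = c(1, 2, 3), DIST = c(10, 30, 20))
  out <- standardize_design(d)
  expect_equal(out$design$SNOW, c(-1, 0, 1))      # sample sd = 1 for {1,2,3}
  expect_equal(mean(out$design$DIST), 0)
  expect_equal(sd(out$design$DIST), 1)
  expect_equal(out$design$used, d$used)            # response untouched
  # round trip
  expect_equal(out$design$DIST * out$sds[["DIST"]] + out$means[["DIST"]],
               d$DIST)
  # already-standardized data are unchanged
  again <- standardize_design(out$design)
  expect_equal(again$design$SNOW, out$design$SNOW, tolerance = 1e-12)
  dcon <- data.frame(used = c(1, 0), SNOW = c(2, 2))
  expect_error(standardize_design(dcon), "SNOW")
})

test_that("the cloglog response function has its closed form", {
  expect_equal(snowsel:::cloglog_inv(0), 1 - exp(-1))
  expect_equal(snowsel:::cloglog_inv(0), 0.63212, tolerance = 1e-5)
  expect_equal(snowsel:::cloglog_inv(-Inf), 0)
})

sim_design <- function(n, beta, seed, link = "cloglog") {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n)
  colnames(X) <- paste0("x", seq_along(beta))
  eta <- -1 + X %*% beta
  p <- if (link == "cloglog") 1 - exp(-exp(eta)) else plogis(eta)
  data.frame(used = rbinom(n, 1, p), X)
}

test_that("cloglog ML fitting agrees with an independent GLM on coefficients and likelihood", {
  d <- sim_design(2000, c(0.5, -0.3), seed = 2)
  fit <- fit_rspf(d, c("x1", "x2"))
  ref <- glm(used ~ x1 + x2, family = binomial("cloglog"), data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  # observed-information SEs close to the GLM's expected-information SEs
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 0.05)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$log_lik)   # AIC identity
})

test_that("known selection coefficients are recovered within 3 SE", {
  d <- sim_design(5000, 0.7, seed = 5)
  fit <- fit_rspf(d, "x1")
  expect_lt(abs(fit$coefficients[["x1"]] - 0.7), 3 * fit$se[["x1"]])
  # logit link path
  dl <- sim_design(5000, 0.7, seed = 6, link = "logit")
  fl <- fit_rspf(dl, "x1", link = "logit")
  expect_lt(abs(fl$coefficients[["x1"]] - 0.7), 3 * fl$se[["x1"]])
})

test_that("the intercept-only model reproduces the sample proportion and binomial likelihood", {
  d <- data.frame(used = rep(c(1, 0), c(30, 70)), x1 = rnorm(100))
  for (lnk in c("cloglog", "logit")) {
    fit <- fit_rspf(d, "1", link = lnk)
    expect_equal(unique(round(fit$fitted, 10)), 0.3)
    expect_equal(fit$log_lik, 30 * log(0.3) + 70 * log(0.7), tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- data.frame(used = c(1, 1, 0, 0), x1 = 1:4, x2 = 2 * (1:4))
  expect_error(fit_rspf(d, c("x1", "x2")), "rank")
  expect_error(fit_rspf(data.frame(used = c(1, 1), x1 = 1:2), "x1"),
               "used and one available")
  expect_error(fit_rspf(data.frame(used = c(2, 0), x1 = 1:2), "x1"), "binary")
})

test_that("interaction terms follow model-formula syntax", {
  set.seed(9)
  n <- 3000
  d <- data.frame(SNOW = rnorm(n), LICHEN = rnorm(n))
  eta <- -1 + 0.4 * d$SNOW - 0.5 * d$SNOW * d$LICHEN
  d$used <- rbinom(n, 1, 1 - exp(-exp(eta)))
  fit <- fit_rspf(d, c("SNOW", "LICHEN", "SNOW:LICHEN"))
  expect_true("SNOW:LICHEN" %in% names(fit$coefficients))
  expect_lt(abs(fit$coefficients[["SNOW:LICHEN"]] + 0.5),
            3 * fit$se[["SNOW:LICHEN"]])
})

test_that("AIC ranking sorts models, zeroes the best, and flags the 2-unit band", {
  f1 <- list(aic = 100, k = 3); f2 <- list(aic = 101.5, k = 4)
  f3 <- list(aic = 130, k = 2)
  rk <- rank_models(list(a = f1, b = f2, c = f3))
  expect_equal(rk$model, c("a", "b", "c"))
  expect_equal(rk$delta_aic, c(0, 1.5, 30))
  expect_equal(rk$within_2, c(TRUE, TRUE, FALSE))
  expect_true(all(diff(rk$delta_aic) >= 0))
  # permutation invariance
  rk2 <- rank_models(list(c = f3, b = f2, a = f1))
  expect_equal(rk2$model, rk$model)
  single <- rank_models(list(only = f1))
  expect_equal(single$delta_aic, 0)
})

test_that("Hosmer-Lemeshow groups by fitted deciles with df = groups - 2", {
  d <- sim_design(2000, 0.8, seed = 11)
  fit <- fit_rspf(d, "x1")
  hl <- hosmer_lemeshow(fit, d, groups = 10)
  expect_equal(hl$df, 8)
  expect_equal(hl$groups_used, 10)
  expect_equal(sum(hl$table$n), 2000L)
  expect_equal(sum(hl$table$observed), sum(d$used))
  expect_gte(hl$p_value, 0)
  # identical fitted values cannot be grouped
  const <- list(fitted = rep(0.3, 100))
  expect_error(hosmer_lemeshow(const, data.frame(used = rbinom(100, 1, 0.3))),
               "identical")
  expect_error(hosmer_lemeshow(fit, d, groups = 2), ">= 3")
})

test_that("variance inflation factors match their closed form", {
  n <- 400
  # mean-zero orthonormal columns: QR against an explicit intercept column
  set.seed(12)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, -1]
  d <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3])
  expect_equal(unname(vif(d, c("a", "b", "c"))), rep(1, 3), tolerance = 1e-10)

  # two predictors with correlation exactly 0.6: VIF = 1/(1 - 0.36)
  x <- q[, 1]; z <- q[, 2]
  y <- 0.6 * x + sqrt(1 - 0.36) * z
  d2 <- data.frame(x = x, y = y)
  expect_equal(unname(vif(d2, c("x", "y"))), rep(1.5625, 2), tolerance = 1e-10)

  d3 <- data.frame(x = x, x2 = 2 * x)
  expect_true(all(is.infinite(vif(d3, c("x", "x2")))))
  expect_error(vif(d2, "x"), "two terms")
})

test_that("the design builder pairs snapped used cells with sampled availability", {
  cfg <- small_cfg(seed = 23)
  b <- generate_bundle(cfg)
  dist_surface <- distance_to_snowfree(threshold_mask(b$snow_fraction_true, 0.3))
  layers <- list(snow_depth = b$snow_depth, dem = b$dem, tpi = b$tpi_fine,
                 dist = dist_surface, lichen = b$lichen)
  d <- build_design(b$tracks, layers, n_avail = 500, seed = 1)
  counts <- attr(d, "counts")
  expect_equal(unname(counts["n_avail"]), 500L)
  expect_true(all(c("SNOW", "DIST", "LICHEN", "DEM", "DEM2", "TPI", "XCOORD")
                  %in% names(d)))
  expect_equal(d$DEM2, d$DEM^2)
  expect_false(anyNA(d))
  # determinism of the availability draw
  d2 <- build_design(b$tracks, layers, n_avail = 500, seed = 1)
  expect_equal(d, d2, ignore_attr = TRUE)
  # used rows snapped to lower snow than the raw fix on average
  pts <- do.call(rbind, b$tracks)
  raw <- grid_extract(b$snow_depth, pts$x, pts$y)
  expect_lte(mean(d$SNOW[d$used == 1]), mean(raw, na.rm = TRUE))
})
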