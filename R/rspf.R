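#' Snap a GPS position to the lowest-snow fine cell within a buffer
#'
#' GPS fixes can be off by a few meters; following the rationale that an
#' animal standing near bare ground is best represented by it, each position
#' is snapped to the fine (1 m) cell with the lowest snow depth among cells
#' whose centers lie within `buffer` meters of the fix. Ties go to the cell
#' nearest the original position, then to row-major order.
#'
#' @param x,y position coordinates (map m).
#' @param depth_fine fine snow-depth grid (cm).
#' @param buffer radius (m); 0 returns the containing cell.
#' @return list: `row`, `col`, `x`, `y` (snapped cell center), `depth`.
#' @export
snap_position <- function(x, y, depth_fine, buffer = 5) {
  if (buffer < 0) stop("`buffer` must be >= 0")
  g <- depth_fine
  rc0 <- grid_locate(g, x, y)
  if (is.na(rc0$row)) stop("position outside the grid extent")
  h <- ceiling(buffer / g$cell)
  rows <- max(1, rc0$row - h):min(nrow(g$values), rc0$row + h)
  cols <- max(1, rc0$col - h):min(ncol(g$values), rc0$col + h)
  cand <- expand.grid(row = rows, col = cols)
  cx <- g$origin_x + (cand$col - 0.5) * g$cell
  cy <- g$origin_y - (cand$row - 0.5) * g$cell
  d2 <- (cx - x)^2 + (cy - y)^2
  inside <- d2 <= buffer^2
  depth <- g$values[cbind(cand$row, cand$col)]
  ok <- inside & !is.na(depth)
  if (!any(ok)) {   # nothing usable in the buffer: keep the containing cell
    return(list(row = rc0$row, col = rc0$col,
                x = g$origin_x + (rc0$col - 0.5) * g$cell,
                y = g$origin_y - (rc0$row - 0.5) * g$cell,
                depth = g$values[rc0$row, rc0$col]))
  }
  # order: min depth, then nearest to the fix, then row-major (row, col)
  o <- order(!ok, depth, d2, cand$row, cand$col)[1]
  list(row = cand$row[o], col = cand$col[o], x = cx[o], y = cy[o],
       depth = depth[o])
}

#' Build a use-availability design from grids and tracks
#'
#' Used rows are GPS positions snapped to the lowest-snow fine cell within a
#' buffer; available rows are fine cells sampled uniformly at random without
#' replacement. Predictors extracted per fine cell: SNOW (cm), DIST (m, from
#' a distance-to-snow-free surface), LICHEN (%), DEM (m), DEM2 (DEM squared,
#' computed before standardization), TPI (m), XCOORD (map x, the east-west
#' climate-gradient proxy).
#'
#' @param tracks track data.frame or list of them.
#' @param layers named list of grids: `snow_depth` (fine), `dem` (fine),
#'   `tpi` (fine), `dist` (any resolution; looked up by coordinate),
#'   `lichen` (coarse; optional — omitted from the design when absent).
#' @param n_avail number of available cells to sample.
#' @param seed RNG seed for availability sampling.
#' @param buffer snapping radius (m).
#' @return data.frame: `used` (1/0) plus predictor columns; attribute
#'   `counts` holds `n_used`, `n_avail`.
#' @export
build_design <- function(tracks, layers, n_avail, seed = 1L, buffer = 5) {
  pts <- bind_tracks(tracks)
  g <- layers$snow_depth
  snapped <- lapply(seq_len(nrow(pts)), function(i)
    snap_position(pts$x[i], pts$y[i], g, buffer = buffer))
  used_idx <- vapply(snapped, function(s)
    (s$col - 1L) * nrow(g$values) + s$row, 0)
  avail_idx <- with_seed(seed, {
    ok <- which(!is.na(g$values))
    sample(ok, min(n_avail, length(ok)))
  })
  idx <- c(used_idx, avail_idx)
  nr <- nrow(g$values)
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1
  x <- g$origin_x + (col - 0.5) * g$cell
  y <- g$origin_y - (row - 0.5) * g$cell
  d <- data.frame(
    used = rep(c(1, 0), c(length(used_idx), length(avail_idx))),
    SNOW = g$values[cbind(row, col)],
    DIST = grid_extract(layers$dist, x, y),
    DEM = grid_extract(layers$dem, x, y),
    TPI = grid_extract(layers$tpi, x, y),
    XCOORD = x
  )
  d$DEM2 <- d$DEM^2
  if (!is.null(layers$lichen)) d$LICHEN <- grid_extract(layers$lichen, x, y)
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  attr(d, "counts") <- c(n_used = sum(d$used == 1), n_avail = sum(d$used == 0))
  d
}

#' Standardize design predictors to z-scores
#'
#' Each predictor column (everything except `used`) is centered and scaled
#' using the sample standard deviation (n - 1 denominator), computed over all
#' rows, used and available alike. DEM2 is squared before standardization.
#'
#' @param design data.frame from [build_design()].
#' @return list: `design` (standardized), `means`, `sds` (named vectors
#'   allowing exact back-transform `x * sd + mean`).
#' @export
standardize_design <- function(design) {
  cols <- setdiff(names(design), "used")
  means <- vapply(design[cols], mean, 0)
  sds <- vapply(design[cols], stats::sd, 0)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(cols[sds == 0], collapse = ", "))
  for (j in cols) design[[j]] <- (design[[j]] - means[[j]]) / sds[[j]]
  list(design = design, means = means, sds = sds)
}

cloglog_inv <- function(eta) -expm1(-exp(eta))

binom_loglik <- function(y, p) {
  eps <- .Machine$double.eps
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a resource selection probability function (binary GLM, cloglog link)
#'
#' Maximum-likelihood fit of P(used = 1 | x) with the complementary log-log
#' response `p = 1 - exp(-exp(eta))` on a used-vs-available design.
#' Estimation is iteratively reweighted least squares (Fisher scoring),
#' converged on relative log-likelihood change < `tol`; standard errors come
#' from the observed information evaluated at the optimum. Note this is the
#' naive use-availability estimator, not a weighted-distribution
#' (sampled-availability) estimator.
#'
#' @param design data.frame with a binary `used` column and predictors.
#' @param terms character vector of model terms, formula right-hand-side
#'   syntax (`"SNOW:LICHEN"` for an interaction), or a one-sided formula.
#' @param link "cloglog" (default) or "logit".
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return a `snowsel_rspf` fit: `coefficients`, `se`, `z`, `p_value`,
#'   `log_lik`, `aic`, `k`, `n`, `link`, `terms`, `fitted`, `converged`,
#'   `iterations`, `trace` (per-iteration log-likelihood).
#' @export
fit_rspf <- function(design, terms, link = c("cloglog", "logit"),
                     tol = 1e-8, max_iter = 100) {
  link <- match.arg(link)
  if (!is.numeric(design$used) || !all(design$used %in% c(0, 1)))
    stop("`used` must be a binary 0/1 column")
  if (!any(design$used == 1) || !any(design$used == 0))
    stop("need at least one used and one available row")
  f <- if (inherits(terms, "formula")) terms else stats::reformulate(terms)
  X <- stats::model.matrix(f, data = design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  y <- design$used
  linkfun <- if (link == "cloglog")
    list(inv = cloglog_inv,
         mu_eta = function(eta) exp(eta - exp(eta)))
  else
    list(inv = stats::plogis,
         mu_eta = function(eta) stats::dlogis(eta))
  beta <- numeric(ncol(X))
  # start from the intercept matching the sample proportion
  pbar <- mean(y)
  beta[1] <- if (link == "cloglog") log(-log(1 - pbar)) else stats::qlogis(pbar)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(X %*% beta)
    mu <- linkfun$inv(eta)
    mp <- linkfun$mu_eta(eta)
    v <- mu * (1 - mu)
    bad <- v < .Machine$double.eps | mp < .Machine$double.eps
    w <- ifelse(bad, 0, mp^2 / v)
    z <- eta + ifelse(bad, 0, (y - mu) / mp)
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new))
      stop("IRLS step produced NA coefficients (separation or collinearity); ",
           "iteration trace: ", paste(signif(trace, 8), collapse = ", "))
    ll <- binom_loglik(y, linkfun$inv(drop(X %*% beta_new)))
    trace <- c(trace, ll)
    beta <- beta_new
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations; ",
         "log-likelihood trace: ",
         paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
  eta <- drop(X %*% beta)
  nll <- function(b) -binom_loglik(y, linkfun$inv(drop(X %*% b)))
  H <- stats::optimHess(beta, nll)       # observed information
  se <- sqrt(diag(solve(H)))
  ll <- binom_loglik(y, linkfun$inv(eta))
  k <- ncol(X)
  zval <- beta / se
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(zval, colnames(X)),
    p_value = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
    log_lik = ll, aic = 2 * k - 2 * ll, k = k, n = length(y),
    link = link, terms = f, fitted = linkfun$inv(eta),
    converged = converged, iterations = it, trace = trace
  ), class = "snowsel_rspf")
}

#' @export
print.snowsel_rspf <- function(x, ...) {
  cat(sprintf("RSPF fit (%s link): n = %d, logLik = %.2f, AIC = %.1f\n",
              x$link, x$n, x$log_lik, x$aic))
  print(data.frame(coef = round(x$coefficients, 4), se = round(x$se, 4),
                   z = round(x$z, 2), p = signif(x$p_value, 3)))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `snowsel_rspf` fits (names label the models).
#' @return data.frame sorted by AIC: `model`, `k`, `aic`, `delta_aic`
#'   (AIC minus the minimum), `within_2` (TRUE for models within 2 AIC units
#'   of the best, where interpretation warrants caution for models that add
#'   parameters).
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fits to rank")
  if (is.null(names(fits)))
    names(fits) <- paste0("model_", seq_along(fits))
  aic <- vapply(fits, function(f) if (is.numeric(f)) f else f$aic, 0)
  k <- vapply(fits, function(f) if (is.numeric(f)) NA_integer_ else
    as.integer(f$k), 0L)
  out <- data.frame(model = names(fits), k = k, aic = aic,
                    row.names = NULL)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  out$within_2 <- out$delta_aic < 2
  rownames(out) <- NULL
  out
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Rows are grouped into `groups` bins by deciles of fitted probability;
#' `X2 = sum over groups of (O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E)`,
#' compared to chi-squared with `groups - 2` degrees of freedom. Tied fitted
#' values that empty a group merge it with its neighbor (df adjusted, noted
#' in the result).
#'
#' @param fit a `snowsel_rspf` (or list with `fitted`).
#' @param design the design the model was fit on (for the response).
#' @param groups number of probability bins (>= 3).
#' @return list: `statistic`, `df`, `p_value`, `groups_used`, `table`
#'   (per-group n, observed, expected).
#' @export
hosmer_lemeshow <- function(fit, design, groups = 10) {
  if (groups < 3) stop("`groups` must be >= 3")
  p <- fit$fitted
  y <- design$used
  if (length(unique(p)) == 1)
    stop("all fitted probabilities identical; grouping is degenerate")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) < 4)
    stop("fitted probabilities too heavily tied to form >= 3 groups")
  gidx <- cut(p, breaks = br, include.lowest = TRUE)
  tab <- data.frame(
    n = as.integer(table(gidx)),
    observed = as.numeric(tapply(y, gidx, sum)),
    expected = as.numeric(tapply(p, gidx, sum))
  )
  merged <- groups - (length(br) - 1)
  x2 <- sum((tab$observed - tab$expected)^2 / tab$expected +
              ((tab$n - tab$observed) - (tab$n - tab$expected))^2 /
              (tab$n - tab$expected))
  df <- nrow(tab) - 2
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE),
       groups_used = nrow(tab), groups_merged = merged, table = tab)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor j on
#' the remaining predictors. Perfectly collinear terms give `Inf`.
#'
#' @param design data.frame (the `used` column, if present, is ignored).
#' @param terms character vector of >= 2 column names.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design, terms = setdiff(names(design), "used")) {
  if (length(terms) < 2) stop("need at least two terms for VIF")
  X <- as.matrix(design[terms])
  vapply(stats::setNames(seq_along(terms), terms), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}
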