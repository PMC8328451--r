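# Shared fixtures: everything is built in code at test time.

# Grid from a matrix with default georeference (origin top-left at (0, nrow)).
g <- function(m, cell = 1, origin_x = 0, origin_y = nrow(as.matrix(m)) * cell) {
  grid_create(as.matrix(m), origin_x = origin_x, origin_y = origin_y,
              cell = cell)
}

# Small synthetic configuration for fast tests.
small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(list(seed = seed, extent = 300L, n_animals = 2L,
                                 n_steps = 60L), list(...))
  do.call(synthetic_config, args)
}

# A learner that always predicts a constant (for ensemble arithmetic tests).
learner_const <- function(value, name = paste0("const_", value)) {
  structure(list(name = name, n_hyper = 0L,
                 fit = function(data) value,
                 predict = function(model, newdata)
                   rep(model, nrow(newdata))),
            class = "snowsel_learner")
}

# Shoelace polygon area for GeoJSON round-trip checks.
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Independent brute-force odds-ratio/CI oracle (plain arithmetic, no reuse of
# package internals).
or_oracle <- function(a, b, c, d, z = qnorm(0.975)) {
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       p = 2 * pnorm(-abs(log(or) / se)))
}
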