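# Independent brute-force oracles for the psychometric fits.
# These evaluate the model on dense parameter grids and take the minimum
# residual sum of squares; they share no code with the package's
# Levenberg-Marquardt path.

oracle_gaussian_sse <- function(x, y,
                                a_grid = seq(0.01, 1, length.out = 34),
                                b_grid = seq(-600, 600, by = 10),
                                c_grid = seq(1, 1000, length.out = 150)) {
  bc <- expand.grid(b = b_grid, c = c_grid)
  # shape matrix: one row per (b, c), one column per SOA
  E <- exp(-((matrix(x, nrow(bc), length(x), byrow = TRUE) - bc$b) / bc$c)^2)
  best <- Inf
  for (a in a_grid) {
    sse <- rowSums((a * E - matrix(y, nrow(bc), length(y), byrow = TRUE))^2)
    best <- min(best, min(sse))
  }
  best
}

oracle_logistic_sse <- function(x, y, side,
                                b_mag = seq(0, 1, length.out = 201),
                                t_grid = seq(-800, 800, by = 5)) {
  b_grid <- if (side == "AL") b_mag else -b_mag
  bt <- expand.grid(b = b_grid, t = t_grid)
  P <- 1 / (1 + exp(bt$b * (bt$t - matrix(x, nrow(bt), length(x), byrow = TRUE))))
  min(rowSums((P - matrix(y, nrow(bt), length(y), byrow = TRUE))^2))
}

# one simulated subject's proportion curve on the standard grid
simulate_subject_curve <- function(params, n_reps = 5, seed = 1,
                                   conditions = exp1_conditions()[3, ]) {
  design <- build_design(conditions, n_reps = n_reps, seed = seed)
  resp <- simulate_responses(design, params, seed = seed + 1000L)
  sj_proportions(resp)
}

# deterministic spread of ground-truth observers over the default priors
local_params_for_seed <- function(seed) {
  draws <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(90000 + seed)
    list(a = runif(1, 0.85, 1), b = rnorm(1, 50, 40),
         c = runif(1, 200, 500), u = runif(1, 0, 0.15))
  })
  observer_params(a_peak = draws$a, b_pss = draws$b, c_tbw = draws$c,
                  unsure_rate = draws$u)
}
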