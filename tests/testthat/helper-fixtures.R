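# Fixtures built in code: final-stage analytic curves and tiny cohorts.

final_grid <- function(step = 0.1) seq(45, 90, by = step)

# A final-stage thermogram from a function of temperature.
make_final <- function(f, step = 0.1, sample_id = "fix", group = NA_character_) {
  g <- final_grid(step)
  thermogram(sample_id, g, f(g), stage = "final", group = group)
}

gaussian_curve <- function(center, sigma, height = 1) {
  function(t) height * exp(-((t - center)^2) / (2 * sigma^2))
}

# Brute-force two-sided Mann-Whitney p by enumerating labelings of the
# pooled values directly (independent of the rank-based implementation).
brute_force_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  u_obs <- u_of(x, y)
  dev <- abs(u_obs - nx * ny / 2)
  combs <- combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - nx * ny / 2) >= dev - 1e-9)
}

# Noiseless single-transition pipeline run.
noiseless_metrics <- function(mix) {
  sim <- simulate_plasma_thermogram(mix, seed = 1)
  compute_metrics(process_thermogram(sim$sample, sim$buffer))
}
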