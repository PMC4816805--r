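# Small in-code fixtures shared across test files.

make_test_cohort <- function(n = 20, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    viv <- pmin(pmax(rnorm(n, 5, 1), 1), 7)
    ctl <- pmin(pmax(rnorm(n, 5.3, 1), 1), 7)
    d <- data.frame(
      subject_id = sprintf("s%02d", seq_len(n)),
      age = runif(n, 20, 81),
      gender = rbinom(n, 1, 0.5),
      total_gm = rnorm(n, 700, 50),
      digit_span = sample(4:9, n, replace = TRUE),
      music_years = rpois(n, 3),
      bais_vividness = viv,
      bais_control = ctl,
      bais_total = (viv + ctl) / 2,
      vviq_vividness = pmin(pmax(rnorm(n, 3.6, 0.8), 1), 5),
      stringsAsFactors = FALSE)
    class(d) <- c("cohort", "data.frame")
    d
  })
}

# Random subject stack of pure-noise maps on a small grid.
make_noise_stack <- function(n = 20, shape = c(10, 10, 10), voxel = 2,
                             seed = 1, kind = "gray_matter") {
  set.seed(seed)
  g <- voxel_grid(shape, voxel)
  volume_stack(matrix(rnorm(n * prod(shape)), n), g, kind = kind)
}

# Brute-force sphere membership: triple loop over every voxel center.
oracle_sphere_count <- function(center, radius, grid) {
  cnt <- 0L
  for (i in seq_len(grid$shape[1]))
    for (j in seq_len(grid$shape[2]))
      for (k in seq_len(grid$shape[3])) {
        p <- grid$origin_mm + (c(i, j, k) - 1) * grid$voxel_size_mm
        if (sum((p - center)^2) <= radius^2 + 1e-9) cnt <- cnt + 1L
      }
  cnt
}

# Magnitude spectrum (one-sided) of a clip.
mag_spectrum <- function(clip) {
  n <- length(clip$samples)
  sp <- abs(stats::fft(clip$samples))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * clip$sample_rate / n
  list(freq = freq, mag = sp)
}
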