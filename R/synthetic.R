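#' @title Synthetic cohorts, gray-matter maps and condition t-maps
#' @name synthetic_data
#' @description
#' Generators that emulate the statistical structure the analyses assume,
#' with known ground truth for parameter recovery: a cohort of adults
#' (default n = 74 structural / 56 functional, ages 20--81) whose
#' vividness, control and visual-imagery scores are correlated latent
#' Gaussians mapped into their scale ranges; modulated-gray-matter-like
#' maps with an implanted ellipsoidal region whose volume tracks
#' vividness (target ROI correlation 0.46); and five-condition (+1
#' rotated) t-map stacks whose within-sphere representational similarity
#' is negatively coupled to vividness (target coupling -0.34). Every
#' generator is a pure function of (config, seed); ground-truth artifacts
#' are returned alongside the data and are never consumed by the analysis
#' modules.
NULL

#' Default synthetic-study configuration
#'
#' @param n_structural subjects in the structural arm.
#' @param n_functional subjects in the functional arm (first
#'   `n_functional` of the cohort).
#' @param rho_vividness_control,rho_vividness_vviq,rho_control_vviq
#'   target latent correlations between the behavioural scores.
#' @param gm_target_r target correlation between ROI gray matter and
#'   vividness.
#' @param gm_effect_center_mm,gm_effect_extent_mm center and semi-axes
#'   (mm) of the implanted ellipsoid.
#' @param gm_effect_sd between-subject SD of the implanted GM offset.
#' @param gm_noise_sd SD of the smooth between-subject GM noise field.
#' @param gm_noise_fwhm FWHM (mm) of the generator's noise smoothing.
#' @param rsa_coupling target correlation between within-vocal mean
#'   similarity and vividness (negative: more vivid = more distinct).
#' @param rsa_mean_z,rsa_sd_z cohort mean and SD of the per-subject mean
#'   within-vocal Fisher-z similarity.
#' @param rot_coupling,rot_mean_z,rot_sd_z same for the vocal-vs-rotated
#'   summary.
#' @param rsa_lambda share (in SD units) of the condition-specific
#'   pattern that is common across subjects — this is what the
#'   repeated-measures ANOVA detects.
#' @param sphere_center_mm,sphere_radius_mm the RSA/SVC target sphere.
#' @param structural_grid,functional_grid `voxel_grid`s (1.5-mm and 2-mm
#'   isotropic by default, boxes centered on the world origin).
#' @param smooth_fwhm analysis-stage smoothing FWHM in mm.
#' @param seed default seed used when a generator is called without one.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_structural = 74L,
                         n_functional = 56L,
                         rho_vividness_control = 0.68,
                         rho_vividness_vviq = 0.57,
                         rho_control_vviq = 0.40,
                         gm_target_r = 0.46,
                         gm_effect_center_mm = c(0, 0, 0),
                         gm_effect_extent_mm = c(10, 9, 9),
                         gm_effect_sd = 0.05,
                         gm_noise_sd = 0.02,
                         gm_noise_fwhm = 6,
                         rsa_coupling = -0.34,
                         rsa_mean_z = 0.83,
                         rsa_sd_z = 0.10,
                         rot_coupling = -0.42,
                         rot_mean_z = 0.55,
                         rot_sd_z = 0.12,
                         rsa_lambda = 0.5,
                         sphere_center_mm = c(0, 0, 0),
                         sphere_radius_mm = 12,
                         structural_grid = voxel_grid(c(33L, 39L, 33L), 1.5),
                         functional_grid = voxel_grid(c(31L, 37L, 31L), 2),
                         smooth_fwhm = 10,
                         seed = 1L) {
  cfg <- as.list(environment())
  R <- matrix(c(1, rho_vividness_control, rho_vividness_vviq,
                rho_vividness_control, 1, rho_control_vviq,
                rho_vividness_vviq, rho_control_vviq, 1), 3, 3)
  if (any(abs(c(rho_vividness_control, rho_vividness_vviq, rho_control_vviq,
                rsa_coupling, rot_coupling)) >= 1))
    stop("all correlation targets must lie in (-1, 1)", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("behavioural correlation target matrix is not positive definite", call. = FALSE)
  if (n_structural < 10L) stop("need at least 10 subjects", call. = FALSE)
  cfg$behavioral_R <- R
  class(cfg) <- "synth_config"
  cfg
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort
#'
#' Latent multivariate-normal imagery scores mapped into their scale
#' ranges by truncation (vividness and control on \[1, 7\], inverted
#' visual vividness on \[1, 5\]), plus the five nuisance covariates with
#' study-like means and SDs: age 42.6 (17.1) years in 20--81, binary
#' gender, total gray-matter volume in arbitrary units, forward digit
#' span 4--9, and years of musical training (0 for the untrained).
#'
#' @param config a `synth_config`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a `cohort` data frame with attribute `"latent_z"` (the
#'   untruncated latent scores — ground truth, not an analysis input).
#' @export
gen_cohort <- function(config = synth_config(), seed = config$seed) {
  n <- config$n_structural
  with_seed(seed, {
    Z <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = config$behavioral_R)
    viv <- .clamp(4.96 + 0.95 * Z[, 1], 1, 7)
    ctl <- .clamp(5.28 + 0.95 * Z[, 2], 1, 7)
    vvq <- .clamp(3.63 + 0.81 * Z[, 3], 1, 5)
    age <- .clamp(stats::rnorm(n, 42.61, 17.11), 20, 81)
    gender <- stats::rbinom(n, 1, 40 / 74)
    total_gm <- stats::rnorm(n, 700, 60)
    digit_span <- .clamp(round(stats::rnorm(n, 7.08, 1.21)), 4, 9)
    trained <- stats::rbinom(n, 1, 30 / 74)
    music_years <- trained * .clamp(round(stats::rnorm(n, 6.03, 4.47)), 1, 20)
    d <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                    age = age, gender = gender, total_gm = total_gm,
                    digit_span = digit_span, music_years = music_years,
                    bais_vividness = viv, bais_control = ctl,
                    bais_total = (viv + ctl) / 2, vviq_vividness = vvq,
                    stringsAsFactors = FALSE)
    class(d) <- c("cohort", "data.frame")
    attr(d, "latent_z") <- Z
    d
  })
}

# Smooth radial baseline "brain" with GM amount falling below the
# absolute-mask threshold toward the box edge.
.gm_baseline <- function(grid) {
  ctr <- voxel_centers(grid)
  r0 <- 0.42 * min((grid$shape - 1) * grid$voxel_size_mm)
  d2 <- rowSums(sweep(ctr, 2, grid$origin_mm + (grid$shape - 1) / 2 * grid$voxel_size_mm)^2)
  0.7 * exp(-d2 / r0^2)
}

.ellipsoid_mask <- function(grid, center_mm, extent_mm) {
  ctr <- voxel_centers(grid)
  u <- sweep(ctr, 2, center_mm)
  inside <- rowSums(sweep(u, 2, extent_mm, "/")^2) <= 1
  if (!any(inside)) stop("effect region lies outside the grid", call. = FALSE)
  inside
}

#' Generate per-subject gray-matter maps with an implanted effect
#'
#' Each map is a shared radial baseline plus a spatially smooth
#' between-subject noise field plus, inside an ellipsoidal effect region,
#' a subject-specific offset `d_i` constructed so that the ROI-mean gray
#' matter correlates with vividness at the configured target (0.46 by
#' default); values are floored at zero. Maps are returned *unsmoothed* —
#' the analysis stage applies its own 10-mm FWHM smoothing, mirroring a
#' standard morphometry pipeline.
#'
#' @param cohort a cohort from [gen_cohort()].
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return list with `stack` (a `volume_stack`, kind `"gray_matter"`) and
#'   `truth` (effect mask as a `volume_map`, per-subject implanted offset
#'   `d`, and the target correlation) — `truth` must not feed analyses.
#' @export
gen_gm_maps <- function(cohort, config = synth_config(), seed = config$seed + 1L) {
  grid <- config$structural_grid
  n <- nrow(cohort)
  V <- n_voxels(grid)
  zviv <- as.numeric(scale(cohort$bais_vividness))
  with_seed(seed, {
    base <- .gm_baseline(grid)
    inside <- .ellipsoid_mask(grid, config$gm_effect_center_mm,
                              config$gm_effect_extent_mm)
    eps <- stats::rnorm(n)
    d <- config$gm_effect_sd *
      (config$gm_target_r * zviv + sqrt(1 - config$gm_target_r^2) * eps)
    noise <- matrix(stats::rnorm(n * V), n, V)
    stk <- volume_stack(noise, grid, kind = "gray_matter",
                        subject_ids = cohort$subject_id)
    stk <- gaussian_smooth(stk, config$gm_noise_fwhm)
    # renormalize the smoothed field to the configured between-subject SD
    stk$data <- stk$data / stats::sd(as.vector(stk$data)) * config$gm_noise_sd
    stk$data <- sweep(stk$data, 2, base, "+")
    stk$data[, inside] <- stk$data[, inside] + outer(d, rep(1, sum(inside)))
    stk$data <- pmax(stk$data, 0)
    list(stack = stk,
         truth = list(effect_mask = volume_map(as.numeric(inside), grid, "mask"),
                      d = d, target_r = config$gm_target_r,
                      effect_center_mm = config$gm_effect_center_mm))
  })
}

#' Generate five-condition (+ rotated) t-map stacks
#'
#' Within the target sphere, subject `i`'s map for condition `j` is
#' `sqrt(r_i) g_i + sqrt(1 - r_i) (lambda P_j + sqrt(1 - lambda^2) q_ij)`
#' where `g_i` is a subject-shared pattern, `P_j` a condition pattern
#' common to all subjects (what the ANOVA detects), `q_ij` idiosyncratic,
#' and `r_i = tanh(z_i)` with the per-subject similarity target
#' `z_i ~ mean_z + sd_z * (coupling * z_viv + sqrt(1 - coupling^2) eps)` —
#' so the expected within-sphere pairwise correlation is `r_i` and the
#' population correlation between mean similarity and vividness equals
#' the configured coupling. The rotated condition shares `g_i` with a
#' mixing weight solved so its expected correlation with each vocal
#' condition is `tanh(z_rot_i)`. Outside the sphere all conditions share
#' a subject background plus noise (no condition effect).
#'
#' @param cohort a cohort from [gen_cohort()]; the first
#'   `config$n_functional` subjects form the functional arm.
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return list with `stack` (a `condition_stack` of kind-t maps,
#'   conditions `neutral, laughter, scream, pleasure, disgust, rotated`)
#'   and `truth` (per-subject similarity targets and the sphere).
#' @export
gen_condition_tmaps <- function(cohort, config = synth_config(),
                                seed = config$seed + 2L) {
  grid <- config$functional_grid
  n <- min(config$n_functional, nrow(cohort))
  sub <- cohort[seq_len(n), , drop = FALSE]
  zviv <- as.numeric(scale(sub$bais_vividness))
  sphere <- make_sphere_mask(config$sphere_center_mm, config$sphere_radius_mm, grid)
  V <- n_voxels(grid)
  L <- sphere$n_voxels
  k <- length(vocal_conditions)
  with_seed(seed, {
    rho <- config$rsa_coupling
    z_t <- config$rsa_mean_z +
      config$rsa_sd_z * (rho * zviv + sqrt(1 - rho^2) * stats::rnorm(n))
    r_i <- .clamp(tanh(z_t), 0.05, 0.985)
    rho2 <- config$rot_coupling
    zrot_t <- config$rot_mean_z +
      config$rot_sd_z * (rho2 * zviv + sqrt(1 - rho2^2) * stats::rnorm(n))
    rr_i <- .clamp(tanh(zrot_t)^2 / r_i, 0.02, 0.98)
    lam <- config$rsa_lambda
    P <- matrix(stats::rnorm((k + 1) * L), k + 1, L)  # row k+1 = rotated pattern
    A <- array(NA_real_, dim = c(n, k + 1, V))
    sel <- sphere$linear_indices
    out <- setdiff(seq_len(V), sel)
    for (s in seq_len(n)) {
      g <- stats::rnorm(L)
      bg <- stats::rnorm(length(out))
      for (j in seq_len(k)) {
        q <- stats::rnorm(L)
        A[s, j, sel] <- sqrt(r_i[s]) * g +
          sqrt(1 - r_i[s]) * (lam * P[j, ] + sqrt(1 - lam^2) * q)
        A[s, j, out] <- bg + 0.4 * stats::rnorm(length(out))
      }
      qr_ <- stats::rnorm(L)
      A[s, k + 1, sel] <- sqrt(rr_i[s]) * g +
        sqrt(1 - rr_i[s]) * (lam * P[k + 1, ] + sqrt(1 - lam^2) * qr_)
      A[s, k + 1, out] <- bg + 0.4 * stats::rnorm(length(out))
    }
    A <- A * 2  # t-like scale; all downstream statistics are scale-invariant
    stk <- condition_stack(A, grid,
                           conditions = c(vocal_conditions, "rotated"),
                           subject_ids = sub$subject_id)
    list(stack = stk,
         truth = list(z_target = z_t, zrot_target = zrot_t,
                      coupling = rho, rot_coupling = rho2,
                      sphere = sphere))
  })
}
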