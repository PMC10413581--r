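#' Synthetic FLAIR phantom specification
#'
#' Phantoms emulate the features the segmentation and volumetry pipeline
#' depends on: blob-like hyperintense lesions (randomly oriented digitized
#' ellipsoids, merged by union) on a darker noisy background, on a grid with
#' the acquisition geometry of 2 mm isotropic voxels. They do not attempt
#' anatomical realism or MRI physics.
#'
#' @param dim grid size in voxels (length 3).
#' @param spacing voxel spacing in mm.
#' @param n_lesions number of ellipsoidal lesions (0 gives a pure-noise
#'   phantom with an empty mask).
#' @param semi_axes range (min, max) of ellipsoid semi-axes, voxels.
#' @param mu_bg,mu_lesion background and lesion mean intensities (arbitrary
#'   FLAIR-like units; `mu_lesion > mu_bg` for hyperintensity).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed optional RNG seed for a reproducible phantom.
#' @return list of class `wmh_phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32, 32, 32), spacing = c(2, 2, 2),
                         n_lesions = 3, semi_axes = c(2, 4),
                         mu_bg = 100, mu_lesion = 160, noise_sd = 15,
                         seed = NULL) {
  if (mu_lesion <= mu_bg)
    stop_wmh("lesions must be hyperintense (mu_lesion > mu_bg)",
             class = "wmh_config_error")
  if (any(semi_axes < 1))
    stop_wmh("semi-axes must be >= 1 voxel", class = "wmh_config_error")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 semi_axes = as.numeric(semi_axes),
                 mu_bg = mu_bg, mu_lesion = mu_lesion, noise_sd = noise_sd,
                 seed = seed),
            class = "wmh_phantom_spec")
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rasterize one randomly oriented ellipsoid into `mask` (modified copy
# returned). Lesion centres keep the whole ellipsoid inside the grid.
add_ellipsoid <- function(mask, axes, dims) {
  margin <- ceiling(max(axes)) + 1
  if (any(2 * margin >= dims))
    stop_wmh("lesion of semi-axis ", max(axes),
             " cannot fit inside the ", paste(dims, collapse = "x"),
             " grid margin", class = "wmh_placement_error")
  ctr <- vapply(dims, function(n) stats::runif(1, margin + 1, n - margin),
                numeric(1))
  R <- random_rotation()
  lo <- pmax(floor(ctr - margin), 1)
  hi <- pmin(ceiling(ctr + margin), dims)
  gd <- lo[1]:hi[1]; gh <- lo[2]:hi[2]; gw <- lo[3]:hi[3]
  pts <- as.matrix(expand.grid(d = gd, h = gh, w = gw))
  u <- (pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% t(R)
  inside <- (u[, 1] / axes[1])^2 + (u[, 2] / axes[2])^2 +
    (u[, 3] / axes[3])^2 <= 1
  mask[pts[inside, , drop = FALSE]] <- 1
  mask
}

#' Generate one FLAIR-like phantom with its WMH mask
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`wmh_volume`) and `mask` (`wmh_mask`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "wmh_phantom_spec"))
  gen <- function() {
    dims <- spec$dim
    mask <- array(0, dims)
    if (spec$n_lesions > 0) {
      for (i in seq_len(spec$n_lesions)) {
        axes <- sort(stats::runif(3, spec$semi_axes[1], spec$semi_axes[2]),
                     decreasing = TRUE)
        mask <- add_ellipsoid(mask, axes, dims)
      }
    }
    img <- spec$mu_bg + (spec$mu_lesion - spec$mu_bg) * mask +
      stats::rnorm(prod(dims), 0, spec$noise_sd)
    list(image = image_volume(array(img, dims), spacing = spec$spacing),
         mask = label_mask(mask, spacing = spec$spacing))
  }
  if (!is.null(spec$seed)) with_seed(spec$seed, gen()) else gen()
}

#' Synthetic cohort specification
#'
#' Defines the statistical structure the analysis assumes: three groups with
#' ordered WMH burden (dementia > MCI > NCI, log-normal within group, group
#' means taken from the reference cohort's volume scale), covariates, and a
#' linear score model `score = b0 + bv * volume + ba * age + be * education
#' + bs * sex + noise` with negative volume coefficients for every
#' higher-is-better instrument (strongly so for MMSE and MoCA) and positive
#' ones for the timed tests. Scores are clipped to each instrument's range.
#'
#' @param group_n subjects per group, named dementia/MCI/NCI; defaults to
#'   the reference cohort sizes (8, 82, 44).
#' @param burden_meanlog,burden_sdlog per-group log-normal parameters of the
#'   WMH volume (mm3), ordered dementia, MCI, NCI.
#' @param volume_effect multiplier applied to every score's volume
#'   coefficient; 0 gives the null generator in which scores are independent
#'   of volume given the covariates.
#' @param seed optional RNG seed.
#' @return list of class `wmh_cohort_spec` (includes the per-score
#'   coefficient table as `$scores`).
#' @export
cohort_spec <- function(group_n = c(dementia = 8, MCI = 82, NCI = 44),
                        burden_meanlog = log(c(30000, 14000, 3000)),
                        burden_sdlog = c(0.5, 0.4, 0.5),
                        volume_effect = 1,
                        seed = NULL) {
  if (any(group_n <= 0))
    stop_wmh("group sizes must be positive", class = "wmh_config_error")
  if (is.unsorted(rev(burden_meanlog), strictly = TRUE))
    stop_wmh("burden means must be ordered dementia > MCI > NCI",
             class = "wmh_config_error")
  scores <- tibble::tribble(
    ~score,   ~b0,  ~bv,      ~ba,    ~be,   ~bs,  ~sd,  ~lo, ~hi,
    "mmse",   30,   -3.0e-4,  -0.04,  0.08,  0.3,  1.5,  0,   30,
    "moca",   30,   -3.5e-4,  -0.05,  0.15,  0.3,  2.0,  0,   30,
    "tmt_a",  20,    3.0e-3,   0.60, -1.00, -2.0,  20,   10,  300,
    "tmt_b",  80,    6.0e-3,   1.00, -2.00, -3.0,  35,   30,  400,
    "stroop", 60,    2.0e-3,   0.50, -0.80, -1.0,  18,   20,  250,
    "vft",    18,   -2.0e-4,  -0.05,  0.20,  0.5,  2.5,  0,   30,
    "avlt4",   8,   -1.5e-4,  -0.03,  0.08,  0.3,  1.5,  0,   15,
    "avlt5",   7.5, -1.7e-4,  -0.03,  0.08,  0.3,  1.5,  0,   15,
    "rey_o",  38,   -3.0e-4,  -0.05,  0.15,  0.0,  3.0,  0,   36,
    "bnt",    27,   -2.5e-4,  -0.03,  0.15,  0.0,  2.5,  0,   30)
  scores$bv <- scores$bv * volume_effect
  structure(list(group_n = group_n, burden_meanlog = burden_meanlog,
                 burden_sdlog = burden_sdlog, scores = scores,
                 age_mean = 70, age_sd = 7,
                 edu_mean = 10, edu_sd = 4, p_female = 0.5,
                 seed = seed),
            class = "wmh_cohort_spec")
}

#' Generate a synthetic subject cohort
#'
#' Draws per-group WMH burdens, covariates, and scores from the linear model
#' in [cohort_spec()]. With `phantoms = TRUE`, each subject additionally gets
#' a FLAIR phantom whose lesion load targets the drawn burden (lesion count
#' scaled to the burden at the template's typical lesion volume) and the
#' recorded `wmh_volume` is the instantiated mask's volume; otherwise the
#' analytic burden is used directly.
#'
#' @param spec a [cohort_spec()].
#' @param phantoms logical; also instantiate image/mask phantom pairs.
#' @param template a [phantom_spec()] used as the phantom template.
#' @return a tibble (`id`, `group`, `sex`, `age`, `education`,
#'   `wmh_volume`, ten score columns); with `phantoms = TRUE`, a list with
#'   `records` and `phantoms`.
#' @export
make_cohort <- function(spec = cohort_spec(), phantoms = FALSE,
                        template = phantom_spec()) {
  stopifnot(inherits(spec, "wmh_cohort_spec"))
  gen <- function() {
    groups <- rep(names(spec$group_n), spec$group_n)
    n <- length(groups)
    gi <- match(groups, names(spec$group_n))
    vol <- stats::rlnorm(n, spec$burden_meanlog[gi], spec$burden_sdlog[gi])
    sex <- stats::rbinom(n, 1, spec$p_female)
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    edu <- pmax(stats::rnorm(n, spec$edu_mean, spec$edu_sd), 0)
    ph <- NULL
    if (phantoms) {
      vox_mm3 <- prod(template$spacing)
      mean_axis <- mean(template$semi_axes)
      typ_vol <- 4 / 3 * pi * mean_axis^3 * vox_mm3
      ph <- lapply(vol, function(v) {
        sp <- template
        sp$seed <- NULL
        sp$n_lesions <- max(1L, round(v / typ_vol))
        make_phantom(sp)
      })
      vol <- vapply(ph, function(p) lesion_volume(p$mask), numeric(1))
    }
    rec <- tibble::tibble(
      id = sprintf("S%03d", seq_len(n)),
      group = factor(groups, levels = names(spec$group_n)),
      sex = sex, age = age, education = edu, wmh_volume = vol)
    for (i in seq_len(nrow(spec$scores))) {
      cf <- spec$scores[i, ]
      raw <- cf$b0 + cf$bv * vol + cf$ba * age + cf$be * edu + cf$bs * sex +
        stats::rnorm(n, 0, cf$sd)
      rec[[cf$score]] <- pmin(pmax(raw, cf$lo), cf$hi)
    }
    if (phantoms) list(records = rec, phantoms = ph) else rec
  }
  if (!is.null(spec$seed)) with_seed(spec$seed, gen()) else gen()
}
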