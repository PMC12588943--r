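# Synthetic multi-rater study generator: star-convex phantom tumours on a
# speckled B-mode-like background, a boundary-jitter rater model with
# omission and spurious-region errors, and difficulty ratings linked to
# expected disagreement. Everything is deterministic given the master seed.

#' Rater perturbation model
#'
#' Parameters of the synthetic observer process for one image:
#' \describe{
#'   \item{boundary_jitter}{radial perturbation scale of the truth contour,
#'     in pixels (sigma of a smooth low-order harmonic radial field).}
#'   \item{omission_prob}{probability the rater segments nothing at all.}
#'   \item{spurious_prob}{probability the rater adds a disconnected false
#'     region (e.g. mistaking posterior acoustic enhancement for tumour).}
#'   \item{spurious_size}{area of the spurious disc, in pixels.}
#'   \item{difficulty_link}{`(intercept, slope)` mapping the image's
#'     expected disagreement (0 = none, 1 = total) to the mean Likert
#'     difficulty rating.}
#'   \item{rating_noise}{sigma of the Gaussian noise on ratings before
#'     rounding and clipping to 1..10.}
#' }
#'
#' @param boundary_jitter,omission_prob,spurious_prob,spurious_size,difficulty_link,rating_noise
#'   see Description.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(boundary_jitter = 2, omission_prob = 0,
                        spurious_prob = 0, spurious_size = 60,
                        difficulty_link = c(1, 8), rating_noise = 1) {
  stopifnot(boundary_jitter >= 0,
            omission_prob >= 0, omission_prob <= 1,
            spurious_prob >= 0, spurious_prob <= 1,
            spurious_size > 0, rating_noise >= 0,
            length(difficulty_link) == 2)
  structure(list(boundary_jitter = boundary_jitter,
                 omission_prob = omission_prob,
                 spurious_prob = spurious_prob,
                 spurious_size = spurious_size,
                 difficulty_link = as.numeric(difficulty_link),
                 rating_noise = rating_noise),
            class = "rater_model")
}

# smooth periodic unit-scale field over theta: low-order harmonics, so
# rater disagreement is spatially coherent along the margin rather than
# pixelwise noise
harmonic_field <- function(theta, n_harmonics = 4, include_dc = TRUE) {
  ks <- seq_len(n_harmonics)
  amp <- stats::rnorm(n_harmonics)
  phase <- stats::runif(n_harmonics, 0, 2 * pi)
  dc <- if (include_dc) stats::rnorm(1, sd = 0.7) else 0
  f <- rep(dc, length(theta))
  for (i in ks) f <- f + amp[i] * cos(i * theta + phase[i])
  f / sqrt(if (include_dc) 0.7^2 + n_harmonics / 2 else n_harmonics / 2)
}

#' Generate a phantom tumour image
#'
#' The ground-truth "tumour" is a star-convex blob: radius
#' `r(theta) = r0 * (1 + irregularity * field(theta))` around a centre,
#' with `r0` chosen so the truth area is approximately
#' `area_frac * prod(grid)`. The synthetic B-mode base image is a speckled
#' background with the truth region brightened and, optionally, a bright
#' band beneath the truth region mimicking posterior acoustic enhancement.
#'
#' @param grid `(height, width)` in pixels, both >= 32.
#' @param area_frac target truth area as a fraction of the grid (default 0.1).
#' @param irregularity relative amplitude of the boundary harmonics.
#' @param enhancement_band add the bright sub-lesion band.
#' @param image_id identifier.
#' @param seed integer; the phantom is a deterministic function of it.
#' @return An object of class `phantom`: `image_id`, `grid`, `truth`
#'   (0/1 matrix), `base` (grayscale \[0, 255\]), plus the radial
#'   parameterisation (`centre`, `r0`, `radius_field` sampled on a fine
#'   theta grid) that [simulate_rater()] perturbs.
#' @export
make_phantom <- function(grid = c(128, 128), area_frac = 0.1,
                         irregularity = 0.12, enhancement_band = TRUE,
                         image_id = "phantom", seed = 1) {
  stopifnot(length(grid) == 2, all(grid >= 32))
  h <- grid[1]; w <- grid[2]
  r0 <- sqrt(area_frac * h * w / pi)
  if (r0 * (1 + 2 * irregularity) > min(h, w) / 2 - 2)
    stop("requested truth area is infeasible for this grid")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centre <- c(h / 2 + stats::runif(1, -h / 16, h / 16),
              w / 2 + stats::runif(1, -w / 16, w / 16))
  theta_grid <- seq(0, 2 * pi, length.out = 721)[-721]
  radius_field <- r0 * (1 + irregularity *
                          harmonic_field(theta_grid, include_dc = FALSE))
  truth <- radial_mask(h, w, centre, theta_grid, radius_field)
  # speckle-like background: gamma multiplicative texture
  base <- 60 * stats::rgamma(h * w, shape = 4, rate = 4)
  base <- matrix(base, h, w)
  base[truth == 1] <- base[truth == 1] + 70
  if (enhancement_band) {
    rows_truth <- which(rowSums(truth) > 0)
    cols_truth <- which(colSums(truth) > 0)
    if (length(rows_truth) && length(cols_truth)) {
      lo <- max(rows_truth) + 1
      hi <- min(h, lo + max(4, round(h / 12)))
      if (lo <= h)
        base[lo:hi, cols_truth] <- base[lo:hi, cols_truth] + 50
    }
  }
  base <- pmin(pmax(base, 0), 255)
  structure(list(image_id = image_id, grid = c(h, w), truth = truth,
                 base = base, centre = centre, r0 = r0,
                 theta_grid = theta_grid, radius_field = radius_field,
                 seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s: %dx%d px, truth area %d px (%.1f%%)\n",
              x$image_id, x$grid[1], x$grid[2], sum(x$truth),
              100 * mean(x$truth)))
  invisible(x)
}

# pixels whose polar radius about `centre` is below the (interpolated)
# radius field
radial_mask <- function(h, w, centre, theta_grid, radius_field) {
  rows <- matrix(seq_len(h), h, w) - centre[1]
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - centre[2]
  r <- sqrt(rows^2 + cols^2)
  th <- atan2(cols, rows) %% (2 * pi)
  idx <- findInterval(th, theta_grid)
  idx[idx == 0] <- length(theta_grid)
  matrix(as.integer(r <= radius_field[idx]), h, w)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one observer's segmentation of a phantom
#'
#' With probability `omission_prob` the rater returns an empty mask
#' (reports no tumour). Otherwise the truth contour is perturbed by a
#' smooth radial jitter field of scale `boundary_jitter` pixels, and with
#' probability `spurious_prob` a disconnected false-positive disc of area
#' `spurious_size` is added away from the truth region. Deterministic
#' given `seed`; with all perturbations zero the mask equals the truth.
#'
#' @param phantom a [make_phantom()] result.
#' @param model a [rater_model()].
#' @param seed integer.
#' @param observer_id identifier for the resulting mask.
#' @return A [mask_image].
#' @export
simulate_rater <- function(phantom, model, seed, observer_id = "rater") {
  stopifnot(inherits(phantom, "phantom"), inherits(model, "rater_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- phantom$grid[1]; w <- phantom$grid[2]
  u_omit <- stats::runif(1)
  u_spur <- stats::runif(1)
  jitter_field <- harmonic_field(phantom$theta_grid)  # drawn regardless,
  # so the stream is aligned across jitter scales and omission settings
  spur_centre <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
  if (u_omit < model$omission_prob)
    return(mask_image(matrix(0L, h, w), phantom$image_id, observer_id))
  radius <- pmax(phantom$radius_field + model$boundary_jitter * jitter_field, 1)
  px <- radial_mask(h, w, phantom$centre, phantom$theta_grid, radius)
  if (u_spur < model$spurious_prob) {
    r_spur <- sqrt(model$spurious_size / pi)
    # keep the false region disconnected from the perturbed truth blob
    max_r <- max(radius)
    for (try in 1:25) {
      d <- sqrt(sum((spur_centre - phantom$centre)^2))
      if (d > max_r + r_spur + 2 &&
          all(spur_centre > r_spur + 1) &&
          spur_centre[1] < h - r_spur && spur_centre[2] < w - r_spur) break
      spur_centre <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    }
    rows <- matrix(seq_len(h), h, w) - spur_centre[1]
    cols <- matrix(seq_len(w), h, w, byrow = TRUE) - spur_centre[2]
    px[rows^2 + cols^2 <= r_spur^2] <- 1L
  }
  mask_image(px, phantom$image_id, observer_id)
}

# analytic proxy for 1 - expected pairwise DSC of an image: omissions plus
# the boundary-jitter symmetric difference relative to the blob radius
expected_disagreement <- function(model, phantom) {
  jit <- 0.8 * model$boundary_jitter / phantom$r0
  p_om <- model$omission_prob
  base <- p_om * (2 - p_om) + (1 - p_om)^2 * jit
  min(1, base + 0.3 * model$spurious_prob)
}

#' Scenario specification for a synthetic study
#'
#' One rater model per image; per-(image, observer) child seeds are
#' derived deterministically from `master_seed` by a counter scheme
#' (`image index * 256 + observer index`), so adding an observer never
#' shifts another observer's draws.
#'
#' @param images data.frame with columns `image_id`, `tumour_type`,
#'   `stage` plus a parallel list-column or list `models` of
#'   [rater_model()]s (one per image).
#' @param n_observers number of observers.
#' @param master_seed integer master seed (< 2^31 after derivation).
#' @param grid phantom grid `(height, width)`.
#' @param area_frac phantom truth area fraction.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(images, models, n_observers = 18,
                          master_seed = 20251023, grid = c(128, 128),
                          area_frac = 0.1) {
  images <- as.data.frame(images, stringsAsFactors = FALSE)
  stopifnot(length(models) == nrow(images), n_observers >= 2)
  for (m in models) stopifnot(inherits(m, "rater_model"))
  structure(list(images = images, models = models,
                 n_observers = as.integer(n_observers),
                 master_seed = as.integer(master_seed),
                 grid = grid, area_frac = area_frac),
            class = "scenario_spec")
}

child_seed <- function(master_seed, image_idx, observer_idx = 0) {
  # counter-based: stable under adding observers or images
  (abs(master_seed) %% 2^15) * 2^16 + image_idx * 256 + observer_idx
}

#' Canonical synthetic scenario
#'
#' The default study conditions: 9 images crossing 3 tumour types
#' (metastasis, HGG, LGG) with 3 operative stages (before, during,
#' completion) for 18 observers (5 attendings, 7 fellows, 6 residents;
#' 5 high-experience `>50`, 6 low-experience `<10`). Agreement decays with
#' stage (boundary jitter 1.5 / 3 / 6 px, omission 0 / 0.02 / 0.15,
#' spurious-region probability 0.02 / 0.05 / 0.15) and is modulated by
#' tumour type (jitter multipliers 0.8 metastasis, 1.0 HGG, 1.3 LGG,
#' reflecting progressively less distinct margins). Difficulty ratings
#' follow `1 + 8 * expected disagreement` with unit rating noise, so
#' harder images get lower agreement.
#'
#' @param master_seed integer master seed.
#' @param n_observers number of observers (default 18).
#' @param grid phantom grid.
#' @return A [scenario_spec()].
#' @export
canonical_scenario <- function(master_seed = 20251023, n_observers = 18,
                               grid = c(128, 128)) {
  stage_par <- list(
    before = list(jitter = 1.5, omit = 0, spur = 0.02),
    during = list(jitter = 3, omit = 0.02, spur = 0.05),
    completion = list(jitter = 6, omit = 0.15, spur = 0.15))
  type_mult <- c(metastasis = 0.8, HGG = 1.0, LGG = 1.3)
  images <- expand.grid(tumour_type = TUMOUR_TYPES, stage = STAGES,
                        stringsAsFactors = FALSE)
  images$image_id <- sprintf("img_%s_%s", images$tumour_type, images$stage)
  models <- lapply(seq_len(nrow(images)), function(i) {
    sp <- stage_par[[images$stage[i]]]
    rater_model(boundary_jitter = sp$jitter * type_mult[[images$tumour_type[i]]],
                omission_prob = sp$omit, spurious_prob = sp$spur,
                spurious_size = 60, difficulty_link = c(1, 8),
                rating_noise = 1)
  })
  scenario_spec(images[, c("image_id", "tumour_type", "stage")], models,
                n_observers = n_observers, master_seed = master_seed,
                grid = grid)
}

canonical_observers <- function(n_observers) {
  # 18-observer template: 5 attendings (high experience), 7 fellows
  # (middle bands), 6 residents (low experience); recycled beyond 18
  grades <- rep(c("attending", "fellow", "resident"), times = c(5, 7, 6))
  bands <- rep(c(">50", "10-25", "25-50", "<10"), times = c(5, 4, 3, 6))
  idx <- ((seq_len(n_observers) - 1) %% 18) + 1
  data.frame(observer_id = sprintf("obs%02d", seq_len(n_observers)),
             grade = grades[idx], experience_band = bands[idx],
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Generates one phantom per scenario image, one mask per (image,
#' observer) cell via [simulate_rater()], and integer difficulty ratings
#' in 1..10 drawn around the difficulty-link mean for the image's expected
#' disagreement. Bit-identical output for identical specs (including
#' `master_seed`).
#'
#' @param spec a [scenario_spec()] (default: [canonical_scenario()]).
#' @return A [study_dataset] whose `base_images` are the phantom B-mode
#'   stands-ins; phantoms are attached as attribute `"phantoms"`.
#' @export
simulate_study <- function(spec = canonical_scenario()) {
  stopifnot(inherits(spec, "scenario_spec"))
  observers <- canonical_observers(spec$n_observers)
  design <- study_design(spec$images, observers)
  masks <- list()
  base_images <- list()
  phantoms <- list()
  difficulty <- vector("list", nrow(spec$images) * spec$n_observers)
  di <- 0
  for (i in seq_len(nrow(spec$images))) {
    img <- spec$images$image_id[i]
    model <- spec$models[[i]]
    ph <- make_phantom(grid = spec$grid, area_frac = spec$area_frac,
                       image_id = img,
                       seed = child_seed(spec$master_seed, i, 0))
    phantoms[[img]] <- ph
    base_images[[img]] <- ph$base
    dis <- expected_disagreement(model, ph)
    mu <- model$difficulty_link[1] + model$difficulty_link[2] * dis
    for (j in seq_len(spec$n_observers)) {
      oid <- observers$observer_id[j]
      sj <- child_seed(spec$master_seed, i, j)
      masks[[paste(img, oid, sep = "/")]] <-
        simulate_rater(ph, model, seed = sj, observer_id = oid)
      old <- .Random.seed_save()
      # ratings use their own counter slot (image index offset by 100)
      set.seed(child_seed(spec$master_seed, i + 100, j))
      rating <- as.integer(pmin(10, pmax(1, round(
        stats::rnorm(1, mu, model$rating_noise)))))
      .Random.seed_restore(old)
      di <- di + 1
      difficulty[[di]] <- data.frame(image_id = img, observer_id = oid,
                                     rating = rating, stringsAsFactors = FALSE)
    }
  }
  ds <- study_dataset(design, masks, base_images, do.call(rbind, difficulty))
  attr(ds, "phantoms") <- phantoms
  attr(ds, "scenario") <- spec
  ds
}
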