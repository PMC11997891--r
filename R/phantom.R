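#' Gaussian band model for a tissue class spectrum
#'
#' Each tissue class is emulated as a sum of Gaussian absorption bands (the
#' protein Amide A+B, Amide I and Amide II bands, the collagen 1337 cm^-1
#' band, carbohydrate and DNA/RNA bands of the fingerprint region, CH-stretch
#' lipid bands) on top of a smooth low-order polynomial drift. Every tissue
#' class must carry an Amide I component (center within 1585-1762 cm^-1) with
#' positive amplitude, because the analysis normalizes all metrics to Amide I.
#'
#' @param class_name One of benign, cancer, PanIN, inflammation, fiber,
#'   blood, necrosis.
#' @param bands Data frame with columns `center` (cm^-1, in 900-3850),
#'   `width` (cm^-1, Gaussian sigma) and `amplitude` (absorbance, >= 0).
#' @param baseline_coeffs Numeric polynomial coefficients (constant first)
#'   evaluated on the axis scaled to [0, 1]; models smooth drift.
#'
#' @return An object of class `class_spectrum_model`.
#' @export
class_spectrum_model <- function(class_name, bands, baseline_coeffs = 0) {
  stopifnot(is.data.frame(bands))
  if (!all(c("center", "width", "amplitude") %in% names(bands)))
    abort("`bands` needs columns center, width, amplitude")
  if (nrow(bands) == 0) abort("band list is empty")
  if (any(bands$amplitude < 0)) abort("band amplitudes must be >= 0")
  if (any(bands$center < 900 | bands$center > 3850))
    abort("band centers must lie within [900, 3850] cm-1")
  amide1 <- bands$center >= 1585 & bands$center <= 1762
  if (class_name %in% names(SH_CLASSES)[-1] &&
      !any(amide1 & bands$amplitude > 0))
    abort(sprintf("class '%s' lacks an Amide I band with positive amplitude",
                  class_name))
  structure(
    list(class_name = class_name, bands = tibble::as_tibble(bands),
         baseline_coeffs = as.numeric(baseline_coeffs)),
    class = "class_spectrum_model"
  )
}

#' Evaluate a class spectrum model on a wavenumber axis
#'
#' @param model A [class_spectrum_model()].
#' @param axis Strictly monotone wavenumber axis within [900, 3850] cm^-1.
#' @return Numeric vector (length of `axis`) of nonnegative absorbance.
#' @export
make_class_spectrum <- function(model, axis) {
  stopifnot(inherits(model, "class_spectrum_model"))
  axis <- as.numeric(axis)
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0)))
    abort("axis must be strictly monotone")
  if (min(axis) < 900 || max(axis) > 3850)
    abort("axis extends outside the model's band support [900, 3850] cm-1")
  if (nrow(model$bands) == 0) abort("band list is empty")
  s <- numeric(length(axis))
  for (i in seq_len(nrow(model$bands))) {
    b <- model$bands[i, ]
    s <- s + b$amplitude * exp(-0.5 * ((axis - b$center) / b$width)^2)
  }
  u <- (axis - 900) / (3850 - 900)
  drift <- numeric(length(axis))
  for (p in seq_along(model$baseline_coeffs))
    drift <- drift + model$baseline_coeffs[p] * u^(p - 1)
  pmax(s + drift, 0)
}

#' Default class spectrum models
#'
#' Surrogate band parameterizations for the seven tissue classes. Band
#' positions follow the standard mid-IR assignments (Amide A+B near 3290,
#' lipid CH stretches 2925/2855, Amide I 1655, Amide II 1545, collagen
#' amide III / proline 1337 and 1235, carbohydrate C-C/C-OH 1160, nucleic
#' acid PO2- 1080 and glycogen 1030 cm^-1); amplitudes are chosen so the
#' classes differ where the real tissue classes differ (fiber rich in
#' collagen bands, cancer/PanIN elevated in DNA/RNA and carbohydrate bands,
#' blood dominated by hemoglobin protein, necrosis protein-depleted).
#'
#' @return Named list of [class_spectrum_model()] objects.
#' @export
default_class_models <- function() {
  base_bands <- function(amide1, amide2, amideAB, lip1, lip2, coll1337,
                         coll1235, carb1160, dna1080, glyc1030) {
    data.frame(
      center   = c(1655,  1545,  3290,  2925, 2855, 1337,   1235,   1160,   1080,  1030),
      width    = c(35,    30,    120,   25,   22,   14,     22,     18,     22,    14),
      amplitude = c(amide1, amide2, amideAB, lip1, lip2, coll1337, coll1235,
                    carb1160, dna1080, glyc1030)
    )
  }
  drift <- c(0.01, 0.005)
  list(
    benign = class_spectrum_model("benign",
      base_bands(0.80, 0.42, 0.30, 0.10, 0.07, 0.040, 0.060, 0.060, 0.080, 0.070), drift),
    cancer = class_spectrum_model("cancer",
      base_bands(0.80, 0.44, 0.30, 0.07, 0.05, 0.050, 0.070, 0.130, 0.180, 0.035), drift),
    PanIN = class_spectrum_model("PanIN",
      base_bands(0.80, 0.43, 0.30, 0.08, 0.06, 0.045, 0.065, 0.105, 0.140, 0.050), drift),
    inflammation = class_spectrum_model("inflammation",
      base_bands(0.78, 0.47, 0.29, 0.06, 0.04, 0.035, 0.055, 0.075, 0.120, 0.045), drift),
    fiber = class_spectrum_model("fiber",
      base_bands(0.82, 0.40, 0.34, 0.04, 0.03, 0.130, 0.140, 0.085, 0.060, 0.045), drift),
    blood = class_spectrum_model("blood",
      base_bands(0.95, 0.55, 0.33, 0.03, 0.02, 0.020, 0.035, 0.040, 0.050, 0.020), drift),
    necrosis = class_spectrum_model("necrosis",
      base_bands(0.55, 0.28, 0.20, 0.12, 0.09, 0.030, 0.045, 0.055, 0.060, 0.030), drift)
  )
}

#' Phantom generation parameters
#'
#' The study conditions the generator emulates: a 64 x 64 focal-plane-array
#' tile measured over 3850-900 cm^-1 at 4 cm^-1 point spacing, multiplicative
#' section-thickness variation, smooth baseline drift, spatially correlated
#' plus white noise, and a per-mouse batch effect perturbing band amplitudes.
#'
#' @param image_size `(H, W)` in pixels.
#' @param axis_range Wavenumber range `(lo, hi)` in cm^-1.
#' @param axis_spacing Grid spacing in cm^-1.
#' @param class_fractions Named area fractions (classes among the seven);
#'   must sum to <= 1, remainder is background.
#' @param thickness_range Multiplicative thickness factor interval.
#' @param noise_sigma_white White-noise sigma (absorbance).
#' @param noise_sigma_corr Spatially correlated noise sigma (absorbance).
#' @param noise_corr_length Correlation length in pixels for the correlated
#'   component (Gaussian kernel sigma).
#' @param mouse_effect_sigma Log-normal sigma of the per-mouse multiplicative
#'   perturbation of each band amplitude.
#' @param background_level Flat absorbance of background (off-tissue) pixels.
#' @param seed Integer seed.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(64, 64),
                           axis_range = c(900, 3850),
                           axis_spacing = 4,
                           class_fractions = c(benign = 0.45, fiber = 0.15,
                                               inflammation = 0.10, blood = 0.05),
                           thickness_range = c(0.6, 1.4),
                           noise_sigma_white = 0.01,
                           noise_sigma_corr = 0.005,
                           noise_corr_length = 2,
                           mouse_effect_sigma = 0.05,
                           background_level = 0.02,
                           seed = 1L) {
  if (axis_spacing <= 0) abort("axis_spacing must be > 0")
  if (any(class_fractions < 0)) abort("class fractions must be >= 0")
  if (sum(class_fractions) > 1 + 1e-12)
    abort("class fractions sum exceeds 1")
  if (any(c(noise_sigma_white, noise_sigma_corr, mouse_effect_sigma) < 0))
    abort("noise and batch-effect sigmas must be >= 0")
  if (thickness_range[1] <= 0 || thickness_range[2] < thickness_range[1])
    abort("thickness_range must be an interval of positive factors")
  structure(
    list(image_size = as.integer(image_size), axis_range = axis_range,
         axis_spacing = axis_spacing, class_fractions = class_fractions,
         thickness_range = thickness_range,
         noise_sigma_white = noise_sigma_white,
         noise_sigma_corr = noise_sigma_corr,
         noise_corr_length = noise_corr_length,
         mouse_effect_sigma = mouse_effect_sigma,
         background_level = background_level, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

phantom_axis <- function(params) {
  seq(params$axis_range[1], params$axis_range[2], by = params$axis_spacing)
}

# contiguous class blobs grown by dilation from random seed pixels;
# exact pixel budget per class (targets rounded from fractions)
grow_label_mask <- function(H, W, fractions) {
  total <- H * W
  targets <- round(fractions * total)
  if (sum(targets) > total) abort("image too small to honor class fractions")
  lab <- matrix(0L, H, W)
  codes <- SH_CLASSES[names(fractions)]
  need <- as.integer(targets)
  names(need) <- names(fractions)
  place_seed <- function(lab, code) {
    free <- which(lab == 0L)
    if (length(free) == 0) return(lab)
    lab[free[sample.int(length(free), 1)]] <- code
    lab
  }
  for (cl in names(fractions)) {
    if (need[cl] > 0) {
      lab <- place_seed(lab, codes[cl])
      need[cl] <- need[cl] - 1L
    }
  }
  # frontier of class `code`: free pixels 4-adjacent to the class region
  frontier <- function(lab, code) {
    m <- lab == code
    nb <- matrix(FALSE, H, W)
    nb[-1, ] <- nb[-1, ] | m[-H, ]
    nb[-H, ] <- nb[-H, ] | m[-1, ]
    nb[, -1] <- nb[, -1] | m[, -W]
    nb[, -W] <- nb[, -W] | m[, -1]
    which(nb & lab == 0L)
  }
  while (any(need > 0)) {
    progressed <- FALSE
    for (cl in names(fractions)) {
      if (need[cl] == 0) next
      fr <- frontier(lab, codes[cl])
      if (length(fr) == 0) {
        lab2 <- place_seed(lab, codes[cl])
        if (identical(lab2, lab)) next  # image full
        lab <- lab2
        need[cl] <- need[cl] - 1L
        progressed <- TRUE
        next
      }
      take <- min(need[cl], max(1L, length(fr) %/% 2L))
      sel <- if (length(fr) == 1) fr else sample(fr, take)
      lab[sel] <- codes[cl]
      need[cl] <- need[cl] - length(sel)
      progressed <- TRUE
    }
    if (!progressed) break
  }
  lab
}

# smooth HxW random field via separable Gaussian kernel smoothing of white
# noise; rescaled to unit sd (empirical, deterministic given the draw)
smooth_field <- function(H, W, corr_len) {
  z <- matrix(rnorm(H * W), H, W)
  if (corr_len <= 0) return(z)
  half <- max(1L, ceiling(3 * corr_len))
  k <- exp(-0.5 * ((-half:half) / corr_len)^2)
  k <- k / sum(k)
  smat <- function(n) {
    S <- matrix(0, n, n)
    for (d in -half:half) {
      idx <- seq_len(n)
      j <- idx + d
      ok <- j >= 1 & j <= n
      S[cbind(idx[ok], j[ok])] <- S[cbind(idx[ok], j[ok])] + k[d + half + 1]
    }
    S / rowSums(S)
  }
  f <- smat(H) %*% z %*% t(smat(W))
  f / stats::sd(f)
}

#' Generate one synthetic mouse measurement
#'
#' Lays out contiguous class blobs matching the requested area fractions,
#' assigns every tissue pixel its (mouse-perturbed) class spectrum scaled by
#' a smooth multiplicative thickness field, and adds spatially correlated and
#' white noise. The noise-free, thickness-scaled cube is retained as
#' `clean_cube` so denoising can be scored against ground truth.
#'
#' @param params A [phantom_params()].
#' @param class_models Named list of class spectrum models; must cover the
#'   classes named in `params$class_fractions`.
#' @param mouse_id,genotype_tag Identity metadata (`control`, `KC` or `KPC`).
#' @param seed Integer seed; overrides `params$seed` when given.
#' @return An object of class `mouse_phantom` with elements `mouse_id`,
#'   `genotype`, `cube`, `labels`, `clean_cube`.
#' @export
make_phantom <- function(params, class_models = default_class_models(),
                         mouse_id = "m01", genotype_tag = "control",
                         seed = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  fr <- params$class_fractions
  if (!all(names(fr) %in% names(class_models)))
    abort("class_fractions refers to classes without a spectrum model")
  if (sum(fr) > 1 + 1e-12) abort("class fractions sum exceeds 1")
  H <- params$image_size[1]; W <- params$image_size[2]
  if (H * W < length(fr)) abort("image too small to honor class fractions")
  axis <- phantom_axis(params)
  B <- length(axis)
  seed <- if (is.null(seed)) params$seed else as.integer(seed)

  with_seed(seed, {
    labels <- grow_label_mask(H, W, fr)
    # per-mouse batch effect: log-normal multiplier on every band amplitude
    models <- lapply(class_models, function(m) {
      if (params$mouse_effect_sigma > 0) {
        mult <- exp(rnorm(nrow(m$bands), 0, params$mouse_effect_sigma))
        m$bands$amplitude <- m$bands$amplitude * mult
      }
      m
    })
    spectra <- vapply(models, make_class_spectrum, numeric(B), axis = axis)

    thick_lo <- params$thickness_range[1]; thick_hi <- params$thickness_range[2]
    tfield <- smooth_field(H, W, 4)
    u <- stats::pnorm(tfield)                 # smooth field -> [0,1]
    thickness <- thick_lo + (thick_hi - thick_lo) * u

    flat <- rep(params$background_level, B)
    Xc <- matrix(flat, H * W, B, byrow = TRUE)
    for (cl in names(fr)) {
      px <- which(labels == SH_CLASSES[cl])
      if (length(px))
        Xc[px, ] <- outer(thickness[px], spectra[, cl])
    }
    clean <- array(Xc, c(H, W, B))

    noisy <- Xc
    if (params$noise_sigma_corr > 0) {
      for (b in seq_len(B)) {
        f <- smooth_field(H, W, params$noise_corr_length)
        noisy[, b] <- noisy[, b] + params$noise_sigma_corr * as.vector(f)
      }
    }
    if (params$noise_sigma_white > 0)
      noisy <- noisy + rnorm(length(noisy), 0, params$noise_sigma_white)

    mask <- labels > 0L
    cube <- hyper_cube(array(noisy, c(H, W, B)), axis, mask,
                       mouse_id = mouse_id, genotype = genotype_tag)
    clean_cube <- hyper_cube(clean, axis, mask,
                             mouse_id = mouse_id, genotype = genotype_tag)
    structure(
      list(mouse_id = mouse_id, genotype = genotype_tag, cube = cube,
           labels = labels, clean_cube = clean_cube),
      class = "mouse_phantom"
    )
  })
}

#' @export
print.mouse_phantom <- function(x, ...) {
  cat(sprintf("<mouse_phantom> %s (%s); classes: %s\n", x$mouse_id, x$genotype,
              paste(names(SH_CLASSES)[SH_CLASSES %in% unique(as.vector(x$labels))],
                    collapse = ", ")))
  invisible(x)
}

# per-genotype area fractions: controls carry no neoplastic classes, KC mice
# develop PanIN without invasive cancer, KPC mice progress to cancer
genotype_fractions <- function(tag) {
  switch(tag,
    control = c(benign = 0.55, fiber = 0.12, inflammation = 0.08, blood = 0.05),
    KC = c(benign = 0.40, PanIN = 0.18, fiber = 0.12, inflammation = 0.08,
           blood = 0.04),
    KPC = c(benign = 0.25, cancer = 0.18, PanIN = 0.12, fiber = 0.15,
            inflammation = 0.08, blood = 0.04, necrosis = 0.06),
    abort(sprintf("unknown genotype tag '%s'", tag))
  )
}

#' Generate a synthetic cohort of mouse measurements
#'
#' Builds `n_mice` phantoms with per-genotype class layouts (controls carry
#' no cancer or PanIN pixels; KC mice carry PanIN; KPC mice carry cancer and
#' PanIN) and derives the tissue-level truth: a mouse is pathological iff its
#' label mask contains at least one cancer or PanIN pixel. Per-mouse seeds
#' are derived deterministically from the cohort seed.
#'
#' @param n_mice Number of mice (>= 2; default 19, the cohort size the
#'   pipeline is validated on).
#' @param genotype_mix Named counts over `control`, `KC`, `KPC`; must sum to
#'   `n_mice`.
#' @param params A [phantom_params()]; its `class_fractions` are replaced
#'   per genotype.
#' @param class_models Named list of class spectrum models.
#' @param seed Cohort seed.
#' @return An object of class `sh_cohort`: list with `mice` (list of
#'   [make_phantom()] results) and `tissue_truth` (named character,
#'   `healthy`/`pathological`).
#' @export
make_cohort <- function(n_mice = 19,
                        genotype_mix = c(control = 6, KC = 7, KPC = 6),
                        params = phantom_params(),
                        class_models = default_class_models(),
                        seed = 1L) {
  if (n_mice < 2) abort("need at least 2 mice for cross-validation")
  if (sum(genotype_mix) != n_mice)
    abort("genotype_mix counts must sum to n_mice")
  tags <- rep(names(genotype_mix), genotype_mix)
  mouse_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_mice))
  mice <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    p <- params
    p$class_fractions <- genotype_fractions(tags[i])
    mice[[i]] <- make_phantom(p, class_models,
                              mouse_id = sprintf("m%02d", i),
                              genotype_tag = tags[i], seed = mouse_seeds[i])
  }
  ids <- vapply(mice, `[[`, "", "mouse_id")
  truth <- vapply(mice, function(m) {
    if (any(m$labels %in% SH_CLASSES[c("cancer", "PanIN")]))
      "pathological" else "healthy"
  }, "")
  names(truth) <- ids
  structure(list(mice = mice, tissue_truth = truth), class = "sh_cohort")
}

#' @export
print.sh_cohort <- function(x, ...) {
  tab <- table(vapply(x$mice, `[[`, "", "genotype"))
  cat(sprintf("<sh_cohort> %d mice (%s); %d pathological\n",
              length(x$mice),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              sum(x$tissue_truth == "pathological")))
  invisible(x)
}
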