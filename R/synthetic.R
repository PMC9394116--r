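# Synthetic multimodal generator: labelled VIS/NIR reflectance and
# chlorophyll-fluorescence kinetic curves with controllable cross-modal
# complementarity, so fusion models can be benchmarked without field data.

#' Configuration for the synthetic multimodal generator
#'
#' Defines the statistical conditions under which labelled five-class
#' multimodal samples are simulated: per-class sample counts, curve lengths,
#' the amplitude of class-specific spectral perturbations, within-class noise,
#' and the degree of cross-modal complementarity.
#'
#' @details
#' `complementarity` interpolates between two regimes. At 0 every class is
#' separable in every modality (all four sources carry the same class signal).
#' At 1 the class pairs split: the butachlor/quinclorac pair (labels 3, 4)
#' collapses to a common template in the reflectance modalities and is
#' separable only in the kinetic curves, while the cadmium/copper pair
#' (labels 1, 2) collapses in the kinetic modalities and is separable only in
#' reflectance. In that regime no single source can exceed 80% accuracy on a
#' balanced set, while the four sources jointly identify every class.
#'
#' Default per-class counts (240, 360, 360, 268, 358) follow the group sizes
#' of the rice stress experiment the generator emulates.
#'
#' @param n_per_class Integer vector of length 5: samples per class
#'   (labels 0--4).
#' @param n_bands Number of reflectance wavebands per spectrum.
#' @param n_timepoints Number of timepoints per fluorescence kinetic curve.
#' @param class_effect_scale Nonnegative amplitude multiplier for the
#'   class-specific perturbations (0 removes all class signal).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian measurement noise
#'   added to every curve (same units as the curves; both modality families
#'   are generated on a 0--1 scale).
#' @param complementarity Real in \[0, 1\]; see Details.
#' @param seed Integer seed fixing the generated dataset.
#' @return A `synthetic_config` object (a named list).
#' @examples
#' cfg <- synthetic_config(n_per_class = rep(10, 5), noise_sd = 0)
#' @export
synthetic_config <- function(n_per_class = c(240, 360, 360, 268, 358),
                             n_bands = 396,
                             n_timepoints = 286,
                             class_effect_scale = 1,
                             noise_sd = 0.02,
                             complementarity = 0.5,
                             seed = 1L) {
  if (length(n_per_class) != 5 || any(n_per_class < 0) ||
      any(n_per_class != floor(n_per_class))) {
    stop("`n_per_class` must be 5 nonnegative integers", call. = FALSE)
  }
  if (n_bands < 1 || n_timepoints < 1) {
    stop("`n_bands` and `n_timepoints` must be positive", call. = FALSE)
  }
  if (class_effect_scale < 0) stop("`class_effect_scale` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (complementarity < 0 || complementarity > 1) {
    stop("`complementarity` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      n_bands = as.integer(n_bands),
      n_timepoints = as.integer(n_timepoints),
      class_effect_scale = class_effect_scale,
      noise_sd = noise_sd,
      complementarity = complementarity,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  samples/class:", paste(x$n_per_class, collapse = "/"), "\n")
  cat("  bands:", x$n_bands, " timepoints:", x$n_timepoints, "\n")
  cat(sprintf("  effect scale: %g  noise sd: %g  complementarity: %g  seed: %d\n",
              x$class_effect_scale, x$noise_sd, x$complementarity, x$seed))
  invisible(x)
}

check_label <- function(label) {
  if (length(label) != 1 || !label %in% 0:4) {
    stop("`label` must be a single integer in 0..4", call. = FALSE)
  }
  as.integer(label)
}

check_organ <- function(organ) {
  match.arg(organ, c("leaf", "stem"))
}

gaussian_bump <- function(x, center, width) exp(-((x - center) / width)^2)

# Reflectance class-effect bump patterns on the wavelength grid, before the
# complementarity collapse. CK (label 0) is the unperturbed control.
refl_class_pattern <- function(label, wl, organ) {
  shift <- if (organ == "stem") 8 else 0   # stem chemistry shifts bands slightly
  amp <- if (organ == "stem") 0.9 else 1
  g <- function(c0, w) gaussian_bump(wl, c0 + shift, w)
  p <- switch(as.character(label),
    "0" = 0 * wl,
    "1" =  0.9 * g(505, 18) - 1.0 * g(672, 15) + 0.5 * g(760, 22),
    "2" = -0.9 * g(528, 18) + 1.0 * g(640, 15) - 0.5 * g(805, 25),
    "3" =  1.0 * g(562, 20) + 0.8 * g(718, 16) - 0.4 * g(880, 30),
    "4" = -1.0 * g(585, 22) + 0.8 * g(692, 13) + 0.4 * g(930, 30)
  )
  amp * p
}

# Kinetic class effects: multiplicative modulations of (Fm - F0), the rise
# time constant and the steady-state fraction, before the collapse.
fkc_class_modifiers <- function(label, organ) {
  m <- switch(as.character(label),
    "0" = c(dA = 0,     dtau = 0,     ds = 0),
    "1" = c(dA = 0.22,  dtau = -0.25, ds = -0.10),
    "2" = c(dA = -0.20, dtau = 0.30,  ds = 0.12),
    "3" = c(dA = 0.28,  dtau = 0.35,  ds = -0.14),
    "4" = c(dA = -0.26, dtau = -0.30, ds = 0.16)
  )
  if (organ == "stem") m * 0.9 else m
}

# Complementarity collapse: as c -> 1 the reflectance patterns of the
# herbicide pair (3, 4) merge, and the kinetic modifiers of the heavy-metal
# pair (1, 2) merge, so each pair stays separable in one modality family only.
collapse_pair <- function(value, other, comp) {
  pair_mean <- (value + other) / 2
  (1 - comp) * value + comp * pair_mean
}

#' Smooth vegetation reflectance baseline
#'
#' The class-independent reflectance template: low visible reflectance with a
#' green-peak local maximum, a red absorption dip, and a sigmoidal red-edge
#' rise to a near-infrared plateau.
#'
#' @param n_bands Number of wavebands.
#' @param organ `"leaf"` or `"stem"`.
#' @return Tibble with columns `wavelength` (nm, spanning 454--957) and
#'   `reflectance`.
#' @export
visnir_baseline <- function(n_bands = 396, organ = c("leaf", "stem")) {
  organ <- check_organ(organ)
  wl <- seq(454, 957, length.out = n_bands)
  green <- if (organ == "leaf") 0.09 else 0.07
  plateau <- if (organ == "leaf") 0.46 else 0.42
  r <- 0.05 +
    green * gaussian_bump(wl, 552, 28) -
    0.02 * gaussian_bump(wl, 672, 22) +
    plateau / (1 + exp(-(wl - 716) / 11))
  tibble::tibble(wavelength = wl, reflectance = r)
}

#' Noise-free class templates
#'
#' The exact mean curves the generator perturbs with noise: useful as oracle
#' centroids for nearest-template classification and for plotting the class
#' structure of a configuration.
#'
#' @param label Class label in 0..4.
#' @param organ `"leaf"` or `"stem"`.
#' @param cfg A [synthetic_config()].
#' @return Numeric vector (`n_bands` for `visnir_template`, `n_timepoints`
#'   for `fkc_template`).
#' @export
visnir_template <- function(label, organ, cfg) {
  label <- check_label(label)
  organ <- check_organ(organ)
  base <- visnir_baseline(cfg$n_bands, organ)
  wl <- base$wavelength
  pat <- refl_class_pattern(label, wl, organ)
  if (label %in% 3:4) {
    other <- refl_class_pattern(if (label == 3) 4 else 3, wl, organ)
    pat <- collapse_pair(pat, other, cfg$complementarity)
  }
  pmax(base$reflectance + 0.06 * cfg$class_effect_scale * pat, 0)
}

#' @rdname visnir_template
#' @export
fkc_template <- function(label, organ, cfg) {
  label <- check_label(label)
  organ <- check_organ(organ)
  mod <- fkc_class_modifiers(label, organ)
  if (label %in% 1:2) {
    other <- fkc_class_modifiers(if (label == 1) 2 else 1, organ)
    mod <- collapse_pair(mod, other, cfg$complementarity)
  }
  s_eff <- cfg$class_effect_scale
  f0 <- if (organ == "leaf") 0.18 else 0.16
  amp <- (if (organ == "leaf") 0.75 else 0.68) * (1 + s_eff * mod[["dA"]])
  tau_r <- 0.06 * (1 + s_eff * mod[["dtau"]])
  steady <- min(max(0.55 * (1 + s_eff * mod[["ds"]]), 0.05), 0.95)
  tau_d <- 0.45
  t <- seq(0, 1, length.out = cfg$n_timepoints)
  # saturating rise from F0 toward Fm, then exponential relaxation toward the
  # steady-state fraction of the variable fluorescence
  f <- f0 + amp * (1 - exp(-t / tau_r)) * (steady + (1 - steady) * exp(-t / tau_d))
  pmax(f, 0)
}

#' Simulate one reflectance spectrum or kinetic curve
#'
#' Draws a single noisy curve for a given class and organ: the class template
#' (smooth baseline plus class-specific perturbation) plus i.i.d. Gaussian
#' noise, clipped at zero.
#'
#' @inheritParams visnir_template
#' @param seed Optional integer; when given, the draw is made reproducible by
#'   seeding the R random stream, otherwise the current stream is consumed.
#' @return Numeric nonnegative vector.
#' @examples
#' cfg <- synthetic_config(noise_sd = 0)
#' x <- generate_visnir(1, "leaf", cfg)
#' @export
generate_visnir <- function(label, organ, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- visnir_template(label, organ, cfg)
  pmax(tpl + rnorm(length(tpl), sd = cfg$noise_sd), 0)
}

#' @rdname generate_visnir
#' @export
generate_fkc <- function(label, organ, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- fkc_template(label, organ, cfg)
  pmax(tpl + rnorm(length(tpl), sd = cfg$noise_sd), 0)
}

#' Generate a labelled multimodal dataset
#'
#' Draws `sum(n_per_class)` samples, each carrying the four modality vectors
#' (leaf and stem reflectance, leaf and stem fluorescence kinetics) and the
#' class label. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per sample and columns `sample_id` (chr),
#'   `label` (int, 0--4), `class` (factor over [stress_classes]) and
#'   list-columns `l_visnir`, `s_visnir`, `l_fkc`, `s_fkc` holding the
#'   numeric curves.
#' @examples
#' d <- generate_dataset(synthetic_config(n_per_class = rep(3, 5)))
#' dplyr::count(d, class)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  labels <- rep(0:4, times = cfg$n_per_class)
  n <- length(labels)
  draw <- function(lab, fun, organ) fun(lab, organ, cfg)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    label = as.integer(labels),
    class = factor(stress_classes[labels + 1], levels = stress_classes),
    l_visnir = purrr::map(labels, draw, fun = generate_visnir, organ = "leaf"),
    s_visnir = purrr::map(labels, draw, fun = generate_visnir, organ = "stem"),
    l_fkc = purrr::map(labels, draw, fun = generate_fkc, organ = "leaf"),
    s_fkc = purrr::map(labels, draw, fun = generate_fkc, organ = "stem")
  )
}

#' Nearest-template classification
#'
#' Assigns each sample to the class whose noise-free generator template is
#' closest in Euclidean distance over the selected modalities. This is the
#' analytic Bayes-style reference classifier for synthetic data: with no noise
#' and no complementarity collapse it is exact.
#'
#' @param data Dataset tibble from [generate_dataset()].
#' @param cfg The [synthetic_config()] that generated `data`.
#' @param modalities Character subset of
#'   `c("l_visnir", "s_visnir", "l_fkc", "s_fkc")`.
#' @return `data` with an added integer column `nearest_template`.
#' @export
classify_nearest_template <- function(data, cfg,
                                      modalities = c("l_visnir", "s_visnir",
                                                     "l_fkc", "s_fkc")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  tpl_fun <- list(
    l_visnir = function(k) visnir_template(k, "leaf", cfg),
    s_visnir = function(k) visnir_template(k, "stem", cfg),
    l_fkc = function(k) fkc_template(k, "leaf", cfg),
    s_fkc = function(k) fkc_template(k, "stem", cfg)
  )
  templates <- lapply(0:4, function(k) {
    unlist(lapply(modalities, function(m) tpl_fun[[m]](k)))
  })
  feats <- modality_matrix(data, modalities)
  pred <- apply(feats, 1, function(x) {
    which.min(vapply(templates, function(tp) sum((x - tp)^2), numeric(1))) - 1L
  })
  dplyr::mutate(data, nearest_template = as.integer(pred))
}

# Stack the selected list-columns of a dataset tibble into one numeric matrix
# (rows = samples, fixed modality order).
modality_matrix <- function(data, modalities) {
  mats <- lapply(modalities, function(m) {
    do.call(rbind, data[[m]])
  })
  do.call(cbind, mats)
}
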