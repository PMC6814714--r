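# Cone-plate rheometer shear-force model for surface-tethered
# protein-filament complexes. A spinning cone applies a uniform shear rate
# to the fluid over the plate; a filament of length L and width d tethered
# flat on the surface presents a rectangular area A = L*d to the shear
# stress tau = eta * gammadot, so the tether experiences F = tau * A.
# Whether rods lie flat is judged by the Weissenberg number, the ratio of
# the shear rate to the rod's rotational diffusion coefficient.
#
# All quantities are SI internally (Pa.s, 1/s, m, N); the report/print layer
# converts to Pa, um^2 and pN.

KB_SI <- 1.380649e-23  # Boltzmann constant, J/K

#' Rheometer fluid parameters
#'
#' Defaults describe the shear-labeling experiment this model was built for:
#' a 50% glycerol solution of measured viscosity 0.02 Pa s (about 20 times
#' that of water) sheared at 6000 1/s at 16 degrees C.
#'
#' @param viscosity Dynamic viscosity, Pa s (> 0).
#' @param shear_rate Shear rate, 1/s (>= 0).
#' @param temperature Temperature, K (> 0).
#' @return List of class `rheometer_setup`.
#' @export
rheometer_setup <- function(viscosity = 0.02, shear_rate = 6000,
                            temperature = 289.15) {
  stopifnot(viscosity > 0, shear_rate >= 0, temperature > 0)
  structure(
    list(viscosity = viscosity, shear_rate = shear_rate,
         temperature = temperature),
    class = "rheometer_setup"
  )
}

#' Filament geometry
#'
#' Defaults describe phalloidin-stabilized actin filaments: mean length
#' 4.9 um, width 8 nm, lengths approximately exponentially distributed up to
#' about 20 um.
#'
#' @param mean_length Mean filament length, m.
#' @param width Filament width, m.
#' @param max_length Upper truncation of the length distribution, m
#'   (`Inf` for an untruncated exponential).
#' @return List of class `filament_geometry`.
#' @export
filament_geometry <- function(mean_length = 4.9e-6, width = 8e-9,
                              max_length = 20e-6) {
  stopifnot(width > 0, mean_length > width, max_length >= mean_length)
  structure(
    list(mean_length = mean_length, width = width, max_length = max_length),
    class = "filament_geometry"
  )
}

#' Shear stress of the fluid
#'
#' @param setup A [rheometer_setup()].
#' @return `viscosity * shear_rate`, Pa.
#' @examples
#' shear_stress(rheometer_setup(0.02, 6000))  # 120 Pa
#' @export
shear_stress <- function(setup) {
  stopifnot(inherits(setup, "rheometer_setup"))
  setup$viscosity * setup$shear_rate
}

#' Rectangular filament area
#'
#' @param geometry A [filament_geometry()].
#' @param length Filament length, m; defaults to the mean length.
#' @return `length * width`, m^2.
#' @export
filament_area <- function(geometry, length = geometry$mean_length) {
  stopifnot(inherits(geometry, "filament_geometry"), all(length > 0))
  length * geometry$width
}

#' Force on a tethered complex
#'
#' @param tau Shear stress, Pa (>= 0).
#' @param area Area presented to the shear, m^2 (>= 0).
#' @return `tau * area`, N.
#' @export
tether_force <- function(tau, area) {
  stopifnot(all(tau >= 0), all(area >= 0))
  tau * area
}

#' Rotational diffusion coefficient of a rigid rod
#'
#' Dilute-solution rigid-rod formula with a logarithmic end correction:
#' `D_r = 3 kB T (ln(L/d) - end_correction) / (pi * eta * L^3)`.
#'
#' @param geometry A [filament_geometry()]; uses the mean length and width.
#' @param setup A [rheometer_setup()]; uses viscosity and temperature.
#' @param end_correction Dimensionless end-effect constant; default 0.8.
#' @return Rotational diffusion coefficient, 1/s.
#' @export
rod_rotational_diffusion <- function(geometry, setup, end_correction = 0.8) {
  stopifnot(inherits(geometry, "filament_geometry"),
            inherits(setup, "rheometer_setup"))
  L <- geometry$mean_length
  d <- geometry$width
  if (L <= d) stop("rod length must exceed its width", call. = FALSE)
  3 * KB_SI * setup$temperature * (log(L / d) - end_correction) /
    (pi * setup$viscosity * L^3)
}

#' Weissenberg number
#'
#' Ratio of the shear rate to the rod's rotational diffusion coefficient.
#' Values far above unity mean the rods are flow-aligned and effectively lie
#' flat on the surface.
#'
#' @param setup A [rheometer_setup()].
#' @param d_r Rotational diffusion coefficient, 1/s (> 0).
#' @return Dimensionless Weissenberg number.
#' @export
weissenberg <- function(setup, d_r) {
  stopifnot(inherits(setup, "rheometer_setup"), d_r > 0)
  setup$shear_rate / d_r
}

#' Viscosity relative to a reference fluid
#'
#' @param eta Viscosity, Pa s.
#' @param eta_ref Reference viscosity, Pa s; default is water,
#'   1.0e-3 Pa s.
#' @return `eta / eta_ref`.
#' @export
viscosity_ratio <- function(eta, eta_ref = 1.0e-3) {
  stopifnot(eta_ref > 0)
  eta / eta_ref
}

# rate of an exponential truncated at max_len whose truncated mean equals
# mean_len; untruncated (max_len = Inf) reduces to 1/mean_len
truncated_exp_rate <- function(mean_len, max_len) {
  if (!is.finite(max_len)) return(1 / mean_len)
  if (mean_len >= max_len / 2) {
    stop("mean_length must be < max_length/2: the mean of an exponential ",
         "truncated at max_length cannot exceed max_length/2", call. = FALSE)
  }
  tmean <- function(lam) 1 / lam - max_len * exp(-lam * max_len) /
    (1 - exp(-lam * max_len))
  stats::uniroot(
    function(lam) tmean(lam) - mean_len,
    lower = 1e-6 / mean_len, upper = 1e3 / mean_len, tol = 1e-14
  )$root
}

# survival function P(L > l) of the (possibly truncated) exponential
truncated_exp_sf <- function(l, rate, max_len) {
  if (!is.finite(max_len)) return(exp(-rate * l))
  z <- 1 - exp(-rate * max_len)
  out <- (exp(-rate * pmin(l, max_len)) - exp(-rate * max_len)) / z
  out[l >= max_len] <- 0
  out
}

truncated_exp_quantile <- function(q, rate, max_len) {
  z <- if (is.finite(max_len)) 1 - exp(-rate * max_len) else 1
  -log(1 - q * z) / rate
}

#' Force distribution over a filament-length ensemble
#'
#' Filament lengths follow an exponential distribution truncated at
#' `max_length`, with rate solved so the truncated mean equals
#' `mean_length`. Since `F = tau * L * width` is linear in length, force
#' quantiles and threshold-exceedance fractions follow in closed form from
#' the length distribution; a seeded Monte Carlo sample cross-checks them.
#'
#' @param geometry A [filament_geometry()].
#' @param setup A [rheometer_setup()].
#' @param thresholds Numeric vector of force thresholds (N, >= 0) whose
#'   exceedance fractions are reported.
#' @param quantiles Probability levels for reported force quantiles.
#' @param n_samples Monte Carlo sample size.
#' @param seed Integer seed for the Monte Carlo draw (RNG state restored on
#'   exit).
#' @return List of class `force_report`: `shear_stress` (Pa), `area` (m^2,
#'   at mean length), `force` (N, at mean length), `rotational_diffusion`
#'   (1/s), `weissenberg`, `mean_force` (N, ensemble mean, equal to `force`
#'   by construction), `force_quantiles` (N), `fraction_above` (closed
#'   form), `mc_mean_force` and `mc_fraction_above` (Monte Carlo
#'   cross-checks), `rate` (1/m), and the inputs.
#' @export
force_distribution <- function(geometry, setup, thresholds = numeric(),
                               quantiles = c(0.25, 0.5, 0.75, 0.95),
                               n_samples = 1e5, seed = 1L) {
  stopifnot(inherits(geometry, "filament_geometry"),
            inherits(setup, "rheometer_setup"),
            all(thresholds >= 0), all(quantiles > 0 & quantiles < 1))
  tau <- shear_stress(setup)
  rate <- truncated_exp_rate(geometry$mean_length, geometry$max_length)
  per_len <- tau * geometry$width          # N per metre of filament
  thr_len <- if (per_len > 0) thresholds / per_len else rep(Inf, length(thresholds))

  frac_above <- truncated_exp_sf(thr_len, rate, geometry$max_length)
  names(frac_above) <- format(thresholds, digits = 4)
  fq <- per_len * truncated_exp_quantile(quantiles, rate, geometry$max_length)
  names(fq) <- format(quantiles)

  lens <- with_preserved_seed(seed, {
    u <- stats::runif(n_samples)
    truncated_exp_quantile(u, rate, geometry$max_length)
  })
  mc_forces <- per_len * lens
  mc_above <- vapply(thresholds, function(th) mean(mc_forces > th), double(1))
  names(mc_above) <- names(frac_above)

  d_r <- rod_rotational_diffusion(geometry, setup)
  structure(
    list(
      shear_stress = tau,
      area = filament_area(geometry),
      force = tether_force(tau, filament_area(geometry)),
      rotational_diffusion = d_r,
      weissenberg = weissenberg(setup, d_r),
      mean_force = per_len * geometry$mean_length,
      force_quantiles = fq,
      fraction_above = frac_above,
      mc_mean_force = mean(mc_forces),
      mc_fraction_above = mc_above,
      rate = rate,
      geometry = geometry,
      setup = setup,
      n_samples = n_samples,
      seed = seed
    ),
    class = "force_report"
  )
}

#' @export
print.force_report <- function(x, ...) {
  cat("Cone-plate shear-force report\n")
  cat(sprintf("  shear stress          %8.3g Pa\n", x$shear_stress))
  cat(sprintf("  mean filament area    %8.4g um^2\n", x$area * 1e12))
  cat(sprintf("  force (mean length)   %8.3g pN\n", x$force * 1e12))
  cat(sprintf("  rotational diffusion  %8.3g 1/s\n", x$rotational_diffusion))
  cat(sprintf("  Weissenberg number    %8.3g\n", x$weissenberg))
  if (length(x$fraction_above)) {
    cat("  fraction above threshold (closed form):\n")
    for (i in seq_along(x$fraction_above)) {
      cat(sprintf("    F > %s N: %.4f\n",
                  names(x$fraction_above)[i], x$fraction_above[i]))
    }
  }
  invisible(x)
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
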