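# Quencher-diffusion model of fluorescence decay through a porous cell wall.
#
# The wall (thickness h) separates a quencher bath at constant concentration
# q_b from the fluorophore-labelled plasma membrane (thickness h_m << h).
# Fickian diffusion through the porous wall, with an effective diffusion
# coefficient shaped by the porosity phi and Bruggeman tortuosity
# eta(phi) = phi^(-1/2), loads the membrane with quencher:
#   q_m(t) = q_b * (1 - exp(-t/T)),   T = h_m * h / D_e
# and Stern-Volmer quenching maps concentration to relative fluorescence:
#   I(t) = 1 / (1 + K * q_m(t)).
# Fitting I(t) per genotype yields (K, T); under the Bruggeman law the
# porosity ratio of two samples follows from their characteristic times as
# (T_ref/T_alt)^(2/3).

#' Wall geometry
#'
#' Geometric description of the cell wall/plasma membrane sandwich.
#'
#' @param h Wall thickness in metres (reference magnitude ~280e-9).
#' @param h_m Membrane thickness in metres (~10e-9); must be smaller than
#'   `h`, as the model assumes a thin membrane compartment.
#' @param A Sample area in square metres. It cancels in the membrane
#'   concentration dynamics and only scales the cumulative diffused amount.
#' @return An object of class `wall_geometry`.
#' @export
wall_geometry <- function(h, h_m, A = 1) {
  if (!is.numeric(h) || h <= 0) stop("wall thickness h must be > 0")
  if (!is.numeric(h_m) || h_m <= 0) stop("membrane thickness h_m must be > 0")
  if (h_m >= h) stop("membrane thickness h_m must be smaller than wall thickness h")
  if (!is.numeric(A) || A <= 0) stop("sample area A must be > 0")
  structure(list(h = h, h_m = h_m, A = A), class = "wall_geometry")
}

#' Porous medium description of the cell wall
#'
#' @param phi Porosity (void fraction), in (0, 1].
#' @param C Pore diffusion attenuation factor in (0, 1]: the quencher
#'   diffuses at `C * D` inside a pore, with `C` typically much below 1.
#' @param D Bath diffusion coefficient of the quencher, m^2 s^-1.
#' @param tortuosity_rule Name of the tortuosity law; only `"bruggeman"`
#'   ships.
#' @return An object of class `porous_medium`.
#' @export
porous_medium <- function(phi, C, D, tortuosity_rule = "bruggeman") {
  if (!is.numeric(phi) || phi <= 0 || phi > 1) stop("porosity phi must lie in (0, 1]")
  if (!is.numeric(C) || C <= 0 || C > 1) stop("attenuation factor C must lie in (0, 1]")
  if (!is.numeric(D) || D <= 0) stop("bath diffusion coefficient D must be > 0")
  structure(list(phi = phi, C = C, D = D, tortuosity_rule = tortuosity_rule),
            class = "porous_medium")
}

#' Bruggeman tortuosity
#'
#' Tortuosity of a homogeneous isotropic porous medium as a function of its
#' porosity, `eta = phi^(-1/2)`.
#'
#' @param phi Porosity in (0, 1].
#' @return Tortuosity, a dimensionless value >= 1, decreasing in `phi`.
#' @examples
#' bruggeman_tortuosity(1)    # 1
#' bruggeman_tortuosity(0.25) # 2
#' @export
bruggeman_tortuosity <- function(phi) {
  if (!is.numeric(phi) || any(phi <= 0) || any(phi > 1))
    stop("porosity phi must lie in (0, 1]")
  phi^(-1 / 2)
}

#' Evaluate a tortuosity law by name
#'
#' @param phi Porosity in (0, 1].
#' @param rule Law identifier; `"bruggeman"` is the only built-in rule.
#' @return Tortuosity eta(phi).
#' @export
tortuosity <- function(phi, rule = "bruggeman") {
  switch(rule,
    bruggeman = bruggeman_tortuosity(phi),
    stop("unknown tortuosity rule: ", rule)
  )
}

#' Effective diffusion coefficient in the wall
#'
#' `D_e = C * phi * D / eta(phi)`: the bath coefficient attenuated by
#' confinement (`C`), reduced cross-section (`phi`) and path complexity
#' (`eta`).
#'
#' @param medium A [porous_medium()].
#' @return Effective diffusion coefficient in m^2 s^-1, bounded by `D`.
#' @export
effective_diffusion <- function(medium) {
  stopifnot(inherits(medium, "porous_medium"))
  eta <- tortuosity(medium$phi, medium$tortuosity_rule)
  medium$C * medium$phi * medium$D / eta
}

#' Characteristic time of membrane quencher accumulation
#'
#' `T = h_m * h / D_e`: the exponential timescale of the membrane
#' concentration; slower for thicker walls and less porous media.
#'
#' @param geom A [wall_geometry()].
#' @param medium A [porous_medium()].
#' @return Characteristic time in seconds.
#' @export
characteristic_time <- function(geom, medium) {
  stopifnot(inherits(geom, "wall_geometry"))
  geom$h_m * geom$h / effective_diffusion(medium)
}

#' Membrane quencher concentration at time t
#'
#' Closed-form solution `q_m(t) = q_b * (1 - exp(-t/T))` of the lumped
#' loading equation, with `q_m(0) = 0`.
#'
#' @param t Time(s) in seconds, non-negative.
#' @param q_b Bath quencher concentration, mol m^-3.
#' @param T_char Characteristic time in seconds.
#' @return Membrane concentration(s), mol m^-3, bounded by `q_b`.
#' @export
membrane_concentration <- function(t, q_b, T_char) {
  if (any(t < 0)) stop("time t must be non-negative")
  if (q_b <= 0) stop("bath concentration q_b must be > 0")
  if (T_char <= 0) stop("characteristic time must be > 0")
  q_b * (1 - exp(-t / T_char))
}

#' Diffusional flux of quencher into the wall
#'
#' Fick's law across the wall with the lumped concentration gradient
#' `(q_b - q_m)/h`: `J_D = -D_e * (q_b - q_m)/h`. The sign convention is
#' that flux into the wall is negative while the membrane is undersaturated.
#'
#' @param D_e Effective diffusion coefficient, m^2 s^-1.
#' @param q_b Bath concentration, mol m^-3.
#' @param q_m Membrane concentration, mol m^-3.
#' @param h Wall thickness, m.
#' @return Flux in mol m^-2 s^-1.
#' @export
diffusional_flux <- function(D_e, q_b, q_m, h) {
  if (h <= 0) stop("wall thickness h must be > 0")
  -D_e * (q_b - q_m) / h
}

#' Numerically integrate the membrane loading ODE
#'
#' Solves `dq_m/dt = (q_b - q_m)/T` with `q_m(0) = 0` using `deSolve::lsoda`
#' at tight tolerances. Serves as the independent numerical check of the
#' closed form computed by [membrane_concentration()].
#'
#' @param q_b Bath concentration, mol m^-3.
#' @param T_char Characteristic time, s.
#' @param t_grid Increasing time grid starting at 0, s.
#' @param rtol,atol Solver tolerances.
#' @return Numeric vector of q_m on `t_grid`.
#' @export
integrate_ode <- function(q_b, T_char, t_grid, rtol = 1e-10, atol = NULL) {
  if (t_grid[1] != 0) stop("t_grid must start at 0 (initial condition q_m(0) = 0)")
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  if (T_char <= 0) stop("characteristic time must be > 0")
  if (is.null(atol)) atol <- max(1e-14 * q_b, 1e-30)
  rhs <- function(t, y, parms) list((parms$q_b - y) / parms$T_char)
  sol <- deSolve::lsoda(
    y = 0, times = t_grid, func = rhs,
    parms = list(q_b = q_b, T_char = T_char),
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "))
  as.numeric(sol[, 2])
}

#' Stern-Volmer relative fluorescence intensity
#'
#' `I = 1 / (1 + K * q_m)` relates relative intensity F/F0 to the quencher
#' concentration at the fluorophore.
#'
#' @param q_m Quencher concentration(s), mol m^-3, non-negative.
#' @param K Stern-Volmer quencher constant, m^3 mol^-1 (equal to the product
#'   of the quenching rate coefficient and the unquenched decay timescale).
#' @return Relative intensity in (0, 1].
#' @export
stern_volmer_intensity <- function(q_m, K) {
  if (any(q_m < 0)) stop("quencher concentration q_m must be non-negative")
  if (K <= 0) stop("Stern-Volmer constant K must be > 0")
  1 / (1 + K * q_m)
}

#' Forward-simulate the fluorescence decay curve
#'
#' Composes membrane loading with Stern-Volmer quenching:
#' `I(t) = 1 / (1 + K * q_b * (1 - exp(-t/T)))`. `I(0) = 1` and the curve
#' decays monotonically to the plateau `1 / (1 + K * q_b)`.
#'
#' @param times Times in seconds (non-negative).
#' @param K Stern-Volmer constant, m^3 mol^-1.
#' @param T_char Characteristic time, s.
#' @param q_b Bath concentration, mol m^-3.
#' @param label Sample label attached to the returned series.
#' @return A `data.frame` with columns `time_s`, `intensity`, `label`,
#'   `replicate_id` (a fluorescence series).
#' @export
forward_decay <- function(times, K, T_char, q_b, label = "sample") {
  q_m <- membrane_concentration(times, q_b, T_char)
  data.frame(
    time_s = times,
    intensity = stern_volmer_intensity(q_m, K),
    label = label,
    replicate_id = 1L,
    stringsAsFactors = FALSE
  )
}

#' Fit the quenching decay model to a fluorescence series
#'
#' Nonlinear least squares of `I(t) = 1/(1 + K*q_b*(1 - exp(-t/T)))` jointly
#' over `(K, T)` with positivity bounds (Levenberg-Marquardt via
#' \pkg{minpack.lm}). The objective is ordinary least squares on the
#' intensities themselves, since that is where measurement noise lives; the
#' t = 0 observation participates like any other and `I(0)` is not pinned
#' to 1. By default replicate ROIs are averaged per time point before
#' fitting (`mode = "mean"`); `mode = "pooled"` fits all replicate
#' observations jointly with shared `(K, T)`.
#'
#' @param series A fluorescence series `data.frame` with columns `time_s`,
#'   `intensity` and optionally `replicate_id`.
#' @param q_b Bath quencher concentration, mol m^-3 (known from the assay).
#' @param init Optional named list with starting values `K` and `T`. When
#'   absent, `K` starts from the plateau estimate `(1/I_last - 1)/q_b` and
#'   `T` from half the observation window.
#' @param mode `"mean"` (default) or `"pooled"`; see Details.
#' @return An object of class `quench_fit`: a list with `K_hat`, `T_hat`,
#'   `se_K`, `se_T`, `rss`, `n`, `converged`.
#' @export
fit_decay <- function(series, q_b, init = NULL, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(series), all(c("time_s", "intensity") %in% names(series)))
  if (q_b <= 0) stop("bath concentration q_b must be > 0")
  if (any(series$intensity <= 0)) stop("intensities must be > 0")

  if (mode == "mean" && "replicate_id" %in% names(series)) {
    agg <- stats::aggregate(intensity ~ time_s, data = series, FUN = mean)
    tt <- agg$time_s
    ii <- agg$intensity
  } else {
    tt <- series$time_s
    ii <- series$intensity
  }
  ord <- order(tt)
  tt <- tt[ord]; ii <- ii[ord]
  if (length(unique(tt)) < 3) stop("need at least 3 distinct time points to fit (K, T)")
  if (stats::sd(ii) == 0)
    stop("degenerate fit: intensities are constant (no quenching signal)")

  # starting values: K from the plateau of the last time point; T by
  # inverting the model at the earliest interior point, with half the
  # observation window as fallback. Several T starts guard against the
  # spurious local minimum at T -> 0 (a step-shaped fit).
  window <- max(tt)
  if (is.null(init)) {
    i_last <- mean(ii[tt == max(tt)])
    K0 <- max((1 / i_last - 1) / q_b, 1e-6)
    T0 <- window / 2
    t1 <- min(tt[tt > 0])
    i1 <- mean(ii[tt == t1])
    x <- (1 / i1 - 1) / (q_b * K0)
    if (is.finite(x) && x > 0 && x < 1) T0 <- -t1 / log(1 - x)
  } else {
    K0 <- init$K
    T0 <- init$T
  }
  starts <- list(c(K0, T0), c(K0, window / 2), c(K0, window / 10),
                 c(K0, 2 * window))

  dat <- data.frame(t = tt, I = ii)
  best <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ 1 / (1 + K * q_b * (1 - exp(-t / T))),
        data = dat,
        start = list(K = st[1], T = st[2]),
        lower = c(K = 1e-12, T = 1e-12),
        control = minpack.lm::nls.lm.control(
          maxiter = 1024, ftol = 1e-15, ptol = 1e-15, gtol = 0
        )
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      last_err <- fit
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15 * best$rss)
      best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- list(K_hat = NA_real_, T_hat = NA_real_, se_K = NA_real_,
                se_T = NA_real_, rss = NA_real_, n = length(ii),
                converged = FALSE,
                message = if (is.null(last_err)) "fit failed"
                          else conditionMessage(last_err))
    class(out) <- "quench_fit"
    return(out)
  }
  fit <- best$fit

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(K = NA_real_, T = NA_real_))
  out <- list(
    K_hat = unname(cf["K"]),
    T_hat = unname(cf["T"]),
    se_K = unname(se["K"]),
    se_T = unname(se["T"]),
    rss = sum(stats::resid(fit)^2),
    n = length(ii),
    converged = fit$convInfo$isConv
  )
  class(out) <- "quench_fit"
  out
}

#' @export
print.quench_fit <- function(x, ...) {
  cat("Quenching decay fit: I(t) = 1 / (1 + K q_b (1 - exp(-t/T)))\n")
  cat(sprintf("  K = %.6g m^3/mol (se %.3g)\n", x$K_hat, x$se_K))
  cat(sprintf("  T = %.6g s (se %.3g)\n", x$T_hat, x$se_T))
  cat(sprintf("  rss = %.3g over n = %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' Porosity ratio from two characteristic times
#'
#' Under the Bruggeman tortuosity law, two samples differing only in
#' porosity satisfy `T_ref/T_alt = (phi_alt/phi_ref)^(3/2)`, so the
#' alternative-to-reference porosity ratio is `(T_ref/T_alt)^(2/3)`. The
#' unknown attenuation factor `C` and geometry cancel in the ratio.
#'
#' @param T_ref Characteristic time of the reference sample, s.
#' @param T_alt Characteristic time of the alternative sample, s.
#' @return The porosity ratio phi_alt / phi_ref.
#' @export
porosity_ratio_from_times <- function(T_ref, T_alt) {
  if (T_ref <= 0 || T_alt <= 0) stop("characteristic times must be > 0")
  (T_ref / T_alt)^(2 / 3)
}

#' Fit all genotypes in a series table and infer porosity ratios
#'
#' Runs [fit_decay()] once per `label` and, when a reference label is
#' given, converts each pair of characteristic times into a porosity ratio
#' relative to that reference.
#'
#' @param series Fluorescence series table with columns `time_s`,
#'   `intensity`, `label` and optionally `replicate_id`.
#' @param q_b Bath quencher concentration, mol m^-3.
#' @param reference Optional reference label for the porosity ratio.
#' @param mode Passed to [fit_decay()].
#' @return A list with `fits` (a data.frame, one row per label) and
#'   `porosity_ratio` (named vector of phi_label / phi_reference, or NULL).
#' @export
fit_genotypes <- function(series, q_b, reference = NULL, mode = "mean") {
  stopifnot("label" %in% names(series))
  labels <- unique(series$label)
  rows <- lapply(labels, function(lb) {
    f <- fit_decay(series[series$label == lb, , drop = FALSE], q_b, mode = mode)
    data.frame(label = lb, K_hat = f$K_hat, T_hat = f$T_hat,
               se_K = f$se_K, se_T = f$se_T, rss = f$rss, n = f$n,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  ratio <- NULL
  if (!is.null(reference)) {
    if (!reference %in% fits$label)
      stop("reference label not present: ", reference)
    T_ref <- fits$T_hat[fits$label == reference]
    others <- setdiff(fits$label, reference)
    ratio <- vapply(others, function(lb) {
      porosity_ratio_from_times(T_ref, fits$T_hat[fits$label == lb])
    }, numeric(1))
    names(ratio) <- others
  }
  list(fits = fits, porosity_ratio = ratio)
}
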