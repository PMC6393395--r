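#' Worm-like chain parameter set
#'
#' Bundles the parameters of one inextensible Marko-Siggia worm-like chain
#' (WLC): a persistence length, a contour length and a temperature. One
#' `wlc_params` object describes one elastic element of a tethered construct,
#' e.g. the dsDNA handles or the unfolded ssDNA of a hairpin.
#'
#' @param persistence_length Persistence length in nm (> 0). Fitted values
#'   for dsDNA handles in bead-tether assays are typically 20-50 nm; ssDNA
#'   is far more flexible (~2 nm).
#' @param contour_length Contour length in nm (> 0).
#' @param temperature Absolute temperature in K (> 0). Default 298.15 K.
#' @return An object of class `wlc_params`.
#' @examples
#' handles <- wlc_params(20, 580)
#' wlc_force(handles, 290)
#' @export
wlc_params <- function(persistence_length, contour_length,
                       temperature = hp_constants$T_default) {
  stopifnot(is.numeric(persistence_length), length(persistence_length) == 1,
            is.numeric(contour_length), length(contour_length) == 1,
            is.numeric(temperature), length(temperature) == 1)
  if (!is.finite(persistence_length) || persistence_length <= 0)
    rlang::abort("`persistence_length` must be a positive finite number (nm).")
  if (!is.finite(contour_length) || contour_length <= 0)
    rlang::abort("`contour_length` must be a positive finite number (nm).")
  if (!is.finite(temperature) || temperature <= 0)
    rlang::abort("`temperature` must be a positive finite number (K).")
  structure(
    list(persistence_length = persistence_length,
         contour_length = contour_length,
         temperature = temperature),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("<wlc_params> p = %g nm, L = %g nm, T = %g K\n",
              x$persistence_length, x$contour_length, x$temperature))
  invisible(x)
}

#' Marko-Siggia worm-like chain force at a given extension
#'
#' Interpolation formula for the force of an inextensible WLC held at
#' end-to-end extension `x`:
#' \deqn{F(x) = \frac{k_B T}{p}\left(\frac{1}{4}(1 - x/L)^{-2} + x/L -
#'   \frac{1}{4}\right)}
#' The force is zero at `x = 0`, strictly increasing, and diverges as `x`
#' approaches the contour length `L`.
#'
#' @param params A [wlc_params()] object.
#' @param x Extension(s) in nm; each must satisfy `0 <= x < L`.
#' @return Force(s) in pN, same length as `x`.
#' @export
wlc_force <- function(params, x) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(x))
  L <- params$contour_length
  if (any(!is.finite(x)) || any(x < 0) || any(x >= L))
    rlang::abort("extension `x` must satisfy 0 <= x < contour_length.")
  z <- x / L
  kBT(params$temperature) / params$persistence_length *
    (0.25 * (1 - z)^-2 + z - 0.25)
}

# Inverse of the scaled Marko-Siggia relation: given f = F p / kBT, return
# the fractional extension z in [0, 1). Substituting u = 1 - z turns the
# relation into the depressed-free cubic 4 u^3 + (4 f - 3) u^2 - 1 = 0,
# which has exactly one root in (0, 1]; we take it in closed form and
# polish with two Newton steps on the force residual for full double
# precision. Vectorised over f.
ms_inverse_scaled <- function(f) {
  stopifnot(all(is.finite(f)), all(f >= 0))
  # cubic u^3 + b u^2 + d = 0 with b = f - 3/4, d = -1/4
  b <- f - 0.75
  d <- -0.25
  # depressed cubic t^3 + p t + q = 0 with u = t - b/3
  p <- -b^2 / 3
  q <- (2 * b^3) / 27 + d
  disc <- (q / 2)^2 + (p / 3)^3
  u <- numeric(length(f))
  pos <- disc >= 0
  if (any(pos)) {
    s <- sqrt(disc[pos])
    t1 <- cbrt(-q[pos] / 2 + s) + cbrt(-q[pos] / 2 - s)
    u[pos] <- t1 - b[pos] / 3
  }
  if (any(!pos)) {
    # three real roots: trigonometric form, pick the smallest in (0, 1]
    pp <- p[!pos]; qq <- q[!pos]; bb <- b[!pos]
    m <- 2 * sqrt(-pp / 3)
    theta <- acos(pmin(pmax(3 * qq / (pp * m), -1), 1)) / 3
    pick <- rep(Inf, length(pp))
    for (k in 0:2) {
      rk <- m * cos(theta - 2 * pi * k / 3) - bb / 3
      ok <- rk > 0 & rk <= 1 + 1e-12 & rk < pick
      pick[ok] <- rk[ok]
    }
    pick[!is.finite(pick)] <- 0.5        # safeguarded by the Newton polish
    u[!pos] <- pick
  }
  u <- pmin(pmax(u, 1e-12), 1)
  z <- 1 - u
  # Newton polish on g(z) = 1/4 (1-z)^-2 + z - 1/4 - f
  for (k in 1:2) {
    g <- 0.25 * (1 - z)^-2 + z - 0.25 - f
    dg <- 0.5 * (1 - z)^-3 + 1
    z <- pmin(pmax(z - g / dg, 0), 1 - 1e-15)
  }
  z
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Worm-like chain extension at a given force
#'
#' Inverts the Marko-Siggia force law: returns the unique extension
#' `x` in `[0, L)` at which [wlc_force()] equals `force`. The inversion is
#' performed in closed form on the underlying cubic and polished by Newton
#' iteration, so the round trip `wlc_extension(wlc_force(x))` reproduces `x`
#' to well below 1e-6 nm.
#'
#' @param params A [wlc_params()] object.
#' @param force Force(s) in pN, strictly positive.
#' @return Extension(s) in nm.
#' @export
wlc_extension <- function(params, force) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force <= 0))
    rlang::abort("`force` must be strictly positive (pN).")
  f <- force * params$persistence_length / kBT(params$temperature)
  params$contour_length * ms_inverse_scaled(f)
}

# extension and compliance of one WLC in a single pass (one cubic
# inversion); used by the force-balance Newton solvers in hot loops
wlc_ext_slope <- function(p, L, kT, force) {
  z <- ms_inverse_scaled(force * p / kT)
  dFdz <- kT / p * (0.5 * (1 - z)^-3 + 1)
  list(x = L * z, dxdF = L / dFdz)
}

# derivative dx/dF of the WLC at force F (nm/pN); used by Newton solvers
wlc_compliance <- function(params, force) {
  z <- ms_inverse_scaled(force * params$persistence_length /
                           kBT(params$temperature))
  dFdz <- kBT(params$temperature) / params$persistence_length *
    (0.5 * (1 - z)^-3 + 1)
  params$contour_length / dFdz
}

#' Handles-plus-hairpin construct model
#'
#' Describes the serial mechanical circuit of an optical-tweezers tether:
#' dsDNA handles in series with (optionally) the unfolded ssDNA of the
#' hairpin, held in a trap of stiffness `trap_stiffness`. When `ssdna` is
#' `NULL` the hairpin is folded and contributes only its fixed end-to-end
#' distance `folded_end_to_end` (default 2 nm) to the tether extension.
#'
#' @param handles A [wlc_params()] for the dsDNA handles.
#' @param ssdna A [wlc_params()] for the unfolded ssDNA, or `NULL` when the
#'   hairpin is folded.
#' @param folded_end_to_end Fixed end-to-end distance (nm, >= 0) contributed
#'   by the folded hairpin; default 2 nm.
#' @param trap_stiffness Effective trap stiffness in pN/nm; must lie in the
#'   physically sensible range 0.001-10.
#' @return An object of class `construct_model`.
#' @examples
#' m <- construct_model(wlc_params(20, 580), wlc_params(2, 41.52),
#'                      trap_stiffness = 0.06)
#' construct_extension(m, 5)
#' @export
construct_model <- function(handles, ssdna = NULL, folded_end_to_end = 2,
                            trap_stiffness = 0.06) {
  stopifnot(inherits(handles, "wlc_params"))
  if (!is.null(ssdna)) stopifnot(inherits(ssdna, "wlc_params"))
  if (!is.numeric(folded_end_to_end) || folded_end_to_end < 0)
    rlang::abort("`folded_end_to_end` must be >= 0 (nm).")
  if (!is.numeric(trap_stiffness) || trap_stiffness < 0.001 ||
      trap_stiffness > 10)
    rlang::abort("`trap_stiffness` must lie in [0.001, 10] pN/nm.")
  structure(
    list(handles = handles, ssdna = ssdna,
         folded_end_to_end = folded_end_to_end,
         trap_stiffness = trap_stiffness),
    class = "construct_model"
  )
}

#' @export
print.construct_model <- function(x, ...) {
  cat("<construct_model>\n  handles: ")
  print(x$handles)
  if (is.null(x$ssdna)) {
    cat(sprintf("  hairpin: folded (end-to-end %g nm)\n", x$folded_end_to_end))
  } else {
    cat("  ssDNA:   ")
    print(x$ssdna)
  }
  cat(sprintf("  trap stiffness: %g pN/nm\n", x$trap_stiffness))
  invisible(x)
}

#' Extension of the full construct at a given force
#'
#' Because the handles and the unfolded ssDNA are mechanically in series,
#' the tether extension at force `F` is the sum of the element extensions
#' at that same force,
#' \deqn{\xi(F) = x_\mathrm{handles}(F) + \xi_\mathrm{hairpin}(F),}
#' where the hairpin term is the ssDNA WLC extension when the hairpin is
#' unfolded and the fixed folded end-to-end distance otherwise.
#'
#' @param model A [construct_model()].
#' @param force Force(s) in pN, strictly positive.
#' @return Extension(s) in nm.
#' @export
construct_extension <- function(model, force) {
  stopifnot(inherits(model, "construct_model"))
  xi <- wlc_extension(model$handles, force)
  if (is.null(model$ssdna)) {
    xi + model$folded_end_to_end
  } else if (model$ssdna$contour_length <= 0) {
    xi
  } else {
    xi + wlc_extension(model$ssdna, force)
  }
}

# d xi / dF of the construct (nm/pN)
construct_compliance <- function(model, force) {
  cc <- wlc_compliance(model$handles, force)
  if (!is.null(model$ssdna) && model$ssdna$contour_length > 0)
    cc <- cc + wlc_compliance(model$ssdna, force)
  cc
}

#' Force of the full construct at a given extension
#'
#' Numerically inverts [construct_extension()]: finds the unique force at
#' which the serial construct reaches extension `xi`. Safeguarded Newton
#' iteration on the monotone extension-force relation, vectorised over
#' `xi`; the returned force reproduces `xi` to within 1e-6 nm.
#'
#' @param model A [construct_model()].
#' @param xi Extension(s) in nm; must be positive and below the summed
#'   contour lengths (minus the folded end-to-end offset where applicable).
#' @return Force(s) in pN.
#' @export
construct_force <- function(model, xi) {
  stopifnot(inherits(model, "construct_model"))
  offset <- if (is.null(model$ssdna)) model$folded_end_to_end else 0
  L_tot <- model$handles$contour_length +
    (if (is.null(model$ssdna)) 0 else model$ssdna$contour_length)
  if (any(!is.finite(xi)) || any(xi <= offset) || any(xi >= L_tot + offset))
    rlang::abort("extension `xi` outside the reachable range of the construct.")
  # Damped Newton with bracket safeguard; construct_extension is strictly
  # increasing in F so the bracket always contains the root. Initial
  # guess: treat the construct as a single WLC of the summed contour.
  lo <- rep(1e-12, length(xi))
  hi <- rep(1e6, length(xi))
  p_eff <- model$handles$persistence_length
  F <- wlc_force(wlc_params(p_eff, (L_tot + offset) * 1.0001,
                            model$handles$temperature),
                 pmin(xi, L_tot + offset - 1e-9))
  F <- pmax(F, 1e-9)
  for (k in 1:60) {
    g <- construct_extension(model, F) - xi
    if (all(abs(g) < 1e-8)) break
    hi[g > 0] <- pmin(hi[g > 0], F[g > 0])
    lo[g < 0] <- pmax(lo[g < 0], F[g < 0])
    Fn <- F - g / construct_compliance(model, F)
    bad <- Fn <= lo | Fn >= hi | !is.finite(Fn)
    Fn[bad] <- sqrt(lo[bad] * pmin(hi[bad], 1e3))   # geometric bisection
    F <- Fn
  }
  F
}
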