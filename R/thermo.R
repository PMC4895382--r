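# Single-site ITC thermodynamics: linkage, simulation, fitting.
#
# Conventions: R = 1.9872e-3 kcal/(mol K); temperature default 298.15 K
# (25 C); delta-G of association reported as R*T*ln(Kd) with Kd in molar
# (standard state 1 M), so favourable binding is negative; positive heat =
# heat absorbed (endothermic).

R_KCAL <- 1.9872e-3
UCAL_PER_KCAL <- 1e9

#' Gibbs free energy of binding from the dissociation constant
#'
#' @param Kd Dissociation constant (molar).
#' @param temperature Temperature in K (default 298.15).
#' @return Delta-G in kcal/mol: `R * T * ln(Kd)`; negative for sub-molar Kd.
#' @export
#' @examples
#' delta_g(104.2e-6) # about -5.43 kcal/mol at 25 C
delta_g <- function(Kd, temperature = 298.15) {
  if (any(Kd <= 0) || any(temperature <= 0)) {
    stop_input("Kd and temperature must be positive")
  }
  R_KCAL * temperature * log(Kd)
}

#' Entropic term from enthalpy and free energy
#'
#' @param delta_h Binding enthalpy (kcal/mol).
#' @param delta_g_val Binding free energy (kcal/mol).
#' @return `T * delta-S = delta-H - delta-G` (kcal/mol).
#' @export
#' @examples
#' t_delta_s(2.10, -5.44) # 7.54 kcal/mol
t_delta_s <- function(delta_h, delta_g_val) {
  delta_h - delta_g_val
}

#' Full thermodynamic parameter set for single-site binding
#'
#' @param n Stoichiometry (sites per protein).
#' @param Kd Dissociation constant (molar).
#' @param delta_h Binding enthalpy (kcal/mol).
#' @param temperature Temperature (K).
#' @param offset Per-injection dilution heat (ucal).
#' @return A one-row tibble with `n`, `Kd`, `delta_h`, `delta_g`,
#'   `t_delta_s`, `temperature`, `offset`; `delta_g = delta_h - t_delta_s`
#'   holds by construction.
#' @export
thermo_params <- function(n, Kd, delta_h, temperature = 298.15, offset = 0) {
  dg <- delta_g(Kd, temperature)
  tibble(n = n, Kd = Kd, delta_h = delta_h, delta_g = dg,
         t_delta_s = t_delta_s(delta_h, dg),
         temperature = temperature, offset = offset)
}

#' Define an ITC experiment design
#'
#' @param cell_concentration Protein concentration in the cell (molar).
#' @param syringe_concentration Ligand concentration in the syringe (molar).
#' @param cell_volume Cell volume (litre), e.g. `200e-6` for a 200 uL cell.
#' @param injection_volumes Injection volumes (litre), e.g.
#'   `rep(2e-6, 20)`.
#' @param temperature Temperature (K).
#' @param heats Optional measured heats (ucal), one per injection.
#' @return An `itc_experiment` list.
#' @export
itc_experiment <- function(cell_concentration, syringe_concentration,
                           cell_volume, injection_volumes,
                           temperature = 298.15, heats = NULL) {
  if (cell_concentration <= 0 || syringe_concentration <= 0 ||
      cell_volume <= 0 || any(injection_volumes <= 0)) {
    stop_input("concentrations and volumes must be positive")
  }
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    stop_input("one heat per injection is required")
  }
  structure(list(cell_concentration = cell_concentration,
                 syringe_concentration = syringe_concentration,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 temperature = temperature, heats = heats),
            class = "itc_experiment")
}

#' Read / write an ITC injection table
#'
#' CSV with columns `volume_uL` and `heat_ucal`; experiment metadata
#' (concentrations, cell volume, temperature) in a companion YAML file.
#'
#' @param heats_csv Injection table CSV.
#' @param meta_yaml Metadata YAML with fields `cell_concentration_M`,
#'   `syringe_concentration_M`, `cell_volume_L`, `temperature_K`.
#' @return An `itc_experiment`.
#' @export
read_itc <- function(heats_csv, meta_yaml) {
  inj <- readr::read_csv(heats_csv, show_col_types = FALSE)
  meta <- yaml::read_yaml(meta_yaml)
  itc_experiment(meta$cell_concentration_M, meta$syringe_concentration_M,
                 meta$cell_volume_L, inj$volume_uL * 1e-6,
                 meta$temperature_K %||% 298.15, inj$heat_ucal)
}

#' @rdname read_itc
#' @param exp An `itc_experiment` with heats.
#' @export
write_itc <- function(exp, heats_csv, meta_yaml) {
  readr::write_csv(tibble(volume_uL = exp$injection_volumes * 1e6,
                          heat_ucal = exp$heats), heats_csv)
  yaml::write_yaml(list(cell_concentration_M = exp$cell_concentration,
                        syringe_concentration_M = exp$syringe_concentration,
                        cell_volume_L = exp$cell_volume,
                        temperature_K = exp$temperature), meta_yaml)
  invisible(heats_csv)
}

# Core per-injection model. Totals are updated with the perfusion dilution
# (displaced volume leaves the cell at pre-injection composition); the
# injection heat charges the change in bound concentration, so the summed
# heats telescope to delta_h * [PL]_final * V0 + sum(offset).
itc_heats <- function(n, Kd, delta_h, offset, design) {
  V0 <- design$cell_volume
  P <- design$cell_concentration
  L <- 0
  PL_prev <- 0
  q <- numeric(length(design$injection_volumes))
  ratio <- numeric(length(q))
  for (i in seq_along(q)) {
    v <- design$injection_volumes[i]
    f <- 1 - v / V0
    P <- P * f
    L <- L * f + design$syringe_concentration * v / V0
    PL <- bound_complex(n * P, L, Kd)
    q[i] <- delta_h * V0 * (PL - PL_prev) * UCAL_PER_KCAL + offset
    ratio[i] <- L / P
    PL_prev <- PL
  }
  list(heats = q, molar_ratio = ratio, PL_final = PL_prev)
}

#' Simulate a single-site ITC thermogram
#'
#' @param params One-row tibble from [thermo_params()] (fields `n`, `Kd`,
#'   `delta_h`, `offset` are used).
#' @param design An [itc_experiment()] (heats ignored).
#' @return The design with simulated `heats` (ucal) filled in, plus a
#'   `thermogram` attribute: tibble of injection, molar ratio and heat.
#'   A warning is raised if the cumulative injected volume exceeds the cell
#'   volume (physically saturating design).
#' @export
simulate_itc <- function(params, design) {
  if (sum(design$injection_volumes) > design$cell_volume) {
    warn("cumulative injection volume exceeds the cell volume")
  }
  sim <- itc_heats(params$n, params$Kd, params$delta_h,
                   params$offset %||% 0, design)
  design$heats <- sim$heats
  attr(design, "thermogram") <- tibble(
    injection = seq_along(sim$heats),
    molar_ratio = sim$molar_ratio,
    heat_ucal = sim$heats
  )
  attr(design, "PL_final") <- sim$PL_final
  design
}

#' Fit the single-site model to an ITC experiment
#'
#' Least squares over (n, Kd, delta-H, offset) with Levenberg-Marquardt and
#' box bounds, three log-spaced Kd starts. Delta-G and T*delta-S are derived
#' from the fitted Kd via [delta_g()] / [t_delta_s()]. A warning flags
#' c-values (`n * P0 / Kd`) outside \[0.01, 1000\], the weakly informative
#' regime.
#'
#' @param exp An [itc_experiment()] with measured `heats`.
#' @param fix_n Optional fixed stoichiometry.
#' @return An `itc_fit` object with `params` (a [thermo_params()] row),
#'   standard errors, `c_value`, `converged` and `identifiable` flags and
#'   the per-injection fit table. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_itc <- function(exp, fix_n = NULL) {
  if (is.null(exp$heats)) stop_input("experiment carries no measured heats")
  if (length(exp$heats) < 8) stop_input("at least 8 injections are required")
  q <- exp$heats
  identifiable <- sd(q) > .Machine$double.eps^0.5 * max(abs(q), 1e-12)

  # moles of ligand delivered ~ bound at full saturation: rough dH scale
  inj_mol <- exp$syringe_concentration * sum(exp$injection_volumes)
  cap_mol <- exp$cell_concentration * exp$cell_volume
  dh0 <- sum(q) / (min(inj_mol, cap_mol) * UCAL_PER_KCAL)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- 1e-3

  resid_fn <- function(par) {
    if (is.null(fix_n)) {
      n <- par[1]; kd <- par[2]; dh <- par[3]; off <- par[4]
    } else {
      n <- fix_n; kd <- par[1]; dh <- par[2]; off <- par[3]
    }
    q - itc_heats(n, kd, dh, off, exp)$heats
  }
  lower <- c(if (is.null(fix_n)) 0.01, 1e-9, -1e3, -Inf)
  upper <- c(if (is.null(fix_n)) 10, 1, 1e3, Inf)
  fits <- map(KD_STARTS, function(kd0) {
    par0 <- c(if (is.null(fix_n)) 1, kd0, dh0, 0)
    run_nlslm(par0, lower, upper, resid_fn)
  })
  best <- fits[[which.min(map_dbl(fits, "deviance"))]]
  se <- nlslm_se(best)
  p <- best$par
  if (is.null(fix_n)) {
    n <- p[1]; kd <- p[2]; dh <- p[3]; off <- p[4]
    n_se <- se[1]; kd_se <- se[2]; dh_se <- se[3]
  } else {
    n <- fix_n; kd <- p[1]; dh <- p[2]; off <- p[3]
    n_se <- NA_real_; kd_se <- se[1]; dh_se <- se[2]
  }
  c_value <- n * exp$cell_concentration / kd
  if (identifiable && (c_value < 0.01 || c_value > 1000)) {
    warn(sprintf("c-value %.3g outside [0.01, 1000]: weak information regime",
                 c_value))
  }
  params <- thermo_params(n, kd, dh, exp$temperature, off)
  fitted <- q - best$fvec
  structure(list(
    params = params,
    se = tibble(n = n_se, Kd = kd_se, delta_h = dh_se),
    c_value = c_value,
    converged = best$info %in% 1:3 && identifiable,
    identifiable = identifiable,
    data = tibble(injection = seq_along(q),
                  molar_ratio = itc_heats(n, kd, dh, off, exp)$molar_ratio,
                  heat_ucal = q, fitted = fitted, residual = best$fvec),
    deviance = best$deviance,
    n_injections = length(q)
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "single-site ITC fit: n = %.3g, Kd = %.4g M, dH = %.3g, dG = %.3g, TdS = %.3g kcal/mol (c = %.3g)%s\n",
    p$n, p$Kd, p$delta_h, p$delta_g, p$t_delta_s, x$c_value,
    if (x$converged) "" else " [NOT CONVERGED / UNIDENTIFIABLE]"))
  invisible(x)
}

#' @rdname fit_itc
#' @param x,object An `itc_fit`.
#' @param ... Unused.
#' @export
tidy.itc_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("n", "Kd", "delta_h", "delta_g", "t_delta_s", "offset"),
         estimate = c(p$n, p$Kd, p$delta_h, p$delta_g, p$t_delta_s, p$offset),
         std.error = c(x$se$n, x$se$Kd, x$se$delta_h, NA, NA, NA))
}

#' @rdname fit_itc
#' @export
glance.itc_fit <- function(x, ...) {
  mutate(x$params, c_value = x$c_value, deviance = x$deviance,
         n_injections = x$n_injections, converged = x$converged)
}

#' @rdname fit_itc
#' @export
autoplot.itc_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_ucal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "molar ratio [Ca2+]/[protein]",
                  y = "injection heat [ucal]",
                  title = sprintf("single-site fit: n = %.2f, Kd = %.3g M",
                                  object$params$n, object$params$Kd)) +
    ggplot2::theme_minimal()
}
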