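# Kd estimation from CSP titration curves by nonlinear least squares
# against the exact 1:1 isotherm. Levenberg-Marquardt with box bounds
# (minpack.lm), three log-spaced Kd starts to avoid local minima.

KD_BOUNDS <- c(1e-9, 1)      # molar
DMAX_BOUNDS <- c(1e-6, 10)   # ppm
KD_STARTS <- 10^c(-6, -4, -2) # molar, log-spaced

#' Fit the 1:1 binding isotherm to CSP titration data
#'
#' Minimises \eqn{\sum (\Delta\delta_{obs} - \Delta\delta_{model})^2} over
#' the titration, where the model is [isotherm_1to1()]. In `global` mode one
#' Kd is shared across residues with residue-specific `delta_max`; in
#' `per_residue` mode each residue is fitted independently and the headline
#' Kd is the median across residues. Missing (broadened) peaks are excluded
#' from the residual, never imputed.
#'
#' @param series Long titration tibble (see [titration_series()]).
#' @param residues Residue numbers to fit. Default: residues above
#'   `threshold` ppm at the final titration point ([map_binding_site()]).
#' @param mode `"global"` (default) or `"per_residue"`.
#' @param nitrogen_weight 15N scaling weight for the CSP combination.
#' @param threshold End-point CSP threshold (ppm) for the default residue
#'   selection.
#' @return An object of class `kd_fit`: headline `Kd` and `Kd_se` (molar),
#'   per-residue `delta_max` table, fitted curves in `data`, `converged`
#'   flag, residual `sigma` and metadata. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_kd <- function(series, residues = NULL,
                   mode = c("global", "per_residue"),
                   nitrogen_weight = 0.2, threshold = 0.3) {
  mode <- match.arg(mode)
  series <- validate_titration(series)
  prof <- csp_series(series, nitrogen_weight)
  if (all(prof$ligand_total == 0)) {
    stop_input("series has zero ligand at every point: no binding information")
  }
  if (is.null(residues)) {
    endpoint <- filter(prof, .data$point == max(prof$point))
    residues <- map_binding_site(
      tibble(residue = endpoint$residue, csp = endpoint$csp), threshold)
    if (length(residues) == 0) {
      stop_input("no residues above threshold at the end point; supply `residues`")
    }
  }
  dat <- prof |>
    filter(.data$residue %in% residues, !.data$missing) |>
    select("point", "residue", "ligand_total", "protein_total", "csp")
  npts <- dat |> group_by(.data$residue) |> summarise(n = n())
  if (any(npts$n < 4)) {
    stop_input(paste0("fewer than 4 observed titration points for residue(s): ",
                      paste(npts$residue[npts$n < 4], collapse = ", ")))
  }

  if (mode == "global") {
    fit <- fit_kd_global(dat)
  } else {
    fit <- fit_kd_per_residue(dat)
  }
  fit$mode <- mode
  fit$nitrogen_weight <- nitrogen_weight
  fit$residues <- sort(unique(dat$residue))
  fit$n_points <- nrow(dat)
  structure(fit, class = "kd_fit")
}

# residual function: measured CSP minus isotherm prediction
kd_resid <- function(par, dat, res_levels) {
  kd <- par[1]
  dmax <- par[-1][match(dat$residue, res_levels)]
  dat$csp - isotherm_1to1(dat$protein_total, dat$ligand_total, kd, dmax)
}

run_nlslm <- function(par0, lower, upper, fn, ...) {
  minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn, ...,
                     control = minpack.lm::nls.lm.control(
                       maxiter = 200, ftol = 1e-14, ptol = 1e-14))
}

fit_kd_global <- function(dat) {
  res_levels <- sort(unique(dat$residue))
  dmax0 <- dat |>
    group_by(.data$residue) |>
    summarise(d0 = max(.data$csp)) |>
    pull("d0") |>
    pmin(DMAX_BOUNDS[2]) |> pmax(DMAX_BOUNDS[1] * 10)
  fits <- map(KD_STARTS, function(kd0) {
    run_nlslm(c(kd0, dmax0),
              lower = c(KD_BOUNDS[1], rep(DMAX_BOUNDS[1], length(dmax0))),
              upper = c(KD_BOUNDS[2], rep(DMAX_BOUNDS[2], length(dmax0))),
              fn = kd_resid, dat = dat, res_levels = res_levels)
  })
  best <- fits[[which.min(map_dbl(fits, "deviance"))]]
  se <- nlslm_se(best)
  dof <- nrow(dat) - length(best$par)
  list(
    Kd = unname(best$par[1]), Kd_se = se[1],
    delta_max = tibble(residue = res_levels,
                       delta_max = unname(best$par[-1]),
                       se = se[-1]),
    per_residue = NULL,
    data = mutate(dat, fitted = .data$csp - best$fvec,
                  residual = best$fvec),
    deviance = best$deviance,
    sigma = sqrt(best$deviance / max(dof, 1)),
    converged = best$info %in% 1:3
  )
}

fit_kd_per_residue <- function(dat) {
  res_levels <- sort(unique(dat$residue))
  per <- map(res_levels, function(r) {
    d <- filter(dat, .data$residue == r)
    fits <- map(KD_STARTS, function(kd0) {
      run_nlslm(c(kd0, min(max(d$csp), DMAX_BOUNDS[2])),
                lower = c(KD_BOUNDS[1], DMAX_BOUNDS[1]),
                upper = c(KD_BOUNDS[2], DMAX_BOUNDS[2]),
                fn = kd_resid, dat = d, res_levels = r)
    })
    best <- fits[[which.min(map_dbl(fits, "deviance"))]]
    se <- nlslm_se(best)
    tibble(residue = r, Kd = unname(best$par[1]), Kd_se = se[1],
           delta_max = unname(best$par[2]), se = se[2],
           deviance = best$deviance, converged = best$info %in% 1:3,
           fitted = list(mutate(d, fitted = .data$csp - best$fvec,
                                residual = best$fvec)))
  }) |> list_rbind()
  dat_fit <- list_rbind(per$fitted)
  list(
    Kd = median(per$Kd),
    Kd_se = 1.4826 * mad(per$Kd, constant = 1) / sqrt(nrow(per)),
    delta_max = select(per, "residue", "delta_max", "se"),
    per_residue = select(per, "residue", "Kd", "Kd_se", "delta_max",
                         "deviance", "converged"),
    data = dat_fit,
    deviance = sum(per$deviance),
    sigma = sqrt(sum(per$deviance) / max(nrow(dat_fit) - 2 * nrow(per), 1)),
    converged = all(per$converged)
  )
}

# standard errors from the LM fit covariance (sigma^2 * (J'J)^-1)
nlslm_se <- function(fit) {
  out <- rep(NA_real_, length(fit$par))
  dof <- length(fit$fvec) - length(fit$par)
  if (dof < 1) return(out)
  h <- try(chol2inv(chol(fit$hessian)), silent = TRUE)
  if (inherits(h, "try-error")) {
    h <- try(solve(fit$hessian), silent = TRUE)
    if (inherits(h, "try-error")) return(out)
  }
  sqrt(pmax(diag(h), 0) * fit$deviance / dof)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 isotherm fit (%s mode, w = %.3g): Kd = %.4g M (se %.2g), %d residues, %d points%s\n",
    x$mode, x$nitrogen_weight, x$Kd, x$Kd_se, length(x$residues), x$n_points,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname fit_kd
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "Kd", residue = NA_integer_, estimate = x$Kd,
           std.error = x$Kd_se),
    tibble(term = "delta_max", residue = x$delta_max$residue,
           estimate = x$delta_max$delta_max, std.error = x$delta_max$se)
  )
}

#' @rdname fit_kd
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(Kd = x$Kd, Kd_se = x$Kd_se, mode = x$mode,
         nitrogen_weight = x$nitrogen_weight,
         n_residues = length(x$residues), n_points = x$n_points,
         sigma = x$sigma, deviance = x$deviance, converged = x$converged)
}

#' @rdname fit_kd
#' @param object A `kd_fit` object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  dat <- mutate(object$data,
                equivalents = .data$ligand_total / .data$protein_total)
  P0 <- dat$protein_total[1]
  grid <- tidyr::expand_grid(
    residue = object$delta_max$residue,
    equivalents = seq(0, max(dat$equivalents), length.out = 100)
  ) |>
    left_join(object$delta_max, by = "residue") |>
    left_join(if (is.null(object$per_residue)) {
      tibble(residue = object$delta_max$residue, Kd = object$Kd)
    } else {
      select(object$per_residue, "residue", "Kd")
    }, by = "residue") |>
    mutate(csp = isotherm_1to1(P0, .data$equivalents * P0, .data$Kd,
                               .data$delta_max))
  ggplot2::ggplot(dat, ggplot2::aes(.data$equivalents, .data$csp,
                                    colour = factor(.data$residue))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "ligand equivalents", y = "Δδ(H,N) [ppm]",
                  colour = "residue",
                  title = sprintf("1:1 isotherm fit: Kd = %.3g M", object$Kd)) +
    ggplot2::theme_minimal()
}

#' Write Kd fit outputs (parameters JSON, per-residue curves CSV)
#'
#' @param fit A `kd_fit` object.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
write_kd_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(Kd_M = fit$Kd, Kd_se_M = fit$Kd_se, mode = fit$mode,
         nitrogen_weight = fit$nitrogen_weight, converged = fit$converged,
         sigma_ppm = fit$sigma,
         delta_max = fit$delta_max,
         per_residue = fit$per_residue),
    file.path(dir, "kd_fit.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  readr::write_csv(fit$data, file.path(dir, "fit_curves.csv"))
  invisible(dir)
}
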