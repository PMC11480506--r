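#' Synthetic single-site binding (anisotropy) curve
#'
#' Fluorescence anisotropy versus ligand concentration for one-site binding:
#' `r(L) = r0 + (r_max - r0) L / (Kd + L)`, plus Gaussian noise. A warning
#' flag is set when the concentration grid does not bracket the Kd (the fit
#' will be ill-conditioned).
#'
#' @param kd_uM dissociation constant, micromolar (> 0).
#' @param r0 anisotropy at zero ligand.
#' @param r_max anisotropy at saturation.
#' @param conc_grid ligand concentrations, micromolar, distinct and
#'   ascending.
#' @param noise_sd Gaussian noise SD (anisotropy units).
#' @param seed RNG seed.
#' @return Object of class `binding_curve`: data.frame `data`
#'   (`conc_uM`, `anisotropy`), `ground_truth`, `ill_conditioned` flag.
#' @examples
#' synth_binding(2, 0.05, 0.25, c(0.05, 0.2, 0.8, 3, 12, 50))
#' @export
synth_binding <- function(kd_uM, r0 = 0.05, r_max = 0.25, conc_grid,
                          noise_sd = 0, seed = 1L) {
  if (kd_uM <= 0) stop("kd_uM must be > 0")
  conc_grid <- as.numeric(conc_grid)
  if (anyDuplicated(conc_grid)) stop("concentrations must be distinct")
  if (is.unsorted(conc_grid)) stop("concentrations must be ascending")
  if (any(conc_grid < 0)) stop("concentrations must be >= 0")
  ill <- all(conc_grid < kd_uM) || all(conc_grid > kd_uM)
  if (ill) warning("concentration grid does not bracket Kd; fit will be ",
                   "ill-conditioned")
  set.seed(seed)
  r <- r0 + (r_max - r0) * conc_grid / (kd_uM + conc_grid) +
    stats::rnorm(length(conc_grid), 0, noise_sd)
  structure(list(data = data.frame(conc_uM = conc_grid, anisotropy = r),
                 ground_truth = list(kd_uM = kd_uM, r0 = r0, r_max = r_max,
                                     noise_sd = noise_sd),
                 ill_conditioned = ill),
            class = "binding_curve")
}

#' Read / write binding curves as CSV
#'
#' Columns `conc_uM`, `anisotropy`; ground truth, if any, in a JSON sidecar.
#'
#' @param curve a `binding_curve`.
#' @param path CSV path.
#' @export
write_binding_csv <- function(curve, path) {
  utils::write.csv(curve$data, path, row.names = FALSE)
  if (!is.null(curve$ground_truth))
    jsonlite::write_json(curve$ground_truth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binding_csv
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("conc_uM", "anisotropy"), names(df))
  if (length(miss)) stop("binding CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  structure(list(data = df, ground_truth = NULL, ill_conditioned = NA),
            class = "binding_curve")
}

#' Fit a single-site binding isotherm
#'
#' Least-squares fit of `r(L) = r0 + (r_max - r0) L / (Kd + L)`.
#' Initialisation is deterministic: `r0` from the minimum, `r_max` from the
#' maximum, `Kd` from the geometric middle of the (positive) grid. The fit
#' is flagged when Kd lands outside the measured concentration range or
#' when the curve is flat (unidentifiable).
#'
#' @param curve a `binding_curve` with >= 5 concentrations.
#' @return Object of class `binding_fit`: `kd_uM`, `r0`, `r_max`, `rss`,
#'   `converged`, `flags`.
#' @export
fit_binding <- function(curve) {
  stopifnot(inherits(curve, "binding_curve"))
  df <- curve$data
  if (nrow(df) < 5L) stop("need >= 5 concentrations")
  flags <- character()
  if (stats::sd(df$anisotropy) < 1e-12) {
    return(structure(list(kd_uM = NA_real_, r0 = mean(df$anisotropy),
                          r_max = mean(df$anisotropy), rss = 0,
                          converged = FALSE,
                          flags = "unidentifiable: flat curve"),
                     class = "binding_fit"))
  }
  pos <- df$conc_uM[df$conc_uM > 0]
  kd0 <- exp(mean(log(range(pos))))
  fit <- nls_strict_then_relaxed(
    anisotropy ~ r0 + (r_max - r0) * conc_uM / (kd + conc_uM), df,
    list(r0 = min(df$anisotropy), r_max = max(df$anisotropy), kd = kd0))
  cf <- stats::coef(fit)
  kd <- unname(cf["kd"])
  if (kd <= 0) flags <- c(flags, "non-positive Kd")
  if (kd < min(pos) || kd > max(df$conc_uM))
    flags <- c(flags, "Kd outside the measured concentration range")
  if (abs(unname(cf["r_max"]) - unname(cf["r0"])) < 1e-12)
    flags <- c(flags, "degenerate amplitude")
  structure(list(kd_uM = kd, r0 = unname(cf["r0"]),
                 r_max = unname(cf["r_max"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g uM (r0 %.3g, r_max %.3g)%s\n",
              x$kd_uM, x$r0, x$r_max,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                collapse = "; "), "]") else ""))
  invisible(x)
}
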