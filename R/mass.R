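#' Synthetic mass-photometry event sample
#'
#' Draws per-event masses from a Gaussian mixture with known components.
#' Draws are not truncated at zero: a broad component (e.g. 135 +- 67 kDa)
#' legitimately produces a small negative tail, as raw contrast-calibrated
#' event masses do; truncation would bias the component means.
#'
#' @param components list of numeric vectors `c(mean, sd, weight)` (kDa,
#'   kDa, fraction), or a data.frame with those columns. Weights must sum
#'   to 1, SDs must be positive.
#' @param n_events number of events.
#' @param seed RNG seed.
#' @return Object of class `mass_sample`: `masses` (kDa), `calibrated`
#'   (TRUE), `ground_truth` data.frame.
#' @examples
#' s <- synth_masses(list(c(135, 67, 1)), 5000, seed = 42)
#' @export
synth_masses <- function(components, n_events, seed = 1L) {
  if (is.data.frame(components)) {
    comp <- components
  } else {
    comp <- as.data.frame(do.call(rbind, components))
    names(comp) <- c("mean", "sd", "weight")
  }
  stopifnot(all(c("mean", "sd", "weight") %in% names(comp)))
  if (any(comp$sd <= 0)) stop("component SDs must be > 0")
  if (abs(sum(comp$weight) - 1) > 1e-8) stop("component weights must sum to 1")
  set.seed(seed)
  which_comp <- sample.int(nrow(comp), n_events, replace = TRUE,
                           prob = comp$weight)
  masses <- stats::rnorm(n_events, comp$mean[which_comp], comp$sd[which_comp])
  structure(list(masses = masses, calibrated = TRUE, ground_truth = comp),
            class = "mass_sample")
}

#' Read / write mass-photometry event lists as CSV
#'
#' One column `mass_kda` (calibrated) or `contrast` (raw); ground truth, if
#' any, in a JSON sidecar `<path>.json`.
#'
#' @param sample a `mass_sample`.
#' @param path CSV path.
#' @export
write_masses_csv <- function(sample, path) {
  utils::write.csv(data.frame(mass_kda = sample$masses), path,
                   row.names = FALSE)
  if (!is.null(sample$ground_truth))
    jsonlite::write_json(sample$ground_truth, paste0(path, ".json"),
                         digits = NA)
  invisible(path)
}

#' @rdname write_masses_csv
#' @export
read_masses_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("mass_kda" %in% names(df)) {
    structure(list(masses = df$mass_kda, calibrated = TRUE,
                   ground_truth = NULL), class = "mass_sample")
  } else if ("contrast" %in% names(df)) {
    structure(list(masses = df$contrast, calibrated = FALSE,
                   ground_truth = NULL), class = "mass_sample")
  } else {
    stop("mass CSV needs a 'mass_kda' or 'contrast' column")
  }
}

#' The BSA calibration ladder
#'
#' Sequence masses of the BSA monomer, dimer and trimer used as the
#' standard ladder (66.4 kDa and integer multiples); overridable wherever a
#' ladder is accepted.
#'
#' @return named numeric vector, kDa.
#' @export
bsa_ladder <- function() c(monomer = 66.4, dimer = 132.8, trimer = 199.2)

#' Linear contrast-to-mass calibration
#'
#' Ordinary least squares of known standard masses on their interferometric
#' scattering contrasts. A warning is raised if the contrast values are
#' larger in magnitude than the masses, which usually means the arguments
#' were swapped.
#'
#' @param contrasts measured contrasts of the standards (>= 2 distinct).
#' @param known_masses their known masses, kDa (default the BSA ladder).
#' @return Object of class `mass_calibration`: `slope` (kDa/contrast),
#'   `intercept` (kDa), `r_squared`.
#' @export
calibrate_masses <- function(contrasts, known_masses = bsa_ladder()) {
  contrasts <- as.numeric(contrasts); known_masses <- as.numeric(known_masses)
  if (length(contrasts) != length(known_masses))
    stop("contrasts and known_masses must have equal length")
  if (length(unique(contrasts)) < 2L)
    stop("need >= 2 standards with distinct contrasts")
  if (stats::median(abs(contrasts)) > stats::median(abs(known_masses)))
    warning("contrasts exceed masses in magnitude; arguments may be swapped")
  fit <- stats::lm(known_masses ~ contrasts)
  # direct R^2 (summary.lm warns on exactly linear standards)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((known_masses - mean(known_masses))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "mass_calibration")
}

#' @rdname calibrate_masses
#' @param calibration a `mass_calibration`.
#' @param raw_contrasts contrasts to convert.
#' @return `apply_calibration`: masses in kDa.
#' @export
apply_calibration <- function(calibration, raw_contrasts) {
  stopifnot(inherits(calibration, "mass_calibration"))
  calibration$intercept + calibration$slope * as.numeric(raw_contrasts)
}

#' Gaussian mixture fit to a mass distribution
#'
#' Expectation-maximisation on the event list (not on a histogram, so the
#' result is bin-width independent) with deterministic quantile-based
#' initialisation: events are sorted and split into `n_components` equal
#' groups whose means/SDs/weights seed the iteration. Components are
#' returned sorted by mean. If a component degenerates (vanishing weight or
#' SD), the fit is rerun with one component fewer and flagged. With a
#' monomer mass supplied, each component is assigned the nearest integer
#' oligomer state (>= 1).
#'
#' @param sample a `mass_sample` with >= 50 events.
#' @param n_components number of Gaussians (>= 1).
#' @param monomer_kda optional monomer mass for oligomer assignment.
#' @param max_iter,tol EM iteration controls (`tol` on the mean
#'   log-likelihood change).
#' @return Object of class `mass_fit`: `components` (data.frame `mean`,
#'   `sd`, `weight`, optionally `oligomer`), `loglik`, `n_iter`,
#'   `converged`, `flags`.
#' @export
fit_mass_distribution <- function(sample, n_components = 1L,
                                  monomer_kda = NULL, max_iter = 500L,
                                  tol = 1e-9) {
  stopifnot(inherits(sample, "mass_sample"))
  x <- sample$masses
  if (length(x) < 50L) stop("need >= 50 events")
  if (n_components < 1L) stop("n_components must be >= 1")
  flags <- character()
  sd_floor <- max(diff(range(x)) * 1e-6, 1e-9)

  k <- as.integer(n_components)
  repeat {
    fit <- em_gaussian_mixture(x, k, max_iter, tol, sd_floor)
    if (!fit$degenerate || k == 1L) break
    k <- k - 1L
    flags <- c(flags, sprintf("component degenerated; refit with %d", k))
  }
  comp <- fit$components[order(fit$components$mean), , drop = FALSE]
  rownames(comp) <- NULL
  if (!is.null(monomer_kda)) {
    if (monomer_kda <= 0) stop("monomer_kda must be > 0")
    comp$oligomer <- pmax(1L, as.integer(round(comp$mean / monomer_kda)))
  }
  structure(list(components = comp, loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged, flags = flags),
            class = "mass_fit")
}

em_gaussian_mixture <- function(x, k, max_iter, tol, sd_floor) {
  n <- length(x)
  if (k == 1L) {  # closed form: MLE mean and SD
    mu <- mean(x); sg <- max(sqrt(mean((x - mu)^2)), sd_floor)
    ll <- sum(stats::dnorm(x, mu, sg, log = TRUE))
    return(list(components = data.frame(mean = mu, sd = sg, weight = 1),
                loglik = ll, n_iter = 0L, converged = TRUE,
                degenerate = FALSE))
  }
  ord <- sort(x)
  groups <- split(ord, cut(seq_len(n), k, labels = FALSE))
  mu <- unname(vapply(groups, mean, 0))
  sg <- pmax(unname(vapply(groups, stats::sd, 0)), sd_floor)
  sg[is.na(sg)] <- sd_floor
  w <- unname(lengths(groups)) / n
  ll_old <- -Inf; converged <- FALSE; degenerate <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8 * n)) { degenerate <- TRUE; break }
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], 0))
    if (any(sg < sd_floor)) { degenerate <- TRUE; break }
    ll <- sum(log(rowsum_d))
    if (is.finite(ll_old) && abs(ll - ll_old) / n < tol) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  list(components = data.frame(mean = mu, sd = sg, weight = w),
       loglik = ll_old, n_iter = it, converged = converged,
       degenerate = degenerate)
}

#' @export
print.mass_fit <- function(x, ...) {
  cat(sprintf("<mass_fit> %d component(s), loglik %.1f%s\n",
              nrow(x$components), x$loglik,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                collapse = "; "), "]") else ""))
  for (r in seq_len(nrow(x$components)))
    cat(sprintf("  %0.1f +- %0.1f kDa (weight %.2f)%s\n",
                x$components$mean[r], x$components$sd[r],
                x$components$weight[r],
                if ("oligomer" %in% names(x$components))
                  sprintf("  %d-mer", x$components$oligomer[r]) else ""))
  invisible(x)
}
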