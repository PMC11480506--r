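STICKER_CLASSES <- c("negative", "positive", "aromatic")

sticker_class_index <- function(beads) {
  idx <- match(beads$class, STICKER_CLASSES)
  idx[is.na(idx) | !beads$sticker] <- 0L
  as.integer(idx)
}

#' Run overdamped Langevin sticker-spacer dynamics
#'
#' Evolves a starting configuration with the bespoke dynamics standing in
#' for coarse-grained MD: per-bead updates
#' `dx = F D dt / kT + sqrt(2 D dt) xi`, with harmonic bonds, soft repulsion
#' between all non-bonded bead pairs, and Gaussian attraction wells between
#' sticker beads whose depths are scaled by the crowding knob `chi(t)`.
#' Coordinates are wrapped periodically; runs are reproducible from `seed`.
#'
#' @param start a `sim_frame` from [build_system()] or [plant_clusters()].
#' @param config the [system_config()] the frame was built from.
#' @param n_steps number of integration steps (>= 0).
#' @param save_every save a frame every this many steps.
#' @param schedule optional time course of `chi`: a function of time (ns)
#'   or a numeric vector of length `n_steps` (per-step values). Default:
#'   constant `config$params$chi`.
#' @param seed RNG seed (default `config$seed`).
#' @return A `cg_trajectory` whose first frame is `start`; provenance
#'   records config, seed, schedule and per-saved-frame potential energies
#'   (all finite, checked).
#' @export
simulate_system <- function(start, config, n_steps, save_every = 100L,
                            schedule = NULL, seed = config$seed) {
  stopifnot(inherits(start, "sim_frame"), inherits(config, "system_config"))
  p <- config$params
  kT <- KB_KJ_MOL * p$temperature
  step_sd <- sqrt(2 * p$diffusion * p$dt)
  if (step_sd >= p$sigma / 4)
    stop(sprintf(paste0("dt too large: per-step displacement SD %.4f nm ",
                        "must stay below sigma/4 = %.4f nm"),
                 step_sd, p$sigma / 4))
  # explicit Euler is stable only while stiffness * mobility < 1; beyond it,
  # overlapping pairs oscillate instead of relaxing and act as bound states
  mob <- p$diffusion * p$dt / kT
  stiffness <- max(p$k_bond, 2 * p$eps_rep / p$sigma^2,
                   (max(p$eps_matrix) + p$eps_bg) * p$chi / p$delta^2)
  if (stiffness * mob >= 1)
    stop(sprintf(paste0("dt too large for the stiffest interaction: ",
                        "stiffness * D * dt / kT = %.2f must stay below 1 ",
                        "(reduce dt or soften the potentials)"),
                 stiffness * mob))
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop("n_steps must be >= 0")

  chi_steps <- if (is.null(schedule)) {
    p$chi
  } else if (is.function(schedule)) {
    vapply(start$time + seq_len(n_steps) * p$dt, schedule, 0)
  } else {
    if (length(schedule) != n_steps)
      stop("schedule vector must have length n_steps")
    as.numeric(schedule)
  }
  if (any(chi_steps < 0)) stop("chi must be >= 0 throughout the schedule")

  bonds <- system_bonds(config)
  scls <- sticker_class_index(start$beads)

  frames <- list(start$coords)
  times <- start$time
  if (n_steps > 0L) {
    res <- cpp_simulate(start$coords, start$box, bonds, p$b0, p$k_bond,
                        p$sigma, p$eps_rep, p$r0, p$delta, scls,
                        p$eps_matrix, p$eps_bg, chi_steps, kT, p$diffusion,
                        p$dt, n_steps, as.integer(save_every), start$time,
                        as.integer(seed))
    frames <- c(frames, res$frames)
    times <- c(times, res$times)
  }

  chi_of_frame <- function(t) {
    if (is.null(schedule)) return(p$chi)
    k <- round((t - start$time) / p$dt)
    if (k <= 0) chi_steps[1] else chi_steps[min(k, n_steps)]
  }
  energies <- vapply(seq_along(frames), function(i)
    cpp_energy(frames[[i]], start$box, bonds, p$b0, p$k_bond, p$sigma,
               p$eps_rep, p$r0, p$delta, scls, p$eps_matrix, p$eps_bg,
               chi_of_frame(times[i])), 0)
  if (any(!is.finite(energies)))
    stop("non-finite potential energy at saved frame ",
         which(!is.finite(energies))[1])

  new_trajectory(frames, times, start$beads, start$box,
                 provenance = list(config = config, seed = seed,
                                   n_steps = n_steps, dt = p$dt,
                                   save_every = save_every,
                                   schedule = if (is.null(schedule)) "constant"
                                              else "time-varying",
                                   energies = energies))
}
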