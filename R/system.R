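AVOGADRO <- 6.02214076e23
KB_KJ_MOL <- 8.31446261815324e-3  # kJ mol^-1 K^-1

#' Protein concentration of a periodic box
#'
#' Molar concentration of `n_chains` molecules in a cubic periodic box of
#' edge `box_edge` nanometres, in mM. 33 chains in a 30 nm box give 2.03 mM,
#' the 2 mM working concentration of the 33-copy simulations.
#'
#' @param n_chains number of molecules (>= 0).
#' @param box_edge cubic box edge, nm (> 0).
#' @return concentration in mM.
#' @examples
#' concentration(33, 30)  # ~2 mM
#' @export
concentration <- function(n_chains, box_edge) {
  if (!is.numeric(box_edge) || box_edge <= 0) stop("box_edge must be > 0")
  if (!is.numeric(n_chains) || any(n_chains < 0)) stop("n_chains must be >= 0")
  volume_l <- box_edge^3 * 1e-24          # nm^3 -> L
  n_chains / (AVOGADRO * volume_l) * 1e3  # mol/L -> mM
}

#' Sodium / chloride bookkeeping for a salted periodic box
#'
#' Ion counts corresponding to a nominal salt concentration, minimally
#' adjusted to neutralise the net system charge (ions are bookkeeping only;
#' they are never simulated).
#'
#' @param box_edge cubic box edge, nm.
#' @param salt_mM nominal NaCl concentration, mM (>= 0).
#' @param net_system_charge total protein charge to neutralise (integer).
#' @return list with `n_na` and `n_cl`, both non-negative integers.
#' @examples
#' ion_counts(30, 150, 0)  # 2439 of each
#' @export
ion_counts <- function(box_edge, salt_mM, net_system_charge = 0L) {
  if (salt_mM < 0) stop("salt_mM must be >= 0")
  if (box_edge <= 0) stop("box_edge must be > 0")
  volume_l <- box_edge^3 * 1e-24
  base <- round(salt_mM * 1e-3 * AVOGADRO * volume_l)
  q <- as.integer(round(net_system_charge))
  # add counter-ions for the protein charge: negative protein -> extra Na+
  n_na <- base + max(0L, -q)
  n_cl <- base + max(0L, q)
  if (n_na < 0 || n_cl < 0) stop("cannot neutralise charge ", q,
                                 " with non-negative ion counts")
  list(n_na = as.integer(n_na), n_cl = as.integer(n_cl))
}

#' Interaction parameters for the sticker-spacer model
#'
#' Defaults define the bespoke overdamped Langevin stand-in used throughout:
#' harmonic bonds (`b0` = 0.38 nm, `k_bond` = 500 kJ mol^-1 nm^-2), soft
#' pairwise repulsion `U = eps_rep (1 - r/sigma)^2` for `r < sigma`
#' (`sigma` = 0.47 nm), and Gaussian attraction wells between sticker beads,
#' `U = -eps * chi * exp(-(r - r0)^2 / (2 delta^2))` with `r0` = 0.5 nm and
#' `delta` = 0.12 nm. `eps_matrix` holds well depths (kJ/mol) per sticker
#' class pair; the default couples opposite charges and aromatic pairs.
#' `chi` is the single crowding knob scaling all well depths (the PEG proxy).
#'
#' @param sigma repulsion diameter, nm.
#' @param eps_rep repulsion strength at full overlap, kJ/mol. The default
#'   (100, i.e. 40 kT at 300 K) makes `sigma` an effective excluded-volume
#'   diameter, so that an athermal (`chi = 0`) system stays inert under the
#'   0.5 nm contact definition; much softer walls let chains interpenetrate
#'   and register spurious contacts.
#' @param b0 bond rest length, nm.
#' @param k_bond bond force constant, kJ mol^-1 nm^-2.
#' @param r0 attraction well centre, nm.
#' @param delta attraction well width, nm.
#' @param eps_ss base well depth for the default attractive pairs, kJ/mol.
#' @param eps_bg weak nonspecific well depth between all non-bonded bead
#'   pairs (same Gaussian shape, also scaled by `chi`), kJ/mol. It stands in
#'   for the dispersion attraction every coarse-grained bead pair feels in
#'   the force field this model emulates; without it, sparse strong stickers
#'   alone either exchange too fast to hold chains together or saturate
#'   within a chain and collapse it, and no condensation occurs. The default
#'   (0.8, i.e. about 0.3 kT per contact at `chi` = 1) leaves the athermal
#'   system inert and puts the condensation transition within reach of the
#'   crowding knob.
#' @param eps_matrix optional full class-pair depth matrix (kJ/mol), rows and
#'   columns named `negative`, `positive`, `aromatic`; overrides `eps_ss`.
#' @param chi crowding scale, >= 0, multiplying all well depths.
#' @param temperature K.
#' @param diffusion free-bead diffusion coefficient fixing the friction,
#'   nm^2/ns.
#' @param dt integration time step, ns. Must keep the per-step random
#'   displacement SD below `sigma/4` (checked at run time).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(sigma = 0.47, eps_rep = 100, b0 = 0.38, k_bond = 500,
                       r0 = 0.50, delta = 0.12, eps_ss = 3, eps_bg = 0.8,
                       eps_matrix = NULL, chi = 1,
                       temperature = 300, diffusion = 1, dt = 0.002) {
  classes <- c("negative", "positive", "aromatic")
  if (is.null(eps_matrix)) {
    eps_matrix <- matrix(0, 3, 3, dimnames = list(classes, classes))
    eps_matrix["negative", "positive"] <- eps_ss
    eps_matrix["positive", "negative"] <- eps_ss
    eps_matrix["aromatic", "aromatic"] <- eps_ss
  } else {
    stopifnot(identical(dim(eps_matrix), c(3L, 3L)),
              isTRUE(all.equal(eps_matrix, t(eps_matrix))))
    dimnames(eps_matrix) <- list(classes, classes)
  }
  if (chi < 0) stop("chi must be >= 0")
  if (eps_bg < 0) stop("eps_bg must be >= 0")
  p <- list(sigma = sigma, eps_rep = eps_rep, b0 = b0, k_bond = k_bond,
            r0 = r0, delta = delta, eps_matrix = eps_matrix, eps_bg = eps_bg,
            chi = chi,
            temperature = temperature, diffusion = diffusion, dt = dt)
  class(p) <- "sim_params"
  p
}

#' System configuration: species, copy numbers, box, salt, seed
#'
#' The stated world of the multi-chain simulations: a cubic periodic box
#' (default 30 nm) holding identical disordered chains at millimolar
#' concentration with 150 mM salt bookkeeping at 300 K.
#'
#' @param species named list of [chain_topology()] objects.
#' @param copies integer vector of copy numbers, same length/order as
#'   `species`.
#' @param box_edge cubic box edge, nm.
#' @param salt_mM nominal salt concentration for ion bookkeeping.
#' @param seed RNG seed used by [build_system()] / [simulate_system()].
#' @param params [sim_params()].
#' @return list of class `system_config`.
#' @examples
#' cfg <- system_config(list(DR2 = region_topology("DR2")), copies = 33)
#' @export
system_config <- function(species, copies, box_edge = 30, salt_mM = 150,
                          seed = 1L, params = sim_params()) {
  stopifnot(is.list(species), length(species) == length(copies))
  if (is.null(names(species)))
    names(species) <- vapply(species, `[[`, "", "name")
  copies <- as.integer(copies)
  if (any(copies < 0)) stop("copy numbers must be >= 0")
  structure(list(species = species, copies = copies, box_edge = box_edge,
                 salt_mM = salt_mM, seed = as.integer(seed), params = params),
            class = "system_config")
}

# Per-bead bookkeeping table for a configured system.
system_beads <- function(config) {
  out <- list(); chain <- 0L
  for (s in seq_along(config$species)) {
    top <- config$species[[s]]
    for (k in seq_len(config$copies[s])) {
      chain <- chain + 1L
      b <- top$beads
      out[[chain]] <- data.frame(
        chain = chain, species = top$name, residue = b$residue,
        slot = b$slot, aa = b$aa, class = b$class, charge = b$charge,
        sticker = b$sticker, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Bond list (global bead indices) for a configured system.
system_bonds <- function(config) {
  out <- list(); offset <- 0L; i <- 0L
  for (s in seq_along(config$species)) {
    top <- config$species[[s]]
    nb <- n_beads(top)
    for (k in seq_len(config$copies[s])) {
      i <- i + 1L
      if (nrow(top$bonds)) out[[i]] <- top$bonds + offset
      offset <- offset + nb
    }
  }
  if (!length(out)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, out)
}

new_frame <- function(coords, beads, box, time = 0) {
  structure(list(coords = coords, beads = beads, box = box, time = time),
            class = "sim_frame")
}

#' @export
print.sim_frame <- function(x, ...) {
  cat(sprintf("<sim_frame> %d beads, %d chains, box %g nm, t = %g ns\n",
              nrow(x$coords), length(unique(x$beads$chain)), x$box, x$time))
  invisible(x)
}

wrap_coords <- function(coords, box) coords - box * floor(coords / box)

#' Build a packed starting configuration
#'
#' Places every chain as a self-avoiding random walk (bond length `b0`) at a
#' random position and orientation in the periodic box, rejecting any
#' placement that brings two non-bonded beads closer than `sigma` (minimum
#' image). Deterministic for a given `config$seed`. Ion bookkeeping is
#' recorded as metadata.
#'
#' @param config a [system_config()].
#' @param max_attempts restarts allowed per chain before giving up.
#' @return A `sim_frame`: wrapped coordinates, per-bead bookkeeping, box,
#'   time 0; attributes `ions` and `concentration_mM`.
#' @export
build_system <- function(config, max_attempts = 200L) {
  stopifnot(inherits(config, "system_config"))
  p <- config$params
  box <- config$box_edge
  beads <- system_beads(config)
  set.seed(config$seed)

  placed <- matrix(numeric(), 0L, 3L)
  chains <- split(seq_len(nrow(beads)), beads$chain)
  tops <- rep(config$species, times = config$copies)

  min_image_ok <- function(pt, others, cut) {
    if (!nrow(others)) return(TRUE)
    d <- abs(sweep(others, 2L, pt))
    d <- pmin(d, box - d)
    all(rowSums(d * d) >= cut * cut)
  }

  for (ci in seq_along(chains)) {
    top <- tops[[ci]]
    nb <- n_beads(top)
    # grow along the bond graph in bead order; with 2 beads/residue the
    # parent of each bead is its bonded predecessor
    parent <- rep(NA_integer_, nb)
    if (nrow(top$bonds)) for (r in seq_len(nrow(top$bonds))) {
      a <- top$bonds[r, 1L]; b <- top$bonds[r, 2L]
      if (b > a && is.na(parent[b])) parent[b] <- a
    }
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      xyz <- matrix(NA_real_, nb, 3L)
      xyz[1L, ] <- stats::runif(3L, 0, box)
      good <- TRUE
      for (bi in seq_len(nb)[-1L]) {
        anchor <- xyz[parent[bi], ]
        hit <- FALSE
        for (try in seq_len(60L)) {
          u <- stats::rnorm(3L)
          cand <- anchor + p$b0 * u / sqrt(sum(u * u))
          cand <- cand - box * floor(cand / box)
          prev <- xyz[seq_len(bi - 1L)[-parent[bi]], , drop = FALSE]
          if (min_image_ok(cand, prev, p$sigma) &&
              min_image_ok(cand, placed, p$sigma)) {
            xyz[bi, ] <- cand; hit <- TRUE; break
          }
        }
        if (!hit) { good <- FALSE; break }
      }
      if (good && min_image_ok(xyz[1L, ], placed, p$sigma)) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to insert chain ", ci, " after ", max_attempts,
                  " attempts; try a larger box")
    placed <- rbind(placed, xyz)
  }

  fr <- new_frame(wrap_coords(placed, box), beads, box, time = 0)
  net_q <- sum(beads$charge)
  attr(fr, "ions") <- ion_counts(box, config$salt_mM, net_q)
  attr(fr, "concentration_mM") <- concentration(length(chains), box)
  fr
}

#' Plant a known cluster partition (oracle generator)
#'
#' Places chains so that every planted set forms one connected cluster under
#' the bead-contact definition (a chain of guaranteed bead contacts below
#' `contact_cutoff`) while distinct sets stay farther apart than
#' `3 * contact_cutoff`. Used as the ground-truth oracle for cluster
#' detection; the partition is recovered exactly by construction.
#'
#' @param config a [system_config()]; all chains of one species.
#' @param partition list of integer vectors partitioning `1:n_chains`.
#' @param seed RNG seed.
#' @param contact_cutoff bead-contact cutoff the partition must satisfy, nm.
#' @param straddle_boundary if TRUE, the first planted set is centred on a
#'   box corner so its contacts cross the periodic boundary.
#' @return A `sim_frame` with attribute `planted_partition`.
#' @export
plant_clusters <- function(config, partition, seed = config$seed,
                           contact_cutoff = 0.5, straddle_boundary = FALSE) {
  stopifnot(inherits(config, "system_config"))
  p <- config$params
  box <- config$box_edge
  beads <- system_beads(config)
  n_chains <- length(unique(beads$chain))
  got <- sort(unlist(partition))
  if (!identical(as.integer(got), seq_len(n_chains)))
    stop("partition must cover chains 1..", n_chains, " exactly once")
  set.seed(seed)

  tops <- rep(config$species, times = config$copies)
  nb_of <- vapply(tops, n_beads, 1L)
  # straight-rod footprint of the largest chain
  rod <- max(nb_of) * p$b0
  gap <- 0.9 * contact_cutoff   # guaranteed-contact spacing between chains
  # lay out cluster anchor sites on a coarse grid spaced so distinct sets,
  # including their stacked members, stay > 3*cutoff apart
  spacing <- rod + 3 * contact_cutoff + 1 + max(lengths(partition)) * gap
  per_side <- max(1L, floor(box / spacing))
  if (per_side^3 < length(partition))
    stop("box too small to separate ", length(partition),
         " planted clusters by > 3 * cutoff; enlarge the box")
  sites <- as.matrix(expand.grid(x = seq_len(per_side), y = seq_len(per_side),
                                 z = seq_len(per_side))) - 0.5
  sites <- sites * (box / per_side)
  sites <- sites[sample.int(nrow(sites), length(partition)), , drop = FALSE]
  if (straddle_boundary) sites[1L, ] <- c(0, box / 2, box / 2)

  coords <- matrix(NA_real_, nrow(beads), 3L)
  for (gi in seq_along(partition)) {
    members <- partition[[gi]]
    for (mi in seq_along(members)) {
      ci <- members[mi]
      nb <- nb_of[ci]
      # straight rods along x, stacked along y with first beads gap apart:
      # consecutive members share a bead pair at distance gap < cutoff
      start <- sites[gi, ] + c(-rod / 2, (mi - 1) * gap, 0)
      rows <- which(beads$chain == ci)
      coords[rows, ] <- cbind(start[1] + (seq_len(nb) - 1L) * p$b0,
                              start[2], start[3])
    }
  }
  fr <- new_frame(wrap_coords(coords, box), beads, box, time = 0)
  attr(fr, "planted_partition") <- lapply(partition, as.integer)
  fr
}
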