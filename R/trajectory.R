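new_trajectory <- function(frames, times, beads, box, provenance = list()) {
  stopifnot(length(frames) == length(times))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame time stamps must be strictly increasing")
  structure(list(frames = frames, times = times, beads = beads, box = box,
                 provenance = provenance),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames, %d beads, %d chains, box %g nm, t = [%g, %g] ns\n",
              length(x$frames), nrow(x$beads), length(unique(x$beads$chain)),
              x$box, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a `sim_frame`
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= length(traj$frames))
  new_frame(traj$frames[[i]], traj$beads, traj$box, traj$times[i])
}

#' Write / read multi-chain trajectories as XYZ-dialect text
#'
#' One block per frame: a bead-count line, a comment line
#' `t= <ns> box= <nm>`, then one line per bead (`<aa> x y z`, nm). The chain
#' and residue bookkeeping lives in a plain-text topology sidecar
#' ([write_topology_sidecar()]); the two files together round-trip a
#' trajectory exactly at the printed precision.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_along(traj$frames)) {
    m <- traj$frames[[i]]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("t= %.6f box= %.6f", traj$times[i], traj$box), con)
    writeLines(sprintf(fmt, traj$beads$aa, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @param config a [system_config()] or a `cg_trajectory` (its provenance
#'   must carry the config), describing species and chain order.
#' @export
write_topology_sidecar <- function(config, path) {
  if (inherits(config, "cg_trajectory")) config <- config$provenance$config
  stopifnot(inherits(config, "system_config"))
  lines <- c("format: drcluster-topology-1",
             sprintf("box_edge: %.6f", config$box_edge))
  for (s in seq_along(config$species)) {
    top <- config$species[[s]]
    lines <- c(lines, sprintf("species: %s %d %s", top$name,
                              top$beads_per_residue, top$sequence))
  }
  chain_species <- rep(vapply(config$species, `[[`, "", "name"),
                       times = config$copies)
  lines <- c(lines, paste("chains:", paste(chain_species, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_topology_sidecar <- function(path) {
  lines <- readLines(path)
  if (!grepl("^format: drcluster-topology-1", lines[1]))
    stop("not a drcluster topology sidecar: ", path)
  get1 <- function(key) {
    v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), lines,
                                               value = TRUE))
    if (!length(v)) stop("missing '", key, ":' in ", path)
    v
  }
  box <- as.numeric(get1("box_edge")[1])
  species <- list()
  for (sv in get1("species")) {
    parts <- strsplit(trimws(sv), " +")[[1]]
    species[[parts[1]]] <- chain_topology(parts[1], parts[3],
                                          beads_per_residue = as.integer(parts[2]))
  }
  chain_species <- strsplit(trimws(get1("chains")[1]), " +")[[1]]
  copies <- table(factor(chain_species, levels = names(species)))
  # chain order must be reconstructible: require grouped order
  grouped <- rep(names(species), times = as.integer(copies))
  if (!identical(chain_species, grouped))
    stop("sidecar chain order must group species contiguously")
  system_config(species, as.integer(copies), box_edge = box)
}

#' @rdname write_trajectory_xyz
#' @param xyz_path trajectory file written by [write_trajectory_xyz()].
#' @param sidecar_path topology sidecar path.
#' @export
read_trajectory_xyz <- function(xyz_path, sidecar_path) {
  config <- read_topology_sidecar(sidecar_path)
  beads <- system_beads(config)
  nb <- nrow(beads)
  lines <- readLines(xyz_path)
  block <- nb + 2L
  if (length(lines) %% block != 0L)
    stop("trajectory/topology bead-count mismatch: expected blocks of ",
         block, " lines, file has ", length(lines), " lines")
  nf <- length(lines) %/% block
  frames <- vector("list", nf); times <- numeric(nf)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * block
    n_decl <- as.integer(lines[off + 1L])
    if (n_decl != nb)
      stop("frame ", f, " declares ", n_decl, " beads, topology has ", nb)
    hdr <- lines[off + 2L]
    times[f] <- as.numeric(sub("^t= *([-0-9.eE+]+).*", "\\1", hdr))
    body <- lines[off + 2L + seq_len(nb)]
    parts <- strsplit(body, " +")
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3L,
                byrow = TRUE)
    frames[[f]] <- m
  }
  new_trajectory(frames, times, beads, config$box_edge,
                 provenance = list(config = config, source = xyz_path))
}

#' Export a single frame in GRO format (visualisation only)
#'
#' @param frame a `sim_frame`.
#' @param path output file.
#' @export
write_frame_gro <- function(frame, path) {
  n <- nrow(frame$coords)
  lines <- c(sprintf("drcluster frame t= %.3f ns", frame$time),
             sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     frame$beads$chain %% 100000L,
                     substr(frame$beads$species, 1, 5),
                     frame$beads$aa, seq_len(n) %% 100000L,
                     frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box, frame$box, frame$box))
  writeLines(lines, path)
  invisible(path)
}
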