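#' Connected-component clusters of a chain interaction graph
#'
#' Clusters are the connected components of the interaction graph; singleton
#' chains are reported as size-1 sets ("free" chains). Components are
#' returned sorted by their lowest chain id, members ascending.
#'
#' @param graph a `chain_graph` from [interaction_graph()].
#' @return list of integer vectors partitioning `1:graph$n`.
#' @export
find_clusters <- function(graph) {
  stopifnot(inherits(graph, "chain_graph"))
  g <- igraph::make_graph(rbind(graph$edges$a, graph$edges$b), n = graph$n,
                          directed = FALSE)
  comp <- igraph::components(g)
  out <- unname(split(seq_len(graph$n), comp$membership))
  out <- lapply(out, function(v) sort(unname(as.integer(v))))
  out[order(vapply(out, min, 1L))]
}

#' Per-frame cluster partitions of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param params a [contact_params()].
#' @return list of class `cluster_partition`: per analysed frame, the
#'   partition (list of chain-id sets), the central chain of every component
#'   of size >= 2, and the frame time stamp.
#' @export
cluster_partition <- function(traj, params = contact_params()) {
  stopifnot(inherits(traj, "cg_trajectory"))
  idx <- frame_indices(traj, params)
  frames <- lapply(idx, function(f) {
    fr <- get_frame(traj, f)
    graph <- interaction_graph(fr, params)
    partition <- find_clusters(graph)
    centrals <- vapply(partition, function(cl)
      if (length(cl) >= 2L) central_chain(graph, cl) else NA_integer_, 1L)
    list(frame = f, time = traj$times[f], partition = partition,
         central = centrals)
  })
  structure(list(frames = frames, n_chains = length(unique(traj$beads$chain)),
                 params = params),
            class = "cluster_partition")
}

largest_cluster_size <- function(partition) max(lengths(partition))

#' Cluster kinetics of a trajectory
#'
#' Computes the time series of largest-cluster size and cluster count, the
#' frame-to-frame association events (a join is a chain free at one frame
#' and in a cluster of size >= 2 at the next; a leave is the reverse), the
#' per-chain dwell segments (maximal in-cluster runs), and the mean
#' free-chain fraction per species. Events are defined at the saved-frame
#' resolution with no smoothing.
#'
#' @param traj a `cg_trajectory`.
#' @param params a [contact_params()].
#' @param partitions optionally, a precomputed [cluster_partition()].
#' @return list of class `cluster_kinetics` with elements `series`
#'   (data.frame: frame, time, largest_cluster, largest_fraction,
#'   n_clusters), `events` (data.frame: chain, frame, type), `dwell`
#'   (data.frame: chain, start_frame, end_frame, n_frames), `free_fraction`
#'   (named by species), `status` (`"ok"`, or `"empty"` for trajectories
#'   shorter than 2 frames, whose event/dwell tables are empty).
#' @export
cluster_kinetics <- function(traj, params = contact_params(),
                             partitions = NULL) {
  if (is.null(partitions)) partitions <- cluster_partition(traj, params)
  pf <- partitions$frames
  n_chains <- partitions$n_chains
  nf <- length(pf)
  series <- data.frame(
    frame = vapply(pf, `[[`, 1L, "frame"),
    time = vapply(pf, `[[`, 0, "time"),
    largest_cluster = vapply(pf, function(p) largest_cluster_size(p$partition), 1L),
    n_clusters = vapply(pf, function(p)
      sum(lengths(p$partition) >= 2L), 1L))
  series$largest_fraction <- series$largest_cluster / n_chains

  # in-cluster membership matrix: frames x chains
  incl <- t(vapply(pf, function(p) {
    v <- logical(n_chains)
    for (s in p$partition) if (length(s) >= 2L) v[s] <- TRUE
    v
  }, logical(n_chains)))

  chain_species <- traj$beads$species[!duplicated(traj$beads$chain)]
  free_fraction <- vapply(split(seq_len(n_chains), chain_species),
                          function(cols) mean(!incl[, cols, drop = FALSE]), 0)

  if (nf < 2L) {
    return(structure(list(series = series,
                          events = data.frame(chain = integer(),
                                              frame = integer(),
                                              type = character()),
                          dwell = data.frame(chain = integer(),
                                             start_frame = integer(),
                                             end_frame = integer(),
                                             n_frames = integer()),
                          free_fraction = free_fraction, status = "empty"),
                     class = "cluster_kinetics"))
  }

  ev <- list(); k <- 0L
  for (f in seq_len(nf - 1L)) {
    joined <- which(!incl[f, ] & incl[f + 1L, ])
    left <- which(incl[f, ] & !incl[f + 1L, ])
    if (length(joined)) {
      k <- k + 1L
      ev[[k]] <- data.frame(chain = joined, frame = series$frame[f + 1L],
                            type = "join")
    }
    if (length(left)) {
      k <- k + 1L
      ev[[k]] <- data.frame(chain = left, frame = series$frame[f + 1L],
                            type = "leave")
    }
  }
  events <- if (k) do.call(rbind, ev) else
    data.frame(chain = integer(), frame = integer(), type = character())

  dw <- list(); k <- 0L
  for (ch in seq_len(n_chains)) {
    r <- rle(incl[, ch])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values)) {
      k <- k + 1L
      dw[[k]] <- data.frame(chain = ch, start_frame = series$frame[starts[seg]],
                            end_frame = series$frame[ends[seg]],
                            n_frames = r$lengths[seg])
    }
  }
  dwell <- if (k) do.call(rbind, dw) else
    data.frame(chain = integer(), start_frame = integer(),
               end_frame = integer(), n_frames = integer())

  structure(list(series = series, events = events, dwell = dwell,
                 free_fraction = free_fraction, status = "ok"),
            class = "cluster_kinetics")
}

#' @export
print.cluster_kinetics <- function(x, ...) {
  cat(sprintf("<cluster_kinetics> %d frames (%s), mean largest fraction %.2f, %d join / %d leave events\n",
              nrow(x$series), x$status, mean(x$series$largest_fraction),
              sum(x$events$type == "join"), sum(x$events$type == "leave")))
  invisible(x)
}

#' Two-species mixing statistics
#'
#' Quantifies whether two chain species co-cluster: the observed heterotypic
#' fraction is the share of inter-chain interaction edges joining chains of
#' different species, pooled over frames; the expected fraction under random
#' partnering is `2 p_A p_B / (p_A + p_B)^2` with `p` the chain-count
#' fractions; their ratio is the enrichment (about 1 for well-mixed
#' clusters, much less than 1 when one species is excluded). An optional
#' seeded permutation null (shuffling species labels over chains) gives an
#' empirical p-value for depletion/enrichment.
#'
#' @param traj a `cg_trajectory` with >= 2 species.
#' @param params a [contact_params()].
#' @param permutations number of label permutations for the optional
#'   significance test (0 to skip).
#' @param seed seed for the permutation null.
#' @return list of class `mixing_stats`: `observed`, `expected`,
#'   `enrichment`, `n_edges`, `free_fraction` (per species), `defined`
#'   (FALSE when no inter-chain edges exist; ratios are then NA by flag,
#'   not NaN propagation), and optionally `p_value`.
#' @export
mixing_stats <- function(traj, params = contact_params(), permutations = 0L,
                         seed = 1L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  chain_species <- traj$beads$species[!duplicated(traj$beads$chain)]
  species <- unique(chain_species)
  if (length(species) < 2L) stop("mixing_stats needs >= 2 species")
  partitions <- cluster_partition(traj, params)

  edges <- list()
  for (f in seq_along(traj$frames)) {
    g <- interaction_graph(get_frame(traj, f), params)
    if (nrow(g$edges)) edges[[length(edges) + 1L]] <- g$edges[, c("a", "b")]
  }
  kin <- cluster_kinetics(traj, params, partitions = partitions)
  free_fraction <- kin$free_fraction

  if (!length(edges)) {
    return(structure(list(observed = NA_real_, expected = NA_real_,
                          enrichment = NA_real_, n_edges = 0L,
                          free_fraction = free_fraction, defined = FALSE),
                     class = "mixing_stats"))
  }
  edges <- do.call(rbind, edges)
  het_of <- function(labels)
    mean(labels[edges$a] != labels[edges$b])
  observed <- het_of(chain_species)
  p <- table(chain_species) / length(chain_species)
  pa <- as.numeric(p[species[1]]); pb <- as.numeric(p[species[2]])
  expected <- 2 * pa * pb / (pa + pb)^2
  out <- list(observed = observed, expected = expected,
              enrichment = observed / expected, n_edges = nrow(edges),
              free_fraction = free_fraction, defined = TRUE)
  if (permutations > 0L) {
    set.seed(seed)
    null <- replicate(permutations, het_of(sample(chain_species)))
    out$p_value <- (1 + sum(null <= observed)) / (permutations + 1)
  }
  structure(out, class = "mixing_stats")
}

#' @export
print.mixing_stats <- function(x, ...) {
  if (!x$defined) {
    cat("<mixing_stats> undefined: no inter-chain edges\n")
  } else {
    cat(sprintf("<mixing_stats> observed heterotypic %.3f, expected %.3f, enrichment %.2f (%d edges)\n",
                x$observed, x$expected, x$enrichment, x$n_edges))
  }
  invisible(x)
}

#' Tidy CSV / JSON exports for cluster kinetics and mixing
#'
#' @param kinetics a `cluster_kinetics`.
#' @param prefix output path prefix; writes `<prefix>_series.csv` and
#'   `<prefix>_events.csv`.
#' @export
write_kinetics_csv <- function(kinetics, prefix) {
  utils::write.csv(kinetics$series, paste0(prefix, "_series.csv"),
                   row.names = FALSE)
  utils::write.csv(kinetics$events, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_kinetics_csv
#' @param mixing a `mixing_stats`.
#' @param path JSON output path.
#' @export
write_mixing_json <- function(mixing, path) {
  jsonlite::write_json(unclass(mixing), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
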