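#' Parameters for contact-map analysis
#'
#' @param cutoff bead-contact distance cutoff, nm; two beads are in contact
#'   iff their minimum-image distance is strictly below it (default 0.5 nm).
#' @param chain_threshold minimum number of inter-chain bead contacts for two
#'   chains to count as interacting (default 1).
#' @param exclusion minimum residue separation along a chain for intra-chain
#'   contacts (default 3: residue pairs closer than 3 apart are ignored).
#' @param stride analyse every `stride`-th frame.
#' @param frames optional integer vector of frame indices to analyse.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(cutoff = 0.5, chain_threshold = 1L, exclusion = 3L,
                           stride = 1L, frames = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (chain_threshold < 1L) stop("chain_threshold must be >= 1")
  if (exclusion < 1L) stop("exclusion must be >= 1")
  structure(list(cutoff = cutoff, chain_threshold = as.integer(chain_threshold),
                 exclusion = as.integer(exclusion), stride = as.integer(stride),
                 frames = frames),
            class = "contact_params")
}

frame_indices <- function(traj, params) {
  idx <- if (is.null(params$frames)) seq_along(traj$frames) else
    as.integer(params$frames)
  idx[seq(1L, length(idx), by = params$stride)]
}

# Bond pairs (global bead indices) reconstructed from the bead table:
# consecutive backbone beads of a chain, plus backbone-sidechain within a
# residue for two-bead mappings.
frame_bonds <- function(beads) {
  out <- list(); k <- 0L
  for (ch in split(seq_len(nrow(beads)), beads$chain)) {
    b <- beads[ch, ]
    bb <- ch[b$slot == 1L]
    if (length(bb) > 1L) { k <- k + 1L; out[[k]] <- cbind(bb[-length(bb)], bb[-1L]) }
    sc <- ch[b$slot == 2L]
    if (length(sc)) {
      m <- match(b$residue[b$slot == 2L], b$residue[b$slot == 1L])
      k <- k + 1L; out[[k]] <- cbind(bb[m], sc)
    }
  }
  if (!k) return(matrix(integer(), 0L, 2L))
  do.call(rbind, out)
}

#' Bead contacts within a frame
#'
#' All unordered bead pairs whose minimum-image distance is strictly below
#' the cutoff, excluding bonded pairs and intra-chain pairs whose residue
#' separation is below the exclusion window. The production path uses a
#' periodic cell list; its correctness is pinned to a brute-force all-pairs
#' oracle in the test suite.
#'
#' @param frame a `sim_frame`.
#' @param params a [contact_params()].
#' @return data.frame with columns `i`, `j` (global bead indices, `i < j`),
#'   `chain_i`, `chain_j`, `bead_i`, `bead_j` (bead index within chain).
#' @export
bead_contacts <- function(frame, params = contact_params()) {
  stopifnot(inherits(frame, "sim_frame"))
  beads <- frame$beads
  bonds <- frame_bonds(beads)
  prs <- cpp_contact_pairs(frame$coords, frame$box, params$cutoff,
                           as.integer(beads$chain), as.integer(beads$residue),
                           bonds, params$exclusion)
  within_idx <- stats::ave(seq_len(nrow(beads)), beads$chain, FUN = seq_along)
  data.frame(i = prs[, 1], j = prs[, 2],
             chain_i = beads$chain[prs[, 1]], chain_j = beads$chain[prs[, 2]],
             bead_i = within_idx[prs[, 1]], bead_j = within_idx[prs[, 2]])
}

#' Chain interaction graph of a frame
#'
#' Undirected graph over chain ids with an edge between two distinct chains
#' iff they share at least `chain_threshold` bead contacts. Connected
#' components of this graph are the clusters.
#'
#' @inheritParams bead_contacts
#' @param contacts optionally, precomputed [bead_contacts()] output.
#' @return list of class `chain_graph`: `n` (chain count), `edges`
#'   (data.frame `a`, `b`, `contacts` with `a < b`).
#' @export
interaction_graph <- function(frame, params = contact_params(),
                              contacts = NULL) {
  if (is.null(contacts)) contacts <- bead_contacts(frame, params)
  n <- length(unique(frame$beads$chain))
  inter <- contacts[contacts$chain_i != contacts$chain_j, , drop = FALSE]
  if (nrow(inter)) {
    a <- pmin(inter$chain_i, inter$chain_j)
    b <- pmax(inter$chain_i, inter$chain_j)
    tab <- stats::aggregate(list(contacts = rep(1L, length(a))),
                            by = list(a = a, b = b), FUN = sum)
    tab <- tab[tab$contacts >= params$chain_threshold, , drop = FALSE]
    tab <- tab[order(tab$a, tab$b), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(a = integer(), b = integer(), contacts = integer())
  }
  structure(list(n = n, edges = tab), class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("<chain_graph> %d chains, %d interacting pairs\n", x$n,
              nrow(x$edges)))
  invisible(x)
}

new_contact_matrix <- function(matrix, level, mode, frames_total,
                               frames_contributing, cutoff,
                               symmetrized = FALSE, species = NA_character_,
                               beads_per_residue = 1L) {
  structure(list(matrix = matrix, level = level, mode = mode,
                 frames_total = frames_total,
                 frames_contributing = frames_contributing, cutoff = cutoff,
                 symmetrized = symmetrized, species = species,
                 beads_per_residue = beads_per_residue),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  if (is_empty_contact_matrix(x)) {
    cat(sprintf("<contact_matrix> EMPTY (%s): no contributing frames out of %d\n",
                x$mode, x$frames_total))
  } else {
    cat(sprintf("<contact_matrix> %s-level, %s, %dx%d, %d/%d frames contributing, cutoff %g nm\n",
                x$level, x$mode, nrow(x$matrix), ncol(x$matrix),
                x$frames_contributing, x$frames_total, x$cutoff))
  }
  invisible(x)
}

#' Is a contact matrix the explicit empty result?
#' @param m a `contact_matrix`.
#' @export
is_empty_contact_matrix <- function(m) is.null(m$matrix)

# species checks for multi-chain matrices
single_species <- function(traj) {
  sp <- unique(traj$beads$species)
  if (length(sp) != 1L)
    stop("all chains must be of the same species for this analysis; found: ",
         paste(sp, collapse = ", "))
  sp
}

# per-frame 0/1 indicator of contacts between the central chain and one
# neighbour, accumulated into an nb x nb matrix
pair_indicator <- function(contacts, chain_a, chain_b, nb) {
  m <- matrix(0, nb, nb)
  sel <- (contacts$chain_i == chain_a & contacts$chain_j == chain_b)
  if (any(sel)) m[cbind(contacts$bead_i[sel], contacts$bead_j[sel])] <- 1
  sel <- (contacts$chain_i == chain_b & contacts$chain_j == chain_a)
  if (any(sel)) m[cbind(contacts$bead_j[sel], contacts$bead_i[sel])] <- 1
  m
}

# pick the analysis cluster: largest component of size >= 2; ties broken by
# the cluster containing the lowest chain id
select_cluster <- function(partition) {
  sizes <- lengths(partition)
  cand <- which(sizes >= 2L)
  if (!length(cand)) return(NULL)
  best <- cand[sizes[cand] == max(sizes[cand])]
  if (length(best) > 1L)
    best <- best[which.min(vapply(partition[best], min, 1L))]
  partition[[best]]
}

# central chain of a cluster: max degree in the interaction graph restricted
# to the cluster; ties -> max total bead contacts with neighbours -> lowest id
central_chain <- function(graph, cluster) {
  e <- graph$edges
  e <- e[e$a %in% cluster & e$b %in% cluster, , drop = FALSE]
  deg <- table(factor(c(e$a, e$b), levels = cluster))
  tot <- stats::setNames(rep(0L, length(cluster)), cluster)
  for (r in seq_len(nrow(e))) {
    tot[as.character(e$a[r])] <- tot[as.character(e$a[r])] + e$contacts[r]
    tot[as.character(e$b[r])] <- tot[as.character(e$b[r])] + e$contacts[r]
  }
  ord <- order(-as.integer(deg), -as.integer(tot), cluster)
  cluster[ord[1]]
}

#' Central-chain-averaged contact matrix
#'
#' For every analysed frame that contains a cluster of two or more chains:
#' select the analysis cluster (the largest; all clusters with
#' `all_clusters = TRUE`), identify its central chain, and record, for each
#' bead pair (i of the central chain, j of a neighbouring chain), whether
#' that contact exists, averaged over the chains adjacent to the central one.
#' The final matrix is the mean of these per-frame matrices over contributing
#' frames; frames without a qualifying cluster contribute nothing and are
#' only counted in `frames_total`. Entries therefore lie in [0, 1].
#'
#' @param traj a `cg_trajectory`; all chains of one species.
#' @param params a [contact_params()].
#' @param all_clusters average over every cluster of each frame instead of
#'   only the largest.
#' @return A bead-level `contact_matrix` (mode `central-chain-averaged`), or
#'   the explicit empty result if no frame contributes.
#' @export
central_chain_matrix <- function(traj, params = contact_params(),
                                 all_clusters = FALSE) {
  stopifnot(inherits(traj, "cg_trajectory"))
  sp <- single_species(traj)
  idx <- frame_indices(traj, params)
  nb <- sum(traj$beads$chain == traj$beads$chain[1])
  acc <- matrix(0, nb, nb)
  contributing <- 0L
  for (f in idx) {
    fr <- get_frame(traj, f)
    contacts <- bead_contacts(fr, params)
    graph <- interaction_graph(fr, params, contacts = contacts)
    partition <- find_clusters(graph)
    clusters <- if (all_clusters) {
      Filter(function(s) length(s) >= 2L, partition)
    } else {
      cl <- select_cluster(partition)
      if (is.null(cl)) list() else list(cl)
    }
    if (!length(clusters)) next
    frame_m <- matrix(0, nb, nb)
    for (cl in clusters) {
      cc <- central_chain(graph, cl)
      e <- graph$edges
      nbrs <- c(e$b[e$a == cc], e$a[e$b == cc])
      nbrs <- nbrs[nbrs %in% cl]
      m <- matrix(0, nb, nb)
      for (nbr in nbrs) m <- m + pair_indicator(contacts, cc, nbr, nb)
      frame_m <- frame_m + m / length(nbrs)
    }
    acc <- acc + frame_m / length(clusters)
    contributing <- contributing + 1L
  }
  if (contributing == 0L)
    return(new_contact_matrix(NULL, "bead", "central-chain-averaged",
                              length(idx), 0L, params$cutoff, species = sp))
  new_contact_matrix(acc / contributing, "bead", "central-chain-averaged",
                     length(idx), contributing, params$cutoff, species = sp,
                     beads_per_residue = nb %/%
                       sum(traj$beads$chain == traj$beads$chain[1] &
                           traj$beads$slot == 1L))
}

#' Two-chain contact matrix
#'
#' For a trajectory of exactly two chains of the same species: entry (i, j)
#' of the per-frame matrix is 1 iff bead i of chain 1 contacts bead j of
#' chain 2; the final matrix is the mean over all analysed frames (frames
#' without contacts contribute zeros). There is no central chain.
#'
#' @inheritParams central_chain_matrix
#' @return A bead-level `contact_matrix` (mode `two-chain`).
#' @export
two_chain_matrix <- function(traj, params = contact_params()) {
  stopifnot(inherits(traj, "cg_trajectory"))
  chains <- sort(unique(traj$beads$chain))
  if (length(chains) != 2L)
    stop("two_chain_matrix needs exactly 2 chains, got ", length(chains))
  sp <- single_species(traj)
  idx <- frame_indices(traj, params)
  nb <- sum(traj$beads$chain == chains[1])
  acc <- matrix(0, nb, nb)
  for (f in idx) {
    contacts <- bead_contacts(get_frame(traj, f), params)
    acc <- acc + pair_indicator(contacts, chains[1], chains[2], nb)
  }
  new_contact_matrix(acc / length(idx), "bead", "two-chain", length(idx),
                     length(idx), params$cutoff, species = sp,
                     beads_per_residue = nb %/%
                       sum(traj$beads$chain == chains[1] &
                           traj$beads$slot == 1L))
}

#' Intra-chain contact matrix
#'
#' Mean over analysed frames and over chain copies of the within-chain
#' contact indicators, respecting the exclusion window (residue pairs closer
#' along the chain than `params$exclusion` never count). The matrix is
#' symmetric by construction.
#'
#' @inheritParams central_chain_matrix
#' @param species chain species to analyse (default: the single species
#'   present).
#' @return A bead-level `contact_matrix` (mode `intra-chain`).
#' @export
intra_chain_matrix <- function(traj, params = contact_params(),
                               species = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(species)) species <- single_species(traj)
  sel <- traj$beads$species == species
  if (!any(sel)) stop("species '", species, "' not present")
  chains <- unique(traj$beads$chain[sel])
  nb <- sum(traj$beads$chain == chains[1])
  idx <- frame_indices(traj, params)
  within_idx <- stats::ave(seq_len(nrow(traj$beads)), traj$beads$chain,
                           FUN = seq_along)
  acc <- matrix(0, nb, nb)
  for (f in idx) {
    contacts <- bead_contacts(get_frame(traj, f), params)
    intra <- contacts[contacts$chain_i == contacts$chain_j &
                      contacts$chain_i %in% chains, , drop = FALSE]
    if (nrow(intra)) {
      m <- matrix(0, nb, nb)
      m[cbind(intra$bead_i, intra$bead_j)] <- 1
      m[cbind(intra$bead_j, intra$bead_i)] <- 1
      acc <- acc + m
    }
  }
  new_contact_matrix(acc / (length(idx) * length(chains)), "bead",
                     "intra-chain", length(idx), length(idx), params$cutoff,
                     symmetrized = TRUE, species = species,
                     beads_per_residue = nb %/%
                       sum(traj$beads$chain == chains[1] &
                           traj$beads$slot == 1L))
}

#' Convert a bead-level contact matrix to residue level
#'
#' Residue entry (p, q) is the maximum score over all bead pairs (i in p,
#' j in q) of the bead-level matrix. With one bead per residue this is the
#' identity transformation.
#'
#' @param m a bead-level `contact_matrix`.
#' @param topology the [chain_topology()] of the chain species.
#' @return A residue-level `contact_matrix`.
#' @export
beads_to_residues <- function(m, topology) {
  stopifnot(inherits(m, "contact_matrix"), inherits(topology, "chain_topology"))
  if (is_empty_contact_matrix(m)) stop("cannot aggregate an empty contact matrix")
  if (m$level != "bead") stop("matrix is already at ", m$level, " level")
  g <- topology$beads$residue
  if (length(g) != nrow(m$matrix))
    stop("dimension mismatch: matrix has ", nrow(m$matrix), " beads, topology ",
         length(g))
  groups <- split(seq_along(g), g)
  nres <- length(groups)
  rowmax <- matrix(0, nres, ncol(m$matrix))
  for (p in seq_len(nres))
    rowmax[p, ] <- apply(m$matrix[groups[[p]], , drop = FALSE], 2L, max)
  out <- matrix(0, nres, nres)
  for (q in seq_len(nres))
    out[, q] <- apply(rowmax[, groups[[q]], drop = FALSE], 1L, max)
  res <- m
  res$matrix <- out
  res$level <- "residue"
  res
}

#' 1D per-residue contact projection
#'
#' Sums all contributions of each residue in a residue-level contact matrix:
#' the matrix is symmetrised as `(M + t(M)) / 2` (for identical chains the
#' two residue roles are exchangeable) and row sums are reported. When a
#' [region] is supplied the scores are annotated with LD residue numbering.
#'
#' @param m a residue-level `contact_matrix`.
#' @param region optional [region] for LD numbering of the rows.
#' @return data.frame with `residue` (chain-internal), optionally
#'   `ld_residue` and `aa`, and `score`.
#' @export
project_1d <- function(m, region = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is_empty_contact_matrix(m)) stop("cannot project an empty contact matrix")
  if (m$level != "residue")
    stop("projection requires a residue-level matrix; see beads_to_residues()")
  sym <- (m$matrix + t(m$matrix)) / 2
  out <- data.frame(residue = seq_len(nrow(sym)), score = rowSums(sym))
  if (!is.null(region)) {
    if (length(region) != nrow(sym))
      stop("region '", region$name, "' length ", length(region),
           " does not match matrix dimension ", nrow(sym))
    out$ld_residue <- region$start + out$residue - 1L
    out$aa <- strsplit(region$sequence, "")[[1]]
    out <- out[, c("residue", "ld_residue", "aa", "score")]
  }
  out
}

#' Write / read a contact matrix as annotated TSV
#'
#' Tab-delimited text with a `#`-prefixed header block carrying level, mode,
#' frame counts and cutoff; rows/columns labelled by bead or residue index
#' (LD numbering when a region is supplied).
#'
#' @param m a `contact_matrix`.
#' @param path output file.
#' @param region optional [region] for LD residue labels.
#' @export
write_contact_matrix <- function(m, path, region = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is_empty_contact_matrix(m)) stop("refusing to write an empty contact matrix")
  labels <- seq_len(nrow(m$matrix))
  if (!is.null(region) && m$level == "residue")
    labels <- region$start + labels - 1L
  hdr <- c(sprintf("# level: %s", m$level),
           sprintf("# mode: %s", m$mode),
           sprintf("# frames_total: %d", m$frames_total),
           sprintf("# frames_contributing: %d", m$frames_contributing),
           sprintf("# cutoff_nm: %g", m$cutoff),
           sprintf("# symmetrized: %s", m$symmetrized))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("", labels), collapse = "\t"), con)
  for (r in seq_len(nrow(m$matrix)))
    writeLines(paste(c(labels[r], format(m$matrix[r, ], digits = 8,
                                         scientific = FALSE, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  val <- function(key) sub(paste0("^# ", key, ": *"), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  new_contact_matrix(unname(as.matrix(tab)), val("level"), val("mode"),
                     as.integer(val("frames_total")),
                     as.integer(val("frames_contributing")),
                     as.numeric(val("cutoff_nm")),
                     symmetrized = as.logical(val("symmetrized")))
}

#' @rdname write_contact_matrix
#' @param projection data.frame from [project_1d()].
#' @export
write_projection_tsv <- function(projection, path) {
  utils::write.table(projection, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
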