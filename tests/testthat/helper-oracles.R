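# Brute-force reference implementations, deliberately independent of the
# package's cell-list / igraph production paths. Everything here is O(n^2)
# (or worse) plain R and is only run on small systems.

min_image_dist2 <- function(a, b, box) {
  d <- abs(a - b)
  d <- pmin(d, box - d)
  sum(d * d)
}

# all bead pairs below cutoff, honouring bonds and the intra-chain exclusion
oracle_contacts <- function(frame, params = contact_params()) {
  x <- frame$coords; b <- frame$beads; box <- frame$box
  n <- nrow(x)
  bonds <- drcluster:::frame_bonds(b)
  bonded <- new.env(hash = TRUE)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds)))
    assign(paste(bonds[r, 1], bonds[r, 2]), TRUE, envir = bonded)
  out <- list(); k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (b$chain[i] == b$chain[j]) {
      if (abs(b$residue[i] - b$residue[j]) < params$exclusion) next
      if (exists(paste(i, j), envir = bonded, inherits = FALSE)) next
    }
    if (min_image_dist2(x[i, ], x[j, ], box) < params$cutoff^2) {
      k <- k + 1L; out[[k]] <- c(i, j)
    }
  }
  if (!k) return(matrix(integer(), 0L, 2L))
  do.call(rbind, out)
}

# chain-pair interaction edges from an oracle contact list
oracle_edges <- function(frame, pairs, threshold = 1L) {
  ch <- frame$beads$chain
  inter <- pairs[ch[pairs[, 1]] != ch[pairs[, 2]], , drop = FALSE]
  if (!nrow(inter)) return(matrix(integer(), 0L, 2L))
  a <- pmin(ch[inter[, 1]], ch[inter[, 2]])
  b <- pmax(ch[inter[, 1]], ch[inter[, 2]])
  key <- paste(a, b)
  counts <- table(key)
  keep <- names(counts)[counts >= threshold]
  if (!length(keep)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, lapply(strsplit(keep, " "), as.integer))
}

# connected components by breadth-first search over an edge matrix
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, 1L))]
}

# full re-implementation of the central-chain-averaged matrix without cell
# lists or igraph
oracle_central_matrix <- function(traj, params = contact_params()) {
  nb <- sum(traj$beads$chain == traj$beads$chain[1])
  n_chains <- length(unique(traj$beads$chain))
  acc <- matrix(0, nb, nb); contributing <- 0L
  widx <- stats::ave(seq_len(nrow(traj$beads)), traj$beads$chain,
                     FUN = seq_along)
  for (fidx in seq_along(traj$frames)) {
    fr <- get_frame(traj, fidx)
    pairs <- oracle_contacts(fr, params)
    edges <- oracle_edges(fr, pairs, params$chain_threshold)
    comps <- oracle_components(n_chains, edges)
    sizes <- lengths(comps)
    cand <- which(sizes >= 2L)
    if (!length(cand)) next
    big <- cand[sizes[cand] == max(sizes[cand])]
    if (length(big) > 1L) big <- big[which.min(vapply(comps[big], min, 1L))]
    cl <- comps[[big]]
    # central chain: degree, then total contacts, then lowest id
    ch <- fr$beads$chain
    deg <- tot <- stats::setNames(integer(length(cl)), cl)
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      if (a %in% cl && b %in% cl) {
        deg[as.character(a)] <- deg[as.character(a)] + 1L
        deg[as.character(b)] <- deg[as.character(b)] + 1L
      }
    }
    if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
      ca <- ch[pairs[r, 1]]; cb <- ch[pairs[r, 2]]
      if (ca != cb && ca %in% cl && cb %in% cl) {
        tot[as.character(ca)] <- tot[as.character(ca)] + 1L
        tot[as.character(cb)] <- tot[as.character(cb)] + 1L
      }
    }
    # but total contacts tie-break counts only contacts with graph neighbours
    # of the candidate; with threshold 1 every contacting pair is an edge, so
    # this matches the production rule on these systems
    ord <- order(-deg, -tot, cl)
    central <- cl[ord[1]]
    nbrs <- integer()
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      if (edges[r, 1] == central) nbrs <- c(nbrs, edges[r, 2])
      if (edges[r, 2] == central) nbrs <- c(nbrs, edges[r, 1])
    }
    nbrs <- nbrs[nbrs %in% cl]
    m <- matrix(0, nb, nb)
    for (nbr in nbrs) {
      ind <- matrix(0, nb, nb)
      if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (ch[i] == central && ch[j] == nbr) ind[widx[i], widx[j]] <- 1
        if (ch[j] == central && ch[i] == nbr) ind[widx[j], widx[i]] <- 1
      }
      m <- m + ind
    }
    acc <- acc + m / length(nbrs)
    contributing <- contributing + 1L
  }
  if (contributing == 0L) return(NULL)
  list(matrix = acc / contributing, contributing = contributing)
}

# residue aggregation by explicit enumeration of bead pairs
oracle_beads_to_residues <- function(mat, residue_of) {
  nres <- max(residue_of)
  out <- matrix(0, nres, nres)
  for (p in seq_len(nres)) for (q in seq_len(nres)) {
    ip <- which(residue_of == p); iq <- which(residue_of == q)
    out[p, q] <- max(mat[ip, iq])
  }
  out
}

# random small multi-chain frame for property tests: a few short random-walk
# chains dropped in a periodic box (no excluded volume -- contacts abound)
random_test_frame <- function(n_chains = 4L, n_res = 8L, box = 6,
                              beads_per_residue = 1L, seed = 1L,
                              spread = 0.4) {
  set.seed(seed)
  seqs <- replicate(n_chains, paste(sample(c("D", "K", "F", "S", "G", "L"),
                                           n_res, replace = TRUE),
                                    collapse = ""))
  tops <- lapply(seq_len(n_chains), function(i)
    chain_topology(paste0("SP", i), seqs[i],
                   beads_per_residue = beads_per_residue))
  # treat every chain as its own species so sequences may differ
  cfg <- system_config(tops, copies = rep(1L, n_chains), box_edge = box)
  beads <- drcluster:::system_beads(cfg)
  coords <- NULL
  for (i in seq_len(n_chains)) {
    nb <- n_res * beads_per_residue
    start <- stats::runif(3, 0, box)
    steps <- matrix(stats::rnorm(3 * nb, 0, spread), ncol = 3)
    xyz <- sweep(apply(steps, 2, cumsum), 2, start, `+`)
    coords <- rbind(coords, xyz)
  }
  drcluster:::new_frame(drcluster:::wrap_coords(coords, box), beads, box)
}
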