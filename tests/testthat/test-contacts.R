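make_pair_frame <- function(positions, box = 10, sequence = "DKFS") {
  # two chains of identical short species at given per-bead coordinates
  top <- chain_topology("SP", sequence)
  cfg <- system_config(list(SP = top), copies = 2L, box_edge = box)
  beads <- drcluster:::system_beads(cfg)
  stopifnot(nrow(positions) == nrow(beads))
  drcluster:::new_frame(drcluster:::wrap_coords(positions, box), beads, box)
}

test_that("bead contacts honour the strict 0.5 nm cutoff and minimum image", {
  nb <- 4L
  base <- cbind(seq_len(nb) * 2, 5, 5)           # chain 1, well separated
  other <- cbind(seq_len(nb) * 2, 5 + 0.49, 5)   # chain 2 parallel at 0.49
  fr <- make_pair_frame(rbind(base, other))
  ct <- bead_contacts(fr)
  expect_equal(nrow(ct), nb)  # each bead touches its counterpart only
  expect_true(all(ct$chain_i == 1 & ct$chain_j == 2))

  other2 <- cbind(seq_len(nb) * 2, 5 + 0.51, 5)  # just outside
  expect_equal(nrow(bead_contacts(make_pair_frame(rbind(base, other2)))), 0L)

  # contact across opposite box faces: true image distance 0.3
  a <- cbind(seq_len(nb) * 2, 0.1, 5)
  b <- cbind(seq_len(nb) * 2, 9.8, 5)
  ctp <- bead_contacts(make_pair_frame(rbind(a, b)))
  expect_equal(nrow(ctp), nb)
})

test_that("cell-list contacts match the brute-force oracle on random systems", {
  # >= 20 random small systems, varied density, box and bead mapping
  cases <- expand.grid(seed = 1:6, box = c(4, 6, 9), bpr = 1:2)
  cases <- cases[seq_len(nrow(cases)) %% 3 != 0 | cases$bpr == 2, ]
  expect_gte(nrow(cases), 20)
  for (k in seq_len(nrow(cases))) {
    fr <- random_test_frame(n_chains = 4L, n_res = 7L, box = cases$box[k],
                            beads_per_residue = cases$bpr[k],
                            seed = cases$seed[k])
    got <- bead_contacts(fr)
    want <- oracle_contacts(fr)
    got_key <- sort(paste(got$i, got$j))
    want_key <- if (nrow(want)) sort(paste(want[, 1], want[, 2])) else character()
    expect_identical(got_key, want_key,
                     label = sprintf("case %d (seed %d box %g bpr %d)", k,
                                     cases$seed[k], cases$box[k],
                                     cases$bpr[k]))
  }
})

test_that("cutoff monotonicity: enlarging the cutoff never removes a contact", {
  fr <- random_test_frame(n_chains = 5L, n_res = 10L, box = 7, seed = 42)
  small <- bead_contacts(fr, contact_params(cutoff = 0.5))
  big <- bead_contacts(fr, contact_params(cutoff = 0.8))
  key <- function(d) paste(d$i, d$j)
  expect_true(all(key(small) %in% key(big)))
})

test_that("interaction graph applies the chain threshold", {
  nb <- 4L
  base <- cbind(seq_len(nb) * 2, 5, 5)
  touch3 <- rbind(cbind(1:3 * 2, 5.3, 5), c(20, 20, 20) / 3)  # 3 contacts
  fr <- make_pair_frame(rbind(base, touch3))
  expect_equal(nrow(bead_contacts(fr)[bead_contacts(fr)$chain_i !=
                                      bead_contacts(fr)$chain_j, ]), 3L)
  g1 <- interaction_graph(fr, contact_params(chain_threshold = 1L))
  expect_equal(nrow(g1$edges), 1L)
  g5 <- interaction_graph(fr, contact_params(chain_threshold = 5L))
  expect_equal(nrow(g5$edges), 0L)
})

test_that("central-chain averaging follows the per-frame neighbour rule", {
  # single frame: central chain touches one neighbour at exactly one bead pair
  nb <- 4L
  c1 <- cbind(seq_len(nb) * 2, 5, 5)
  c2 <- matrix(c(2, 5.4, 5,   10, 1, 1,  12, 1, 1,  14, 1, 1), ncol = 3,
               byrow = TRUE)  # only bead 1 of chain 2 touches bead 1 of chain 1
  fr <- make_pair_frame(rbind(c1, c2), box = 20)
  traj <- drcluster:::new_trajectory(list(fr$coords), 0, fr$beads, fr$box)
  m <- central_chain_matrix(traj)
  expect_false(is_empty_contact_matrix(m))
  expect_equal(m$frames_contributing, 1L)
  want <- matrix(0, nb, nb); want[1, 1] <- 1
  expect_equal(m$matrix, want)

  # two neighbours contributing the same single contact average to 1
  top <- chain_topology("SP", "DKFS")
  cfg3 <- system_config(list(SP = top), copies = 3L, box_edge = 20)
  beads3 <- drcluster:::system_beads(cfg3)
  cc <- cbind(seq_len(nb) * 2, 10, 10)
  n1 <- rbind(c(2, 10.4, 10), cbind(c(30, 32, 34) / 2, 2, 2))
  n2 <- rbind(c(2, 10, 10.4), cbind(c(30, 32, 34) / 2, 18, 18))
  fr3 <- drcluster:::new_frame(rbind(cc, n1, n2), beads3, 20)
  traj3 <- drcluster:::new_trajectory(list(fr3$coords), 0, beads3, 20)
  m3 <- central_chain_matrix(traj3)
  want3 <- matrix(0, nb, nb); want3[1, 1] <- 1  # (1 + 1) / 2 neighbours
  expect_equal(m3$matrix, want3)

  # no cluster anywhere: explicit empty result, not a silent zero matrix
  apart <- rbind(cbind(seq_len(nb) * 2, 2, 2), cbind(seq_len(nb) * 2, 15, 15))
  fr0 <- make_pair_frame(apart, box = 20)
  traj0 <- drcluster:::new_trajectory(list(fr0$coords), 0, fr0$beads, 20)
  m0 <- central_chain_matrix(traj0)
  expect_true(is_empty_contact_matrix(m0))
  expect_equal(m0$frames_contributing, 0L)
})

test_that("central-chain matrices match the brute-force oracle on clustering systems", {
  for (seed in 1:4) {
    cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 5L,
                         box_edge = 8, seed = seed,
                         params = sim_params(chi = 2))
    start <- build_system(cfg)
    traj <- simulate_system(start, cfg, n_steps = 600L, save_every = 60L)
    m <- central_chain_matrix(traj)
    o <- oracle_central_matrix(traj)
    if (is.null(o)) {
      expect_true(is_empty_contact_matrix(m))
    } else {
      expect_equal(m$frames_contributing, o$contributing)
      expect_equal(m$matrix, o$matrix)
      # score bounds: averaged indicators live in [0, 1]
      expect_true(all(m$matrix >= 0 & m$matrix <= 1))
    }
  }
})

test_that("chain relabelling leaves the central-chain matrix unchanged", {
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 4L,
                       box_edge = 7, seed = 9L, params = sim_params(chi = 2))
  traj <- simulate_system(build_system(cfg), cfg, n_steps = 400L,
                          save_every = 100L)
  m <- central_chain_matrix(traj)
  # permute chain blocks (identical species, so only labels change)
  perm <- c(3L, 1L, 4L, 2L)
  nb <- 22L
  traj2 <- traj
  reorder <- unlist(lapply(perm, function(ch) which(traj$beads$chain == ch)))
  traj2$frames <- lapply(traj$frames, function(fr) fr[reorder, , drop = FALSE])
  m2 <- central_chain_matrix(traj2)
  expect_equal(m2$matrix, m$matrix)
  expect_equal(m2$frames_contributing, m$frames_contributing)
})

test_that("two-chain matrices average indicators over all frames", {
  nb <- 4L
  base <- cbind(seq_len(nb) * 2, 5, 5)
  near <- cbind(seq_len(nb) * 2, 5.4, 5)
  far <- cbind(seq_len(nb) * 2, 15, 5)
  fr_touch <- make_pair_frame(rbind(base, near), box = 20)
  fr_apart <- make_pair_frame(rbind(base, far), box = 20)
  traj <- drcluster:::new_trajectory(list(fr_touch$coords, fr_apart$coords),
                                     c(0, 1), fr_touch$beads, 20)
  m <- two_chain_matrix(traj)
  expect_equal(m$frames_contributing, 2L)  # contact-free frames contribute zeros
  expect_equal(diag(m$matrix), rep(0.5, nb))
  expect_equal(sum(m$matrix), nb * 0.5)

  # never in contact -> zero matrix over all frames
  traj0 <- drcluster:::new_trajectory(list(fr_apart$coords), 0,
                                      fr_apart$beads, 20)
  expect_true(all(two_chain_matrix(traj0)$matrix == 0))

  # requires exactly two chains
  fr3 <- random_test_frame(n_chains = 3L, n_res = 4L)
  traj3 <- drcluster:::new_trajectory(list(fr3$coords), 0, fr3$beads, fr3$box)
  expect_error(two_chain_matrix(traj3), "exactly 2 chains")
})

test_that("intra-chain maps respect the exclusion window", {
  # hairpin: bead k touches bead k+10 (12-residue chain, one copy)
  top <- chain_topology("HP", "DKFSDKFSDKFS")
  cfg <- system_config(list(HP = top), copies = 1L, box_edge = 10)
  beads <- drcluster:::system_beads(cfg)
  xyz <- matrix(0, 12, 3)
  for (i in 1:6) xyz[i, ] <- c(i * 0.38, 5, 5)
  for (i in 7:12) xyz[i, ] <- c((13 - i) * 0.38, 5.45, 5)
  fr <- drcluster:::new_frame(drcluster:::wrap_coords(xyz, 10), beads, 10)
  traj <- drcluster:::new_trajectory(list(fr$coords), 0, beads, 10)
  m <- intra_chain_matrix(traj)
  expect_true(m$symmetrized)
  expect_equal(m$matrix, t(m$matrix))
  expect_equal(m$matrix[2, 11], 1)  # bead 2 touches bead 11 across the turn
  # exclusion window 3: band |i - j| < 3 identically zero
  band <- abs(row(m$matrix) - col(m$matrix)) < 3
  expect_true(all(m$matrix[band] == 0))

  # fully extended chain has no intra contacts at all
  straight <- cbind(seq_len(12) * 0.38, 5, 5)
  fr2 <- drcluster:::new_frame(straight, beads, 10)
  traj2 <- drcluster:::new_trajectory(list(fr2$coords), 0, beads, 10)
  expect_true(all(intra_chain_matrix(traj2)$matrix == 0))
})

test_that("bead-to-residue aggregation retains the maximum score", {
  top2 <- chain_topology("SP", "DKFS", beads_per_residue = 2L)
  m <- new_contact_matrix <- drcluster:::new_contact_matrix(
    matrix(stats::runif(64), 8, 8), "bead", "two-chain", 10L, 10L, 0.5,
    beads_per_residue = 2L)
  res <- beads_to_residues(m, top2)
  expect_equal(res$level, "residue")
  expect_equal(dim(res$matrix), c(4L, 4L))
  expect_equal(res$matrix,
               oracle_beads_to_residues(m$matrix, top2$beads$residue))

  # explicit max rule: bead scores {0.2, 0.7} for one residue pair
  mm <- matrix(0, 8, 8); mm[1, 3] <- 0.2; mm[2, 4] <- 0.7
  m2 <- drcluster:::new_contact_matrix(mm, "bead", "two-chain", 1L, 1L, 0.5,
                                       beads_per_residue = 2L)
  expect_equal(beads_to_residues(m2, top2)$matrix[1, 2], 0.7)

  # one bead per residue: identity
  top1 <- chain_topology("SP", "DKFS")
  m1 <- drcluster:::new_contact_matrix(matrix(stats::runif(16), 4, 4),
                                       "bead", "two-chain", 1L, 1L, 0.5)
  expect_equal(beads_to_residues(m1, top1)$matrix, m1$matrix)

  expect_error(beads_to_residues(m1, top2), "mismatch")
})

test_that("1D projection symmetrises and sums per-residue contributions", {
  mm <- matrix(0, 5, 5); mm[2, 4] <- 1; mm[4, 2] <- 1
  m <- drcluster:::new_contact_matrix(mm, "residue", "two-chain", 1L, 1L, 0.5)
  p <- project_1d(m)
  expect_equal(p$score, c(0, 1, 0, 1, 0))

  zero <- drcluster:::new_contact_matrix(matrix(0, 5, 5), "residue",
                                         "two-chain", 1L, 1L, 0.5)
  expect_true(all(project_1d(zero)$score == 0))

  # asymmetric entry contributes half to each residue after symmetrisation
  mm2 <- matrix(0, 5, 5); mm2[1, 5] <- 1
  m2 <- drcluster:::new_contact_matrix(mm2, "residue", "two-chain", 1L, 1L, 0.5)
  expect_equal(project_1d(m2)$score, c(0.5, 0, 0, 0, 0.5))

  # LD numbering annotation via a region
  reg <- region("toy", 101, 105, "DKFSD")
  p2 <- project_1d(m2, region = reg)
  expect_equal(p2$ld_residue, 101:105)
  expect_equal(p2$aa, c("D", "K", "F", "S", "D"))

  bead <- drcluster:::new_contact_matrix(mm2, "bead", "two-chain", 1L, 1L, 0.5)
  expect_error(project_1d(bead), "residue-level")
})

test_that("contact matrices round-trip through annotated TSV", {
  mm <- matrix(stats::runif(16), 4, 4)
  m <- drcluster:::new_contact_matrix(mm, "residue", "central-chain-averaged",
                                      20L, 17L, 0.5)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(m, tmp)
  back <- read_contact_matrix(tmp)
  expect_equal(back$matrix, m$matrix, tolerance = 1e-7)
  expect_equal(back$mode, m$mode)
  expect_equal(back$frames_contributing, 17L)
  expect_equal(back$cutoff, 0.5)
})
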