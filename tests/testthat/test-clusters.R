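test_that("find_clusters equals brute-force components on random graphs", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(5:50, 1)
    m <- sample(0:(2 * n), 1)
    edges <- if (m) cbind(sample(n, m, TRUE), sample(n, m, TRUE)) else
      matrix(integer(), 0, 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- structure(list(n = n,
                        edges = data.frame(a = pmin(edges[, 1], edges[, 2]),
                                           b = pmax(edges[, 1], edges[, 2]),
                                           contacts = rep(1L, nrow(edges)))),
                   class = "chain_graph")
    expect_equal(find_clusters(g), oracle_components(n, edges))
  }
  # edgeless graph: all singletons
  g0 <- structure(list(n = 33L, edges = data.frame(a = integer(),
                                                   b = integer(),
                                                   contacts = integer())),
                  class = "chain_graph")
  expect_equal(lengths(find_clusters(g0)), rep(1L, 33L))
})

planted_trajectory <- function(partition, n_frames = 3L, seed = 21L) {
  cfg <- system_config(list(DR1 = region_topology("DR1")),
                       copies = length(unlist(partition)), box_edge = 30,
                       seed = seed)
  fr <- plant_clusters(cfg, partition)
  drcluster:::new_trajectory(rep(list(fr$coords), n_frames),
                             seq_len(n_frames) - 1, fr$beads, fr$box)
}

test_that("cluster partitions and sizes are consistent per frame", {
  partition <- list(c(1L, 2L, 3L), 4L, c(5L, 6L))
  traj <- planted_trajectory(partition)
  parts <- cluster_partition(traj)
  for (p in parts$frames) {
    expect_equal(sort(unlist(p$partition)), 1:6)  # sizes sum to chain count
    expect_equal(p$partition, partition)
    # central chain annotated for clusters of size >= 2, member of its set
    for (i in seq_along(p$partition)) {
      if (length(p$partition[[i]]) >= 2L)
        expect_true(p$central[i] %in% p$partition[[i]])
      else expect_true(is.na(p$central[i]))
    }
  }
})

test_that("static planted clusters yield zero events and full dwell times", {
  partition <- list(c(1L, 2L), c(3L, 4L, 5L), 6L)
  traj <- planted_trajectory(partition, n_frames = 5L)
  kin <- cluster_kinetics(traj)
  expect_equal(kin$status, "ok")
  expect_equal(nrow(kin$events), 0L)
  expect_equal(kin$series$largest_cluster, rep(3L, 5L))
  expect_equal(kin$series$n_clusters, rep(2L, 5L))
  # every clustered chain dwells for the whole trajectory
  clustered <- unlist(partition[lengths(partition) >= 2])
  expect_setequal(kin$dwell$chain, clustered)
  expect_true(all(kin$dwell$n_frames == 5L))
  expect_equal(unname(kin$free_fraction["DR1"]), 1 / 6)
})

test_that("join and leave events reproduce a hand-built membership sequence", {
  # frame 1: all free; frame 2: {1,2} together; frame 3: all free again
  cfg <- system_config(list(DR1 = region_topology("DR1")), copies = 3L,
                       box_edge = 30, seed = 2L)
  together <- plant_clusters(cfg, list(c(1L, 2L), 3L))
  apart <- plant_clusters(cfg, list(1L, 2L, 3L))
  traj <- drcluster:::new_trajectory(
    list(apart$coords, together$coords, apart$coords), 0:2, apart$beads, 30)
  kin <- cluster_kinetics(traj)
  joins <- kin$events[kin$events$type == "join", ]
  leaves <- kin$events[kin$events$type == "leave", ]
  expect_setequal(joins$chain, c(1L, 2L))
  expect_true(all(joins$frame == 2L))
  expect_setequal(leaves$chain, c(1L, 2L))
  expect_true(all(leaves$frame == 3L))

  # event counts are recomputable from the stored partition sequence
  parts <- cluster_partition(traj)
  kin2 <- cluster_kinetics(traj, partitions = parts)
  expect_identical(kin$events, kin2$events)

  # single frame: kinetics empty with status flag
  traj1 <- drcluster:::new_trajectory(list(apart$coords), 0, apart$beads, 30)
  expect_equal(cluster_kinetics(traj1)$status, "empty")
})

test_that("mixing statistics separate well-mixed from demixed systems", {
  # null case: one physical system, labels split across two "species"
  tops <- list(A = region_topology("DR1"), B = region_topology("DR1"))
  tops$B$name <- "B"; tops$A$name <- "A"
  cfg <- system_config(tops, copies = c(3L, 3L), box_edge = 30, seed = 5L)
  # plant mixed pairs: each cluster holds one A and one B chain (A: 1-3, B: 4-6)
  fr <- plant_clusters(cfg, list(c(1L, 4L), c(2L, 5L), c(3L, 6L)))
  traj <- drcluster:::new_trajectory(list(fr$coords), 0, fr$beads, 30)
  mix <- mixing_stats(traj)
  expect_true(mix$defined)
  expect_equal(mix$observed, 1)          # every edge heterotypic
  expect_equal(mix$expected, 0.5)        # p = 0.5 each
  expect_equal(mix$enrichment, 2)

  # demixed: A clusters with A, B stays free
  fr2 <- plant_clusters(cfg, list(c(1L, 2L, 3L), 4L, 5L, 6L))
  traj2 <- drcluster:::new_trajectory(list(fr2$coords), 0, fr2$beads, 30)
  mix2 <- mixing_stats(traj2)
  expect_equal(mix2$observed, 0)
  expect_equal(mix2$enrichment, 0)
  expect_equal(unname(mix2$free_fraction["B"]), 1)
  expect_equal(unname(mix2$free_fraction["A"]), 0)

  # no edges at all: undefined-flagged, not NaN
  fr3 <- plant_clusters(cfg, as.list(1:6))
  traj3 <- drcluster:::new_trajectory(list(fr3$coords), 0, fr3$beads, 30)
  mix3 <- mixing_stats(traj3)
  expect_false(mix3$defined)
  expect_true(is.na(mix3$enrichment))

  # permutation null is seeded and sane
  mixp <- mixing_stats(traj2, permutations = 99L, seed = 3L)
  expect_lt(mixp$p_value, 0.2)
  expect_equal(mixp$p_value,
               mixing_stats(traj2, permutations = 99L, seed = 3L)$p_value)

  expect_error(mixing_stats(planted_trajectory(list(c(1L, 2L)))), "2 species")
})

test_that("kinetics and mixing exports are tidy", {
  traj <- planted_trajectory(list(c(1L, 2L), 3L, 4L), n_frames = 3L)
  kin <- cluster_kinetics(traj)
  prefix <- file.path(withr::local_tempdir(), "kin")
  write_kinetics_csv(kin, prefix)
  series <- utils::read.csv(paste0(prefix, "_series.csv"))
  expect_equal(nrow(series), 3L)
  expect_true(all(c("frame", "time", "largest_cluster", "n_clusters",
                    "largest_fraction") %in% names(series)))
})
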