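# Cross-link detection and trajectory statistics, checked against
# brute-force oracles and planted schedules.

toy_frame <- function(coords, box = c(10, 10, 10)) {
  list(coords = coords, box = box, time = 0)
}

test_that("minimum-image distance matches the 27-image exhaustive search", {
  box <- c(10, 10, 10)
  expect_equal(min_image_distance(c(1, 1, 1), c(1, 1, 1), box), 0)
  expect_equal(min_image_distance(c(0.1, 0, 0), c(9.9, 0, 0), box), 0.2)
  expect_error(min_image_distance(c(0, 0, 0), c(1, 1, 1), c(-1, 10, 10)), "> 0")
  set.seed(501)
  for (k in 1:50) {
    box <- runif(3, 2, 12)
    p1 <- runif(3, -5, 15)
    p2 <- runif(3, -5, 15)
    expect_equal(min_image_distance(p1, p2, box), brute_min_image(p1, p2, box),
                 tolerance = 1e-12)
  }
})

test_that("calcium bridge detector handles planted, distant and intra-chain ions", {
  topo <- chain_topology("DD", n_chains = 2, n_ions = 1)
  # atoms 1-6 chain 1 (BB,OD,OD x2 residues), 7-12 chain 2, ion = 13;
  # spread everything out, then plant the geometry of interest
  coords <- cbind(seq(0, 6, length.out = 13),
                  rep(c(1, 3, 8), c(6, 6, 1)), 0)
  od1 <- topo$atoms$id[topo$atoms$role == "OD" & topo$atoms$chain == 1][1]
  od2 <- topo$atoms$id[topo$atoms$role == "OD" & topo$atoms$chain == 2][1]
  ion <- topo$ions[1]
  # ion equidistant 0.25 nm from one O on each chain -> one bridge
  coords[od1, ] <- c(5, 5, 5)
  coords[od2, ] <- c(5.5, 5, 5)
  coords[ion, ] <- c(5.25, 5, 5)
  det <- detect_ca_bridges(toy_frame(coords), topo)
  expect_equal(nrow(det), 1)
  expect_equal(det$chain_i, 1)
  expect_equal(det$chain_j, 2)
  # ion 0.5 nm from everything -> nothing
  coords2 <- coords
  coords2[ion, ] <- c(5.25, 5.6, 5)
  expect_equal(nrow(detect_ca_bridges(toy_frame(coords2), topo)), 0)
  # ion bridging two oxygens of the same chain -> no inter-chain bridge
  od1b <- topo$atoms$id[topo$atoms$role == "OD" & topo$atoms$chain == 1][2]
  coords3 <- coords
  coords3[od2, ] <- c(9, 9, 9)
  coords3[od1b, ] <- c(5.5, 5, 5)
  expect_equal(nrow(detect_ca_bridges(toy_frame(coords3), topo)), 0)
  # no ions at all -> empty result, not an error
  topo0 <- chain_topology("DD", n_chains = 2, n_ions = 0)
  expect_equal(nrow(detect_ca_bridges(toy_frame(coords[1:12, ]), topo0)), 0)
  # strict zipper mode needs two oxygens per chain
  coords4 <- coords
  coords4[od1b, ] <- c(5, 5.1, 5)
  expect_equal(nrow(detect_ca_bridges(toy_frame(coords4), topo,
                                      min_oxygens_per_chain = 2)), 0)
  od2b <- topo$atoms$id[topo$atoms$role == "OD" & topo$atoms$chain == 2][2]
  coords4[od2b, ] <- c(5.5, 5.1, 5)
  expect_equal(nrow(detect_ca_bridges(toy_frame(coords4), topo,
                                      min_oxygens_per_chain = 2)), 1)
})

test_that("hydrogen-bond detectors apply their cutoffs and chain exclusion", {
  topo <- chain_topology("M", n_chains = 2, n_ions = 0)
  cm <- topo$atoms$id[topo$atoms$role == "CM" & topo$atoms$chain == 1]
  om <- topo$atoms$id[topo$atoms$role == "OM" & topo$atoms$chain == 2]
  coords <- matrix(c(1, 1, 1,  5, 5, 5,  3, 3, 3,
                     1, 2, 1,  5, 5, 5.35,  3, 4, 3), ncol = 3, byrow = TRUE)
  # arrange: atoms 1..3 chain1 (BB,CM,OM), 4..6 chain2 (BB,CM,OM)
  coords <- matrix(0, 6, 3)
  coords[1, ] <- c(0, 0, 0); coords[2, ] <- c(5, 5, 5); coords[3, ] <- c(9, 1, 1)
  coords[4, ] <- c(0, 3, 0); coords[5, ] <- c(2, 3, 2); coords[6, ] <- c(5, 5, 5.35)
  det <- detect_hb_ch3_o(toy_frame(coords), topo)
  expect_equal(nrow(det), 1)   # chain1 CM to chain2 OM at 0.35
  expect_equal(det$atom_a, cm)
  expect_equal(det$atom_b, om)
  coords[6, 3] <- 5.45
  expect_equal(nrow(detect_hb_ch3_o(toy_frame(coords), topo)), 0)
  # all-M topology has no COOH sites: empty result
  expect_equal(nrow(detect_hb_cooh(toy_frame(coords), topo)), 0)
  # COOH detector: H...O at 0.18 in range, 0.30 out
  topoP <- chain_topology("P", n_chains = 2, n_ions = 0)
  hp <- topoP$atoms$id[topoP$atoms$role == "HP" & topoP$atoms$chain == 1]
  op <- topoP$atoms$id[topoP$atoms$role == "OP" & topoP$atoms$chain == 2]
  cp <- matrix(0, 6, 3)
  cp[1, ] <- c(0, 0, 0); cp[2, ] <- c(1, 1, 8); cp[3, ] <- c(4, 4, 4)
  cp[4, ] <- c(0, 3, 0); cp[5, ] <- c(4, 4, 4.18); cp[6, ] <- c(8, 8, 8)
  d1 <- detect_hb_cooh(toy_frame(cp), topoP)   # hp (atom 3) ... op (atom 5)
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$atom_a, d1$atom_b), c(hp, op))
  cp[5, 3] <- 4.30
  expect_equal(nrow(detect_hb_cooh(toy_frame(cp), topoP)), 0)
})

test_that("detectors agree with a brute-force all-pairs scan on random frames", {
  topo <- chain_topology("DPM", n_chains = 3, n_ions = 3)
  natoms <- nrow(topo$atoms)
  set.seed(502)
  cfg <- xlink_config()
  for (k in 1:25) {
    box <- c(4, 4, 4)
    coords <- matrix(runif(natoms * 3, 0, 4), natoms, 3)
    fr <- toy_frame(coords, box)
    got <- sort(detect_frame(fr, topo, cfg)$key)
    expect_identical(got, brute_detect_keys(fr, topo, cfg))
  }
})

test_that("results are invariant under rigid translation and whole-box shifts", {
  topo <- chain_topology("DPM", n_chains = 3, n_ions = 3)
  natoms <- nrow(topo$atoms)
  set.seed(503)
  box <- c(5, 5, 5)
  coords <- matrix(runif(natoms * 3, 0, 5), natoms, 3)
  base <- sort(detect_frame(toy_frame(coords, box), topo)$key)
  shift <- matrix(rep(c(1.3, -0.7, 2.2), each = natoms), natoms, 3)
  expect_identical(sort(detect_frame(toy_frame(coords + shift, box), topo)$key), base)
  wholebox <- coords + matrix(rep(box * c(2, -1, 3), each = natoms), natoms, 3)
  expect_identical(sort(detect_frame(toy_frame(wholebox, box), topo)$key), base)
})

test_that("contact events merge runs according to the gap tolerance", {
  # hand-enumerated 4-frame toy: on-on-off-on
  det_on <- data.frame(type = "HB_CH3_O", key = "HB_CH3_O:1-2",
                       chain_i = 1L, chain_j = 2L, atom_a = 1L, atom_b = 2L,
                       stringsAsFactors = FALSE)
  det_off <- det_on[0, ]
  dets <- list(det_on, det_on, det_off, det_on)
  ev0 <- link_events(dets, frame_spacing = 0.5, gap_tolerance_frames = 0)
  expect_equal(nrow(ev0), 2)
  expect_equal(sort(ev0$lifetime_ns), c(0.5, 1.0))
  ev1 <- link_events(dets, frame_spacing = 0.5, gap_tolerance_frames = 1)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$lifetime_ns, 2.0)
  # always-on contact: one event covering the trajectory
  evF <- link_events(rep(list(det_on), 6), frame_spacing = 1)
  expect_equal(nrow(evF), 1)
  expect_equal(evF$lifetime_ns, 6)
  expect_equal(nrow(link_events(rep(list(det_off), 4), 1)), 0)
  # with zero tolerance, events per key equal 0->1 transitions in presence
  set.seed(504)
  for (k in 1:10) {
    pres <- runif(12) < 0.5
    dets <- lapply(pres, function(p) if (p) det_on else det_off)
    n_events <- nrow(link_events(dets, 1))
    transitions <- sum(diff(c(0, as.integer(pres))) == 1)
    expect_equal(n_events, transitions)
  }
})

test_that("mean counts average instantaneous contacts over frames", {
  det_on <- data.frame(type = "CA_BRIDGE", key = "k", chain_i = 1L,
                       chain_j = 2L, atom_a = 1L, atom_b = NA_integer_,
                       stringsAsFactors = FALSE)
  det_off <- det_on[0, ]
  dets <- c(rep(list(det_on), 20), rep(list(det_off), 20))
  m <- mean_counts(dets)
  expect_equal(unname(m["CA_BRIDGE"]), 0.5)
  expect_equal(unname(m["HB_COOH"]), 0)
  expect_error(mean_counts(list()), "at least one frame")
})

test_that("largest aggregate sizes follow graph components over chains", {
  none <- list(data.frame(type = character(0), key = character(0),
                          chain_i = integer(0), chain_j = integer(0),
                          atom_a = integer(0), atom_b = integer(0)))
  expect_equal(largest_aggregate(none, 8), 1)
  ring <- data.frame(type = "CA_BRIDGE", key = paste0("k", 1:8),
                     chain_i = 1:8, chain_j = c(2:8, 1),
                     atom_a = 1:8, atom_b = NA_integer_)
  expect_equal(largest_aggregate(list(ring, ring), 8), 8)
  # alternating 5-chain and 3-chain clusters: max is the constant 5
  c5 <- data.frame(type = "CA_BRIDGE", key = paste0("a", 1:4),
                   chain_i = 1:4, chain_j = 2:5, atom_a = 1:4, atom_b = NA_integer_)
  c3 <- data.frame(type = "CA_BRIDGE", key = paste0("b", 1:2),
                   chain_i = c(1, 2), chain_j = c(2, 3),
                   atom_a = 1:2, atom_b = NA_integer_)
  both <- list(c5, rbind(c5, c3)[c(1:4, 5:6), ], c5, c5)
  expect_equal(largest_aggregate(list(c5, c3), 8), 4)      # (5 + 3) / 2
  expect_equal(largest_aggregate(list(c5, c3), 8, mode = "max"), 5)
  # adding a link never decreases the instantaneous largest component
  set.seed(505)
  for (k in 1:10) {
    n <- 6
    edges <- data.frame(chain_i = sample(n, 5, TRUE), chain_j = sample(n, 5, TRUE))
    edges <- edges[edges$chain_i != edges$chain_j, , drop = FALSE]
    if (nrow(edges) < 2) next
    mk <- function(e) cbind(type = "CA_BRIDGE", key = paste0("k", seq_len(nrow(e))),
                            e, atom_a = 1L, atom_b = NA_integer_)
    sub <- edges[-nrow(edges), , drop = FALSE]
    expect_lte(largest_aggregate(list(mk(sub)), n),
               largest_aggregate(list(mk(edges)), n))
  }
  bad <- data.frame(type = "CA_BRIDGE", key = "k", chain_i = 1, chain_j = 99,
                    atom_a = 1, atom_b = NA)
  expect_error(largest_aggregate(list(bad), 8), "invalid chain")
})

test_that("planted schedules are recovered exactly, with and without jitter", {
  topo <- chain_topology("DDPDPPDP")
  sched <- data.frame(
    type = c("CA_BRIDGE", "CA_BRIDGE", "HB_COOH"),
    chain_i = c(1, 3, 5), chain_j = c(2, 4, 6),
    start = c(10, 1, 5), end = c(20, 40, 24)
  )
  for (js in c(0, 0.02)) {
    tr <- gen_trajectory(topo, sched, n_frames = 40, frame_spacing = 1,
                         jitter_sd = js, seed = 506)
    dets <- detect_trajectory(tr$trajectory, topo)
    ev <- link_events(dets, tr$trajectory$frame_spacing)
    ev <- ev[order(ev$key), ]
    truth <- tr$truth$schedule[order(tr$truth$schedule$key), ]
    expect_equal(nrow(ev), 3)
    expect_equal(ev$key, truth$key)
    expect_equal(ev$start_frame, truth$start)
    expect_equal(ev$end_frame, truth$end)
    expect_equal(ev$lifetime_ns, truth$end - truth$start + 1)
    m <- mean_counts(dets)
    expect_equal(unname(m["CA_BRIDGE"]), (11 + 40) / 40)
    expect_equal(unname(m["HB_COOH"]), 20 / 40)
    expect_equal(unname(m["HB_CH3_O"]), 0)
  }
})

test_that("empty schedule with zero jitter yields no links anywhere", {
  topo <- chain_topology("DDPDPPDP", n_chains = 4)
  tr <- gen_trajectory(topo, NULL, n_frames = 5, jitter_sd = 0)
  dets <- detect_trajectory(tr$trajectory, topo)
  expect_true(all(vapply(dets, nrow, integer(1)) == 0))
  expect_equal(largest_aggregate(dets, 4), 1)
})

test_that("trajectory summary reports Table-1-style statistics", {
  # all-M system: only the methyl/carbonyl columns are populated
  topoM <- chain_topology("MMMMMMMM")
  schedM <- data.frame(type = "HB_CH3_O", chain_i = 1, chain_j = 2,
                       start = 1, end = 10)
  trM <- gen_trajectory(topoM, schedM, n_frames = 20, jitter_sd = 0, seed = 507)
  sM <- summarize_crosslinks(trM$trajectory, topoM)
  expect_true(is.na(sM$ca_count) && is.na(sM$hb_cooh_count))
  expect_equal(sM$hb_ch3_o_count, 0.5)
  expect_equal(sM$hb_ch3_o_lifetime_ns, 10)
  expect_equal(sM$hb_ch3_o_sites, 32)   # 64 M residues / 2
  # no-ion system: zero bridges even between D-rich chains
  topoD0 <- chain_topology("DDDDDDDD", n_ions = 0)
  trD0 <- gen_trajectory(topoD0, NULL, n_frames = 5, jitter_sd = 0.02, seed = 508)
  sD0 <- summarize_crosslinks(trD0$trajectory, topoD0)
  expect_equal(sD0$ca_count, 0)
  expect_equal(sD0$n_agg, 1)
  # chain ring linked in every frame -> N_agg = n_chains
  topoD <- chain_topology("DDDDDDDD")
  ring <- data.frame(type = "CA_BRIDGE", chain_i = 1:8, chain_j = c(2:8, 1),
                     start = 1, end = 10)
  trD <- gen_trajectory(topoD, ring, n_frames = 10, jitter_sd = 0.02, seed = 509)
  sD <- summarize_crosslinks(trD$trajectory, topoD)
  expect_equal(sD$n_agg, 8)
  expect_equal(sD$ca_count, 8)
  expect_equal(sD$ca_sites, 32)
  expect_equal(sD$ca_lifetime_ns, 10)
  # single-frame trajectory: lifetimes equal one frame spacing
  tr1 <- gen_trajectory(topoD, data.frame(type = "CA_BRIDGE", chain_i = 1,
                                          chain_j = 2, start = 1, end = 1),
                        n_frames = 1, frame_spacing = 2.5, jitter_sd = 0,
                        seed = 510)
  s1 <- summarize_crosslinks(tr1$trajectory, topoD)
  expect_equal(s1$ca_lifetime_ns, 2.5)
})

test_that("lifetimes never exceed the trajectory duration", {
  topo <- chain_topology("DDPDPPDP")
  sched <- data.frame(type = "CA_BRIDGE", chain_i = 1, chain_j = 2,
                      start = 1, end = 40)
  tr <- gen_trajectory(topo, sched, n_frames = 40, seed = 511)
  ev <- link_events(detect_trajectory(tr$trajectory, topo),
                    tr$trajectory$frame_spacing)
  expect_true(all(ev$lifetime_ns <= 40 * tr$trajectory$frame_spacing))
})

test_that("topology construction validates patterns and balances ions", {
  topo <- chain_topology("DDPDPPDP")
  expect_equal(topo$residues_per_chain, 8)
  expect_equal(length(topo$ions), 8 * 4 / 2)   # half the D residues
  topo40 <- chain_topology("ddpd")
  expect_equal(topo40$residues_per_chain, 40)
  expect_equal(sum(topo40$states == "D"), 30)
  expect_equal(length(topo40$ions), 30 * 8 / 2)
  expect_error(chain_topology("DDXD"), "P, D, M")
  expect_error(chain_topology("DDP", residues_per_chain = 8), "multiple")
})
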