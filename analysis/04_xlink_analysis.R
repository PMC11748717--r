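#!/usr/bin/env Rscript
# Cross-link statistics for functionalised chain systems.
#
# Eight-chain systems with different residue functionalisation (D =
# carboxylate, P = protonated carboxyl, M = methyl-esterified) are
# generated with planted cross-link schedules whose density reflects the
# chemistry: D-rich systems form many long-lived calcium bridges and
# aggregate into one cluster, M-only systems form fewer, short-lived
# methyl/carbonyl hydrogen bonds. The analyzer recovers per-type mean
# counts, site counts, mean lifetimes, and the time-averaged largest
# aggregate N_agg, one row per system.

library(pectinporo)

seed <- 20260401
dir.create("results", showWarnings = FALSE)
n_frames <- 40

# planted schedule builder: n_links random chain pairs of one type, with
# lifetimes drawn from [lo, hi] frames
rand_sched <- function(type, n_links, lo, hi, n_chains = 8) {
  prs <- t(replicate(n_links, sort(sample(n_chains, 2))))
  start <- sample(seq_len(n_frames - hi), n_links, replace = TRUE)
  len <- sample(lo:hi, n_links, replace = TRUE)
  data.frame(type = type, chain_i = prs[, 1], chain_j = prs[, 2],
             start = start, end = pmin(start + len - 1, n_frames))
}

set.seed(seed)
systems <- list(
  DDDDDDDD = rand_sched("CA_BRIDGE", 14, 15, 35),
  MMMMMMMM = rand_sched("HB_CH3_O", 6, 1, 4),
  PPPPPPPP = rand_sched("HB_COOH", 9, 1, 3),
  DDPDPPDP = rbind(rand_sched("CA_BRIDGE", 8, 10, 30),
                   rand_sched("HB_COOH", 4, 1, 3)),
  DDMDMMDM = rbind(rand_sched("CA_BRIDGE", 8, 10, 30),
                   rand_sched("HB_CH3_O", 2, 1, 4))
)

rows <- list()
for (pat in names(systems)) {
  topo <- chain_topology(pat)
  tr <- gen_trajectory(topo, systems[[pat]], n_frames = n_frames,
                       frame_spacing = 1, seed = seed + match(pat, names(systems)))
  rows[[pat]] <- summarize_crosslinks(tr$trajectory, topo)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/xlink_summary.csv", row.names = FALSE)

cat("Cross-link summary (planted synthetic trajectories, 40 frames x 1 ns):\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nD-rich systems show dense, long-lived calcium bridging and large",
    "aggregates;\nM/P-only systems form sparse, short-lived hydrogen bonds.\n")
cat("Wrote results/xlink_summary.csv\n")
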