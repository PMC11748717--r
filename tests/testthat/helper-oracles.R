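# Independent brute-force oracles used across the test files. These stay
# deliberately naive (nested loops, exhaustive enumeration) so they check
# the implementation rather than mirror it.

# minimum-image distance by exhaustive search over the 27 periodic images
# (positions are wrapped into the box first, which makes +/-1 exhaustive)
brute_min_image <- function(p1, p2, box) {
  p1 <- p1 %% box
  p2 <- p2 %% box
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    shift <- c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((p1 - (p2 + shift))^2)))
  }
  best
}

# all-pairs distance scan version of the three detectors; returns the set
# of contact keys for one frame
brute_detect_keys <- function(frame, topology, config = xlink_config()) {
  at <- topology$atoms
  keys <- character(0)
  # calcium bridges
  for (ion in topology$ions) {
    chains_hit <- integer(0)
    for (ch in seq_len(topology$n_chains)) {
      ods <- at$id[at$role == "OD" & at$chain == ch]
      n_close <- 0
      for (o in ods) {
        d <- brute_min_image(frame$coords[ion, ], frame$coords[o, ], frame$box)
        if (d <= config$ca_cutoff_nm) n_close <- n_close + 1
      }
      if (n_close >= config$min_oxygens_per_chain)
        chains_hit <- c(chains_hit, ch)
    }
    if (length(chains_hit) >= 2) {
      prs <- utils::combn(sort(chains_hit), 2)
      for (p in seq_len(ncol(prs)))
        keys <- c(keys, paste0("CA_BRIDGE:ion", ion, ":", prs[1, p], "-", prs[2, p]))
    }
  }
  # hydrogen bonds
  hb <- function(role_a, role_b, cutoff, type) {
    out <- character(0)
    A <- at[at$role == role_a, ]
    B <- at[at$role == role_b, ]
    for (ia in seq_len(nrow(A))) for (ib in seq_len(nrow(B))) {
      if (A$chain[ia] == B$chain[ib]) next
      d <- brute_min_image(frame$coords[A$id[ia], ],
                           frame$coords[B$id[ib], ], frame$box)
      if (d <= cutoff) out <- c(out, paste0(type, ":", A$id[ia], "-", B$id[ib]))
    }
    out
  }
  keys <- c(keys, hb("CM", "OM", config$ch3_o_cutoff_nm, "HB_CH3_O"))
  keys <- c(keys, hb("HP", "OP", config$cooh_cutoff_nm, "HB_COOH"))
  sort(keys)
}

# recursive flood-fill connected components (8- or 4-connectivity)
brute_label <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] < 1 || q[2] < 1 || q[1] > nrow(mask) || q[2] > ncol(mask)) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# brute-force binary erosion/dilation with a square element
brute_morph <- function(mask, op = c("erode", "dilate"), element = 3) {
  op <- match.arg(op)
  half <- (element - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    ri <- max(1, i - half):min(nrow(mask), i + half)
    rj <- max(1, j - half):min(ncol(mask), j + half)
    win <- mask[ri, rj]
    full_window <- length(win) == element^2
    out[i, j] <- if (op == "erode") full_window && all(win) else any(win)
  }
  out
}
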