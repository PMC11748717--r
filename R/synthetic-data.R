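# Seedable synthetic-data generators with planted ground truth for the
# three pipeline stages: fluorescence decay series, pore micrographs, and
# multi-chain trajectories with scheduled cross-link events. Every
# generator is a deterministic function of its arguments plus the seed,
# and returns the planted truth alongside the data so recovery can be
# scored without external inputs.

#' Generate replicate fluorescence decay series
#'
#' Simulates the quenching assay design: relative intensities F/F0 at a
#' handful of time points (default every 3 min over 0-15 min) for many
#' replicate regions of interest, with additive Gaussian noise on the
#' intensity truncated to stay positive.
#'
#' @param K Stern-Volmer constant, m^3 mol^-1.
#' @param T_char Characteristic time, s.
#' @param q_b Bath quencher concentration, mol m^-3.
#' @param times_min Observation times in minutes (default `seq(0, 15, 3)`).
#' @param noise_sd Gaussian noise standard deviation on the intensity.
#' @param n_replicates Number of replicate ROIs (default 40).
#' @param label Sample label.
#' @param seed Optional integer seed.
#' @param floor Positivity floor for truncation (default 1e-6).
#' @return List with `series` (data.frame `time_s`, `time_min`,
#'   `intensity`, `label`, `replicate_id`) and `truth` (the planted
#'   parameters and the noiseless curve).
#' @export
gen_fluorescence <- function(K, T_char, q_b, times_min = seq(0, 15, 3),
                             noise_sd = 0.02, n_replicates = 40,
                             label = "sample", seed = NULL, floor = 1e-6) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  times_s <- times_min * 60
  clean <- forward_decay(times_s, K, T_char, q_b)$intensity
  nt <- length(times_s)
  rows <- lapply(seq_len(n_replicates), function(rep) {
    noisy <- pmax(clean + stats::rnorm(nt, sd = noise_sd), floor)
    data.frame(time_s = times_s, time_min = times_min, intensity = noisy,
               label = label, replicate_id = rep, stringsAsFactors = FALSE)
  })
  list(
    series = do.call(rbind, rows),
    truth = list(K = K, T_char = T_char, q_b = q_b, noise_sd = noise_sd,
                 clean_intensity = clean, times_s = times_s)
  )
}

#' Generate a two-genotype fluorescence experiment with a planted porosity ratio
#'
#' The alternative genotype's characteristic time follows from the planted
#' porosity ratio under the Bruggeman law: `T_alt = T_ref * ratio^(-3/2)`,
#' so a more porous wall loads faster. Both genotypes share `K` and `q_b`.
#' Replicate counts default to the 39/42 ROI design of the assay.
#'
#' @param phi_ratio Planted porosity ratio phi_alt / phi_ref (> 0).
#' @param T_ref Reference characteristic time, s.
#' @param K,q_b Shared Stern-Volmer constant and bath concentration.
#' @param times_min,noise_sd As in [gen_fluorescence()].
#' @param n_replicates Length-2 replicate counts (reference, alternative).
#' @param labels Length-2 genotype labels.
#' @param seed Optional integer seed.
#' @return List with `series` (both genotypes stacked) and `truth`
#'   (including `T_ref`, `T_alt` and the planted ratio).
#' @export
gen_two_genotypes <- function(phi_ratio, T_ref, K = 1e4, q_b = 5e-4,
                              times_min = seq(0, 15, 3), noise_sd = 0.02,
                              n_replicates = c(39, 42),
                              labels = c("Col0", "sfr8"), seed = NULL) {
  if (phi_ratio <= 0) stop("phi_ratio must be > 0")
  if (!is.null(seed)) set.seed(seed)
  T_alt <- T_ref * phi_ratio^(-3 / 2)
  a <- gen_fluorescence(K, T_ref, q_b, times_min, noise_sd,
                        n_replicates[1], labels[1], seed = NULL)
  b <- gen_fluorescence(K, T_alt, q_b, times_min, noise_sd,
                        n_replicates[2], labels[2], seed = NULL)
  list(
    series = rbind(a$series, b$series),
    truth = list(phi_ratio = phi_ratio, T_ref = T_ref, T_alt = T_alt,
                 K = K, q_b = q_b, noise_sd = noise_sd, labels = labels)
  )
}

# rasterise one ellipse; returns arr.ind matrix of covered pixel centres
rasterise_ellipse <- function(cx, cy, a, b, theta, nrow_px, ncol_px) {
  half <- max(a, b) + 1
  rows <- max(1, floor(cy - half)):min(nrow_px, ceiling(cy + half))
  cols <- max(1, floor(cx - half)):min(ncol_px, ceiling(cx + half))
  grid <- expand.grid(row = rows, col = cols)
  dx <- grid$col - cx
  dy <- grid$row - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(grid[inside, c("row", "col"), drop = FALSE])
}

#' Generate a synthetic pore micrograph with ground truth
#'
#' Plants dark elliptical pores (aspect ratio sampled in [1, 3]) on a light
#' background, non-overlapping with a guard gap so connected components
#' are unambiguous, then optionally blurs and adds pixel noise. The truth
#' records the exact rasterised pixel area of every pore, which is what a
#' perfect segmentation recovers on a clean image.
#'
#' @param width_nm,height_nm Scene size in nm (default 750 x 500, the
#'   analysis region used for micrographs).
#' @param nm_per_px Calibration (default 1).
#' @param n_pores Number of pores to plant.
#' @param area_dist Target-area sampler: list
#'   `list(type = "uniform", min, max)` or
#'   `list(type = "lognormal", meanlog, sdlog)` (areas in nm^2).
#' @param pore_intensity,background_intensity Grey levels in [0, 1].
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd Additive pixel noise sd (0 = none).
#' @param gap_px Minimum guard gap between pores, pixels.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling retry cap per pore.
#' @return List with `image` (a [calibrated_image()]), `truth` (list:
#'   `records` data.frame with `pore_id`, `target_area_nm2`,
#'   `pixel_count`, `area_nm2`; `mask` logical matrix; `coverage`).
#' @export
gen_pore_image <- function(width_nm = 750, height_nm = 500, nm_per_px = 1,
                           n_pores = 60,
                           area_dist = list(type = "uniform", min = 20, max = 120),
                           pore_intensity = 0.15, background_intensity = 0.85,
                           blur_sigma = 0, noise_sd = 0, gap_px = 3,
                           seed = NULL, max_tries = 200) {
  if (!is.null(seed)) set.seed(seed)
  ncol_px <- round(width_nm / nm_per_px)
  nrow_px <- round(height_nm / nm_per_px)
  px <- matrix(background_intensity, nrow_px, ncol_px)
  occupied <- matrix(FALSE, nrow_px, ncol_px)
  mask <- matrix(FALSE, nrow_px, ncol_px)
  draw_area <- function() {
    switch(area_dist$type,
      uniform = stats::runif(1, area_dist$min, area_dist$max),
      lognormal = stats::rlnorm(1, area_dist$meanlog, area_dist$sdlog),
      stop("unknown area_dist type: ", area_dist$type)
    )
  }
  recs <- vector("list", n_pores)
  for (p in seq_len(n_pores)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      A_nm2 <- draw_area()
      A_px <- A_nm2 / nm_per_px^2
      ar <- stats::runif(1, 1, 3)
      a <- sqrt(A_px * ar / pi)
      b <- sqrt(A_px / (ar * pi))
      theta <- stats::runif(1, 0, pi)
      half <- max(a, b) + 1 + gap_px
      if (2 * half >= min(nrow_px, ncol_px))
        stop("pore too large for the scene; reduce areas or enlarge the image")
      cx <- stats::runif(1, half, ncol_px - half)
      cy <- stats::runif(1, half, nrow_px - half)
      pix <- rasterise_ellipse(cx, cy, a, b, theta, nrow_px, ncol_px)
      if (nrow(pix) == 0) next
      rwin <- max(1, min(pix[, 1]) - gap_px):min(nrow_px, max(pix[, 1]) + gap_px)
      cwin <- max(1, min(pix[, 2]) - gap_px):min(ncol_px, max(pix[, 2]) + gap_px)
      if (any(occupied[rwin, cwin])) next
      occupied[pix] <- TRUE
      mask[pix] <- TRUE
      px[pix] <- pore_intensity
      recs[[p]] <- data.frame(pore_id = p, target_area_nm2 = A_nm2,
                              pixel_count = nrow(pix),
                              area_nm2 = nrow(pix) * nm_per_px^2)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place pore ", p, " after ", max_tries,
           " tries; request fewer or smaller pores")
  }
  if (blur_sigma > 0) {
    img <- EBImage::gblur(EBImage::Image(t(px)), sigma = blur_sigma)
    px <- t(EBImage::imageData(img))
  }
  if (noise_sd > 0) {
    px <- px + matrix(stats::rnorm(length(px), sd = noise_sd), nrow_px, ncol_px)
    px <- pmin(pmax(px, 0), 1)
  }
  records <- if (n_pores > 0) do.call(rbind, recs) else
    data.frame(pore_id = integer(0), target_area_nm2 = numeric(0),
               pixel_count = integer(0), area_nm2 = numeric(0))
  list(
    image = calibrated_image(px, nm_per_px),
    truth = list(records = records, mask = mask,
                 coverage = sum(mask) / length(mask))
  )
}

# rest-position layout for a topology: chains as straight bead rows, ions
# parked on a distant grid; all coordinates strictly inside the box
rest_coords <- function(topology, box = NULL) {
  res_dx <- 0.5
  chain_dy <- 1.5
  natoms <- nrow(topology$atoms) + 0L
  R <- topology$residues_per_chain
  n_ions <- length(topology$ions)
  need_x <- R * res_dx + 2
  need_y <- topology$n_chains * chain_dy + 3
  if (is.null(box)) {
    ion_cols <- max(1, floor((need_x - 2) / 0.8))
    ion_rows <- ceiling(n_ions / ion_cols)
    box <- c(max(need_x, 10), max(need_y, 10), max(10, 6 + ion_rows * 0.8))
  }
  coords <- matrix(0, nrow(topology$atoms), 3)
  offs <- list(
    BB = c(0, 0, 0),
    OD = NULL,  # handled per residue (two oxygens)
    OP = c(0.06, 0.12, 0), HP = c(-0.06, 0.12, 0),
    CM = c(0.06, 0.12, 0), OM = c(-0.06, 0.12, 0)
  )
  at <- topology$atoms
  od_seen <- list()
  for (i in seq_len(nrow(at))) {
    if (at$role[i] == "CA") next
    base <- c(at$residue[i] * res_dx, at$chain[i] * chain_dy, 1.0)
    if (at$role[i] == "OD") {
      kk <- paste(at$chain[i], at$residue[i])
      nth <- (od_seen[[kk]] <- (if (is.null(od_seen[[kk]])) 1L else od_seen[[kk]] + 1L))
      off <- if (nth == 1) c(0.06, 0.12, 0) else c(-0.06, 0.12, 0)
    } else {
      off <- offs[[at$role[i]]]
    }
    coords[i, ] <- base + off
  }
  ion_cols <- max(1, floor((box[1] - 2) / 0.8))
  for (k in seq_along(topology$ions)) {
    row <- (k - 1) %/% ion_cols
    col <- (k - 1) %% ion_cols
    coords[topology$ions[k], ] <- c(1 + col * 0.8, box[2] - 1, 5 + row * 0.8)
  }
  list(coords = coords, box = box)
}

# pick the next unused atom of a role on a chain; errors when exhausted
take_atom <- function(topology, used, role, chain) {
  cand <- topology$atoms$id[topology$atoms$role == role &
                              topology$atoms$chain == chain]
  cand <- setdiff(cand, used)
  if (length(cand) == 0)
    stop("schedule needs more ", role, " atoms on chain ", chain,
         " than the topology provides")
  cand[1]
}

#' Generate a trajectory with a planted cross-link schedule
#'
#' Chains are laid out as straight bead rows far apart (all inter-chain
#' distances well beyond every detection cutoff); ions are parked on a
#' distant grid. During each scheduled event the participating atoms (and
#' ion, for calcium bridges) are moved to a dedicated meeting site at
#' binding distance; outside its frames they sit at rest. Isotropic
#' Gaussian jitter (default 0.02 nm, well under the cutoffs) is added to
#' every atom every frame. The returned truth carries the schedule with
#' the allocated atoms, which is exactly what the detectors should report.
#'
#' @param topology A [chain_topology()].
#' @param schedule `data.frame` with columns `type` (one of `CA_BRIDGE`,
#'   `HB_CH3_O`, `HB_COOH`), `chain_i`, `chain_j`, `start`, `end` (frame
#'   indices, inclusive) and optionally `slot`: rows sharing a slot reuse
#'   the same atoms and meeting site (for on-off-on contact patterns);
#'   rows sharing a slot must agree on type and chains.
#' @param n_frames Number of frames (default 40).
#' @param frame_spacing Frame spacing in ns (default 1).
#' @param box Optional box lengths (nm); computed from the layout if NULL.
#' @param jitter_sd Per-coordinate jitter sd in nm (default 0.02).
#' @param seed Optional integer seed.
#' @return List with `trajectory` (list: `frames`, `frame_spacing`),
#'   `topology`, and `truth` (schedule with allocated atom ids and keys).
#' @export
gen_trajectory <- function(topology, schedule = NULL, n_frames = 40,
                           frame_spacing = 1, box = NULL, jitter_sd = 0.02,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule))
    schedule <- data.frame(type = character(0), chain_i = integer(0),
                           chain_j = integer(0), start = integer(0),
                           end = integer(0))
  rest <- rest_coords(topology, box)
  box <- rest$box

  sched <- schedule
  if (nrow(sched) > 0) {
    if (!all(sched$type %in% .xlink_types)) stop("unknown link type in schedule")
    if (any(sched$chain_i == sched$chain_j)) stop("links must join distinct chains")
    if (any(sched$start > sched$end) || any(sched$start < 1) ||
        any(sched$end > n_frames))
      stop("schedule frames must satisfy 1 <= start <= end <= n_frames")
    if (!"slot" %in% names(sched)) sched$slot <- seq_len(nrow(sched))
  } else {
    sched$slot <- integer(0)
  }

  # allocate atoms and meeting sites per slot
  used <- integer(0)
  slots <- unique(sched$slot)
  alloc <- list()
  for (si in seq_along(slots)) {
    rows <- sched[sched$slot == slots[si], , drop = FALSE]
    if (nrow(unique(rows[, c("type", "chain_i", "chain_j")])) != 1)
      stop("rows sharing a slot must agree on type and chain pair")
    tp <- rows$type[1]; ci <- rows$chain_i[1]; cj <- rows$chain_j[1]
    site <- c(1 + (si - 1) * 1.2, (ci + cj) / 2 * 1.5, 2.5)
    if (site[1] > box[1] - 1) {
      wrap <- floor((site[1] - 1) / (box[1] - 2))
      site[1] <- 1 + (site[1] - 1) %% (box[1] - 2)
      site[3] <- site[3] + wrap * 1.2
    }
    al <- switch(tp,
      CA_BRIDGE = {
        oi <- take_atom(topology, used, "OD", ci)
        used <- c(used, oi)
        oj <- take_atom(topology, used, "OD", cj)
        used <- c(used, oj)
        ion_free <- setdiff(topology$ions, used)
        if (length(ion_free) == 0) stop("schedule needs more Ca2+ ions than available")
        ion <- ion_free[1]; used <- c(used, ion)
        list(atoms = c(oi, oj, ion),
             pos = rbind(site + c(-0.15, 0, 0), site + c(0.15, 0, 0), site),
             key = paste0("CA_BRIDGE:ion", ion, ":", min(ci, cj), "-", max(ci, cj)))
      },
      HB_CH3_O = {
        cm <- take_atom(topology, used, "CM", ci); used <- c(used, cm)
        om <- take_atom(topology, used, "OM", cj); used <- c(used, om)
        list(atoms = c(cm, om),
             pos = rbind(site + c(-0.125, 0, 0), site + c(0.125, 0, 0)),
             key = paste0("HB_CH3_O:", cm, "-", om))
      },
      HB_COOH = {
        hp <- take_atom(topology, used, "HP", ci); used <- c(used, hp)
        op <- take_atom(topology, used, "OP", cj); used <- c(used, op)
        list(atoms = c(hp, op),
             pos = rbind(site + c(-0.06, 0, 0), site + c(0.06, 0, 0)),
             key = paste0("HB_COOH:", hp, "-", op))
      }
    )
    alloc[[as.character(slots[si])]] <- al
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    coords <- rest$coords
    if (nrow(sched) > 0) {
      active <- sched[sched$start <= f & f <= sched$end, , drop = FALSE]
      for (r in seq_len(nrow(active))) {
        al <- alloc[[as.character(active$slot[r])]]
        coords[al$atoms, ] <- al$pos
      }
    }
    if (jitter_sd > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter_sd),
                                nrow(coords), 3)
    frames[[f]] <- list(coords = coords, box = box,
                        time = (f - 1) * frame_spacing)
  }

  truth_sched <- sched
  if (nrow(sched) > 0) {
    truth_sched$key <- vapply(as.character(sched$slot),
                              function(s) alloc[[s]]$key, character(1))
  } else {
    truth_sched$key <- character(0)
  }
  list(
    trajectory = list(frames = frames, frame_spacing = frame_spacing),
    topology = topology,
    truth = list(schedule = truth_sched, box = box, jitter_sd = jitter_sd)
  )
}
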