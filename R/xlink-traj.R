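# Cross-link detection in multi-chain homogalacturonan (HG) bead
# trajectories under periodic boundary conditions. Three link types are
# resolved, mirroring the chemistry of the chain functionalisation:
#   CA_BRIDGE : -COO- || Ca2+ || -COO-  (carboxylate oxygens of D residues)
#   HB_CH3_O  : methyl carbon ... carbonyl oxygen (M residues)
#   HB_COOH   : carboxyl hydrogen ... carboxyl oxygen (P residues)
# All criteria are distance-based with configurable cutoffs; only
# inter-chain contacts count. Per-trajectory statistics are the mean
# instantaneous count per type, the mean contact lifetime per type, and the
# time-averaged size of the largest cross-linked chain aggregate (N_agg).

# atom roles used throughout:
#   OD = carboxylate oxygen (D), OP = carboxyl oxygen (P),
#   HP = carboxyl hydrogen (P), CM = methyl carbon (M),
#   OM = carbonyl oxygen (M), BB = backbone bead, CA = calcium ion
.xlink_types <- c("CA_BRIDGE", "HB_CH3_O", "HB_COOH")

#' Minimum-image distance in an orthorhombic periodic box
#'
#' @param p1,p2 Numeric length-3 coordinates (nm).
#' @param box Length-3 box edge lengths (nm), all positive.
#' @return Euclidean distance between the nearest periodic images.
#' @export
min_image_distance <- function(p1, p2, box) {
  if (any(box <= 0)) stop("box lengths must be > 0")
  d <- p1 - p2
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# all pairwise minimum-image distances between two coordinate matrices
min_image_cross_dist <- function(A, B, box) {
  if (any(box <= 0)) stop("box lengths must be > 0")
  out <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

#' Build a functionalised multi-chain topology
#'
#' Each chain carries `residues_per_chain` galacturonic-acid units in one
#' of three states: protonated carboxyl (P), deprotonated carboxylate (D)
#' or methyl-esterified (M). Short patterns tile longer chains by
#' repetition (the convention used for 40-unit chains written with 4-letter
#' lowercase codes). Every residue contributes a backbone bead plus its
#' state-specific functional-group beads: two carboxylate oxygens for D,
#' a carboxyl oxygen and hydrogen for P, a methyl carbon and carbonyl
#' oxygen for M. Ca2+ ions are added for charge balance: one per two D
#' residues.
#'
#' @param pattern Residue state string over P/D/M (lowercase accepted;
#'   lowercase 4-letter codes denote 40-unit chains).
#' @param n_chains Number of identical chains (default 8).
#' @param residues_per_chain Chain length; defaults to `nchar(pattern)` for
#'   uppercase patterns and 40 for lowercase ones. Must be a multiple of
#'   the pattern length.
#' @param balance_ions Add `n_D/2` Ca2+ ions (default TRUE).
#' @param n_ions Explicit ion count, overriding `balance_ions`.
#' @return Object of class `chain_topology`: list with `n_chains`,
#'   `residues_per_chain`, `pattern`, `atoms` (data.frame: id, chain,
#'   residue, role), `ions` (atom ids).
#' @export
chain_topology <- function(pattern, n_chains = 8, residues_per_chain = NULL,
                           balance_ions = TRUE, n_ions = NULL) {
  is_lower <- pattern == tolower(pattern) && pattern != toupper(pattern)
  pat <- toupper(pattern)
  if (!grepl("^[PDM]+$", pat)) stop("pattern must use letters P, D, M only")
  if (is.null(residues_per_chain))
    residues_per_chain <- if (is_lower) 40L else nchar(pat)
  if (residues_per_chain %% nchar(pat) != 0)
    stop("residues_per_chain must be a multiple of the pattern length")
  states <- rep(strsplit(pat, "")[[1]], residues_per_chain / nchar(pat))

  rows <- list()
  id <- 0L
  for (ch in seq_len(n_chains)) {
    for (r in seq_len(residues_per_chain)) {
      roles <- switch(states[r],
        D = c("BB", "OD", "OD"),
        P = c("BB", "OP", "HP"),
        M = c("BB", "CM", "OM")
      )
      for (ro in roles) {
        id <- id + 1L
        rows[[id]] <- list(id = id, chain = ch, residue = r, role = ro)
      }
    }
  }
  n_D <- sum(states == "D") * n_chains
  if (is.null(n_ions)) {
    n_ions <- if (balance_ions) n_D %/% 2L else 0L
  }
  ion_ids <- integer(0)
  for (k in seq_len(n_ions)) {
    id <- id + 1L
    rows[[id]] <- list(id = id, chain = 0L, residue = 0L, role = "CA")
    ion_ids <- c(ion_ids, id)
  }
  atoms <- do.call(rbind.data.frame, rows)
  structure(list(
    n_chains = n_chains,
    residues_per_chain = residues_per_chain,
    pattern = pattern,
    states = states,
    atoms = atoms,
    ions = ion_ids
  ), class = "chain_topology")
}

# count residues of a given state across all chains
n_state_residues <- function(topology, state) {
  sum(topology$states == state) * topology$n_chains
}

#' Detect instantaneous calcium bridges in one frame
#'
#' A Ca2+ ion bridges chains i != j when it lies within `cutoff_nm` of at
#' least `min_oxygens_per_chain` carboxylate oxygen(s) on each chain. The
#' default of one oxygen per chain counts any shared coordination as a
#' bridge; `min_oxygens_per_chain = 2` gives the strict zipper criterion in
#' which the ion engages both oxygens of each carboxylate.
#'
#' @param frame List with `coords` (n x 3 matrix, nm) and `box` (length 3).
#' @param topology A [chain_topology()].
#' @param cutoff_nm Ca-O contact cutoff, nm (default 0.30, inside the first
#'   coordination shell of Ca2+).
#' @param min_oxygens_per_chain Minimum coordinated oxygens per chain.
#' @return `data.frame` with columns `type`, `key`, `chain_i`, `chain_j`,
#'   `atom_a`, `atom_b` -- one row per (ion, chain pair).
#' @export
detect_ca_bridges <- function(frame, topology, cutoff_nm = 0.30,
                              min_oxygens_per_chain = 1) {
  od <- topology$atoms[topology$atoms$role == "OD", , drop = FALSE]
  ions <- topology$ions
  empty <- xlink_empty()
  if (nrow(od) == 0 || length(ions) == 0) return(empty)
  D <- min_image_cross_dist(frame$coords[ions, , drop = FALSE],
                            frame$coords[od$id, , drop = FALSE], frame$box)
  rows <- empty
  for (k in seq_along(ions)) {
    hit <- which(D[k, ] <= cutoff_nm)
    if (length(hit) < 2) next
    per_chain <- table(od$chain[hit])
    chains <- as.integer(names(per_chain)[per_chain >= min_oxygens_per_chain])
    if (length(chains) < 2) next
    prs <- utils::combn(sort(chains), 2)
    for (p in seq_len(ncol(prs))) {
      rows <- rbind(rows, data.frame(
        type = "CA_BRIDGE",
        key = paste0("CA_BRIDGE:ion", ions[k], ":", prs[1, p], "-", prs[2, p]),
        chain_i = prs[1, p], chain_j = prs[2, p],
        atom_a = ions[k], atom_b = NA_integer_,
        stringsAsFactors = FALSE
      ))
    }
  }
  rows
}

xlink_empty <- function() {
  data.frame(type = character(0), key = character(0),
             chain_i = integer(0), chain_j = integer(0),
             atom_a = integer(0), atom_b = integer(0),
             stringsAsFactors = FALSE)
}

# shared machinery for the two hydrogen-bond detectors: inter-chain
# atom-pair contacts between roles role_a and role_b within cutoff
detect_pair_contacts <- function(frame, topology, role_a, role_b,
                                 cutoff_nm, type) {
  A <- topology$atoms[topology$atoms$role == role_a, , drop = FALSE]
  B <- topology$atoms[topology$atoms$role == role_b, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) return(xlink_empty())
  D <- min_image_cross_dist(frame$coords[A$id, , drop = FALSE],
                            frame$coords[B$id, , drop = FALSE], frame$box)
  inter <- outer(A$chain, B$chain, "!=")
  hit <- which(D <= cutoff_nm & inter, arr.ind = TRUE)
  if (nrow(hit) == 0) return(xlink_empty())
  ci <- pmin(A$chain[hit[, 1]], B$chain[hit[, 2]])
  cj <- pmax(A$chain[hit[, 1]], B$chain[hit[, 2]])
  data.frame(
    type = type,
    key = paste0(type, ":", A$id[hit[, 1]], "-", B$id[hit[, 2]]),
    chain_i = ci, chain_j = cj,
    atom_a = A$id[hit[, 1]], atom_b = B$id[hit[, 2]],
    stringsAsFactors = FALSE
  )
}

#' Detect methyl-carbonyl hydrogen-bond contacts in one frame
#'
#' Contact when a methyl carbon on one chain lies within `cutoff_nm` of a
#' carbonyl oxygen on a different chain. The criterion is distance-only,
#' matching the coordinate used to characterise this interaction.
#'
#' @inheritParams detect_ca_bridges
#' @param cutoff_nm Contact cutoff, nm (default 0.40).
#' @return Contact `data.frame` (see [detect_ca_bridges()]).
#' @export
detect_hb_ch3_o <- function(frame, topology, cutoff_nm = 0.40) {
  detect_pair_contacts(frame, topology, "CM", "OM", cutoff_nm, "HB_CH3_O")
}

#' Detect carboxyl-carboxyl hydrogen-bond contacts in one frame
#'
#' Contact when a carboxyl hydrogen on one chain lies within `cutoff_nm`
#' of a carboxyl oxygen on a different chain.
#'
#' @inheritParams detect_ca_bridges
#' @param cutoff_nm Contact cutoff, nm (default 0.25).
#' @return Contact `data.frame` (see [detect_ca_bridges()]).
#' @export
detect_hb_cooh <- function(frame, topology, cutoff_nm = 0.25) {
  detect_pair_contacts(frame, topology, "HP", "OP", cutoff_nm, "HB_COOH")
}

#' Run all three detectors on one frame
#'
#' @inheritParams detect_ca_bridges
#' @param config An [xlink_config()].
#' @return Combined contact `data.frame` for the frame.
#' @export
detect_frame <- function(frame, topology, config = xlink_config()) {
  rbind(
    detect_ca_bridges(frame, topology, config$ca_cutoff_nm,
                      config$min_oxygens_per_chain),
    detect_hb_ch3_o(frame, topology, config$ch3_o_cutoff_nm),
    detect_hb_cooh(frame, topology, config$cooh_cutoff_nm)
  )
}

#' Cross-link analysis configuration
#'
#' Geometric cutoffs and bookkeeping options for the trajectory analysis.
#' Cutoffs default to values inside the first coordination/contact shells
#' of the respective interactions: Ca-O 0.30 nm, methyl-C to carbonyl-O
#' 0.40 nm, H to O 0.25 nm.
#'
#' @param ca_cutoff_nm,ch3_o_cutoff_nm,cooh_cutoff_nm Contact cutoffs, nm.
#' @param min_oxygens_per_chain 1 (default) or 2 ("strict zipper").
#' @param gap_tolerance_frames Interruptions of up to this many frames do
#'   not terminate a contact event (default 0: strict).
#' @param n_agg_mode `"mean"` (time-average of the per-frame largest
#'   aggregate, default) or `"max"`.
#' @return A named list of class `xlink_config`.
#' @export
xlink_config <- function(ca_cutoff_nm = 0.30, ch3_o_cutoff_nm = 0.40,
                         cooh_cutoff_nm = 0.25, min_oxygens_per_chain = 1,
                         gap_tolerance_frames = 0,
                         n_agg_mode = c("mean", "max")) {
  structure(list(
    ca_cutoff_nm = ca_cutoff_nm,
    ch3_o_cutoff_nm = ch3_o_cutoff_nm,
    cooh_cutoff_nm = cooh_cutoff_nm,
    min_oxygens_per_chain = min_oxygens_per_chain,
    gap_tolerance_frames = gap_tolerance_frames,
    n_agg_mode = match.arg(n_agg_mode)
  ), class = "xlink_config")
}

#' Per-frame contact detections for a whole trajectory
#'
#' @param trajectory List with `frames` (list of frames) and
#'   `frame_spacing` (ns).
#' @param topology A [chain_topology()].
#' @param config An [xlink_config()].
#' @return List of per-frame contact data.frames.
#' @export
detect_trajectory <- function(trajectory, topology, config = xlink_config()) {
  lapply(trajectory$frames, detect_frame, topology = topology, config = config)
}

#' Contact events with lifetimes from per-frame detections
#'
#' A contact event is a maximal run of frames in which the same contact
#' (identified by its atoms and chain pair) is present, allowing
#' interruptions of at most `gap_tolerance_frames` frames. The lifetime is
#' `(end - start + 1) * frame_spacing`.
#'
#' @param detections Per-frame list from [detect_trajectory()].
#' @param frame_spacing Frame spacing in ns.
#' @param gap_tolerance_frames Allowed interruption length (default 0).
#' @return `data.frame`: `type`, `key`, `chain_i`, `chain_j`,
#'   `start_frame`, `end_frame`, `lifetime_ns`.
#' @export
link_events <- function(detections, frame_spacing = 1,
                        gap_tolerance_frames = 0) {
  if (gap_tolerance_frames < 0) stop("gap tolerance must be >= 0")
  pres <- list()  # key -> frames present
  meta <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    for (r in seq_len(nrow(det))) {
      k <- det$key[r]
      pres[[k]] <- c(pres[[k]], f)
      if (is.null(meta[[k]]))
        meta[[k]] <- det[r, c("type", "chain_i", "chain_j")]
    }
  }
  out <- list()
  for (k in names(pres)) {
    fr <- pres[[k]]
    brk <- which(diff(fr) > gap_tolerance_frames + 1)
    starts <- fr[c(1, brk + 1)]
    ends <- fr[c(brk, length(fr))]
    for (e in seq_along(starts)) {
      out[[length(out) + 1]] <- data.frame(
        type = meta[[k]]$type, key = k,
        chain_i = meta[[k]]$chain_i, chain_j = meta[[k]]$chain_j,
        start_frame = starts[e], end_frame = ends[e],
        lifetime_ns = (ends[e] - starts[e] + 1) * frame_spacing,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(type = character(0), key = character(0),
                      chain_i = integer(0), chain_j = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      lifetime_ns = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Mean instantaneous cross-link counts per type
#'
#' @param detections Per-frame list from [detect_trajectory()].
#' @return Named numeric vector, mean count per frame for each link type.
#' @export
mean_counts <- function(detections) {
  n_frames <- length(detections)
  if (n_frames < 1) stop("need at least one frame")
  per_type <- sapply(.xlink_types, function(tp) {
    mean(vapply(detections, function(d) sum(d$type == tp), numeric(1)))
  })
  per_type
}

#' Time-averaged size of the largest chain aggregate
#'
#' Per frame, chains are graph nodes with an edge for any active
#' cross-link between them (multiple links collapse to one edge); the
#' largest connected component's size is recorded and averaged over frames
#' (or maximised with `mode = "max"`). Chains without links count as
#' singleton aggregates, so the floor is 1.
#'
#' @param detections Per-frame list from [detect_trajectory()].
#' @param n_chains Number of chains.
#' @param mode `"mean"` (default) or `"max"` over frames.
#' @return N_agg, in `[1, n_chains]`.
#' @export
largest_aggregate <- function(detections, n_chains, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  per_frame <- vapply(detections, function(det) {
    if (nrow(det) == 0) return(1)
    edges <- unique(det[, c("chain_i", "chain_j")])
    bad <- edges$chain_i < 1 | edges$chain_j < 1 |
      edges$chain_i > n_chains | edges$chain_j > n_chains
    if (any(bad)) stop("link references an invalid chain index")
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_chains - igraph::vcount(g)))
    max(igraph::components(g)$csize)
  }, numeric(1))
  if (mode == "mean") mean(per_frame) else max(per_frame)
}

#' Summarise cross-linking of one trajectory
#'
#' One row of per-system statistics: mean instantaneous count and eligible
#' site count per link type, mean contact lifetime per type
#' (event-averaged), and the time-averaged largest aggregate size N_agg.
#' Link types with no eligible sites in the topology are reported as NA,
#' matching the convention of leaving such columns blank. The site count
#' is half the number of residues of the relevant state across all chains.
#'
#' @param trajectory Trajectory list (`frames`, `frame_spacing`).
#' @param topology A [chain_topology()].
#' @param config An [xlink_config()].
#' @param label System label for the output row (defaults to the pattern).
#' @return One-row `data.frame` with columns `system`, `ca_count`,
#'   `ca_sites`, `hb_ch3_o_count`, `hb_ch3_o_sites`, `hb_cooh_count`,
#'   `hb_cooh_sites`, `ca_lifetime_ns`, `hb_ch3_o_lifetime_ns`,
#'   `hb_cooh_lifetime_ns`, `n_agg`.
#' @export
summarize_crosslinks <- function(trajectory, topology,
                                 config = xlink_config(), label = NULL) {
  if (is.null(label)) label <- topology$pattern
  detections <- detect_trajectory(trajectory, topology, config)
  counts <- mean_counts(detections)
  events <- link_events(detections, trajectory$frame_spacing,
                        config$gap_tolerance_frames)
  mean_life <- function(tp) {
    lt <- events$lifetime_ns[events$type == tp]
    if (length(lt) == 0) NA_real_ else mean(lt)
  }
  sites <- c(
    CA_BRIDGE = n_state_residues(topology, "D") / 2,
    HB_CH3_O = n_state_residues(topology, "M") / 2,
    HB_COOH = n_state_residues(topology, "P") / 2
  )
  avail <- sites > 0
  val <- function(tp, x) if (avail[tp]) x else NA_real_
  data.frame(
    system = label,
    ca_count = val("CA_BRIDGE", counts["CA_BRIDGE"]),
    ca_sites = val("CA_BRIDGE", sites["CA_BRIDGE"]),
    hb_ch3_o_count = val("HB_CH3_O", counts["HB_CH3_O"]),
    hb_ch3_o_sites = val("HB_CH3_O", sites["HB_CH3_O"]),
    hb_cooh_count = val("HB_COOH", counts["HB_COOH"]),
    hb_cooh_sites = val("HB_COOH", sites["HB_COOH"]),
    ca_lifetime_ns = val("CA_BRIDGE", mean_life("CA_BRIDGE")),
    hb_ch3_o_lifetime_ns = val("HB_CH3_O", mean_life("HB_CH3_O")),
    hb_cooh_lifetime_ns = val("HB_COOH", mean_life("HB_COOH")),
    n_agg = largest_aggregate(detections, topology$n_chains,
                              config$n_agg_mode),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
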