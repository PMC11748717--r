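# Readers and writers for the pipeline's plain-text formats (CSV series,
# XYZ trajectories with JSON topologies, PNG/TIFF micrographs) plus the
# end-to-end orchestration that ties the stages together.

#' Read a fluorescence series table
#'
#' Expects a delimited table with columns `time_min`, `intensity`, `label`
#' and optionally `replicate_id` (absent means one series per label).
#' Times are converted to seconds; intensities must be positive and times
#' strictly increasing within each (label, replicate) series.
#'
#' @param path CSV file path.
#' @return `data.frame` with `time_s`, `time_min`, `intensity`, `label`,
#'   `replicate_id`.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "intensity", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("series file is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
  if (length(bad) > 0)
    stop("non-positive or missing intensity at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  sp <- split(df, list(df$label, df$replicate_id), drop = TRUE)
  for (nm in names(sp)) {
    tt <- sp[[nm]]$time_min
    if (is.unsorted(tt, strictly = TRUE))
      stop("times are not strictly increasing within series ", nm)
  }
  df$time_s <- df$time_min * 60
  df[, c("time_s", "time_min", "intensity", "label", "replicate_id")]
}

#' Write a fluorescence series table
#'
#' @param series Series `data.frame` (needs `time_min` or `time_s`,
#'   `intensity`, `label`, optionally `replicate_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- series
  if (!"time_min" %in% names(df)) df$time_min <- df$time_s / 60
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  utils::write.csv(df[, c("time_min", "intensity", "label", "replicate_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a topology (plus box and frame spacing) to JSON
#'
#' @param topology A [chain_topology()].
#' @param path Output JSON path.
#' @param box Optional box lengths (nm) stored with the topology.
#' @param frame_spacing Optional frame spacing (ns).
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path, box = NULL, frame_spacing = NULL) {
  obj <- list(
    pattern = topology$pattern,
    n_chains = topology$n_chains,
    residues_per_chain = topology$residues_per_chain,
    atoms = topology$atoms,
    ions = topology$ions,
    box = box,
    frame_spacing = frame_spacing
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a topology JSON
#'
#' @param path JSON path written by [write_topology_json()].
#' @return List with `topology` (a `chain_topology`), `box`,
#'   `frame_spacing`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- chain_topology(obj$pattern, n_chains = obj$n_chains,
                         residues_per_chain = obj$residues_per_chain,
                         n_ions = length(obj$ions))
  if (nrow(topo$atoms) != nrow(obj$atoms) ||
      !all(topo$atoms$role == obj$atoms$role) ||
      !all(topo$atoms$chain == obj$atoms$chain))
    stop("topology file is inconsistent with its pattern/chain layout")
  list(topology = topo,
       box = if (is.null(obj$box)) NULL else as.numeric(obj$box),
       frame_spacing = if (is.null(obj$frame_spacing)) NULL
                       else as.numeric(obj$frame_spacing))
}

#' Write a trajectory to XYZ
#'
#' One block per frame: the atom count, a comment line
#' `time=<ns> box=<Lx> <Ly> <Lz>`, then one `ROLE x y z` line per atom
#' (coordinates in nm).
#'
#' @param trajectory Trajectory list (`frames`, `frame_spacing`).
#' @param topology The matching [chain_topology()] (for atom roles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  roles <- topology$atoms$role
  for (fr in trajectory$frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("time=%.10g box=%.10g %.10g %.10g",
                       fr$time, fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", roles,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory with its JSON topology
#'
#' @param xyz_path XYZ file (constant atom count across frames).
#' @param topology_path Topology JSON covering every atom.
#' @return List with `trajectory` (`frames`, `frame_spacing`) and
#'   `topology`.
#' @export
read_trajectory <- function(xyz_path, topology_path) {
  tp <- read_topology_json(topology_path)
  topo <- tp$topology
  lines <- readLines(xyz_path)
  frames <- list()
  i <- 1
  fidx <- 0
  natoms_expected <- nrow(topo$atoms)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    fidx <- fidx + 1
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("frame ", fidx, ": expected an atom count, got: ", lines[i])
    if (n != natoms_expected)
      stop("frame ", fidx, ": atom count ", n, " does not match topology (",
           natoms_expected, ")")
    if (i + 1 + n > length(lines))
      stop("frame ", fidx, ": file truncated (expected ", n, " atom lines)")
    comment <- lines[i + 1]
    time <- NA_real_
    box <- tp$box
    m <- regmatches(comment, regexec("time=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2) time <- as.numeric(m[2])
    b <- regmatches(comment,
      regexec("box=([0-9.eE+-]+) ([0-9.eE+-]+) ([0-9.eE+-]+)", comment))[[1]]
    if (length(b) == 4) box <- as.numeric(b[2:4])
    if (is.null(box)) stop("frame ", fidx, ": no box in comment line or topology")
    toks <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "[[:space:]]+")
    coords <- matrix(NA_real_, n, 3)
    for (a in seq_len(n)) {
      tk <- toks[[a]]
      if (length(tk) < 4) stop("frame ", fidx, ", atom ", a, ": malformed line")
      if (tk[1] != topo$atoms$role[a])
        stop("frame ", fidx, ", atom ", a, ": role ", tk[1],
             " does not match topology role ", topo$atoms$role[a])
      coords[a, ] <- as.numeric(tk[2:4])
    }
    if (any(!is.finite(coords))) stop("frame ", fidx, ": non-finite coordinate")
    frames[[fidx]] <- list(coords = coords, box = box, time = time)
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames found in ", xyz_path)
  spacing <- tp$frame_spacing
  if (is.null(spacing)) {
    tms <- vapply(frames, `[[`, numeric(1), "time")
    spacing <- if (length(tms) > 1 && all(is.finite(tms))) tms[2] - tms[1] else 1
  }
  list(trajectory = list(frames = frames, frame_spacing = spacing),
       topology = topo)
}

#' Read a grayscale micrograph (PNG or TIFF) with calibration
#'
#' Multi-channel images are averaged to one grayscale channel.
#'
#' @param path Image path; format chosen by extension.
#' @param nm_per_px Pixel calibration, nm.
#' @param roi Optional ROI `c(width_nm, height_nm)`.
#' @return A [calibrated_image()].
#' @export
read_pore_image <- function(path, nm_per_px, roi = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  calibrated_image(arr, nm_per_px, roi)
}

#' Write a calibrated image to PNG or TIFF
#'
#' @param image A [calibrated_image()].
#' @param path Output path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_pore_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  ext <- tolower(tools::file_ext(path))
  px <- pmin(pmax(image$pixels, 0), 1)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Run the combined analysis pipeline
#'
#' Executes whichever stages the configuration enables and assembles a
#' combined report. Stage errors are caught and reported per stage without
#' aborting the remaining independent stages.
#'
#' @param config List with any of:
#'   \describe{
#'     \item{fluorescence}{list(`series` data.frame or `path`, `q_b`,
#'       optional `reference` label, optional `mode`)}
#'     \item{pores}{list(`images` = named list of [calibrated_image()]s or
#'       file paths, `nm_per_px` (for paths), optional `roi`,
#'       `min_nm2`, `max_nm2`, `bin_width`, `lo`, `hi`)}
#'     \item{xlink}{list(`trajectory` + `topology`, or `xyz_path` +
#'       `topology_path`, optional `config` = [xlink_config()])}
#'   }
#' @return List with per-stage results (`fluorescence`, `pores`, `xlink`),
#'   `errors` (named list of stage error messages) and `run_record`
#'   (version, timestamp, effective config summary).
#' @export
full_pipeline <- function(config) {
  stages <- intersect(names(config), c("fluorescence", "pores", "xlink"))
  if (length(stages) == 0)
    stop("configuration enables no stages (need fluorescence, pores and/or xlink)")
  report <- list(errors = list())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$errors[[name]] <<- conditionMessage(res)
      NULL
    } else res
  }

  if ("fluorescence" %in% stages) {
    report$fluorescence <- run_stage("fluorescence", function() {
      cf <- config$fluorescence
      series <- if (!is.null(cf$series)) cf$series else read_series(cf$path)
      fit_genotypes(series, cf$q_b, reference = cf$reference,
                    mode = if (is.null(cf$mode)) "mean" else cf$mode)
    })
  }

  if ("pores" %in% stages) {
    report$pores <- run_stage("pores", function() {
      cf <- config$pores
      defaults <- list(min_nm2 = 5, max_nm2 = 300, bin_width = 15,
                       lo = 5, hi = 305)
      for (nm in names(defaults)) if (is.null(cf[[nm]])) cf[[nm]] <- defaults[[nm]]
      out <- lapply(cf$images, function(im) {
        img <- if (inherits(im, "calibrated_image")) im
               else read_pore_image(im, cf$nm_per_px, cf$roi)
        cropped <- apply_roi(img)
        mask <- threshold_pores(img)
        mask <- morph_filter(mask)
        recs <- label_pores(mask, img)
        kept <- filter_pores(recs, cf$min_nm2, cf$max_nm2)
        dist <- size_histogram(kept, cf$bin_width, cf$lo, cf$hi)
        area_nm2 <- length(cropped$pixels) * img$nm_per_px^2
        list(records = kept, distribution = dist,
             porosity = porosity_estimate(kept, area_nm2))
      })
      out
    })
  }

  if ("xlink" %in% stages) {
    report$xlink <- run_stage("xlink", function() {
      cf <- config$xlink
      if (!is.null(cf$xyz_path)) {
        tr <- read_trajectory(cf$xyz_path, cf$topology_path)
        trajectory <- tr$trajectory
        topology <- tr$topology
      } else {
        trajectory <- cf$trajectory
        topology <- cf$topology
      }
      xc <- if (is.null(cf$config)) xlink_config() else cf$config
      summarize_crosslinks(trajectory, topology, xc, label = cf$label)
    })
  }

  report$run_record <- list(
    package_version = as.character(utils::packageVersion("pectinporo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    config_summary = lapply(config, function(cf)
      names(cf))
  )
  report
}
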