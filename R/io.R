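# File formats. Scan sets travel as a human-diffable columnar text format:
# "key: value" header lines (geometry, rotor speed, temperature, buffer,
# wavelength), then one block per scan introduced by "scan <k> time <t>"
# followed by "radius,signal" rows. Radii are cm, signals unitless OD,
# scans are numbered from 1. Fitted models travel as JSON.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a scan set to the columnar text format
#'
#' @param scans A [scan_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scanset <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# sedgrid scanset v1",
           paste("meniscus:", fmt_num(scans$geometry$meniscus)),
           paste("bottom:", fmt_num(scans$geometry$bottom)),
           paste("omega:", fmt_num(scans$omega)),
           paste("temperature:", fmt_num(scans$temperature)),
           paste("wavelength:", fmt_num(scans$wavelength)))
  buf <- scans$buffer
  if (inherits(buf, "buffer_spec")) {
    hdr <- c(hdr,
             paste("d2o_fraction:", fmt_num(buf$d2o_fraction)),
             paste("density_increment:", fmt_num(buf$density_increment)),
             paste("viscosity_multiplier:", fmt_num(buf$viscosity_multiplier)))
  } else if (inherits(buf, "buffer_state")) {
    hdr <- c(hdr,
             paste("rho:", fmt_num(buf$rho)),
             paste("eta:", fmt_num(buf$eta)))
  }
  writeLines(hdr, con)
  for (k in seq_along(scans$times)) {
    writeLines(sprintf("scan %d time %s", k, fmt_num(scans$times[k])), con)
    writeLines(paste(fmt_num(scans$radii),
                     fmt_num(scans$signal[k, ]), sep = ","), con)
  }
  invisible(path)
}

#' Read a scan set from the columnar text format
#'
#' Malformed headers, non-monotone radii and scans with mismatched radius
#' vectors raise parse errors naming the offending line.
#'
#' @param path Input path.
#' @return A [scan_set()].
#' @export
#' @examples
#' # a small synthetic example shipped with the package
#' sc <- read_scanset(system.file("extdata", "synthetic_scanset.txt",
#'                                package = "sedgrid"))
#' sc
read_scanset <- function(path) {
  lines <- readLines(path)
  perr <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg))
  hdr <- list()
  i <- 1
  n <- length(lines)
  while (i <= n && !grepl("^scan ", lines[i])) {
    ln <- lines[i]
    if (!grepl("^#", ln) && nzchar(trimws(ln))) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+):\\s*(\\S+)\\s*$", ln))[[1]]
      if (length(m) != 3) perr(i, sprintf("malformed header line '%s'", ln))
      val <- suppressWarnings(as.numeric(m[3]))
      if (is.na(val) && m[3] != "NA")
        perr(i, sprintf("non-numeric header value '%s'", m[3]))
      hdr[[m[2]]] <- val
    }
    i <- i + 1
  }
  need <- c("meniscus", "bottom", "omega", "temperature")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("%s: missing header key(s): %s", path,
                 paste(miss, collapse = ", ")))
  times <- numeric(0)
  rows <- list()
  radii_ref <- NULL
  while (i <= n) {
    m <- regmatches(lines[i],
                    regexec("^scan\\s+(\\d+)\\s+time\\s+(\\S+)\\s*$",
                            lines[i]))[[1]]
    if (length(m) != 3) perr(i, "expected 'scan <k> time <t>' line")
    times <- c(times, as.numeric(m[3]))
    i <- i + 1
    start <- i
    while (i <= n && !grepl("^scan ", lines[i])) i <- i + 1
    block <- lines[start:(i - 1)]
    parts <- strsplit(block, ",", fixed = TRUE)
    if (any(lengths(parts) != 2))
      perr(start + which(lengths(parts) != 2)[1] - 1,
           "expected 'radius,signal' row")
    r <- as.numeric(vapply(parts, `[`, "", 1))
    v <- as.numeric(vapply(parts, `[`, "", 2))
    if (anyNA(r) || anyNA(v))
      perr(start + which(is.na(r) | is.na(v))[1] - 1,
           "non-numeric radius or signal")
    if (any(diff(r) <= 0))
      perr(start + which(diff(r) <= 0)[1],
           "radii not strictly increasing")
    if (is.null(radii_ref)) radii_ref <- r
    else if (length(r) != length(radii_ref) ||
             any(abs(r - radii_ref) > 1e-12))
      perr(start, "scan radius vector differs from the first scan's")
    rows[[length(rows) + 1]] <- v
  }
  if (!length(rows)) stop(sprintf("%s: no scans found", path))
  buf <- if (!is.null(hdr$rho)) solvent_state(hdr$rho, hdr$eta,
                                              hdr$temperature)
  else if (!is.null(hdr$d2o_fraction))
    buffer_spec(hdr$d2o_fraction,
                if (is.null(hdr$density_increment)) 0.0046
                else hdr$density_increment,
                if (is.null(hdr$viscosity_multiplier)) 1
                else hdr$viscosity_multiplier,
                hdr$temperature)
  else NULL
  scan_set(cell_geometry(hdr$meniscus, hdr$bottom), buf, hdr$omega, times,
           radii_ref, do.call(rbind, rows), temperature = hdr$temperature,
           wavelength = if (is.null(hdr$wavelength)) NA_real_
           else hdr$wavelength)
}

#' Import adapter stub for instrument-native scan files
#'
#' Raw sedimentation-velocity archives (Beckman Optima / UltraScan
#' `.RA`/`.RI`-style exports and openAUC deposits) are not read natively.
#' This stub documents the field mapping an adapter must perform so a
#' converter can be written without consulting the package internals:
#'
#' * one file or record per scan; the scan header carries rotor speed
#'   (rpm; convert via [rpm_to_omega()]), run temperature (convert C to K),
#'   elapsed time in seconds, wavelength in nm;
#' * data rows are (radius cm, signal) pairs on an instrument radius
#'   vector — resample onto one common strictly increasing vector if scans
#'   differ;
#' * meniscus and bottom are not stored per scan: take them from the run
#'   record or fit them later via [fit_boundary_positions()];
#' * the buffer (D2O fraction, salts, temperature) comes from the
#'   experiment description, not the scan files, and is supplied as a
#'   [buffer_spec()].
#'
#' Once mapped, assemble with [scan_set()] and persist with
#' [write_scanset()].
#'
#' @param path Path to an instrument-native file.
#' @return Never returns; raises an error describing the required mapping.
#' @export
read_instrument_scans <- function(path) {
  stop("native instrument formats are not supported; map the fields as ",
       "documented in ?read_instrument_scans and assemble a scan_set()")
}

#' Write / read a fitted model as structured text (JSON)
#'
#' The file carries the solute table with amplitudes, the TI/RI noise
#' vectors, rmsd, fitted boundary positions, the solvent state, and fit
#' provenance, at full precision.
#'
#' @param model A `fit_model`.
#' @param path File path.
#' @param buffer Optional [buffer_spec()]/[solvent_state()] stored with the
#'   model (needed by the density-matching command).
#' @return `write_fit_model`: the path, invisibly. `read_fit_model`: a
#'   `fit_model` with attribute `buffer`.
#' @export
write_fit_model <- function(model, path, buffer = NULL) {
  payload <- list(
    format = "sedgrid fit_model v1",
    rmsd = model$rmsd,
    meniscus = model$meniscus,
    bottom = model$bottom,
    solutes = model$solutes,
    ti_noise = model$ti_noise,
    ri_noise = model$ri_noise,
    provenance = model$provenance[setdiff(names(model$provenance),
                                          "boundary_search")])
  if (!is.null(buffer)) {
    bst <- as_buffer_state(buffer)
    payload$buffer <- list(rho = bst$rho, eta = bst$eta,
                           temperature = bst$temperature)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_model
#' @export
read_fit_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(solutes = as.data.frame(p$solutes),
                          ti_noise = p$ti_noise, ri_noise = p$ri_noise,
                          rmsd = p$rmsd, meniscus = p$meniscus,
                          bottom = p$bottom,
                          provenance = as.list(p$provenance)),
                     class = "fit_model")
  if (!is.null(p$buffer))
    attr(model, "buffer") <- solvent_state(p$buffer$rho, p$buffer$eta,
                                           p$buffer$temperature)
  model
}

#' Read and validate a run configuration (YAML)
#'
#' Required top-level sections: `buffers` (list with `d2o_fraction` each),
#' `grid` (`s_min`, `s_max`, `n_s`, `n_vbar`), `fit` (`seed`), and
#' `output_dir`. A missing key raises a validation error naming it.
#'
#' @param path YAML file path.
#' @return The configuration list, with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need_key <- function(obj, key, where) {
    if (is.null(obj[[key]]))
      stop(errorCondition(
        sprintf("config %s: missing required key '%s' in '%s'",
                path, key, where),
        class = c("sedgrid_validation", "error", "condition")))
  }
  for (k in c("buffers", "grid", "fit", "output_dir"))
    need_key(cfg, k, "top level")
  for (i in seq_along(cfg$buffers))
    need_key(cfg$buffers[[i]], "d2o_fraction", sprintf("buffers[%d]", i))
  for (k in c("s_min", "s_max", "n_s", "n_vbar"))
    need_key(cfg$grid, k, "grid")
  need_key(cfg$fit, "seed", "fit")
  cfg$grid <- modifyList(list(vbar_sed = c(0.94, 0.999),
                              vbar_float = c(1.003, 1.05),
                              alpha = 1.1, s_spacing = "linear"), cfg$grid)
  cfg$fit <- modifyList(list(fit_ti = TRUE, fit_ri = TRUE,
                             n_partitions = 8, mc_iterations = 0,
                             n_radii = 300), cfg$fit)
  cfg$density_matching <- modifyList(list(n_fractions = 100,
                                          tail_exclusion = 0.02),
                                     as.list(cfg$density_matching))
  cfg
}

#' Write the ground truth of a synthetic series as structured text
#'
#' @param series A [make_density_series()] result.
#' @param path JSON output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(series, path) {
  jsonlite::write_json(
    list(format = "sedgrid ground_truth v1",
         seed = series$seed,
         d2o_fractions = series$d2o_fractions,
         noise = series$noise,
         population = series$truth,
         solutes_by_density = series$solutes_by_density),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
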