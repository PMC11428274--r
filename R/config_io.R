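# Configuration, trace TSV input/output, run manifests, and the workflow
# entry points behind the command-line wrapper. Configuration is declarative
# YAML with units embedded in key names; unknown keys fail loudly.

run_config_defaults <- function() {
  list(
    wavelength_nm = 1064,
    numerical_aperture = 1.3,
    filling_factor = 0.98,
    n_glass = 1.518,
    n_water = 1.326,
    transmission = 0.42,
    power_mW = 8.4,
    cylinder_bottom_nm = 473,
    cylinder_top_nm = 589,
    cylinder_height_nm = 1016,
    n_extraordinary = 1.5428,
    n_ordinary = 1.5341,
    contour_per_bp_nm = 0.338,
    spacing_nm = 50,
    n_theta = 120,
    mst_n_face = 20,
    mst_margin_nm = 200,
    zsurf_min_nm = 1000,
    zsurf_max_nm = 3000,
    zsurf_points = 5,
    seed = 1,
    outdir = "."
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration and merges it over the physical defaults
#' (1064 nm, NA 1.3, fill 0.98, n 1.518/1.326, transmission 0.42, the
#' fabricated cylinder dimensions and quartz indices, 0.338 nm/bp). An empty
#' or missing-keys file yields the full defaults; unknown keys raise an
#' error naming the key.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path) %||% list()
    if (!is.list(user)) stopf("configuration must be a YAML mapping")
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0)
      stopf("unknown configuration key(s): %s",
            paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

config_trap_setup <- function(cfg) {
  trap_setup(
    beam = beam_spec(cfg$wavelength_nm, cfg$power_mW,
                     filling_factor = cfg$filling_factor),
    objective = objective_spec(cfg$numerical_aperture, cfg$n_glass,
                               cfg$transmission),
    cylinder = cylinder_spec(cfg$cylinder_bottom_nm, cfg$cylinder_top_nm,
                             cfg$cylinder_height_nm, cfg$n_ordinary,
                             cfg$n_extraordinary),
    n_glass = cfg$n_glass, n_water = cfg$n_water,
    spacing_nm = cfg$spacing_nm, n_theta = cfg$n_theta,
    mst_n_face = cfg$mst_n_face, mst_margin_nm = cfg$mst_margin_nm)
}

#' Write a trace to TSV with metadata header
#'
#' Metadata (the data.frame's scalar attributes) is written as
#' `# key\tvalue` comment lines above the column header, so a trace file
#' round-trips through [read_trace()].
#'
#' @param trace a trace data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- attributes(trace)
  meta <- meta[setdiff(names(meta), c("names", "row.names", "class"))]
  con <- file(path, "w")
  on.exit(close(con))
  cls <- setdiff(class(trace), "data.frame")[1]
  if (!is.na(cls)) writeLines(sprintf("# type\t%s", cls), con)
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.atomic(v) && length(v) == 1)
      writeLines(sprintf("# %s\t%s", k, format(v, digits = 15)), con)
  }
  utils::write.table(trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path TSV path.
#' @return data.frame with restored metadata attributes and class.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  metaln <- grep("^# ", lines)
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), metaln)],
                          sep = "\t", header = TRUE)
  cls <- NULL
  for (ln in lines[metaln]) {
    kv <- strsplit(sub("^# ", "", ln), "\t")[[1]]
    if (length(kv) != 2) next
    if (kv[1] == "type") {
      cls <- kv[2]
    } else {
      num <- suppressWarnings(as.numeric(kv[2]))
      attr(df, kv[1]) <- if (is.na(num)) kv[2] else num
    }
  }
  if (!is.null(cls)) class(df) <- c(cls, "data.frame")
  df
}

# Deterministic manifest describing a run: configuration, seed, package
# version. No timestamps, so identical configs give identical artifacts.
write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "aotrap",
                version = as.character(utils::packageVersion("aotrap"))),
           extra, list(config = unclass(cfg)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a named workflow
#'
#' Deterministic end-to-end workflows writing TSV/JSON artifacts plus a run
#' manifest into `cfg$outdir`:
#' \describe{
#'   \item{focalfield}{axial intensity profiles with and without the
#'     interface and the beam focal-shift fit.}
#'   \item{trapmap}{equilibrium sweep over zsurf: trap heights, the trap
#'     focal-shift ratio, and the axial stiffness trend.}
#'   \item{calibration}{synthetic stretching/fringe/angular/twist traces at
#'     the configured seed and every estimator run on them.}
#' }
#'
#' @param name workflow name.
#' @param cfg a [load_config()] result.
#' @return named list of files written, invisibly.
#' @export
run_workflow <- function(name = c("focalfield", "trapmap", "calibration"),
                         cfg = load_config()) {
  name <- match.arg(name)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  files <- character()
  beam <- beam_spec(cfg$wavelength_nm, cfg$power_mW,
                    filling_factor = cfg$filling_factor)
  obj <- objective_spec(cfg$numerical_aperture, cfg$n_glass,
                        cfg$transmission)
  zsurfs <- seq(cfg$zsurf_min_nm, cfg$zsurf_max_nm,
                length.out = cfg$zsurf_points)

  if (name == "focalfield") {
    prof0 <- focus_axial_profile(beam, obj, NULL)
    prof1 <- focus_axial_profile(beam, obj,
                                 interface_spec(mean(zsurfs), cfg$n_glass,
                                                cfg$n_water))
    utils::write.table(
      data.frame(z_nm = prof0$z_nm, intensity_free = prof0$intensity),
      out("axial_profile_free.tsv"), sep = "\t", row.names = FALSE)
    utils::write.table(
      data.frame(z_nm = prof1$z_nm, intensity = prof1$intensity),
      out("axial_profile_interface.tsv"), sep = "\t", row.names = FALSE)
    fsb <- focus_shift_ratio_beam(beam, obj, depths_nm = zsurfs,
                                  n_glass = cfg$n_glass,
                                  n_water = cfg$n_water,
                                  n_theta = cfg$n_theta)
    jsonlite::write_json(list(fs_beam = fsb$fs, se = fsb$se),
                         out("focal_shift_beam.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, "axial_profile_free.tsv",
               "axial_profile_interface.tsv", "focal_shift_beam.json")
  } else if (name == "trapmap") {
    st <- config_trap_setup(cfg)
    fst <- focal_shift_ratio_trap(st, zsurfs)
    utils::write.table(
      data.frame(zsurf_nm = fst$zsurf_nm, htrap_nm = fst$htrap_nm),
      out("trap_heights.tsv"), sep = "\t", row.names = FALSE)
    jsonlite::write_json(list(fs_trap = fst$fs, se = fst$se),
                         out("focal_shift_trap.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, "trap_heights.tsv", "focal_shift_trap.json")
  } else if (name == "calibration") {
    scfg <- synthetic_config(seed = cfg$seed)
    p1 <- wlc_params(scfg$dna_lengths_bp[1],
                     contour_per_bp = cfg$contour_per_bp_nm)
    p2 <- wlc_params(scfg$dna_lengths_bp[2],
                     contour_per_bp = cfg$contour_per_bp_nm)
    ts <- gen_stretch_trace(scfg, scfg$dna_lengths_bp[1])
    tl <- gen_stretch_trace(scfg, scfg$dna_lengths_bp[2])
    fr <- gen_fringe_trace(scfg)
    tw <- gen_twist_trace(scfg)
    for (tr in list(list(ts, "stretch_short.tsv"),
                    list(tl, "stretch_long.tsv"),
                    list(fr, "fringes.tsv"), list(tw, "twist.tsv"))) {
      write_trace(tr[[1]], out(tr[[2]]))
      files <- c(files, tr[[2]])
    }
    ruler <- dna_ruler_focal_shift(ts, tl, p1, p2)
    fp <- fabry_perot_focal_shift(fr, cfg$n_water, cfg$wavelength_nm)
    twfit <- twist_analysis(tw)
    jsonlite::write_json(
      list(fs_dna_ruler = ruler$fs, fs_dna_ruler_se = ruler$se,
           fs_fabry_perot = fp$fs, fs_fabry_perot_se = fp$se,
           twist = twfit[c("torque_slope_pNnm_per_turn", "buckling_turn",
                           "plateau_torque_pNnm",
                           "extension_slope_nm_per_turn")]),
      out("calibration_estimates.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "calibration_estimates.json")
  }
  write_manifest(cfg, out(paste0("manifest_", name, ".json")),
                 extra = list(workflow = name))
  files <- c(files, paste0("manifest_", name, ".json"))
  invisible(file.path(cfg$outdir, files))
}
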