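# Thin orchestration layer: YAML project configuration, stage dispatch,
# flat-file intermediates with a JSON manifest, and the canonical
# end-to-end synthetic demo (simulate -> ctf -> pick -> classify2d ->
# ab-initio -> auto-refine -> sharpen).

pipeline_stages <- c("simulate", "ctf", "pick", "classify2d", "abinitio",
                     "autorefine", "sharpen")

#' Default pipeline configuration
#'
#' All module defaults named explicitly; override any entry through the
#' YAML file or the `overrides` list.
#'
#' @param output_dir directory for intermediates and the report
#' @param seed RNG seed used by every stochastic stage
#' @return nested configuration list
#' @export
default_pipeline_config <- function(output_dir = "cryopipe_run", seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    microscope = list(voltage = 300, cs = 2.7, amplitude_contrast = 0.07),
    simulate = list(box = 48, pixel_size = 3, n_particles = 200,
                    snr = 0.1, defocus = 15000, defocus_spread = 2000,
                    symmetry = "C1"),
    classify2d = list(K = 4, n_iterations = 8, R_start = 40, R_finish = 12),
    abinitio = list(n_iterations = 8, R_start = 20, R_finish = 12),
    autorefine = list(max_iterations = 8),
    particle = list(mask_radius = 55, mw = 4e5),
    sharpen = list(bfactor = -50, whiten_beyond = 8))
}

validate_config <- function(config) {
  ref <- default_pipeline_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(ref, config)
  out
}

#' Load a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file
#' @return validated configuration list
#' @export
load_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the standard single-particle workflow on synthetic data with
#' known ground truth: particle simulation, CTF determination on a
#' synthetic micrograph, particle picking, 2D classification, ab-initio
#' reconstruction, automatic refinement and map sharpening. Intermediates
#' are persisted under `config$output_dir` (MRC maps, parameter tables,
#' TSV logs) together with a JSON report; stages listed in `skip` are
#' loaded from previous outputs instead of recomputed.
#'
#' @param config configuration list (see [default_pipeline_config()])
#' @param skip character vector of stage names to skip/restart from
#' @param verbose print stage progress
#' @return report list (also written to `report.json`)
#' @export
run_pipeline <- function(config = default_pipeline_config(), skip = NULL,
                         verbose = TRUE) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  report <- list(seed = config$seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  stage_failed <- function(stage, e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  set.seed(config$seed)
  mic <- config$microscope
  sim <- config$simulate
  base_ctf <- ctf_params(defocus1 = sim$defocus, voltage = mic$voltage,
                         cs = mic$cs,
                         amplitude_contrast = mic$amplitude_contrast,
                         pixel_size = sim$pixel_size)

  # --- simulate -------------------------------------------------------------
  if (!"simulate" %in% skip) {
    tryCatch({
      say("stage simulate: %d particles, box %d", sim$n_particles, sim$box)
      phantom <- default_phantom(sim$box, sim$pixel_size, sim$symmetry)
      defoci <- sim$defocus +
        runif(sim$n_particles, -sim$defocus_spread, sim$defocus_spread)
      ctfs <- lapply(defoci, function(d)
        ctf_params(defocus1 = d, voltage = mic$voltage, cs = mic$cs,
                   amplitude_contrast = mic$amplitude_contrast,
                   pixel_size = sim$pixel_size))
      ps <- simulate_particles(phantom, sim$n_particles, snr = sim$snr,
                               ctfs = ctfs,
                               mask_radius = config$particle$mask_radius,
                               shift_sd = sim$pixel_size / 2,
                               seed = config$seed)
      write_mrc(ps$stack, out("particles.mrc"))
      write_mrc(phantom, out("phantom.mrc"))
      write_par(alignment_to_par(par_to_alignment(
        data.frame(psi = ps$truth$psi, theta = ps$truth$theta,
                   phi = ps$truth$phi, sx = ps$truth$sx, sy = ps$truth$sy,
                   mag = 1, index = ps$truth$index)), ctfs = ctfs),
        out("truth.par"))
      report$stages$simulate <- list(n_particles = sim$n_particles,
                                     box = sim$box)
    }, error = function(e) stage_failed("simulate", e))
  }
  phantom <- read_mrc(out("phantom.mrc"))
  stack <- read_mrc(out("particles.mrc"))
  truth_par <- read_par(out("truth.par"))
  ctfs <- lapply(seq_len(nrow(truth_par)), function(i)
    ctf_params(defocus1 = truth_par$defocus1[i],
               defocus2 = truth_par$defocus2[i],
               astig_angle = truth_par$astig_angle[i],
               voltage = mic$voltage, cs = mic$cs,
               amplitude_contrast = mic$amplitude_contrast,
               pixel_size = sim$pixel_size))

  # --- ctf ------------------------------------------------------------------
  if (!"ctf" %in% skip) {
    tryCatch({
      say("stage ctf: synthetic micrograph + CTF determination")
      mg <- simulate_micrograph(phantom, n_particles = 12, box = 512,
                                snr = 0.2, ctf = base_ctf,
                                seed = config$seed)
      fit <- fit_ctf(mg$micrograph, base_ctf,
                     defocus_range = c(sim$defocus - 6000,
                                       sim$defocus + 6000),
                     defocus_step = 250, tile = 256)
      report$stages$ctf <- list(
        defocus1 = fit$params$defocus1, defocus2 = fit$params$defocus2,
        true_defocus = base_ctf$defocus1,
        fit_resolution = fit$diagnostics$fit_resolution,
        aliasing = fit$diagnostics$aliasing_warning)
      utils::write.table(
        data.frame(defocus1 = fit$params$defocus1,
                   defocus2 = fit$params$defocus2,
                   astig_angle = fit$params$astig_angle,
                   phase_shift = fit$params$phase_shift,
                   fit_resolution = fit$diagnostics$fit_resolution),
        out("ctf.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    }, error = function(e) stage_failed("ctf", e))
  }

  # --- pick -----------------------------------------------------------------
  if (!"pick" %in% skip) {
    tryCatch({
      say("stage pick: matched-filter picking on a synthetic micrograph")
      mg <- simulate_micrograph(phantom, n_particles = 20, box = 1024,
                                snr = 0.3, ctf = base_ctf,
                                seed = config$seed + 1)
      pp <- pick_params(template_radius = config$particle$mask_radius * 0.8,
                        max_particle_radius = config$particle$mask_radius,
                        threshold_sd = 4)
      picks <- pick_particles(mg$micrograph, pp, ctf = base_ctf)
      utils::write.table(picks, out("picks.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      report$stages$pick <- list(n_true = nrow(mg$coords),
                                 n_picked = nrow(picks))
    }, error = function(e) stage_failed("pick", e))
  }

  # --- classify2d -----------------------------------------------------------
  if (!"classify2d" %in% skip) {
    tryCatch({
      say("stage classify2d: K=%d", config$classify2d$K)
      c2 <- config$classify2d
      cls <- classify2d(stack,
                        classify2d_config(K = c2$K,
                                          n_iterations = c2$n_iterations,
                                          R_start = c2$R_start,
                                          R_finish = c2$R_finish,
                                          mask_radius =
                                            config$particle$mask_radius,
                                          seed = config$seed),
                        ctfs = ctfs)
      write_mrc(cls$averages, out("class_averages.mrc"))
      utils::write.table(
        data.frame(index = seq_along(cls$assignments),
                   class = cls$assignments),
        out("class_assignments.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      report$stages$classify2d <- list(K = c2$K,
                                       occupancy = as.numeric(table(
                                         factor(cls$assignments,
                                                levels = seq_len(c2$K)))))
    }, error = function(e) stage_failed("classify2d", e))
  }

  # --- abinitio -------------------------------------------------------------
  if (!"abinitio" %in% skip) {
    tryCatch({
      say("stage abinitio: %d iterations", config$abinitio$n_iterations)
      ab <- abinitio_run(stack,
                         abinitio_config(
                           n_iterations = config$abinitio$n_iterations,
                           R_start = config$abinitio$R_start,
                           R_finish = config$abinitio$R_finish,
                           symmetry = sim$symmetry, seed = config$seed),
                         mw = config$particle$mw,
                         mask_radius = config$particle$mask_radius,
                         ctfs = ctfs)
      write_mrc(ab$volume, out("abinitio.mrc"))
      write_par(alignment_to_par(ab$params, ctfs = ctfs),
                out("abinitio.par"))
      utils::write.table(ab$log, out("abinitio_log.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      report$stages$abinitio <- list(iterations = nrow(ab$log))
    }, error = function(e) stage_failed("abinitio", e))
  }

  # --- autorefine -----------------------------------------------------------
  if (!"autorefine" %in% skip) {
    tryCatch({
      say("stage autorefine")
      init <- par_to_alignment(read_par(out("abinitio.par")))
      ar <- autorefine_run(stack, init, read_mrc(out("abinitio.mrc")),
                           mw = config$particle$mw,
                           mask_radius = config$particle$mask_radius,
                           ctfs = ctfs,
                           max_iterations =
                             config$autorefine$max_iterations,
                           seed = config$seed)
      write_mrc(ar$volume, out("refined.mrc"))
      write_par(alignment_to_par(ar$params, ctfs = ctfs),
                out("refined.par"))
      utils::write.table(ar$log, out("autorefine_log.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(shell = ar$fsc$shells, fsc = ar$fsc$fsc),
        out("fsc.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
      report$stages$autorefine <- list(
        iterations = ar$state$iteration,
        resolution = resolution_at_threshold(ar$fsc, 0.143))
    }, error = function(e) stage_failed("autorefine", e))
  }

  # --- sharpen --------------------------------------------------------------
  if (!"sharpen" %in% skip) {
    tryCatch({
      say("stage sharpen")
      vol <- read_mrc(out("refined.mrc"))
      sh <- sharpen_map(vol,
                        sharpen_config(
                          bfactor = config$sharpen$bfactor,
                          whiten_beyond = config$sharpen$whiten_beyond,
                          mask_outer = config$particle$mask_radius * 1.2))
      write_mrc(sh, out("sharpened.mrc"))
      report$stages$sharpen <- list(bfactor = config$sharpen$bfactor)
    }, error = function(e) stage_failed("sharpen", e))
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
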