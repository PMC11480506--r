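RUN_CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "stages", "system", "contacts", "clusters",
          "frap", "massfit", "binding"),
  system = c("species", "copies", "box_edge", "salt_mM", "chi", "eps_ss",
             "n_steps", "save_every", "dt"),
  contacts = c("cutoff", "chain_threshold", "exclusion", "stride", "mode"),
  clusters = c("cutoff", "chain_threshold", "permutations"),
  frap = c("mobile_fraction", "t_half_s", "frame_interval_s", "n_frames",
           "bleach_frame", "bleach_decay_per_frame", "noise_sd", "w_um",
           "no_offset", "traces_csv"),
  massfit = c("components", "n_events", "n_fit_components", "monomer_kda",
              "events_csv"),
  binding = c("kd_uM", "r0", "r_max", "conc_grid", "noise_sd", "curve_csv"))

check_keys <- function(block, name) {
  allowed <- RUN_CONFIG_KEYS[[name]]
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown key(s) in '", name, "' config block: ",
         paste(unknown, collapse = ", "))
  block
}

#' Assemble and validate a pipeline run configuration
#'
#' Every parameter has a documented default; unknown keys are rejected.
#' Configurations are plain lists (or JSON files via [read_run_config()]);
#' `stages` selects which stages run. Defaults define a small demonstration
#' run: a 12-copy DR2 system, its contact and cluster analysis, and one
#' synthetic FRAP / mass / binding dataset each, fitted back.
#'
#' @param seed global RNG seed.
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("simulate", "contacts", "clusters", "frap",
#'   "massfit", "binding")`.
#' @param system,contacts,clusters,frap,massfit,binding per-stage parameter
#'   blocks (named lists); see the pipeline vignette for the keys.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "drcluster-run",
                       stages = c("simulate", "contacts", "clusters", "frap",
                                  "massfit", "binding"),
                       system = list(), contacts = list(), clusters = list(),
                       frap = list(), massfit = list(), binding = list()) {
  known <- c("simulate", "contacts", "clusters", "frap", "massfit", "binding")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
              system = check_keys(system, "system"),
              contacts = check_keys(contacts, "contacts"),
              clusters = check_keys(clusters, "clusters"),
              frap = check_keys(frap, "frap"),
              massfit = check_keys(massfit, "massfit"),
              binding = check_keys(binding, "binding"))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON configuration file.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, "top")
  do.call(run_config, raw)
}

default_or <- function(block, key, default)
  if (!is.null(block[[key]])) block[[key]] else default

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order (generate, analyse,
#' fit), writing all outputs plus a `manifest.json` recording inputs,
#' parameters, seed, package version and md5 checksums of every output.
#' Identical configuration and seed give identical outputs. A stage failure
#' aborts with the failing stage named; outputs written so far are kept next
#' to a `FAILED` marker naming the stage.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[drcluster] ", ...)
  results <- list()
  outputs <- character()
  current_stage <- NA_character_

  record <- function(path) outputs[[length(outputs) + 1L]] <<- path

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    current_stage <<- name
    say("stage: ", name)
    results[[name]] <<- fun()
  }

  out <- function(file) file.path(config$out_dir, file)

  tryCatch({
    run_stage("simulate", function() {
      s <- config$system
      species_names <- default_or(s, "species", "DR2")
      copies <- default_or(s, "copies", rep(12L, length(species_names)))
      params <- sim_params(chi = default_or(s, "chi", 3),
                           eps_ss = default_or(s, "eps_ss", 3),
                           dt = default_or(s, "dt", 0.002))
      cfg <- system_config(lapply(species_names, region_topology),
                           copies = copies,
                           box_edge = default_or(s, "box_edge", 30),
                           salt_mM = default_or(s, "salt_mM", 150),
                           seed = config$seed, params = params)
      start <- build_system(cfg)
      traj <- simulate_system(start, cfg,
                              n_steps = default_or(s, "n_steps", 2000L),
                              save_every = default_or(s, "save_every", 200L))
      write_trajectory_xyz(traj, out("trajectory.xyz"))
      write_topology_sidecar(cfg, out("topology.txt"))
      record(out("trajectory.xyz")); record(out("topology.txt"))
      traj
    })

    run_stage("contacts", function() {
      traj <- results$simulate
      if (is.null(traj)) stop("contacts stage needs the simulate stage")
      cc <- config$contacts
      params <- contact_params(
        cutoff = default_or(cc, "cutoff", 0.5),
        chain_threshold = default_or(cc, "chain_threshold", 1L),
        exclusion = default_or(cc, "exclusion", 3L),
        stride = default_or(cc, "stride", 1L))
      mode <- default_or(cc, "mode", "central")
      m <- switch(mode,
                  central = central_chain_matrix(traj, params),
                  pair = two_chain_matrix(traj, params),
                  intra = intra_chain_matrix(traj, params),
                  stop("unknown contacts mode: ", mode))
      res <- list(bead = m)
      if (!is_empty_contact_matrix(m)) {
        sp <- unique(traj$beads$species)[1]
        top <- traj$provenance$config$species[[sp]]
        mr <- beads_to_residues(m, top)
        reg <- tryCatch(builtin_regions()[[sp]], error = function(e) NULL)
        proj <- project_1d(mr, region = reg)
        write_contact_matrix(mr, out("contact_matrix.tsv"), region = reg)
        write_projection_tsv(proj, out("projection.tsv"))
        record(out("contact_matrix.tsv")); record(out("projection.tsv"))
        res$residue <- mr; res$projection <- proj
      }
      res
    })

    run_stage("clusters", function() {
      traj <- results$simulate
      if (is.null(traj)) stop("clusters stage needs the simulate stage")
      cl <- config$clusters
      params <- contact_params(
        cutoff = default_or(cl, "cutoff", 0.5),
        chain_threshold = default_or(cl, "chain_threshold", 1L))
      kin <- cluster_kinetics(traj, params)
      write_kinetics_csv(kin, out("clusters"))
      record(out("clusters_series.csv")); record(out("clusters_events.csv"))
      kin
    })

    run_stage("frap", function() {
      fp <- config$frap
      traces <- if (!is.null(fp$traces_csv)) read_frap_csv(fp$traces_csv)
      else synth_frap(
        mobile_fraction = default_or(fp, "mobile_fraction", 0.82),
        t_half_s = default_or(fp, "t_half_s", 169),
        frame_interval_s = default_or(fp, "frame_interval_s", 5),
        n_frames = default_or(fp, "n_frames", 122L),
        bleach_frame = default_or(fp, "bleach_frame", 3L),
        bleach_decay_per_frame = default_or(fp, "bleach_decay_per_frame", 0),
        noise_sd = default_or(fp, "noise_sd", 0),
        w_um = default_or(fp, "w_um", 2),
        seed = config$seed)
      curve <- process_frap(traces)
      fit <- fit_one_phase(curve, no_offset = default_or(fp, "no_offset", FALSE),
                           w_um = traces$w_um)
      jsonlite::write_json(unclass(fit), out("frap_fit.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      utils::write.table(curve, out("frap_curve.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      record(out("frap_fit.json")); record(out("frap_curve.tsv"))
      fit
    })

    run_stage("massfit", function() {
      mp <- config$massfit
      sample <- if (!is.null(mp$events_csv)) read_masses_csv(mp$events_csv)
      else synth_masses(default_or(mp, "components", list(c(135, 67, 1))),
                        default_or(mp, "n_events", 5000L), seed = config$seed)
      fit <- fit_mass_distribution(sample,
        n_components = default_or(mp, "n_fit_components", 1L),
        monomer_kda = default_or(mp, "monomer_kda", NULL))
      jsonlite::write_json(list(components = fit$components,
                                loglik = fit$loglik, flags = fit$flags),
                           out("mass_fit.json"), digits = NA)
      record(out("mass_fit.json"))
      fit
    })

    run_stage("binding", function() {
      bp <- config$binding
      curve <- if (!is.null(bp$curve_csv)) read_binding_csv(bp$curve_csv)
      else synth_binding(default_or(bp, "kd_uM", 2),
                         r0 = default_or(bp, "r0", 0.05),
                         r_max = default_or(bp, "r_max", 0.25),
                         conc_grid = default_or(bp, "conc_grid",
                           exp(seq(log(0.05), log(100), length.out = 12))),
                         noise_sd = default_or(bp, "noise_sd", 0),
                         seed = config$seed)
      fit <- fit_binding(curve)
      jsonlite::write_json(unclass(fit), out("binding_fit.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      record(out("binding_fit.json"))
      fit
    })
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", current_stage),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package = "drcluster",
    version = as.character(utils::packageVersion("drcluster")),
    seed = config$seed,
    stages = config$stages,
    config = config[setdiff(names(config), c("seed", "stages", "out_dir"))],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done; manifest written")
  invisible(list(results = results, manifest = manifest))
}

#' Validate pipeline input files
#'
#' Report-only checks of headers and shapes for the file formats the
#' pipeline consumes; never raises on malformed input.
#'
#' @param paths named list/vector of file paths.
#' @param formats character vector of the same length naming each file's
#'   expected format: `"frap_csv"`, `"mass_csv"`, `"binding_csv"`,
#'   `"trajectory_xyz"` (requires the matching `"topology"` entry to be
#'   listed first), `"topology"`.
#' @return data.frame report with `path`, `format`, `ok`, `message`; empty
#'   messages for a valid bundle.
#' @export
validate_inputs <- function(paths, formats) {
  paths <- unlist(paths)
  stopifnot(length(paths) == length(formats))
  topo <- NULL
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[i]; fmt <- formats[i]
    msg <- ""
    ok <- TRUE
    res <- tryCatch({
      if (!file.exists(p)) stop("file does not exist")
      switch(fmt,
        frap_csv = {
          df <- utils::read.csv(p, nrows = 5)
          need <- c("time_s", "frap", "reference", "background")
          miss <- setdiff(need, names(df))
          if (length(miss)) stop("missing column(s): ",
                                 paste(miss, collapse = ", "))
        },
        mass_csv = {
          df <- utils::read.csv(p, nrows = 5)
          if (!any(c("mass_kda", "contrast") %in% names(df)))
            stop("needs a 'mass_kda' or 'contrast' column")
        },
        binding_csv = {
          df <- utils::read.csv(p, nrows = 5)
          miss <- setdiff(c("conc_uM", "anisotropy"), names(df))
          if (length(miss)) stop("missing column(s): ",
                                 paste(miss, collapse = ", "))
        },
        topology = { topo <<- read_topology_sidecar(p) },
        trajectory_xyz = {
          if (is.null(topo)) stop("list the topology sidecar before the trajectory")
          invisible(read_trajectory_xyz(p, paths[formats == "topology"][1]))
        },
        stop("unknown format: ", fmt))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) { ok <- FALSE; msg <- res }
    data.frame(path = unname(p), format = fmt, ok = ok, message = msg)
  })
  do.call(rbind, rows)
}
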