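#' Configuration for a rigidity-comparison experiment
#'
#' One self-contained description of a multi-class, multi-seed simulation
#' campaign: network geometry, NP construction, interaction parameters, run
#' settings and analysis settings. Defaults are the desk-scale protocol: a
#' 49 sigma box (3 mesh cells per axis, 27 chains, effective mesh ~16.33
#' sigma), 10 sigma NPs, kT = 0.23 eps, dt = 0.01 tau, 2e4 tau per run and
#' 3 seeds per class. This preserves the mesh-to-NP size ratio of the
#' full-scale system (98 sigma box, 108 chains, 27 NPs, 2e6 tau), which is
#' the geometry that controls the transport physics; the full-scale numbers
#' are available by overriding the fields.
#'
#' @param box_length,mesh_size,bead_spacing,bond_k,tether_k Network
#'   parameters, see [network_spec()].
#' @param np_diameter,np_spacing NP shell construction, see
#'   [build_np_shell()].
#' @param n_np NPs per run.
#' @param min_clearance Placement clearance (sigma).
#' @param classes Character vector of NP classes per run: any of `"soft"`,
#'   `"semi_elastic"`, `"hard"`, `"rigid_sphere"`, or `"rigid_arK"` for a
#'   rigid equal-volume prolate ellipsoid of aspect ratio K (e.g.
#'   `"rigid_ar2"`).
#' @param eps_polymer_np Polymer-shell adhesion (eps).
#' @param total_time,dt,temperature,langevin_gamma,gamma_r,output_interval
#'   Run settings, see [run_config()].
#' @param thermostat_interval Langevin kick interval in steps, see
#'   [run_config()].
#' @param seeds Integer vector, one run per seed per class.
#' @param contact_cutoff Contact distance (sigma).
#' @param burn_in_fraction Fraction of each run discarded before averaging
#'   contacts and shapes.
#' @param fit_fraction Length-2 fractions of the maximum lag bounding the
#'   diffusivity fit window.
#' @param compute_shapes Compute gyration shape metrics per run (set FALSE
#'   to skip this analysis).
#' @param mixed_classes Simulate all rigidity classes together in the same
#'   box (one run per seed, `n_np` NPs of each class, per-NP interaction
#'   presets, shared network and thermal noise — a paired comparison).
#'   Applies when every class is a deformable preset; rigid-particle classes
#'   always run separately.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(box_length = 49, mesh_size = 16,
                              bead_spacing = 2, bond_k = 100, tether_k = 10,
                              np_diameter = 10, np_spacing = 2.5, n_np = 2,
                              min_clearance = 2,
                              classes = c("soft", "semi_elastic", "hard"),
                              eps_polymer_np = 0.1,
                              total_time = 2e4, dt = 0.01,
                              temperature = 0.23, langevin_gamma = 0.1,
                              gamma_r = 10, thermostat_interval = 4,
                              output_interval = NULL,
                              seeds = c(1, 2, 3),
                              contact_cutoff = 3, burn_in_fraction = 0.25,
                              fit_fraction = c(0.75, 1),
                              compute_shapes = TRUE,
                              mixed_classes = TRUE,
                              out_dir = NULL) {
  cfg <- list(box_length = box_length, mesh_size = mesh_size,
              bead_spacing = bead_spacing, bond_k = bond_k,
              tether_k = tether_k, np_diameter = np_diameter,
              np_spacing = np_spacing, n_np = n_np,
              min_clearance = min_clearance, classes = classes,
              eps_polymer_np = eps_polymer_np, total_time = total_time,
              dt = dt, temperature = temperature,
              langevin_gamma = langevin_gamma, gamma_r = gamma_r,
              thermostat_interval = thermostat_interval,
              output_interval = output_interval, seeds = seeds,
              contact_cutoff = contact_cutoff,
              burn_in_fraction = burn_in_fraction,
              fit_fraction = fit_fraction,
              compute_shapes = compute_shapes,
              mixed_classes = mixed_classes, out_dir = out_dir)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  box %.4g sigma, NP %.4g sigma x %d, classes: %s\n",
              x$box_length, x$np_diameter, x$n_np,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  %.4g tau per run, %d seeds, kT %.3g\n",
              x$total_time, length(x$seeds), x$temperature))
  invisible(x)
}

np_model_for_class <- function(class, cfg) {
  if (class %in% c("soft", "semi_elastic", "hard", "rigid_sphere")) {
    build_np_shell(cfg$np_diameter, cfg$np_spacing, rigidity_class = class)
  } else if (grepl("^rigid_ar[0-9.]+$", class)) {
    ar <- as.numeric(sub("^rigid_ar", "", class))
    build_rigid_ellipsoid(cfg$np_diameter, ar, cfg$np_spacing)
  } else stop("unknown NP class: ", class)
}

force_field_for_class <- function(class, cfg) {
  rig <- if (class %in% rownames(rigidity_presets())) class else NULL
  model <- np_model_for_class(class, cfg)
  # soft-core minimum at the realized nearest-neighbor spacing of the shell
  # lattice; spontaneous curvature matched to the shell radius
  d <- as.matrix(dist(model$bead_positions)); diag(d) <- Inf
  rmin <- mean(apply(d, 1, min))
  force_field(rigidity = rig, np_rmin = rmin, np_rcut = rmin + 1.8,
              np_theta0 = asin(min(1, rmin / cfg$np_diameter)),
              eps_polymer_np = cfg$eps_polymer_np,
              tether_k = cfg$tether_k)
}

run_config_for <- function(cfg, seed) {
  run_config(total_time = cfg$total_time, dt = cfg$dt,
             temperature = cfg$temperature,
             langevin_gamma = cfg$langevin_gamma,
             gamma_r = cfg$gamma_r,
             thermostat_interval = cfg$thermostat_interval %||% 1L,
             seed = seed,
             output_interval = cfg$output_interval %||%
               max(1L, round(cfg$total_time / cfg$dt / 500)))
}

simulate_class_run <- function(class, seed, cfg) {
  spec <- network_spec(cfg$box_length, cfg$mesh_size, cfg$bead_spacing,
                       cfg$bond_k, cfg$tether_k)
  sys <- build_network(spec)
  model <- np_model_for_class(class, cfg)
  sys <- place_nps(sys, model, cfg$n_np, cfg$min_clearance, seed = seed,
                   temperature = cfg$temperature)
  run_simulation(sys, force_field_for_class(class, cfg),
                 run_config_for(cfg, seed))
}

# one box containing n_np NPs of every class; per-NP interaction presets
simulate_mixed_run <- function(seed, cfg) {
  spec <- network_spec(cfg$box_length, cfg$mesh_size, cfg$bead_spacing,
                       cfg$bond_k, cfg$tether_k)
  sys <- build_network(spec)
  for (ki in seq_along(cfg$classes)) {
    model <- np_model_for_class(cfg$classes[ki], cfg)
    sys <- place_nps(sys, model, cfg$n_np, cfg$min_clearance,
                     seed = seed + ki, temperature = cfg$temperature)
  }
  base <- force_field_for_class(cfg$classes[1], cfg)
  ff <- force_field(rigidity = "per_np", np_rmin = base$np_rmin,
                    np_rcut = base$np_rcut, np_theta0 = base$np_theta0,
                    eps_polymer_np = cfg$eps_polymer_np,
                    tether_k = cfg$tether_k)
  run_simulation(sys, ff, run_config_for(cfg, seed))
}

#' Run the full rigidity-comparison experiment
#'
#' For every class and seed: build the network, insert the NPs, simulate,
#' and analyze (ensemble MSD and fitted diffusivity, polymer contact
#' counts, gyration shape metrics). Contacts and shapes are averaged after
#' discarding the burn-in fraction of each run. A machine-readable summary
#' with the per-class diffusivity means and the semi-elastic/hard and
#' semi-elastic/soft ratios is returned (and written to `out_dir` when
#' configured).
#'
#' @param config An [experiment_config()].
#' @return A `gel_experiment` list: `runs` (per-run tibble with `class`,
#'   `seed`, `diffusivity`, `mean_contacts`, `mean_ar`), `class_summary`,
#'   `ratios`, `msd_curves`, `contacts`, `shapes`, `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  zero_steps <- config$total_time < config$dt
  runs <- list(); msd_curves <- list(); contacts <- list(); shapes <- list()
  t_burn <- config$burn_in_fraction * config$total_time
  mixed <- isTRUE(config$mixed_classes %||% FALSE) &&
    all(config$classes %in% rownames(rigidity_presets())) &&
    length(config$classes) > 1

  analyze_class <- function(traj, class, seed, np_idx) {
    msd <- msd_3d(traj, np = np_idx)
    fit <- fit_diffusivity(msd, window = config$fit_fraction * max(msd$lag))
    cc <- contact_counts(traj, cutoff = config$contact_cutoff)
    cc <- cc[cc$np %in% np_idx, ]
    row <- tibble::tibble(
      class = class, seed = seed,
      diffusivity = fit$diffusivity, slope = fit$slope,
      mean_contacts = mean(cc$contacts[cc$time >= t_burn]),
      mean_ar = NA_real_, sd_ar = NA_real_)
    if (isTRUE(config$compute_shapes %||% TRUE)) {
      sh <- shape_metrics(traj)
      sh <- sh[sh$np %in% np_idx, ]
      row$mean_ar <- mean(sh$ar[sh$time >= t_burn], na.rm = TRUE)
      row$sd_ar <- sd(sh$ar[sh$time >= t_burn], na.rm = TRUE)
      shapes[[length(shapes) + 1L]] <<-
        dplyr::mutate(tibble::as_tibble(sh), class = class, seed = seed)
    }
    runs[[length(runs) + 1L]] <<- row
    msd_curves[[length(msd_curves) + 1L]] <<-
      dplyr::mutate(tibble::as_tibble(msd), class = class, seed = seed)
    contacts[[length(contacts) + 1L]] <<-
      dplyr::mutate(tibble::as_tibble(cc), class = class, seed = seed)
  }

  if (zero_steps) {
    for (class in config$classes) for (seed in config$seeds) {
      sys <- build_network(network_spec(config$box_length, config$mesh_size,
                                        config$bead_spacing, config$bond_k,
                                        config$tether_k))
      sys <- place_nps(sys, np_model_for_class(class, config),
                       config$n_np, config$min_clearance, seed = seed,
                       temperature = config$temperature)
    }
  } else if (mixed) {
    for (seed in config$seeds) {
      traj <- simulate_mixed_run(seed, config)
      cls_of_np <- vapply(traj$final_system$np_models,
                          function(m) m$rigidity_class, "")
      for (class in config$classes)
        analyze_class(traj, class, seed, which(cls_of_np == class))
    }
  } else {
    for (class in config$classes) for (seed in config$seeds) {
      traj <- simulate_class_run(class, seed, config)
      analyze_class(traj, class, seed, seq_along(traj$rigid))
    }
  }

  runs <- dplyr::bind_rows(runs)
  msd_curves <- dplyr::bind_rows(msd_curves)
  if (nrow(runs) > 0) {
    # class diffusivity from the seed-averaged (pooled) MSD, mirroring the
    # repeat-and-average-the-MSD procedure; per-run fits stay in `runs`
    pooled <- msd_curves |>
      dplyr::group_by(.data$class, .data$lag) |>
      dplyr::summarise(msd = mean(.data$msd), .groups = "drop")
    pooled_fit <- pooled |>
      dplyr::group_by(.data$class) |>
      dplyr::group_modify(function(d, key) {
        f <- fit_diffusivity(d, window = config$fit_fraction * max(d$lag))
        tibble::tibble(d_pooled = f$diffusivity)
      }) |>
      dplyr::ungroup()
    class_summary <- runs |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        d_mean = mean(.data$diffusivity), d_sd = sd(.data$diffusivity),
        contacts_mean = mean(.data$mean_contacts),
        contacts_sd = sd(.data$mean_contacts),
        ar_mean = mean(.data$mean_ar), n_runs = dplyr::n(),
        .groups = "drop") |>
      dplyr::left_join(pooled_fit, by = "class")
    dd <- setNames(class_summary$d_pooled, class_summary$class)
    cc <- setNames(class_summary$contacts_mean, class_summary$class)
    ratios <- tibble::tibble(ratio = character(0), value = numeric(0))
    have <- function(...) all(c(...) %in% names(dd))
    if (have("semi_elastic", "hard"))
      ratios <- dplyr::add_row(ratios, ratio = "D semi_elastic / hard",
                               value = dd[["semi_elastic"]] / dd[["hard"]])
    if (have("semi_elastic", "soft"))
      ratios <- dplyr::add_row(ratios, ratio = "D semi_elastic / soft",
                               value = dd[["semi_elastic"]] / dd[["soft"]])
    if (all(c("soft", "hard") %in% names(cc)))
      ratios <- dplyr::add_row(ratios, ratio = "contacts soft / hard",
                               value = cc[["soft"]] / cc[["hard"]])
    if (all(c("soft", "semi_elastic") %in% names(cc)))
      ratios <- dplyr::add_row(ratios, ratio = "contacts soft / semi_elastic",
                               value = cc[["soft"]] / cc[["semi_elastic"]])
  } else {
    class_summary <- tibble::tibble()
    ratios <- tibble::tibble(ratio = character(0), value = numeric(0))
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seeds = config$seeds,
    classes = config$classes,
    package_version = as.character(utils::packageVersion("gelperm")),
    r_version = as.character(getRversion()))

  out <- structure(
    list(runs = runs, class_summary = class_summary, ratios = ratios,
         msd_curves = msd_curves,
         contacts = dplyr::bind_rows(contacts),
         shapes = dplyr::bind_rows(shapes),
         manifest = manifest, config = config),
    class = "gel_experiment")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(out$runs, file.path(config$out_dir, "runs.csv"))
    write_results_csv(out$msd_curves, file.path(config$out_dir, "msd.csv"))
    write_results_csv(out$contacts, file.path(config$out_dir, "contacts.csv"))
    write_results_csv(out$shapes, file.path(config$out_dir, "shapes.csv"))
    jsonlite::write_json(
      list(class_summary = out$class_summary, ratios = out$ratios,
           manifest = manifest),
      file.path(config$out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}

#' @export
print.gel_experiment <- function(x, ...) {
  cat("<gel_experiment>\n")
  if (nrow(x$runs) == 0) { cat("  (no simulated runs)\n"); return(invisible(x)) }
  print(x$class_summary)
  print(x$ratios)
  invisible(x)
}
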