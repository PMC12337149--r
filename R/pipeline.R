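#' Default pipeline configuration for the toy fixture
#'
#' Returns the configuration list understood by [run_pipeline()], filled
#' with the package defaults: a toy gas-binding system whose ligand count
#' and box size give a concentration close to 120 mM, plus labelling,
#' assignment and MSM defaults.
#'
#' @return nested named list.
#' @export
default_toy_config <- function() {
  list(
    system = list(box_edge = 5, protein_radius = 1.2, site_radius = 0.5,
                  diffusion_coeff = 4.5, timestep = 0.005,
                  contact_cutoff = 0.4,
                  channels = list(
                    list(axis = c(0, 0, 1),  radius = 0.45),
                    list(axis = c(1, 0, 0),  radius = 0.45),
                    list(axis = c(0, -1, 0), radius = 0.35))),
    simulate = list(n_ligands = 9, n_frames = 10000),
    label = list(bound_cutoff = 5, contact_cutoff = 4, min_dwell = 1,
                 trace_window = 25),
    pathways = list(max_assign_dist = 3, min_expected = 5,
                    mc_replicates = 1e5),
    kinetics = list(n_boot = 1000),
    gating = list(p01 = 0.01, p10 = 0.03,
                  emissions = list(c(4.5, 0.3), c(7.5, 0.5)),
                  n_frames = 50000, n_bins = 40, temperature = 300)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every numeric parameter against its documented range and errors
#' naming the first failing key.
#'
#' @param config configuration list (see [default_toy_config()]).
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  need_pos <- c(system.box_edge = config$system$box_edge,
                system.protein_radius = config$system$protein_radius,
                system.site_radius = config$system$site_radius,
                system.diffusion_coeff = config$system$diffusion_coeff,
                system.timestep = config$system$timestep,
                label.bound_cutoff = config$label$bound_cutoff,
                label.contact_cutoff = config$label$contact_cutoff,
                pathways.max_assign_dist = config$pathways$max_assign_dist,
                gating.temperature = config$gating$temperature)
  for (k in names(need_pos)) {
    v <- need_pos[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v <= 0)
      stopf("invalid config: '%s' must be a positive number", k)
  }
  if (config$simulate$n_ligands < 1)
    stopf("invalid config: 'simulate.n_ligands' must be >= 1")
  if (config$simulate$n_frames < 2)
    stopf("invalid config: 'simulate.n_frames' must be >= 2")
  if (config$label$min_dwell < 1)
    stopf("invalid config: 'label.min_dwell' must be >= 1")
  for (p in c("p01", "p10")) {
    v <- config$gating[[p]]
    if (is.null(v) || v <= 0 || v >= 1)
      stopf("invalid config: 'gating.%s' must lie in (0, 1)", p)
  }
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing keys are filled from [default_toy_config()].
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_toy_config(), user)
  validate_config(config)
  config
}

.toy_system_from_config <- function(config) {
  s <- config$system
  toy_system(box_edge = s$box_edge, protein_radius = s$protein_radius,
             channels = lapply(s$channels, function(ch)
               list(axis = as.numeric(ch$axis), radius = ch$radius)),
             site_radius = s$site_radius,
             diffusion_coeff = s$diffusion_coeff, timestep = s$timestep,
             contact_cutoff = s$contact_cutoff)
}

#' Run the analysis pipeline on the synthetic toy fixture
#'
#' Orchestrates the pipeline stages: `simulate` (Brownian toy
#' trajectories), `label` (state labelling + event extraction),
#' `kinetics` (k_on / k_off with bootstrap errors), `pathways` (tunnel
#' assignment, pathway probabilities, binding/unbinding chi-square
#' symmetry test), `gating` (two-state bottleneck stand-in, density and
#' classification), `msm` (Markov state model + free-energy landscape),
#' or `all`. Each stage writes CSV/JSON artifacts to `out_dir` plus a
#' provenance record (`provenance.json`) with the config, seed and
#' package version; outputs are byte-identical for identical config and
#' seed.
#'
#' @param config configuration list or YAML path (see
#'   [default_toy_config()]).
#' @param stage one of `"all"`, `"simulate"`, `"label"`, `"kinetics"`,
#'   `"pathways"`, `"gating"`, `"msm"`.
#' @param out_dir output directory, created if needed.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param quiet suppress progress messages.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = default_toy_config(), stage = "all",
                         out_dir, seed = 1, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  stage <- match.arg(stage, c("all", "simulate", "label", "kinetics",
                              "pathways", "gating", "msm"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()
  stages <- if (stage == "all")
    c("simulate", "label", "kinetics", "pathways", "gating", "msm")
  else stage

  sys <- .toy_system_from_config(config)
  traj <- NULL; events <- NULL; assignments <- NULL; gate <- NULL

  need_traj <- function() {
    if (is.null(traj)) {
      pdb <- file.path(out_dir, "trajectory.pdb")
      if (!file.exists(pdb))
        stopf("no trajectory in %s; run the 'simulate' stage first", out_dir)
      traj <<- read_toy_trajectory(pdb, sys)
    }
    traj
  }
  need_events <- function() {
    if (is.null(events)) {
      series <- label_frames(need_traj(),
                             contact_cutoff = config$label$contact_cutoff)
      events <<- extract_events(series,
                                min_dwell = config$label$min_dwell,
                                trace_window = config$label$trace_window)
    }
    events
  }

  for (st in stages) {
    t0 <- Sys.time()
    if (st == "simulate") {
      traj <- simulate_ligand_diffusion(sys, config$simulate$n_ligands,
                                        config$simulate$n_frames,
                                        seed = seed)
      write_toy_trajectory(traj, file.path(out_dir, "trajectory.pdb"))
      res$trajectory <- traj
      say("simulate: %d ground-truth events", nrow(traj$events))
    } else if (st == "label") {
      ev <- need_events()
      write_events_csv(ev, file.path(out_dir, "events.csv"))
      res$events <- ev
      say("label: %d events extracted", nrow(ev))
    } else if (st == "kinetics") {
      ev <- need_events()
      fpts <- site_fpts(ev)   # site-level waiting times for k_on
      rts <- ev$passage_time[ev$type == "unbinding"]
      conc <- ligand_concentration(config$simulate$n_ligands,
                                   config$system$box_edge^3)
      kin <- list(concentration_M = conc)
      if (length(fpts) > 0) {
        kon <- estimate_kon(fpts, conc, n_boot = config$kinetics$n_boot,
                            seed = seed + 1L)
        kin$kon <- unclass(kon)
        say("kinetics: k_on = %.3g +/- %.2g 1/(M s) (n=%d)", kon$rate,
            kon$standard_error, kon$n_events)
      }
      if (length(rts) > 0) {
        koff <- estimate_koff(rts, n_boot = config$kinetics$n_boot,
                              seed = seed + 2L)
        kin$koff <- unclass(koff)
        say("kinetics: k_off = %.3g +/- %.2g 1/s (n=%d)", koff$rate,
            koff$standard_error, koff$n_events)
      }
      jsonlite::write_json(kin, file.path(out_dir, "kinetics.json"),
                           auto_unbox = TRUE, digits = NA)
      res$kinetics <- kin
    } else if (st == "pathways") {
      ev <- need_events()
      tunnels <- toy_tunnels(sys)
      asg <- assign_events(ev, tunnels,
                           max_assign_dist = config$pathways$max_assign_dist)
      cats <- c(vapply(tunnels, `[[`, character(1), "id"), "unassigned")
      res$assignments <- asg
      out <- list()
      for (ty in c("binding", "unbinding")) {
        a <- asg[ev$type == ty]
        if (sum(!is.na(a)) == 0) next
        pd <- pathway_distribution(a, n_boot = config$kinetics$n_boot,
                                   seed = seed + 3L, categories = cats)
        pd$type <- ty
        out[[ty]] <- pd
      }
      if (length(out) > 0) {
        dist_df <- do.call(rbind, lapply(out, as.data.frame))
        utils::write.csv(dist_df, file.path(out_dir, "pathways.csv"),
                         row.names = FALSE)
        res$pathways <- out
      }
      if (length(out) == 2) {
        ca <- stats::setNames(out$binding$count, out$binding$pathway)
        cb <- stats::setNames(out$unbinding$count, out$unbinding$pathway)
        sym <- chi_square_compare(ca, cb,
                                  min_expected = config$pathways$min_expected,
                                  mc_replicates = config$pathways$mc_replicates,
                                  seed = seed + 4L)
        jsonlite::write_json(
          list(statistic = sym$statistic, df = sym$degrees_of_freedom,
               p_value = sym$p_value, method = sym$method),
          file.path(out_dir, "symmetry.json"), auto_unbox = TRUE,
          digits = NA)
        res$symmetry <- sym
        say("pathways: symmetry chi-square p = %.3g (%s)", sym$p_value,
            sym$method)
      }
    } else if (st == "gating") {
      g <- config$gating
      gate <- generate_two_state_series(c(g$p01, g$p10), g$emissions,
                                        g$n_frames, seed = seed + 5L)
      dens <- distance_density(gate)
      cls <- classify_states(dens, gate)
      write_density_csv(dens, file.path(out_dir, "bottleneck_density.csv"),
                        summary = cls)
      res$gating <- list(series = gate, density = dens, states = cls)
      say("gating: bimodal = %s, open fraction = %s", cls$bimodal,
          format(cls$open_fraction))
    } else if (st == "msm") {
      if (is.null(gate)) {
        g <- config$gating
        gate <- generate_two_state_series(c(g$p01, g$p10), g$emissions,
                                          g$n_frames, seed = seed + 5L)
      }
      msm <- build_msm(gate, n_bins = config$gating$n_bins,
                       temperature = config$gating$temperature,
                       dt = config$system$timestep)
      utils::write.csv(as.data.frame(msm$fel),
                       file.path(out_dir, "fel.csv"), row.names = FALSE)
      utils::write.csv(msm$model$transition_matrix,
                       file.path(out_dir, "transition_matrix.csv"),
                       row.names = FALSE)
      res$msm <- msm
      say("msm: %d active states, lag %d frames",
          length(msm$model$active_set), msm$model$lag)
    }
    say("stage %s done in %.2f s", st,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  prov <- list(package = "umdkin",
               version = as.character(utils::packageVersion("umdkin")),
               seed = seed, stage = stage, config = config)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
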