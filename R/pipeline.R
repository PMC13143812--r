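# End-to-end orchestration: generate world -> diurnal rescaling -> ABM
# simulation -> exposures (RES / ABM / ABMkWP / GPS) -> agreement analysis,
# with every stage seeded from one root seed and all outputs written as
# deterministic text files plus a manifest.

#' Default pipeline configuration
#'
#' Bundles the per-stage configurations with the cohort size, the number of
#' Monte Carlo realizations (default 50) and the GPS campaign parameters.
#' `n_gps_agents` limits the tracked subsample (GPS generation dominates the
#' runtime); `NULL` tracks everyone.
#'
#' @param ... named overrides of any element.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    world = world_config(),
    demographics = demographics_config(),
    n_agents = 500L,
    n_realizations = 50L,
    n_gps_agents = NULL,
    gps = list(sampling = sampling_config(), noise_sd = 10, dropout_rate = 0),
    homemaker_buffer_km = 5,
    comparison_pairs = list(c("RES", "ABM"), c("RES", "GPS"), c("ABM", "GPS"),
                            c("ABM", "ABMkWP"))
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$n_realizations < 1L)
    stop("n_realizations must be >= 1", call. = FALSE)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Named entries override [pipeline_config()] defaults; nested `world`,
#' `demographics`, `gps$sampling` entries override element-wise.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_into(cfg, y)
  # YAML turns named numeric vectors into lists; restore where needed
  for (m in c("sex", "age", "ses", "employment")) {
    if (is.list(cfg$demographics[[m]]))
      cfg$demographics[[m]] <- unlist(cfg$demographics[[m]])
  }
  if (is.list(cfg$world$speeds)) cfg$world$speeds <- unlist(cfg$world$speeds)
  cfg
}

#' Ground-truth diary for one agent
#'
#' The diary the GPS device observes: commuters with a known workplace use
#' it (deterministic modal mode and shortest route); other commuters draw
#' one workplace from their O-D row under the `truth` substream; homemakers
#' draw their excursion points; residential agents stay home.
#'
#' @param agent one-row agent data frame.
#' @param world a `mobair_world`.
#' @param seed root seed (substream `truth:<id>` is used).
#' @param mode_table,schedule,homemaker_buffer_km as in [simulate_agent()].
#' @return An [activity_diary()].
#' @export
true_diary <- function(agent, world, seed = 1L,
                       mode_table = default_mode_table(),
                       schedule = schedule_config(),
                       homemaker_buffer_km = 5) {
  profile <- assign_profile(agent, homemaker_buffer_km)
  home <- c(agent$x, agent$y)
  with_seed(derive_seed(seed, paste0("truth:", agent$id)), {
    if (profile$kind == "commuter") {
      work <- if (!is.na(agent$known_work_x)) {
        c(agent$known_work_x, agent$known_work_y)
      } else {
        sample_work_location(agent, world$od[[profile$commuter_subcategory]],
                             world$municipalities)
      }
      dist <- sqrt(sum((work - home)^2))
      mode <- modal_mode(dist, mode_table)
      route <- shortest_route(world$network, home, work, mode)
      build_diary(profile, agent$id, home, work, route, schedule)
    } else {
      build_diary(profile, agent$id, home, schedule = schedule)
    }
  })
}

#' Run the full exposure-comparison pipeline
#'
#' Executes generate -> rescale -> simulate -> expose -> compare and writes
#' all artifacts into `out_dir`: the world (rasters, stations, network,
#' municipalities, O-D), the agent roster, merged tracks, per-agent exposure
#' records with missingness reasons, the distribution summary table, the
#' pairwise agreement table, the single-draw experiment and a manifest.
#' Rerunning with the same config and seed reproduces every CSV
#' byte-identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param seed integer root seed.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results (`world`,
#'   `agents`, `hsets`, `records`, `summary`, `agreement`, `single_draw`,
#'   `excluded`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = tempfile("mobair_run_"), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[1/6] generating world")
  world <- generate_world(config$world, seed)
  say("[2/6] computing diurnal ratios and hourly surfaces")
  hsets <- lapply(names(world$surfaces), function(pol) {
    apply_diurnal_ratios(world$surfaces[[pol]],
                         compute_diurnal_ratios(world$stations[[pol]]))
  })
  names(hsets) <- names(world$surfaces)

  say("[3/6] generating %d agents", config$n_agents)
  agents <- generate_population(world, config$demographics,
                                config$n_agents, seed)

  say("[4/6] simulating %d ABM realization(s) per agent",
      config$n_realizations)
  sims <- simulate_population(agents, world, config$n_realizations, seed,
                              homemaker_buffer_km = config$homemaker_buffer_km)

  say("[5/6] generating GPS tracks and computing exposures")
  gps_idx <- seq_len(if (is.null(config$n_gps_agents)) nrow(agents)
                     else min(config$n_gps_agents, nrow(agents)))
  gps_agents <- agents[gps_idx, , drop = FALSE]
  diaries <- stats::setNames(
    lapply(gps_idx, function(i)
      true_diary(agents[i, ], world, seed,
                 homemaker_buffer_km = config$homemaker_buffer_km)),
    gps_agents$id)
  tracks <- generate_tracks(gps_agents, diaries, config$gps$sampling,
                            config$gps$noise_sd, config$gps$dropout_rate,
                            seed)
  merged <- lapply(tracks, function(tr) merge_tracks(tr$app, tr$tracker))

  records <- cohort_exposures(agents, sims, hsets, world, tracks = NULL)
  gps_span <- c(0, config$gps$sampling$duration_days * 86400)
  gps_rows <- list()
  for (pol in names(hsets)) {
    for (id in names(merged)) {
      gps_rows[[length(gps_rows) + 1L]] <-
        track_exposure(merged[[id]], hsets[[pol]], id, span = gps_span)
    }
  }
  records <- rbind(records, do.call(rbind, gps_rows))
  class(records) <- "data.frame"

  say("[6/6] agreement analysis")
  summary_tab <- exposure_summary(records)
  wide <- function(pol, met) {
    v <- records[records$pollutant == pol & records$metric == met, ]
    v$mean[match(agents$id, v$agent_id)]
  }
  agreement <- list()
  for (pol in names(hsets)) {
    for (pair in config$comparison_pairs) {
      a <- wide(pol, pair[1]); b <- wide(pol, pair[2])
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3L) next
      ba <- bland_altman(a, b, labels = pair)
      r2 <- r_squared(a, b)
      agreement[[length(agreement) + 1L]] <- data.frame(
        pollutant = pol, pair = paste(pair, collapse = "-"),
        n = ba$n_pairs, r2 = r2, category = classify_agreement(r2),
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        slope = ba$slope, intercept = ba$intercept,
        r2_diff_vs_mean = ba$r2_diff_vs_mean, stringsAsFactors = FALSE)
    }
  }
  agreement <- do.call(rbind, agreement)

  # mean-of-50 vs single draw (first pollutant, commuter-driven spread)
  pol1 <- names(hsets)[1]
  realmat <- do.call(rbind, lapply(agents$id, function(id) {
    vals <- vapply(sims[[id]]$realizations,
                   function(r) diary_exposure(r$diary, hsets[[pol1]]),
                   numeric(1))
    # deterministic profiles contribute their single realization throughout
    c(vals, rep(vals[length(vals)], config$n_realizations - length(vals)))
  }))
  single_draw <- single_draw_experiment(wide(pol1, "RES"), realmat, seed)

  excluded <- records[is.na(records$mean), c("agent_id", "pollutant",
                                             "metric", "reason")]
  for (pol in names(hsets)) {
    n_excl <- sum(excluded$pollutant == pol & excluded$metric == "ABM")
    say("  %s: %d agent(s) excluded from ABM (out of extent)", pol, n_excl)
  }

  # ---- write artifacts ----
  for (pol in names(world$surfaces)) {
    write_esri_ascii(world$surfaces[[pol]],
                     file.path(out_dir, sprintf("annual_%s.asc", pol)))
  }
  write_network_geojson(world$network, file.path(out_dir, "network.geojson"))
  write_municipalities_geojson(world$municipalities,
                               file.path(out_dir, "municipalities.geojson"))
  write_od_csv(world$od, file.path(out_dir, "od_matrices.csv"))
  write_agents_csv(agents, file.path(out_dir, "agents.csv"))
  write_tracks_csv(merged, file.path(out_dir, "tracks.csv"))
  write_csv_det(records, file.path(out_dir, "exposures.csv"))
  write_csv_det(summary_tab, file.path(out_dir, "summary.csv"))
  write_csv_det(agreement, file.path(out_dir, "agreement.csv"))
  jsonlite::write_json(single_draw[c("r2_mean50", "r2_single", "n_agents",
                                     "drawn_idx")],
                       file.path(out_dir, "single_draw.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(unclass(config), seed, file.path(out_dir, "manifest.json"))
  say("run complete: %s", out_dir)

  invisible(list(world = world, agents = agents, hsets = hsets, sims = sims,
                 tracks = merged, records = records, summary = summary_tab,
                 agreement = agreement, single_draw = single_draw,
                 excluded = excluded, out_dir = out_dir))
}
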