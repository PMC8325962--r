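# End-to-end pipeline wiring: named stages over the package's functions,
# with a run manifest (config echo, seed, counts in/out per filter) written
# per invocation so every run is reproducible from its logged config + seed.

pipeline_commands <- c("simulate", "segment-measure", "tubules", "cv",
                       "traces", "track", "dextran", "coloc", "summarize")

#' Run one pipeline stage
#'
#' Dispatches to the named stage, writes its outputs and a machine-readable
#' run manifest (\code{manifest.json}: command, seed, configuration, file
#' list, filter counts) into \code{output_dir}.
#'
#' Stages: \code{simulate} (render a synthetic scene or time-lapse to TIFF
#' + ground truth), \code{segment-measure} (segment a channel, measure all
#' channels), \code{tubules} (detect + classify tubules per cell),
#' \code{cv} (circumference CV per vesicle), \code{traces} (membrane ROI
#' traces, normalize, align, aggregate), \code{track} (detect, link,
#' filter, metrics, fates), \code{dextran} (sum projection, whole-cell and
#' organelle dextran), \code{coloc} (masked Pearson), \code{summarize}
#' (nested summaries of a measurement CSV).
#'
#' @param command One of the stage names above.
#' @param output_dir Directory for outputs (created if needed).
#' @param input Path to the input TIFF or CSV, as the stage requires.
#' @param config An \code{\link{analysis_config}}.
#' @param seed Integer seed for stochastic stages.
#' @param options Named list of stage-specific options (see details of the
#'   underlying functions): e.g. \code{timelapse = TRUE},
#'   \code{scene = scene_params(...)}, \code{channel}, \code{marks},
#'   \code{mask}, \code{channels = c(ch1, ch2)}.
#' @param verbose Print progress lines.
#' @return Invisibly, a list of the stage's main results and output paths.
#' @export
run_pipeline <- function(command, output_dir, input = NULL,
                         config = analysis_config(), seed = 1L,
                         options = list(), verbose = FALSE) {
  if (!command %in% pipeline_commands)
    stop("unknown command '", command, "'; usage: one of ",
         paste(pipeline_commands, collapse = ", "), call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  say("command: ", command, "; seed: ", seed)
  counts <- list()
  res <- switch(command,
    "simulate" = {
      sp <- options$scene %||% scene_params(seed = seed)
      if (isTRUE(options$timelapse) && !inherits(sp, "timelapse_params"))
        sp <- timelapse_params(scene = sp)
      sp$seed <- as.integer(seed)
      r <- if (inherits(sp, "timelapse_params")) render_timelapse(sp)
           else render_scene(sp)
      write_image_stack(r$stack, file.path(output_dir, "scene.tif"))
      write_ground_truth(r$truth, output_dir)
      counts$vesicles <- if (is.null(r$truth$vesicle_records)) 0L
                         else nrow(r$truth$vesicle_records)
      say("rendered ", counts$vesicles, " vesicle(s)")
      r
    },
    "segment-measure" = {
      stk <- read_image_stack(input)
      ch <- options$channel %||% 1L
      mask <- segment_structures(get_plane(stk, options$plane %||% 1L, ch),
                                 config)
      rec <- measure_structures(mask, stk$pixels[options$plane %||% 1L, , , ,
                                                 drop = TRUE],
                                channel_names = stk$channel_names)
      counts$structures <- mask$n_structures
      say("segmented ", mask$n_structures, " structure(s)")
      utils::write.csv(rec, file.path(output_dir, "structures.csv"),
                       row.names = FALSE, na = "NA")
      list(mask = mask, records = rec)
    },
    "tubules" = {
      stk <- read_image_stack(input)
      mem <- get_plane(stk, 1L, options$membrane_channel %||% "membrane")
      sig <- get_plane(stk, 1L, options$signal_channel %||% "marker2")
      vmask <- segment_structures(mem, config)
      tubs <- list()
      for (l in seq_len(vmask$n_structures)) {
        tl <- detect_tubules(vmask$labels == l, config)
        for (tb in tl) { tb$tubule_id <- length(tubs) + 1L
                         tubs[[length(tubs) + 1L]] <- tb }
      }
      counts$tubules <- length(tubs)
      # cytoplasm must be estimated inside the cell: take the broad
      # low-intensity footprint of the signal channel as the cell mask
      cell_mask <- sig > 0.25 * stats::median(sig[sig > 0])
      bg <- cytoplasmic_background(sig, config = config,
                                   cell_mask = cell_mask,
                                   exclude_mask = vmask$labels > 0L)
      cl <- classify_tubules(tubs, sig, bg, config)
      say("detected ", length(tubs), " tubule(s), ",
          sum(cl$calls$positive), " positive")
      utils::write.csv(cl$calls, file.path(output_dir, "tubule_calls.csv"),
                       row.names = FALSE, na = "NA")
      utils::write.csv(cl$cell_fractions,
                       file.path(output_dir, "tubule_fractions.csv"),
                       row.names = FALSE, na = "NA")
      cl
    },
    "cv" = {
      stk <- read_image_stack(input)
      mem <- get_plane(stk, 1L, options$membrane_channel %||% "membrane")
      vmask <- segment_structures(mem, config)
      rows <- list()
      for (l in seq_len(vmask$n_structures)) {
        cv <- tryCatch({
          ctr <- extract_contour(vmask, l, stk$pixel_size_nm)
          ctr <- snap_contour_to_ridge(mem, ctr)
          pr <- contour_profile(mem, ctr, config$profile_width_px)
          tubulation_cv(pr, 1L, config)
        }, error = function(e) NA_real_)
        rows[[l]] <- data.frame(vesicle = l, cv = cv)
      }
      df <- do.call(rbind, rows) %||% data.frame(vesicle = integer(),
                                                 cv = numeric())
      counts$vesicles_measured <- sum(is.finite(df$cv))
      say("CV measured on ", counts$vesicles_measured, " of ",
          vmask$n_structures, " vesicle(s)")
      utils::write.csv(df, file.path(output_dir, "cv.csv"),
                       row.names = FALSE, na = "NA")
      df
    },
    "traces" = {
      stk <- read_image_stack(input)
      marks <- utils::read.csv(options$marks)
      ids <- unique(marks$vesicle_id)
      traces <- lapply(ids, function(id)
        normalize_trace(sample_membrane_roi(stk,
          marks[marks$vesicle_id == id, ], config, vesicle_id = id)))
      agg <- align_traces(traces, options$reference_channel %||% 1L, config,
                          align = !isTRUE(options$no_align))
      counts$traces <- length(traces)
      write_trace_aggregate(agg, file.path(output_dir, "trace_aggregate.csv"))
      agg
    },
    "track" = {
      stk <- read_image_stack(input)
      det <- detect_per_frame(stk, options$marker_channel %||% "membrane",
                              config)
      tracks <- link_tracks(det, stk$pixel_size_nm, config)
      counts$detections <- nrow(det)
      counts$tracks_linked <- length(tracks)
      kept <- filter_new_tracks(tracks, config)
      counts$tracks_after_filters <- length(kept)
      say("tracks: ", length(tracks), " linked, ", length(kept),
          " after the 400 nm and present-at-start filters")
      dur_min <- (n_planes(stk) - 1) * stk$frame_interval_s / 60
      met <- track_metrics(kept, dur_min, options$n_cells %||% 1L)
      bg <- options$marker_background %||%
        median(stk$pixels[1, resolve_channel(stk,
          options$fate_channel %||% "marker2"), , ])
      fates <- vapply(kept, function(tr)
        classify_maturation(tr, stk, bg, config,
                            marker_channel = options$fate_channel %||%
                              "marker2"), "")
      for (i in seq_along(kept)) kept[[i]]$fate <- fates[i]
      rate <- maturation_success_rate(fates)
      write_tracks(kept, file.path(output_dir, "tracks.csv"))
      tab <- measurement_table(
        scope = c(rep("track", length(met$diameters_um)), "experiment",
                  "experiment"),
        structure_id = c(vapply(kept, `[[`, "", "track_id"), NA, NA),
        experiment_id = "E1",
        metric_name = c(rep("diameter_um", length(met$diameters_um)),
                        "frequency_per_cell_per_min", "success_rate"),
        value = c(met$diameters_um, met$frequency_per_cell_per_min,
                  rate$success_rate))
      write_measurements(tab, file.path(output_dir, "track_metrics.csv"))
      list(tracks = kept, metrics = met, fates = fates, rate = rate)
    },
    "dextran" = {
      stk <- read_image_stack(input)
      proj <- sum_projection(stk)
      cm <- if (!is.null(options$cell_mask)) options$cell_mask else
        matrix(TRUE, dim(proj)[2], dim(proj)[3])
      sq <- options$background_square
      dex_ch <- options$dextran_channel %||% "dextran"
      total <- if (is.null(sq)) sum(proj[dex_ch, , ][cm]) else
        whole_cell_dextran(proj[dex_ch, , ], cm, sq)
      focus <- best_focus_plane(stk, options$organelle_channel %||%
                                  "organelle")
      od <- organelle_dextran(stk$pixels[focus, , , , drop = TRUE],
                              options$organelle_channel %||% "organelle",
                              dex_ch, cell_mask = cm, config = config,
                              channel_names = stk$channel_names)
      say("whole-cell dextran ", signif(total, 6), "; organelle dextran ",
          signif(od$organelle_dextran, 6), " over ", od$n_organelles,
          " organelle(s)")
      out <- cbind(od, total_dextran = total, focus_plane = focus)
      utils::write.csv(out, file.path(output_dir, "dextran.csv"),
                       row.names = FALSE, na = "NA")
      out
    },
    "coloc" = {
      stk <- read_image_stack(input)
      chs <- options$channels %||% c(1L, 2L)
      r <- pearson_coloc(get_plane(stk, 1L, chs[1]),
                         get_plane(stk, 1L, chs[2]), options$mask)
      say("Pearson r = ", signif(r, 4))
      utils::write.csv(data.frame(channel_1 = chs[1], channel_2 = chs[2],
                                  pearson_r = r),
                       file.path(output_dir, "coloc.csv"),
                       row.names = FALSE)
      r
    },
    "summarize" = {
      tab <- read_measurements(input)
      metrics <- unique(tab$metric_name)
      rows <- lapply(metrics, function(mn) {
        sub <- tab[tab$metric_name == mn & is.finite(tab$value), ]
        if (!nrow(sub)) return(NULL)
        ns <- nested_summary(sub$value, sub$experiment_id, mn)
        data.frame(metric_name = mn, grand_mean = ns$grand_mean,
                   ci_half_width_95 = ns$ci_half_width_95,
                   n_experiments = ns$n_experiments)
      })
      df <- do.call(rbind, rows)
      counts$metrics <- length(metrics)
      utils::write.csv(df, file.path(output_dir, "summary.csv"),
                       row.names = FALSE, na = "NA")
      df
    })
  manifest <- list(command = command, seed = as.integer(seed),
                   input = input,
                   config = unclass(config)[!vapply(config, is.null,
                                                    TRUE)],
                   counts = counts,
                   outputs = list.files(output_dir),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("pinoquant")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(res)
}
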