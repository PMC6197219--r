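# File I/O and the end-to-end pipeline driver.
#
# Movies travel as multi-page 32-bit float TIFF stacks (one per channel, or
# one interleaved stack) with a YAML sidecar carrying the frame rate and
# channel names. Traces, annotations and events travel as CSV.

#' Write a TwoChannelMovie to TIFF stacks plus a sidecar
#'
#' Writes \code{<prefix>_activity.tif}, \code{<prefix>_structural.tif}
#' (multi-page 16-bit TIFF, the standard acquisition bit depth) and
#' \code{<prefix>_meta.yaml}. Intensities are affinely mapped to the 16-bit
#' range; the scale factors live in the sidecar so [loadMovie()] restores
#' the original units (to 16-bit quantization on the first write; further
#' round trips are exact).
#'
#' @param movie a [TwoChannelMovie-class].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeMovie <- function(movie, prefix) {
  stopifnot(is(movie, "TwoChannelMovie"))
  fa <- paste0(prefix, "_activity.tif")
  fs <- paste0(prefix, "_structural.tif")
  fm <- paste0(prefix, "_meta.yaml")
  quant <- function(arr, path) {
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[3]), function(t)
      round((arr[, , t] - lo) / scale * 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
    list(offset = lo, scale = scale)
  }
  sa <- quant(activityChannel(movie), fa)
  ss <- quant(structuralChannel(movie), fs)
  yaml::write_yaml(list(frame_rate = frameRate(movie),
                        n_frames = nFrames(movie),
                        channels = c("activity", "structural"),
                        layout = "separate",
                        intensity_scale = list(activity = sa,
                                               structural = ss)), fm)
  invisible(c(fa, fs, fm))
}

#' Load a TwoChannelMovie from TIFF
#'
#' Reads either the pair written by [writeMovie()] (via its prefix) or a
#' single interleaved stack with 2N pages plus a sidecar stating
#' \code{layout: interleaved} and \code{channel_order}.
#'
#' @param prefix path prefix (for pairs) or path to an interleaved stack.
#' @return A [TwoChannelMovie-class].
#' @export
loadMovie <- function(prefix) {
  fm <- if (file.exists(paste0(prefix, "_meta.yaml")))
    paste0(prefix, "_meta.yaml") else sub("\\.tif$", "_meta.yaml", prefix)
  if (!file.exists(fm)) stop("missing sidecar metadata file: ", fm)
  meta <- yaml::read_yaml(fm)
  for (fld in c("frame_rate", "n_frames", "layout"))
    if (is.null(meta[[fld]])) stop("sidecar is missing the field '", fld, "'")
  toArray <- function(pages) {
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  if (identical(meta$layout, "interleaved")) {
    pages <- tiff::readTIFF(prefix, all = TRUE)
    if (length(pages) != 2 * meta$n_frames)
      stop("truncated file: expected ", 2 * meta$n_frames, " pages, found ",
           length(pages))
    ord <- meta$channel_order %||% c("activity", "structural")
    aOff <- if (ord[1] == "activity") 1 else 2
    act <- toArray(pages[seq(aOff, length(pages), by = 2)])
    str <- toArray(pages[seq(3 - aOff, length(pages), by = 2)])
  } else {
    fa <- paste0(prefix, "_activity.tif"); fs <- paste0(prefix, "_structural.tif")
    pa <- tiff::readTIFF(fa, all = TRUE); ps <- tiff::readTIFF(fs, all = TRUE)
    if (length(pa) != meta$n_frames || length(ps) != meta$n_frames)
      stop("truncated file: channel page counts (", length(pa), ", ",
           length(ps), ") do not match n_frames = ", meta$n_frames)
    act <- toArray(pa); str <- toArray(ps)
    isc <- meta$intensity_scale
    if (!is.null(isc)) {
      act <- act * isc$activity$scale + isc$activity$offset
      str <- str * isc$structural$scale + isc$structural$offset
    }
  }
  TwoChannelMovie(act, str, meta$frame_rate)
}

#' Write / read optic-flow and velocity traces as CSV
#'
#' @param trace data.frame (\code{t, ap, ml, yaw} or
#'   \code{t, v_forward, v_side, v_rotation}).
#' @param path CSV path.
#' @return \code{readTrace} returns the data.frame.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) utils::read.csv(path)

#' Write / read an EventSeries as CSV
#'
#' Columns: \code{onset_s, source}; vetoed onsets appear with
#' \code{source = "vetoed"}.
#'
#' @param events an [EventSeries-class].
#' @param path CSV path.
#' @param tRange time support used when reading back.
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventSeries"))
  df <- data.frame(onset_s = c(events@onsets, events@vetoed),
                   source = c(events@source,
                              rep("vetoed", length(events@vetoed))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path, tRange) {
  df <- utils::read.csv(path)
  keep <- df$source != "vetoed"
  o <- order(df$onset_s[keep])
  EventSeries(df$onset_s[keep][o], tRange = tRange,
              source = df$source[keep][o],
              vetoed = df$onset_s[!keep])
}

#' Pipeline configuration
#'
#' Bundles every stage's parameter block with stage toggles and a global
#' seed propagated to all stochastic stages. Values can be overridden from
#' a YAML config file; explicit arguments take precedence over the file.
#'
#' @param synthetic a [syntheticConfig()] (the pipeline input generator).
#' @param registration a [registrationParams()].
#' @param events an [eventConfig()].
#' @param stages character subset of
#'   \code{c("synth", "register", "behavior", "maps", "roi", "events")}.
#' @param rng_seed global seed.
#' @param output_dir output directory.
#' @param config_file optional YAML file with overrides (top-level keys
#'   matching the argument names; scalar fields only).
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           registration = registrationParams(),
                           events = eventConfig(),
                           stages = c("synth", "register", "behavior",
                                      "maps", "roi", "events"),
                           rng_seed = 1, output_dir = tempfile("vncrun"),
                           config_file = NULL) {
  if (!is.null(config_file)) {
    ov <- yaml::read_yaml(config_file)
    for (blk in intersect(names(ov), c("synthetic", "registration", "events")))
      for (k in names(ov[[blk]])) {
        obj <- get(blk); obj[[k]] <- ov[[blk]][[k]]; assign(blk, obj)
      }
    if (!is.null(ov$stages)) stages <- ov$stages
    if (!is.null(ov$rng_seed)) rng_seed <- ov$rng_seed
  }
  bad <- setdiff(stages, c("synth", "register", "behavior", "maps", "roi",
                           "events"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  synthetic$rng_seed <- as.integer(rng_seed)
  structure(list(synthetic = synthetic, registration = registration,
                 events = events, stages = stages,
                 rng_seed = as.integer(rng_seed), output_dir = output_dir),
            class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Executes the selected stages in order — synthetic-data generation,
#' registration, behavior quantification, regression maps, ROI extraction
#' and event detection — writing each stage's outputs under
#' \code{output_dir} and a run manifest (parameter snapshot, output
#' checksums, package version, timestamps) as \code{manifest.yaml}.
#' Deterministic given \code{rng_seed}.
#'
#' @param config a [pipelineConfig()].
#' @return the manifest, invisibly (list of class \code{"RunManifest"}).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(version = as.character(utils::packageVersion("vncactivity")),
                   rng_seed = config$rng_seed, stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(completed = TRUE)
    res
  }
  if (!"synth" %in% config$stages)
    stop("pipeline stage 'synth' is required: external loading is configured ",
         "through loadMovie()/readTrace() and the stage toggles")
  exp <- stage("synth", function() {
    e <- generateSyntheticExperiment(config$synthetic)
    writeMovie(e$movie, out("movie"))
    writeTrace(e$flow, out("optic_flow.csv"))
    e
  })
  movie <- exp$movie
  if ("register" %in% config$stages) {
    reg <- stage("register", function()
      registerMovie(movie, config$registration))
    movie <- reg$movie
    writeMovie(movie, out("registered"))
    reports <- lapply(reg$fields, detectArtifacts)
    utils::write.csv(data.frame(
      frame = reg$frames,
      n_clusters = vapply(reports, function(r) length(r$sizes), integer(1)),
      flagged = vapply(reports, function(r) r$flagged, logical(1))),
      out("artifact_report.csv"), row.names = FALSE)
  }
  vel <- NULL; annot <- NULL
  if ("behavior" %in% config$stages) {
    b <- stage("behavior", function() {
      vel <- convertOpticFlow(exp$flow)
      writeTrace(vel, out("velocity.csv"))
      ap <- annotationParams(exp$video$roi_walk, exp$video$roi_groom)
      an <- annotateVideo(exp$video$frames, ap)
      utils::write.csv(data.frame(S_w = an$S_w, S_g = an$S_g),
                       out("annotation.csv"), row.names = FALSE)
      list(vel = vel, annot = an)
    })
    vel <- b$vel; annot <- b$annot
  }
  if ("maps" %in% config$stages) {
    stage("maps", function() {
      act <- activityChannel(movie)
      dff <- computeDff(act, proposeBaselineWindow(act))
      cir <- calciumImpulseResponse(config$synthetic$cir_half_life,
                                    frameRate(movie))
      fr <- frameRate(movie)
      states <- exp$ground_truth$behavior_states
      Sw <- as.numeric(states %in% .walkStates)
      Sg <- as.numeric(states == "groom")
      ww <- normalizeMap(fitWeights(buildRegressor(Sw, cir), dff))
      wg <- normalizeMap(fitWeights(buildRegressor(Sg, cir), dff))
      tiff::writeTIFF(list(unitScale(ww), unitScale(wg)), out("weight_maps.tif"),
                      bits.per.sample = 32)
      invisible(NULL)
    })
  }
  traces <- NULL
  if ("roi" %in% config$stages) {
    traces <- stage("roi", function() {
      gt <- exp$ground_truth
      lapply(c(left = "left", right = "right"), function(side) {
        trk <- trackRoi(gt$masks[[side]], structuralChannel(movie)[, , 1],
                        movie, search_radius = 5)
        tr <- extractRatioTrace(movie, trk$masks, roi_label = side)
        writeTrace(tr, out(paste0("ratio_", side, ".csv")))
        tr
      })
    })
  }
  if ("events" %in% config$stages) {
    if (is.null(traces)) stop("pipeline stage 'events' requires stage 'roi'")
    stage("events", function() {
      th <- poolDerivativeThreshold(traces, config$events$percentile)
      evL <- detectEvents(traces$left, th, config$events)
      evR <- detectEvents(traces$right, th, config$events)
      rec <- reconcileBilateral(evL, evR, config$events)
      writeEvents(rec$left, out("events_left.csv"))
      writeEvents(rec$right, out("events_right.csv"))
      invisible(NULL)
    })
  }
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$parameters <- list(
    synthetic = unclass(config$synthetic)[
      !vapply(config$synthetic, is.data.frame, logical(1))],
    registration = unclass(config$registration),
    events = unclass(config$events))
  class(manifest) <- "RunManifest"
  yaml::write_yaml(lapply(unclass(manifest), function(x)
    if (is.list(x)) lapply(x, unclass) else x), out("manifest.yaml"))
  invisible(manifest)
}
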