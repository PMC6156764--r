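#' Discover three-channel fields in a directory
#'
#' Channels are identified by the filename suffix convention
#' `<prefix>_dapi.tif`, `<prefix>_flag.tif`, `<prefix>_edu.tif` (the
#' layout written by [simulate_to_dir()]); each prefix becomes one field.
#'
#' @param dir directory to scan.
#' @param suffixes named character vector overriding the channel
#'   suffixes.
#' @return data frame with `field`, `dapi`, `flag`, `edu` path columns.
#' @export
discover_fields <- function(dir,
                            suffixes = c(dapi = "_dapi.tif",
                                         flag = "_flag.tif",
                                         edu = "_edu.tif")) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  dapis <- list.files(dir, pattern = paste0(gsub("\\.", "\\\\.",
                                                 suffixes[["dapi"]]), "$"),
                      full.names = TRUE)
  if (!length(dapis)) stop("no '", suffixes[["dapi"]], "' files in ", dir)
  prefix <- sub(paste0(gsub("\\.", "\\\\.", suffixes[["dapi"]]), "$"), "",
                basename(dapis))
  out <- data.frame(field = prefix,
                    dapi = dapis,
                    flag = file.path(dir, paste0(prefix, suffixes[["flag"]])),
                    edu = file.path(dir, paste0(prefix, suffixes[["edu"]])))
  for (i in seq_len(nrow(out))) for (ch in c("flag", "edu"))
    if (!file.exists(out[[ch]][i]))
      stop("missing ", ch, " channel file for field '", out$field[i],
           "': ", out[[ch]][i])
  out
}

#' Run configuration for the end-to-end analysis
#'
#' Describes one analysis run: which fields belong to which
#' condition/replicate, which condition is the control, and every stage
#' parameter. Field entries are data frames as returned by
#' [discover_fields()] with added `condition` and `replicate` columns, or
#' built by hand.
#'
#' @param fields data frame with columns `field`, `dapi`, `flag`, `edu`,
#'   `condition`, `replicate`.
#' @param control_condition the condition analyzed under the control
#'   proliferation-rate definition; must name exactly one of the
#'   conditions present (or be `NA` when no control is present).
#' @param dog,seg,classify stage parameter objects.
#' @param output_dir where outputs are written (`NULL`: nothing written).
#' @param pixel_size micrometres per pixel.
#' @param seed integer recorded in the manifest.
#' @param write_overlays write per-field overlay PNGs (default TRUE when
#'   `output_dir` is set).
#' @return object of class `run_config`.
#' @export
run_config <- function(fields, control_condition = NA_character_,
                       dog = dog_params(), seg = segmentation_params(),
                       classify = classify_params(), output_dir = NULL,
                       pixel_size = 0.65, seed = 1L,
                       write_overlays = !is.null(output_dir)) {
  stopifnot(is.data.frame(fields),
            all(c("field", "dapi", "flag", "edu", "condition", "replicate")
                %in% names(fields)))
  if (!is.na(control_condition) &&
      !control_condition %in% fields$condition)
    stop("control condition '", control_condition,
         "' not among the conditions: ",
         paste(unique(fields$condition), collapse = ", "))
  structure(list(fields = fields, control_condition = control_condition,
                 dog = dog, seg = seg, classify = classify,
                 output_dir = output_dir, pixel_size = pixel_size,
                 seed = as.integer(seed),
                 write_overlays = isTRUE(write_overlays)),
            class = "run_config")
}

#' Run the full image-analysis pipeline
#'
#' Executes, per field: nucleus segmentation of the DAPI channel, per-cell
#' Flag/EdU measurement, and transfection/proliferation classification
#' (the transfection threshold is selected once from the pooled Flag
#' intensities of all fields, mirroring the one-threshold-per-experiment
#' workflow, unless a numeric threshold is configured). Condition-level
#' proliferation rates are then summarized and, when at least two
#' conditions have at least two replicates, compared with the
#' Levene/ANOVA/Tukey chain. When `output_dir` is set, the per-cell
#' table, the counts summary, a statistics report, overlay PNGs and a run
#' manifest are written.
#'
#' @param config a [run_config()].
#' @return object of class `prolif_run`: list with `cells` (per-cell
#'   table), `summary` (condition summary), `comparison`
#'   (`group_comparison` or NULL), `flag_threshold`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fields <- config$fields
  per_field <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    fi <- fields[i, ]
    stage <- function(what, path, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed on '%s' (%s): %s", what, fi$field,
                     path, conditionMessage(e)), call. = FALSE))
    }
    dapi <- stage("read", fi$dapi, read_channel_tiff(fi$dapi))
    flag <- stage("read", fi$flag, read_channel_tiff(fi$flag))
    edu <- stage("read", fi$edu, read_channel_tiff(fi$edu))
    nuclei <- stage("segment", fi$dapi,
                    segment_nuclei(dapi, config$dog, config$seg))
    rec <- stage("measure", fi$field,
                 measure_channels(nuclei, flag, edu, dog = config$dog,
                                  dapi_image = dapi,
                                  pixel_size = config$pixel_size))
    rec$field <- fi$field
    rec$condition <- fi$condition
    rec$replicate <- fi$replicate
    per_field[[i]] <- list(records = rec, nuclei = nuclei, dapi = dapi)
  }
  cells <- do.call(rbind, lapply(per_field, `[[`, "records"))
  if (!nrow(cells)) stop("no nuclei detected in any field")

  thr <- config$classify$flag_threshold
  if (identical(thr, "auto"))
    thr <- as.numeric(select_transfection_threshold(
      cells$mean_flag, config$classify$fallback_quantile))
  resolved <- config$classify
  resolved$flag_threshold <- thr
  cells <- classify_cells(cells, resolved, condition = cells$condition)

  summary_tab <- summarize_conditions(cells, config$control_condition)
  comparison <- NULL
  rep_counts <- table(unique(summary_tab[, c("condition", "replicate")])$condition)
  if (length(rep_counts) >= 2L && all(rep_counts >= 2L))
    comparison <- compare_groups(summary_tab)

  run <- structure(list(cells = cells, summary = summary_tab,
                        comparison = comparison, flag_threshold = thr,
                        config = config), class = "prolif_run")
  if (!is.null(config$output_dir))
    write_run_outputs(run, per_field)
  run
}

write_run_outputs <- function(run, per_field) {
  config <- run$config
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(run$summary, file.path(dir, "counts_summary.csv"),
                   row.names = FALSE)
  rep_lines <- utils::capture.output({
    cat(sprintf("Transfection threshold (mean DoG Flag intensity): %.6g\n\n",
                run$flag_threshold))
    if (!is.null(run$comparison)) print(run$comparison)
    else cat("No group comparison (need >= 2 conditions x >= 2 replicates)\n")
  })
  writeLines(rep_lines, file.path(dir, "stats_report.txt"))
  manifest <- list(
    seed = config$seed, pixel_size = config$pixel_size,
    control_condition = config$control_condition,
    sigma_low = config$dog$sigma_low, sigma_high = config$dog$sigma_high,
    k_clusters = config$seg$k_clusters,
    min_mean_intensity = config$seg$min_mean_intensity,
    min_region_area = config$seg$min_region_area,
    clear_border = config$seg$clear_border,
    watershed_tolerance = config$seg$watershed_tolerance,
    flag_threshold = run$flag_threshold,
    edu_min_intensity = config$classify$edu_min_intensity,
    flag_min_intensity = config$classify$flag_min_intensity,
    fields = paste(config$fields$field, collapse = ", "),
    conditions = paste(config$fields$condition, collapse = ", "),
    replicates = paste(config$fields$replicate, collapse = ", ")
  )
  write_plain_config(manifest, file.path(dir, "manifest.txt"))
  if (config$write_overlays) {
    for (i in seq_along(per_field)) {
      pf <- per_field[[i]]
      fid <- config$fields$field[i]
      sub <- run$cells[run$cells$field == fid, ]
      overlay_image(pf$nuclei, sub, pf$dapi,
                    file.path(dir, paste0(fid, "_overlay.png")))
      write_label_tiff(pf$nuclei, file.path(dir, paste0(fid, "_labels.tif")))
    }
  }
  invisible(dir)
}

#' @export
print.prolif_run <- function(x, ...) {
  cat(sprintf("Proliferation analysis: %d fields, %d cells\n",
              nrow(x$config$fields), nrow(x$cells)))
  cat(sprintf("Transfection threshold (DoG Flag scale): %.6g\n",
              x$flag_threshold))
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
summary.prolif_run <- function(object, ...) object$summary

#' Plot the Flag-intensity distribution with the applied threshold
#'
#' Histogram of per-cell mean Flag intensities with the selected
#' transfection threshold as a vertical red line — the diagnostic used to
#' judge whether the threshold separates the non-transfected and
#' transfected modes.
#'
#' @param x a `prolif_run`.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @param ... further arguments to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plot.prolif_run <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$cells$mean_flag, breaks = breaks,
                      main = "Flag intensity distribution",
                      xlab = "per-cell mean Flag intensity (DoG scale)", ...)
  graphics::abline(v = x$flag_threshold, col = "red", lwd = 2)
  invisible(h)
}
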