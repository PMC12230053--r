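#' Read width profiles from CSV
#'
#' Reads the documented width-profile schema
#' (`cultivar,plant,rank,method,position_cm,width_cm`), rejects rows with
#' non-finite measurements (reporting their line numbers), and returns rows
#' grouped by `(cultivar, plant, rank, method)` sorted by position within
#' each group.
#'
#' @param path CSV file path.
#' @return A data.frame with the schema columns, sorted by group and
#'   position; attribute `rejected` lists 1-based data line numbers of
#'   dropped rows.
#' @export
read_width_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cultivar", "plant", "rank", "method", "position_cm", "width_cm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("width-profile schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty width-profile file: ", path, call. = FALSE)
  bad <- !is.finite(df$position_cm) | !is.finite(df$width_cm)
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at data line(s): %s",
                    sum(bad), paste(which(bad), collapse = ", ")), call. = FALSE)
    df <- df[!bad, ]
  }
  if (nrow(df) == 0L) stop("no valid rows in width-profile file", call. = FALSE)
  df <- df[order(df$cultivar, df$plant, df$rank, df$method, df$position_cm), ]
  rownames(df) <- NULL
  attr(df, "rejected") <- which(bad)
  df
}

#' Write width profiles to CSV
#'
#' @param profiles data.frame with the width-profile schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_width_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Split a width-profile table into normalized profiles per leaf
#'
#' @param df a data.frame from [read_width_profiles()].
#' @return A named list of [width_profile()] objects, one per
#'   `(cultivar, plant, rank, method)` group.
#' @export
profiles_by_leaf <- function(df) {
  key <- interaction(df$cultivar, df$plant, df$rank, df$method, drop = TRUE)
  lapply(split(df, key), function(g)
    normalize_profile(g$position_cm, g$width_cm,
                      cultivar = g$cultivar[1L], plant = g$plant[1L],
                      rank = g$rank[1L], method = g$method[1L]))
}

#' Write shape-fit results to JSON
#'
#' @param fits named list of `fit_result` objects (names identify leaves) or
#'   a single `fit_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fit = fits)
  out <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    list(leaf = nm, alpha = f$params$alpha, a = f$params$a,
         adj_r2 = f$adj_r2, rmse = f$rmse, n_points = f$n_points,
         converged = f$converged)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    leaf = list(length_cm = 50, max_width_cm = 8, alpha = 0.85, a = 0.70),
    scene = list(px_per_cm = 6, frame_width = 480L, frame_height = 270L,
                 belt_speed = 8),
    measure = list(n_segments = 100L),
    stages = c("synth", "measure", "fit"))
}

validate_config <- function(cfg, defaults = pipeline_defaults(), path = "config") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", path, paste(unknown, collapse = ", ")),
         call. = FALSE)
  out <- defaults
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- validate_config(cfg[[nm]], defaults[[nm]],
                                   paste0(path, "$", nm))
    } else out[[nm]] <- cfg[[nm]]
  }
  out
}

#' Run the synth -> measure -> fit pipeline
#'
#' End-to-end pipeline over one synthetic leaf: generate a conveyor video,
#' measure the width profile with the vision pipeline, and fit the shape
#' function. Deterministic for a fixed config and seed; every artifact is
#' listed in the returned manifest with an MD5 checksum. If a stage fails,
#' the manifest marks it and keeps the artifacts of completed stages.
#'
#' @param config a named list (see `leafshape:::pipeline_defaults()` for
#'   recognised keys) or path to a YAML file. Unknown keys are an error.
#' @return A manifest data.frame: `stage`, `path`, `md5`, `status`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0), status = character(0))
  add <- function(stage, path, status = "ok") {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, path = path,
      md5 = if (status == "ok") unname(tools::md5sum(path)) else NA_character_,
      status = status))
  }

  video <- NULL
  if ("synth" %in% cfg$stages) {
    res <- tryCatch({
      spec <- synthetic_leaf_spec(cfg$leaf$length_cm, cfg$leaf$max_width_cm,
                                  shape_params(cfg$leaf$alpha, cfg$leaf$a))
      mask <- make_leaf_mask(spec, cfg$scene$px_per_cm,
                             seed = derive_seed(cfg$seed, "mask"))
      scn <- scene_spec(cfg$scene$px_per_cm,
                        frame_width = cfg$scene$frame_width,
                        frame_height = cfg$scene$frame_height,
                        belt_speed = cfg$scene$belt_speed,
                        seed = derive_seed(cfg$seed, "render"))
      video <- render_video_frames(mask, scn)
      p <- file.path(cfg$out_dir, "ground_truth.csv")
      utils::write.csv(mask$truth, p, row.names = FALSE)
      p
    }, error = function(e) e)
    if (inherits(res, "error")) {
      add("synth", NA_character_, paste("failed:", conditionMessage(res)))
      return(manifest)
    }
    add("synth", res)
  }

  measurement <- NULL
  if ("measure" %in% cfg$stages) {
    res <- tryCatch({
      measurement <- process_video(video, n_segments = cfg$measure$n_segments)
      p <- file.path(cfg$out_dir, "profile.csv")
      write_width_profiles(measurement$profile, p)
      p
    }, error = function(e) e)
    if (inherits(res, "error")) {
      add("measure", NA_character_, paste("failed:", conditionMessage(res)))
      return(manifest)
    }
    add("measure", res)
  }

  if ("fit" %in% cfg$stages) {
    res <- tryCatch({
      prof <- normalize_profile(measurement$segments$position_cm,
                                measurement$segments$width_cm)
      fit <- fit_shape(prof)
      p <- file.path(cfg$out_dir, "fit.json")
      write_fit_json(list(leaf = fit), p)
      p
    }, error = function(e) e)
    if (inherits(res, "error")) {
      add("fit", NA_character_, paste("failed:", conditionMessage(res)))
      return(manifest)
    }
    add("fit", res)
  }
  manifest
}
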