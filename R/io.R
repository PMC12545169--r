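#' Read and write spike and event tables
#'
#' Plain-CSV interchange formats: spike tables have columns `unit_id`,
#' `area`, `time_s`, `amplitude`; event tables have `stim_id`, `class`,
#' `onset_s`, `duration_s` and optional extra columns (e.g. `block`)
#' carried through a `params_json` column on write.
#'
#' @param spikes,events Data frames in the package's session format.
#' @param path File path.
#' @return The data frame (readers), invisibly the path (writers).
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.csv(spikes[, c("unit_id", "area", "time_s", "amplitude")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "area", "time_s", "amplitude")
  if (!all(need %in% names(df)))
    stop("spike table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname session_io
#' @export
write_event_table <- function(events, path) {
  base <- c("stim_id", "class", "onset_s", "duration_s")
  extra <- setdiff(names(events), base)
  out <- events[, base]
  out$params_json <- if (length(extra))
    vapply(seq_len(nrow(events)), function(i)
      as.character(jsonlite::toJSON(as.list(events[i, extra, drop = FALSE]),
                                    auto_unbox = TRUE)), character(1))
  else "{}"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path)
  if ("params_json" %in% names(df) && any(df$params_json != "{}")) {
    pars <- lapply(df$params_json, function(s)
      as.data.frame(jsonlite::fromJSON(s)))
    df <- cbind(df[setdiff(names(df), "params_json")], do.call(rbind, pars))
  } else df$params_json <- NULL
  df
}

#' Write an image bank as PNG files plus a JSON manifest
#'
#' @param bank An [image_bank].
#' @param dir Output directory (created if missing).
#' @return Invisibly the manifest path.
#' @export
write_image_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("img_%05d.png", bank$image_ids)
  for (i in seq_along(bank$image_ids))
    png::writePNG(bank$pixels[, , i], file.path(dir, files[i]))
  manifest <- list(images = data.frame(
    id = bank$image_ids, file = files, category = bank$category,
    family = bank$family, repeats = bank$repeats))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, dataframe = "rows", auto_unbox = TRUE,
                       na = "null")
  invisible(mp)
}

#' Read an image bank written by [write_image_bank]
#'
#' @param dir Directory holding the PNGs and `manifest.json`.
#' @return An [image_bank].
#' @export
read_image_bank <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))$images
  imgs <- lapply(man$file, function(f) png::readPNG(file.path(dir, f)))
  px <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  fam <- if ("family" %in% names(man)) man$family else NULL
  image_bank(px, category = man$category, family = fam,
             repeats = man$repeats, image_ids = man$id)
}

#' Write and read a feature bank (plain text)
#'
#' Stores `features`, `pc_basis`, `pc_mean` and `pc_scores` as CSV files
#' with a small JSON header recording the layer name.
#'
#' @param fb A [feature_bank].
#' @param dir Output directory.
#' @return Invisibly `dir` (writer); a [feature_bank] (reader).
#' @export
write_feature_bank <- function(fb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fb$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(fb$pc_basis, file.path(dir, "pc_basis.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pc_mean = fb$pc_mean),
                   file.path(dir, "pc_mean.csv"), row.names = FALSE)
  utils::write.csv(fb$pc_scores, file.path(dir, "pc_scores.csv"), row.names = FALSE)
  jsonlite::write_json(list(layer_name = fb$layer_name,
                            image_ids = fb$image_ids),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_feature_bank
#' @export
read_feature_bank <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  fb <- list(
    layer_name = meta$layer_name,
    features = as.matrix(utils::read.csv(file.path(dir, "features.csv"))),
    pc_basis = as.matrix(utils::read.csv(file.path(dir, "pc_basis.csv"))),
    pc_mean = utils::read.csv(file.path(dir, "pc_mean.csv"))$pc_mean,
    pc_scores = as.matrix(utils::read.csv(file.path(dir, "pc_scores.csv"))),
    image_ids = meta$image_ids
  )
  dimnames(fb$features) <- NULL
  names(fb$pc_mean) <- colnames(fb$features)
  class(fb) <- "feature_bank"
  fb
}
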