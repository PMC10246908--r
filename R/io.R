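#' Write / read a single image channel as tab-separated text
#'
#' Plain-text serialization used for all image artifacts: portable,
#' diff-able, and round-trips doubles via `%.10g`.
#'
#' @param mat numeric matrix.
#' @param path output file.
#' @export
write_image_txt <- function(mat, path) {
  write.table(format(mat, digits = 10, scientific = TRUE, trim = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_image_txt
#' @export
read_image_txt <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE,
                       colClasses = "numeric"))
}

#' Write a scene to a directory (text channels + JSON sidecar)
#'
#' Each channel and ground-truth mask goes to one TSV file; a JSON sidecar
#' records pixel size, channel names, seed, and the file map.
#'
#' @param scene result of [generate_scene()] (or a list with an `image`
#'   field).
#' @param dir output directory, created if needed.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- scene$image
  files <- list()
  for (ch in img$channel_names) {
    f <- paste0("channel_", ch, ".tsv")
    write_image_txt(img$channels[[ch]], file.path(dir, f))
    files[[ch]] <- f
  }
  masks <- list()
  if (!is.null(scene$truth)) {
    for (mk in c("tumor_mask", "vessel_mask")) {
      f <- paste0(mk, ".tsv")
      write_image_txt(scene$truth[[mk]]$mask + 0, file.path(dir, f))
      masks[[mk]] <- f
    }
  }
  sidecar <- list(pixel_size_um = img$pixel_size_um,
                  channel_names = img$channel_names,
                  seed = scene$truth$params$seed %||% NA,
                  channels = files, masks = masks)
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "scene.json"),
                            simplifyVector = TRUE)
  chans <- lapply(sc$channels, function(f) read_image_txt(file.path(dir, f)))
  img <- spectral_image(chans, sc$pixel_size_um, names(chans))
  masks <- lapply(sc$masks, function(f)
    read_image_txt(file.path(dir, f)) > 0.5)
  list(image = img, masks = masks, seed = sc$seed)
}

#' Write a cell-sample or peritumoral-ROI table as CSV
#' @param tab data.frame.
#' @param path output CSV.
#' @export
write_table_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write image-level metrics as JSON
#' @param metrics named list of scalars.
#' @param path output JSON file.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
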