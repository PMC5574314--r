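#' Write an image stack as a portable text file
#'
#' Plain-text stack interchange format (used in place of TIFF so that the
#' package has no binary-format dependency): a one-line JSON header with
#' the geometry and physical calibration, followed by one comma-separated
#' line per image row, plane by plane, channel by channel.
#'
#' @param x A numeric matrix, 3-D array `[y, x, z]`, or named list of such
#'   arrays (channels).
#' @param path Output file.
#' @param pixel_size_xy,z_step Physical calibration recorded in the
#'   header (um).
#' @return `path`, invisibly.
#' @export
write_stack_txt <- function(x, path, pixel_size_xy = 0.08, z_step = 0.25) {
  chans <- if (is.list(x) && !is.data.frame(x)) x else list(image = x)
  chans <- lapply(chans, function(a) {
    if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
    a
  })
  d <- dim(chans[[1]])
  for (a in chans) if (!identical(dim(a), d))
    stopf("write_stack_txt: channels differ in shape")
  hdr <- jsonlite::toJSON(list(ny = d[1], nx = d[2], nz = d[3],
                               channels = names(chans),
                               pixel_size_xy = pixel_size_xy,
                               z_step = z_step),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (ch in chans) for (z in seq_len(d[3]))
    write.table(ch[, , z], con, sep = ",", row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read an image stack written by [write_stack_txt()]
#'
#' @param path File path.
#' @return Named list of arrays `[y, x, z]` with attributes
#'   `pixel_size_xy` and `z_step`.
#' @export
read_stack_txt <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  body <- lines[-1]
  nrow_chan <- hdr$ny * hdr$nz
  out <- list()
  for (i in seq_along(hdr$channels)) {
    rows <- body[((i - 1) * nrow_chan + 1):(i * nrow_chan)]
    vals <- scan(text = rows, sep = ",", quiet = TRUE)
    a <- array(0, dim = c(hdr$ny, hdr$nx, hdr$nz))
    m <- matrix(vals, nrow = nrow_chan, ncol = hdr$nx, byrow = TRUE)
    for (z in seq_len(hdr$nz))
      a[, , z] <- m[((z - 1) * hdr$ny + 1):(z * hdr$ny), ]
    out[[hdr$channels[i]]] <- a
  }
  attr(out, "pixel_size_xy") <- hdr$pixel_size_xy
  attr(out, "z_step") <- hdr$z_step
  out
}

#' Write the ground-truth sidecar of a synthetic scene
#'
#' Particles as CSV and scene parameters as JSON, next to each other.
#'
#' @param scene A `jc1_scene`.
#' @param prefix Output path prefix; writes `<prefix>_particles.csv` and
#'   `<prefix>_params.json`.
#' @return The two paths, invisibly.
#' @export
write_truth_sidecar <- function(scene, prefix) {
  stopifnot(inherits(scene, "jc1_scene"))
  pcsv <- paste0(prefix, "_particles.csv")
  pjson <- paste0(prefix, "_params.json")
  write.csv(scene$truth$particles, pcsv, row.names = FALSE)
  par <- scene$params
  par$seed <- par$seed %||% NA
  jsonlite::write_json(
    c(unclass(par),
      list(cell_area_um2 = scene$truth$cell_area_um2,
           total_mito_area_um2 = scene$truth$total_mito_area_um2)),
    pjson, auto_unbox = TRUE, digits = NA)
  invisible(c(pcsv, pjson))
}
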