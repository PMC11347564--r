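#' Read / write a JSON configuration file
#'
#' Flat or nested key-value configuration (wavelength_nm, waist_mm, ell, p,
#' nx, ny, pitch_um, layers, detector, ...), stored as JSON.
#'
#' @param path file path
#' @return the configuration list
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config configuration list to write
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read an ASCII PGM (P2) image
#'
#' Plain-text greyscale interchange format used for all on-disk images
#' (stacks are one file per frame plus a CSV timestamp sidecar).
#'
#' @param image integer matrix of counts
#' @param path file path
#' @param maxval maximum grey value (default from the data, at least 1)
#' @export
write_pgm <- function(image, path, maxval = NULL) {
  stopifnot(is.matrix(image))
  v <- as.integer(round(image))
  if (is.null(maxval)) maxval <- max(1L, max(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)),
               sprintf("%d", maxval)), con)
  # row-major pixel order
  apply(image, 1, function(r) writeLines(paste(as.integer(round(r)),
                                               collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @return `read_pgm` returns the integer matrix
#' @export
read_pgm <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  stopifnot(ln[1] == "P2")
  dims <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(ln[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Export a complex field as amplitude/phase images plus a JSON sidecar
#'
#' @param field a `complex_field`
#' @param prefix output path prefix; writes `<prefix>_amp.pgm`,
#'   `<prefix>_phase.pgm` (phase mapped from (-pi, pi] to 0..65535) and
#'   `<prefix>.json`
#' @return invisibly, the sidecar path
#' @export
write_field <- function(field, prefix) {
  stopifnot(inherits(field, "complex_field"))
  amp <- Mod(field$amplitude)
  sc <- if (max(amp) > 0) 65535 / max(amp) else 1
  write_pgm(round(amp * sc), paste0(prefix, "_amp.pgm"), maxval = 65535)
  ph <- (Arg(field$amplitude) + pi) / (2 * pi) * 65535
  write_pgm(round(ph), paste0(prefix, "_phase.pgm"), maxval = 65535)
  side <- list(nx = field$grid$nx, ny = field$grid$ny,
               pitch_m = field$grid$pitch, origin = field$grid$origin,
               z_m = field$z, amp_scale = 1 / sc,
               phase_encoding = "counts/65535*2*pi - pi")
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(prefix, ".json"))
}

#' Write a twist series as CSV with unit-annotated header
#'
#' @param ts a `twist_series` (or compatible data.frame)
#' @param path output path
#' @export
write_twist_csv <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# oamtwist relative twist series",
               "# columns: frame (index), t_s (s), theta_rad (rad), theta_deg (deg), petals_found (count), flagged (logical)"),
             con)
  utils::write.table(as.data.frame(ts), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
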