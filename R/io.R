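#' Write a line cut as a 3-column text table
#'
#' Plain whitespace-separated columns `qpar`, `intensity`, `sigma`, with
#' the cut position and background status in `#` header comments.
#'
#' @param cut A `line_cut`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_line_cut <- function(cut, path) {
  stopifnot(inherits(cut, "line_cut"))
  hdr <- c(sprintf("# qz_center = %.12g", attr(cut, "qz_center")),
           sprintf("# background_subtracted = %s",
                   isTRUE(attr(cut, "background_subtracted"))),
           "# qpar intensity sigma")
  body <- sprintf("%.10e %.10e %.10e", cut$qpar, cut$intensity, cut$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a line cut written by [write_line_cut()]
#'
#' @param path Path to the 3-column file.
#' @return A `line_cut` tibble.
#' @export
read_line_cut <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  qz <- NA_real_
  bg <- FALSE
  mqz <- grep("qz_center", hdr, value = TRUE)
  if (length(mqz)) qz <- as.numeric(sub(".*= *", "", mqz[1]))
  mbg <- grep("background_subtracted", hdr, value = TRUE)
  if (length(mbg)) bg <- identical(sub(".*= *", "", mbg[1]), "TRUE")
  df <- readr::read_table(path, comment = "#",
                          col_names = c("qpar", "intensity", "sigma"),
                          col_types = "ddd", progress = FALSE)
  new_line_cut(qpar = df$qpar, intensity = df$intensity, sigma = df$sigma,
               qz_center = qz, background_subtracted = bg)
}

#' Write a reflectivity profile as 3-column text
#'
#' @param profile A `reflectivity_profile`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_reflectivity <- function(profile, path) {
  stopifnot(inherits(profile, "reflectivity_profile"))
  writeLines(c("# qz intensity sigma",
               sprintf("%.10e %.10e %.10e", profile$qz,
                       profile$intensity, profile$sigma)), path)
  invisible(path)
}

#' Write a structure-factor map as a plain-text matrix
#'
#' First row: `0` followed by the `qpar` axis; subsequent rows: `qz`
#' followed by the intensities.
#'
#' @param map An `sf_map` tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sf_map <- function(map, path) {
  qpar <- sort(unique(map$qpar))
  qz <- sort(unique(map$qz))
  mat <- matrix(NA_real_, length(qz), length(qpar))
  mat[cbind(match(map$qz, qz), match(map$qpar, qpar))] <- map$intensity
  lines <- c(paste(c(0, qpar), collapse = " "),
             vapply(seq_along(qz), function(i) {
               paste(c(qz[i], mat[i, ]), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle run outputs into an archive
#'
#' Collects the given files into a single gzip-compressed tar bundle (a
#' portable stand-in for a zip download).
#'
#' @param files Paths to include.
#' @param archive Output archive path (e.g. `results.tar.gz`).
#' @return The archive path, invisibly.
#' @export
bundle_outputs <- function(files, archive) {
  stopifnot(all(file.exists(files)))
  arch_abs <- if (startsWith(archive, "/")) archive
              else file.path(getwd(), archive)
  owd <- getwd()
  on.exit(setwd(owd), add = TRUE)
  setwd(dirname(files[1]))
  utils::tar(arch_abs, files = basename(files), compression = "gzip",
             tar = "internal")
  invisible(archive)
}
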