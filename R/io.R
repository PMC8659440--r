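# Plain-text and ENVI input/output.

#' Read / write chemistry tables as CSV
#'
#' Header: sample_id,time_h,layer,total,egc,c,ec,egcg,ecg.
#' @param chem chemistry tibble.
#' @param path file path.
#' @return `write_chem_csv` the path (invisibly); `read_chem_csv` a tibble.
#' @export
write_chem_csv <- function(chem, path) {
  readr::write_csv(chem, path)
  invisible(path)
}

#' @rdname write_chem_csv
#' @export
read_chem_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    layer = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Read / write spectra as CSV with a companion wavelength file
#'
#' The spectra file holds one metadata id column (`spectrum_id`) followed by
#' one column per band; the companion file lists the band wavelengths in nm.
#' @param set a `spectra_set`.
#' @param path spectra CSV path.
#' @param wavelength_path companion wavelength CSV path.
#' @export
write_spectra_csv <- function(set, path, wavelength_path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- dplyr::bind_cols(
    tibble::tibble(spectrum_id = set$meta$spectrum_id),
    tibble::as_tibble(set$values,
                      .name_repair = ~ sprintf("b%04d", seq_along(.x)))
  )
  readr::write_csv(df, path)
  readr::write_csv(tibble::tibble(wavelength_nm = as.numeric(set$grid)),
                   wavelength_path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param quantity quantity tag for the restored set.
#' @export
read_spectra_csv <- function(path, wavelength_path,
                             quantity = "reflectance") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  wl <- readr::read_csv(wavelength_path, show_col_types = FALSE)
  grid <- structure(wl$wavelength_nm, class = "wavelength_grid")
  spectra_set(as.matrix(df[, -1]), grid,
              meta = tibble::tibble(spectrum_id = df[[1]]),
              quantity = quantity)
}

#' Write a hypercube in ENVI format
#'
#' Produces a text header (`<base>.hdr`) and a raw binary file (`<base>.raw`)
#' with 32-bit little-endian floats in BSQ or BIL interleave, carrying the
#' wavelength list in the header.
#'
#' @param cube a `hyper_cube`.
#' @param base path without extension.
#' @param interleave "bsq" or "bil".
#' @return the header path, invisibly.
#' @export
write_envi <- function(cube, base, interleave = c("bsq", "bil")) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)  # lines (h), samples (w), bands
  hdr <- c(
    "ENVI",
    "description = {teaspec hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(as.numeric(cube$grid), trim = TRUE), collapse = ", "),
           "}")
  )
  writeLines(hdr, paste0(base, ".hdr"))
  v <- cube$values
  ord <- switch(interleave,
    # BSQ: band -> line -> sample ; BIL: line -> band -> sample
    bsq = aperm(v, c(2, 1, 3)),  # sample fastest, then line, then band
    bil = aperm(v, c(2, 3, 1))
  )
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(ord), con, size = 4, endian = "little")
  invisible(paste0(base, ".hdr"))
}

#' @rdname write_envi
#' @param hdr_path path to the `.hdr` file (the raw file is `<base>.raw`).
#' @export
read_envi <- function(hdr_path) {
  lines <- readLines(hdr_path)
  joined <- paste(lines, collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(joined, regexec(paste0(key, "\\s*=\\s*(\\S+)"), joined))[[1]]
    if (length(m) < 2) stop("missing ENVI header field: ", key, call. = FALSE)
    m[2]
  }
  samples <- as.integer(get1("samples"))
  nlines <- as.integer(get1("lines"))
  bands <- as.integer(get1("bands"))
  dtype <- as.integer(get1("data type"))
  interleave <- tolower(get1("interleave"))
  if (dtype != 4) stop("only ENVI data type 4 (float32) is supported.", call. = FALSE)
  wl_match <- regmatches(joined,
                         regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", joined))[[1]]
  if (length(wl_match) < 2) stop("header lacks a wavelength list.", call. = FALSE)
  wl <- as.numeric(strsplit(wl_match[2], ",")[[1]])
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = samples * nlines * bands, size = 4,
               endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, nlines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(samples, bands, nlines)), c(3, 1, 2)),
    stop("unsupported interleave: ", interleave, call. = FALSE)
  )
  hyper_cube(arr, structure(wl, class = "wavelength_grid"))
}
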