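.band_df <- function(center, fwhm, amp, assignment, redox) {
  data.frame(center = center, fwhm = fwhm, rel_amplitude = amp,
             assignment = assignment, redox_sensitive = redox,
             stringsAsFactors = FALSE)
}

#' Cytochrome c SERS marker-band library
#'
#' Four band sets encoding the principal heme bands seen in SERS spectra of
#' mitochondria and of purified cytochrome c, in the oxidized and the
#' (dithionite-)reduced state. Band centers (cm-1) follow the published
#' assignments; the ν4 symmetric pyrrole half-ring mode sits at 1371 cm-1
#' when the heme iron is oxidized and shifts to 1356 cm-1 on reduction, the
#' B1g ν10 marker shifts from 1638 to 1605 cm-1, and reduction adds a band
#' at 690 cm-1 and raises the relative intensity of the 748 cm-1 heme
#' breathing mode.
#'
#' Band *widths* and *relative amplitudes* are not part of the published
#' assignments; the defaults here (Lorentzian FWHM 12 cm-1 for every band,
#' amplitudes ordered to resemble measured mitochondrial traces, with the
#' reduced state showing the stronger 748 cm-1 breathing mode) are package
#' fixture constants, editable by the user, not literature values.
#'
#' @return a `band_library`: named list of four data frames
#'   (`mito_oxidized`, `mito_reduced`, `cyt_oxidized`, `cyt_reduced`), each
#'   with columns `center`, `fwhm`, `rel_amplitude`, `assignment`,
#'   `redox_sensitive`.
#' @export
band_library <- function() {
  fw <- 12
  mito_ox <- .band_df(
    center = c(748, 1127, 1170, 1313, 1371, 1403, 1565, 1585, 1638),
    fwhm = fw,
    amp = c(0.90, 0.45, 0.55, 0.50, 1.00, 0.35, 0.55, 0.75, 0.70),
    assignment = c("nu15 heme breathing", "nu5 Cb-CH3",
                   "nu30 asym pyrrole half-ring", "all heme c bonds",
                   "nu4 sym pyrrole half-ring", "CaCb, CbC1",
                   "B1g CaCm/CaCb/CaN", "A2g CaCm/CaCmH/CaCb",
                   "nu10 CaCm/CaCmH/CaCb"),
    redox = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  mito_red <- .band_df(
    center = c(690, 748, 1127, 1170, 1311, 1356, 1396, 1545, 1605),
    fwhm = fw,
    amp = c(0.25, 1.30, 0.50, 0.55, 0.55, 1.10, 0.35, 0.80, 0.75),
    assignment = c("redox marker", "nu15 heme breathing", "nu5 Cb-CH3",
                   "nu30 asym pyrrole half-ring", "all heme c bonds",
                   "nu4 sym pyrrole half-ring", "CaCb, CbC1",
                   "A2g CaCm/CaCmH/CaCb", "nu10 CaCm/CaCmH/CaCb"),
    redox = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  cyt_ox <- .band_df(
    center = c(758, 1130, 1172, 1317, 1373, 1403, 1569, 1638),
    fwhm = fw,
    amp = c(0.90, 0.45, 0.55, 0.50, 1.00, 0.35, 0.65, 0.70),
    assignment = c("nu15 heme breathing", "nu5 Cb-CH3",
                   "nu30 asym pyrrole half-ring", "all heme c bonds",
                   "nu4 sym pyrrole half-ring", "CaCb, CbC1",
                   "B1g CaCm/CaCb/CaN", "nu10 CaCm/CaCmH/CaCb"),
    redox = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cyt_red <- .band_df(
    center = c(690, 758, 1130, 1172, 1316, 1363, 1400, 1549, 1608),
    fwhm = fw,
    amp = c(0.25, 1.30, 0.50, 0.55, 0.55, 1.10, 0.35, 0.80, 0.75),
    assignment = c("redox marker", "nu15 heme breathing", "nu5 Cb-CH3",
                   "nu30 asym pyrrole half-ring", "all heme c bonds",
                   "nu4 sym pyrrole half-ring", "CaCb, CbC1",
                   "A2g CaCm/CaCmH/CaCb", "nu10 CaCm/CaCmH/CaCb"),
    redox = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  structure(list(mito_oxidized = mito_ox, mito_reduced = mito_red,
                 cyt_oxidized = cyt_ox, cyt_reduced = cyt_red),
            class = "band_library")
}

#' @export
print.band_library <- function(x, ...) {
  cat("<band_library>\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %d bands: %s cm-1\n", nm, nrow(x[[nm]]),
                paste(x[[nm]]$center, collapse = ", ")))
  invisible(x)
}

#' Serialize a band library to/from a YAML config file
#'
#' Round-trips all band parameters unchanged.
#'
#' @param lib a [band_library()]-shaped object.
#' @param path file path.
#' @return `read_band_library()` returns a `band_library`;
#'   `write_band_library()` returns `path` invisibly.
#' @export
write_band_library <- function(lib, path) {
  x <- lapply(lib, function(df) {
    lapply(seq_len(nrow(df)), function(i) list(
      center = df$center[i], fwhm = df$fwhm[i],
      rel_amplitude = df$rel_amplitude[i],
      assignment = df$assignment[i],
      redox_sensitive = df$redox_sensitive[i]))
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_band_library
#' @export
read_band_library <- function(path) {
  x <- yaml::read_yaml(path)
  out <- lapply(x, function(set) {
    .band_df(center = vapply(set, `[[`, numeric(1), "center"),
             fwhm = vapply(set, `[[`, numeric(1), "fwhm"),
             amp = vapply(set, `[[`, numeric(1), "rel_amplitude"),
             assignment = vapply(set, `[[`, character(1), "assignment"),
             redox = vapply(set, `[[`, logical(1), "redox_sensitive"))
  })
  structure(out, class = "band_library")
}
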