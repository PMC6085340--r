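#' Default tissue optical property table
#'
#' Absorption and reduced-scattering coefficients per tissue class and
#' wavelength, with a common refractive index of 1.40 for all tissue layers.
#' The numeric values are a documented stand-in compiled from standard
#' 800 nm-region cranial tissue-optics compilations (human/macaque); they are
#' NOT measured values for any individual subject. Every solver operation
#' reads properties exclusively from this table, so a user table with the
#' same columns (`class`, `wavelength_nm`, `mu_a`, `mu_s_prime`, `n`) can be
#' substituted anywhere a model is built.
#'
#' Units: `mu_a` and `mu_s_prime` in mm^-1; `wavelength_nm` in nm.
#'
#' @return A tibble with one row per (class, wavelength).
#' @export
default_tissue_optics <- function() {
  path <- system.file("extdata", "tissue_optics.csv", package = "nirsim")
  if (nzchar(path)) return(read_tissue_optics(path))
  tissue_optics_builtin()
}

# fallback used before installation (e.g. pkgload); identical content to
# inst/extdata/tissue_optics.csv
tissue_optics_builtin <- function() {
  w <- c(780, 805, 830)
  rows <- list(
    air         = list(mu_a = c(0, 0, 0),          mu_sp = c(1e-4, 1e-4, 1e-4)),
    soft_tissue = list(mu_a = c(.018, .019, .020), mu_sp = c(1.94, 1.90, 1.86)),
    skull       = list(mu_a = c(.011, .0115, .012), mu_sp = c(1.55, 1.50, 1.45)),
    csf         = list(mu_a = c(.0026, .0026, .0026), mu_sp = c(.32, .30, .29)),
    gray        = list(mu_a = c(.018, .019, .020), mu_sp = c(2.10, 2.05, 2.00)),
    white       = list(mu_a = c(.016, .0165, .017), mu_sp = c(5.2, 5.0, 4.8)))
  out <- purrr::imap(rows, function(r, cls) {
    tibble(class = cls, wavelength_nm = w, mu_a = r$mu_a,
           mu_s_prime = r$mu_sp, n = 1.40)
  })
  bind_rows(out)
}

#' Read / write tissue optical property tables
#'
#' Plain CSV with columns `class`, `wavelength_nm`, `mu_a`, `mu_s_prime`,
#' `n`. Round-trips bit-exactly through [write_tissue_optics()].
#'
#' @param path CSV file path.
#' @return A tibble (read) or `path`, invisibly (write).
#' @export
read_tissue_optics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          class = readr::col_character(),
                          wavelength_nm = readr::col_double(),
                          mu_a = readr::col_double(),
                          mu_s_prime = readr::col_double(),
                          n = readr::col_double()))
  need <- c("class", "wavelength_nm", "mu_a", "mu_s_prime", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("optics table lacks columns: ",
                                 paste(miss, collapse = ", ")))
  df
}

#' @param optics Tibble as returned by [default_tissue_optics()].
#' @rdname read_tissue_optics
#' @export
write_tissue_optics <- function(optics, path) {
  readr::write_csv(optics, path)
  invisible(path)
}
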