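## CSV dialects. All writers put metadata in leading '# key: value'
## comment lines, then a standard header row; readers validate the
## expected columns and report offending rows on parse errors.

.write_csv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, ": ", meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv_meta <- function(path) {
  lines <- readLines(path)
  metaln <- grep("^#", lines)
  meta <- list()
  for (l in lines[metaln]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines),
                                                   metaln)],
                                     collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write an emission spectrum CSV
#'
#' Columns \code{wavelength_nm}, \code{intensity_arb}; header metadata
#' records bias, NA, variant and the normalization scalar.
#'
#' @param spectrum a \code{liet_emission} (or data.frame lambda_nm,
#'   intensity).
#' @param path output file.
#' @param variant device-variant tag.
#' @export
write_spectrum_csv <- function(spectrum, path, variant = "") {
  .write_csv_meta(
    data.frame(wavelength_nm = spectrum$lambda_nm,
               intensity_arb = spectrum$intensity),
    path,
    list(bias_V = attr(spectrum, "V_b"), NA_obj = attr(spectrum, "NA_obj"),
         variant = variant, normalization = attr(spectrum, "scale")))
}

#' Read an emission spectrum CSV written by [write_spectrum_csv()]
#' @param path file.
#' @return data.frame(lambda_nm, intensity) with attribute \code{meta}.
#' @export
read_spectrum_csv <- function(path) {
  df <- .read_csv_meta(path)
  if (!all(c("wavelength_nm", "intensity_arb") %in% names(df)))
    stop("spectrum CSV must have columns wavelength_nm, intensity_arb")
  out <- data.frame(lambda_nm = df$wavelength_nm,
                    intensity = df$intensity_arb)
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' Write an H spectrum as two-column CSV (wavelength_nm, H_arb)
#' @param H a \code{liet_hspectrum}.
#' @param path output file.
#' @export
write_h_csv <- function(H, path) {
  .write_csv_meta(data.frame(wavelength_nm = H$lambda_nm, H_arb = H$H),
                  path, list(bias_V = attr(H, "V_b"),
                             normalization = attr(H, "scale")))
}

#' Write / read I-V CSV (columns voltage_V, current_density_A_per_m2)
#' @param iv an \code{iv_curve} or data.frame(V, J).
#' @param path file.
#' @export
write_iv_csv <- function(iv, path) {
  .write_csv_meta(data.frame(voltage_V = iv$V,
                             current_density_A_per_m2 = iv$J),
                  path, list(units = "A_per_m2"))
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  df <- .read_csv_meta(path)
  cur <- intersect(c("current_density_A_per_m2", "current_A"), names(df))
  if (!("voltage_V" %in% names(df)) || length(cur) == 0) {
    bad <- setdiff(c("voltage_V", "current_density_A_per_m2 (or current_A)"),
                   names(df))
    stop("I-V CSV dialect violation: missing column(s) ",
         paste(bad, collapse = ", "))
  }
  nonnum <- which(is.na(df$voltage_V) | is.na(df[[cur[1]]]))
  if (length(nonnum))
    stop("unparseable I-V rows: ", paste(utils::head(nonnum, 10),
                                         collapse = ", "))
  out <- data.frame(V = df$voltage_V, J = df[[cur[1]]])
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Write an angle-resolved map in CSV long format
#' (lambda_nm, theta_deg, G_arb)
#' @param map a \code{liet_angular_map}.
#' @param path file.
#' @export
write_map_csv <- function(map, path) {
  df <- expand.grid(lambda_nm = map$lambda_nm,
                    theta_deg = map$theta_rad * 180 / pi)
  df$G_arb <- as.vector(map$G)
  .write_csv_meta(df, path, list(n_collect = map$n_collect))
}

#' Write a dose-response table CSV
#' @param series result of [analyte_dose_series()].
#' @param path file.
#' @param band,threshold recorded in the header.
#' @export
write_dose_csv <- function(series, path, band = c(620, 700),
                           threshold = "3x noise level") {
  .write_csv_meta(series$responses, path,
                  list(band_nm = paste(band, collapse = "-"),
                       threshold_rule = threshold,
                       noise_level = series$noise_level))
}
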