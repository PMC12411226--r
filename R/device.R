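## Device geometry and detection configuration.
##
## The modelled stack, superstrate to substrate:
##   [optional analyte overlayer] | Au wires (grating) | Cr wires (grating)
##   | Al2O3 tunnelling barrier | Al film | glass.
## The wire mesh's long period along y (>= 100 um) is far larger than the
## wavelength, so the electromagnetic problem is treated as 1D-periodic in x
## and invariant along y.

#' Construct a device specification
#'
#' @param period_x grating period along x, nm.
#' @param wire_width Au/Cr wire width, nm (must be < period_x).
#' @param wire_thickness Au wire thickness, nm.
#' @param adhesion_thickness Cr adhesion-layer thickness, nm (patterned with
#'   the wires).
#' @param barrier_thickness Al2O3 tunnelling-barrier thickness, nm.
#' @param bottom_thickness Al bottom-electrode thickness, nm.
#' @param superstrate,substrate material names (resolved in \code{materials}).
#' @param overlayer optional analyte film: list(material =, thickness_nm =),
#'   or NULL for the bare device.
#' @param materials material database, see [liet_material_db()].
#' @return object of class \code{liet_device}.
#' @export
device_spec <- function(period_x = 400, wire_width = 92,
                        wire_thickness = 50, adhesion_thickness = 5,
                        barrier_thickness = 5, bottom_thickness = 25,
                        superstrate = "air", substrate = "glass",
                        overlayer = NULL,
                        materials = liet_material_db()) {
  thick <- c(wire_thickness, adhesion_thickness, barrier_thickness,
             bottom_thickness)
  if (any(thick <= 0)) stop("all thicknesses must be > 0")
  if (!(wire_width > 0 && wire_width < period_x))
    stop("wire_width must satisfy 0 < wire_width < period_x")
  if (!is.null(overlayer)) {
    stopifnot(is.list(overlayer),
              all(c("material", "thickness_nm") %in% names(overlayer)),
              overlayer$thickness_nm > 0)
  }
  d <- list(period_x = period_x, wire_width = wire_width,
            wire_thickness = wire_thickness,
            adhesion_thickness = adhesion_thickness,
            barrier_thickness = barrier_thickness,
            bottom_thickness = bottom_thickness,
            superstrate = superstrate, substrate = substrate,
            overlayer = overlayer, materials = materials)
  class(d) <- "liet_device"
  d
}

#' @export
print.liet_device <- function(x, ...) {
  cat("<liet_device> period", x$period_x, "nm | wire", x$wire_width, "x",
      x$wire_thickness, "nm Au /", x$adhesion_thickness, "nm Cr | barrier",
      x$barrier_thickness, "nm Al2O3 | Al", x$bottom_thickness, "nm on",
      x$substrate, "\n")
  if (!is.null(x$overlayer))
    cat("  overlayer:", x$overlayer$thickness_nm, "nm",
        x$overlayer$material, "\n")
  invisible(x)
}

#' Construct a detection specification
#'
#' Emission is collected through the glass substrate (inverted-microscope
#' geometry). The polar angle theta is the emission angle used by the
#' solver in the glass half-space and the numerical aperture restricts it
#' to theta_max = asin(NA). This keeps the leakage-radiation branch of the
#' plasmonic lattice mode (beyond the glass/air critical angle) inside the
#' NA = 0.8 collection cone, which is essential to the shape of G(w); see
#' the methods vignette.
#'
#' @param NA_obj objective numerical aperture, in (0, 1].
#' @param lambda_nm wavelength grid, nm.
#' @param n_theta number of polar quadrature nodes between 0 and theta_max.
#' @param n_collect refractive index of the collection-side half-space
#'   (used for in-plane-wavevector conversions).
#' @return object of class \code{liet_detection} with fields \code{NA_obj},
#'   \code{lambda_nm}, \code{theta_max_rad}, \code{n_theta}.
#' @export
detection_spec <- function(NA_obj = 0.8,
                           lambda_nm = seq(500, 950, by = 2.5),
                           n_theta = 13, n_collect = 1.52) {
  if (!(NA_obj > 0 && NA_obj <= 1)) stop("NA must be in (0, 1]")
  stopifnot(all(lambda_nm > 0), !is.unsorted(lambda_nm), n_theta >= 2)
  s <- list(NA_obj = NA_obj, lambda_nm = lambda_nm,
            theta_max_rad = asin(NA_obj),
            n_theta = n_theta, n_collect = n_collect)
  class(s) <- "liet_detection"
  s
}

#' Default device variants
#'
#' \code{characterization}: 92 nm wires, collection NA 0.8 over 500-950 nm.
#' \code{sensing}: 120 nm wires, collection NA 0.3. Both share the 400 nm
#' period and the Au 50 / Cr 5 / Al2O3 5 / Al 25 / glass stack.
#'
#' @param variant "characterization" or "sensing".
#' @param materials material database.
#' @return list with elements \code{device} and \code{detection}.
#' @export
#' @examples
#' d <- default_device("characterization")
#' d$device$wire_width   # 92
default_device <- function(variant = c("characterization", "sensing"),
                           materials = liet_material_db()) {
  variant <- match.arg(variant)
  if (variant == "characterization") {
    list(device = device_spec(wire_width = 92, materials = materials),
         detection = detection_spec(NA_obj = 0.8),
         variant = variant)
  } else {
    list(device = device_spec(wire_width = 120, materials = materials),
         detection = detection_spec(NA_obj = 0.3),
         variant = variant)
  }
}

# --- configuration file I/O ---------------------------------------------

.device_config_keys <- c("period_x", "wire_width", "wire_thickness",
                         "adhesion_thickness", "barrier_thickness",
                         "bottom_thickness", "superstrate", "substrate",
                         "overlayer", "analyte_n")
.detection_config_keys <- c("NA_obj", "lambda_min", "lambda_max",
                            "lambda_step", "n_theta", "n_collect")

#' Write device + detection configuration to JSON
#'
#' @param device a \code{liet_device}.
#' @param detection a \code{liet_detection}.
#' @param path output file.
#' @export
write_device_config <- function(device, detection, path) {
  lam <- detection$lambda_nm
  cfg <- list(
    device = list(
      period_x = device$period_x, wire_width = device$wire_width,
      wire_thickness = device$wire_thickness,
      adhesion_thickness = device$adhesion_thickness,
      barrier_thickness = device$barrier_thickness,
      bottom_thickness = device$bottom_thickness,
      superstrate = device$superstrate, substrate = device$substrate,
      overlayer = device$overlayer
    ),
    detection = list(
      NA_obj = detection$NA_obj,
      lambda_min = min(lam), lambda_max = max(lam),
      lambda_step = if (length(lam) > 1) lam[2] - lam[1] else 1,
      n_theta = detection$n_theta, n_collect = detection$n_collect
    )
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a device + detection configuration written by
#' [write_device_config()]
#'
#' Unknown keys are rejected (schema validation).
#'
#' @param path JSON file.
#' @param materials material database.
#' @return list(device =, detection =).
#' @export
read_device_config <- function(path, materials = liet_material_db()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("device", "detection") %in% names(cfg)))
    stop("config must contain 'device' and 'detection' sections")
  bad <- setdiff(names(cfg$device), .device_config_keys)
  if (length(bad)) stop("unknown device config key(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$detection), .detection_config_keys)
  if (length(bad)) stop("unknown detection config key(s): ",
                        paste(bad, collapse = ", "))
  dv <- cfg$device
  # JSON round-trip returns whole numbers as integers; the contract is
  # field-for-field identity, so restore doubles
  for (k in names(dv)) if (is.numeric(dv[[k]])) dv[[k]] <- as.numeric(dv[[k]])
  ov <- dv$overlayer
  if (!is.null(ov) && (is.list(ov) && length(ov) == 0)) ov <- NULL
  if (!is.null(ov)) ov <- list(material = ov$material,
                               thickness_nm = ov$thickness_nm)
  device <- device_spec(period_x = dv$period_x, wire_width = dv$wire_width,
                        wire_thickness = dv$wire_thickness,
                        adhesion_thickness = dv$adhesion_thickness,
                        barrier_thickness = dv$barrier_thickness,
                        bottom_thickness = dv$bottom_thickness,
                        superstrate = dv$superstrate,
                        substrate = dv$substrate,
                        overlayer = ov, materials = materials)
  if (!is.null(ov) && is.numeric(ov$thickness_nm))
    ov$thickness_nm <- as.numeric(ov$thickness_nm)
  dt <- cfg$detection
  for (k in names(dt)) if (is.numeric(dt[[k]])) dt[[k]] <- as.numeric(dt[[k]])
  detection <- detection_spec(NA_obj = dt$NA_obj,
                              lambda_nm = seq(dt$lambda_min, dt$lambda_max,
                                              by = dt$lambda_step),
                              n_theta = dt$n_theta,
                              n_collect = dt$n_collect)
  list(device = device, detection = detection)
}
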