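#' Plane-strain stiffness constants from engineering constants
#'
#' Converts Young's modulus and Poisson's ratio to the isotropic
#' plane-strain stiffnesses used by the elastodynamic solver:
#' `c11 = lambda + 2 mu`, `c12 = lambda`, `c33 = mu`, with
#' `lambda = E*sigma/((1+sigma)(1-2 sigma))` and `mu = E/(2(1+sigma))`.
#' For isotropic media `c22 = c11`.
#'
#' @param E Young's modulus, Pa. Must be positive.
#' @param sigma Poisson's ratio, dimensionless, in `[0, 0.5)`.
#' @return Named numeric vector with elements `c11`, `c12`, `c33` (Pa).
#' @examples
#' stiffness_constants(1e9, 0)        # c(1e9, 0, 5e8)
#' @export
stiffness_constants <- function(E, sigma) {
  check_elastic(E, sigma)
  lambda <- E * sigma / ((1 + sigma) * (1 - 2 * sigma))
  mu <- E / (2 * (1 + sigma))
  c(c11 = lambda + 2 * mu, c12 = lambda, c33 = mu)
}

#' Longitudinal (P-wave) velocity of a bulk isotropic solid
#'
#' `sqrt(E (1-sigma) / (rho (1+sigma)(1-2 sigma)))`, equivalently
#' `sqrt(c11/rho)`.
#'
#' @inheritParams stiffness_constants
#' @param rho mass density, kg/m^3. Must be positive.
#' @return velocity in m/s.
#' @examples
#' longitudinal_velocity(15e9, 0.37, 1970)   # cortical bone, ~3669.74
#' @export
longitudinal_velocity <- function(E, sigma, rho) {
  check_elastic(E, sigma)
  if (!is.numeric(rho) || any(rho <= 0)) stop("rho must be positive")
  sqrt(E * (1 - sigma) / (rho * (1 + sigma) * (1 - 2 * sigma)))
}

#' Specific acoustic impedance
#'
#' @param rho density, kg/m^3 (non-negative).
#' @param c_l longitudinal velocity, m/s (non-negative).
#' @return impedance `rho * c_l` in kg m^-2 s^-1.
#' @seealso [format_impedance()] for the conventional 1e5-scaled display.
#' @export
acoustic_impedance <- function(rho, c_l) {
  if (any(rho < 0) || any(c_l < 0)) stop("rho and c_l must be non-negative")
  rho * c_l
}

#' Impedance on the conventional printed scale (x 1e-5)
#' @param z impedance in kg m^-2 s^-1
#' @return `z / 1e5`
#' @export
format_impedance <- function(z) z / 1e5

check_elastic <- function(E, sigma) {
  if (!is.numeric(E) || any(E <= 0)) stop("E must be positive")
  if (!is.numeric(sigma) || any(sigma < 0) || any(sigma >= 0.5))
    stop("sigma must satisfy 0 <= sigma < 0.5")
  invisible(TRUE)
}

#' Construct a tissue description
#'
#' Bundles one material's engineering constants with the derived
#' wave-propagation constants. Internally everything is SI; Young's
#' modulus is taken in Pa.
#'
#' @param name label for the material.
#' @param E Young's modulus, Pa.
#' @param sigma Poisson's ratio in `[0, 0.5)`.
#' @param rho density, kg/m^3.
#' @return An object of class `tissue`: a list with `name`, `E`, `sigma`,
#'   `rho`, `c11`, `c12`, `c33` (Pa), `c_l` (m/s) and `z` (kg m^-2 s^-1).
#' @export
tissue_properties <- function(name, E, sigma, rho) {
  cc <- stiffness_constants(E, sigma)
  if (rho <= 0) stop("rho must be positive")
  c_l <- sqrt(cc[["c11"]] / rho)
  structure(
    list(name = name, E = E, sigma = sigma, rho = rho,
         c11 = cc[["c11"]], c12 = cc[["c12"]], c33 = cc[["c33"]],
         c_l = c_l, z = rho * c_l),
    class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("<tissue> %s: E=%.4g Pa, sigma=%.6g, rho=%g kg/m3, c_l=%.2f m/s, Z=%.2f x1e5\n",
              x$name, x$E, x$sigma, x$rho, x$c_l, x$z / 1e5))
  invisible(x)
}

# Canonical five-tissue table. E printed in GPa; printed_cl / printed_z are
# the published reference values the derived constants are checked against.
.tissue_rows <- function() {
  data.frame(
    name = c("skin", "fat", "muscle", "bone marrow", "cortical bone"),
    E_gpa = c(0.000035, 0.000035, 0.000012, 0.002, 15),
    sigma = c(0.499998, 0.499997, 0.4999993, 0.49985, 0.37),
    rho = c(1050, 1940, 1040, 1020, 1970),
    printed_cl = c(1666.67, 1462.84, 1657.48, 1476.32, 3669.74),
    printed_z = c(17.50, 13.75, 17.24, 15.06, 72.29),
    stringsAsFactors = FALSE)
}

#' Built-in five-tissue material table
#'
#' Returns skin, fat, muscle, bone marrow and cortical bone with derived
#' stiffness, longitudinal velocity and impedance. For four of the five
#' tissues the derived velocity and impedance reproduce the published
#' reference values from (E, sigma, rho); the fat row does not: its
#' published density (1940 kg/m^3) is incompatible with its published
#' velocity and impedance, which together imply a density of 940 kg/m^3.
#'
#' @param variant `"verbatim"` keeps every published value as printed;
#'   `"reconciled"` (the simulation default) substitutes `rho = 940` for
#'   fat so that its impedance is close to the published Z column, which
#'   governs interface reflections. The inconsistency flag is retained in
#'   both variants.
#' @return A data frame of class `tissue_table`, one row per tissue, with
#'   columns `name`, `E_gpa`, `sigma`, `rho`, `c11`, `c12`, `c33`, `c_l`,
#'   `z`, `printed_cl`, `printed_z`, `consistent`.
#' @examples
#' tissue_table()
#' @export
tissue_table <- function(variant = c("reconciled", "verbatim")) {
  variant <- match.arg(variant)
  tab <- .tissue_rows()
  if (variant == "reconciled") tab$rho[tab$name == "fat"] <- 940
  E <- tab$E_gpa * 1e9
  cc <- mapply(stiffness_constants, E, tab$sigma)
  tab$c11 <- cc["c11", ]
  tab$c12 <- cc["c12", ]
  tab$c33 <- cc["c33", ]
  tab$c_l <- sqrt(tab$c11 / tab$rho)
  tab$z <- tab$rho * tab$c_l
  tab$consistent <- abs(tab$c_l - tab$printed_cl) <= 0.05 &
    abs(tab$z / 1e5 - tab$printed_z) <= 0.01
  attr(tab, "variant") <- variant
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Consistency report for a material table
#'
#' Re-derives velocity and impedance from (E, sigma, rho) for every row
#' and compares them with the table's reference columns.
#'
#' @param tab a `tissue_table` (default: the verbatim built-in table).
#' @return data frame with per-row derived values, absolute deviations and
#'   a `consistent` flag.
#' @export
table_consistency <- function(tab = tissue_table("verbatim")) {
  data.frame(
    name = tab$name,
    derived_cl = tab$c_l,
    printed_cl = tab$printed_cl,
    dev_cl = abs(tab$c_l - tab$printed_cl),
    derived_z1e5 = tab$z / 1e5,
    printed_z = tab$printed_z,
    dev_z = abs(tab$z / 1e5 - tab$printed_z),
    consistent = tab$consistent,
    stringsAsFactors = FALSE)
}

#' Read / write material tables as delimited text
#'
#' The on-disk format is TSV with columns `name`, `E_gpa`, `sigma`, `rho`;
#' derived constants are recomputed on read so files stay minimal.
#'
#' @param path file path.
#' @return `read_materials` returns a `tissue_table`-like data frame.
#' @export
read_materials <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "E_gpa", "sigma", "rho")
  if (!all(need %in% names(raw))) stop("materials file needs columns: ",
                                       paste(need, collapse = ", "))
  E <- raw$E_gpa * 1e9
  cc <- mapply(stiffness_constants, E, raw$sigma)
  raw$c11 <- cc["c11", ]; raw$c12 <- cc["c12", ]; raw$c33 <- cc["c33", ]
  raw$c_l <- sqrt(raw$c11 / raw$rho)
  raw$z <- raw$rho * raw$c_l
  class(raw) <- c("tissue_table", "data.frame")
  raw
}

#' @rdname read_materials
#' @param tab material table to write.
#' @export
write_materials <- function(tab, path) {
  utils::write.table(tab[, c("name", "E_gpa", "sigma", "rho")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
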