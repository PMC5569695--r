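# 3-2-2-2 nine-accelerometer array geometry.
#
# The array is a central triax (three orthogonal uniaxial accelerometers at
# the array centre) plus three dual-accelerometer arms along the anatomical
# x, y and z axes. The arm-tip sensing axes are exactly the ones the
# nine-accelerometer (Padgaonkar) transform needs:
#   x-arm: senses y and z;  y-arm: senses x and z;  z-arm: senses x and y.

#' Construct a 3-2-2-2 nine-accelerometer array geometry
#'
#' Positions are expressed in the head-fixed anatomical frame with the origin
#' at the head centre of mass; by default the array centre coincides with the
#' origin. Arm offsets are the distances from the array centre to the arm-tip
#' accelerometer pairs.
#'
#' @param rho Numeric length-3 vector of strictly positive arm offsets
#'   (metres) along the x, y and z axes.
#' @param center Numeric length-3 position of the array centre (metres).
#' @return An object of class `nap_geometry`: a list with `center`, `rho` and
#'   a nine-row `sensors` data frame (`channel`, `label`, `arm`, `axis`,
#'   position `px/py/pz`, unit sensing axis `nx/ny/nz`).
#' @examples
#' geom <- nap_geometry()
#' geom$sensors
#' @export
nap_geometry <- function(rho = c(0.05, 0.05, 0.05), center = c(0, 0, 0)) {
  rho <- as.numeric(rho)
  center <- as.numeric(center)
  axes <- diag(3)
  rownames(axes) <- colnames(axes) <- c("x", "y", "z")
  # arm label, sensing axis, arm direction ("c" = array centre)
  plan <- data.frame(
    arm  = c("c", "c", "c", "x", "x", "y", "y", "z", "z"),
    axis = c("x", "y", "z", "y", "z", "x", "z", "x", "y"),
    stringsAsFactors = FALSE
  )
  pos <- t(vapply(seq_len(9), function(i) {
    if (plan$arm[i] == "c") center else center + rho[match(plan$arm[i], c("x", "y", "z"))] * axes[plan$arm[i], ]
  }, numeric(3)))
  n <- t(vapply(seq_len(9), function(i) axes[plan$axis[i], ], numeric(3)))
  sensors <- data.frame(
    channel = seq_len(9),
    label = paste0(ifelse(plan$arm == "c", "c", plan$arm), plan$axis),
    arm = plan$arm, axis = plan$axis,
    px = pos[, 1], py = pos[, 2], pz = pos[, 3],
    nx = n[, 1], ny = n[, 2], nz = n[, 3],
    stringsAsFactors = FALSE
  )
  geom <- structure(list(center = center, rho = rho, sensors = sensors),
                    class = "nap_geometry")
  validate_nap_geometry(geom)
  geom
}

#' Validate a 3-2-2-2 array geometry
#'
#' Checks the structural invariants the nine-accelerometer transform relies
#' on: exactly nine sensors, a full central triax, the three arm pairs with
#' the required sensing axes, strictly positive arm offsets, unit-norm
#' sensing axes and arm-tip positions consistent with the stated offsets.
#'
#' @param geom A `nap_geometry` object.
#' @return `geom`, invisibly, if valid; otherwise an error naming the first
#'   missing or inconsistent channel.
#' @export
validate_nap_geometry <- function(geom) {
  if (!inherits(geom, "nap_geometry")) stop("not a nap_geometry object")
  s <- geom$sensors
  if (nrow(s) != 9L) stop("geometry must contain exactly 9 accelerometers, found ", nrow(s))
  if (any(!is.finite(geom$rho)) || any(geom$rho <= 0)) {
    stop("arm offsets rho must be strictly positive")
  }
  need <- c("cx", "cy", "cz", "xy", "xz", "yx", "yz", "zx", "zy")
  missing <- setdiff(need, s$label)
  if (length(missing)) {
    stop("geometry missing channel(s): ", paste(missing, collapse = ", "))
  }
  nmat <- as.matrix(s[, c("nx", "ny", "nz")])
  norms <- sqrt(rowSums(nmat^2))
  bad <- which(abs(norms - 1) > 1e-12)
  if (length(bad)) {
    stop("sensing axis of channel ", s$label[bad[1]], " is not unit norm")
  }
  axes <- diag(3); rownames(axes) <- c("x", "y", "z")
  for (i in seq_len(9)) {
    expected <- if (s$arm[i] == "c") geom$center else {
      geom$center + geom$rho[match(s$arm[i], c("x", "y", "z"))] * axes[s$arm[i], ]
    }
    if (max(abs(c(s$px[i], s$py[i], s$pz[i]) - expected)) > 1e-9) {
      stop("channel ", s$label[i], " position inconsistent with arm offsets")
    }
  }
  invisible(geom)
}

#' Write an array geometry to JSON
#'
#' @param geom A `nap_geometry` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geom, path) {
  validate_nap_geometry(geom)
  obj <- list(units = "m", center = geom$center, rho = geom$rho,
              sensors = geom$sensors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an array geometry from JSON
#'
#' @param path Path to a geometry JSON file written by
#'   [write_geometry_json()].
#' @return A validated `nap_geometry` object.
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- structure(list(center = as.numeric(obj$center),
                         rho = as.numeric(obj$rho),
                         sensors = as.data.frame(obj$sensors)),
                    class = "nap_geometry")
  validate_nap_geometry(geom)
  geom
}
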