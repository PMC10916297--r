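#' Scattering-vector magnitude 1/d for pixel positions
#'
#' Converts continuous pixel coordinates on the panel to the magnitude of the
#' scattering vector, \eqn{1/d = 2 \sin\theta / \lambda}, with
#' \eqn{2\theta = \arctan(r / D)} for a pixel at radial distance r (meters)
#' from the beam center and detector distance D.
#'
#' @param geometry a [GeometryModel-class].
#' @param fastPos,slowPos continuous pixel coordinates (pixel centers at
#'   integers, counting from 0). Vectors are recycled together.
#' @return 1/d in 1/Angstrom, same length as the inputs.
#' @examples
#' geo <- geometryModel(128, 128, 200e-6, 0.08)
#' pixelInvD(geo, 0, 0)        # panel corner
#' pixelInvD(geo, 63.5, 63.5)  # beam center -> 0
#' @export
pixelInvD <- function(geometry, fastPos, slowPos) {
  r <- sqrt((fastPos - geometry@beamCenterFast)^2 +
            (slowPos - geometry@beamCenterSlow)^2) * geometry@pixelSize
  theta <- 0.5 * atan2(r, geometry@detectorDistance)
  2 * sin(theta) / wavelengthAngstrom(geometry)
}

#' Largest 1/d reachable on the panel (its farthest corner)
#' @param geometry a [GeometryModel-class].
#' @return 1/d in 1/Angstrom at the panel corner farthest from the beam center.
#' @export
maxInvD <- function(geometry) {
  corners <- expand.grid(fast = c(-0.5, geometry@nFast - 0.5),
                         slow = c(-0.5, geometry@nSlow - 0.5))
  max(pixelInvD(geometry, corners$fast, corners$slow))
}

## radial pixel distance (pixels) from the beam center, full panel
.radiusMatrix <- function(geometry) {
  f <- (seq_len(geometry@nFast) - 1) - geometry@beamCenterFast
  s <- (seq_len(geometry@nSlow) - 1) - geometry@beamCenterSlow
  sqrt(outer(s^2, f^2, "+"))
}
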