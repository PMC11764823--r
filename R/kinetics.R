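#' Derive the seven kinetic variables from raw triaxial samples
#'
#' Augments raw accelerometer samples with the four derived channels used
#' throughout the pipeline:
#' \itemize{
#'   \item pitch (rad): \code{atan2(y, sqrt(x^2 + z^2))}, the tilt of the
#'     device about its x-axis, in [-pi/2, pi/2];
#'   \item roll (rad): \code{atan2(-x, z)}, the rotation about the y-axis,
#'     in (-pi, pi];
#'   \item power (milli-G): the Euclidean norm of the acceleration vector;
#'   \item total energy (milli-G): \code{sqrt(|power^2 - G^2|)} with
#'     G = 1000 milli-G — the movement magnitude purged of gravity. The
#'     absolute value means sub-1G power yields a positive energy rather
#'     than an error.
#' }
#' Together with the pass-through x/y/z axes these are the seven kinetic
#' variables (see \code{\link{kinetic_variables}}).
#'
#' A resting watch reading (0, 0, 1000) milli-G gives pitch 0, roll 0,
#' power 1000 and total energy 0.
#'
#' @param raw Data frame with numeric columns \code{x_mG}, \code{y_mG},
#'   \code{z_mG} (milli-G). Other columns are preserved.
#' @return The input with columns \code{pitch_rad}, \code{roll_rad},
#'   \code{power_mG}, \code{total_energy_mG} appended.
#' @details An all-zero sample (physically impossible for a gravity-loaded
#'   sensor) is mapped to pitch 0, roll 0 by the \code{atan2(0, 0) = 0}
#'   convention and counted in a warning, rather than poisoning the stream.
#'   Non-finite inputs are rejected with the offending row positions.
#' @examples
#' derive_kinetics(data.frame(x_mG = 0, y_mG = 0, z_mG = 1000))
#' @export
derive_kinetics <- function(raw) {
  need <- c("x_mG", "y_mG", "z_mG")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("raw samples lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- raw$x_mG; y <- raw$y_mG; z <- raw$z_mG
  bad <- !(is.finite(x) & is.finite(y) & is.finite(z))
  if (any(bad)) {
    stop("non-finite acceleration at stream position(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  degenerate <- x == 0 & y == 0 & z == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " all-zero sample(s); pitch/roll set to 0 ",
            "by convention")
  }
  raw$pitch_rad <- atan2(y, sqrt(x^2 + z^2))
  raw$roll_rad <- atan2(-x, z)
  raw$power_mG <- sqrt(x^2 + y^2 + z^2)
  raw$total_energy_mG <- sqrt(abs(raw$power_mG^2 - .G_MG^2))
  raw
}
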