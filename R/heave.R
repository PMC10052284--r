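#' Sinusoidal ship-heave specification
#'
#' The deck of the ship moves with a purely sinusoidal heave
#' `z_ship(t) = A * sin(phase + 2*pi*f*t)` about its mean plane. `phase` is
#' the heave phase at the reference time `t = 0`, taken throughout the
#' package to be the onset of the helicopter's descent.
#'
#' @param amplitude Heave amplitude A in metres (>= 0). Default 2.5 m,
#'   a moderate sea state for a light frigate.
#' @param frequency Heave frequency f in hertz (> 0). Default 0.14 Hz.
#' @param phase Phase in radians at `t = 0`; stored modulo 2*pi.
#' @return An object of class `heave_spec`.
#' @examples
#' h <- heave_spec(phase = pi / 2)
#' heave_state(h, 0) # deck at its crest, momentarily at rest
#' @export
heave_spec <- function(amplitude = 2.5, frequency = 0.14, phase = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, is.finite(amplitude),
            is.numeric(frequency), length(frequency) == 1, is.finite(frequency),
            is.numeric(phase), length(phase) == 1, is.finite(phase))
  if (amplitude < 0) stop("heave amplitude must be >= 0")
  if (frequency <= 0) stop("heave frequency must be > 0")
  structure(
    list(amplitude = amplitude, frequency = frequency,
         phase = phase %% (2 * pi)),
    class = "heave_spec"
  )
}

#' @export
print.heave_spec <- function(x, ...) {
  cat(sprintf("<heave_spec> A = %g m, f = %g Hz, phase = %.4f rad\n",
              x$amplitude, x$frequency, x$phase))
  invisible(x)
}

#' Deck position and velocity at a given time
#'
#' @param heave A [heave_spec()].
#' @param t Time(s) in seconds from the phase reference (descent onset).
#' @return A list with numeric vectors `position` (m, up-positive, relative
#'   to the deck's mean plane) and `velocity` (m/s).
#' @examples
#' heave_state(heave_spec(), 1 / 0.14)$position # one full period later
#' @export
heave_state <- function(heave, t) {
  stopifnot(inherits(heave, "heave_spec"), is.numeric(t))
  w <- 2 * pi * heave$frequency
  arg <- heave$phase + w * t
  list(position = heave$amplitude * sin(arg),
       velocity = heave$amplitude * w * cos(arg))
}

heave_position <- function(heave, t) {
  heave$amplitude * sin(heave$phase + 2 * pi * heave$frequency * t)
}

heave_velocity <- function(heave, t) {
  w <- 2 * pi * heave$frequency
  heave$amplitude * w * cos(heave$phase + w * t)
}
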