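#' Generate dot-field stimulus kinematics
#'
#' Simulates the optokinetic roll stimulus: 1000 randomly placed dots
#' rotating in the roll plane at the design's rotation speed. In the
#' coherent condition every dot advances rigidly at exactly that speed. In
#' the incoherent condition each dot follows its circular trajectory plus
#' a sinusoidal perturbation of its polar angle and radius whose phase,
#' amplitude and frequency are randomized separately per dot, so that
#' individual trajectories look random while the global pattern keeps the
#' designed mean angular velocity.
#'
#' Clockwise rotation is mapped to negative angular velocity,
#' counter-clockwise to positive (see [rotation_sign()]).
#'
#' @param condition `"coherent"` or `"incoherent"`.
#' @param direction `"CW"` or `"CCW"`.
#' @param duration Stimulus duration in seconds (> 0).
#' @param design An [experiment_design()] (supplies the rotation speed).
#' @param seed Optional integer seed.
#' @param n_dots Number of dots.
#' @param frame_rate Frames per second.
#' @return An object of class `dot_kinematics`: `angular_position` and
#'   `radial_position` are `n_dots x n_frames` matrices (degrees wrapped
#'   to \[0, 360) and unit-disc radius), plus `frame_rate`,
#'   `global_direction`, `condition`.
#' @examples
#' dk <- generate_dot_stimulus("coherent", "CW", 2, seed = 1, n_dots = 10)
#' mean_angular_velocity(dk)  # exactly -30
#' @export
generate_dot_stimulus <- function(condition = c("coherent", "incoherent"),
                                  direction = c("CW", "CCW"),
                                  duration,
                                  design = experiment_design(),
                                  seed = NULL,
                                  n_dots = 1000L,
                                  frame_rate = 60) {
  condition <- match.arg(condition)
  direction <- match.arg(direction)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a positive number of seconds", call. = FALSE)
  }
  stopifnot(n_dots >= 1, frame_rate > 0)
  if (!is.null(seed)) set.seed(seed)

  n_frames <- as.integer(round(duration * frame_rate)) + 1L
  t <- (seq_len(n_frames) - 1L) / frame_rate
  s <- rotation_sign(direction)
  omega <- s * design$rotation_speed

  theta0 <- stats::runif(n_dots, 0, 360)
  r0 <- sqrt(stats::runif(n_dots, 0.01, 1))  # uniform over the disc area

  base <- outer(theta0, rep(1, n_frames)) +
    outer(rep(omega, n_dots), t, function(w, tt) w * tt)

  if (condition == "incoherent") {
    amp <- stats::runif(n_dots, 2, 10)        # deg
    freq <- stats::runif(n_dots, 0.2, 1)      # Hz
    phase <- stats::runif(n_dots, 0, 2 * pi)
    ramp <- stats::runif(n_dots, 0.01, 0.05)  # radius units
    rfreq <- stats::runif(n_dots, 0.2, 1)
    rphase <- stats::runif(n_dots, 0, 2 * pi)
    wob <- amp * sin(2 * pi * outer(freq, t) + phase)
    theta <- base + wob
    radius <- pmin(1, pmax(0.02,
      r0 + ramp * sin(2 * pi * outer(rfreq, t) + rphase)))
  } else {
    theta <- base
    radius <- matrix(r0, n_dots, n_frames)
  }

  structure(
    list(n_dots = as.integer(n_dots),
         frame_rate = frame_rate,
         angular_position = theta %% 360,
         radial_position = radius,
         global_direction = direction,
         condition = condition),
    class = "dot_kinematics"
  )
}

#' Sign convention for rotation directions
#'
#' Clockwise (CW) maps to -1, counter-clockwise (CCW) to +1.
#'
#' @param direction `"CW"` or `"CCW"`.
#' @return -1 or +1.
#' @export
rotation_sign <- function(direction) {
  stopifnot(direction %in% c("CW", "CCW"))
  ifelse(direction == "CW", -1, 1)
}

#' Mean global angular velocity of a dot stimulus
#'
#' Unwraps each dot's frame-to-frame angular steps (steps are far below
#' 180 deg/frame at any sane frame rate), averages each dot's velocity
#' over the trial, and averages across dots.
#'
#' @param dk A `dot_kinematics` object.
#' @return Scalar mean angular velocity in deg/s (signed; CW negative).
#' @export
mean_angular_velocity <- function(dk) {
  stopifnot(inherits(dk, "dot_kinematics"))
  th <- dk$angular_position
  step <- th[, -1L, drop = FALSE] - th[, -ncol(th), drop = FALSE]
  step <- (step + 180) %% 360 - 180
  per_dot <- rowSums(step) / ((ncol(th) - 1L) / dk$frame_rate)
  mean(per_dot)
}

#' Export dot kinematics as CSV
#'
#' Long format: one row per (frame, dot) with the wrapped polar angle and
#' radius.
#'
#' @param dk A `dot_kinematics` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot_kinematics_csv <- function(dk, path) {
  stopifnot(inherits(dk, "dot_kinematics"))
  n_frames <- ncol(dk$angular_position)
  out <- data.frame(
    frame = rep(seq_len(n_frames) - 1L, each = dk$n_dots),
    dot = rep(seq_len(dk$n_dots), n_frames),
    angle_deg = as.vector(dk$angular_position),
    radius = as.vector(dk$radial_position)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
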