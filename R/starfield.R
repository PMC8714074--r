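# Starfield stimulus geometry and per-frame stimulus composition.
#
# The stimulus is a 3-D cloud of small spheres in a cube centred on the
# animal, projected onto a flat screen in front of it. Roll rotates the cloud
# about the body axis (perpendicular to the screen); lift translates it
# vertically. The analysis pipeline consumes only the per-frame stimulus
# trace (impulse signs and increments); pixel rendering is for inspection.
#
# Coordinate frame: x right, y up, z toward the screen (metres).
# Counter-clockwise roll on the screen (positive roll here) is excitatory
# for a neuron with a left-side receptive field.

#' Screen geometry of the stimulus display
#'
#' @param view_distance_cm Eye-to-screen distance (cm, default 6.5).
#' @param pixel_width,pixel_height Screen resolution (default 2560 x 1440).
#' @param azimuth_deg,elevation_deg Angular extent subtended by the screen
#'   (default 155 x 138 deg).
#' @param frame_rate_hz Display refresh rate (Hz, default 165).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(view_distance_cm = 6.5,
                            pixel_width = 2560L, pixel_height = 1440L,
                            azimuth_deg = 155, elevation_deg = 138,
                            frame_rate_hz = 165) {
  stopifnot(view_distance_cm > 0, pixel_width > 0, pixel_height > 0,
            azimuth_deg > 0, azimuth_deg < 180,
            elevation_deg > 0, elevation_deg < 180,
            frame_rate_hz > 0)
  structure(list(
    view_distance_cm = view_distance_cm,
    pixel_width = as.integer(pixel_width),
    pixel_height = as.integer(pixel_height),
    azimuth_deg = azimuth_deg,
    elevation_deg = elevation_deg,
    frame_rate_hz = frame_rate_hz,
    # physical half-extent of the screen plane (cm), from the angular extent
    half_width_cm = view_distance_cm * tan(azimuth_deg / 2 * pi / 180),
    half_height_cm = view_distance_cm * tan(elevation_deg / 2 * pi / 180)
  ), class = "screen_geometry")
}

#' Build a random starfield world
#'
#' Places `round(density * cube_side^3)` spheres uniformly inside a cube
#' centred on the observer (6400 spheres at the defaults). Positions are
#' drawn from R's global RNG stream.
#'
#' @param cube_side_m Cube side length (m, default 4).
#' @param density_per_m3 Sphere density (spheres per cubic metre, default 100).
#' @param sphere_diameter_cm Sphere diameter (cm, default 2).
#' @return An object of class `starfield_world` with an `n x 3` `positions`
#'   matrix (metres; columns x, y, z).
#' @export
make_world <- function(cube_side_m = 4, density_per_m3 = 100,
                       sphere_diameter_cm = 2) {
  if (cube_side_m <= 0 || sphere_diameter_cm <= 0 || density_per_m3 < 0)
    stop("world parameters must be positive (density may be zero)", call. = FALSE)
  n <- round(density_per_m3 * cube_side_m^3)
  pos <- matrix(stats::runif(3 * n, -cube_side_m / 2, cube_side_m / 2),
                ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  structure(list(
    cube_side_m = cube_side_m,
    density_per_m3 = density_per_m3,
    sphere_diameter_cm = sphere_diameter_cm,
    positions = pos
  ), class = "starfield_world")
}

#' Apply one frame of roll and lift to a starfield world
#'
#' Roll rotates every sphere about the z (body/viewing) axis,
#' counter-clockwise on the screen for positive angles; lift translates
#' spheres downward on the screen (negative y) for positive values, which is
#' the excitatory lift direction. Roll is applied before lift. Positions are
#' wrapped modulo the cube so the density stays stationary over a trial.
#'
#' @param world A `starfield_world`.
#' @param roll_deg Roll increment (degrees, signed).
#' @param lift_cm Lift increment (cm, signed; positive moves spheres down).
#' @return The transformed `starfield_world`.
#' @export
transform_world <- function(world, roll_deg = 0, lift_cm = 0) {
  stopifnot(is.finite(roll_deg), is.finite(lift_cm))
  p <- world$positions
  if (roll_deg != 0) {
    th <- roll_deg * pi / 180
    x <- p[, 1] * cos(th) - p[, 2] * sin(th)
    y <- p[, 1] * sin(th) + p[, 2] * cos(th)
    p[, 1] <- x
    p[, 2] <- y
  }
  if (lift_cm != 0)
    p[, 2] <- p[, 2] - lift_cm / 100
  s <- world$cube_side_m
  # wrap into [-s/2, s/2)
  p <- ((p + s / 2) %% s) - s / 2
  world$positions <- p
  world
}

# Rendering limits: spheres closer than 6 cm are not drawn; at 2 m they are
# white on the white background, hence invisible, so they are not drawn
# either. Brightness interpolates linearly between black at 6 cm and white
# at 2 m.
.render_near_cm <- 6
.render_far_cm <- 200

#' Project a sphere onto the screen
#'
#' Gnomonic (planar) projection onto the screen plane at the viewing
#' distance. Returns `NULL` for spheres behind the animal (`z <= 0`), closer
#' than 6 cm, farther than 2 m (white on the white background), or whose
#' centre projects outside the pixel raster.
#'
#' @param position Numeric length-3 position (m; x right, y up, z toward
#'   screen).
#' @param screen A `screen_geometry`.
#' @param world A `starfield_world` (supplies the sphere diameter).
#' @return A list (`center_px`, `diameter_px`, `gray` with 0 = black,
#'   1 = white) or `NULL` when the sphere is not rendered.
#' @export
project_sphere <- function(position, screen, world) {
  x <- position[1] * 100  # cm
  y <- position[2] * 100
  z <- position[3] * 100
  if (z <= 0) return(NULL)
  d <- sqrt(x^2 + y^2 + z^2)
  if (d < .render_near_cm || d > .render_far_cm) return(NULL)
  D <- screen$view_distance_cm
  sx <- D * x / z
  sy <- D * y / z
  if (abs(sx) > screen$half_width_cm || abs(sy) > screen$half_height_cm)
    return(NULL)
  scale_x <- screen$pixel_width / (2 * screen$half_width_cm)   # px per cm
  scale_y <- screen$pixel_height / (2 * screen$half_height_cm)
  cx <- screen$pixel_width / 2 + sx * scale_x
  cy <- screen$pixel_height / 2 - sy * scale_y
  gray <- (d - .render_near_cm) / (.render_far_cm - .render_near_cm)
  gray <- min(max(gray, 0), 1)
  # apparent size ~ sphere diameter scaled by viewing distance over range
  diameter_px <- world$sphere_diameter_cm * D / d * scale_x
  list(center_px = c(cx, cy), diameter_px = diameter_px, gray = gray)
}

#' Count rendered spheres
#'
#' Number of spheres in the world for which [project_sphere()] produces a
#' circle. At the default geometry roughly 1200 of the 6400 spheres fall in
#' the rendered anterior region.
#'
#' @param world A `starfield_world`.
#' @param screen A `screen_geometry`.
#' @return Integer count.
#' @export
count_rendered <- function(world, screen = screen_geometry()) {
  p <- world$positions
  if (nrow(p) == 0L) return(0L)
  x <- p[, 1] * 100; y <- p[, 2] * 100; z <- p[, 3] * 100
  d <- sqrt(x^2 + y^2 + z^2)
  D <- screen$view_distance_cm
  ok <- z > 0 & d >= .render_near_cm & d <= .render_far_cm &
    abs(D * x / z) <= screen$half_width_cm &
    abs(D * y / z) <= screen$half_height_cm
  sum(ok)
}

#' Define a flow condition
#'
#' A condition is a base m-sequence impulse size plus optional constant roll
#' and/or lift. Positive constant roll is excitatory (counter-clockwise on
#' screen for a left-field neuron); positive constant lift is excitatory
#' (spheres moving down on screen).
#'
#' @param base_impulse_deg Rotation per m-sequence impulse (deg; the protocol
#'   used 0.18, 0.33 and 0.48).
#' @param constant_roll_dps Added constant roll velocity (deg/s, signed).
#' @param constant_lift_cmps Added constant lift velocity (cm/s, signed).
#' @param label Condition label; defaults to a systematic name such as
#'   `"roll33"`, `"roll33_er50"` or `"roll33_lift-50"`.
#' @return An object of class `flow_condition`.
#' @export
flow_condition <- function(base_impulse_deg, constant_roll_dps = 0,
                           constant_lift_cmps = 0, label = NULL) {
  stopifnot(base_impulse_deg >= 0)
  if (is.null(label)) {
    label <- sprintf("roll%d", round(base_impulse_deg * 100))
    if (constant_roll_dps != 0)
      label <- sprintf("%s_%s%d", label,
                       if (constant_roll_dps > 0) "er" else "ir",
                       abs(round(constant_roll_dps)))
    if (constant_lift_cmps != 0)
      label <- sprintf("%s_lift%+d", label, round(constant_lift_cmps))
  }
  structure(list(
    base_impulse_deg = base_impulse_deg,
    constant_roll_dps = constant_roll_dps,
    constant_lift_cmps = constant_lift_cmps,
    label = label
  ), class = "flow_condition")
}

#' Compose the per-frame stimulus trace for a condition
#'
#' Combines an extended +/-1 impulse sequence with a condition's constant
#' velocities into per-frame roll and lift increments at the screen frame
#' rate:
#' `roll[f] = sign[f] * base_impulse + constant_roll / frame_rate` and
#' `lift[f] = constant_lift / frame_rate`. Increments are kept un-rounded;
#' e.g. Roll 33 with constant roll -50 deg/s at 165 Hz gives +0.33 - 50/165
#' (prints as 0.03 deg) on +1 frames and -0.633 deg on -1 frames.
#'
#' @param extended_sequence +/-1 vector, one value per frame (typically from
#'   [extend_circular()]).
#' @param condition A `flow_condition`.
#' @param screen A `screen_geometry` (supplies the frame rate).
#' @param analysis_length Number of final frames analysed downstream
#'   (default one m-sequence period, 255).
#' @return An object of class `stimulus_trace` with fields `sign_sequence`,
#'   `roll_increment_deg`, `lift_increment_cm`, `frame_times_s`, `presented`
#'   (frame log), `condition`, `frame_rate_hz`, `analysis_length`.
#' @export
compose_trace <- function(extended_sequence, condition,
                          screen = screen_geometry(),
                          analysis_length = NULL) {
  if (!inherits(condition, "flow_condition"))
    stop("'condition' must be a flow_condition", call. = FALSE)
  sgn <- as.integer(extended_sequence)
  if (!all(sgn %in% c(-1L, 1L)))
    stop("sequence values must be +1/-1", call. = FALSE)
  fr <- screen$frame_rate_hz
  n <- length(sgn)
  if (is.null(analysis_length)) analysis_length <- min(255L, n)
  structure(list(
    sign_sequence = sgn,
    roll_increment_deg = sgn * condition$base_impulse_deg +
      condition$constant_roll_dps / fr,
    lift_increment_cm = rep(condition$constant_lift_cmps / fr, n),
    frame_times_s = (seq_len(n) - 1L) / fr,
    presented = rep(TRUE, n),
    condition = condition,
    frame_rate_hz = fr,
    analysis_length = as.integer(analysis_length)
  ), class = "stimulus_trace")
}

#' Duration of a stimulus trace in seconds
#' @param trace A `stimulus_trace`.
#' @return Duration (s) from the first frame onset to the end of the last
#'   frame.
#' @export
trace_duration <- function(trace) {
  length(trace$sign_sequence) / trace$frame_rate_hz
}

#' Write / read a stimulus trace as CSV
#'
#' Columns: `frame_index`, `time_s`, `sign`, `roll_increment_deg`,
#' `lift_increment_cm`, `presented`. Condition metadata travels in a JSON
#' sidecar written by the dataset exporter; `read_trace_csv()` accepts the
#' condition separately.
#'
#' @param trace A `stimulus_trace`.
#' @param path CSV file path.
#' @param condition `flow_condition` to attach on read.
#' @param frame_rate_hz Frame rate to attach on read.
#' @param analysis_length Analysis window length to attach on read.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   a `stimulus_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(
    frame_index = seq_along(trace$sign_sequence),
    time_s = trace$frame_times_s,
    sign = trace$sign_sequence,
    roll_increment_deg = trace$roll_increment_deg,
    lift_increment_cm = trace$lift_increment_cm,
    presented = trace$presented
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, condition, frame_rate_hz = 165,
                           analysis_length = 255L) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "time_s", "sign", "roll_increment_deg",
            "lift_increment_cm", "presented")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing columns %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  structure(list(
    sign_sequence = as.integer(df$sign),
    roll_increment_deg = df$roll_increment_deg,
    lift_increment_cm = df$lift_increment_cm,
    frame_times_s = df$time_s,
    presented = as.logical(df$presented),
    condition = condition,
    frame_rate_hz = frame_rate_hz,
    analysis_length = as.integer(analysis_length)
  ), class = "stimulus_trace")
}
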