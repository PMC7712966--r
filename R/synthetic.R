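## Geometric benchmark trajectories with a known time ordering.
##
## Each system is a smooth, monotone-in-time motion of P points whose
## contact map changes slowly, mimicking a domain motion: since the true
## "state" coordinate is time itself, the quality of an unsupervised
## categorization can be scored by how well categories form contiguous runs
## in time.  The overall geometry of every system is fixed; increasing P
## increases the point density (and hence the number of contact features)
## without changing the motion, so the number of detectable states should
## not depend on P.

#' Specify a synthetic benchmark system
#'
#' @param name one of `"chomp"` (a closing 2D angle), `"heli"` (a line
#'   rotating past a static reference line in 3D), `"glob"` (three moving
#'   spheres of points in 3D).
#' @param P approximate total number of points (generators round per-part
#'   counts; `heli` adds a static reference copy of `floor(P/3)` points on
#'   top of `P`).
#' @param N number of frames.
#' @param noise_sigma width of the i.i.d. Gaussian noise added to every
#'   coordinate of every frame, in the system's length units.
#' @param seed integer seed making the generator a pure function of the
#'   spec.
#' @return an object of class `"system_spec"`.
#' @export
system_spec <- function(name = c("chomp", "heli", "glob"), P = 18L,
                        N = 1000L, noise_sigma = 0.1, seed = 1L) {
  name <- match.arg(name)
  if (P < 6L) stop("'P' must be at least 6")
  if (N < 10L) stop("'N' must be at least 10")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  structure(list(name = name, P = as.integer(P), N = as.integer(N),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "system_spec")
}

add_noise <- function(coords, sigma) {
  if (sigma > 0)
    coords <- coords + stats::rnorm(length(coords), sd = sigma)
  coords
}

#' Generate the 'chomp' system: a closing angle
#'
#' Two straight arms of `ceiling(P/2)` and `floor(P/2)` points hinged at
#' the origin in 2D.  Each arm spans a fixed length of 8 units (so spacing
#' shrinks as `P` grows), and the inter-arm angle closes linearly from 150
#' to 10 degrees over the `N` frames; points on opposite arms come within
#' the contact cutoff in order of their distance from the hinge.
#'
#' @param spec a [system_spec()].
#' @return a [trajectory()] of shape `(N, P, 2)`.
#' @export
gen_chomp <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  set.seed(spec$seed)
  n1 <- ceiling(spec$P / 2); n2 <- floor(spec$P / 2)
  arm_len <- 8
  s1 <- seq(0, arm_len, length.out = n1)
  s2 <- seq(0, arm_len, length.out = n2)
  phi <- seq(150, 10, length.out = spec$N) * pi / 180
  coords <- array(NA_real_, c(spec$N, n1 + n2, 2L))
  for (f in seq_len(spec$N)) {
    h <- phi[f] / 2
    coords[f, , 1] <- c(s1 * cos(h), s2 * cos(-h))
    coords[f, , 2] <- c(s1 * sin(h), s2 * sin(-h))
  }
  trajectory(add_noise(coords, spec$noise_sigma))
}

#' Generate the 'heli' system: a rotating line
#'
#' `P` points span a fixed segment of length 17 centred on the origin in
#' the xy-plane.  The segment rotates rigidly about the z axis through its
#' midpoint by 180 degrees linearly over the frames.  A static reference
#' line of `floor(P/3)` points sits parallel to the initial segment at unit
#' height; contacts between the rotating and static points switch on and
#' off in sequence as the rotation proceeds (a rigid rotation alone would
#' change no internal distance, so the reference copy is what makes the
#' motion visible to a contact model).
#'
#' @param spec a [system_spec()].
#' @return a [trajectory()] of shape `(N, P + floor(P/3), 3)`.
#' @export
gen_heli <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  set.seed(spec$seed)
  half_len <- 8.5
  s <- seq(-half_len, half_len, length.out = spec$P)
  n_fix <- floor(spec$P / 3)
  s_fix <- seq(-half_len, half_len, length.out = n_fix)
  psi <- seq(0, pi, length.out = spec$N)
  Pp <- spec$P + n_fix
  coords <- array(0, c(spec$N, Pp, 3L))
  for (f in seq_len(spec$N)) {
    coords[f, , 1] <- c(s * cos(psi[f]), s_fix)
    coords[f, , 2] <- c(s * sin(psi[f]), rep(0, n_fix))
    coords[f, , 3] <- c(rep(0, spec$P), rep(1, n_fix))
  }
  trajectory(add_noise(coords, spec$noise_sigma))
}

## quasi-uniform points on a unit sphere (Fibonacci lattice)
fib_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  th <- (seq_len(m) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate the 'glob' system: three moving spheres
#'
#' Three clusters of `floor(P/3)` points each, placed quasi-uniformly on
#' spheres of radius 1.5.  The left sphere is fixed at the origin; the
#' right sphere starts 5.2 units to its right and sweeps once around a
#' small out-of-plane circular arc ("behind and back"), approaching the
#' left sphere mid-trajectory; the top sphere starts 5.2 units away above
#' and translates downward by 2 units linearly.  At frame 0 all
#' surface-to-surface separations exceed the contact cutoff of 2, so only
#' intra-sphere contacts exist; cross-sphere contacts appear as the gaps
#' close.
#'
#' @param spec a [system_spec()].
#' @return a [trajectory()] of shape `(N, 3 * floor(P/3), 3)`.
#' @export
gen_glob <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  set.seed(spec$seed)
  m <- floor(spec$P / 3)
  shell <- 1.5 * fib_sphere(m)
  tt <- seq(0, 1, length.out = spec$N)
  coords <- array(NA_real_, c(spec$N, 3L * m, 3L))
  for (f in seq_len(spec$N)) {
    c_left <- c(0, 0, 0)
    c_right <- c(4.4 + 0.8 * cos(2 * pi * tt[f]), 0,
                 -0.8 * sin(2 * pi * tt[f]))
    c_top <- c(2.6, 4.5 - 2 * tt[f], 0)
    coords[f, , ] <- rbind(sweep(shell, 2L, c_left, "+"),
                           sweep(shell, 2L, c_right, "+"),
                           sweep(shell, 2L, c_top, "+"))
  }
  trajectory(add_noise(coords, spec$noise_sigma))
}

#' Generate a benchmark system and its contact features
#'
#' Dispatches to the named generator, then extracts binary contacts at
#' cutoff 2 length units and prunes constant features, exactly as in the
#' standard benchmark protocol.
#'
#' @param spec a [system_spec()].
#' @param cutoff contact cutoff (default 2 length units).
#' @return a list with `trajectory` and `features` (a pruned
#'   [feature_matrix()]).
#' @export
gen_system <- function(spec, cutoff = 2.0) {
  stopifnot(inherits(spec, "system_spec"))
  traj <- switch(spec$name,
                 chomp = gen_chomp(spec),
                 heli = gen_heli(spec),
                 glob = gen_glob(spec))
  fm <- prune_constant_features(extract_contacts(traj, cutoff))
  list(trajectory = traj, features = fm)
}
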