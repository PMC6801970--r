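#' Reduced N-O frame of one nitroxide monomer
#'
#' Minimal geometric description of one radical: the N and O nuclear
#' positions plus the unit axis of the p-type (pi*) lobe, which is
#' perpendicular to the N-O bond. This C-NO-C reduced representation is
#' all the point-spin models consume; ring atoms are never needed.
#'
#' @param n_position,o_position Numeric 3-vectors, Angstrom.
#' @param pi_direction Numeric 3-vector; normalized internally, must be
#'   orthogonal to the N-O axis.
#' @return An object of class `no_frame`.
#' @export
no_frame <- function(n_position, o_position, pi_direction) {
  stopifnot(length(n_position) == 3, length(o_position) == 3,
            length(pi_direction) == 3)
  bond <- o_position - n_position
  d <- sqrt(sum(bond^2))
  if (d <= 0) stop("N and O positions coincide")
  pi_direction <- pi_direction / sqrt(sum(pi_direction^2))
  if (abs(sum(pi_direction * bond / d)) > 1e-9) {
    stop("pi_direction must be orthogonal to the N-O axis")
  }
  structure(list(n_position = as.numeric(n_position),
                 o_position = as.numeric(o_position),
                 pi_direction = as.numeric(pi_direction),
                 d_no = d),
            class = "no_frame")
}

#' Idealized two-radical arrangement
#'
#' Parametric description of a colinear nitroxide dimer: both N-O bonds on
#' a common line, oxygen atoms facing each other at distance `r_oo`, and
#' the two p-type lobe axes twisted by `alpha` about the common axis.
#' `configuration` names the two archetypes: `config1` (alpha = 90,
#' orthogonal lobes, ferromagnetic) and `config2` (alpha = 0, parallel
#' lobes, antiferromagnetic). Solvent placements `a`/`b` are carried as
#' labels only, with the steric constraint r_oo >= 5 Angstrom.
#'
#' @param r_oo Oxygen-oxygen separation, Angstrom, positive.
#' @param alpha Lobe angle, degrees, in `[0, 90]`. Ignored (and fixed by
#'   the archetype) when `configuration` is given.
#' @param configuration Optional, `"config1"` or `"config2"`.
#' @param solvent_placement `"none"`, `"a"` or `"b"`.
#' @param n_solvent Number of interposed solvent molecules, >= 0.
#' @return An object of class `dimer_configuration`.
#' @examples
#' dimer_configuration(r_oo = 6, configuration = "config1")
#' @export
dimer_configuration <- function(r_oo, alpha = NULL, configuration = NULL,
                                solvent_placement = c("none", "a", "b"),
                                n_solvent = 0L) {
  solvent_placement <- match.arg(solvent_placement)
  if (!is.numeric(r_oo) || r_oo <= 0) {
    stop("r_oo must be positive, got ", r_oo)
  }
  if (!is.null(configuration)) {
    configuration <- match.arg(configuration, c("config1", "config2"))
    fixed <- c(config1 = 90, config2 = 0)[[configuration]]
    if (!is.null(alpha) && abs(alpha - fixed) > 1e-12) {
      stop(configuration, " implies alpha = ", fixed, ", got ", alpha)
    }
    alpha <- fixed
  }
  if (is.null(alpha)) stop("either alpha or configuration must be given")
  if (alpha < 0 || alpha > 90) stop("alpha must lie in [0, 90], got ", alpha)
  if (solvent_placement != "none") {
    if (n_solvent < 1) n_solvent <- 1L
    if (r_oo < 5) {
      stop("solvent placement '", solvent_placement,
           "' requires r_oo >= 5 Angstrom (steric hindrance), got ", r_oo)
    }
  }
  if (n_solvent < 0) stop("n_solvent must be >= 0")
  structure(list(r_oo = r_oo, alpha = alpha,
                 configuration = configuration,
                 solvent_placement = solvent_placement,
                 n_solvent = as.integer(n_solvent)),
            class = "dimer_configuration")
}

#' Build the two N-O frames of a colinear dimer
#'
#' Coordinate convention: the common NO...ON line is the z-axis; monomer
#' 1 has its oxygen at the origin and N at z = -d_no, with pi lobe along
#' +x; monomer 2 is the mirror arrangement at z = r_oo with its lobe
#' rotated by alpha about z.
#'
#' @param config A [dimer_configuration()].
#' @param d_no N-O bond length, Angstrom; default from [spin_constants()].
#' @return A list of two [no_frame()] objects.
#' @examples
#' frames <- build_dimer(dimer_configuration(6, configuration = "config1"))
#' lobe_angle(frames[[1]], frames[[2]])  # 90
#' @export
build_dimer <- function(config, d_no = spin_constants()$d_no_angstrom) {
  stopifnot(inherits(config, "dimer_configuration"))
  if (d_no <= 0) stop("d_no must be positive, got ", d_no)
  a <- config$alpha * pi / 180
  f1 <- no_frame(n_position = c(0, 0, -d_no),
                 o_position = c(0, 0, 0),
                 pi_direction = c(1, 0, 0))
  f2 <- no_frame(n_position = c(0, 0, config$r_oo + d_no),
                 o_position = c(0, 0, config$r_oo),
                 pi_direction = c(cos(a), sin(a), 0))
  list(f1, f2)
}

#' Angle between the p-type lobes of two frames
#'
#' @param frame1,frame2 [no_frame()] objects.
#' @return Angle in degrees, in `[0, 90]` (the lobe axis is a line, so
#'   the angle is folded to the first quadrant).
#' @export
lobe_angle <- function(frame1, frame2) {
  d <- abs(sum(frame1$pi_direction * frame2$pi_direction))
  acos(pmin(1, d)) * 180 / pi
}

#' A point carrying a fraction of one unpaired electron
#'
#' @param position Numeric 3-vector, Angstrom.
#' @param population Spin fraction, >= 0.
#' @return An object of class `point_spin_site`.
#' @export
point_spin_site <- function(position, population) {
  stopifnot(length(position) == 3)
  if (population < 0) stop("population must be >= 0")
  structure(list(position = as.numeric(position),
                 population = as.numeric(population)),
            class = "point_spin_site")
}

#' Place the point-spin representation of one monomer
#'
#' Two variants of the distributed-spin picture of a nitroxide group:
#' \describe{
#'   \item{two_point}{one site at the midpoint of the N-O bond carrying
#'     the whole monomer spin population `pop_n + pop_o` (capped at 1).}
#'   \item{four_point}{four sites at the barycentres of the p-type lobes:
#'     N +/- l_pi_n and O +/- l_pi_o along the lobe axis, each carrying
#'     half the corresponding atomic spin population.}
#' }
#'
#' @param frame A [no_frame()].
#' @param model `"two_point"` or `"four_point"`.
#' @param l_pi_n,l_pi_o Lobe-barycentre offsets from N and O, Angstrom,
#'   >= 0; defaults are the fitted values from [spin_constants()].
#' @param pop_n,pop_o Atomic spin populations of N and O; defaults 0.45
#'   and 0.51.
#' @return A list of [point_spin_site()] objects (length 1 or 4).
#' @examples
#' f <- build_dimer(dimer_configuration(9, configuration = "config2"))[[1]]
#' sites <- place_point_spins(f, "four_point")
#' vapply(sites, function(s) s$population, numeric(1))
#' @export
place_point_spins <- function(frame,
                              model = c("four_point", "two_point"),
                              l_pi_n = spin_constants()$l_pi_n_angstrom,
                              l_pi_o = spin_constants()$l_pi_o_angstrom,
                              pop_n = spin_constants()$pop_n,
                              pop_o = spin_constants()$pop_o) {
  stopifnot(inherits(frame, "no_frame"))
  model <- match.arg(model)
  if (l_pi_n < 0 || l_pi_o < 0) stop("lobe offsets must be >= 0")
  if (pop_n < 0 || pop_o < 0) stop("populations must be >= 0")
  if (pop_n + pop_o > 1 + 1e-9) {
    stop("populations of one radical must sum to <= 1, got ", pop_n + pop_o)
  }
  if (model == "two_point") {
    mid <- (frame$n_position + frame$o_position) / 2
    return(list(point_spin_site(mid, min(1, pop_n + pop_o))))
  }
  u <- frame$pi_direction
  list(
    point_spin_site(frame$n_position + l_pi_n * u, pop_n / 2),
    point_spin_site(frame$n_position - l_pi_n * u, pop_n / 2),
    point_spin_site(frame$o_position + l_pi_o * u, pop_o / 2),
    point_spin_site(frame$o_position - l_pi_o * u, pop_o / 2)
  )
}

#' Write frames (and optional spin sites) to an XYZ file
#'
#' Standard XYZ: atom-count line, free comment line, then
#' `element x y z` records in Angstrom. Spin sites are written as dummy
#' atoms with element symbol `X` and the population appended as a fifth
#' column.
#'
#' @param frames A list of [no_frame()] objects (at least one).
#' @param path Output file path.
#' @param sites Optional list of [point_spin_site()] objects.
#' @param comment Comment line; default records r_oo and alpha when two
#'   frames are given.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, sites = NULL, comment = NULL) {
  if (inherits(frames, "no_frame")) frames <- list(frames)
  if (length(frames) < 1) stop("at least one frame is required")
  if (is.null(comment)) {
    if (length(frames) == 2) {
      r_oo <- sqrt(sum((frames[[2]]$o_position - frames[[1]]$o_position)^2))
      comment <- sprintf("nitroxide dimer r_oo=%.6g alpha=%.6g",
                         r_oo, lobe_angle(frames[[1]], frames[[2]]))
    } else {
      comment <- "nitroxide frames"
    }
  }
  rec <- function(el, p, extra = "") {
    sprintf("%-2s %18.10f %18.10f %18.10f%s", el, p[1], p[2], p[3], extra)
  }
  lines <- character(0)
  for (f in frames) {
    lines <- c(lines, rec("N", f$n_position), rec("O", f$o_position))
  }
  for (s in sites %||% list()) {
    lines <- c(lines, rec("X", s$position, sprintf(" %12.8f", s$population)))
  }
  out <- c(as.character(length(lines)), comment, lines)
  ok <- tryCatch({
    suppressWarnings(writeLines(out, path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write XYZ file '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()]
#'
#' @param path XYZ file path.
#' @return A list with `elements` (character), `coords` (n x 3 matrix,
#'   Angstrom), `populations` (numeric, NA for real atoms) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file: ", path)
  recs <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  elements <- vapply(recs, `[`, character(1), 1)
  coords <- t(vapply(recs, function(x) as.numeric(x[2:4]), numeric(3)))
  populations <- vapply(recs, function(x) {
    if (length(x) >= 5) as.numeric(x[5]) else NA_real_
  }, numeric(1))
  list(elements = elements, coords = coords, populations = populations,
       comment = lines[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
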