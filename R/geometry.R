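# Implant-in-bone-gap geometry: parameterized screw profile, seeded
# microroughness, rasterization to a structured grid, and analysis-zone masks.

#' Implant geometry parameters
#'
#' Defines the 2-D planar half-section of a screw implant seated in a bone
#' gap. The centerline of the implant is the left domain edge (a symmetry
#' boundary); the bone wall is the right edge. Threads are symmetric
#' triangular teeth.
#'
#' @param threaded_length Axial length of the threaded section (m). Must be
#'   an integer multiple of `thread_pitch` (whole threads only).
#' @param tip_radius_offset Half-width of the implant at the thread tips,
#'   measured from the centerline (m).
#' @param thread_pitch Axial distance between successive thread tips (m).
#' @param thread_depth Radial depth of a thread (m). Must be smaller than
#'   `outer_gap_width` so blood can always pass the outer channel.
#' @param outer_gap_width Distance from the thread-tip envelope to the bone
#'   wall (m).
#' @param apex_clearance Gap below the implant apex where the apical blood
#'   inlet sits (m).
#' @param thread_fill_fraction Fraction of the thread-envelope band occupied
#'   by implant solid (0.5 gives a continuous symmetric zigzag).
#'
#' @return An object of class `implant_geometry`.
#' @examples
#' geo <- implant_geometry()
#' geo$threaded_length / geo$thread_pitch  # number of threads
#' @export
implant_geometry <- function(threaded_length = 8e-3,
                             tip_radius_offset = 0.8e-3,
                             thread_pitch = 0.8e-3,
                             thread_depth = 0.4e-3,
                             outer_gap_width = 0.8e-3,
                             apex_clearance = 0.8e-3,
                             thread_fill_fraction = 0.5) {
  lens <- c(threaded_length, tip_radius_offset, thread_pitch, thread_depth,
            outer_gap_width, apex_clearance)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all implant geometry lengths must be positive and finite")
  }
  if (thread_fill_fraction <= 0 || thread_fill_fraction >= 1) {
    stop("thread_fill_fraction must lie strictly in (0, 1)")
  }
  if (thread_depth >= outer_gap_width) {
    stop("thread_depth must be < outer_gap_width (outer channel must stay open)")
  }
  if (thread_depth >= tip_radius_offset) {
    stop("thread_depth must be < tip_radius_offset")
  }
  n_threads <- threaded_length / thread_pitch
  if (abs(n_threads - round(n_threads)) > 1e-9) {
    stop("threaded_length must be an integer multiple of thread_pitch")
  }
  structure(
    list(threaded_length = threaded_length,
         tip_radius_offset = tip_radius_offset,
         thread_pitch = thread_pitch,
         thread_depth = thread_depth,
         outer_gap_width = outer_gap_width,
         apex_clearance = apex_clearance,
         thread_fill_fraction = thread_fill_fraction,
         n_threads = as.integer(round(n_threads))),
    class = "implant_geometry")
}

#' Microroughness specification
#'
#' Seeded random sawtooth roughness emulating acid-etched titanium: random
#' peaks and valleys with peak-to-valley amplitudes drawn uniformly from
#' `[amplitude_min, amplitude_max]` and along-surface feature widths from
#' `feature_width_range`. For desk-scale grids both are multiplied by
#' `coarsening_factor` so features stay resolvable; results carrying
#' coarsened roughness are scale-reduced representations of the micrometre
#' original.
#'
#' @param amplitude_min,amplitude_max Peak-to-valley amplitude bounds (m);
#'   physical reference 0.5e-6 to 3.0e-6.
#' @param feature_width_range Length-2 numeric, along-surface width bounds (m).
#' @param coarsening_factor Multiplier (>= 1) applied to amplitudes and
#'   widths before they are imprinted on the profile.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   profile.
#' @return An object of class `roughness_spec`.
#' @export
roughness_spec <- function(amplitude_min = 0.5e-6,
                           amplitude_max = 3.0e-6,
                           feature_width_range = c(0.5e-6, 3.0e-6),
                           coarsening_factor = 20,
                           seed = 42L) {
  if (!(amplitude_min >= 0 && amplitude_max >= amplitude_min)) {
    stop("need 0 <= amplitude_min <= amplitude_max")
  }
  if (amplitude_max > 0 && amplitude_min <= 0) {
    stop("amplitude_min must be > 0 when amplitude_max > 0 (or both zero)")
  }
  if (length(feature_width_range) != 2 || any(feature_width_range <= 0) ||
      feature_width_range[2] < feature_width_range[1]) {
    stop("feature_width_range must be an increasing positive pair")
  }
  if (coarsening_factor < 1) stop("coarsening_factor must be >= 1")
  structure(
    list(amplitude_min = amplitude_min, amplitude_max = amplitude_max,
         feature_width_range = as.numeric(feature_width_range),
         coarsening_factor = coarsening_factor, seed = as.integer(seed)),
    class = "roughness_spec")
}

# Smooth profile vertices in implant coordinates (y = 0 at the apex plane,
# increasing toward the coronal end; x = 0 at the centerline).
smooth_profile_vertices <- function(params) {
  p <- params$thread_pitch
  d <- params$thread_depth
  r_tip <- params$tip_radius_offset
  r_root <- r_tip - d
  b <- 2 * params$thread_fill_fraction * p   # tooth base width
  if (b > p + 1e-15) stop("thread_fill_fraction > 0.5 not representable by triangular teeth")
  xs <- c(0, r_root)
  ys <- c(0, 0)
  for (k in seq_len(params$n_threads) - 1L) {
    y0 <- k * p
    flat <- (p - b) / 2
    if (flat > 1e-15) { xs <- c(xs, r_root); ys <- c(ys, y0 + flat) }
    xs <- c(xs, r_tip);  ys <- c(ys, y0 + p / 2)
    if (flat > 1e-15) { xs <- c(xs, r_root); ys <- c(ys, y0 + p - flat) }
    xs <- c(xs, r_root); ys <- c(ys, y0 + p)   # thread root
  }
  keep <- c(TRUE, abs(diff(xs)) + abs(diff(ys)) > 1e-15)
  cbind(x = xs[keep], y = ys[keep])
}

polyline_arclength <- function(v) {
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

# Linear interpolation of a point and unit outward normal at arclength s.
# The fluid lies to the right of the direction of travel, so the outward
# normal is (dy, -dx)/|seg|.
profile_point_normal <- function(v, s_query) {
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  s_query <- pmin(pmax(s_query, 0), total)
  idx <- findInterval(s_query, cs, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(seg))
  t <- (s_query - cs[idx]) / seg[idx]
  px <- v[idx, 1] + t * (v[idx + 1, 1] - v[idx, 1])
  py <- v[idx, 2] + t * (v[idx + 1, 2] - v[idx, 2])
  nx <- (v[idx + 1, 2] - v[idx, 2]) / seg[idx]
  ny <- -(v[idx + 1, 1] - v[idx, 1]) / seg[idx]
  list(x = px, y = py, nx = nx, ny = ny)
}

# Remove self-intersection loops whose arc length is below max_loop by
# replacing the loop with the intersection point. Larger folds are left for
# the caller to reject.
prune_small_loops <- function(v, max_loop, max_iter = 200L) {
  seg_int <- function(p1, p2, p3, p4) {
    d <- (p2[1] - p1[1]) * (p4[2] - p3[2]) - (p2[2] - p1[2]) * (p4[1] - p3[1])
    if (abs(d) < 1e-300) return(NULL)
    t <- ((p3[1] - p1[1]) * (p4[2] - p3[2]) - (p3[2] - p1[2]) * (p4[1] - p3[1])) / d
    u <- ((p3[1] - p1[1]) * (p2[2] - p1[2]) - (p3[2] - p1[2]) * (p2[1] - p1[1])) / d
    if (t <= 0 || t >= 1 || u <= 0 || u >= 1) return(NULL)
    p1 + t * (p2 - p1)
  }
  for (iter in seq_len(max_iter)) {
    n <- nrow(v) - 1L
    seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
    cs <- c(0, cumsum(seg))
    found <- FALSE
    for (i in seq_len(max(n - 2L, 0L))) {
      # only look ahead within the prunable arc window
      jmax <- n
      if (i + 2L > jmax) next
      for (j in (i + 2L):jmax) {
        if (cs[j + 1] - cs[i] > max_loop) break
        p <- seg_int(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ])
        if (!is.null(p)) {
          v <- rbind(v[seq_len(i), , drop = FALSE], p,
                     v[(j + 1):(n + 1), , drop = FALSE])
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  unname(v)
}

segments_self_intersect <- function(v) {
  n <- nrow(v) - 1L
  if (n < 3) return(FALSE)
  x1 <- v[1:n, 1]; y1 <- v[1:n, 2]
  x2 <- v[2:(n + 1), 1]; y2 <- v[2:(n + 1), 2]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n           # skip the shared-vertex neighbour
    d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
    d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
    d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
    d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Build the blood-contacting implant wall profile
#'
#' Traces the implant surface from the apex centerline along the apex face
#' and the triangular threads to the coronal end, in implant coordinates
#' (y = 0 at the apex plane). With a [roughness_spec()], a seeded random
#' sawtooth perturbation is superimposed normal to the smooth profile:
#' node offsets alternate in sign with peak-to-valley amplitudes drawn
#' uniformly from the (coarsened) amplitude range.
#'
#' @param params An [implant_geometry()].
#' @param roughness A [roughness_spec()], or `NULL` for the smooth surface.
#' @param cell_size Optional intended rasterization cell size (m); when
#'   supplied, roughness whose coarsened feature width is below
#'   `2 * cell_size` is rejected as unresolvable.
#' @return A tibble with columns `x`, `y` (m) of ordered vertices, class
#'   `implant_profile`; the smooth reference vertices and applied offsets
#'   are attached as attributes.
#' @export
build_implant_profile <- function(params, roughness = NULL, cell_size = NULL) {
  stopifnot(inherits(params, "implant_geometry"))
  sm <- smooth_profile_vertices(params)
  if (is.null(roughness)) {
    out <- tibble::tibble(x = sm[, 1], y = sm[, 2])
    class(out) <- c("implant_profile", class(out))
    attr(out, "smooth") <- sm
    attr(out, "params") <- params
    return(out)
  }
  stopifnot(inherits(roughness, "roughness_spec"))
  cf <- roughness$coarsening_factor
  wmin <- roughness$feature_width_range[1] * cf
  wmax <- roughness$feature_width_range[2] * cf
  if (!is.null(cell_size) && wmin < 2 * cell_size) {
    stop("unresolvable roughness: coarsened feature width ", signif(wmin, 3),
         " m is below 2 * cell_size = ", signif(2 * cell_size, 3), " m")
  }
  total <- polyline_arclength(sm)
  rng <- seeded_rng(roughness$seed)
  # node positions along the arc
  s_nodes <- 0
  repeat {
    s_next <- s_nodes[length(s_nodes)] + rng$unif(1, wmin, wmax)
    if (s_next >= total) break
    s_nodes <- c(s_nodes, s_next)
  }
  s_nodes <- c(s_nodes, total)
  n_nodes <- length(s_nodes)
  p2v <- rng$unif(n_nodes, roughness$amplitude_min * cf, roughness$amplitude_max * cf)
  offs <- p2v / 2 * rep_len(c(1, -1), n_nodes)
  offs[c(1, n_nodes)] <- 0                      # anchor the profile ends
  # evaluate at roughness nodes plus the smooth corner vertices
  seg <- sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2)
  s_corners <- c(0, cumsum(seg))
  s_all <- sort(unique(c(s_nodes, s_corners)))
  d_all <- stats::approx(s_nodes, offs, xout = s_all, rule = 2)$y
  pn <- profile_point_normal(sm, s_all)
  v <- cbind(x = pn$x + d_all * pn$nx, y = pn$y + d_all * pn$ny)
  # clamp: never cross the centerline
  v[, 1] <- pmax(v[, 1], 0)
  # offset polylines self-cross in tiny loops at concave thread corners;
  # clip those, but reject amplitudes that fold on the thread scale
  v <- prune_small_loops(v, max_loop = 4 * wmax)
  if (segments_self_intersect(v)) {
    stop("self-intersecting profile: roughness amplitude too large for the thread geometry")
  }
  out <- tibble::tibble(x = v[, 1], y = v[, 2])
  class(out) <- c("implant_profile", class(out))
  attr(out, "smooth") <- sm
  attr(out, "params") <- params
  attr(out, "offsets") <- tibble::tibble(s = s_all, offset = d_all)
  out
}

#' Roughness metrics of a profile against its smooth reference
#'
#' Computes the mean absolute normal deviation, the maximum peak-to-valley
#' excursion, and the roughness ratio `r` (true arc length over the smooth
#' reference arc length; the Wenzel ratio).
#'
#' @param profile Polyline (tibble or 2-column matrix of `x`, `y`).
#' @param smooth_reference Polyline of the smooth surface over the same arc
#'   domain (shared endpoints).
#' @return A tibble with one row: `mean_abs_deviation`, `peak_to_valley_max`,
#'   `roughness_ratio`.
#' @export
roughness_metrics <- function(profile, smooth_reference) {
  v <- as.matrix(profile[, c(1, 2)])
  s <- as.matrix(smooth_reference[, c(1, 2)])
  storage.mode(v) <- "double"; storage.mode(s) <- "double"
  tol <- 1e-9 * max(polyline_arclength(s), 1e-30)
  if (sqrt(sum((v[1, ] - s[1, ])^2)) > 1e3 * tol ||
      sqrt(sum((v[nrow(v), ] - s[nrow(s), ])^2)) > 1e3 * tol) {
    stop("mismatched arc domains: profile and reference endpoints differ")
  }
  dev <- signed_distance_to_polyline(v, s)
  tibble::tibble(
    mean_abs_deviation = mean(abs(dev)),
    peak_to_valley_max = max(dev) - min(dev),
    roughness_ratio = polyline_arclength(v) / polyline_arclength(s))
}

# Signed normal distance of each point to the nearest segment of a polyline;
# positive on the outward (fluid) side, i.e. along (dy, -dx).
signed_distance_to_polyline <- function(pts, poly) {
  n <- nrow(poly) - 1L
  ax <- poly[1:n, 1]; ay <- poly[1:n, 2]
  bx <- poly[2:(n + 1), 1]; by <- poly[2:(n + 1), 2]
  ex <- bx - ax; ey <- by - ay
  L2 <- pmax(ex^2 + ey^2, 1e-300)
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- pts[k, 1]; py <- pts[k, 2]
    t <- pmin(pmax(((px - ax) * ex + (py - ay) * ey) / L2, 0), 1)
    qx <- ax + t * ex; qy <- ay + t * ey
    d2 <- (px - qx)^2 + (py - qy)^2
    j <- which.min(d2)
    cross <- ex[j] * (py - qy[j]) - ey[j] * (px - qx[j])
    # outward normal (dy,-dx): outward side has negative cross product
    out[k] <- sqrt(d2[j]) * ifelse(cross <= 0, 1, -1)
  }
  out
}

#' Wenzel roughness ratio of a roughness specification
#'
#' Generates the specified roughness at its physical scale on a straight
#' reference line and returns the arc-length roughness ratio `r`; used by
#' the Wenzel-effective wetting mode.
#'
#' @param roughness A [roughness_spec()].
#' @param ref_length Length of the straight reference line (m).
#' @return Scalar `r >= 1`.
#' @export
roughness_ratio_physical <- function(roughness, ref_length = 2e-4) {
  stopifnot(inherits(roughness, "roughness_spec"))
  if (roughness$amplitude_max == 0) return(1)
  rng <- seeded_rng(roughness$seed + 7919L)
  s <- 0
  repeat {
    nxt <- s[length(s)] + rng$unif(1, roughness$feature_width_range[1],
                                   roughness$feature_width_range[2])
    if (nxt >= ref_length) break
    s <- c(s, nxt)
  }
  s <- c(s, ref_length)
  p2v <- rng$unif(length(s), roughness$amplitude_min, roughness$amplitude_max)
  off <- p2v / 2 * rep_len(c(1, -1), length(s))
  off[c(1, length(s))] <- 0
  sum(sqrt(diff(s)^2 + diff(off)^2)) / ref_length
}

# Deterministic local RNG stream that does not disturb the global seed.
seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$unif <- function(n, lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
  env
}

#' Rasterize the implant domain to a structured grid
#'
#' Cell-centered classification on a uniform grid with the origin at the
#' domain lower-left. Cells whose centers fall inside the implant polygon
#' are `implant_solid`; the right boundary column is the bone wall
#' (`inlet_bone` along the threaded span, `bone_solid` elsewhere); the
#' bottom boundary strip is `inlet_apex`; the top strip over the gap is
#' `outlet`; the remainder is `fluid`.
#'
#' @param profile An [build_implant_profile()] polyline.
#' @param params The [implant_geometry()] used to build it.
#' @param cell_size Grid spacing (m); must resolve `thread_depth` with at
#'   least 4 cells.
#' @return An object of class `domain_grid` with fields `cell_size`, `nx`,
#'   `ny`, `cell_class` (integer matrix, codes in [cell_class_codes()]),
#'   `width`, `height`, plus the generating profile and parameters.
#' @export
rasterize_domain <- function(profile, params, cell_size) {
  stopifnot(inherits(params, "implant_geometry"))
  if (params$thread_depth / cell_size < 4 - 1e-9) {
    stop("cell_size must resolve thread_depth with >= 4 cells")
  }
  W <- params$tip_radius_offset + params$outer_gap_width
  H <- params$apex_clearance + params$threaded_length
  nx <- as.integer(round(W / cell_size))
  ny <- as.integer(round(H / cell_size))
  xc <- (seq_len(nx) - 0.5) * cell_size
  yc <- (seq_len(ny) - 0.5) * cell_size
  # closed implant polygon in domain coordinates
  v <- as.matrix(profile[, c("x", "y")])
  v[, 2] <- v[, 2] + params$apex_clearance
  poly_x <- c(0, v[, 1], 0)
  poly_y <- c(params$apex_clearance, v[, 2], H)
  cls <- matrix(CLASS_FLUID, nx, ny)
  inside <- point_in_polygon_grid(xc, yc, poly_x, poly_y)
  cls[inside] <- CLASS_IMPLANT
  # bone wall: right boundary column
  span <- yc >= params$apex_clearance & yc <= H + 1e-15
  cls[nx, ] <- ifelse(span, CLASS_INLET_BONE, CLASS_BONE)
  # apical inlet: bottom row (excluding the bone corner)
  bot <- cls[, 1] == CLASS_FLUID
  cls[bot, 1] <- CLASS_INLET_APEX
  # outlet: top strip over the remaining gap
  top <- cls[, ny] == CLASS_FLUID
  cls[top, ny] <- CLASS_OUTLET
  if (!any(cls == CLASS_INLET_APEX) || !any(cls == CLASS_INLET_BONE) ||
      !any(cls == CLASS_OUTLET)) {
    stop("degenerate rasterization: missing inlet or outlet cells")
  }
  grid <- structure(
    list(cell_size = cell_size, nx = nx, ny = ny, cell_class = cls,
         width = W, height = H, params = params, profile = profile),
    class = "domain_grid")
  check_fluid_connected(grid)
  grid
}

#' Cell classification codes
#'
#' Integer codes used in `domain_grid$cell_class`.
#' @return Named integer vector.
#' @export
cell_class_codes <- function() {
  c(fluid = 0L, implant_solid = 1L, bone_solid = 2L,
    inlet_apex = 3L, inlet_bone = 4L, outlet = 5L)
}
CLASS_FLUID <- 0L; CLASS_IMPLANT <- 1L; CLASS_BONE <- 2L
CLASS_INLET_APEX <- 3L; CLASS_INLET_BONE <- 4L; CLASS_OUTLET <- 5L

is_solid_class <- function(cls) cls == CLASS_IMPLANT | cls == CLASS_BONE

# Even-odd point-in-polygon for all grid cell centers; vectorized over cells
# per polygon edge. Returns a logical nx x ny matrix.
point_in_polygon_grid <- function(xc, yc, px, py) {
  nx <- length(xc); ny <- length(yc)
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  inside <- matrix(FALSE, nx, ny)
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > Y) != (py[j] > Y))
    if (any(crosses)) {
      xint <- px[i] + (Y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      inside <- xor(inside, crosses & (X < xint))
    }
    j <- i
  }
  inside
}

check_fluid_connected <- function(grid) {
  cls <- grid$cell_class
  open <- !is_solid_class(cls)
  seed <- cls == CLASS_INLET_APEX | cls == CLASS_INLET_BONE
  reach <- seed
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(grown), ] <- grown[-nrow(grown), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(grown)] <- grown[, -ncol(grown)] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (any(open & !reach)) {
    stop("disconnected fluid region: some fluid cells are unreachable from the inlets")
  }
  invisible(TRUE)
}

#' Label the interface, thread, and outer analysis zones
#'
#' The interface zone is the set of fluid cells whose centers lie within
#' `delta` (Euclidean, center-to-center) of an implant-solid cell; thread
#' cells lie between the interface band and the thread-tip envelope within
#' the threaded span; outer cells lie between the tip envelope and the bone
#' wall. Cells outside the peri-implant gap carry no zone.
#'
#' @param grid A [rasterize_domain()] result.
#' @param delta Interface band width (m); default 2 cell widths. A `delta`
#'   below one cell width yields an empty interface zone (its cells fall to
#'   the thread zone).
#' @return An object of class `zone_mask`: integer matrix `zone` (codes in
#'   [zone_codes()]) plus `delta`.
#' @export
compute_zone_masks <- function(grid, delta = 2 * grid$cell_size) {
  stopifnot(inherits(grid, "domain_grid"))
  h <- grid$cell_size
  if (delta < 0) stop("delta must be non-negative")
  cls <- grid$cell_class
  fluid <- cls == CLASS_FLUID
  imp <- cls == CLASS_IMPLANT
  near <- matrix(FALSE, grid$nx, grid$ny)
  r <- floor(delta / h + 1e-12)
  if (r >= 1) {
    for (di in -r:r) for (dj in -r:r) {
      if (sqrt(di^2 + dj^2) * h <= delta + 1e-12) {
        near <- near | shift_mat(imp, di, dj)
      }
    }
  }
  p <- grid$params
  xc <- matrix((seq_len(grid$nx) - 0.5) * h, grid$nx, grid$ny)
  yc <- matrix((seq_len(grid$ny) - 0.5) * h, grid$nx, grid$ny, byrow = TRUE)
  span <- yc >= p$apex_clearance & yc <= p$apex_clearance + p$threaded_length
  inner <- xc < p$tip_radius_offset
  zone <- matrix(ZONE_NONE, grid$nx, grid$ny)
  zone[fluid & near] <- ZONE_INTERFACE
  zone[fluid & !near & span & inner] <- ZONE_THREAD
  zone[fluid & !near & span & !inner] <- ZONE_OUTER
  if (!any(zone == ZONE_THREAD) && any(zone == ZONE_INTERFACE)) {
    warning("interface band delta swallows the entire thread zone")
  }
  structure(list(zone = zone, delta = delta, cell_size = h), class = "zone_mask")
}

#' Zone codes
#' @return Named integer vector of zone labels.
#' @export
zone_codes <- function() c(none = 0L, interface = 1L, thread = 2L, outer = 3L)
ZONE_NONE <- 0L; ZONE_INTERFACE <- 1L; ZONE_THREAD <- 2L; ZONE_OUTER <- 3L

shift_mat <- function(m, di, dj) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  xs <- max(1, 1 + di):min(nx, nx + di)
  ys <- max(1, 1 + dj):min(ny, ny + dj)
  out[xs, ys] <- m[xs - di, ys - dj]
  out
}

#' Zone areas
#'
#' @param mask A [compute_zone_masks()] result.
#' @param grid The matching [rasterize_domain()] grid.
#' @return Tibble with `zone`, `cells`, `area` (m^2 per unit depth).
#' @export
zone_areas <- function(mask, grid) {
  zc <- zone_codes()
  counts <- unname(vapply(zc, function(z) sum(mask$zone == z), integer(1)))
  tibble::tibble(zone = names(zc), cells = counts,
                 area = counts * grid$cell_size^2)
}

#' Analytic (shoelace) area of the implant polygon
#'
#' @param profile An [build_implant_profile()] polyline.
#' @param params The matching [implant_geometry()].
#' @return Area in m^2 (per unit depth) of the implant cross-section within
#'   the domain.
#' @export
implant_polygon_area <- function(profile, params) {
  v <- as.matrix(profile[, c("x", "y")])
  H <- params$apex_clearance + params$threaded_length
  px <- c(0, v[, 1], 0)
  py <- c(params$apex_clearance, v[, 2] + params$apex_clearance, H)
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

#' @export
print.domain_grid <- function(x, ...) {
  cat("<domain_grid> ", x$nx, "x", x$ny, " cells, h = ", signif(x$cell_size, 3),
      " m (", signif(x$width * 1e3, 3), " x ", signif(x$height * 1e3, 3), " mm)\n", sep = "")
  tab <- table(factor(x$cell_class, levels = cell_class_codes(),
                      labels = names(cell_class_codes())))
  print(tab)
  invisible(x)
}

#' Export a profile as a two-column CSV (arclength, normal offset)
#'
#' @param profile Roughened [build_implant_profile()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  off <- attr(profile, "offsets")
  if (is.null(off)) {
    sm <- attr(profile, "smooth")
    seg <- sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2)
    off <- tibble::tibble(s = c(0, cumsum(seg)), offset = 0)
  }
  utils::write.csv(off, path, row.names = FALSE)
  invisible(path)
}
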