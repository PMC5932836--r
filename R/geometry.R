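# Parametric synthetic aortas: an ascending segment, a circular arch in the
# x-z plane carrying three vertical branch vessels (BA, LCCA, LSA), and a
# descending segment with an aortic-isthmus (AI) region that can be
# narrowed. All lengths in mm. Coordinates are right-handed with the inlet
# plane at z = 0 and its normal along +z; the descending aorta returns to
# the z = 0 plane, so the inlet and DAo outlet caps share the bottom
# boundary and the branch outlet caps share the top boundary.

#' Parametric aorta specification
#'
#' Describes a synthetic aorta: inlet (ascending) diameter, descending
#' diameter, isthmus diameter with an optional stenosis factor, branch
#' diameters, arch radius and segment lengths. With `arch_radius = NULL`
#' and no branches the spec degenerates to a straight tube along +z (see
#' [tube_spec()]).
#'
#' @param inlet_diameter ascending aorta (inlet) diameter, mm.
#' @param dao_diameter descending aorta diameter, mm.
#' @param ai_diameter aortic-isthmus diameter before stenosis, mm.
#' @param branch_diameters named numeric vector `c(BA=, LCCA=, LSA=)`, mm.
#'   Defaults to fixed fractions (0.45, 0.35, 0.35) of the inlet diameter.
#' @param arch_radius radius of the arch centerline arc, mm; default
#'   `0.85 * inlet_diameter`.
#' @param asc_length length of the straight ascending segment, mm. The
#'   descending segment mirrors it so the DAo outlet returns to z = 0.
#' @param branch_clearance vertical length of branch tube above the top of
#'   the arch lumen, mm.
#' @param branch_angles_deg attachment angles of the branches along the arch
#'   (180 = ascending end, 0 = descending end).
#' @param ai_offset distance of the AI plane below the arch end, mm.
#' @param ai_stenosis_factor multiplier in (0, 1] applied to `ai_diameter`
#'   at the isthmus plane (1 = no narrowing).
#' @param ai_width half-width of the smooth isthmus narrowing, mm; default
#'   `0.75 * ai_diameter`.
#' @param tube_length straight-tube mode only: tube length, mm.
#' @return An object of class `aorta_spec`.
#' @examples
#' aorta_spec(19.2, 10.9, 12.1)            # cohort-mean synthetic aorta
#' tube_spec(diameter = 20, length = 100)  # degenerate cylinder
#' @export
aorta_spec <- function(inlet_diameter, dao_diameter, ai_diameter,
                       branch_diameters = NULL, arch_radius = NULL,
                       asc_length = 35, branch_clearance = NULL,
                       branch_angles_deg = c(BA = 130, LCCA = 95, LSA = 65),
                       ai_offset = 8, ai_stenosis_factor = 1,
                       ai_width = NULL, tube_length = NULL) {
  if (!is.null(tube_length)) {
    spec <- structure(list(kind = "tube", inlet_diameter = inlet_diameter,
                           outlet_diameter = dao_diameter,
                           length = tube_length),
                      class = "aorta_spec")
    return(validate_aorta_spec(spec))
  }
  if (is.null(branch_diameters))
    branch_diameters <- c(BA = 0.45, LCCA = 0.35, LSA = 0.35) * inlet_diameter
  if (is.null(arch_radius)) arch_radius <- 0.85 * inlet_diameter
  if (is.null(ai_width)) ai_width <- 0.75 * ai_diameter
  if (is.null(branch_clearance)) branch_clearance <- inlet_diameter / 2 + 5
  spec <- structure(list(
    kind = "aorta",
    inlet_diameter = inlet_diameter, dao_diameter = dao_diameter,
    ai_diameter = ai_diameter, branch_diameters = branch_diameters,
    arch_radius = arch_radius, asc_length = asc_length,
    branch_clearance = branch_clearance,
    branch_angles_deg = branch_angles_deg, ai_offset = ai_offset,
    ai_stenosis_factor = ai_stenosis_factor, ai_width = ai_width
  ), class = "aorta_spec")
  validate_aorta_spec(spec)
}

#' @rdname aorta_spec
#' @param diameter tube inlet diameter, mm.
#' @param length tube length, mm.
#' @param outlet_diameter tube outlet diameter, mm (a cone when it differs
#'   from `diameter`; radius interpolates linearly along the axis).
#' @export
tube_spec <- function(diameter, length, outlet_diameter = diameter) {
  aorta_spec(inlet_diameter = diameter, dao_diameter = outlet_diameter,
             ai_diameter = diameter, tube_length = length)
}

validate_aorta_spec <- function(spec) {
  pos <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("invalid aorta spec: ", what, " must be positive and finite",
           call. = FALSE)
  }
  if (spec$kind == "tube") {
    pos(spec$inlet_diameter, "inlet_diameter")
    pos(spec$outlet_diameter, "outlet_diameter")
    pos(spec$length, "length")
    return(spec)
  }
  pos(spec$inlet_diameter, "inlet_diameter")
  pos(spec$dao_diameter, "dao_diameter")
  pos(spec$ai_diameter, "ai_diameter")
  pos(spec$branch_diameters, "branch diameters")
  pos(spec$arch_radius, "arch_radius")
  pos(spec$asc_length, "asc_length")
  pos(spec$ai_offset, "ai_offset")
  if (spec$ai_stenosis_factor <= 0 || spec$ai_stenosis_factor > 1)
    stop("invalid aorta spec: ai_stenosis_factor must lie in (0, 1]",
         call. = FALSE)
  if (any(spec$branch_diameters >= spec$inlet_diameter))
    stop("invalid aorta spec: branch diameters must be smaller than the inlet diameter",
         call. = FALSE)
  if (length(spec$branch_diameters) != length(spec$branch_angles_deg))
    stop("invalid aorta spec: one attachment angle per branch required",
         call. = FALSE)
  if (any(spec$branch_angles_deg <= 5) || any(spec$branch_angles_deg >= 175))
    stop("invalid aorta spec: branch angles must lie strictly on the arch",
         call. = FALSE)
  # branches are vertical tubes; adjacent axes must not overlap
  Ra <- spec$arch_radius
  xs <- Ra * (1 + cos(spec$branch_angles_deg * pi / 180))
  rr <- spec$branch_diameters / 2
  ord <- order(xs)
  xs <- xs[ord]; rr <- rr[ord]
  if (length(xs) > 1) {
    gap <- diff(xs) - (rr[-length(rr)] + rr[-1])
    if (any(gap < 0.2))
      stop("invalid aorta spec: overlapping branches (axes ",
           paste(round(diff(xs), 1), collapse = ", "),
           " mm apart); increase arch_radius or branch spacing",
           call. = FALSE)
  }
  # descending segment must be long enough to finish the isthmus narrowing
  # and the taper to the DAo diameter above the DAo probe plane
  dao_trans <- 8
  need <- spec$ai_offset + spec$ai_width + dao_trans + 3
  if (spec$asc_length < need)
    stop("invalid aorta spec: asc_length must be at least ", round(need, 1),
         " mm for these isthmus settings", call. = FALSE)
  spec
}

#' Build the analytic geometry for an aorta specification
#'
#' Constructs the centerline polyline, the radius profile along arclength,
#' branch definitions and the named probe planes (`AscAo`, `AI`, `DAo` for
#' the full aorta; `inlet`, `mid`, `outlet` for a tube).
#'
#' @param spec an [aorta_spec()].
#' @param ds centerline sampling step, mm.
#' @return An object of class `aorta_geometry`.
#' @export
build_aorta <- function(spec, ds = 0.5) {
  stopifnot(inherits(spec, "aorta_spec"))
  if (spec$kind == "tube") {
    L <- spec$length
    z <- seq(0, L, by = min(ds, L / 8))
    if (z[length(z)] < L) z <- c(z, L)
    r1 <- spec$inlet_diameter / 2
    r2 <- spec$outlet_diameter / 2
    rad <- r1 + (r2 - r1) * z / L
    geom <- structure(list(
      kind = "tube", spec = spec,
      centerline = cbind(x = 0 * z, y = 0 * z, z = z),
      s = z, radius = rad,
      branches = list(),
      z_top = L,
      probes = list(
        inlet = list(z = 0, center = c(0, 0), segment = "main"),
        mid = list(z = L / 2, center = c(0, 0), segment = "main"),
        outlet = list(z = L, center = c(0, 0), segment = "main")
      )
    ), class = "aorta_geometry")
    return(geom)
  }

  La <- spec$asc_length
  Ra <- spec$arch_radius
  r_in <- spec$inlet_diameter / 2
  r_ai <- spec$ai_diameter / 2
  r_dao <- spec$dao_diameter / 2
  s_arch0 <- La
  s_top <- La + Ra * pi / 2
  s_arch1 <- La + Ra * pi
  s_ai <- s_arch1 + spec$ai_offset
  dao_trans <- 8
  s_end <- s_arch1 + La  # descending returns to z = 0

  radius_at <- function(s) {
    base <- ifelse(s <= s_top, r_in,
            ifelse(s <= s_ai, r_in + (r_ai - r_in) * (s - s_top) / (s_ai - s_top),
            ifelse(s <= s_ai + dao_trans,
                   r_ai + (r_dao - r_ai) * (s - s_ai) / dao_trans, r_dao)))
    f <- spec$ai_stenosis_factor
    w <- spec$ai_width
    if (f < 1) {
      inb <- abs(s - s_ai) < w
      base[inb] <- base[inb] *
        (1 - (1 - f) * cos(pi * (s[inb] - s_ai) / (2 * w))^2)
    }
    base
  }

  # centerline samples: ascending, arch (phi 180 -> 0), descending
  s_asc <- seq(0, La, by = ds)
  s_arc <- seq(La, s_arch1, by = ds)[-1]
  s_des <- seq(s_arch1, s_end, by = ds)[-1]
  if (s_des[length(s_des)] < s_end) s_des <- c(s_des, s_end)
  s_all <- c(s_asc, s_arc, s_des)
  pt <- function(s) {
    out <- matrix(0, length(s), 3)
    asc <- s <= La
    out[asc, 3] <- s[asc]
    arc <- s > La & s <= s_arch1
    phi <- pi - (s[arc] - La) / Ra
    out[arc, 1] <- Ra + Ra * cos(phi)
    out[arc, 3] <- La + Ra * sin(phi)
    des <- s > s_arch1
    out[des, 1] <- 2 * Ra
    out[des, 3] <- La - (s[des] - s_arch1)
    colnames(out) <- c("x", "y", "z")
    out
  }
  cl <- pt(s_all)

  # vertical branches from attachment points on the arch centerline
  lumen_top <- La + Ra + r_in
  z_top <- lumen_top + spec$branch_clearance - r_in  # = La + Ra + clearance
  if (z_top <= lumen_top + 1.5)
    stop("branch_clearance too small: branch caps would cut the arch lumen",
         call. = FALSE)
  branches <- list()
  for (nm in names(spec$branch_angles_deg)) {
    phi <- spec$branch_angles_deg[[nm]] * pi / 180
    base <- c(Ra + Ra * cos(phi), 0, La + Ra * sin(phi))
    branches[[nm]] <- list(name = nm, base = base,
                           radius = spec$branch_diameters[[nm]] / 2,
                           z_top = z_top, attach_phi = phi)
  }

  geom <- structure(list(
    kind = "aorta", spec = spec,
    centerline = cl, s = s_all, radius = radius_at(s_all),
    radius_at = radius_at,
    arch = list(R = Ra, center = c(Ra, 0, La)),
    s_keys = list(arch0 = s_arch0, top = s_top, arch1 = s_arch1,
                  # the isthmus spans from the last branch attachment (LSA)
                  # to just past the AI plane
                  isthmus0 = if ("LSA" %in% names(branches))
                    s_arch0 + (pi - branches$LSA$attach_phi) * Ra else s_arch1,
                  ai = s_ai, end = s_end, ai_width = spec$ai_width),
    branches = branches,
    z_top = z_top,
    probes = list(
      AscAo = list(z = La / 2, center = c(0, 0), segment = "asc"),
      AI = list(z = La - spec$ai_offset, center = c(2 * Ra, 0), segment = "desc"),
      DAo = list(z = 3, center = c(2 * Ra, 0), segment = "desc")
    )
  ), class = "aorta_geometry")
  geom
}

#' @export
print.aorta_geometry <- function(x, ...) {
  if (x$kind == "tube") {
    cat(sprintf("synthetic tube: D %.1f -> %.1f mm, length %.1f mm\n",
                x$spec$inlet_diameter, x$spec$outlet_diameter, x$spec$length))
  } else {
    cat(sprintf("synthetic aorta: AscAo %.1f mm, AI %.1f mm (stenosis factor %.2f), DAo %.1f mm\n",
                x$spec$inlet_diameter, x$spec$ai_diameter,
                x$spec$ai_stenosis_factor, x$spec$dao_diameter))
    cat(sprintf("  arch radius %.1f mm, branches: %s\n", x$spec$arch_radius,
                paste(sprintf("%s %.1f mm", names(x$branches),
                              2 * vapply(x$branches, `[[`, 0, "radius")),
                      collapse = ", ")))
  }
  cat("  probe planes:", paste(names(x$probes), collapse = ", "), "\n")
  invisible(x)
}

# arclength coordinate of a named probe plane
probe_s <- function(geom, location) {
  pl <- geom$probes[[location]]
  if (is.null(pl))
    stop("unknown probe location '", location, "'; known: ",
         paste(names(geom$probes), collapse = ", "), call. = FALSE)
  if (geom$kind == "tube") return(pl$z)
  if (pl$segment == "asc") pl$z else geom$s_keys$arch1 + (geom$spec$asc_length - pl$z)
}

#' Lumen diameter at a named probe plane
#'
#' For analytic geometries the diameter is evaluated exactly from the
#' radius profile. For voxelized domains ([voxelize()]) the cross-section
#' is taken as the connected set of fluid cells in the plane's slice around
#' the plane center and converted to an equivalent-circle diameter
#' `2 * sqrt(area / pi)`. For imported surface meshes the section polygon
#' area is used the same way.
#'
#' @param x an `aorta_geometry`, `voxel_domain` or `aorta_mesh`.
#' @param location probe plane name (see [build_aorta()]).
#' @param ... unused.
#' @return Diameter in mm.
#' @export
measure_diameter <- function(x, location, ...) UseMethod("measure_diameter")

#' @export
measure_diameter.aorta_geometry <- function(x, location, ...) {
  s <- probe_s(x, location)
  if (x$kind == "tube") {
    r1 <- x$spec$inlet_diameter / 2
    r2 <- x$spec$outlet_diameter / 2
    return(2 * (r1 + (r2 - r1) * s / x$spec$length))
  }
  2 * x$radius_at(s)
}
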