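# Surface mesh export/import (ASCII STL) and a legacy-VTK image writer for
# voxel fields. The analytic tube-union geometry is triangulated as one
# closed shell per tube (rings of vertices along each centerline, capped
# with fans), so every edge of each shell is shared by exactly two
# triangles.

triangulate_tube <- function(centers, radii, e1s, e2s, nseg = 32) {
  nr <- nrow(centers)
  verts <- matrix(0, nr * nseg + 2, 3)
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  for (i in seq_len(nr)) {
    ring <- centers[rep(i, nseg), ] + radii[i] *
      (cos(th) %o% e1s[i, ] + sin(th) %o% e2s[i, ])
    verts[(i - 1) * nseg + seq_len(nseg), ] <- ring
  }
  c0 <- nr * nseg + 1  # start cap center
  c1 <- nr * nseg + 2  # end cap center
  verts[c0, ] <- centers[1, ]
  verts[c1, ] <- centers[nr, ]
  faces <- list()
  vid <- function(i, s) (i - 1) * nseg + ((s - 1) %% nseg) + 1
  for (i in seq_len(nr - 1)) {
    for (s in seq_len(nseg)) {
      a <- vid(i, s); b <- vid(i, s + 1); cth <- vid(i + 1, s); dth <- vid(i + 1, s + 1)
      faces[[length(faces) + 1]] <- c(a, b, dth)
      faces[[length(faces) + 1]] <- c(a, dth, cth)
    }
  }
  for (s in seq_len(nseg)) {
    faces[[length(faces) + 1]] <- c(c0, vid(1, s + 1), vid(1, s))
    faces[[length(faces) + 1]] <- c(c1, vid(nr, s), vid(nr, s + 1))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# triangulated surface of an aorta geometry (one shell per tube)
surface_mesh <- function(geom, nseg = 32, ds = 1) {
  shells <- list()
  # main vessel: frames from the planar centerline (binormal = +y)
  keep <- unique(c(seq(1, nrow(geom$centerline), by = max(1L, round(ds / mean(diff(geom$s))))),
                   nrow(geom$centerline)))
  ctr <- geom$centerline[keep, , drop = FALSE]
  rad <- geom$radius[keep]
  n <- nrow(ctr)
  tang <- rbind(ctr[2, ] - ctr[1, ],
                if (n > 2) ctr[3:n, , drop = FALSE] - ctr[1:(n - 2), , drop = FALSE],
                ctr[n, ] - ctr[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  e2 <- matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE)
  e1 <- cbind(tang[, 3], 0, -tang[, 1])  # y x tangent for planar curves
  e1 <- e1 / sqrt(rowSums(e1^2))
  shells[[1]] <- triangulate_tube(ctr, rad, e1, e2, nseg)
  for (br in geom$branches) {
    zz <- seq(br$base[3], br$z_top, length.out = max(2, ceiling((br$z_top - br$base[3]) / ds)))
    ctrb <- cbind(br$base[1], br$base[2], zz)
    nb <- length(zz)
    shells[[length(shells) + 1]] <- triangulate_tube(
      ctrb, rep(br$radius, nb),
      matrix(rep(c(1, 0, 0), nb), nb, 3, byrow = TRUE),
      matrix(rep(c(0, 1, 0), nb), nb, 3, byrow = TRUE), nseg)
  }
  verts <- do.call(rbind, lapply(shells, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(shells, function(s) nrow(s$vertices), 0)))
  faces <- do.call(rbind, Map(function(s, o) s$faces + o, shells, off[-length(off)]))
  structure(list(vertices = verts, faces = faces), class = "aorta_mesh")
}

#' Export an aorta geometry as a triangulated surface
#'
#' Writes an ASCII STL of the lumen surface (one closed shell per vessel
#' tube) and optionally a legacy-VTK polydata copy carrying the same
#' triangles.
#'
#' @param geom an [build_aorta()] geometry (or an `aorta_mesh`).
#' @param path output STL path.
#' @param vtk_path optional .vtk polydata path.
#' @param nseg circumferential resolution.
#' @return The mesh (invisibly).
#' @export
export_surface <- function(geom, path, vtk_path = NULL, nseg = 32) {
  mesh <- if (inherits(geom, "aorta_mesh")) geom else surface_mesh(geom, nseg)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
  nrm <- nrm / nn
  writeLines("solid aorta", con)
  body <- sprintf(
    "facet normal %.9e %.9e %.9e\n outer loop\n  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(body, con)
  writeLines("endsolid aorta", con)
  if (!is.null(vtk_path)) write_vtk_polydata(mesh, vtk_path)
  invisible(mesh)
}

#' Import a triangulated surface from ASCII STL
#'
#' @param path STL file path.
#' @param digits vertex-merge rounding (decimal digits).
#' @return An `aorta_mesh` (vertices, faces with shared vertex indices).
#' @export
import_surface <- function(path, digits = 6) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (is.null(nums) || nrow(nums) %% 3 != 0)
    stop("malformed STL: '", path, "'", call. = FALSE)
  key <- apply(round(nums, digits), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  id <- match(key, key[uk])
  faces <- matrix(id, ncol = 3, byrow = TRUE)
  structure(list(vertices = verts, faces = faces), class = "aorta_mesh")
}

#' Check that every edge of a mesh is shared by exactly two triangles
#'
#' @param mesh an `aorta_mesh`.
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' @export
measure_diameter.aorta_mesh <- function(x, location, ...) {
  z <- if (is.numeric(location)) location
       else stop("mesh diameters are measured at a numeric z plane", call. = FALSE)
  v <- x$vertices; f <- x$faces
  # nudge the plane off any vertex ring so edge crossings are well defined
  if (any(abs(v[, 3] - z) < 1e-9)) z <- z + 1e-6
  pts <- list()
  for (edge in list(c(1, 2), c(2, 3), c(3, 1))) {
    a <- v[f[, edge[1]], , drop = FALSE]
    b <- v[f[, edge[2]], , drop = FALSE]
    cross <- (a[, 3] - z) * (b[, 3] - z) < 0
    if (any(cross)) {
      t <- (z - a[cross, 3]) / (b[cross, 3] - a[cross, 3])
      pts[[length(pts) + 1]] <- cbind(a[cross, 1] + t * (b[cross, 1] - a[cross, 1]),
                                      a[cross, 2] + t * (b[cross, 2] - a[cross, 2]))
    }
  }
  p <- unique(round(do.call(rbind, pts), 9))
  if (is.null(p) || nrow(p) < 3)
    stop("plane z = ", z, " does not cut the mesh", call. = FALSE)
  # convex section: order by angle and apply the shoelace formula
  ctr <- colMeans(p)
  o <- order(atan2(p[, 2] - ctr[2], p[, 1] - ctr[1]))
  p <- p[o, , drop = FALSE]
  xn <- c(p[-1, 1], p[1, 1]); yn <- c(p[-1, 2], p[1, 2])
  area <- abs(sum(p[, 1] * yn - xn * p[, 2])) / 2
  2 * sqrt(area / pi)
}

write_vtk_polydata <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", "aorta surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  invisible(path)
}

#' Write a voxel field as legacy VTK structured points
#'
#' Writes the fluid mask plus optional cell-centered scalar fields (e.g.
#' pressure, velocity magnitude, LNH) for inspection in standard viewers.
#'
#' @param domain a [voxelize()] domain.
#' @param path output .vtk path.
#' @param fields named list of 3D arrays matching the domain dims.
#' @export
write_vtk_image <- function(domain, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- domain$dims
  writeLines(c("# vtk DataFile Version 3.0", "voxel domain", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.6f %.6f %.6f",
                       domain$origin[1] + domain$h / 2,
                       domain$origin[2] + domain$h / 2,
                       domain$origin[3] + domain$h / 2),
               sprintf("SPACING %g %g %g", domain$h, domain$h, domain$h),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.vector(domain$mask)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    vals <- as.vector(fields[[nm]])
    vals[is.na(vals)] <- 0
    writeLines(sprintf("%.6g", vals), con)
  }
  invisible(path)
}
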