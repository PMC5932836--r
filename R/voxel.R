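# Voxelized flow domains: the analytic tube-union geometry is rasterized on
# a uniform Cartesian grid (cell-centered, 0-based indices mapping to
# physical centers at origin + (i + 0.5) h), with labeled inlet/outlet cap
# faces on the bottom (z = 0) and top boundaries and anatomical region /
# wall-quadrant labels per fluid cell.

REGION_LEVELS <- c("AscAo", "arch", "AI", "DAo", "BA", "LCCA", "LSA")
QUAD_LEVELS <- c("O", "L", "I", "R")

#' Voxelize an aorta geometry into a labeled flow domain
#'
#' Rasterizes the geometry on an isotropic grid of spacing `h`. Fluid cells
#' are those whose centers lie inside the lumen; every fluid cell must be
#' reachable from the inlet (single connected component). Inlet and outlet
#' caps are the fluid cells on the bottom/top domain boundary; walls are all
#' other fluid-solid interfaces.
#'
#' @param geom an [build_aorta()] geometry.
#' @param h voxel spacing, mm. Must resolve the smallest lumen diameter
#'   with at least 8 cells (a warning is issued below 10).
#' @return An object of class `voxel_domain` with the mask, signed distance
#'   to the lumen surface, per-cell region and wall-quadrant labels, cap
#'   definitions and grid metadata.
#' @export
voxelize <- function(geom, h) {
  stopifnot(inherits(geom, "aorta_geometry"), h > 0)
  min_d <- 2 * min(geom$radius)
  if (length(geom$branches))
    min_d <- min(min_d, 2 * min(vapply(geom$branches, `[[`, 0, "radius")))
  ncross <- min_d / h
  if (ncross < 8)
    stop(sprintf("h = %g mm too coarse: only %.1f cells across the smallest lumen diameter (%.2f mm); need >= 8",
                 h, ncross, min_d), call. = FALSE)
  if (ncross < 10)
    warning(sprintf("marginal resolution: %.1f cells across the smallest lumen diameter", ncross))

  # bounding box from centerline samples inflated by the local radius
  cl <- geom$centerline
  rad <- geom$radius
  xmin <- min(cl[, 1] - rad); xmax <- max(cl[, 1] + rad)
  ymin <- min(cl[, 2] - rad); ymax <- max(cl[, 2] + rad)
  for (br in geom$branches) {
    xmin <- min(xmin, br$base[1] - br$radius)
    xmax <- max(xmax, br$base[1] + br$radius)
    ymin <- min(ymin, br$base[2] - br$radius)
    ymax <- max(ymax, br$base[2] + br$radius)
  }
  # the lateral origin is offset by an irrational-looking fraction of h so
  # vessel axes never align with cell corners across refinement levels
  # (alignment produces a non-vanishing rasterization bias)
  pad <- 2 * h
  x0 <- xmin - pad - 0.2371 * h; y0 <- ymin - pad - 0.3319 * h
  nx <- as.integer(ceiling((xmax + pad - x0) / h))
  ny <- as.integer(ceiling((ymax + pad - y0) / h))
  nz <- as.integer(round(geom$z_top / h))
  if (abs(nz * h - geom$z_top) > 1e-9)
    warning(sprintf("domain height snapped from %.4f to %.4f mm (integer number of cells)",
                    geom$z_top, nz * h))
  origin <- c(x0, y0, 0)
  dims <- c(nx, ny, nz)

  # capsule segment table: main centerline plus vertical branches
  # (branches extended to the snapped top so their caps are flush)
  n <- nrow(cl)
  seg <- cbind(cl[-n, 1], cl[-n, 2], cl[-n, 3], cl[-1, 1], cl[-1, 2], cl[-1, 3],
               rad[-n], rad[-1], 0, geom$s[-n], geom$s[-1])
  bi <- 0
  for (br in geom$branches) {
    bi <- bi + 1
    seg <- rbind(seg, c(br$base[1], br$base[2], br$base[3],
                        br$base[1], br$base[2], nz * h,
                        br$radius, br$radius, bi, 0, nz * h - br$base[3]))
  }
  vox <- voxelize_kernel(origin, h, dims, seg)
  mask <- array(vox$mask, dims)
  sdist <- array(vox$sdist, dims)
  sid <- array(vox$sid, dims)
  snear <- array(vox$snear, dims)

  region <- array(0L, dims)
  quad <- array(0L, dims)
  fl <- mask == 1L
  if (!any(fl)) stop("voxelization produced no fluid cells", call. = FALSE)

  if (geom$kind == "tube") {
    region[fl] <- 4L
  } else {
    ks <- geom$s_keys
    s <- snear[fl]; id <- sid[fl]
    i0 <- if (is.null(ks$isthmus0)) ks$arch1 else ks$isthmus0
    reg <- ifelse(id > 0, 4L + id,
           ifelse(s < ks$arch0, 1L,
           ifelse(s < i0, 2L,
           ifelse(s < ks$ai + ks$ai_width, 3L, 4L))))
    region[fl] <- reg
    # wall quadrant relative to the arch plane (y = 0): outer/inner along
    # the local curvature direction, left/right along +/- y
    idx <- which(fl)
    cc <- cell_centers(origin, h, dims, idx)
    ppx <- vox$px[idx]; ppz <- vox$pz[idx]
    ox <- numeric(length(idx)); oz <- numeric(length(idx))
    asc <- id == 0 & s < ks$arch0
    des <- id == 0 & s >= ks$arch1
    arc <- id == 0 & !asc & !des
    ox[asc] <- -1
    ox[des] <- 1
    dxv <- ppx[arc] - geom$arch$center[1]
    dzv <- ppz[arc] - geom$arch$center[3]
    nn <- sqrt(dxv^2 + dzv^2); nn[nn == 0] <- 1
    ox[arc] <- dxv / nn; oz[arc] <- dzv / nn
    rho_x <- cc[, 1] - vox$px[idx]
    rho_y <- cc[, 2] - vox$py[idx]
    rho_z <- cc[, 3] - vox$pz[idx]
    comp_o <- rho_x * ox + rho_z * oz
    theta <- atan2(rho_y, comp_o)
    qd <- ifelse(abs(theta) <= pi / 4, 1L,
          ifelse(theta > pi / 4 & theta <= 3 * pi / 4, 2L,
          ifelse(abs(theta) > 3 * pi / 4, 3L, 4L)))
    qd[id > 0] <- 0L
    quad[fl] <- qd
  }

  # caps
  caps <- list()
  bot <- which(mask[, , 1] == 1L)
  if (geom$kind == "tube") {
    inlet_ij <- bot
    top <- which(mask[, , nz] == 1L)
    caps$inlet <- list(k = 1L, cells = inlet_ij)
    caps$outlets <- list(outlet = list(k = nz, cells = top, side = "top"))
  } else {
    sb <- snear[, , 1][bot]
    inlet_ij <- bot[sb < geom$s_keys$arch0]
    dao_ij <- bot[sb >= geom$s_keys$arch1]
    caps$inlet <- list(k = 1L, cells = inlet_ij)
    caps$outlets <- list(DAo = list(k = 1L, cells = dao_ij, side = "bottom"))
    sid_top <- sid[, , nz]
    bi <- 0
    for (nm in names(geom$branches)) {
      bi <- bi + 1
      caps$outlets[[nm]] <- list(k = nz, cells = which(sid_top == bi &
                                                         mask[, , nz] == 1L),
                                 side = "top")
    }
  }
  if (length(caps$inlet$cells) == 0) stop("empty inlet cap", call. = FALSE)
  for (nm in names(caps$outlets))
    if (length(caps$outlets[[nm]]$cells) == 0)
      stop("empty outlet cap '", nm, "'", call. = FALSE)

  # connectivity: every fluid cell reachable from the inlet
  nxy <- nx * ny
  seeds <- caps$inlet$cells  # k = 1 slice: linear index == cell index
  lab <- flood_fill(as.integer(mask), as.integer(dims), as.integer(seeds))
  if (sum(lab) != sum(mask))
    stop(sprintf("fluid domain is disconnected: %d of %d fluid cells unreachable from the inlet",
                 sum(mask) - sum(lab), sum(mask)), call. = FALSE)

  structure(list(
    h = h, origin = origin, dims = dims, mask = mask, sdist = sdist,
    sid = sid, snear = snear,
    near_pt = list(x = array(vox$px, dims), y = array(vox$py, dims),
                   z = array(vox$pz, dims)),
    region = region, quad = quad, caps = caps,
    geom = geom, n_fluid = sum(mask),
    region_levels = REGION_LEVELS, quad_levels = QUAD_LEVELS
  ), class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  cat(sprintf("voxel_domain: %d x %d x %d cells at h = %.3g mm, %d fluid cells (%.1f%%)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$n_fluid,
              100 * x$n_fluid / prod(x$dims)))
  cat(sprintf("  inlet: %d cells; outlets: %s\n", length(x$caps$inlet$cells),
              paste(sprintf("%s (%d)", names(x$caps$outlets),
                            vapply(x$caps$outlets, function(o) length(o$cells), 0L)),
                    collapse = ", ")))
  invisible(x)
}

# physical centers of cells given 1-based linear indices
cell_centers <- function(origin, h, dims, idx) {
  idx0 <- idx - 1
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(origin[1] + (i + 0.5) * h,
        origin[2] + (j + 0.5) * h,
        origin[3] + (k + 0.5) * h)
}

#' Fluid volume of a voxel domain
#'
#' @param domain a [voxelize()] domain.
#' @return Volume in mm^3 (`n_fluid * h^3`).
#' @export
voxel_volume <- function(domain) domain$n_fluid * domain$h^3

#' @export
measure_diameter.voxel_domain <- function(x, location, ...) {
  pl <- x$geom$probes[[location]]
  if (is.null(pl))
    stop("unknown probe location '", location, "'; known: ",
         paste(names(x$geom$probes), collapse = ", "), call. = FALSE)
  k <- max(1L, min(x$dims[3], as.integer(round((pl$z - x$origin[3]) / x$h + 0.5))))
  slice <- x$mask[, , k]
  # restrict to the connected 2D component around the plane center
  ci <- max(1L, min(x$dims[1],
                    as.integer(ceiling((pl$center[1] - x$origin[1]) / x$h))))
  cj <- max(1L, min(x$dims[2],
                    as.integer(ceiling((pl$center[2] - x$origin[2]) / x$h))))
  if (slice[ci, cj] != 1L) {
    cand <- which(slice == 1L, arr.ind = TRUE)
    if (nrow(cand) == 0) stop("no fluid cells at probe plane", call. = FALSE)
    dd <- (cand[, 1] - ci)^2 + (cand[, 2] - cj)^2
    ci <- cand[which.min(dd), 1]; cj <- cand[which.min(dd), 2]
  }
  m3 <- array(slice, c(x$dims[1], x$dims[2], 1L))
  seed <- ci + x$dims[1] * (cj - 1)
  lab <- flood_fill(as.integer(m3), as.integer(c(x$dims[1], x$dims[2], 1L)),
                    as.integer(seed))
  area <- sum(lab) * x$h^2
  2 * sqrt(area / pi)
}

#' Area of a labeled cap, mm^2
#'
#' @param domain a [voxelize()] domain.
#' @param cap `"inlet"` or an outlet name.
#' @export
cap_area <- function(domain, cap) {
  n <- if (cap == "inlet") length(domain$caps$inlet$cells)
       else length(domain$caps$outlets[[cap]]$cells)
  n * domain$h^2
}
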