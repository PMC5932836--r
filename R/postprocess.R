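# Extraction of the clinically reported hemodynamic quantities from solved
# fields: wall shear stress maps and their peak-systolic extrema, PSV/PSP
# probe readings, streamlines and localized normalized helicity (LNH).

# cell-centered velocity components (3D arrays, m/s)
cc_velocity <- function(field) {
  d <- dim(field$p)
  list(u = (field$u[1:d[1], , , drop = FALSE] + field$u[2:(d[1] + 1), , , drop = FALSE]) / 2,
       v = (field$v[, 1:d[2], , drop = FALSE] + field$v[, 2:(d[2] + 1), , drop = FALSE]) / 2,
       w = (field$w[, , 1:d[3], drop = FALSE] + field$w[, , 2:(d[3] + 1), drop = FALSE]) / 2)
}

# central-difference curl of the cell-centered velocity (1/s); one-sided at
# array edges, solid cells treated as zero velocity
cc_vorticity <- function(cc, h_mm) {
  h <- h_mm * 1e-3
  dd <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    n <- d[axis]
    ap <- array(0, d); am <- array(0, d)
    if (axis == 1) { ap[1:(n - 1), , ] <- a[2:n, , ]; am[2:n, , ] <- a[1:(n - 1), , ] }
    if (axis == 2) { ap[, 1:(n - 1), ] <- a[, 2:n, ]; am[, 2:n, ] <- a[, 1:(n - 1), ] }
    if (axis == 3) { ap[, , 1:(n - 1)] <- a[, , 2:n]; am[, , 2:n] <- a[, , 1:(n - 1)] }
    (ap - am) / (2 * h)
  }
  list(x = dd(cc$w, 2) - dd(cc$v, 3),
       y = dd(cc$u, 3) - dd(cc$w, 1),
       z = dd(cc$v, 1) - dd(cc$u, 2))
}

#' Wall shear stress map
#'
#' Estimates the viscous shear stress on every wall face of the voxelized
#' domain with a first-order one-sided closure: the tangential velocity
#' magnitude at the first fluid cell divided by the wall-normal distance,
#' times the dynamic viscosity. By default the tangential velocity is the
#' near-wall speed projected onto the analytic lumen surface (using the
#' stored surface normal), and the wall-normal distance is the signed
#' distance to that surface, clamped to `[0.25 h, 1.25 h]` (calibrated once against the analytic Poiseuille wall shear on a voxelized cylinder): cells closer
#' than about half a cell to the surface have their velocity controlled by
#' the stair-step face half a cell away, so the effective no-slip distance
#' is bounded below. This removes most of the stair-step scatter of the
#' voxel wall.
#'
#' @param field a flow field (from [simulate_case()]'s `peak_field` or
#'   [ns_advance()]).
#' @param domain the [voxelize()] domain the field was computed on.
#' @param props [fluid_properties()] (viscosity).
#' @param dn wall-distance convention: `"sdf"` (default, distance to the
#'   analytic surface) or `"half-cell"` (h/2, the distance to the stair-step
#'   face where no-slip is imposed).
#' @return A data frame of class `wss_map`, one row per wall face: cell
#'   indices and center coordinates (mm), face direction, `tau_Pa`, and the
#'   anatomical `region` (with branch-ostium override) and wall-quadrant
#'   (`O`/`L`/`I`/`R`) labels.
#' @export
wall_shear_stress <- function(field, domain, props = fluid_properties(),
                              dn = c("sdf", "half-cell")) {
  dn <- match.arg(dn)
  d <- domain$dims
  if (!all(dim(field$p) == d))
    stop("field and domain dimensions do not match", call. = FALSE)
  m <- domain$mask
  cc <- cc_velocity(field)
  h_m <- domain$h * 1e-3

  shift_solid <- function(axis, side) {
    # TRUE where the neighbor across (axis, side) is solid or outside
    out <- array(TRUE, d)
    n <- d[axis]
    if (axis == 1 && side < 0) out[2:n, , ] <- m[1:(n - 1), , ] == 0L
    if (axis == 1 && side > 0) out[1:(n - 1), , ] <- m[2:n, , ] == 0L
    if (axis == 2 && side < 0) out[, 2:n, ] <- m[, 1:(n - 1), ] == 0L
    if (axis == 2 && side > 0) out[, 1:(n - 1), ] <- m[, 2:n, ] == 0L
    if (axis == 3 && side < 0) out[, , 2:n] <- m[, , 1:(n - 1)] == 0L
    if (axis == 3 && side > 0) out[, , 1:(n - 1)] <- m[, , 2:n] == 0L
    out
  }
  # cap faces are not walls
  capmask_bot <- array(FALSE, c(d[1], d[2]))
  capmask_bot[domain$caps$inlet$cells] <- TRUE
  capmask_top <- array(FALSE, c(d[1], d[2]))
  for (o in domain$caps$outlets) {
    if (o$side == "bottom") capmask_bot[o$cells] <- TRUE else capmask_top[o$cells] <- TRUE
  }

  rows <- list()
  dirs <- list(c(1, -1), c(1, +1), c(2, -1), c(2, +1), c(3, -1), c(3, +1))
  dirnames <- c("-x", "+x", "-y", "+y", "-z", "+z")
  fluid <- m == 1L
  for (di in seq_along(dirs)) {
    axis <- dirs[[di]][1]; side <- dirs[[di]][2]
    wallface <- fluid & shift_solid(axis, side)
    if (axis == 3 && side < 0) wallface[, , 1] <- wallface[, , 1] & !capmask_bot
    if (axis == 3 && side > 0) wallface[, , d[3]] <- wallface[, , d[3]] & !capmask_top
    idx <- which(wallface)
    if (!length(idx)) next
    if (dn == "sdf") {
      # tangential speed relative to the analytic surface normal
      ctr <- cell_centers(domain$origin, domain$h, d, idx)
      nx_ <- ctr[, 1] - domain$near_pt$x[idx]
      ny_ <- ctr[, 2] - domain$near_pt$y[idx]
      nz_ <- ctr[, 3] - domain$near_pt$z[idx]
      nn <- sqrt(nx_^2 + ny_^2 + nz_^2); nn[nn == 0] <- 1
      nx_ <- nx_ / nn; ny_ <- ny_ / nn; nz_ <- nz_ / nn
      un <- cc$u[idx] * nx_ + cc$v[idx] * ny_ + cc$w[idx] * nz_
      tang <- sqrt(pmax(cc$u[idx]^2 + cc$v[idx]^2 + cc$w[idx]^2 - un^2, 0))
      dist_mm <- pmin(pmax(-domain$sdist[idx], 0.25 * domain$h), 1.25 * domain$h)
    } else {
      tang <- sqrt(switch(axis,
                          cc$v[idx]^2 + cc$w[idx]^2,
                          cc$u[idx]^2 + cc$w[idx]^2,
                          cc$u[idx]^2 + cc$v[idx]^2))
      dist_mm <- rep(domain$h / 2, length(idx))
    }
    tau <- props$mu * tang / (dist_mm * 1e-3)
    rows[[di]] <- data.frame(cell = idx, dir = dirnames[di], tau_Pa = tau)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no wall faces found", call. = FALSE)
  ctr <- cell_centers(domain$origin, domain$h, d, out$cell)
  out$x_mm <- ctr[, 1]; out$y_mm <- ctr[, 2]; out$z_mm <- ctr[, 3]
  out$region <- wall_region_tags(domain, out$cell)
  out$quad <- c(NA, domain$quad_levels)[domain$quad[out$cell] + 1L]
  rownames(out) <- NULL
  class(out) <- c("wss_map", "data.frame")
  attr(out, "h") <- domain$h
  attr(out, "z_top") <- domain$dims[3] * domain$h
  attr(out, "time") <- field$t
  out
}

# anatomical region per cell, with branch-ostium override near attachments
wall_region_tags <- function(domain, cells) {
  reg <- domain$region_levels[domain$region[cells]]
  geom <- domain$geom
  if (geom$kind == "tube" || !length(geom$branches)) return(reg)
  ctr <- cell_centers(domain$origin, domain$h, domain$dims, cells)
  for (br in geom$branches) {
    dd <- sqrt((ctr[, 1] - br$base[1])^2 + (ctr[, 2] - br$base[2])^2 +
                 (ctr[, 3] - br$base[3])^2)
    near <- dd <= 2 * br$radius & reg %in% c(br$name, "arch")
    reg[near] <- paste0(br$name, "_ostium")
  }
  reg
}

#' Peak-systolic wall shear stress extrema
#'
#' Finds the global minimum and maximum of a wall shear stress map computed
#' at the peak-systolic instant, with their anatomical region and wall
#' quadrant tags. Faces within `margin` cells of the inlet/outlet cap
#' planes are excluded (entrance/exit artifacts of the truncated domain).
#'
#' @param wss a [wall_shear_stress()] map at the peak-systolic instant,
#'   or a list of maps with a `peak` index.
#' @param margin cap-exclusion margin in cells (default 2).
#' @param include_extensions include the walls of the branch outflow
#'   tubes beyond their ostia. Default `FALSE`: the straight branch tubes
#'   are outflow extensions of the truncated anatomy (ostium faces are
#'   always kept), and extension walls are conventionally excluded from
#'   reported wall-shear maps.
#' @param k number of most extreme faces over which the anatomical
#'   location is taken as the modal region/quadrant (default 9). The
#'   reported `value` is always the true global extremum; the modal
#'   neighborhood makes the *localization* robust, since the argmin of a
#'   near-stagnation stress field over thousands of faces is single-voxel
#'   noise.
#' @return List with `min` and `max`, each `value` (Pa), `region`, `quad`,
#'   and the coordinates of the extreme face.
#' @export
pswss_extrema <- function(wss, margin = 2, include_extensions = FALSE,
                          k = 9) {
  if (is.list(wss) && !is.data.frame(wss)) {
    pk <- attr(wss, "peak")
    if (is.null(pk)) stop("list input needs a 'peak' attribute", call. = FALSE)
    wss <- wss[[pk]]
  }
  if (!inherits(wss, "wss_map") || nrow(wss) == 0)
    stop("empty or invalid wall shear stress map", call. = FALSE)
  h <- attr(wss, "h"); ztop <- attr(wss, "z_top")
  keep <- wss$z_mm > margin * h & wss$z_mm < ztop - margin * h
  if (!include_extensions)
    keep <- keep & !(wss$region %in% c("BA", "LCCA", "LSA"))
  if (!any(keep)) stop("no wall faces outside the cap margin", call. = FALSE)
  ww <- wss[keep, ]
  k <- min(k, nrow(ww))
  pick <- function(ord) {
    i <- ord[1]
    sel <- ord[seq_len(k)]
    key <- paste(ww$region[sel], ifelse(is.na(ww$quad[sel]), "", ww$quad[sel]))
    modal <- sel[match(names(which.max(table(key))), key)]
    list(value = ww$tau_Pa[i], region = ww$region[modal],
         quad = ww$quad[modal],
         x_mm = ww$x_mm[i], y_mm = ww$y_mm[i], z_mm = ww$z_mm[i])
  }
  structure(list(min = pick(order(ww$tau_Pa)),
                 max = pick(order(-ww$tau_Pa)),
                 n_faces = nrow(ww)),
            class = "pswss_extrema")
}

#' @export
print.pswss_extrema <- function(x, ...) {
  cat(sprintf("PSWSS extrema over %d wall faces:\n", x$n_faces))
  cat(sprintf("  max %.3f Pa at %s (%s wall)\n", x$max$value, x$max$region,
              ifelse(is.na(x$max$quad), "branch", x$max$quad)))
  cat(sprintf("  min %.4f Pa at %s (%s wall)\n", x$min$value, x$min$region,
              ifelse(is.na(x$min$quad), "branch", x$min$quad)))
  invisible(x)
}

#' Peak systolic velocity and pressure probes
#'
#' For a completed simulation, reads the probe traces of the final cardiac
#' cycle: PSV is the maximum over the cycle of the largest velocity
#' magnitude on the ascending-aorta probe plane (cm/s, emulating the
#' fastest jet seen by Doppler TTE); PSP is the maximum of the
#' area-averaged pressure on the aortic-isthmus plane (mmHg, emulating a
#' catheter reading).
#'
#' @param x a `hemo_sim` from [simulate_case()], or a single flow field
#'   (then `domain` is required and the instantaneous values are returned).
#' @param domain required for the single-field form.
#' @param ... unused.
#' @return A one-row data frame of class `probe_result`: `psv_cm_s`,
#'   `psp_mmHg`, `t_psv_s`, `t_psp_s` (times within the cycle).
#' @export
extract_probes <- function(x, ...) UseMethod("extract_probes")

#' @rdname extract_probes
#' @export
extract_probes.hemo_sim <- function(x, ...) {
  T <- x$inlet$period
  t0 <- (x$controls$n_cycles - 1) * T
  last <- x$trace[x$trace$t_s > t0 + 1e-12, ]
  i1 <- which.max(last$psv_cm_s)
  i2 <- which.max(last$p_ai_mmHg)
  structure(data.frame(psv_cm_s = last$psv_cm_s[i1],
                       psp_mmHg = last$p_ai_mmHg[i2],
                       t_psv_s = last$t_s[i1] - t0,
                       t_psp_s = last$t_s[i2] - t0),
            class = c("probe_result", "data.frame"))
}

#' @rdname extract_probes
#' @export
extract_probes.default <- function(x, domain, ...) {
  stopifnot(inherits(domain, "voxel_domain"))
  probes <- domain$geom$probes
  psv_nm <- if (domain$geom$kind == "tube") "mid" else "AscAo"
  pai_nm <- if (domain$geom$kind == "tube") "mid" else "AI"
  vals <- lapply(c(psv = psv_nm, pai = pai_nm), function(nm) {
    pl <- probes[[nm]]
    if (is.null(pl)) stop("probe plane outside domain", call. = FALSE)
    k <- max(1L, min(domain$dims[3],
                     as.integer(round((pl$z - domain$origin[3]) / domain$h + 0.5))))
    reg <- domain$region[, , k]
    keep <- if (domain$geom$kind == "tube") reg > 0L
            else if (pl$segment == "asc") reg == 1L else reg %in% c(3L, 4L)
    cells <- which(keep & domain$mask[, , k] == 1L)
    list(k = k, cells = cells)
  })
  cc <- slice_cc_velocity(x, vals$psv$k)
  psv <- 100 * sqrt(max(cc$u[vals$psv$cells]^2 + cc$v[vals$psv$cells]^2 +
                          cc$w[vals$psv$cells]^2))
  psp <- pa_to_mmhg(mean(x$p[, , vals$pai$k][vals$pai$cells]))
  structure(data.frame(psv_cm_s = psv, psp_mmHg = psp,
                       t_psv_s = x$t, t_psp_s = x$t),
            class = c("probe_result", "data.frame"))
}

#' Streamlines and localized normalized helicity
#'
#' Computes the localized normalized helicity LNH = (u . omega) /
#' (|u| |omega|) per fluid cell (the cosine of the angle between velocity
#' and vorticity; +/-1 for purely helical flow) and integrates streamlines
#' from seed points with fixed-step spatial RK4 on the normalized velocity
#' field until they exit the fluid or reach the step cap.
#'
#' @param field a flow field.
#' @param domain its [voxelize()] domain.
#' @param seeds matrix of seed points (mm, one per row); default: a small
#'   grid across the inlet cap.
#' @param step integration step, mm (default h/2).
#' @param max_steps per-streamline step cap.
#' @param eps velocity/vorticity magnitude (SI) below which LNH is set to 0.
#' @return Object of class `helicity_map`: `lnh` (3D array, NA in solid),
#'   `streamlines` (list of matrices of mm coordinates).
#' @export
streamlines_and_lnh <- function(field, domain, seeds = NULL, step = NULL,
                                max_steps = 4000, eps = 1e-10) {
  cc <- cc_velocity(field)
  vort <- cc_vorticity(cc, domain$h)
  # zero out solid for the dot products
  solid <- domain$mask == 0L
  for (nm in c("u", "v", "w")) cc[[nm]][solid] <- 0
  umag <- sqrt(cc$u^2 + cc$v^2 + cc$w^2)
  wmag <- sqrt(vort$x^2 + vort$y^2 + vort$z^2)
  dot <- cc$u * vort$x + cc$v * vort$y + cc$w * vort$z
  lnh <- array(0, domain$dims)
  ok <- umag > eps & wmag > eps
  lnh[ok] <- dot[ok] / (umag[ok] * wmag[ok])
  lnh[solid] <- NA_real_

  if (is.null(step)) step <- domain$h / 2
  if (is.null(seeds)) {
    ctr <- cell_centers(domain$origin, domain$h, domain$dims,
                        domain$caps$inlet$cells)
    ctr[, 3] <- domain$origin[3] + 1.5 * domain$h
    keep <- seq(1, nrow(ctr), length.out = min(9, nrow(ctr)))
    seeds <- ctr[unique(round(keep)), , drop = FALSE]
  }
  interp <- function(pos) {
    # trilinear interpolation of cell-centered velocity at pos (mm)
    g <- (pos - domain$origin) / domain$h - 0.5
    i0 <- floor(g)
    f <- g - i0
    acc <- c(0, 0, 0)
    wsum <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (any(ii < 0) || any(ii >= domain$dims)) next
      wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      ci <- ii[1] + 1; cj <- ii[2] + 1; ck <- ii[3] + 1
      acc <- acc + wgt * c(cc$u[ci, cj, ck], cc$v[ci, cj, ck], cc$w[ci, cj, ck])
      wsum <- wsum + wgt
    }
    if (wsum > 0) acc / wsum else c(0, 0, 0)
  }
  inside <- function(pos) {
    ii <- floor((pos - domain$origin) / domain$h)
    if (any(ii < 0) || any(ii >= domain$dims)) return(FALSE)
    domain$mask[ii[1] + 1, ii[2] + 1, ii[3] + 1] == 1L
  }
  lines <- list()
  for (s in seq_len(nrow(seeds))) {
    pos <- as.numeric(seeds[s, ])
    if (!inside(pos)) {
      warning(sprintf("seed %d lies outside the fluid; skipped", s))
      next
    }
    pts <- matrix(NA_real_, max_steps + 1, 3)
    pts[1, ] <- pos
    n <- 1L
    for (it in seq_len(max_steps)) {
      dir1 <- interp(pos)
      n1 <- sqrt(sum(dir1^2)); if (n1 < eps) break
      k1 <- dir1 / n1
      d2 <- interp(pos + 0.5 * step * k1); n2 <- sqrt(sum(d2^2)); if (n2 < eps) break
      k2 <- d2 / n2
      d3 <- interp(pos + 0.5 * step * k2); n3 <- sqrt(sum(d3^2)); if (n3 < eps) break
      k3 <- d3 / n3
      d4 <- interp(pos + step * k3); n4 <- sqrt(sum(d4^2)); if (n4 < eps) break
      k4 <- d4 / n4
      pos_new <- pos + step * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      if (!inside(pos_new)) break
      pos <- pos_new
      n <- n + 1L
      pts[n, ] <- pos
    }
    lines[[length(lines) + 1L]] <- pts[seq_len(n), , drop = FALSE]
  }
  structure(list(lnh = lnh, streamlines = lines, domain_dims = domain$dims),
            class = "helicity_map")
}

#' @export
print.helicity_map <- function(x, ...) {
  v <- x$lnh[!is.na(x$lnh)]
  cat(sprintf("helicity_map: mean |LNH| %.3f over %d fluid cells; %d streamlines\n",
              mean(abs(v)), length(v), length(x$streamlines)))
  invisible(x)
}

#' Write probe results as CSV
#'
#' @param probes a `probe_result` (or data frame of them with a case column).
#' @param path output path.
#' @export
write_probes <- function(probes, path) {
  write.csv(as.data.frame(probes), path, row.names = FALSE)
  invisible(path)
}
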