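# Structured cell-centered finite-volume discretization.
#
# All model representations are extruded along z (boundaries depend on the
# transverse coordinates only), so the cross-section is classified once and
# replicated over the z slices.  Conductivities are anti-aliased by
# sub-cell sampling, which restores smooth convergence of thresholds under
# refinement despite the staircase representation of curved boundaries.

# cell codes: 0 = air (exterior), then 1-based positions in this vector
tissue_code_levels <- c("bone_marrow", "cortical_bone", "muscle",
                        "fat", "skin", "blood", "nerve")

# classify transverse points; returns integer codes into tissue_code_levels
classify_xsection <- function(model, x, y) {
  code <- integer(length(x))
  if (model$representation == "PM") {
    bounds <- c(0, unname(model$radii))  # marrow at the bottom, skin on top
    lay <- findInterval(y, bounds, rightmost.closed = TRUE)
    inside <- abs(x) <= model$pm_width_cm / 2 & lay >= 1L & lay <= 5L
    code[inside] <- lay[inside]          # layer 1 (marrow) ... 5 (skin)
    return(code)
  }
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  rs <- boundary_radius(model, "skin", th)
  rf <- boundary_radius(model, "fat", th)
  rm_ <- boundary_radius(model, "muscle", th)
  code[r <= rs] <- 5L            # skin
  code[r <= rf] <- 4L            # fat
  code[r <= rm_] <- 3L           # muscle
  cb <- model$bone_offset_mm / 10
  db <- sqrt((x - cb[1])^2 + (y - cb[2])^2)
  code[db <= model$radii[["cortical_bone"]]] <- 2L
  code[db <= model$radii[["bone_marrow"]]] <- 1L
  for (inc in model$inclusions) {
    ic <- inc$axis_offset_mm / 10
    di <- sqrt((x - ic[1])^2 + (y - ic[2])^2)
    code[di <= inc$radius_mm / 10] <- if (inc$kind == "blood_vessel") 6L else 7L
  }
  code
}

# conductivity lookup per tissue code (mS/m), including inclusion overrides
sigma_tables <- function(model) {
  # st/sl are indexed by (cell code + 1): entry 1 is air (zero)
  lut <- match(c("bone_marrow", "cortical_bone", "muscle", "fat", "skin",
                 "blood", "nerve"), tissue_conductivities$tissue)
  st <- c(0, tissue_conductivities$sigma_transverse_mSm[lut])
  sl <- c(0, tissue_conductivities$sigma_longitudinal_mSm[lut])
  # layer conductivity overrides from the spec
  for (l in model$layers) {
    idx <- match(l$name, tissue_code_levels) + 1L
    st[idx] <- l$conductivity$sigma_transverse
    sl[idx] <- l$conductivity$sigma_longitudinal
  }
  for (inc in model$inclusions) {
    idx <- (if (inc$kind == "blood_vessel") 6L else 7L) + 1L
    st[idx] <- inc$conductivity$sigma_transverse
    sl[idx] <- inc$conductivity$sigma_longitudinal
  }
  list(st = st, sl = sl)
}

#' Discretize a volume model for the field solve
#'
#' Builds a cell-centered finite-volume grid at a resolution level.  The
#' degree-of-freedom count grows by at least 2x per level.  Conductivities
#' are averaged over a sub-cell sampling stencil; face conductances use the
#' harmonic mean of the adjacent cells.
#'
#' @param model a `volume_model`.
#' @param electrodes an [place_electrodes()] pair.
#' @param resolution_level integer >= 0 refinement index.
#' @param base_dof approximate degree-of-freedom count at level 0.
#' @param subsample sub-cell sampling points per transverse axis.
#' @param grid `"auto"` chooses the boundary-conforming polar grid for the
#'   radial representations (every layer interface lies exactly on cell
#'   faces) and the Cartesian grid for PM; the Cartesian path can be
#'   forced for comparison.
#' @return A `discrete_domain` object.
#' @export
discretize <- function(model, electrodes, resolution_level = 0,
                       base_dof = 2e5, subsample = 6,
                       grid = c("auto", "polar", "cartesian")) {
  stopifnot(inherits(model, "volume_model"),
            inherits(electrodes, "electrode_pair"),
            resolution_level >= 0)
  grid <- match.arg(grid)
  if (grid == "auto")
    grid <- if (model$representation == "PM") "cartesian" else "polar"
  if (grid == "polar") {
    if (model$representation == "PM")
      stop("the polar grid applies to the radial representations",
           call. = FALSE)
    return(discretize_polar(model, electrodes, resolution_level,
                            base_dof, subsample))
  }
  # 2.08x growth per level guarantees the >=2x DOF contract under grid
  # rounding; the 3% inflation covers boundary cells dropped by the
  # majority rule so the realized count does not fall below base_dof
  target <- 1.03 * base_dof * 2.08^resolution_level
  lz <- model$axial_length_cm
  if (model$representation == "PM") {
    vol <- model$pm_width_cm * model$radii[["skin"]] * lz
  } else {
    th <- seq(0, 2 * pi, length.out = 361)
    vol <- mean(boundary_radius(model, "skin", th)^2) * pi * lz
  }
  h <- (vol / target)^(1 / 3)

  for (inc in model$inclusions) {
    if (h > inc$radius_mm / 10) {
      need <- ceiling(3 * log2(h / (inc$radius_mm / 10)) / log2(2.08)) +
        resolution_level
      stop(sprintf(
        "%s inclusion thinner than 2 cells at level %d; need level >= %d",
        inc$kind, resolution_level, need), call. = FALSE)
    }
  }

  if (model$representation == "PM") {
    nx <- ceiling(model$pm_width_cm / h) + 2L
    ny <- ceiling(model$radii[["skin"]] / h) + 2L
    x0 <- -nx * h / 2
    y0 <- -h  # one guard cell below the slab bottom
  } else {
    rmax <- max(boundary_radius(model, "skin",
                                seq(0, 2 * pi, length.out = 721)))
    nx <- ny <- 2L * ceiling(rmax / h + 1L)
    x0 <- -nx * h / 2
    y0 <- -ny * h / 2
  }
  nz <- 2L * ceiling(lz / (2 * h))  # even cell count, symmetric about z=0
  z0 <- -nz * h / 2

  xc <- x0 + (seq_len(nx) - 0.5) * h
  yc <- y0 + (seq_len(ny) - 0.5) * h
  zc <- z0 + (seq_len(nz) - 0.5) * h

  # Sub-cell conductivity homogenization over the cross-section.  Cells
  # straddling a tissue boundary get two effective transverse values: the
  # arithmetic mean (correct for flow tangential to the layering) and the
  # porosity-weighted harmonic mean (correct for flow normal to it); the
  # face assembly blends them by the face-normal / layer-normal angle.
  # Without the harmonic component, the series resistance of the thin
  # resistive skin would depend on how cell boundaries straddle it.
  off <- (seq_len(subsample) - 0.5) / subsample - 0.5
  sig <- sigma_tables(model)
  st_acc <- matrix(0, nx, ny)
  st_inv_acc <- matrix(0, nx, ny)
  sl_acc <- matrix(0, nx, ny)
  in_acc <- matrix(0L, nx, ny)
  gx <- rep(xc, times = ny)
  gy <- rep(yc, each = nx)
  for (ox in off) for (oy in off) {
    code <- classify_xsection(model, gx + ox * h, gy + oy * h)
    st_s <- sig$st[code + 1L]
    st_acc <- st_acc + matrix(st_s, nx, ny)
    st_inv_acc <- st_inv_acc + matrix(ifelse(st_s > 0, 1 / st_s, 0),
                                      nx, ny)
    sl_acc <- sl_acc + matrix(sig$sl[code + 1L], nx, ny)
    in_acc <- in_acc + matrix((code > 0L) + 0L, nx, ny)
  }
  nsub <- subsample^2
  st2 <- st_acc / nsub
  # harmonic mean over the interior subsamples for layer-normal flow; a
  # void (air) fraction shortens the series path rather than blocking it,
  # so the effective normal conductivity is harm_inside / fill
  st2_harm <- matrix(0, nx, ny)
  nz_in <- in_acc > 0L
  fill <- in_acc[nz_in] / nsub
  st2_harm[nz_in] <- (in_acc[nz_in] / st_inv_acc[nz_in]) / fill
  sl2 <- sl_acc / nsub
  # any cell with a substantial tissue fraction joins the network; its
  # conductances already carry the fill fraction, so the conducting
  # cross-section is represented by weights rather than by cell counts
  active <- in_acc * 4L >= nsub
  tissue_code <- matrix(classify_xsection(model, gx, gy), nx, ny)
  # an active cell whose centre fell outside still needs a tissue label
  tissue_code[active & tissue_code == 0L] <- 5L  # skin (outer boundary)

  map2d <- matrix(0L, nx, ny)
  n2 <- sum(active)
  if (n2 == 0L) stop("empty discretization", call. = FALSE)
  map2d[active] <- seq_len(n2)
  ij <- which(active, arr.ind = TRUE)
  ix2 <- ij[, 1]; iy2 <- ij[, 2]

  # directional blend weights: fraction of each face normal along the
  # local layer normal (radial for the cylindrical stacks, y for PM)
  if (model$representation == "PM") {
    wx2 <- matrix(0, nx, ny)
    wy2 <- matrix(1, nx, ny)
  } else {
    r2 <- outer(xc^2, yc^2, `+`)
    r2[r2 == 0] <- Inf
    wx2 <- outer(xc^2, rep(1, ny)) / r2
    wy2 <- outer(rep(1, nx), yc^2) / r2
  }
  sigx <- (wx2 * st2_harm + (1 - wx2) * st2) / 1000  # S/m
  sigy <- (wy2 * st2_harm + (1 - wy2) * st2) / 1000
  sl2a <- sl2 / 1000

  # in-plane face conductances (S), harmonic mean, h in cm -> SI factor 1e-2
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  e2i <- integer(0); e2j <- integer(0); e2g <- numeric(0)
  right <- active[-nx, ] & active[-1, ]
  if (any(right)) {
    ids <- which(right, arr.ind = TRUE)
    a <- map2d[cbind(ids[, 1], ids[, 2])]
    b <- map2d[cbind(ids[, 1] + 1L, ids[, 2])]
    g <- hm(sigx[cbind(ids[, 1], ids[, 2])],
            sigx[cbind(ids[, 1] + 1L, ids[, 2])]) * h / 100
    e2i <- c(e2i, a); e2j <- c(e2j, b); e2g <- c(e2g, g)
  }
  up <- active[, -ny] & active[, -1]
  if (any(up)) {
    ids <- which(up, arr.ind = TRUE)
    a <- map2d[cbind(ids[, 1], ids[, 2])]
    b <- map2d[cbind(ids[, 1], ids[, 2] + 1L)]
    g <- hm(sigy[cbind(ids[, 1], ids[, 2])],
            sigy[cbind(ids[, 1], ids[, 2] + 1L)]) * h / 100
    e2i <- c(e2i, a); e2j <- c(e2j, b); e2g <- c(e2g, g)
  }
  keep <- e2g > 0
  e2i <- e2i[keep]; e2j <- e2j[keep]; e2g <- e2g[keep]
  gz2 <- sl2a[cbind(ix2, iy2)] * h / 100

  # electrode couplings through the skin boundary faces
  couplings <- electrode_couplings(model, electrodes, map2d, active,
                                   tissue_code, xc, yc, zc, h, n2)

  structure(
    list(model = model, electrodes = electrodes, grid = "cartesian",
         resolution_level = resolution_level,
         h_cm = h, hz_cm = h, nx = nx, ny = ny, nz = nz,
         x0 = x0, y0 = y0, z0 = z0,
         map2d = map2d, n2 = n2, ix2 = ix2, iy2 = iy2,
         n_dof = n2 * nz,
         tissue_code = tissue_code,
         sigma_t_mSm = st2, sigma_l_mSm = sl2,
         edges2d = list(i = e2i, j = e2j, g = e2g),
         gz2 = gz2,
         electrode_cells = couplings$cells,
         patch_area_cm2 = couplings$areas),
    class = "discrete_domain")
}

# Boundary faces of the active cross-section carrying the electrode
# contact.  Each face's geodesic footprint (arc length x axial extent) is
# clipped against the patch rectangle, so the discretized patch area equals
# the nominal area up to float rounding.
electrode_couplings <- function(model, electrodes, map2d, active,
                                tissue_code, xc, yc, zc, h, n2) {
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  sigma_skin <- conductivity_of("skin")$sigma_transverse / 1000 # S/m
  side <- electrodes$side_cm

  faces <- list()  # each: cell2d index, s interval (geodesic, cm)
  if (model$representation == "PM") {
    # outward +y faces on the top (skin) surface
    for (iy in seq_len(ny)) {
      above_inactive <- if (iy == ny) rep(TRUE, nx) else !active[, iy + 1L]
      sel <- which(active[, iy] & above_inactive)
      for (ix in sel)
        faces[[length(faces) + 1L]] <-
          list(cell = map2d[ix, iy], s = c(xc[ix] - h / 2, xc[ix] + h / 2))
    }
  } else {
    r_site <- boundary_radius(model, "skin", electrodes$theta_center)
    ths <- electrodes$theta_center
    wrap <- function(a) atan2(sin(a), cos(a))
    add_face <- function(ix, iy, p1, p2) {
      d1 <- wrap(atan2(p1[2], p1[1]) - ths)
      d2 <- wrap(atan2(p2[2], p2[1]) - ths)
      if (abs(d1 - d2) > pi) return()  # face on the far side of the wrap
      faces[[length(faces) + 1L]] <<-
        list(cell = map2d[ix, iy], s = sort(c(d1, d2)) * r_site)
    }
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      if (!active[ix, iy]) next
      x1 <- xc[ix] - h / 2; x2 <- xc[ix] + h / 2
      y1 <- yc[iy] - h / 2; y2 <- yc[iy] + h / 2
      if (ix == nx || !active[ix + 1L, iy])
        add_face(ix, iy, c(x2, y1), c(x2, y2))
      if (ix == 1L || !active[ix - 1L, iy])
        add_face(ix, iy, c(x1, y1), c(x1, y2))
      if (iy == ny || !active[ix, iy + 1L])
        add_face(ix, iy, c(x1, y2), c(x2, y2))
      if (iy == 1L || !active[ix, iy - 1L])
        add_face(ix, iy, c(x1, y1), c(x2, y1))
    }
  }

  # Injection sites for the prescribed-current formulation.  The skin
  # blocks lateral spread, so each face's current physically crosses the
  # skin-fat interface directly beneath its footprint; depositing it
  # bilinearly at the exact (smooth) interface position removes the
  # grid-phase sensitivity of surface-cell injection (whether the top
  # cell homogenizes skin alone or skin plus fat decides how much the
  # load can shunt laterally, which otherwise jitters with the mesh).
  inj_cells <- function(theta_c) {
    if (model$representation == "PM") {
      p <- c(theta_c, model$radii[["fat"]])
    } else {
      r_inj <- boundary_radius(model, "fat", theta_c)
      p <- c(r_inj * cos(theta_c), r_inj * sin(theta_c))
    }
    fx <- (p[1] - xc[1]) / h; fy <- (p[2] - yc[1]) / h
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    cells <- integer(0); w <- numeric(0)
    for (dx in 0:1) for (dy in 0:1) {
      k2 <- map2d[i0 + dx + 1L, j0 + dy + 1L]
      if (k2 == 0L) next
      cells <- c(cells, k2)
      w <- c(w, (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy))
    }
    if (!length(cells)) return(NULL)
    list(cells = cells, w = w / sum(w))
  }

  out <- list(); areas <- c()
  for (patch in c("proximal", "distal")) {
    zr <- electrodes$z_ranges[[patch]]
    dofs <- integer(0); gs <- numeric(0); a_tot <- 0
    inj_dofs <- integer(0); inj_w <- numeric(0)
    z_lo <- pmax(zc - h / 2, zr[1]); z_hi <- pmin(zc + h / 2, zr[2])
    wz <- pmax(z_hi - z_lo, 0)
    iz_sel <- which(wz > 0)
    r_site <- if (model$representation == "PM") NA_real_ else
      boundary_radius(model, "skin", electrodes$theta_center)
    for (f in faces) {
      ws <- max(0, min(f$s[2], side / 2) - max(f$s[1], -side / 2))
      if (ws <= 0) next
      s_mid <- (max(f$s[1], -side / 2) + min(f$s[2], side / 2)) / 2
      theta_c <- if (model$representation == "PM") s_mid else
        electrodes$theta_center + s_mid / r_site
      ic <- inj_cells(theta_c)
      for (iz in iz_sel) {
        a_cm2 <- ws * wz[iz]
        a_tot <- a_tot + a_cm2
        g <- sigma_skin * (a_cm2 * 1e-4) / (h / 2 * 1e-2)
        dofs <- c(dofs, (iz - 1L) * n2 + f$cell)
        gs <- c(gs, g)
        if (!is.null(ic)) {
          inj_dofs <- c(inj_dofs, (iz - 1L) * n2 + ic$cells)
          inj_w <- c(inj_w, a_cm2 * ic$w)
        }
      }
    }
    if (!length(dofs))
      stop(sprintf("electrode patch '%s' found no surface faces", patch),
           call. = FALSE)
    out[[patch]] <- list(dof = dofs, g = gs,
                         inj_dof = inj_dofs, inj_w = inj_w)
    areas[patch] <- a_tot
  }
  for (patch in names(areas))
    if (abs(areas[patch] - electrodes$area_cm2) / electrodes$area_cm2 > 0.02)
      stop(sprintf(
        "discretized %s patch area %.3f cm^2 deviates >2%% from %.3f cm^2",
        patch, areas[patch], electrodes$area_cm2), call. = FALSE)
  list(cells = out, areas = areas)
}

#' @export
print.discrete_domain <- function(x, ...) {
  if (identical(x$grid, "polar"))
    cat(sprintf(
      "<discrete_domain> polar, level %d, h = %.2f mm, %d(r) x %d(theta) x %d(z), %d DOF\n",
      x$resolution_level, x$h_cm * 10, x$nr, x$ntheta, x$nz, x$n_dof))
  else
    cat(sprintf(
      "<discrete_domain> level %d, h = %.2f mm, %d x %d x %d grid, %d DOF\n",
      x$resolution_level, x$h_cm * 10, x$nx, x$ny, x$nz, x$n_dof))
  invisible(x)
}

#' Homogeneous box domain for solver verification
#'
#' A rectangular block of a single (possibly anisotropic) medium with
#' insulated boundaries and no electrodes; used with
#' [solve_point_sources()] to check the solver against the closed-form
#' potential of a point current source in an unbounded medium.
#'
#' @param lx_cm,ly_cm,lz_cm box edge lengths, cm.
#' @param h_cm transverse (x, y) cell size, cm.
#' @param sigma_t_mSm,sigma_l_mSm transverse (x, y) and longitudinal (z)
#'   conductivities, mS/m.
#' @param hz_cm axial cell size; the default `h_cm * sqrt(sl/st)` makes the
#'   lattice cubic in the conductivity-scaled coordinates, which keeps the
#'   discrete Green function as accurate as in the isotropic case.
#' @export
discretize_box <- function(lx_cm, ly_cm, lz_cm, h_cm,
                           sigma_t_mSm, sigma_l_mSm = sigma_t_mSm,
                           hz_cm = h_cm * sqrt(sigma_l_mSm / sigma_t_mSm)) {
  nx <- max(2L, round(lx_cm / h_cm))
  ny <- max(2L, round(ly_cm / h_cm))
  nz <- max(2L, round(lz_cm / hz_cm))
  h <- h_cm; hz <- hz_cm
  x0 <- -nx * h / 2; y0 <- -ny * h / 2; z0 <- -nz * hz / 2
  n2 <- nx * ny
  map2d <- matrix(seq_len(n2), nx, ny)
  ij <- which(map2d > 0, arr.ind = TRUE)
  st <- sigma_t_mSm / 1000; sl <- sigma_l_mSm / 1000
  gx <- st * hz / 100  # face (h x hz), distance h

  idx <- matrix(seq_len(n2), nx, ny)
  a_r <- as.vector(idx[-nx, ]); b_r <- as.vector(idx[-1, ])
  a_u <- as.vector(idx[, -ny]); b_u <- as.vector(idx[, -1])
  e2i <- c(a_r, a_u); e2j <- c(b_r, b_u)
  e2g <- rep(gx, length(e2i))

  structure(
    list(model = NULL, electrodes = NULL, grid = "cartesian",
         resolution_level = 0L,
         h_cm = h, hz_cm = hz, nx = nx, ny = ny, nz = nz,
         x0 = x0, y0 = y0, z0 = z0,
         map2d = map2d, n2 = n2, ix2 = ij[, 1], iy2 = ij[, 2],
         n_dof = n2 * nz,
         tissue_code = matrix(3L, nx, ny),  # homogeneous muscle-like block
         sigma_t_mSm = matrix(sigma_t_mSm, nx, ny),
         sigma_l_mSm = matrix(sigma_l_mSm, nx, ny),
         edges2d = list(i = e2i, j = e2j, g = e2g),
         gz2 = rep(sl * (h * h / hz) / 100, n2),
         electrode_cells = NULL, patch_area_cm2 = NULL),
    class = "discrete_domain")
}
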