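# Boundary-conforming polar discretization for the radial models.
#
# CM and PSEUDO_AM boundaries are single-valued radial functions r(theta)
# (including the offset bone circles), so a mapped polar grid places every
# layer interface exactly on cell faces: cells are pure tissue except
# where an embedded inclusion crosses them, and refinement changes cell
# sizes smoothly instead of re-rastering a staircase.  This removes the
# grid-phase threshold jitter that a Cartesian voxelization of the curved
# stacks cannot get below a few tenths of a percent.  The grid remains an
# extrusion along z, so the same CG / separable solvers apply unchanged.

# radius of the offset bone circle along the ray at angle theta
offset_circle_radius <- function(center_cm, radius_cm, theta) {
  along <- center_cm[1] * cos(theta) + center_cm[2] * sin(theta)
  perp2 <- sum(center_cm^2) - along^2
  along + sqrt(pmax(radius_cm^2 - perp2, 0))
}

# The marrow interface is star-shaped about the axis only while the bone
# offset stays well inside the marrow radius; otherwise the whole core
# (marrow + cortical bone) is meshed as one conforming band against the
# cortical outer boundary (itself always star-shaped for valid models)
# and marrow is assigned within it by sub-sampling.
polar_bands <- function(model) {
  cb <- model$bone_offset_mm / 10
  marrow_conforming <- sqrt(sum(cb^2)) < 0.5 * model$radii[["bone_marrow"]]
  th <- vapply(model$layers, `[[`, 0, "thickness_cm")
  if (marrow_conforming)
    list(marrow_conforming = TRUE,
         codes = 1:5,
         thickness = unname(th))
  else
    list(marrow_conforming = FALSE,
         codes = c(2L, 3L, 4L, 5L),  # core labelled cortical_bone
         thickness = c(th[1] + th[2], unname(th[3:5])))
}

# interface radii (one row per band, ntheta columns)
polar_interfaces <- function(model, theta, bands) {
  cb <- model$bone_offset_mm / 10
  outer_rows <- rbind(
    boundary_radius(model, "muscle", theta),
    boundary_radius(model, "fat", theta),
    boundary_radius(model, "skin", theta))
  if (bands$marrow_conforming)
    rbind(offset_circle_radius(cb, model$radii[["bone_marrow"]], theta),
          offset_circle_radius(cb, model$radii[["cortical_bone"]], theta),
          outer_rows)
  else
    rbind(offset_circle_radius(cb, model$radii[["cortical_bone"]], theta),
          outer_rows)
}

# grid dimensions for a DOF target; pure arithmetic, used both to build
# the grid and to enforce the at-least-doubling contract across levels
polar_dims_for_target <- function(model, target) {
  lz <- model$axial_length_cm
  th_probe <- seq(0, 2 * pi, length.out = 361)
  r_skin_mean <- mean(boundary_radius(model, "skin", th_probe))
  h <- (2 * pi * r_skin_mean^2 * lz / target)^(1 / 3)
  bands <- polar_bands(model)
  n_k <- pmax(2L, as.integer(round(bands$thickness / h)))
  ntheta <- max(32L, 2L * ceiling(pi * r_skin_mean / h))
  nz <- 2L * ceiling(lz / (2 * h))
  list(h = h, bands = bands, n_k = n_k, nr = sum(n_k), ntheta = ntheta,
       nz = nz, n_dof = sum(n_k) * ntheta * nz)
}

# the layer-count rounding can leave a level just under twice its
# predecessor; bump the target until the realized count doubles
polar_dims_for_level <- function(model, base_dof, level) {
  target <- 1.03 * base_dof * 2.08^level
  dims <- polar_dims_for_target(model, target)
  if (level > 0) {
    prev <- polar_dims_for_level(model, base_dof, level - 1)
    while (dims$n_dof < 2 * prev$n_dof) {
      target <- target * 1.06
      dims <- polar_dims_for_target(model, target)
    }
  }
  dims
}

discretize_polar <- function(model, electrodes, resolution_level = 0,
                             base_dof = 2e5, subsample = 6) {
  lz <- model$axial_length_cm
  dims <- polar_dims_for_level(model, base_dof, resolution_level)
  h <- dims$h

  for (inc in model$inclusions) {
    if (h > inc$radius_mm / 10) {
      need <- ceiling(3 * log2(h / (inc$radius_mm / 10)) / log2(2.08)) +
        resolution_level
      stop(sprintf(
        "%s inclusion thinner than 2 cells at level %d; need level >= %d",
        inc$kind, resolution_level, need), call. = FALSE)
    }
  }

  ntheta <- dims$ntheta
  dtheta <- 2 * pi / ntheta
  theta <- -pi + (seq_len(ntheta) - 0.5) * dtheta
  nz <- dims$nz
  hz <- h
  z0 <- -nz * hz / 2
  zc <- z0 + (seq_len(nz) - 0.5) * hz

  n_k <- dims$n_k
  nr <- dims$nr
  bands <- dims$bands
  nbands <- length(bands$codes)
  layer_of_ring <- rep(bands$codes, times = n_k)
  band_of_ring <- rep(seq_len(nbands), times = n_k)

  # radial faces per theta column: band interfaces exactly on faces
  bounds <- polar_interfaces(model, theta, bands)   # nbands x ntheta
  rf <- matrix(0, nr + 1L, ntheta)
  row <- 1L
  for (k in seq_len(nbands)) {
    lo <- if (k == 1L) rep(0, ntheta) else bounds[k - 1L, ]
    hi <- bounds[k, ]
    for (s in seq_len(n_k[k])) {
      rf[row + s, ] <- lo + (hi - lo) * s / n_k[k]
    }
    row <- row + n_k[k]
  }
  r_c <- (rf[-1L, , drop = FALSE] + rf[-(nr + 1L), , drop = FALSE]) / 2
  dr <- rf[-1L, , drop = FALSE] - rf[-(nr + 1L), , drop = FALSE]

  sig <- sigma_tables(model)
  st2 <- matrix(sig$st[layer_of_ring + 1L], nr, ntheta)
  sl2 <- matrix(sig$sl[layer_of_ring + 1L], nr, ntheta)
  tissue_code <- matrix(layer_of_ring, nr, ntheta)

  if (!bands$marrow_conforming) {
    # assign marrow within the merged core band by sub-sampling
    off <- (seq_len(subsample) - 0.5) / subsample - 0.5
    cb <- model$bone_offset_mm / 10
    rm_cm <- model$radii[["bone_marrow"]]
    core_rows <- which(band_of_ring == 1L)
    for (i in core_rows) for (j in seq_len(ntheta)) {
      rr <- r_c[i, j] + off * dr[i, j]
      tt <- theta[j] + off * dtheta
      px <- outer(rr, cos(tt)); py <- outer(rr, sin(tt))
      frac <- mean((px - cb[1])^2 + (py - cb[2])^2 <= rm_cm^2)
      if (frac == 0) next
      st2[i, j] <- (1 - frac) * st2[i, j] + frac * sig$st[2L]
      sl2[i, j] <- (1 - frac) * sl2[i, j] + frac * sig$sl[2L]
      if (frac > 0.5) tissue_code[i, j] <- 1L
    }
  }

  # inclusions: sub-sample the muscle cells they cross
  if (length(model$inclusions)) {
    off <- (seq_len(subsample) - 0.5) / subsample - 0.5
    for (inc in model$inclusions) {
      ic <- inc$axis_offset_mm / 10
      ri <- inc$radius_mm / 10
      # candidate cells: centre within inclusion radius + cell diagonal
      cx <- r_c * matrix(cos(theta), nr, ntheta, byrow = TRUE)
      cy <- r_c * matrix(sin(theta), nr, ntheta, byrow = TRUE)
      d2 <- (cx - ic[1])^2 + (cy - ic[2])^2
      reach <- (ri + dr / 2 + r_c * dtheta / 2)^2
      cand <- which(d2 <= reach, arr.ind = TRUE)
      for (q in seq_len(nrow(cand))) {
        i <- cand[q, 1]; j <- cand[q, 2]
        rr <- r_c[i, j] + off * dr[i, j]
        tt <- theta[j] + off * dtheta
        px <- outer(rr, cos(tt)); py <- outer(rr, sin(tt))
        frac <- mean((px - ic[1])^2 + (py - ic[2])^2 <= ri^2)
        if (frac == 0) next
        code <- if (inc$kind == "blood_vessel") 6L else 7L
        st2[i, j] <- (1 - frac) * st2[i, j] + frac * sig$st[code + 1L]
        sl2[i, j] <- (1 - frac) * sl2[i, j] + frac * sig$sl[code + 1L]
        if (frac > 0.5) tissue_code[i, j] <- code
      }
    }
  }

  n2 <- nr * ntheta
  map2d <- matrix(seq_len(n2), nr, ntheta)
  st_Sm <- st2 / 1000
  sl_Sm <- sl2 / 1000

  # radial faces (series conductance through the two half-cells), cm/SI
  i_in <- rep(seq_len(nr - 1L), ntheta)
  j_in <- rep(seq_len(ntheta), each = nr - 1L)
  a2i <- map2d[cbind(i_in, j_in)]
  a2j <- map2d[cbind(i_in + 1L, j_in)]
  r_face <- rf[cbind(i_in + 1L, j_in)]
  area_r <- r_face * dtheta * hz                    # cm^2
  res_r <- dr[cbind(i_in, j_in)] / (2 * st_Sm[cbind(i_in, j_in)]) +
    dr[cbind(i_in + 1L, j_in)] / (2 * st_Sm[cbind(i_in + 1L, j_in)])
  g_r <- 1e-2 * area_r / res_r
  # tangential faces (wrap in theta), arc-length distance at the centre
  jp <- c(seq_len(ntheta)[-1L], 1L)
  i_t <- rep(seq_len(nr), ntheta)
  j_t <- rep(seq_len(ntheta), each = nr)
  b2i <- map2d[cbind(i_t, j_t)]
  b2j <- map2d[cbind(i_t, jp[j_t])]
  dr_bar <- (dr[cbind(i_t, j_t)] + dr[cbind(i_t, jp[j_t])]) / 2
  r_bar <- (r_c[cbind(i_t, j_t)] + r_c[cbind(i_t, jp[j_t])]) / 2
  s_a <- st_Sm[cbind(i_t, j_t)]; s_b <- st_Sm[cbind(i_t, jp[j_t])]
  g_t <- 1e-2 * (dr_bar * hz) / (r_bar * dtheta) *
    ifelse(s_a + s_b > 0, 2 * s_a * s_b / (s_a + s_b), 0)
  e2i <- c(a2i, b2i); e2j <- c(a2j, b2j); e2g <- c(g_r, g_t)
  keep <- e2g > 0
  gz2 <- 1e-2 * sl_Sm * (r_c * dtheta * dr) / hz    # nr x ntheta

  # electrode couplings: outer skin faces, geodesic clipping in s and z
  sigma_skin <- conductivity_of("skin")$sigma_transverse / 1000
  r_site <- boundary_radius(model, "skin", electrodes$theta_center)
  side <- electrodes$side_cm
  if (side / r_site > pi / 2 * 1.0001)
    stop("electrode arc exceeds one quadrant", call. = FALSE)
  wrapd <- function(a) atan2(sin(a), cos(a))
  d_th <- wrapd(theta - electrodes$theta_center)
  s_lo <- r_site * (d_th - dtheta / 2)
  s_hi <- r_site * (d_th + dtheta / 2)
  out <- list(); areas <- c()
  for (patch in c("proximal", "distal")) {
    zr <- electrodes$z_ranges[[patch]]
    z_lo <- pmax(zc - hz / 2, zr[1]); z_hi <- pmin(zc + hz / 2, zr[2])
    wz <- pmax(z_hi - z_lo, 0)
    iz_sel <- which(wz > 0)
    dofs <- integer(0); gs <- numeric(0); was <- numeric(0); a_tot <- 0
    for (j in seq_len(ntheta)) {
      ws <- max(0, min(s_hi[j], side / 2) - max(s_lo[j], -side / 2))
      if (ws <= 0) next
      cell <- map2d[nr, j]
      for (iz in iz_sel) {
        a_cm2 <- ws * wz[iz]
        a_tot <- a_tot + a_cm2
        dofs <- c(dofs, (iz - 1L) * n2 + cell)
        gs <- c(gs, sigma_skin * (a_cm2 * 1e-4) / (dr[nr, j] / 2 * 1e-2))
        was <- c(was, a_cm2)
      }
    }
    if (!length(dofs))
      stop(sprintf("electrode patch '%s' found no surface faces", patch),
           call. = FALSE)
    # the conforming outer cells are pure skin, so surface-cell injection
    # is clean for the prescribed-current formulation as well
    out[[patch]] <- list(dof = dofs, g = gs, inj_dof = dofs, inj_w = was)
    areas[patch] <- a_tot
  }
  for (patch in names(areas))
    if (abs(areas[patch] - electrodes$area_cm2) / electrodes$area_cm2 >
          0.02)
      stop(sprintf(
        "discretized %s patch area %.3f cm^2 deviates >2%% from %.3f cm^2",
        patch, areas[patch], electrodes$area_cm2), call. = FALSE)

  structure(
    list(model = model, electrodes = electrodes, grid = "polar",
         resolution_level = resolution_level,
         h_cm = h, hz_cm = hz, nr = nr, ntheta = ntheta, nz = nz,
         dtheta = dtheta, theta = theta, z0 = z0,
         rf = rf, r_c = r_c, dr = dr,
         layer_of_ring = layer_of_ring, n_k = n_k,
         map2d = map2d, n2 = n2, n_dof = n2 * nz,
         tissue_code = tissue_code,
         sigma_t_mSm = st2, sigma_l_mSm = sl2,
         edges2d = list(i = e2i[keep], j = e2j[keep], g = e2g[keep]),
         gz2 = as.numeric(gz2),
         electrode_cells = out,
         patch_area_cm2 = areas),
    class = "discrete_domain")
}

# sample the potential at points of a polar domain: cubic spline over the
# radial centres of the enclosing layer (the field is smooth within a
# layer but kinks at interfaces), Catmull-Rom over four theta columns,
# cubic spline along z
sample_polar <- function(solution, points_cm) {
  d <- solution$domain
  points_cm <- rbind(points_cm)
  zc <- d$z0 + (seq_len(d$nz) - 0.5) * d$hz_cm
  iz_all <- (seq_len(d$nz) - 1L) * d$n2
  cr <- function(u) c(-0.5 * u^3 + u^2 - 0.5 * u,
                      1.5 * u^3 - 2.5 * u^2 + 1,
                      -1.5 * u^3 + 2 * u^2 + 0.5 * u,
                      0.5 * u^3 - 0.5 * u^2)
  out <- numeric(nrow(points_cm))
  cache_key <- NULL
  zfun <- NULL
  for (p in seq_len(nrow(points_cm))) {
    x <- points_cm[p, 1]; y <- points_cm[p, 2]; z <- points_cm[p, 3]
    if (z < d$z0 || z > -d$z0)
      stop(sprintf("point %d lies outside the domain", p), call. = FALSE)
    r <- sqrt(x^2 + y^2); th <- atan2(y, x)
    key <- c(r, th)
    if (is.null(cache_key) || !identical(key, cache_key)) {
      ft <- (th - d$theta[1]) / d$dtheta      # fractional column index
      j0 <- floor(ft)
      u <- ft - j0
      cols <- ((j0 - 1L + 0:3) %% d$ntheta) + 1L
      wth <- cr(u)
      colv <- matrix(0, d$nz, 4)
      for (cc in 1:4) {
        j <- cols[cc]
        if (r > d$rf[d$nr + 1L, j] + 1e-9)
          stop(sprintf("point %d lies outside the domain", p),
               call. = FALSE)
        lay <- findInterval(r, d$rf[, j], rightmost.closed = TRUE)
        lay <- min(max(lay, 1L), d$nr)
        layer <- d$layer_of_ring[lay]
        rings <- which(d$layer_of_ring == layer)
        rr <- d$r_c[rings, j]
        vv <- matrix(solution$potential_V[
          rep(iz_all, each = length(rings)) +
            rep(d$map2d[rings, j], times = d$nz)],
          length(rings), d$nz)
        if (length(rings) >= 4) {
          for (k in seq_len(d$nz))
            colv[k, cc] <- stats::spline(rr, vv[, k], xout = r,
                                         method = "fmm")$y
        } else {
          for (k in seq_len(d$nz))
            colv[k, cc] <- stats::approx(rr, vv[, k], xout = r,
                                         rule = 2)$y
        }
      }
      prof_z <- as.numeric(colv %*% wth)
      zfun <- stats::splinefun(zc, prof_z, method = "fmm")
      cache_key <- key
    }
    out[p] <- zfun(z)
  }
  out
}
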