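#' Mechanical support conditions on the outer boundary
#'
#' Per-edge supports: `"roller"` (zero normal displacement), `"fixed"` (zero
#' displacement), `"free"` (traction-free).  Defaults follow the cryovial
#' setup: rollers on the lateral walls, fixed base, free upper boundary.
#'
#' @param left,right,bottom,top one of `"roller"`, `"fixed"`, `"free"`
#' @return object of class `mech_bc`
#' @export
mech_bc <- function(left = "roller", right = "roller",
                    bottom = "fixed", top = "free") {
  ok <- c("roller", "fixed", "free")
  stopifnot(left %in% ok, right %in% ok, bottom %in% ok, top %in% ok)
  structure(list(left = left, right = right, bottom = bottom, top = top),
            class = "mech_bc")
}

# 2x2 Gauss data for a bilinear rectangle dx x dy (reference [-1,1]^2).
# Returns per-point strain-displacement matrices B (3 x 8, rows exx eyy gxy;
# dof order u1x u1y ... u4x u4y; node order (0,0),(dx,0),(dx,dy),(0,dy))
# and the common weight w|J| = dx dy / 4.
gauss_bilinear <- function(dx, dy) {
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  Bs <- vector("list", 4)
  for (g in 1:4) {
    xi <- pts[g, 1]; eta <- pts[g, 2]
    # dN/dxi, dN/deta for N1..N4
    dNdxi  <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dNdx <- dNdxi * 2 / dx
    dNdy <- dNdeta * 2 / dy
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    Bs[[g]] <- B
  }
  list(B = Bs, wJ = dx * dy / 4)
}

#' Assemble the mechanical solver context
#'
#' Plane-strain bilinear finite elements on the thermal grid (one element per
#' cell), with the support conditions eliminated from the system.  The element
#' stiffness splits exactly into bulk and shear templates,
#' \eqn{K_e = K\,A_1 + G_{\mathrm{eff}}\,A_2}, so per-step reassembly under
#' phase-dependent moduli reduces to two sparse matrix-vector products into
#' the cached factorisation pattern.
#'
#' @param grid a [build_grid()] object
#' @param materials single material or `list(solution=, skin=)` as in
#'   [thermal_system()]
#' @param bc a [mech_bc()]
#' @return object of class `mech_system`
#' @export
mech_system <- function(grid, materials, bc = mech_bc()) {
  if (inherits(materials, "phase_change_material"))
    materials <- list(solution = materials, skin = materials)
  if (all(c(bc$left, bc$right, bc$bottom, bc$top) == "free"))
    stop("all-free supports leave the equilibrium system singular")
  nx <- grid$nx; ny <- grid$ny; nel <- grid$n
  nnx <- nx + 1L; nny <- ny + 1L
  nnodes <- nnx * nny
  ndof <- 2L * nnodes

  mat_id <- ifelse(grid$skin_mask, 2L, 1L)
  ms <- materials$solution; mk <- materials$skin
  pick <- function(f) ifelse(mat_id == 1L, f(ms), f(mk))
  par <- list(
    E1 = pick(function(m) m$phase1$young_modulus),
    E2 = pick(function(m) m$phase2$young_modulus),
    nu1 = pick(function(m) m$phase1$poisson),
    nu2 = pick(function(m) m$phase2$poisson),
    al1 = pick(function(m) m$phase1$expansion),
    al2 = pick(function(m) m$phase2$expansion),
    mu1 = pick(function(m) m$phase1$maxwell_viscosity),
    mu2 = pick(function(m) m$phase2$maxwell_viscosity),
    eig = pick(function(m) (m$phase1$density / m$phase2$density)^(1 / 3) - 1))

  # connectivity: element (i,j) -> nodes ccw from lower-left
  ie <- rep(seq_len(nx), times = ny)
  je <- rep(seq_len(ny), each = nx)
  n1 <- (je - 1L) * nnx + ie
  edof <- cbind(2L * n1 - 1L, 2L * n1,
                2L * (n1 + 1L) - 1L, 2L * (n1 + 1L),
                2L * (n1 + nnx + 1L) - 1L, 2L * (n1 + nnx + 1L),
                2L * (n1 + nnx) - 1L, 2L * (n1 + nnx))

  # supports
  node_i <- rep(seq_len(nnx), times = nny)
  node_j <- rep(seq_len(nny), each = nnx)
  fix_x <- rep(FALSE, nnodes); fix_y <- rep(FALSE, nnodes)
  apply_support <- function(sel, kind, normal) {
    if (kind == "fixed") { fix_x[sel] <<- TRUE; fix_y[sel] <<- TRUE }
    else if (kind == "roller") {
      if (normal == "x") fix_x[sel] <<- TRUE else fix_y[sel] <<- TRUE
    }
  }
  apply_support(node_i == 1L, bc$left, "x")
  apply_support(node_i == nnx, bc$right, "x")
  apply_support(node_j == 1L, bc$bottom, "y")
  apply_support(node_j == nny, bc$top, "y")
  constrained <- logical(ndof)
  constrained[2L * which(fix_x) - 1L] <- TRUE
  constrained[2L * which(fix_y)] <- TRUE
  free <- which(!constrained)
  dofmap <- integer(ndof); dofmap[free] <- seq_along(free)
  nfree <- length(free)

  gb <- gauss_bilinear(grid$dx, grid$dy)
  M1 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  M2 <- matrix(c(4 / 3, -2 / 3, 0, -2 / 3, 4 / 3, 0, 0, 0, 1), 3, 3)
  A1 <- matrix(0, 8, 8); A2 <- matrix(0, 8, 8)
  for (g in 1:4) {
    B <- gb$B[[g]]
    A1 <- A1 + gb$wJ * t(B) %*% M1 %*% B
    A2 <- A2 + gb$wJ * t(B) %*% M2 %*% B
  }

  # stiffness pattern on free dofs + per-element slot maps
  li <- rep(1:8, times = 8); lj <- rep(1:8, each = 8)
  keep_lt <- li <= lj   # upper triangle of the symmetric element matrix
  li <- li[keep_lt]; lj <- lj[keep_lt]
  a1v <- A1[cbind(li, lj)]; a2v <- A2[cbind(li, lj)]
  GI <- edof[, li]; GJ <- edof[, lj]           # nel x nloc
  # orient into global upper triangle
  swap <- GI > GJ
  tmp <- GI[swap]; GI[swap] <- GJ[swap]; GJ[swap] <- tmp
  EL <- row(GI)
  okf <- !constrained[GI] & !constrained[GJ]
  gi <- dofmap[GI[okf]]; gj <- dofmap[GJ[okf]]
  el <- EL[okf]
  v1 <- rep(a1v, each = nel)[okf]; v2 <- rep(a2v, each = nel)[okf]

  K0 <- Matrix::sparseMatrix(i = gi, j = gj, x = 1, dims = c(nfree, nfree),
                             symmetric = TRUE)
  rows <- K0@i + 1L
  cols <- rep(seq_len(nfree), diff(K0@p))
  keys <- rows + (cols - 1) * nfree
  slot <- match(gi + (gj - 1) * nfree, keys)
  stopifnot(!anyNA(slot))
  M1map <- Matrix::sparseMatrix(i = slot, j = el, x = v1,
                                dims = c(length(K0@x), nel))
  M2map <- Matrix::sparseMatrix(i = slot, j = el, x = v2,
                                dims = c(length(K0@x), nel))

  # per-Gauss-point scatter of element stress (3 comps) into nodal forces,
  # restricted to free dofs: F = -sum_g Smap_g %*% sig_g
  dZ <- grid$thickness
  Smap <- vector("list", 4)
  for (g in 1:4) {
    B <- gb$B[[g]]
    ii <- rep(1:8, times = 3); cc <- rep(1:3, each = 8)
    vals <- t(B)[cbind(ii, cc)] * gb$wJ * dZ
    Gd <- edof[, ii]                 # nel x 24
    Cl <- 3L * (seq_len(nel) - 1L)
    JJ <- outer(Cl, cc, "+")         # nel x 24 columns in 3*nel
    okg <- !constrained[Gd]
    Smap[[g]] <- Matrix::sparseMatrix(
      i = dofmap[Gd[okg]], j = JJ[okg],
      x = rep(vals, each = nel)[okg], dims = c(nfree, 3L * nel))
  }

  structure(list(grid = grid, bc = bc, par = par, edof = edof,
                 free = free, nfree = nfree, constrained = constrained,
                 ndof = ndof, K0 = K0, M1map = M1map, M2map = M2map,
                 Smap = Smap, Bg = gb$B, wJ = gb$wJ,
                 cache = new.env(parent = emptyenv())),
            class = "mech_system")
}

#' Initial (stress-free) mechanical state
#'
#' @param msys a [mech_system()]
#' @return object of class `mech_state`: per-element, per-Gauss-point stress
#'   array `sig` (element x component x gp; components xx, yy, zz, xy),
#'   accumulated creep and thermal+phase strains, displacement `u`
#' @export
mech_state <- function(msys) {
  nel <- msys$grid$n
  structure(list(time = 0,
                 sig = array(0, c(nel, 4, 4)),
                 eps_creep = matrix(0, nel, 4),
                 eps_thermal = numeric(nel),
                 u = numeric(msys$ndof)),
            class = "mech_state")
}

# effective per-element moduli at liquid fraction th2 for time step dt
mech_moduli <- function(msys, th2, dt) {
  p <- msys$par
  E <- (1 - th2) * p$E1 + th2 * p$E2
  nu <- (1 - th2) * p$nu1 + th2 * p$nu2
  al <- (1 - th2) * p$al1 + th2 * p$al2
  mu <- (1 - th2) * p$mu1 + th2 * p$mu2
  G <- E / (2 * (1 + nu))
  Kb <- E / (3 * (1 - 2 * nu))
  relax <- ifelse(is.finite(mu), 1 / (1 + G * dt / mu), 1)
  list(E = E, nu = nu, al = al, mu = mu, G = G, Kb = Kb, relax = relax)
}

#' One quasi-static Maxwell viscoelastic stress step
#'
#' Given the thermal increment (per-cell \eqn{\Delta T} and liquid-fraction
#' increment \eqn{\Delta\theta_2}), solves quasi-static equilibrium for the
#' displacement increment and updates the stress by backward-Euler inversion
#' of the Maxwell strain-rate decomposition: the total strain increment from
#' the displacements, minus the thermal increment \eqn{\alpha\Delta T I} and
#' phase eigenstrain increment, minus the implicit creep increment
#' \eqn{\Delta t\,S/2\mu}, is mapped to stress through the isotropic
#' compliance.  Deviatoric relaxation uses the unconditionally stable factor
#' \eqn{1/(1 + G\Delta t/\mu)}; volumetric response is elastic.
#'
#' @param state a [mech_state()]
#' @param msys a [mech_system()]
#' @param dT_field per-cell temperature increment, K
#' @param dth2_field per-cell liquid-fraction increment
#' @param th2_field per-cell liquid fraction at the end of the step (used to
#'   evaluate the phase-interpolated moduli)
#' @param dt time step, s
#' @return updated `mech_state`
#' @export
update_stress <- function(state, msys, dT_field, dth2_field, th2_field, dt,
                          refresh_tol = 0.02) {
  stopifnot(dt > 0)
  nel <- msys$grid$n
  # stiffness moduli are lagged: refactorise only when the phase field has
  # moved by more than refresh_tol anywhere (or dt changed); stress and
  # stiffness always use the same moduli, so equilibrium stays exact
  cache <- msys$cache
  refresh <- is.null(cache$m) || !identical(cache$dt, dt) ||
    max(abs(th2_field - cache$th2_used)) > refresh_tol
  if (refresh) {
    cache$m <- mech_moduli(msys, th2_field, dt)
    cache$th2_used <- th2_field
    cache$dt <- dt
  }
  m <- cache$m
  # eigenstrain uses the fresh phase field (right-hand side only)
  al_now <- (1 - th2_field) * msys$par$al1 + th2_field * msys$par$al2
  d_iso <- al_now * dT_field + msys$par$eig * dth2_field # isotropic eigenstrain

  # history stress per gp and assembled force
  Fh <- numeric(msys$nfree)
  hist <- vector("list", 4)
  for (g in 1:4) {
    sg <- state$sig[, , g]                       # nel x 4: xx yy zz xy
    pm <- (sg[, 1] + sg[, 2] + sg[, 3]) / 3
    Sxx <- sg[, 1] - pm; Syy <- sg[, 2] - pm; Szz <- sg[, 3] - pm
    hxx <- pm - 3 * m$Kb * d_iso + m$relax * Sxx
    hyy <- pm - 3 * m$Kb * d_iso + m$relax * Syy
    hxy <- m$relax * sg[, 4]
    hist[[g]] <- list(pm = pm, Sxx = Sxx, Syy = Syy, Szz = Szz)
    hv <- rbind(hxx, hyy, hxy)                   # 3 x nel, column-major 3*nel
    Fh <- Fh + as.vector(msys$Smap[[g]] %*% as.vector(hv))
  }

  if (refresh || is.null(cache$chol)) {
    K <- msys$K0
    K@x <- as.vector(msys$M1map %*% m$Kb + msys$M2map %*% (m$relax * m$G))
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(K, LDL = FALSE, perm = TRUE, super = TRUE)
    } else {
      cache$chol <- Matrix::update(cache$chol, K)
    }
  }
  du_f <- as.vector(Matrix::solve(cache$chol, -Fh))
  du <- numeric(msys$ndof)
  du[msys$free] <- du_f

  U <- matrix(du[t(msys$edof)], nrow = 8)        # 8 x nel
  sig_new <- state$sig
  creep_inc <- matrix(0, nel, 4)
  inv2mu <- ifelse(is.finite(m$mu), 1 / (2 * m$mu), 0)
  for (g in 1:4) {
    eps <- msys$Bg[[g]] %*% U                    # 3 x nel: exx eyy gxy
    tr <- eps[1, ] + eps[2, ]
    dev_xx <- eps[1, ] - tr / 3
    dev_yy <- eps[2, ] - tr / 3
    dev_zz <- -tr / 3
    h <- hist[[g]]
    Sxx <- m$relax * (h$Sxx + 2 * m$G * dev_xx)
    Syy <- m$relax * (h$Syy + 2 * m$G * dev_yy)
    Szz <- m$relax * (h$Szz + 2 * m$G * dev_zz)
    Sxy <- m$relax * (state$sig[, 4, g] + m$G * eps[3, ])
    pm_new <- h$pm + m$Kb * (tr - 3 * d_iso)
    sig_new[, 1, g] <- pm_new + Sxx
    sig_new[, 2, g] <- pm_new + Syy
    sig_new[, 3, g] <- pm_new + Szz
    sig_new[, 4, g] <- Sxy
    creep_inc <- creep_inc +
      0.25 * dt * cbind(Sxx, Syy, Szz, Sxy) * inv2mu
  }

  structure(list(time = state$time + dt, sig = sig_new,
                 eps_creep = state$eps_creep + creep_inc,
                 eps_thermal = state$eps_thermal + d_iso,
                 u = state$u + du),
            class = "mech_state")
}

#' Discrete equilibrium residual of a mechanical state
#'
#' Assembled internal nodal force (discrete divergence of the stress) on the
#' free dofs; at quasi-static equilibrium this vanishes to solver precision.
#'
#' @param state a [mech_state()]
#' @param msys a [mech_system()]
#' @return max-norm of the internal force residual, N
#' @export
equilibrium_residual <- function(state, msys) {
  Fi <- numeric(msys$nfree)
  for (g in 1:4) {
    sg <- state$sig[, , g]
    hv <- rbind(sg[, 1], sg[, 2], sg[, 4])
    Fi <- Fi + as.vector(msys$Smap[[g]] %*% as.vector(hv))
  }
  max(abs(Fi))
}

#' Per-element (Gauss-averaged) stress components of a mechanical state
#' @param state a [mech_state()]
#' @return matrix `nel x 4` with columns `xx`, `yy`, `zz`, `xy` (Pa)
#' @export
cell_stress <- function(state) {
  out <- (state$sig[, , 1] + state$sig[, , 2] +
          state$sig[, , 3] + state$sig[, , 4]) / 4
  colnames(out) <- c("xx", "yy", "zz", "xy")
  out
}

#' Scalar stress measures
#'
#' `von_mises()` is the second-deviatoric-invariant scalar
#' \eqn{\sqrt{3 J_2}}; `max_principal()` is the largest principal stress
#' (positive = tension), with the out-of-plane \eqn{\sigma_{zz}} included.
#'
#' @param sig matrix with columns xx, yy, zz, xy (Pa), or a numeric length-4
#'   vector
#' @return numeric vector, Pa
#' @export
von_mises <- function(sig) {
  if (is.null(dim(sig))) sig <- matrix(sig, 1)
  pm <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  sqrt(1.5 * ((sig[, 1] - pm)^2 + (sig[, 2] - pm)^2 + (sig[, 3] - pm)^2 +
                2 * sig[, 4]^2))
}

#' @rdname von_mises
#' @export
max_principal <- function(sig) {
  if (is.null(dim(sig))) sig <- matrix(sig, 1)
  c2 <- (sig[, 1] + sig[, 2]) / 2
  r <- sqrt(((sig[, 1] - sig[, 2]) / 2)^2 + sig[, 4]^2)
  pmax(c2 + r, sig[, 3])
}

#' Region masks on the simulation grid
#'
#' `"skin"` and `"solution"` are the cell labels; `"skin_boundary"` is the
#' band of cells within `band` cells of the skin/solution interface (on
#' either side).
#'
#' @param grid a [build_grid()] object
#' @param region `"skin"`, `"solution"`, `"skin_boundary"`, or `"all"`
#' @param band half-width of the interface band, in cells
#' @return logical vector over cells
#' @export
region_mask <- function(grid, region, band = 2L) {
  m <- matrix(grid$skin_mask, grid$nx, grid$ny)
  switch(region,
    skin = grid$skin_mask,
    solution = !grid$skin_mask,
    all = rep(TRUE, grid$n),
    skin_boundary = {
      dist <- interface_distance(grid)
      as.vector(dist <= band)
    },
    stop("unknown region label: ", region))
}

# per-cell Chebyshev distance (in cells) to the nearest cell of the other label
interface_distance <- function(grid) {
  m <- matrix(grid$skin_mask, grid$nx, grid$ny)
  if (!any(m) || all(m)) return(matrix(Inf, grid$nx, grid$ny))
  # interface cells: any 4-neighbour of the opposite label
  shift <- function(M, di, dj) {
    out <- matrix(NA, nrow(M), ncol(M))
    ri <- seq_len(nrow(M)) - di; rj <- seq_len(ncol(M)) - dj
    ok_i <- ri >= 1 & ri <= nrow(M); ok_j <- rj >= 1 & rj <= ncol(M)
    out[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    out
  }
  nb_diff <- matrix(FALSE, grid$nx, grid$ny)
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sm <- shift(m, s[1], s[2])
    nb_diff <- nb_diff | (!is.na(sm) & sm != m)
  }
  d <- matrix(Inf, grid$nx, grid$ny)
  d[nb_diff] <- 0
  # chamfer sweep (Chebyshev metric)
  for (rep_i in 1:2) {
    for (j in seq_len(grid$ny)) for (i in seq_len(grid$nx)) {
      best <- d[i, j]
      for (s in list(c(-1, 0), c(0, -1), c(-1, -1), c(-1, 1)))
        if (i + s[1] >= 1 && i + s[1] <= grid$nx &&
            j + s[2] >= 1 && j + s[2] <= grid$ny)
          best <- min(best, d[i + s[1], j + s[2]] + 1)
      d[i, j] <- best
    }
    d <- d[grid$nx:1, grid$ny:1]
  }
  d
}

#' Peak scalar stress over a recorded history
#'
#' Scans a stress history (list of snapshots with fields `time` and `sig`,
#' the per-cell component matrix) for the maximum of the configured scalar
#' within a region.  Ties are broken by earliest time, then lowest cell
#' index.
#'
#' @param history list of `list(time=, sig=)` snapshots
#' @param grid a [build_grid()] object
#' @param region `"skin"`, `"solution"`, `"skin_boundary"`, or `"all"`
#' @param measure `"von_mises"` (default) or `"max_principal"`
#' @return list `value` (Pa), `time` (s), `cell` (index), `location` (m)
#' @export
peak_stress <- function(history, grid, region = "skin",
                        measure = c("von_mises", "max_principal")) {
  measure <- match.arg(measure)
  stopifnot(length(history) >= 1)
  mask <- region_mask(grid, region)
  fun <- if (measure == "von_mises") von_mises else max_principal
  best <- list(value = -Inf, time = history[[1]]$time, cell = which(mask)[1])
  for (snap in history) {
    s <- fun(snap$sig)
    s[!mask] <- -Inf
    v <- max(s)
    if (v > best$value) {                        # strict: earliest time wins
      cell <- which.max(s)                       # lowest index among ties
      best <- list(value = v, time = snap$time, cell = cell)
    }
  }
  best$location <- c(x = grid$xc_all[best$cell], y = grid$yc_all[best$cell])
  best
}

#' Scalar stress profile along the skin midlines
#'
#' Samples a per-cell scalar stress along the row of cells nearest the skin
#' mid-plane `y = 0` (`axis = "x"`) or the column nearest `x = 0`
#' (`axis = "y"`).
#'
#' @param sig per-cell component matrix (columns xx, yy, zz, xy)
#' @param grid a [build_grid()] object
#' @param axis `"x"` or `"y"`
#' @param measure `"von_mises"`, `"max_principal"`, or a component name
#' @return data.frame with `position` (m) and `value` (Pa)
#' @export
stress_profile <- function(sig, grid, axis = c("x", "y"),
                           measure = "von_mises") {
  axis <- match.arg(axis)
  s <- switch(measure,
              von_mises = von_mises(sig),
              max_principal = max_principal(sig),
              xx = sig[, 1], yy = sig[, 2], zz = sig[, 3], xy = sig[, 4],
              stop("unknown stress measure: ", measure))
  if (axis == "x") {
    j <- which.min(abs(grid$y))
    cells <- (j - 1) * grid$nx + seq_len(grid$nx)
    data.frame(position = grid$x, value = s[cells])
  } else {
    i <- which.min(abs(grid$x))
    cells <- (seq_len(grid$ny) - 1) * grid$nx + i
    data.frame(position = grid$y, value = s[cells])
  }
}
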