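## Lagrangian microsphere transport surrogate. Each branch carries an
## analytic pulsatile Poiseuille profile scaled by its imposed flow; the
## particle force balance (gravity + drag + pressure gradient + virtual
## mass) is integrated with a semi-implicit Euler scheme (the drag
## relaxation time, ~5e-5 s for 40 um spheres, is far below the time step,
## so drag is treated implicitly). Junctions hand particles over by an
## angular-sector map whose sector widths equal the daughter flow shares.

#' Microsphere properties
#'
#' Defaults are resin-microsphere-like 40 um spheres with density
#' 1600 kg/m^3.
#'
#' @param diameter particle diameter, m.
#' @param density particle density, kg/m^3.
#' @param C_V virtual mass coefficient (standard sphere value 0.5).
#' @param drag drag closure: `"schiller_naumann"`
#'   (`C_D Re_p/24 = 1 + 0.15 Re_p^0.687`) or `"stokes"`.
#' @param g gravitational acceleration magnitude, m/s^2; set 0 to disable
#'   gravity.
#' @return object of class `particle_spec` (includes the particle mass).
#' @export
particle_spec <- function(diameter = 40e-6, density = 1600, C_V = 0.5,
                          drag = c("schiller_naumann", "stokes"), g = 9.81) {
  stopifnot(diameter > 0, density > 0, C_V >= 0, g >= 0)
  structure(list(diameter = diameter, density = density, C_V = C_V,
                 drag = match.arg(drag), g = g,
                 mass = density * pi * diameter^3 / 6),
            class = "particle_spec")
}

#' Carrier fluid (blood) properties
#'
#' @param density fluid density, kg/m^3 (default 1060).
#' @param viscosity a [viscosity_model()].
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, viscosity = viscosity_model()) {
  stopifnot(density > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

## drag factor beta [1/s]: F_D = m_p * beta * (u - u_p)
.drag_beta <- function(urel, mu, spec, fluid) {
  beta0 <- 18 * mu / (spec$density * spec$diameter^2)
  if (spec$drag == "stokes") return(beta0)
  Re <- fluid$density * spec$diameter * urel / mu
  beta0 * (1 + 0.15 * Re^0.687)
}

#' Forces on a microsphere
#'
#' Evaluates the force balance terms for given local fluid state: gravity
#' (buoyancy-corrected), drag with the configured closure, pressure-gradient
#' force and the convective part of the virtual mass force. The
#' `-du_p/dt` part of the virtual mass force is not a state function; the
#' integrator accounts for it as an added-mass factor.
#'
#' @param u local fluid velocity, 3-vector, m/s.
#' @param up particle velocity, 3-vector, m/s.
#' @param mu local apparent viscosity, kg/(m s).
#' @param conv convective fluid acceleration seen by the particle,
#'   `(u_p . grad) u`, 3-vector, m/s^2.
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param gravity_dir unit gravity direction (default -z).
#' @return list with `F_G`, `F_D`, `F_P`, `F_V` and `total` (Newtons).
#' @export
particle_forces <- function(u, up, mu, conv = c(0, 0, 0),
                            spec = particle_spec(),
                            fluid = fluid_properties(),
                            gravity_dir = c(0, 0, -1)) {
  mp <- spec$mass
  F_G <- mp * spec$g * gravity_dir * (spec$density - fluid$density) / spec$density
  urel <- sqrt(sum((u - up)^2))
  beta <- .drag_beta(urel, mu, spec, fluid)
  F_D <- mp * beta * (u - up)
  F_P <- mp * fluid$density / spec$density * conv
  F_V <- spec$C_V * mp * fluid$density / spec$density * conv
  list(F_G = F_G, F_D = F_D, F_P = F_P, F_V = F_V,
       total = F_G + F_D + F_P + F_V)
}

#' Build the network flow field
#'
#' Precomputes, per branch, the straight-tube frame (axis from first to last
#' centerline point, arc length as tube length), the steady flow (sum of the
#' imposed outlet flows downstream), the local gravity components, and the
#' junction transfer sectors. All branch flows follow the same normalized
#' waveform shape, so flow is conserved at every junction at all times.
#'
#' @param tree a `vessel_tree`.
#' @param bc a `flow_bc` on the tree's outlet set.
#' @param waveform an `inflow_waveform` (only its normalized shape is used;
#'   flows come from `bc`).
#' @return object of class `network_flow_field`.
#' @export
network_flow_field <- function(tree, bc, waveform) {
  ids <- as.integer(names(tree$branches))
  n <- length(ids)
  slot_of <- setNames(seq_len(n), as.character(ids))
  sub_out <- .subtree_outlets(tree)
  kids <- tree_children(tree)
  missing <- setdiff(as.character(tree_outlets(tree)), names(bc$Q_b))
  if (length(missing))
    stop("flow_bc lacks outlet(s): ", paste(missing, collapse = ", "))
  R <- L <- Qs <- numeric(n)
  e1 <- e2 <- e3 <- g_loc <- matrix(0, n, 3)
  outlet_id <- rep(NA_integer_, n)
  child_slots <- vector("list", n)
  for (i in seq_len(n)) {
    b <- tree$branches[[as.character(ids[i])]]
    R[i] <- b$diameter / 2
    L[i] <- centerline_length(b)
    axis <- b$centerline[nrow(b$centerline), ] - b$centerline[1L, ]
    fr <- .orthonormal_frame(axis)
    e1[i, ] <- fr$e1; e2[i, ] <- fr$e2; e3[i, ] <- fr$e3
    g_loc[i, ] <- c(sum(tree$gravity * fr$e1), sum(tree$gravity * fr$e2),
                    sum(tree$gravity * fr$e3))
    Qs[i] <- sum(bc$Q_b[as.character(sub_out[[as.character(ids[i])]])]) *
      1e-6 / 60  # ml/min -> m^3/s
    outlet_id[i] <- b$outlet_id
    child_slots[[i]] <- unname(slot_of[as.character(kids[[as.character(ids[i])]])])
  }
  ## junction transfer sectors: contiguous angular sectors ordered by
  ## daughter azimuth, widths proportional to daughter flow shares
  transfer <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- child_slots[[i]]
    if (!length(ds)) next
    az <- atan2(e3[ds, , drop = FALSE] %*% e2[i, ],
                e3[ds, , drop = FALSE] %*% e1[i, ])[, 1L]
    ord <- order(az, ids[ds])
    ds <- ds[ord]; az <- az[ord]
    frac <- Qs[ds] / sum(Qs[ds])
    width <- 2 * pi * frac
    start <- az[1L] - width[1L] / 2
    bounds <- start + cumsum(c(0, width))
    transfer[[i]] <- list(d_slots = ds, start = start, bounds = bounds,
                          frac = frac)
  }
  structure(list(ids = ids, slot_of = slot_of, R = R, L = L, Qs = Qs,
                 e1 = e1, e2 = e2, e3 = e3, g_loc = g_loc,
                 outlet_id = outlet_id, child_slots = child_slots,
                 transfer = transfer, root_slot = unname(slot_of[as.character(tree$root)]),
                 shape = waveform_shape_fun(waveform),
                 period = waveform$period),
            class = "network_flow_field")
}

## axial fluid velocity and its radial gradient at radius r in branch slot
.profile <- function(field, slot, r, t) {
  Q <- field$Qs[slot] * field$shape(t)
  R <- field$R[slot]
  Umax <- 2 * Q / (pi * R^2)
  list(u = Umax * (1 - (r / R)^2), du_dr = -2 * Umax * r / R^2)
}

#' Transfer a particle across a junction
#'
#' The parent exit disk is partitioned into contiguous angular sectors
#' ordered by daughter azimuth, with each sector's angular share equal to
#' the daughter's flow share. A particle is assigned by its azimuth; within
#' the sector, the azimuth is rescaled to the full daughter disk and the
#' radius is rescaled to preserve the normalized Poiseuille streamfunction
#' `psi(r) = (r/R)^2 (2 - (r/R)^2)`. Deterministic.
#'
#' @param field a `network_flow_field`.
#' @param branch_id parent branch id (must have daughters).
#' @param x1,x2 particle in-plane position on the parent exit disk, m.
#' @return list with `branch_id`, `x1`, `x2` in the daughter branch.
#' @export
junction_transfer <- function(field, branch_id, x1, x2) {
  slot <- field$slot_of[[as.character(branch_id)]]
  tr <- field$transfer[[slot]]
  if (is.null(tr)) stop("branch ", branch_id, " has no daughters")
  if (field$Qs[slot] == 0) stop("zero parent flow at branch ", branch_id)
  res <- .transfer_vec(field, rep(slot, length(x1)), x1, x2)
  list(branch_id = field$ids[res$slot], x1 = res$x1, x2 = res$x2)
}

## vectorized junction transfer; slots may differ per particle
.transfer_vec <- function(field, slots, x1, x2) {
  n <- length(slots)
  out_slot <- integer(n); ox1 <- numeric(n); ox2 <- numeric(n)
  for (s in unique(slots)) {
    sel <- which(slots == s)
    tr <- field$transfer[[s]]
    Rp <- field$R[s]
    r <- sqrt(x1[sel]^2 + x2[sel]^2)
    r <- pmin(r, Rp)
    theta <- atan2(x2[sel], x1[sel])
    phi <- (theta - tr$start) %% (2 * pi)
    k <- findInterval(phi, tr$bounds - tr$start, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), length(tr$d_slots))
    width <- diff(tr$bounds)
    theta_new <- (phi - (tr$bounds[k] - tr$start)) / width[k] * 2 * pi
    psi <- (r / Rp)^2 * (2 - (r / Rp)^2)     # normalized streamfunction
    xnew <- 1 - sqrt(pmax(0, 1 - psi))        # (r'/R')^2
    dsl <- tr$d_slots[k]
    rnew <- field$R[dsl] * sqrt(xnew)
    out_slot[sel] <- dsl
    ox1[sel] <- rnew * cos(theta_new)
    ox2[sel] <- rnew * sin(theta_new)
  }
  list(slot = out_slot, x1 = ox1, x2 = ox2)
}

#' Advance particles one time step
#'
#' Semi-implicit Euler: the velocity update treats drag implicitly and
#' carries the virtual-mass `-du_p/dt` term as an added-mass factor; the
#' position then advances with the new velocity. Wall contact is specular
#' (restitution 1 in both tangential and normal directions); particles
#' crossing the distal plane are handed to a daughter via the junction map
#' or, at a leaf, marked exited.
#'
#' @param state particle state list (vectors `slot`, `x1`, `x2`, `s`, `v1`,
#'   `v2`, `v3`, `active`, `exit_outlet`, `exit_time`), as built by
#'   [simulate_injection()]; single particles can be built with
#'   [particle_state()].
#' @param field a `network_flow_field`.
#' @param t current time, s.
#' @param dt time step, s (expected in `(0, 1e-3]`).
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @return the updated state.
#' @export
step_particle <- function(state, field, t, dt, spec = particle_spec(),
                          fluid = fluid_properties()) {
  a <- which(state$active)
  if (!length(a)) return(state)
  slot <- state$slot[a]
  x1 <- state$x1[a]; x2 <- state$x2[a]; s <- state$s[a]
  v1 <- state$v1[a]; v2 <- state$v2[a]; v3 <- state$v3[a]
  R <- field$R[slot]
  r <- sqrt(x1^2 + x2^2)
  pr <- .profile(field, slot, r, t)
  u_ax <- pr$u; du_dr <- pr$du_dr
  gdot <- shear_rate(du_dr)
  mu <- quemada_viscosity(gdot, fluid$viscosity)
  urel <- sqrt(v1^2 + v2^2 + (v3 - u_ax)^2)
  beta <- .drag_beta(urel, mu, spec, fluid)
  rho_ratio <- fluid$density / spec$density
  ## convective acceleration (u_p . grad)u: radial motion through the
  ## sheared axial profile
  v_rad <- ifelse(r > 0, (v1 * x1 + v2 * x2) / r, 0)
  conv_ax <- v_rad * du_dr
  mf <- 1 + spec$C_V * rho_ratio                    # added-mass factor
  a1 <- spec$g * field$g_loc[slot, 1L] * (spec$density - fluid$density) / spec$density
  a2 <- spec$g * field$g_loc[slot, 2L] * (spec$density - fluid$density) / spec$density
  a3 <- spec$g * field$g_loc[slot, 3L] * (spec$density - fluid$density) / spec$density +
    (1 + spec$C_V) * rho_ratio * conv_ax
  ## implicit drag: v' = (v + dt/mf (a + beta u)) / (1 + dt beta / mf)
  den <- 1 + dt * beta / mf
  v1 <- (v1 + dt / mf * a1) / den
  v2 <- (v2 + dt / mf * a2) / den
  v3 <- (v3 + dt / mf * (a3 + beta * u_ax)) / den
  x1 <- x1 + dt * v1
  x2 <- x2 + dt * v2
  s <- s + dt * v3
  ## specular wall reflection
  rn <- sqrt(x1^2 + x2^2)
  hit <- which(rn > R)
  if (length(hit)) {
    rh <- rn[hit]; Rh <- R[hit]
    rref <- pmax(2 * Rh - rh, 1e-3 * Rh)
    scl <- rref / rh
    nx <- x1[hit] / rh; ny <- x2[hit] / rh
    x1[hit] <- x1[hit] * scl; x2[hit] <- x2[hit] * scl
    vr <- v1[hit] * nx + v2[hit] * ny
    v1[hit] <- v1[hit] - 2 * vr * nx
    v2[hit] <- v2[hit] - 2 * vr * ny
  }
  neg <- which(s < 0)
  if (length(neg)) { s[neg] <- -s[neg]; v3[neg] <- abs(v3[neg]) }
  ## distal plane crossings
  crossed <- which(s >= field$L[slot])
  if (length(crossed)) {
    cs <- slot[crossed]
    is_leaf <- !is.na(field$outlet_id[cs])
    if (any(is_leaf)) {
      gi <- a[crossed[is_leaf]]
      state$exit_outlet[gi] <- field$outlet_id[cs[is_leaf]]
      state$exit_time[gi] <- t + dt
      state$active[gi] <- FALSE
    }
    inner <- crossed[!is_leaf]
    if (length(inner)) {
      res <- .transfer_vec(field, slot[inner], x1[inner], x2[inner])
      slot[inner] <- res$slot
      x1[inner] <- res$x1; x2[inner] <- res$x2
      s[inner] <- 0
      pr2 <- .profile(field, slot[inner], sqrt(res$x1^2 + res$x2^2), t + dt)
      v1[inner] <- 0; v2[inner] <- 0; v3[inner] <- pr2$u
    }
  }
  state$slot[a] <- slot
  state$x1[a] <- x1; state$x2[a] <- x2; state$s[a] <- s
  state$v1[a] <- v1; state$v2[a] <- v2; state$v3[a] <- v3
  state
}

#' Build a minimal particle state
#'
#' @param field a `network_flow_field`.
#' @param branch_id branch holding the particle.
#' @param x1,x2 in-plane position, m.
#' @param s axial position, m.
#' @param v velocity 3-vector in the branch frame, m/s.
#' @return a particle state list usable with [step_particle()].
#' @export
particle_state <- function(field, branch_id, x1 = 0, x2 = 0, s = 0,
                           v = c(0, 0, 0)) {
  n <- length(x1)
  list(slot = rep(unname(field$slot_of[[as.character(branch_id)]]), n),
       x1 = x1, x2 = x2, s = rep(s, length.out = n),
       v1 = rep(v[1], n), v2 = rep(v[2], n), v3 = rep(v[3], n),
       active = rep(TRUE, n),
       exit_outlet = rep(NA_integer_, n), exit_time = rep(NA_real_, n))
}

#' Injection specification
#'
#' @param mode `"planar"` (particles released over the whole inlet
#'   cross-section) or `"catheter"` (released from a catheter tip disk).
#' @param burst_interval time between injection bursts, s (default 0.01).
#' @param injection_cycle index of the flow cycle during which particles are
#'   injected (default 3; earlier cycles are flow development time).
#' @param n_bursts optional cap on the number of bursts (default: every
#'   `burst_interval` throughout the injection cycle).
#' @param seed_pitch planar seeding pitch across the lumen disk, m (default
#'   1e-4, aligned with the release-grid spacing).
#' @param tip catheter tip in-plane position `c(x, y)`, m (catheter mode).
#' @param catheter_id catheter inner diameter, m (default 0.7e-3).
#' @param catheter_velocity particle injection velocity at the tip, m/s
#'   (default 0.12).
#' @return object of class `injection_spec`.
#' @export
injection_spec <- function(mode = c("planar", "catheter"),
                           burst_interval = 0.01, injection_cycle = 3L,
                           n_bursts = NULL, seed_pitch = 1e-4,
                           tip = c(0, 0), catheter_id = 0.7e-3,
                           catheter_velocity = 0.12) {
  structure(list(mode = match.arg(mode), burst_interval = burst_interval,
                 injection_cycle = as.integer(injection_cycle),
                 n_bursts = n_bursts, seed_pitch = seed_pitch, tip = tip,
                 catheter_id = catheter_id,
                 catheter_velocity = catheter_velocity),
            class = "injection_spec")
}

#' Transport run control
#'
#' @param dt_fine time step during accelerating/decelerating waveform
#'   phases, s (default 0.5e-3).
#' @param dt_coarse time step during flat waveform phases, s (default 1e-3).
#' @param slope_threshold normalized waveform slope (1/s) above which the
#'   fine step is used.
#' @param exit_tol convergence rule: stop after the first whole
#'   post-injection cycle in which fewer than this fraction of all injected
#'   particles exited (default 0.015).
#' @param max_cycles hard cap on simulated flow cycles.
#' @param seed RNG seed (runs are deterministic; the seed covers any
#'   stochastic extensions).
#' @return object of class `run_control`.
#' @export
run_control <- function(dt_fine = 0.5e-3, dt_coarse = 1e-3,
                        slope_threshold = 2, exit_tol = 0.015,
                        max_cycles = 30L, seed = 1L) {
  structure(list(dt_fine = dt_fine, dt_coarse = dt_coarse,
                 slope_threshold = slope_threshold, exit_tol = exit_tol,
                 max_cycles = as.integer(max_cycles), seed = as.integer(seed)),
            class = "run_control")
}

## seed grid on a disk of radius R at the given pitch, excluding the wall
.disk_seeds <- function(R, pitch) {
  ax <- seq(-R, R, by = pitch)
  g <- expand.grid(x = ax, y = ax)
  g <- g[g$x^2 + g$y^2 < R^2 * (1 - 1e-9), , drop = FALSE]
  if (!nrow(g)) stop("no seeds fit the disk: pitch too large")
  as.matrix(g)
}

#' Simulate a particle injection run
#'
#' Injects particle bursts during the injection cycle (planar: a uniform
#' seed grid across the inlet lumen, released at the local fluid velocity;
#' catheter: seeds inside the tip disk released at the catheter injection
#' velocity), advances all particles through the network, and continues in
#' whole flow cycles until fewer than `exit_tol` of all injected particles
#' exit in the latest cycle (or `max_cycles` is hit). Remaining particles
#' are recorded as no-exit.
#'
#' @param field a `network_flow_field`.
#' @param inj an [injection_spec()].
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param control a [run_control()].
#' @return object of class `exit_record_set`: data frame with one row per
#'   injected particle (`particle_id`, `t_inject_s`, `x_m`, `y_m`,
#'   `outlet`, `exit_time_s`; `outlet` is `NA` for no-exit), with
#'   attributes `cycles_run`, `exits_per_cycle`, `n_injected`, and (for
#'   catheter mode) `catheter_flow_ml_min`.
#' @export
simulate_injection <- function(field, inj, spec = particle_spec(),
                               fluid = fluid_properties(),
                               control = run_control()) {
  set.seed(control$seed)
  period <- field$period
  t0 <- (inj$injection_cycle - 1) * period
  t_end_inj <- inj$injection_cycle * period
  bursts <- seq(t0, t_end_inj - 1e-9, by = inj$burst_interval)
  if (!is.null(inj$n_bursts)) bursts <- bursts[seq_len(min(inj$n_bursts,
                                                           length(bursts)))]
  rs <- field$root_slot
  if (inj$mode == "planar") {
    seeds <- .disk_seeds(field$R[rs], inj$seed_pitch)
  } else {
    rc <- inj$catheter_id / 2
    if (sqrt(sum(inj$tip^2)) + rc > field$R[rs])
      stop("catheter tip disk does not fit inside the inlet lumen")
    seeds <- .disk_seeds(rc, inj$seed_pitch / 2)
    seeds[, 1L] <- seeds[, 1L] + inj$tip[1L]
    seeds[, 2L] <- seeds[, 2L] + inj$tip[2L]
  }
  ns <- nrow(seeds); nb <- length(bursts)
  n <- ns * nb
  state <- list(slot = rep(rs, n),
                x1 = rep(seeds[, 1L], nb), x2 = rep(seeds[, 2L], nb),
                s = numeric(n), v1 = numeric(n), v2 = numeric(n),
                v3 = numeric(n), active = rep(FALSE, n),
                exit_outlet = rep(NA_integer_, n),
                exit_time = rep(NA_real_, n))
  t_inject <- rep(bursts, each = ns)
  plane_x <- rep(seeds[, 1L], nb); plane_y <- rep(seeds[, 2L], nb)

  ## numeric slope of the normalized shape, for dt selection
  slope <- function(t) {
    h <- 1e-4
    abs(field$shape(t + h) - field$shape(t - h)) / (2 * h)
  }
  next_burst <- 1L
  exits_per_cycle <- integer(0)
  t <- t0
  cycle <- inj$injection_cycle
  exited_before <- 0L
  repeat {
    cycle_end <- cycle * period
    while (t < cycle_end - 1e-12) {
      dt <- if (slope(t) > control$slope_threshold) control$dt_fine
            else control$dt_coarse
      dt <- min(dt, cycle_end - t)
      if (next_burst <= length(bursts) && bursts[next_burst] < t + dt - 1e-12) {
        dt <- max(bursts[next_burst] - t, 1e-9)
      }
      ## release due bursts
      while (next_burst <= length(bursts) && bursts[next_burst] <= t + 1e-12) {
        idx <- which(t_inject == bursts[next_burst])
        state$active[idx] <- TRUE
        if (inj$mode == "planar") {
          pr <- .profile(field, rs, sqrt(state$x1[idx]^2 + state$x2[idx]^2), t)
          state$v3[idx] <- pr$u
        } else {
          state$v3[idx] <- inj$catheter_velocity
        }
        next_burst <- next_burst + 1L
      }
      state <- step_particle(state, field, t, dt, spec, fluid)
      t <- t + dt
    }
    n_exited <- sum(!is.na(state$exit_outlet))
    exits_per_cycle <- c(exits_per_cycle, n_exited - exited_before)
    exited_before <- n_exited
    done_injecting <- next_burst > length(bursts) && t >= t_end_inj - 1e-9
    latest <- exits_per_cycle[length(exits_per_cycle)]
    if (done_injecting && cycle > inj$injection_cycle &&
        latest < control$exit_tol * n) break
    if (!any(state$active)) {
      if (done_injecting && cycle > inj$injection_cycle) break
    }
    if (cycle >= control$max_cycles) break
    cycle <- cycle + 1L
  }
  rec <- data.frame(particle_id = seq_len(n), t_inject_s = t_inject,
                    x_m = plane_x, y_m = plane_y,
                    outlet = state$exit_outlet,
                    exit_time_s = state$exit_time)
  attr(rec, "cycles_run") <- cycle
  attr(rec, "exits_per_cycle") <- exits_per_cycle
  attr(rec, "n_injected") <- n
  attr(rec, "burst_times") <- bursts
  if (inj$mode == "catheter")
    attr(rec, "catheter_flow_ml_min") <-
      pi * (inj$catheter_id / 2)^2 * inj$catheter_velocity * 6e7
  class(rec) <- c("exit_record_set", "data.frame")
  rec
}

#' Write exit records as CSV
#' @param exits an `exit_record_set`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_exits_csv <- function(exits, path) {
  df <- as.data.frame(exits)
  df$outcome <- ifelse(is.na(df$outlet), "no_exit", as.character(df$outlet))
  write.csv(df[, c("particle_id", "t_inject_s", "x_m", "y_m", "outcome")],
            path, row.names = FALSE)
  invisible(path)
}
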