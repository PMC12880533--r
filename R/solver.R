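# Finite-volume discretization of steady/transient heat transport:
# conduction everywhere (harmonic-mean face conductivities), first-order
# upwind advection inside the channel, fixed-temperature bottom, convective
# (Robin) top, insulated lateral faces, Dirichlet inlet and advective
# outflow at the channel exit. SI units internally; user-facing units are
# mm / mW / degrees C.

# Assemble triplets (i, j, x) and rhs b for A T = b. If dt is given the
# transient mass term rho*cp*V/dt is added (T_old contributes to b).
assemble_system <- function(grid, materials, ambient, flow, actuator_power,
                            dt = NULL, T_old = NULL) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  h <- grid$spacing * 1e-3            # m
  A_face <- h^2

  lab <- grid$labels[grid$material]
  kc <- vapply(materials[lab], function(m) m$conductivity, numeric(1))
  kc <- array(kc, dim = dim(grid$material))
  rhoc <- vapply(materials[lab],
                 function(m) m$density * m$specific_heat, numeric(1))
  rhoc <- array(rhoc, dim = dim(grid$material))

  id <- function(ix, iy, iz) ix + (iy - 1L) * nx + ((iz - 1L) * nx) * ny

  ti <- vector("list", 32); tj <- vector("list", 32); tx <- vector("list", 32)
  np <- 0L
  push <- function(i, j, v) {
    np <<- np + 1L
    ti[[np]] <<- i; tj[[np]] <<- j; tx[[np]] <<- v
  }
  b <- numeric(n)
  diag_extra <- numeric(n)

  # --- conduction across interior faces, one axis at a time
  axes <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  idx <- list(seq_len(nx), seq_len(ny), seq_len(nz))
  for (ax in 1:3) {
    dims <- c(nx, ny, nz)
    ia <- idx; ib <- idx
    ia[[ax]] <- seq_len(dims[ax] - 1L)
    ib[[ax]] <- 2:dims[ax]
    ga <- as.matrix(expand.grid(ia[[1]], ia[[2]], ia[[3]]))
    gb <- ga; gb[, ax] <- gb[, ax] + 1L
    a_id <- id(ga[, 1], ga[, 2], ga[, 3])
    b_id <- id(gb[, 1], gb[, 2], gb[, 3])
    kA <- kc[a_id]; kB <- kc[b_id]
    kf <- 2 * kA * kB / (kA + kB)
    coef <- kf * h                     # k_face * A / h
    push(a_id, b_id, -coef); push(b_id, a_id, -coef)
    push(a_id, a_id,  coef); push(b_id, b_id,  coef)
  }

  # --- advection on x-faces between fluid cells (upwind, u >= 0 along +x)
  u <- grid_velocity(grid, flow)
  fl <- grid$material == 2L
  rc_f <- materials$fluid$density * materials$fluid$specific_heat
  if (flow$speed > 0) {
    ga <- as.matrix(expand.grid(seq_len(nx - 1L), seq_len(ny), seq_len(nz)))
    gb <- ga; gb[, 1] <- gb[, 1] + 1L
    a_id <- id(ga[, 1], ga[, 2], ga[, 3])
    b_id <- id(gb[, 1], gb[, 2], gb[, 3])
    both <- fl[a_id] & fl[b_id]
    a_id <- a_id[both]; b_id <- b_id[both]
    uf <- 0.5 * (u[a_id] + u[b_id])
    Fm <- rc_f * uf * A_face           # W/K
    push(a_id, a_id,  Fm); push(b_id, a_id, -Fm)

    # inlet (x-min fluid cells): advective influx at T_in + Dirichlet diffusion
    gin <- as.matrix(expand.grid(1L, seq_len(ny), seq_len(nz)))
    in_id <- id(gin[, 1], gin[, 2], gin[, 3])
    in_id <- in_id[fl[in_id]]
    Fin <- rc_f * u[in_id] * A_face
    b[in_id] <- b[in_id] + Fin * ambient$inlet
    coef_in <- 2 * kc[in_id] * h
    diag_extra[in_id] <- diag_extra[in_id] + coef_in
    b[in_id] <- b[in_id] + coef_in * ambient$inlet

    # outlet (x-max fluid cells): advective outflow at cell temperature
    gout <- as.matrix(expand.grid(nx, seq_len(ny), seq_len(nz)))
    out_id <- id(gout[, 1], gout[, 2], gout[, 3])
    out_id <- out_id[fl[out_id]]
    Fout <- rc_f * u[out_id] * A_face
    diag_extra[out_id] <- diag_extra[out_id] + Fout
  } else {
    # no flow: treat inlet fluid face as Dirichlet to the inlet temperature
    gin <- as.matrix(expand.grid(1L, seq_len(ny), seq_len(nz)))
    in_id <- id(gin[, 1], gin[, 2], gin[, 3])
    in_id <- in_id[fl[in_id]]
    coef_in <- 2 * kc[in_id] * h
    diag_extra[in_id] <- diag_extra[in_id] + coef_in
    b[in_id] <- b[in_id] + coef_in * ambient$inlet
    gout <- as.matrix(expand.grid(nx, seq_len(ny), seq_len(nz)))
    out_id <- id(gout[, 1], gout[, 2], gout[, 3])
    out_id <- out_id[fl[out_id]]
    coef_out <- 2 * kc[out_id] * h
    diag_extra[out_id] <- diag_extra[out_id] + coef_out
    b[out_id] <- b[out_id] + coef_out * ambient$inlet
  }

  # --- bottom face: fixed temperature
  gbot <- as.matrix(expand.grid(seq_len(nx), seq_len(ny), 1L))
  bot_id <- id(gbot[, 1], gbot[, 2], gbot[, 3])
  coef_b <- 2 * kc[bot_id] * h
  diag_extra[bot_id] <- diag_extra[bot_id] + coef_b
  b[bot_id] <- b[bot_id] + coef_b * ambient$bottom

  # --- top face: convective (Robin), conduction half-cell in series with h
  gtop <- as.matrix(expand.grid(seq_len(nx), seq_len(ny), nz))
  top_id <- id(gtop[, 1], gtop[, 2], gtop[, 3])
  if (ambient$h > 0) {
    U <- 1 / (1 / ambient$h + (h / 2) / kc[top_id])
    coef_t <- U * A_face
    diag_extra[top_id] <- diag_extra[top_id] + coef_t
    b[top_id] <- b[top_id] + coef_t * ambient$ambient
  }

  # --- actuator heat source (mW -> W), uniform over actuator cells
  act <- which(grid$material == 3L)
  if (length(act) && actuator_power > 0)
    b[act] <- b[act] + (actuator_power * 1e-3) / length(act)

  # --- transient mass term (rhs contribution m * T_old added by the caller)
  mass <- NULL
  if (!is.null(dt)) {
    mass <- as.vector(rhoc) * h^3 / dt
    diag_extra <- diag_extra + mass
    if (!is.null(T_old)) b <- b + mass * as.vector(T_old)
  }

  nz_ids <- which(diag_extra != 0)
  push(nz_ids, nz_ids, diag_extra[nz_ids])

  b0 <- if (!is.null(mass) && !is.null(T_old)) b - mass * as.vector(T_old)
  else b
  list(i = unlist(ti[seq_len(np)]), j = unlist(tj[seq_len(np)]),
       x = unlist(tx[seq_len(np)]), b = b, b0 = b0, mass = mass, n = n)
}

#' Solve the steady thermal field
#'
#' Steady solution of conduction in the solids and advection-diffusion in
#' the channel with the benchtop boundary conditions: insulated lateral
#' faces, fixed bottom temperature, convective top surface, Dirichlet inlet
#' and zero-diffusive-flux advective outflow. The linear system is solved
#' with an ILU(0)-preconditioned BiCGSTAB iteration.
#'
#' @param grid A `tf_grid` from [build_grid()].
#' @param materials Named list of `tf_material` covering all grid labels.
#' @param ambient A `tf_ambient`.
#' @param flow A `tf_flow`.
#' @param actuator_power Actuator power in mW.
#' @param tol Relative residual tolerance of the linear solve.
#' @return An object of class `thermal_field`: the temperature array
#'   (degrees C), the grid, the achieved relative residual, and a `steady`
#'   flag.
#' @export
solve_steady <- function(grid, materials, ambient, flow, actuator_power,
                         tol = 1e-8) {
  stopifnot(inherits(grid, "tf_grid"))
  miss <- setdiff(grid$labels[sort(unique(as.vector(grid$material)))],
                  names(materials))
  if (length(miss))
    stop("materials map is missing labels: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sys <- assemble_system(grid, materials, ambient, flow, actuator_power)
  x0 <- rep(mean(c(ambient$bottom, ambient$ambient, ambient$inlet)), sys$n)
  sol <- .bicgstab_ilu0(sys$n, sys$i - 1L, sys$j - 1L, sys$x, sys$b, x0,
                        tol = tol, maxit = 4000L)
  if (!sol$converged)
    stop(sprintf("steady solve did not converge (relative residual %.3g)",
                 sol$relres), call. = FALSE)
  temp <- array(sol$x, dim = c(grid$nx, grid$ny, grid$nz))
  if (any(!is.finite(temp)))
    stop("steady solve produced non-finite temperatures", call. = FALSE)
  structure(list(temperature = temp, grid = grid, steady = TRUE,
                 relres = sol$relres, iterations = sol$iter,
                 time = NA_real_),
            class = "thermal_field")
}

#' Solve the transient thermal field
#'
#' Implicit (backward Euler) time stepping from a uniform initial field at
#' the bottom/ambient temperature, under a piecewise-constant flow profile.
#'
#' @inheritParams solve_steady
#' @param flow_profile Either a single `tf_flow` (constant) or a function
#'   of time `t` (seconds) returning a `tf_flow` (piecewise constant).
#' @param duration Total simulated time in seconds.
#' @param dt Time step in seconds.
#' @param keep_every Keep every `keep_every`-th field (default 1 = all).
#' @param initial_temperature Initial condition: a uniform temperature
#'   (degrees C), a full temperature array, or a `thermal_field` (e.g. a
#'   steady solve, to start a step-response run from equilibrium).
#' @return List with `times` (seconds) and `fields` (list of
#'   `thermal_field` objects, `steady = FALSE`, `time` set).
#' @export
solve_transient <- function(grid, materials, ambient, flow_profile,
                            actuator_power, duration, dt, keep_every = 1L,
                            initial_temperature = NULL, tol = 1e-8) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be at least one time step", call. = FALSE)
  flow_at <- if (is.function(flow_profile)) flow_profile else function(t) flow_profile
  if (is.null(initial_temperature)) initial_temperature <- ambient$bottom

  if (inherits(initial_temperature, "thermal_field"))
    initial_temperature <- initial_temperature$temperature
  nsteps <- floor(duration / dt + 1e-9)
  Tcur <- array(initial_temperature, dim = c(grid$nx, grid$ny, grid$nz))
  times <- c(); fields <- list()
  last_speed <- NA_real_; sys <- NULL
  for (s in seq_len(nsteps)) {
    t_new <- s * dt
    fl <- flow_at(t_new)
    stopifnot(inherits(fl, "tf_flow"))
    if (is.na(last_speed) || fl$speed != last_speed) {
      # matrix changes only when the flow level changes; otherwise just
      # refresh the mass contribution to the right-hand side
      sys <- assemble_system(grid, materials, ambient, fl, actuator_power,
                             dt = dt, T_old = Tcur)
      last_speed <- fl$speed
    }
    b <- sys$b0 + sys$mass * as.vector(Tcur)
    sol <- .bicgstab_ilu0(sys$n, sys$i - 1L, sys$j - 1L, sys$x, b,
                          as.vector(Tcur), tol = tol, maxit = 4000L)
    if (any(!is.finite(sol$x)))
      stop(sprintf("transient solve diverged at t = %.3g s", t_new), call. = FALSE)
    Tcur <- array(sol$x, dim = c(grid$nx, grid$ny, grid$nz))
    if (s %% keep_every == 0L || s == nsteps) {
      times <- c(times, t_new)
      fields[[length(fields) + 1L]] <-
        structure(list(temperature = Tcur, grid = grid, steady = FALSE,
                       relres = sol$relres, iterations = sol$iter,
                       time = t_new),
                  class = "thermal_field")
    }
  }
  list(times = times, fields = fields)
}

#' @export
print.thermal_field <- function(x, ...) {
  cat(sprintf("<thermal_field> %s, T in [%.3f, %.3f] C, relres %.2g\n",
              if (isTRUE(x$steady)) "steady" else sprintf("t = %.3g s", x$time),
              min(x$temperature), max(x$temperature), x$relres))
  invisible(x)
}
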