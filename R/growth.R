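#' Initialize the dome-shaped phase field
#'
#' The initial tissue is a cylinder of radius `R` and height `Hz` capped by a
#' hemisphere of the same radius, centred on the grid's z axis. The phase
#' field is the equilibrium interface profile
#' `phi = tanh(d / (sqrt(2) eps))` of the signed distance `d` to that surface
#' (positive inside), so `phi -> +1` deep inside and `-1` far outside and the
#' zero level set lies on the analytic surface to sub-voxel accuracy.
#'
#' @param grid a [grid_spec()].
#' @param p a [mech_params()] (supplies `R`, `Hz`, `eps`).
#' @return A `scalar_field3d` phase field.
#' @export
initialize_domain <- function(grid, p) {
  cx <- grid$nx * grid$dx / 2
  cy <- grid$ny * grid$dx / 2
  clear <- 5 * grid$dx
  if (p$R + clear > min(cx, cy) || p$Hz + p$R + clear > grid$nz * grid$dx)
    stop("dome does not fit in the grid with 5-voxel clearance")
  scalar_field(function(x, y, z) {
    rho <- sqrt((x - cx)^2 + (y - cy)^2)
    dist <- ifelse(z >= p$Hz,
                   sqrt(rho^2 + (z - p$Hz)^2),  # distance to cap centre
                   rho)                         # lateral distance to the axis
    tanh((p$R - dist) / (sqrt(2) * p$eps))
  }, grid)
}

#' Reset the interface profile to its equilibrium width
#'
#' The printed free energy favours steep phase-field gradients (its tension
#' terms enter with negative sign), so the interface slowly compresses below
#' the width `eps` it was initialized with; left alone this starves every
#' interface-localized coupling (the `1 - phi^2` factors) and stiffens the
#' explicit scheme. This level-set-style maintenance step rebuilds the local
#' tanh profile at width `eps` from the current zero level set, which is
#' preserved: within the band each voxel's signed distance to the surface is
#' estimated from the local profile (`d = atanh(phi) (1 - phi^2) / |grad
#' phi|`) and re-mapped through `tanh(d / (sqrt(2) eps))`; outside the band
#' the bulk values are clamped to -1/+1. The scheduler can apply it every
#' `reinit_every` cycles; it is off by default because clamping the interior
#' also discards the accumulated mass that feeds tip growth (the fixed-width
#' chemistry shell of [interface_indicator()] makes routine re-profiling
#' unnecessary).
#'
#' @param phi a [scalar_field()] phase field.
#' @param p a [mech_params()] (target width `eps`).
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @param band only voxels with `|phi| < band` are re-profiled.
#' @return The re-profiled `scalar_field3d`.
#' @export
reinit_interface <- function(phi, p, grid = NULL, band = 0.99) {
  g <- field_grid(phi, grid)
  gp <- cpp_gradient(as.double(phi), grid_dim(g), g$dx)
  n <- prod(grid_dim(g))
  gm <- sqrt(gp[seq_len(n)]^2 + gp[n + seq_len(n)]^2 + gp[2 * n + seq_len(n)]^2)
  v <- as.double(phi)
  inb <- abs(v) < band & gm > 1e-8
  d <- atanh(v[inb]) * (1 - v[inb]^2) / gm[inb]
  out <- sign(v)
  out[v == 0] <- 0
  out[inb] <- tanh(d / (sqrt(2) * p$eps))
  rewrap(array(out, grid_dim(g)), g)
}

#' Summit height of the dome
#'
#' The apex height: the interpolated zero crossing of the phase field along
#' the central axis column (sub-voxel, by linear interpolation of the
#' axis-averaged profile).
#'
#' @param phi a [scalar_field()] phase field.
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @return Apex height (physical units).
#' @export
summit_height <- function(phi, grid = NULL) {
  g <- field_grid(phi, grid)
  ic <- floor(g$nx / 2) + c(0L, 1L)
  jc <- floor(g$ny / 2) + c(0L, 1L)
  ic <- ic[ic >= 1 & ic <= g$nx]
  jc <- jc[jc >= 1 & jc <= g$ny]
  prof <- apply(phi[ic, jc, , drop = FALSE], 3, mean)
  zs <- (seq_len(g$nz) - 0.5) * g$dx
  inside <- which(prof >= 0)
  if (!length(inside)) return(0)
  k <- max(inside)
  if (k == g$nz) return(zs[k])
  # linear interpolation of the + -> - crossing
  zs[k] + g$dx * prof[k] / (prof[k] - prof[k + 1])
}

#' Mass-addition source
#'
#' `alpha[u] = m u^2` pointwise: the morphogen adds tissue mass wherever it is
#' present, turning pure deformation into growth.
#'
#' @param u a [scalar_field()].
#' @param p a [mech_params()].
#' @return A `scalar_field3d`.
#' @export
mass_source <- function(u, p) {
  g <- field_grid(u)
  rewrap(as.array(p$m * u^2), g)
}

#' Tip-growth Gaussian source
#'
#' An isotropic Gaussian of standard deviation `g_width` and constant
#' amplitude `tip_gain`, centred on the dome axis at a height that tracks the
#' summit as the dome grows, so the distance from the source to the apex
#' stays constant (one dome radius below it). This emulates the elevated
#' mitotic activity under the apex that produces the characteristic tip
#' growth; without it only stationary symmetric patterns form.
#'
#' @param state a simulation state (list with `phi` and optionally
#'   `summit_z0`), or a bare phase field.
#' @param p a [mech_params()].
#' @param grid the [grid_spec()]; defaults to the grid attached to the field.
#' @return A `scalar_field3d` source.
#' @export
tip_gaussian <- function(state, p, grid = NULL) {
  phi <- if (is.list(state)) state$phi else state
  g <- field_grid(phi, grid)
  summit <- summit_height(phi, g)
  amp <- p$tip_gain
  cx <- g$nx * g$dx / 2
  cy <- g$ny * g$dx / 2
  cz <- summit - p$R
  w2 <- 2 * p$g_width^2
  scalar_field(function(x, y, z) {
    amp * exp(-((x - cx)^2 + (y - cy)^2 + (z - cz)^2) / w2)
  }, g)
}

#' Source fields of the fixed primordia
#'
#' Once a primordium is fixed it becomes a relative source of morphogen (young
#' primordia synthesize auxin) and of tissue mass. The sources are constant
#' (`s_u`, `s_phi`) inside balls of radius `r_p` around each fixed primordium
#' and zero elsewhere; overlapping balls take the pointwise maximum rather
#' than the sum, so close primordia do not double-add.
#'
#' @param state a simulation state (list with `primordia`, a data frame with
#'   columns `x`, `y`, `z`), or such a data frame.
#' @param p a [mech_params()].
#' @param grid a [grid_spec()] (required if `state` carries no field).
#' @return A list with `s_phi` and `s_u` scalar fields.
#' @export
apply_primordium_sources <- function(state, p, grid = NULL) {
  prim <- if (is.data.frame(state)) state else state$primordia
  g <- if (!is.null(grid)) grid else field_grid(state$phi)
  dm <- grid_dim(g)
  mask <- array(0, dm)
  if (!is.null(prim) && nrow(prim) > 0) {
    cc <- grid_coords(g)
    for (q in seq_len(nrow(prim))) {
      ir <- which(abs(cc$x - prim$x[q]) <= p$r_p)
      jr <- which(abs(cc$y - prim$y[q]) <= p$r_p)
      kr <- which(abs(cc$z - prim$z[q]) <= p$r_p)
      for (k in kr) for (j in jr) {
        d2 <- (cc$x[ir] - prim$x[q])^2 + (cc$y[j] - prim$y[q])^2 + (cc$z[k] - prim$z[q])^2
        hit <- ir[d2 <= p$r_p^2]
        mask[hit, j, k] <- 1  # max, not sum
      }
    }
  }
  list(s_phi = rewrap(mask * p$s_phi, g),
       s_u = rewrap(mask * p$s_u, g))
}

#' One block of mechanical (phase-field) steps
#'
#' Explicit Euler integration of the coupled master equations
#' \deqn{\partial_t\phi = D_\phi \nabla^2(\delta F/\delta\phi) + m u^2
#'   + \kappa m G + s_\phi}
#' \deqn{\partial_t u = \gamma \nabla\cdot(\sigma \nabla(\delta F/\delta u))
#'   + G + s_u}
#' at time step `dt_mech`. The second morphogen `v` is untouched (the
#' mechanical model contains no `v`). The symmetrized stress tensor is
#' recomputed every `stress_every` steps; it varies on the slow time scale.
#' With all sources off (`m = 0`, `G = 0`, no primordia) both equations are
#' pure divergences, so the grid sums of `phi` and `u` are conserved to
#' floating tolerance.
#'
#' @param state list with scalar fields `phi` and `u` (and optionally
#'   `summit_z0`, `primordia`).
#' @param p a [mech_params()].
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @param nsteps number of Euler steps.
#' @param stress_every recompute cadence of the stress tensor (steps).
#' @param G tip-growth source field; `NULL` computes [tip_gaussian()], or pass
#'   `FALSE`/a zero field to disable.
#' @return The state list with updated `phi` and `u`.
#' @export
mech_step <- function(state, p, grid = NULL, nsteps = 1L, stress_every = 10L,
                      G = NULL) {
  g <- field_grid(state$phi, grid)
  dm <- grid_dim(g)
  if (is.null(G)) G <- tip_gaussian(state, p, g)
  if (isFALSE(G)) G <- array(0, dm)
  src <- apply_primordium_sources(state, p, g)
  out <- cpp_mech_run(as.double(state$phi), as.double(state$u), dm, g$dx,
                      p$eps, p$beta, p$gamma, p$m, p$kappa,
                      p$D_phi, p$rho_phi, p$rho_u,
                      as.double(G), as.double(src$s_phi), as.double(src$s_u),
                      g$dt_mech, as.integer(nsteps), as.integer(stress_every))
  state$phi <- rewrap(out$phi, g)
  state$u <- rewrap(out$u, g)
  state
}

#' Run the coupled mechanochemical simulation
#'
#' The two-time-scale scheduler. The phase field starts as the
#' cylinder-plus-hemisphere dome and the morphogens as a seeded uniform random
#' perturbation of the homogeneous state. The chemistry is first equilibrated
#' for `n_chem_init` reaction-diffusion steps (the Turing pattern is the input
#' of the mechanical model); then each outer cycle runs `n_chem` chemical
#' steps at `dt_chem` (the Turing "pulse") followed by `n_mech` mechanical
#' steps at `dt_mech`, after which primordia are detected on the extracted
#' surface and fixed once persistent. The outer-cycle counter is the
#' trajectory's time axis `T`.
#'
#' @param config a [run_config()].
#' @param quiet suppress the per-cycle log line.
#' @param resume_from a state saved by [save_snapshot()] (or a `phyllo_sim`):
#'   the run continues from that cycle boundary instead of initializing.
#'   Because all randomness enters through the initial fields, a resumed run
#'   is bit-identical to the uninterrupted one.
#' @return An object of class `phyllo_sim`: a list with the final fields
#'   (`phi`, `u`, `v`), the fixed `primordia` (data frame), the per-cycle
#'   `log` (data frame with `T`, free energy `F`, `sum_phi`, `sum_u`,
#'   `summit_z`, primordium and candidate counts), snapshots (if requested)
#'   and the `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(eta = 0.3902, seed = 1, max_cycles = 5)
#' sim <- run_simulation(cfg, quiet = TRUE)
#' summary(sim)
#' }
#' @export
run_simulation <- function(config, quiet = FALSE, resume_from = NULL) {
  stopifnot(inherits(config, "phyllo_config"))
  g <- config$grid
  bp <- config$bvam
  mp <- config$mech
  sc <- config$sched
  dm <- grid_dim(g)

  # seeded initial perturbation; RNG state restored on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  phi <- initialize_domain(g, mp)
  shell_w <- config$chem_shell_width %||% 3
  chem_mask <- switch(config$chem_domain,
                      shell = function(phi) interface_indicator(phi, eps = shell_w, grid = g),
                      tissue = domain_indicator,
                      box = function(phi) NULL)
  chi <- chem_mask(phi)
  # seeded perturbation of the homogeneous state, confined to the chemical
  # domain
  amp <- config$init_amp
  noise_w <- if (is.null(chi)) 1 else chi
  u <- rewrap(array(runif(prod(dm), -amp, amp), dm) * noise_w, g)
  v <- rewrap(array(runif(prod(dm), -amp, amp), dm) * noise_w, g)

  # active z-window: all dynamics is confined to the layers the tissue (and
  # its interface tail) occupies; above it every field is uniform and the
  # crop face reproduces that exactly under the Neumann closure
  active_k <- function(phi) {
    occ <- which(apply(phi > -1 + 1e-4, 3, any))
    min(g$nz, max(8L, (if (length(occ)) max(occ) else 8L) + 3L))
  }
  sub_grid <- function(kc) grid_spec(g$nx, g$ny, kc, g$dx, g$dt_chem, g$dt_mech)

  chem_pulse <- function(u, v, phi, nsteps) {
    chi <- chem_mask(phi)
    kc <- active_k(phi)
    gs <- sub_grid(kc)
    idx <- seq_len(kc)
    ch <- bvam_step(rewrap(u[, , idx, drop = FALSE], gs),
                    rewrap(v[, , idx, drop = FALSE], gs),
                    bp, dt = g$dt_chem, nsteps = nsteps, grid = gs,
                    chi = if (is.null(chi)) NULL else chi[, , idx, drop = FALSE])
    u[, , idx] <- ch$u
    v[, , idx] <- ch$v
    list(u = u, v = v)
  }

  if (is.null(resume_from)) {
    if (sc$n_chem_init > 0) {
      ch <- chem_pulse(u, v, phi, sc$n_chem_init)
      u <- ch$u; v <- ch$v
    }
    state <- list(phi = phi, u = u, v = v,
                  summit_z0 = summit_height(phi, g),
                  primordia = empty_primordia(),
                  T = 0L)
    tracker <- list()   # candidate persistence tracker
    T_start <- 1L
  } else {
    state <- list(phi = resume_from$phi, u = resume_from$u, v = resume_from$v,
                  summit_z0 = resume_from$summit_z0 %||% summit_height(resume_from$phi, g),
                  primordia = resume_from$primordia %||% empty_primordia(),
                  T = resume_from$T %||% 0L)
    tracker <- resume_from$tracker %||% list()
    T_start <- state$T + 1L
  }
  log_rows <- vector("list", sc$max_cycles)
  snapshots <- list()
  first_fix_T <- if (nrow(state$primordia)) min(state$primordia$birth_T) else NA_integer_

  for (T in seq_len(sc$max_cycles)) {
    if (T < T_start) next
    ch <- chem_pulse(state$u, state$v, state$phi, sc$n_chem)
    state$u <- ch$u; state$v <- ch$v

    kc <- active_k(state$phi)
    gs <- sub_grid(kc)
    idx <- seq_len(kc)
    G <- tip_gaussian(state, mp, g)
    src <- apply_primordium_sources(state, mp, g)
    out <- cpp_mech_run(as.double(state$phi[, , idx]), as.double(state$u[, , idx]),
                        grid_dim(gs), g$dx,
                        mp$eps, mp$beta, mp$gamma, mp$m, mp$kappa,
                        mp$D_phi, mp$rho_phi, mp$rho_u,
                        as.double(G[, , idx]), as.double(src$s_phi[, , idx]),
                        as.double(src$s_u[, , idx]),
                        g$dt_mech, sc$n_mech, sc$stress_every)
    state$phi[, , idx] <- out$phi
    state$u[, , idx] <- out$u
    state$T <- T

    if (sc$reinit_every > 0 && T %% sc$reinit_every == 0)
      state$phi <- reinit_interface(state$phi, mp, g)

    det <- detect_and_fix(state, mp, g, tracker, tau = sc$tau,
                          gen_window = sc$gen_window,
                          u_abs_min = sc$u_abs_min,
                          floor_margin = sc$floor_margin)
    tracker <- det$tracker
    state$primordia <- det$primordia
    if (is.na(first_fix_T) && nrow(state$primordia) > 0) first_fix_T <- T

    en <- free_energy(state$phi, state$u, mp, g)
    summit <- summit_height(state$phi, g)
    log_rows[[T]] <- data.frame(
      T = T, F = en$F,
      sum_phi = sum(state$phi) * g$dx^3,
      sum_u = sum(state$u) * g$dx^3,
      summit_z = summit,
      n_primordia = nrow(state$primordia),
      n_candidates = det$n_candidates)
    if (!quiet)
      message(sprintf(
        "T=%4d  F=%12.4f  sum_phi=%10.2f  sum_u=%8.3f  summit=%6.2f  primordia=%d",
        T, en$F, sum(state$phi) * g$dx^3, sum(state$u) * g$dx^3,
        summit, nrow(state$primordia)))

    if (is.finite(sc$snapshot_every) && T %% sc$snapshot_every == 0)
      snapshots[[as.character(T)]] <- list(phi = state$phi, u = state$u,
                                           v = state$v, T = T,
                                           primordia = state$primordia,
                                           tracker = tracker,
                                           summit_z0 = state$summit_z0)
    if (sc$stop_after_first_gen && !is.na(first_fix_T) &&
        T >= first_fix_T + sc$post_fix_cycles) break
  }

  structure(list(
    phi = state$phi, u = state$u, v = state$v,
    primordia = state$primordia,
    log = do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]),
    snapshots = snapshots,
    summit_z0 = state$summit_z0,
    T = state$T,
    first_fix_T = first_fix_T,
    tracker = tracker,
    config = config), class = "phyllo_sim")
}

empty_primordia <- function() {
  data.frame(x = numeric(), y = numeric(), z = numeric(),
             birth_T = integer(), angle = numeric(), generation = integer(),
             z_extent = numeric(), arc_extent = numeric())
}

#' @export
print.phyllo_sim <- function(x, ...) {
  cat(sprintf("<phyllo_sim> %d cycles, %d fixed primordia, summit %.2f -> %.2f\n",
              x$T, nrow(x$primordia), x$summit_z0,
              if (nrow(x$log)) tail(x$log$summit_z, 1) else x$summit_z0))
  if (nrow(x$primordia)) {
    for (gen in sort(unique(x$primordia$generation))) {
      sub <- x$primordia[x$primordia$generation == gen, ]
      cat(sprintf("  generation %d: %d primordia, born T = %s, angles %s deg\n",
                  gen, nrow(sub),
                  paste(range(sub$birth_T), collapse = "-"),
                  paste(round(sort(sub$angle) * 180 / pi), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
summary.phyllo_sim <- function(object, ...) {
  print(object)
  call <- classify_pattern(object)
  cat("pattern call: ")
  print(call)
  invisible(call)
}

#' Plot simulation diagnostics
#'
#' Four base-graphics panels: free energy, summit height, total phase-field
#' mass, and the angular positions of the fixed primordia by generation.
#'
#' @param x a `phyllo_sim`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phyllo_sim <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$T, lg$F, type = "l", xlab = "T", ylab = "free energy F", ...)
  graphics::plot(lg$T, lg$summit_z, type = "l", xlab = "T", ylab = "summit height", ...)
  graphics::plot(lg$T, lg$sum_phi, type = "l", xlab = "T",
                 ylab = expression(Sigma * phi %.% dx^3), ...)
  if (nrow(x$primordia)) {
    graphics::plot(x$primordia$angle * 180 / pi, x$primordia$birth_T,
                   pch = 19, col = x$primordia$generation,
                   xlab = "azimuth (deg)", ylab = "birth T", xlim = c(0, 360))
  } else {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no fixed primordia")
  }
  invisible(x)
}
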