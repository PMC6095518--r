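#' Build a full run configuration
#'
#' Bundles the grid, the reaction-diffusion and mechanical parameter sets, and
#' the two-time-scale scheduler knobs into a single validated configuration.
#' Every default equals the model's reference value where one exists; `eta`
#' has no meaningful default and must always be supplied.
#'
#' @param eta BVAM scaling parameter (pattern-symmetry selector); required.
#' @param seed integer random seed for the initial morphogen perturbation.
#' @param c BVAM cross-kinetics coefficient (stripes at 0, spots near 0.57);
#'   a named formal so it is never partially matched against the
#'   `chem_domain`/`chem_shell_width` arguments.
#' @param grid a [grid_spec()].
#' @param bvam a [bvam_params()]; built from `eta` and `...` overrides if
#'   omitted.
#' @param mech a [mech_params()].
#' @param n_chem_init chemical equilibration steps before the first cycle
#'   (the Turing pattern is the mechanical model's input).
#' @param n_chem chemical steps per outer cycle (the Turing pulse).
#' @param n_mech mechanical steps per outer cycle.
#' @param max_cycles outer-cycle horizon.
#' @param stress_every stress-tensor recompute cadence (mechanical steps).
#' @param snapshot_every record full field snapshots every this many cycles
#'   (`Inf` disables).
#' @param reinit_every re-profile the interface to its equilibrium width every
#'   this many cycles (see [reinit_interface()]); 0 disables.
#' @param u_abs_min absolute morphogen floor for primordium detection (see
#'   [detect_primordia()]).
#' @param floor_margin height above the box floor below which detection is
#'   ignored (box-rim artifact guard).
#' @param tau candidate persistence (cycles) required to fix a primordium.
#' @param gen_window birth window (cycles) within which new primordia join the
#'   current generation.
#' @param stop_after_first_gen stop `post_fix_cycles` cycles after the first
#'   fixation (desk-scale runs to first-generation fixation).
#' @param post_fix_cycles see `stop_after_first_gen`.
#' @param init_amp amplitude of the seeded uniform perturbation of `(u, v)`.
#' @param chem_domain where the reaction-diffusion dynamics lives:
#'   `"shell"` (default) confines it to a surface shell with the
#'   [interface_indicator()] weight — the zero-flux-on-the-surface reading
#'   under which the spherical-harmonic mode selection applies; `"tissue"`
#'   confines it to the whole tissue interior ([domain_indicator()]);
#'   `"box"` runs it unmasked in the full box.
#' @param chem_shell_width width parameter of the chemistry shell (the
#'   indicator is `sech^2(d / (sqrt(2) chem_shell_width))` in the signed
#'   distance `d` to the surface). Thin enough that the pattern lives on the
#'   surface (much smaller than the pattern wavelength), thick enough that
#'   the pattern survives the interface's slow outward motion.
#' @param out_dir optional output directory recorded in the config.
#' @param ... overrides passed to [bvam_params()] (e.g. `c = 0`) when `bvam`
#'   is not supplied.
#' @return An object of class `phyllo_config`.
#' @examples
#' cfg <- run_config(eta = 0.3902, seed = 1)
#' @export
run_config <- function(eta, seed = 1L, c = NULL, grid = grid_spec(),
                       bvam = NULL, mech = mech_params(),
                       n_chem_init = 60000L, n_chem = 100L, n_mech = 250L,
                       max_cycles = 60L, stress_every = 10L,
                       snapshot_every = Inf, reinit_every = 0L,
                       u_abs_min = 0.25, floor_margin = 2,
                       tau = 5L, gen_window = 15L,
                       stop_after_first_gen = FALSE, post_fix_cycles = 5L,
                       init_amp = 0.1,
                       chem_domain = c("shell", "tissue", "box"),
                       chem_shell_width = 3, out_dir = NULL, ...) {
  chem_domain <- match.arg(chem_domain)
  if (is.null(bvam)) {
    bvam <- if (is.null(c)) bvam_params(eta = eta, ...)
            else bvam_params(eta = eta, c = c, ...)
  }
  stopifnot(inherits(grid, "grid_spec"), inherits(bvam, "bvam_params"),
            inherits(mech, "mech_params"))
  sched <- list(n_chem_init = as.integer(n_chem_init),
                n_chem = as.integer(n_chem), n_mech = as.integer(n_mech),
                max_cycles = as.integer(max_cycles),
                stress_every = as.integer(stress_every),
                snapshot_every = snapshot_every,
                reinit_every = as.integer(reinit_every),
                u_abs_min = u_abs_min, floor_margin = floor_margin,
                tau = as.integer(tau), gen_window = as.integer(gen_window),
                stop_after_first_gen = isTRUE(stop_after_first_gen),
                post_fix_cycles = as.integer(post_fix_cycles))
  if (any(vapply(sched[c("n_chem", "n_mech", "max_cycles", "stress_every", "tau")],
                 function(x) x < 1L, logical(1))))
    stop("scheduler counts must be >= 1")
  structure(list(grid = grid, bvam = bvam, mech = mech, sched = sched,
                 seed = as.integer(seed), init_amp = init_amp,
                 chem_domain = chem_domain,
                 chem_shell_width = chem_shell_width, out_dir = out_dir),
            class = "phyllo_config")
}

#' @export
print.phyllo_config <- function(x, ...) {
  cat("<phyllo_config>\n")
  print(x$grid)
  print(x$bvam)
  print(x$mech)
  s <- x$sched
  cat(sprintf("  scheduler: %d init chem steps; per cycle %d chem + %d mech; %d cycles max\n",
              s$n_chem_init, s$n_chem, s$n_mech, s$max_cycles))
  cat(sprintf("  seed = %d, init_amp = %g\n", x$seed, x$init_amp))
  invisible(x)
}

config_known_keys <- function() {
  list(grid = names(formals(grid_spec)),
       bvam = c("a", "b", "c", "h", "D", "eta"),
       mech = names(formals(mech_params)),
       sched = c("n_chem_init", "n_chem", "n_mech", "max_cycles",
                 "stress_every", "snapshot_every", "reinit_every",
                 "u_abs_min", "floor_margin", "tau", "gen_window",
                 "stop_after_first_gen", "post_fix_cycles"),
       top = c("seed", "init_amp", "chem_domain", "chem_shell_width",
               "out_dir"))
}

#' Save or load a run configuration (YAML)
#'
#' The configuration round-trips losslessly through a human-readable YAML
#' file with sections `grid`, `bvam`, `mech`, `sched` plus top-level `seed`,
#' `init_amp` and `out_dir`. On loading, unknown keys and out-of-range values
#' are rejected by name; missing keys take their defaults (`eta` must still
#' be supplied).
#'
#' @param config a `phyllo_config`.
#' @param path file path.
#' @return `load_config()` returns a `phyllo_config`; `save_config()` returns
#'   `path` invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "phyllo_config"))
  obj <- list(grid = unclass(config$grid),
              bvam = unclass(config$bvam),
              mech = unclass(config$mech),
              sched = lapply(config$sched, function(v)
                if (is.infinite(v)) ".inf" else v),
              seed = config$seed, init_amp = config$init_amp,
              chem_domain = config$chem_domain,
              chem_shell_width = config$chem_shell_width,
              out_dir = config$out_dir)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- config_known_keys()
  bad_top <- setdiff(names(raw), c(names(known)[names(known) != "top"], known$top))
  if (length(bad_top))
    stop("unknown configuration keys: ", paste(bad_top, collapse = ", "))
  for (sec in c("grid", "bvam", "mech", "sched")) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(raw$bvam$eta))
    stop("'eta' must be supplied in the bvam section (no printed default)")
  grid <- do.call(grid_spec, raw$grid %||% list())
  bvam <- do.call(bvam_params, raw$bvam)
  mech <- do.call(mech_params, raw$mech %||% list())
  sched <- raw$sched %||% list()
  if (!is.null(sched$snapshot_every) && identical(sched$snapshot_every, ".inf"))
    sched$snapshot_every <- Inf
  args <- c(list(eta = bvam$eta, grid = grid, bvam = bvam, mech = mech),
            sched)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$init_amp)) args$init_amp <- raw$init_amp
  if (!is.null(raw$chem_domain)) args$chem_domain <- raw$chem_domain
  if (!is.null(raw$chem_shell_width)) args$chem_shell_width <- raw$chem_shell_width
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
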