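# Blockwise excursion sampling (BES).
#
# A conformer library is grown by independent "excursion chains", each an
# alternation of a simulated-annealing (SA) block -- which carries the chain
# over barriers from a high maximum temperature down to the base temperature
# -- and a constant-temperature relaxation block, whose tail yields one
# representative structure (the frame closest to the superposed window mean,
# then conjugate-gradient minimised). Dynamics are overdamped Langevin by
# default with a Metropolis fallback, defined over any energy model that
# supplies energy/gradient.

#' Configuration for excursion sampling
#'
#' Defaults follow the study design for a disordered 42-mer: 2000 chains of 5
#' blocks, SA maximum temperatures 700/600/500/400/350 K, relaxation blocks of
#' 120 steps with the last 100 used for representative extraction (the 5/6
#' window ratio mapping a 120 ps block with a 100 ps analysis tail onto step
#' units).
#'
#' @param n_chains number of independent excursion chains.
#' @param blocks_per_chain SA+relaxation blocks per chain.
#' @param sa_max_temperatures K, one per block.
#' @param sa_duration_steps steps per SA block.
#' @param relax_duration_steps steps per relaxation block.
#' @param representative_window_steps tail of the relaxation block (in
#'   recorded frames at `stride` = 1) used for the window mean.
#' @param base_temperature K, the constant relaxation temperature and the SA
#'   end point.
#' @param timestep integrator step, model units.
#' @param friction Langevin friction coefficient.
#' @param stride record every `stride`-th relaxation step.
#' @param dynamics `"langevin"` (overdamped) or `"metropolis"`.
#' @param schedule SA cooling functional form, `"linear"` or `"exponential"`.
#' @param minimize_maxit iteration cap for the conjugate-gradient minimiser.
#' @param seed master seed; per-chain and per-block seeds are derived from it
#'   (see [derive_seed()]) and recorded in the manifest.
#' @return list of class `excursion_config`.
#' @export
excursion_config <- function(n_chains = 2000L,
                             blocks_per_chain = 5L,
                             sa_max_temperatures = c(700, 600, 500, 400, 350),
                             sa_duration_steps = 120L,
                             relax_duration_steps = 120L,
                             representative_window_steps = 100L,
                             base_temperature = 310,
                             timestep = 0.01,
                             friction = 1,
                             stride = 1L,
                             dynamics = c("langevin", "metropolis"),
                             schedule = c("linear", "exponential"),
                             minimize_maxit = 50L,
                             seed = 1L) {
  dynamics <- match.arg(dynamics)
  schedule <- match.arg(schedule)
  stopifnot(n_chains >= 1L, blocks_per_chain >= 1L,
            relax_duration_steps >= 1L, sa_duration_steps >= 1L,
            representative_window_steps >= 1L,
            base_temperature > 0, timestep > 0, friction > 0, stride >= 1L)
  if (length(sa_max_temperatures) != blocks_per_chain)
    stop("need one SA maximum temperature per block (",
         blocks_per_chain, " blocks, ", length(sa_max_temperatures),
         " temperatures)")
  if (representative_window_steps > floor(relax_duration_steps / stride))
    stop("representative window exceeds the number of recorded frames")
  if (any(sa_max_temperatures <= base_temperature))
    stop("SA maximum temperatures must exceed the base temperature")
  structure(list(n_chains = as.integer(n_chains),
                 blocks_per_chain = as.integer(blocks_per_chain),
                 sa_max_temperatures = sa_max_temperatures,
                 sa_duration_steps = as.integer(sa_duration_steps),
                 relax_duration_steps = as.integer(relax_duration_steps),
                 representative_window_steps =
                   as.integer(representative_window_steps),
                 base_temperature = base_temperature,
                 timestep = timestep, friction = friction,
                 stride = as.integer(stride), dynamics = dynamics,
                 schedule = schedule,
                 minimize_maxit = as.integer(minimize_maxit),
                 seed = as.integer(seed)),
            class = "excursion_config")
}

#' Derive a stream seed from a master seed and an index
#'
#' Linear-congruential mix kept below 2^31 so it is always a valid R seed;
#' recorded per chain in the library manifest for reproducibility.
#'
#' @param seed master seed.
#' @param index stream index (chain or block number).
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1103515245 +
                12345) %% 2147483647)
}

# One dynamics sweep at the per-step temperatures in `temps`.
# Returns final coordinates and, if record_stride > 0, recorded frames.
run_dynamics <- function(xyz, model, temps, config, seed, record_stride = 0L) {
  set.seed(seed)
  dt <- config$timestep; gam <- config$friction
  n <- nrow(xyz)
  frames <- if (record_stride > 0L)
    vector("list", floor(length(temps) / record_stride)) else NULL
  energies <- if (record_stride > 0L) numeric(length(frames)) else NULL
  k <- 0L
  if (config$dynamics == "langevin") {
    for (s in seq_along(temps)) {
      g <- model$gradient(xyz)
      if (any(!is.finite(g)))
        stop("energy model produced a non-finite gradient at step ", s,
             " (T = ", temps[s], " K)")
      noise <- sqrt(2 * .kB * temps[s] * dt / gam)
      xyz <- xyz - (dt / gam) * g +
        noise * matrix(stats::rnorm(3L * n), n, 3L)
      if (record_stride > 0L && s %% record_stride == 0L) {
        k <- k + 1L
        frames[[k]] <- xyz
        energies[k] <- model$energy(xyz)
      }
    }
  } else {
    e <- model$energy(xyz)
    step_sd <- 0.3
    for (s in seq_along(temps)) {
      cand <- xyz + step_sd * matrix(stats::rnorm(3L * n), n, 3L)
      ec <- model$energy(cand)
      if (!is.finite(ec)) stop("energy model produced a non-finite energy")
      if (ec <= e || stats::runif(1) < exp(-(ec - e) / (.kB * temps[s]))) {
        xyz <- cand; e <- ec
      }
      if (record_stride > 0L && s %% record_stride == 0L) {
        k <- k + 1L
        frames[[k]] <- xyz
        energies[k] <- e
      }
    }
  }
  ef <- model$energy(xyz)
  if (!is.finite(ef)) stop("energy model produced a non-finite energy")
  list(xyz = xyz, frames = frames, energies = energies, final_energy = ef)
}

sa_temperature_ladder <- function(t_max, t_base, steps, schedule) {
  if (schedule == "linear") {
    seq(t_max, t_base, length.out = steps)
  } else {
    t_base * (t_max / t_base)^(seq(steps - 1, 0) / max(steps - 1, 1))
  }
}

#' Run one simulated-annealing block
#'
#' Anneals from `t_max` down the cooling schedule to the base temperature and
#' returns the final configuration. Deterministic given `seed`.
#'
#' @param start `ens_structure`.
#' @param model energy model.
#' @param t_max maximum temperature, K (> base temperature).
#' @param config `excursion_config` (supplies schedule, step count, timestep,
#'   base temperature).
#' @param seed integer.
#' @return `ens_structure` (final configuration).
#' @export
run_sa_block <- function(start, model, t_max, config, seed) {
  stopifnot(inherits(start, "ens_structure"), t_max > config$base_temperature)
  temps <- sa_temperature_ladder(t_max, config$base_temperature,
                                 config$sa_duration_steps, config$schedule)
  res <- run_dynamics(coords(start), model, temps, config, seed)
  set_coords(start, res$xyz)
}

#' Run one constant-temperature relaxation block
#'
#' @param start `ens_structure`.
#' @param model energy model.
#' @param config `excursion_config`.
#' @param seed integer.
#' @return `ens_trajectory` with frames recorded every `config$stride` steps
#'   and per-frame energies in attribute `"energies"`.
#' @export
run_relaxation_block <- function(start, model, config, seed) {
  stopifnot(inherits(start, "ens_structure"))
  temps <- rep(config$base_temperature, config$relax_duration_steps)
  res <- run_dynamics(coords(start), model, temps, config, seed,
                      record_stride = config$stride)
  traj <- ens_trajectory(start, res$frames, frame_interval = config$stride)
  attr(traj, "energies") <- res$energies
  traj
}

#' Select the representative structure of a relaxation block
#'
#' Over the last `window` recorded frames, each frame is Kabsch-superposed
#' onto the first window frame, the coordinate-mean structure is computed, and
#' the window frame with minimal RMSD to that mean (earliest frame on ties) is
#' conjugate-gradient minimised to give the representative.
#'
#' @param traj `ens_trajectory` (or list of `ens_structure`).
#' @param window number of tail frames to average over.
#' @param model energy model used for the minimisation.
#' @param minimize_maxit conjugate-gradient iteration cap.
#' @return list of class `representative_record` with fields `structure`,
#'   `frame_index` (within the trajectory), `rmsd_to_mean`,
#'   `minimized_energy`, `chain_index`, `block_index`.
#' @export
select_representative <- function(traj, window, model, minimize_maxit = 100L) {
  if (!inherits(traj, "ens_trajectory")) traj <- as_trajectory(traj)
  nf <- n_frames(traj)
  if (window < 1L) stop("empty representative window")
  if (window > nf) stop("window (", window, ") exceeds trajectory length (",
                        nf, ")")
  idx <- seq.int(nf - window + 1L, nf)
  ref <- traj$xyz[[idx[1L]]]
  fitted <- lapply(idx, function(i) kabsch_fit(traj$xyz[[i]], ref)$xyz)
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  rmsds <- vapply(fitted, rmsd_raw, numeric(1), b = mean_xyz)
  best <- which.min(rmsds)  # which.min takes the earliest on exact ties
  sel <- traj$xyz[[idx[best]]]
  opt <- stats::optim(as.vector(sel),
                      fn = function(p) model$energy(matrix(p, ncol = 3L)),
                      gr = function(p) as.vector(model$gradient(matrix(p, ncol = 3L))),
                      method = "CG",
                      control = list(maxit = minimize_maxit))
  structure(list(structure = set_coords(traj$template,
                                        matrix(opt$par, ncol = 3L)),
                 frame_index = idx[best],
                 rmsd_to_mean = rmsds[best],
                 minimized_energy = opt$value,
                 chain_index = NA_integer_, block_index = NA_integer_),
            class = "representative_record")
}

#' Run one excursion chain
#'
#' Alternates an SA block (block k at `sa_max_temperatures[k]`) with a
#' relaxation block; each relaxation block contributes exactly one
#' representative, and block k+1 starts from block k's minimised
#' representative.
#'
#' @param start `ens_structure` (the chain start, typically fully extended).
#' @param model energy model.
#' @param config `excursion_config`.
#' @param chain_index 1-based chain number (drives seed derivation).
#' @return list of `representative_record`, one per block.
#' @export
run_excursion_chain <- function(start, model, config, chain_index = 1L) {
  chain_seed <- derive_seed(config$seed, chain_index)
  current <- start
  records <- vector("list", config$blocks_per_chain)
  for (k in seq_len(config$blocks_per_chain)) {
    annealed <- run_sa_block(current, model, config$sa_max_temperatures[k],
                             config, seed = derive_seed(chain_seed, 2L * k - 1L))
    traj <- run_relaxation_block(annealed, model, config,
                                 seed = derive_seed(chain_seed, 2L * k))
    rec <- select_representative(traj, config$representative_window_steps,
                                 model, config$minimize_maxit)
    rec$chain_index <- as.integer(chain_index)
    rec$block_index <- k
    rec$structure$label <- sprintf("chain%04d_block%d", chain_index, k)
    records[[k]] <- rec
    current <- rec$structure
  }
  records
}

#' Build a conformer library by blockwise excursion sampling
#'
#' Runs `config$n_chains` independent excursion chains, all starting from the
#' supplied structure, and collects every block representative. Library size
#' is always `n_chains * blocks_per_chain`.
#'
#' @param model energy model.
#' @param config `excursion_config`.
#' @param start `ens_structure` every chain starts from.
#' @return object of class `bes_library`: `records` (list of
#'   `representative_record`) and `manifest` (data.frame with receptor label,
#'   chain, block, selected frame, RMSD to the window mean, minimised energy
#'   and chain seed).
#' @export
build_library <- function(model, config, start) {
  stopifnot(inherits(config, "excursion_config"))
  records <- vector("list", config$n_chains * config$blocks_per_chain)
  pos <- 0L
  for (ch in seq_len(config$n_chains)) {
    for (rec in run_excursion_chain(start, model, config, ch)) {
      pos <- pos + 1L
      records[[pos]] <- rec
    }
  }
  manifest <- data.frame(
    receptor_label = sprintf("receptor_%05d", seq_len(pos)),
    chain = vapply(records, `[[`, integer(1), "chain_index"),
    block = vapply(records, `[[`, integer(1), "block_index"),
    frame_index = vapply(records, `[[`, integer(1), "frame_index"),
    rmsd_to_mean = vapply(records, `[[`, numeric(1), "rmsd_to_mean"),
    minimized_energy = vapply(records, `[[`, numeric(1), "minimized_energy"),
    seed = vapply(seq_len(config$n_chains),
                  function(ch) derive_seed(config$seed, ch),
                  integer(1))[vapply(records, `[[`, integer(1), "chain_index")],
    stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest, config = config),
            class = "bes_library")
}

#' @export
print.bes_library <- function(x, ...) {
  cat(sprintf("<bes_library: %d representatives (%d chains x %d blocks)>\n",
              nrow(x$manifest), x$config$n_chains, x$config$blocks_per_chain))
  invisible(x)
}

#' Write a library to disk as numbered PDB files plus a TSV manifest
#'
#' The manifest is written with fixed numeric formatting so repeated runs with
#' the same seed are byte-identical.
#'
#' @param library `bes_library`.
#' @param dir output directory (created if needed).
#' @param write_structures also write one PDB per representative.
#' @return path to the manifest.
#' @export
write_library <- function(library, dir, write_structures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- library$manifest
  if (write_structures)
    for (i in seq_along(library$records))
      write_pdb(library$records[[i]]$structure,
                file.path(dir, paste0(man$receptor_label[i], ".pdb")))
  lines <- c(paste(names(man), collapse = "\t"),
             sprintf("%s\t%d\t%d\t%d\t%.6f\t%.6f\t%d",
                     man$receptor_label, man$chain, man$block,
                     man$frame_index, man$rmsd_to_mean,
                     man$minimized_energy, man$seed))
  manifest_path <- file.path(dir, "manifest.tsv")
  writeLines(lines, manifest_path)
  manifest_path
}
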