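# Trajectory and summary file I/O.
#
# Trajectories are stored as delimited text: "# key: value" metadata header
# lines (integrator, dt, stride, seed, potential, thermo state) followed by
# a TSV table with columns time, position and, for Langevin runs, velocity.
# Values are written with 17 significant digits so round-trips reproduce
# arrays to full double precision.

#' Write/read a trajectory as delimited text
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `write_trajectory_txt` returns the path invisibly;
#'   `read_trajectory_txt` returns a `trajectory`.
#' @export
write_trajectory_txt <- function(traj, path) {
  sp <- traj$params; pot <- traj$potential; th <- traj$thermo
  meta <- c(integrator = sp$integrator, dt = sp$dt, n_steps = sp$n_steps,
            stride = sp$stride, seed = sp$seed,
            initial_position = sp$initial_position,
            family = pot$family,
            domain_lo = pot$domain[1], domain_hi = pot$domain[2],
            kBT = th$kBT, D = th$D,
            mass = if (is.null(th$mass)) "NA" else th$mass)
  if (!is.null(pot$params))
    meta <- c(meta, setNames(unlist(pot$params),
                             paste0("pot_", names(pot$params))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), vapply(meta, function(v)
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v), "")), con)
  has_v <- !is.null(traj$velocities)
  writeLines(if (has_v) "time\tposition\tvelocity" else "time\tposition", con)
  if (has_v) {
    writeLines(sprintf("%.17g\t%.17g\t%.17g", traj$times, traj$positions,
                       traj$velocities), con)
  } else {
    writeLines(sprintf("%.17g\t%.17g", traj$times, traj$positions), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_txt
#' @export
read_trajectory_txt <- function(path) {
  lines <- readLines(path)
  mlines <- grep("^# ", lines, value = TRUE)
  if (!length(mlines)) stop("malformed trajectory file (no metadata header): ", path)
  kv <- regmatches(mlines, regexec("^# ([^:]+): (.*)$", mlines))
  if (any(lengths(kv) != 3)) stop("malformed metadata line in ", path)
  meta <- setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
  need <- c("integrator", "dt", "n_steps", "stride", "seed", "family",
            "domain_lo", "domain_hi", "kBT", "D")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("trajectory metadata missing: ", paste(miss, collapse = ", "))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time", "position") %in% names(df)))
    stop("malformed trajectory table (need time/position columns) in ", path)
  num <- function(k) as.numeric(meta[[k]])
  fam <- meta[["family"]]
  pot <- if (fam == "custom") {
    stop("custom potentials cannot be reconstructed from a trajectory file")
  } else {
    pk <- grep("^pot_", names(meta), value = TRUE)
    pars <- as.list(as.numeric(meta[pk]))
    names(pars) <- sub("^pot_", "", pk)
    potential_1d(fam, params = if (length(pars)) pars else NULL,
                 domain = c(num("domain_lo"), num("domain_hi")))
  }
  mass <- if (!"mass" %in% names(meta) || meta[["mass"]] == "NA") NULL else num("mass")
  th <- thermo_state(kBT = num("kBT"), D = num("D"), mass = mass)
  sp <- sim_params(meta[["integrator"]], dt = num("dt"), n_steps = num("n_steps"),
                   stride = num("stride"), seed = num("seed"),
                   initial_position = if ("initial_position" %in% names(meta))
                     num("initial_position") else df$position[1])
  n_expect <- floor(num("n_steps") / num("stride")) + 1
  if (nrow(df) != n_expect)
    stop(sprintf("truncated trajectory file %s: %d frames found, %d expected",
                 path, nrow(df), as.integer(n_expect)))
  structure(list(times = df$time, positions = df$position,
                 velocities = if ("velocity" %in% names(df)) df$velocity else NULL,
                 params = sp, potential = pot, thermo = th),
            class = "trajectory")
}

#' Write a two-state summary (or any flat record) as JSON
#'
#' @param x A `two_state_summary` or named list of scalars.
#' @param path File path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
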