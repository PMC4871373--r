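#' Read and write flat key-value parameter files
#'
#' Model parameters travel as flat text files with one `key = value` pair per
#' line (`#` comments allowed), keyed by the canonical parameter names of the
#' chosen model. Unknown keys are rejected, which catches typos against the
#' ~125-key namespace of the full model.
#'
#' @param path File path.
#' @param model "cellcycle", "start" or "multip" — selects the key namespace
#'   and default values for keys not present in the file.
#' @return Named numeric parameter vector.
#' @export
read_scm_config <- function(path, model = c("cellcycle", "start", "multip")) {
  model <- match.arg(model)
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  base <- switch(model, cellcycle = cellcycle_params(), start = start_params(),
                 multip = multip_params())
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(base)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad_fmt <- lengths(kv) != 2
  if (any(bad_fmt))
    abort(paste0("malformed line(s): ", paste(lines[bad_fmt], collapse = "; ")))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  unknown <- setdiff(keys, names(base))
  if (length(unknown) > 0)
    abort(paste0("unknown key(s) for the ", model, " parameter table: ",
                 paste(unknown, collapse = ", ")))
  if (any(is.na(vals)))
    abort(paste0("non-numeric value for key(s): ",
                 paste(keys[is.na(vals)], collapse = ", ")))
  neg <- keys[vals < 0]
  if (length(neg) > 0)
    abort(paste0("negative rate/weight not allowed for: ",
                 paste(neg, collapse = ", ")))
  base[keys] <- vals
  base
}

#' @rdname read_scm_config
#' @param params Named numeric vector to write.
#' @export
write_scm_config <- function(params, path) {
  writeLines(sprintf("%s = %.17g", names(params), unname(params)), path)
  invisible(path)
}

#' Write a trajectory as tab-separated text
#'
#' First column time (min), then volume, then the species in declared order;
#' header row mandatory.
#'
#' @param traj Trajectory tibble.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t"))
}

#' Generate the reference fixture set
#'
#' Produces small golden trajectories/records used by the regression tests:
#' (a) a 10-min deterministic Start-model trajectory, (b) a one-cycle
#' deterministic wild-type full-model trajectory, (c) stochastic cell records
#' at a fixed seed. Re-running with the same seed reproduces the fixtures
#' bit-exactly.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the stochastic records.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir = tempdir(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "start_10min.tsv")
  write_trajectory(simulate_start(tend = 10, record_dt = 1), p1)
  p2 <- file.path(dir, "cellcycle_1cycle.tsv")
  tr <- simulate_lineage(n_divisions = 1, record_traj = TRUE, record_dt = 1)
  write_trajectory(attr(tr, "trajectory"), p2)
  p3 <- file.path(dir, "stochastic_records.tsv")
  rec <- simulate_lineage(n_divisions = 20, stochastic = TRUE, seed = seed)
  write.table(as.data.frame(rec), p3, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2, p3))
}
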