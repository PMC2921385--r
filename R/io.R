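#' Read and write model states as delimited text
#'
#' Profiles, layouts, trajectories and branches are exchanged as plain
#' tab-separated text so they can be inspected, plotted, or re-imported
#' anywhere. Run metadata travels as JSON.
#'
#' @name io
NULL

#' @describeIn io Write a [profile1d()] as TSV (cell_index, a, PIN).
#' @param profile a [profile1d()].
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  utils::write.table(
    data.frame(cell_index = seq_len(profile$N), a = profile$a,
               PIN = profile$PIN),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io Read a profile written by [write_profile()].
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  profile1d(d$a, d$PIN)
}

#' @describeIn io Write a `trajectory1d` in long format
#'   (time, cell_index, a, PIN).
#' @param traj a `trajectory1d`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory1d"))
  N <- ncol(traj$a)
  d <- data.frame(
    time = rep(traj$times, each = N),
    cell_index = rep(seq_len(N), length(traj$times)),
    a = as.vector(t(traj$a)),
    PIN = as.vector(t(traj$PIN)))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io Write a [layout2d()] as TSV (row, column, a, PIN).
#' @param layout a [layout2d()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "layout2d"))
  d <- expand.grid(row = seq_len(layout$M), column = seq_len(layout$N))
  d$a <- as.vector(layout$a)
  d$PIN <- as.vector(layout$PIN)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn io Write a `continuation_branch` summary as TSV
#'   (param, a_max, max_cell, a1, leading_eig, stable).
#' @param branch a `continuation_branch`.
#' @export
write_branch <- function(branch, path) {
  stopifnot(inherits(branch, "continuation_branch"))
  utils::write.table(branch$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a digitized reporter profile
#'
#' Two-column delimited text (position or cell index, staining intensity),
#' as produced by line-scan densitometry of reporter-stained root images.
#' Comment lines starting with `#` are skipped; the delimiter is sniffed
#' from tab, comma, or whitespace.
#'
#' @param path file path.
#' @return data.frame with columns `position` and `intensity`.
#' @export
read_digitized_profile <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))][1]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  has_header <- !grepl("^[-0-9.eE+[:space:],\t]+$", first)
  d <- utils::read.table(path, header = has_header, sep = sep,
                         comment.char = "#")
  if (ncol(d) < 2) stop("expected two columns (position, intensity)")
  out <- data.frame(position = as.numeric(d[[1]]),
                    intensity = as.numeric(d[[2]]))
  if (anyNA(out)) stop("non-numeric entries in digitized profile")
  out
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: resolved parameter values,
#' solver settings, seed, and package version.
#'
#' @param path output path.
#' @param set parameter set (from [param_preset()]).
#' @param ... further metadata fields (seed, solver options, experiment
#'   name, schedule, ...).
#' @export
write_manifest <- function(path, set, ...) {
  meta <- list(
    package = "rootauxin",
    version = as.character(utils::packageVersion("rootauxin")),
    parameter_set = set$name,
    transport = unclass(set$transport),
    divf = unclass(set$divf),
    cycle = unclass(set$cycle),
    ...)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
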