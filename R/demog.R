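#' Parse PSMC text output
#'
#' Reads the PA/TR/RS round-block dialect of PSMC output and extracts the
#' final round's parameters: `theta0` and `rho0` from the TR line and the
#' `(t_k, lambda_k)` interval rows from the RS lines (times in units of
#' 2 N0 generations, sizes relative to N0).
#'
#' @param x PSMC output text (single string, character vector of lines, or
#'   a file path).
#' @return object of class `psmc_result`: `theta0`, `rho0`, `t`, `lambda`,
#'   `round_index`.
#' @export
parse_psmc_output <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE))
  rd <- grep("^RD", lines)
  if (!length(rd)) rd <- 1L
  blocks <- split(lines, findInterval(seq_along(lines), rd))
  blocks <- Filter(function(b) any(grepl("^RS", b)), blocks)
  if (!length(blocks)) stop("no RS lines found in PSMC output", call. = FALSE)
  b <- blocks[[length(blocks)]]
  round_index <- if (grepl("^RD", b[1]))
    as.integer(strsplit(b[1], "\\s+")[[1]][2]) else NA_integer_
  tr <- grep("^TR", b, value = TRUE)
  if (!length(tr)) stop("no TR line in final round block", call. = FALSE)
  trf <- as.numeric(strsplit(tr[1], "\\s+")[[1]][2:3])
  rs <- grep("^RS", b, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(rs, "\\s+"), function(p)
    as.numeric(p[2:4])))
  t_k <- m[, 2]
  lambda <- m[, 3]
  if (t_k[1] != 0 || any(diff(t_k) <= 0))
    stop("RS times must start at 0 and increase strictly", call. = FALSE)
  if (any(lambda <= 0)) stop("RS lambda values must be positive", call. = FALSE)
  structure(list(theta0 = trf[1], rho0 = trf[2], t = t_k, lambda = lambda,
                 round_index = round_index),
            class = "psmc_result")
}

#' Scale PSMC output to years and effective population size
#'
#' Applies the standard plot scaling: `N0 = theta0 / (4 * u * s)`,
#' `Ne_k = N0 * lambda_k`, `years_k = 2 * N0 * t_k * g`.
#'
#' @param res a [parse_psmc_output()] result.
#' @param u per-site per-generation substitution rate (default 2.5e-8).
#' @param s consensus bin size in bp (default 100).
#' @param g generation time in years (default 1).
#' @return object of class `ne_trajectory`: a data.frame with `years` and
#'   `Ne`, plus `u`, `s`, `g`, `N0` attributes.
#' @export
scale_trajectory <- function(res, u = 2.5e-8, s = 100, g = 1) {
  stopifnot(u > 0, s >= 1, g > 0)
  N0 <- res$theta0 / (4 * u * s)
  out <- data.frame(years = 2 * N0 * res$t * g, Ne = N0 * res$lambda)
  attr(out, "u") <- u; attr(out, "s") <- s; attr(out, "g") <- g
  attr(out, "N0") <- N0
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

# Step-interpolate a trajectory onto a time grid: Ne at time t is the Ne
# of the interval containing t (piecewise constant, no new levels).
step_interp <- function(traj, grid) {
  traj$Ne[findInterval(grid, traj$years)]
}

#' Median trajectory and bootstrap envelope
#'
#' Resamples every replicate trajectory onto the union time grid by step
#' interpolation and reports the pointwise median and quantile band.
#'
#' @param trajectories non-empty list of [scale_trajectory()] results.
#' @param probs lower/upper band quantiles (default 2.5% / 97.5%).
#' @return data.frame with `years`, `median`, `lo`, `hi`.
#' @export
bootstrap_envelope <- function(trajectories, probs = c(0.025, 0.975)) {
  if (!length(trajectories)) stop("no trajectories given", call. = FALSE)
  grid <- sort(unique(unlist(lapply(trajectories, function(tr) tr$years))))
  vals <- vapply(trajectories, step_interp, numeric(length(grid)),
                 grid = grid)
  vals <- matrix(vals, nrow = length(grid))
  data.frame(years = grid,
             median = apply(vals, 1, median),
             lo = apply(vals, 1, quantile, probs = probs[1], type = 1),
             hi = apply(vals, 1, quantile, probs = probs[2], type = 1))
}

#' Write a trajectory (with optional envelope) as TSV
#'
#' @param traj a `ne_trajectory` or [bootstrap_envelope()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
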