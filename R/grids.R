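#' Build a tastant concentration ladder on a decadic logarithmic grid
#'
#' Constructs `n` concentration levels equidistantly spaced in log10 between
#' `c_min` and `c_max` (both inclusive, both in mM). The step width is
#' `(log10(c_max) - log10(c_min)) / (n - 1)`. The optional start concentration
#' (the predefined, supra-threshold first stimulus of an adaptive run) is
#' snapped to the nearest physical level so it is always a grid member.
#'
#' @param c_min,c_max Lowest / highest concentration, linear mM; positive.
#' @param n Number of levels (>= 2).
#' @param name Tastant label.
#' @param start_mM Optional first-trial concentration, linear mM; snapped to
#'   the nearest level. Defaults to the highest level.
#' @return An object of class `tastant_grid` with fields `name`,
#'   `levels_log10` (ascending), `step_width` (log10 units), `start_index`
#'   and `start_level` (log10 mM).
#' @export
#' @examples
#' g <- build_log_grid(0.015, 46.846, 14, name = "citric acid")
#' g$step_width  # ~0.269
build_log_grid <- function(c_min, c_max, n, name = "", start_mM = NULL) {
  if (!(is.finite(c_min) && is.finite(c_max) && c_min > 0 && c_max > c_min)) {
    stop("need 0 < c_min < c_max")
  }
  if (n < 2) stop("need at least 2 levels")
  levels_log10 <- seq(log10(c_min), log10(c_max), length.out = n)
  grid <- structure(
    list(name = name,
         levels_log10 = levels_log10,
         step_width = (log10(c_max) - log10(c_min)) / (n - 1),
         start_index = n,
         start_level = levels_log10[n]),
    class = "tastant_grid"
  )
  if (!is.null(start_mM)) {
    if (start_mM <= 0) stop("start_mM must be positive")
    grid$start_index <- snap_to_physical(log10(start_mM), grid)
    grid$start_level <- levels_log10[grid$start_index]
  }
  grid
}

#' @export
print.tastant_grid <- function(x, ...) {
  cat(sprintf(
    "tastant grid '%s': %d levels, %.3f to %.3f log10 mM (step %.3f), start %.3f\n",
    x$name, length(x$levels_log10), min(x$levels_log10), max(x$levels_log10),
    x$step_width, x$start_level))
  invisible(x)
}

#' Refine a physical ladder with virtual midpoint levels
#'
#' Inserts a virtual level halfway (in log10) between every pair of adjacent
#' physical levels, producing `2n - 1` levels. Virtual levels refine the
#' threshold candidate grid of the estimation procedures without requiring
#' new physical solutions; proposals landing on them are snapped back to
#' physical levels at presentation time.
#'
#' @param grid A [build_log_grid()] ladder.
#' @return An object of class `virtual_grid` with fields `levels_log10` and
#'   `parent`.
#' @export
insert_midpoints <- function(grid) {
  stopifnot(inherits(grid, "tastant_grid"))
  lv <- grid$levels_log10
  mids <- (lv[-1] + lv[-length(lv)]) / 2
  out <- sort(c(lv, mids))
  structure(list(levels_log10 = out, parent = grid), class = "virtual_grid")
}

#' Snap a proposed concentration to the nearest physical level
#'
#' Returns the index of the physical level closest (in log10 distance) to the
#' proposal. Ties are broken toward the lower concentration; out-of-range
#' proposals snap to the nearest endpoint.
#'
#' @param proposed_log10 Proposed concentration, log10 mM.
#' @param grid A [build_log_grid()] ladder.
#' @return Integer index into `grid$levels_log10`.
#' @export
snap_to_physical <- function(proposed_log10, grid) {
  stopifnot(inherits(grid, "tastant_grid"), length(proposed_log10) == 1)
  d <- abs(grid$levels_log10 - proposed_log10)
  # first index attaining the minimum within fp tolerance = lower level on ties
  which(d <= min(d) + 1e-12)[1L]
}

#' Packaged tastant grid presets
#'
#' The four standard tastant ladders: citric acid (sour), sodium chloride
#' (salty), quinine hydrochloride (bitter), and sucrose (sweet), each with its
#' concentration range, level count, and predefined supra-threshold start
#' concentration. Loaded from the packaged JSON config
#' (`system.file("extdata", "tastants.json", package = "adaptaste")`).
#'
#' @param name Optional tastant name; one of `"citric_acid"`, `"nacl"`,
#'   `"quinine_hcl"`, `"sucrose"`. If omitted, all four are returned.
#' @param path Optional path to an alternative JSON config with the same
#'   schema (fields `name`, `c_min_mM`, `c_max_mM`, `n_levels`, `start_mM`).
#' @return A single `tastant_grid`, or a named list of all of them.
#' @export
#' @examples
#' tastant_grid("citric_acid")
#' names(tastant_grid())
tastant_grid <- function(name = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tastants.json", package = "adaptaste")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  grids <- lapply(cfg, function(x) {
    build_log_grid(x$c_min_mM, x$c_max_mM, x$n_levels,
                   name = x$name, start_mM = x$start_mM)
  })
  names(grids) <- vapply(cfg, `[[`, "", "name")
  if (is.null(name)) return(grids)
  if (!name %in% names(grids)) {
    stop("unknown tastant '", name, "'; available: ",
         paste(names(grids), collapse = ", "))
  }
  grids[[name]]
}
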