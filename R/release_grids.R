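## Particle Grid methodology: Particle Release Maps (PRM, injection position
## -> fate at one burst timing) are rasterized onto a fixed reference grid
## (PRG) and composed across timings (CPRG). Cell-based (CF) and
## particle-based (EF) distributions, and their hybrid extensions to pruned
## outlets (TCF/TEF), are computed from these.

PRG_STATES <- c("tumor", "healthy", "no_exit", "spatially_uncertain", "no_value")
CPRG_STATES <- c("tumor_constant", "healthy_constant", "no_exit_constant",
                 "tumor_mostly", "healthy_mostly", "temporally_uncertain",
                 "spatially_uncertain", "no_value")

#' Extract the Particle Release Map of one burst timing
#'
#' @param exits an `exit_record_set` from [simulate_injection()].
#' @param timing injection timing, s (must match a burst time).
#' @return object of class `prm`: data frame `x`, `y` (plane coordinates,
#'   m) and `outlet` (`NA` for no-exit), with attribute `timing`.
#' @export
release_map <- function(exits, timing) {
  sel <- abs(exits$t_inject_s - timing) < 1e-9
  if (!any(sel)) stop("no particles injected at timing ", timing, " s")
  prm <- data.frame(x = exits$x_m[sel], y = exits$y_m[sel],
                    outlet = exits$outlet[sel])
  attr(prm, "timing") <- timing
  class(prm) <- c("prm", "data.frame")
  prm
}

#' Rasterize a PRM into a Particle Release Grid
#'
#' The reference grid is anchored at the lumen centroid (cell edges at
#' integer multiples of the spacing, half-open cells) and sized to cover the
#' lumen disk, so PRGs of different timings share an identical grid. Cells
#' are classified by the five rules: all particles exit tumor-perfusing
#' outlets -> `tumor`; all exit healthy-perfusing outlets -> `healthy`; all
#' remain stuck -> `no_exit`; any mixture -> `spatially_uncertain`; no
#' particles -> `no_value`. Per-cell outlet unanimity is retained for the
#' cell-fraction computation.
#'
#' @param prm a [release_map()].
#' @param tissue named character vector outlet id -> `"tumor"`/`"healthy"`.
#' @param h grid spacing, m (default 1e-4).
#' @param lumen_radius injection-plane lumen radius, m (fixes the grid
#'   extent).
#' @return object of class `prg`: list with `h`, `half_n`, `dim`, `state`
#'   (character matrix), `cell_outlet` (integer matrix; outlet id where a
#'   cell's particles unanimously exited one outlet, `0` for all-stuck,
#'   `NA` otherwise), `n_particles`, and `timing`.
#' @export
rasterize_prg <- function(prm, tissue, h = 1e-4, lumen_radius) {
  if (!nrow(prm)) stop("empty PRM")
  fates <- prm$outlet
  known <- unique(fates[!is.na(fates)])
  bad <- setdiff(as.character(known), names(tissue))
  if (length(bad)) stop("fate references outlet(s) without tissue label: ",
                        paste(bad, collapse = ", "))
  half_n <- as.integer(ceiling(lumen_radius / h))
  nd <- 2L * half_n
  ci <- floor(prm$x / h) + half_n + 1L   # 1-based matrix indices
  cj <- floor(prm$y / h) + half_n + 1L
  if (any(ci < 1L | ci > nd | cj < 1L | cj > nd))
    stop("particle position outside the reference grid; increase lumen_radius")
  state <- matrix("no_value", nd, nd)
  cell_outlet <- matrix(NA_integer_, nd, nd)
  n_particles <- matrix(0L, nd, nd)
  lin <- ci + (cj - 1L) * nd
  for (cell in unique(lin)) {
    sel <- lin == cell
    f <- fates[sel]
    n_particles[cell] <- sum(sel)
    n_stuck <- sum(is.na(f))
    ex <- f[!is.na(f)]
    if (length(ex) == 0L) {
      state[cell] <- "no_exit"
      cell_outlet[cell] <- 0L
    } else if (n_stuck > 0L) {
      state[cell] <- "spatially_uncertain"
    } else {
      tis <- tissue[as.character(ex)]
      state[cell] <- if (all(tis == "tumor")) "tumor"
                     else if (all(tis == "healthy")) "healthy"
                     else "spatially_uncertain"
      if (length(unique(ex)) == 1L) cell_outlet[cell] <- ex[1L]
    }
  }
  structure(list(h = h, half_n = half_n, dim = c(nd, nd), state = state,
                 cell_outlet = cell_outlet, n_particles = n_particles,
                 timing = attr(prm, "timing")), class = "prg")
}

## check that PRGs share one grid
.check_same_grid <- function(prgs) {
  if (length(prgs) < 1L) stop("need at least one PRG")
  ref <- prgs[[1L]]
  for (p in prgs[-1L])
    if (p$h != ref$h || any(p$dim != ref$dim))
      stop("PRGs are defined on different grids")
  invisible(ref)
}

#' Compose PRGs of several injection timings into a CPRG
#'
#' Per cell, with strict thresholds evaluated in order: `tumor` share >75%
#' -> `tumor_constant`; `healthy` >75% -> `healthy_constant`; `no_exit`
#' >75% -> `no_exit_constant`; `tumor` >50% -> `tumor_mostly`; `healthy`
#' >50% -> `healthy_mostly`; otherwise `no_value` share >37.5% ->
#' `no_value`, else `spatially_uncertain` share >37.5% ->
#' `spatially_uncertain`, else `temporally_uncertain`.
#'
#' @param prgs list of at least 2 `prg` objects on the identical grid
#'   (typically 8 timings spaced 0.1 s across the injection cycle).
#' @return object of class `cprg`: list with `h`, `dim`, `state`
#'   (character matrix of composite states) and `timings`.
#' @export
compose_cprg <- function(prgs) {
  if (length(prgs) < 2L) stop("CPRG needs at least 2 timing PRGs")
  ref <- .check_same_grid(prgs)
  m <- length(prgs)
  frac <- array(0, dim = c(ref$dim, length(PRG_STATES)),
                dimnames = list(NULL, NULL, PRG_STATES))
  for (st in PRG_STATES)
    frac[, , st] <- Reduce(`+`, lapply(prgs, function(p)
      (p$state == st) + 0)) / m
  state <- matrix(NA_character_, ref$dim[1L], ref$dim[2L])
  for (i in seq_len(ref$dim[1L])) for (j in seq_len(ref$dim[2L])) {
    f <- frac[i, j, ]
    state[i, j] <-
      if (f[["tumor"]] > 0.75) "tumor_constant"
      else if (f[["healthy"]] > 0.75) "healthy_constant"
      else if (f[["no_exit"]] > 0.75) "no_exit_constant"
      else if (f[["tumor"]] > 0.5) "tumor_mostly"
      else if (f[["healthy"]] > 0.5) "healthy_mostly"
      else if (f[["no_value"]] > 0.375) "no_value"
      else if (f[["spatially_uncertain"]] > 0.375) "spatially_uncertain"
      else "temporally_uncertain"
  }
  structure(list(h = ref$h, half_n = ref$half_n, dim = ref$dim,
                 state = state,
                 timings = vapply(prgs, function(p)
                   p$timing %||% NA_real_, numeric(1))),
            class = "cprg")
}

#' Grid-based cell fractions (CF)
#'
#' A cell-timing pair is associated with outlet x when all its particles
#' exited x, and with no-exit when all its particles remained stuck;
#' spatially uncertain and empty cells enter neither numerator nor
#' denominator. CF_x is the count for x over the total associated count
#' (including no-exit), aggregated over all timing PRGs.
#'
#' @param prgs list of `prg` objects (all burst timings, identical grid).
#' @param cells optional 2-column matrix of 1-based cell indices restricting
#'   the computation to a grid section (e.g. a catheter-associated square).
#' @param geometry label stored on the result.
#' @return object of class `distribution_result`: list with `fractions`
#'   (named per-outlet), `no_exit_fraction`, `kind = "CF"`, `geometry`.
#' @export
compute_cf <- function(prgs, cells = NULL, geometry = "") {
  .check_same_grid(prgs)
  counts <- list(); no_exit <- 0
  for (p in prgs) {
    co <- p$cell_outlet
    if (!is.null(cells)) co <- co[cells]
    co <- co[!is.na(co)]
    no_exit <- no_exit + sum(co == 0L)
    tab <- table(co[co > 0L])
    for (o in names(tab))
      counts[[o]] <- (counts[[o]] %||% 0) + as.numeric(tab[[o]])
  }
  denom <- sum(unlist(counts)) + no_exit
  if (denom == 0) stop("no associated cells: cell-fraction denominator is zero")
  fr <- vapply(counts, function(x) x / denom, numeric(1))
  fr <- fr[order(as.integer(names(fr)))]
  structure(list(fractions = fr, no_exit_fraction = no_exit / denom,
                 kind = "CF", geometry = geometry),
            class = "distribution_result")
}

#' Particle-based exit fractions (EF)
#'
#' EF_x is the fraction of exited particles that left through outlet x; the
#' no-exit fraction is reported separately relative to all injected
#' particles.
#'
#' @param exits an `exit_record_set`.
#' @param geometry label stored on the result.
#' @return a `distribution_result` with `kind = "EF"`.
#' @export
compute_ef <- function(exits, geometry = "") {
  ex <- exits$outlet[!is.na(exits$outlet)]
  if (!length(ex)) stop("no exited particles")
  tab <- table(ex)
  fr <- as.numeric(tab) / length(ex)
  names(fr) <- names(tab)
  fr <- fr[order(as.integer(names(fr)))]
  structure(list(fractions = fr,
                 no_exit_fraction = mean(is.na(exits$outlet)),
                 kind = "EF", geometry = geometry),
            class = "distribution_result")
}

#' Hybrid flow-proportional redistribution beyond truncated outlets
#'
#' Each truncated outlet's fraction is spread over its full-tree member
#' outlets proportionally to the flow fractions (TCF_x = CF_x* FF_x, and
#' likewise for EF/TEF); the member values sum exactly to the parent value.
#'
#' @param dist a `distribution_result` on a truncated outlet set.
#' @param ff flow-fraction map from [flow_fractions()].
#' @return a `distribution_result` indexed by the full outlet set (`kind`
#'   prefixed with `"T"`).
#' @export
hybrid_redistribute <- function(dist, ff) {
  out <- list()
  for (o in names(dist$fractions)) {
    f <- ff[[o]]
    if (is.null(f)) stop("no flow fractions for truncated outlet ", o)
    vals <- dist$fractions[[o]] * f
    out[names(f)] <- as.list(unname(vals))
  }
  fr <- unlist(out)
  fr <- fr[order(as.integer(names(fr)))]
  structure(list(fractions = fr, no_exit_fraction = dist$no_exit_fraction,
                 kind = paste0("T", sub("^T", "", dist$kind)),
                 geometry = dist$geometry),
            class = "distribution_result")
}

#' Compare two outlet distributions
#'
#' Per-outlet absolute differences in percentage points, with summary order
#' statistics, as used to compare truncated against full-complexity particle
#' distributions and flow against particle distributions.
#'
#' @param a,b `distribution_result`s on the same outlet set (fractions, or
#'   `b` may be a named vector of fractions such as imposed flow fractions).
#' @return list with `diff_pct` (named per-outlet absolute differences,
#'   percentage points), `median`, `iqr`, `min`, `max`, `argmax` (outlet id
#'   of the maximum difference).
#' @export
compare_distributions <- function(a, b) {
  fa <- a$fractions
  fb <- if (inherits(b, "distribution_result")) b$fractions else b
  keys <- union(names(fa), names(fb))
  va <- setNames(rep(0, length(keys)), keys); va[names(fa)] <- fa
  vb <- setNames(rep(0, length(keys)), keys); vb[names(fb)] <- fb
  d <- abs(va - vb) * 100
  d <- d[order(as.integer(names(d)))]
  list(diff_pct = d, median = median(d),
       iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
       min = min(d), max = max(d),
       argmax = as.integer(names(d)[which.max(d)]))
}

#' Write a PRG or CPRG state matrix as CSV
#' @param grid a `prg` or `cprg`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  write.csv(as.data.frame(grid$state), path, row.names = FALSE)
  invisible(path)
}

#' Plot a PRG or CPRG
#'
#' Renders the state matrix with the conventional color code (tumor green,
#' healthy red, no-exit black, spatially uncertain grey, no value white;
#' mostly-tumor yellow, mostly-healthy orange, temporally uncertain pink).
#'
#' @param x a `prg` or `cprg`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.prg <- function(x, ...) .plot_grid(x, PRG_STATES,
  c("green3", "red2", "black", "grey60", "white"), ...)

#' @rdname plot.prg
#' @export
plot.cprg <- function(x, ...) .plot_grid(x, CPRG_STATES,
  c("green3", "red2", "black", "yellow", "orange", "pink", "grey60", "white"),
  ...)

.plot_grid <- function(x, states, cols, ...) {
  z <- matrix(match(x$state, states), x$dim[1L], x$dim[2L])
  graphics::image(seq_len(x$dim[1L]), seq_len(x$dim[2L]), z,
                  col = cols, zlim = c(1, length(states)),
                  xlab = "cell i", ylab = "cell j", asp = 1, ...)
  invisible(x)
}
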