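# Residency distributions and Bhattacharyya-affinity overlap.

new_residency <- function(values, grid, source, n_fish, fish_days) {
  structure(list(values = values, grid = grid, source = source,
                 n_fish = n_fish, fish_days = fish_days),
            class = "residency_distribution")
}

#' Residency distribution of one fish
#'
#' Time-integrated space use: the cellwise mean of the daily smoothed
#' posterior surfaces, hence itself a normalised distribution that carries
#' the positional uncertainty of the fit.
#'
#' @param fit a [geolocate()] fit (or any list with a `smoothed` K x T
#'   matrix and a `grid`).
#' @return object of class `residency_distribution`.
#' @export
residency_distribution <- function(fit) {
  s <- fit$smoothed
  if (is.null(s) || !ncol(s)) stop_input("fit carries no smoothed surfaces")
  new_residency(rowMeans(s), fit$grid,
                source = fit$deployment$tag_id %||% "track",
                n_fish = 1L, fish_days = ncol(s))
}

#' @export
print.residency_distribution <- function(x, ...) {
  cat(sprintf("<residency_distribution> %s: %d cells, %d fish, %d fish-days\n",
              x$source, length(x$values), x$n_fish, x$fish_days))
  invisible(x)
}

#' Combine per-fish residency distributions into a population surface
#'
#' Fish whose ocean migration does not exceed `min_days` days are excluded
#' (strictly greater than, default 10 days). The survivors are combined
#' with equal weight per fish (`weight = "fish"`, the default, so long
#' deployments do not dominate) or pooled by fish-days
#' (`weight = "days"`).
#'
#' @param rds list of `residency_distribution` on one grid.
#' @param track_days numeric vector of migration lengths in days; defaults
#'   to each RD's `fish_days`.
#' @param min_days exclusion threshold (kept if `track_days > min_days`).
#' @param weight `"fish"` or `"days"`.
#' @param source label for the combined distribution.
#' @return a `residency_distribution` for the population.
#' @export
combine_rds <- function(rds, track_days = NULL, min_days = 10,
                        weight = c("fish", "days"), source = "population") {
  weight <- match.arg(weight)
  if (is.null(track_days))
    track_days <- vapply(rds, function(r) r$fish_days, numeric(1))
  if (length(track_days) != length(rds))
    stop_input("track_days must match the number of RDs")
  K <- length(rds[[1]]$values)
  if (any(vapply(rds, function(r) length(r$values), numeric(1)) != K))
    psat_stop("all RDs must live on the same grid", "psat_shape_error")
  keep <- track_days > min_days
  if (!any(keep))
    psat_stop("no fish exceed the minimum migration length",
              "psat_empty_population_error")
  rds <- rds[keep]
  w <- if (weight == "fish") rep(1, length(rds))
       else vapply(rds, function(r) r$fish_days, numeric(1))
  w <- w / sum(w)
  v <- Reduce(`+`, Map(function(r, wi) wi * r$values, rds, w))
  new_residency(v / sum(v), rds[[1]]$grid, source,
                n_fish = length(rds),
                fish_days = sum(vapply(rds, function(r) r$fish_days,
                                       numeric(1))))
}

#' Bhattacharyya's affinity between two residency distributions
#'
#' `BA = sum over cells of sqrt(p * q)`, interpretable as proportion
#' overlap: 1 for identical distributions, 0 for disjoint ones.
#'
#' @param p,q `residency_distribution` objects (or bare normalised numeric
#'   vectors) on the same grid.
#' @return affinity in \[0, 1\].
#' @export
bhattacharyya <- function(p, q) {
  pv <- if (inherits(p, "residency_distribution")) p$values else p
  qv <- if (inherits(q, "residency_distribution")) q$values else q
  if (length(pv) != length(qv))
    psat_stop("distributions live on different grids", "psat_shape_error")
  if (any(pv < 0) || any(qv < 0) ||
      abs(sum(pv) - 1) > 1e-6 || abs(sum(qv) - 1) > 1e-6)
    stop_validation("inputs must be normalised nonnegative distributions")
  sum(sqrt(pv * qv))
}

#' Pairwise overlap matrix between populations
#'
#' @param pops named list of population `residency_distribution`s.
#' @return symmetric matrix of Bhattacharyya affinities with unit diagonal,
#'   labelled by population.
#' @export
overlap_matrix <- function(pops) {
  if (length(pops) < 2) stop_input("need at least 2 populations")
  labels <- names(pops)
  if (is.null(labels) || anyDuplicated(labels))
    stop_input("populations must carry unique labels")
  n <- length(pops)
  M <- diag(1, n)
  dimnames(M) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- bhattacharyya(pops[[i]], pops[[j]])
  }
  M
}
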