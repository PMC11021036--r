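#' Match spines across two aligned sessions
#'
#' Globally optimal one-to-one matching of spine centroids between a
#' session-1 map and a session-2 map already transformed into session 1's
#' frame. Only pairs with centroid distance at most `max_disp` px are
#' eligible; among all maximum-cardinality matchings the one minimizing
#' total centroid distance is returned (optimal linear assignment, not
#' greedy — a new spine near an already-accounted-for spine must still
#' come out as gained). Session-1 spines left unmatched are lost;
#' session-2 spines left unmatched are gained.
#'
#' @param map1 `FeatureMap` of session 1.
#' @param map2_aligned `FeatureMap` of session 2, aligned to session 1.
#' @param max_disp retention radius in px (> 0); spines whose centroids
#'   moved by more than this are treated as different spines. The
#'   appropriate value depends on image resolution and spine size/density;
#'   4 px is the worked default.
#' @return list with `retained` (k x 2 matrix of (id1, id2) pairs), `lost`
#'   (session-1 ids), `gained` (session-2 ids) and `distances` (centroid
#'   distance per retained pair).
#' @export
match_spines <- function(map1, map2_aligned, max_disp = 4) {
  if (max_disp <= 0) stop("max_disp must be positive")
  c1 <- spine_centroids(map1)
  c2 <- spine_centroids(map2_aligned)
  id1 <- vapply(map1$spines, function(s) s$id, integer(1))
  id2 <- vapply(map2_aligned$spines, function(s) s$id, integer(1))
  n1 <- nrow(c1); n2 <- nrow(c2)
  if (n1 == 0 || n2 == 0)
    return(list(retained = matrix(integer(0), 0, 2), lost = id1,
                gained = id2, distances = numeric(0)))
  d <- sqrt(outer(c1[, 1], c2[, 1], "-")^2 + outer(c1[, 2], c2[, 2], "-")^2)
  BIG <- 1e7   # dummy cost: dominates any sum of feasible distances
  cost <- d
  cost[cost > max_disp] <- 2 * BIG
  # append one dummy column per row so every row can stay unmatched
  cost <- cbind(cost, matrix(BIG, n1, n1))
  a <- solve_assignment(cost)
  matched <- which(a <= n2 & d[cbind(seq_len(n1), pmin(a, n2))] <= max_disp)
  pairs <- cbind(id1[matched], id2[a[matched]])
  list(retained = pairs,
       lost = setdiff(id1, pairs[, 1]),
       gained = setdiff(id2, pairs[, 2]),
       distances = d[cbind(matched, a[matched])])
}

spine_centroids <- function(fmap) {
  if (!length(fmap$spines)) return(matrix(numeric(0), 0, 2))
  t(vapply(fmap$spines, function(s) s$centroid, numeric(2)))
}

#' Classify spine turnover and summarize structure
#'
#' Turns a [match_spines()] result into the full turnover report: per-spine
#' status (lost / retained / gained), counts, and the three structural
#' summaries — spine area distributions, nearest-neighbor spine distances
#' (local density), and arc-length positions along the parent dendrite.
#' Spines without a parent dendrite get `NA` arc positions rather than an
#' error.
#'
#' @param map1,map2_aligned as in [match_spines()].
#' @param matching result of [match_spines()]; computed here when `NULL`.
#' @param max_disp passed to [match_spines()] when `matching` is `NULL`.
#' @return A `TurnoverResult`: list with `retained`, `lost`, `gained`,
#'   `max_disp`, `status` (data.frame of session, spine id, status) and
#'   `summaries` (`areas`, `nn_distances`, `arc_positions`, each a
#'   two-element list for the two sessions).
#' @export
classify_and_summarize <- function(map1, map2_aligned, matching = NULL,
                                   max_disp = 4) {
  if (is.null(matching))
    matching <- match_spines(map1, map2_aligned, max_disp)
  id1 <- vapply(map1$spines, function(s) s$id, integer(1))
  id2 <- vapply(map2_aligned$spines, function(s) s$id, integer(1))
  status <- rbind(
    data.frame(session = 1L, id = id1,
               status = ifelse(id1 %in% matching$retained[, 1],
                               "retained", "lost")),
    data.frame(session = 2L, id = id2,
               status = ifelse(id2 %in% matching$retained[, 2],
                               "retained", "gained")))
  summaries <- list(
    areas = list(session1 = vapply(map1$spines, function(s) s$area,
                                   numeric(1)),
                 session2 = vapply(map2_aligned$spines,
                                   function(s) s$area, numeric(1))),
    nn_distances = list(session1 = nn_distances(spine_centroids(map1)),
                        session2 = nn_distances(
                          spine_centroids(map2_aligned))),
    arc_positions = list(session1 = arc_positions(map1),
                         session2 = arc_positions(map2_aligned)))
  structure(list(retained = matching$retained, lost = matching$lost,
                 gained = matching$gained, max_disp = max_disp,
                 status = status, summaries = summaries),
            class = "TurnoverResult")
}

#' @export
print.TurnoverResult <- function(x, ...) {
  cat(sprintf("TurnoverResult: %d retained, %d lost, %d gained (max_disp = %g px)\n",
              nrow(x$retained), length(x$lost), length(x$gained),
              x$max_disp))
  invisible(x)
}

#' Bar plot of turnover counts and the three structural histograms
#' @param x a `TurnoverResult`.
#' @param ... unused.
#' @export
plot.TurnoverResult <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  graphics::barplot(c(retained = nrow(x$retained), lost = length(x$lost),
                      gained = length(x$gained)),
                    ylab = "spines", main = "turnover")
  graphics::hist(unlist(x$summaries$areas), xlab = "area (px^2)",
                 main = "spine areas")
  graphics::hist(unlist(x$summaries$nn_distances),
                 xlab = "nearest-neighbor distance (px)",
                 main = "local density")
  ap <- unlist(x$summaries$arc_positions)
  if (any(is.finite(ap)))
    graphics::hist(ap[is.finite(ap)], xlab = "position along dendrite (px)",
                   main = "linear positions")
  invisible(x)
}

nn_distances <- function(cent) {
  n <- nrow(cent)
  if (n < 2) return(rep(NA_real_, n))
  d <- as.matrix(stats::dist(cent))
  diag(d) <- Inf
  apply(d, 1, min)
}

arc_positions <- function(fmap) {
  vapply(fmap$spines, function(s) {
    if (is.na(s$parent_dendrite)) return(NA_real_)
    dd <- NULL
    for (cand in fmap$dendrites)
      if (cand$id == s$parent_dendrite) dd <- cand
    if (is.null(dd)) return(NA_real_)
    point_polyline_project(matrix(s$centroid, 1), dd$path)$arc
  }, numeric(1))
}

#' Turnover across more than two sessions
#'
#' Reduces a multi-session chain to pairwise comparisons: by default every
#' later session is compared against the first session's map; with
#' `sequential = TRUE` each session is compared against its predecessor.
#'
#' @param maps list of aligned `FeatureMap`s (session order).
#' @param max_disp retention radius in px.
#' @param sequential compare each session to its predecessor instead of to
#'   session 1.
#' @return list of `TurnoverResult`s, one per comparison.
#' @export
turnover_chain <- function(maps, max_disp = 4, sequential = FALSE) {
  if (length(maps) < 2) stop("need at least two sessions")
  out <- list()
  for (k in 2:length(maps)) {
    ref <- if (sequential) maps[[k - 1]] else maps[[1]]
    out[[k - 1]] <- classify_and_summarize(ref, maps[[k]],
                                           max_disp = max_disp)
  }
  out
}
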