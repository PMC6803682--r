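#' Piecewise-linear daily depth trajectory
#'
#' The daily migration of one developmental stage is described by five
#' phases: shallow residence at `H0` over `[0, t0)` (spanning midnight),
#' linear descent to `H1` over `[t0, t1)`, deep residence over `[t1, t2)`
#' (spanning midday), linear ascent over `[t2, t3)`, and shallow residence
#' again over `[t3, 1]`. Continuity fixes the ramp durations from the
#' migration speeds: `t1 - t0 = (H1 - H0) / c_down` and
#' `t3 - t2 = (H1 - H0) / c_up`, and the trajectory is periodic,
#' `h(0) = h(1) = H0`.
#'
#' By default the trajectory is symmetric about midday (`t3 = 1 - t0`), the
#' form taken by the optimum when descent and ascent speeds are equal; `t2`
#' can be given explicitly for asymmetric shapes. The degenerate
#' non-migrating trajectory `H1 = H0` is admissible (the animal then resides,
#' feeds and is active at `H0` all day).
#'
#' @param H0 Shallow (night-time) depth, m.
#' @param H1 Deep (daytime) depth, m; `H1 >= H0`.
#' @param t0 End of the night-time shallow residence, day fraction.
#' @param c_down,c_up Descent and ascent speeds, m/h.
#' @param t2 Start of the ascent, day fraction, or `NULL` for the symmetric
#'   trajectory `t3 = 1 - t0`.
#' @return An object of class `dvm_trajectory` with fields `H0`, `H1`, `t0`,
#'   `t1`, `t2`, `t3`, `c_down_day`, `c_up_day` (speeds in m/day).
#' @examples
#' tr <- dvm_trajectory(H0 = 35, H1 = 120, t0 = 0.2)
#' depth_at(tr, c(0, 0.5, 1))
#' @export
dvm_trajectory <- function(H0, H1 = H0, t0 = 0.25, c_down = 45, c_up = 45,
                           t2 = NULL) {
  stopifnot(is.numeric(H0), is.numeric(H1), is.numeric(t0))
  if (H0 < 0) stop("`H0` must be nonnegative", call. = FALSE)
  if (H1 < H0) stop("`H1` must not be shallower than `H0`", call. = FALSE)
  if (c_down <= 0 || c_up <= 0) stop("speeds must be positive", call. = FALSE)
  cd <- 24 * c_down
  cu <- 24 * c_up
  dH <- H1 - H0
  t1 <- t0 + dH / cd
  if (is.null(t2)) t2 <- 1 - t0 - dH / cu
  t3 <- t2 + dH / cu
  tt <- c(t0, t1, t2, t3)
  if (t0 < 0 || t3 > 1 + 1e-12 || any(diff(c(0, tt, 1)) < -1e-12))
    stop("phase times must satisfy 0 <= t0 <= t1 <= t2 <= t3 <= 1; ",
         "the requested migration does not fit in the day", call. = FALSE)
  structure(list(H0 = H0, H1 = H1, t0 = t0, t1 = t1, t2 = min(t2, t3),
                 t3 = t3, c_down_day = cd, c_up_day = cu,
                 migrating = dH > 1e-9),
            class = "dvm_trajectory")
}

#' @export
print.dvm_trajectory <- function(x, ...) {
  if (x$migrating) {
    cat(sprintf(
      "<dvm_trajectory> %.1f m (night) <-> %.1f m (day); descent %.3f-%.3f, ascent %.3f-%.3f\n",
      x$H0, x$H1, x$t0, x$t1, x$t2, x$t3))
  } else {
    cat(sprintf("<dvm_trajectory> non-migrating at %.1f m\n", x$H0))
  }
  invisible(x)
}

#' Depth at a time of day
#'
#' Evaluates the piecewise-linear trajectory; continuous, with
#' `depth_at(tr, 0) == depth_at(tr, 1) == H0`.
#'
#' @param traj A [dvm_trajectory()].
#' @param t Time of day in `[0, 1]` (vectorised).
#' @return Depth in m.
#' @export
depth_at <- function(traj, t) {
  check_day_fraction(t)
  with(traj, {
    out <- rep(H0, length(t))
    out[t >= t0 & t < t1] <- H0 + c_down_day * (t[t >= t0 & t < t1] - t0)
    out[t >= t1 & t < t2] <- H1
    out[t >= t2 & t < t3] <- H1 - c_up_day * (t[t >= t2 & t < t3] - t2)
    out
  })
}

#' Feeding indicator S_i(t)
#'
#' 1 while the animal grazes, 0 otherwise. Animals moving vertically faster
#' than the critical feeding speed do not feed, which excludes both ramps;
#' food intake during the deep daytime residence is also switched off (the
#' animal sits below the food layer in quiescence), so feeding happens on the
#' shallow night-time segments only. A non-migrating trajectory feeds all
#' day.
#'
#' @inheritParams depth_at
#' @return 0/1 vector.
#' @export
feeding_indicator <- function(traj, t) {
  check_day_fraction(t)
  if (!traj$migrating) return(rep(1, length(t)))
  as.numeric(t < traj$t0 | t >= traj$t3)
}

#' Active-metabolism indicator S_i1(t)
#'
#' 1 while the animal pays the active metabolic cost: during the feeding
#' (shallow) phases and the ascent. Descent is passive (basal cost only,
#' the animal sinks with little effort) and the deep daytime residence is
#' quiescent. A non-migrating trajectory is active all day.
#'
#' @inheritParams depth_at
#' @return 0/1 vector.
#' @export
active_indicator <- function(traj, t) {
  check_day_fraction(t)
  if (!traj$migrating) return(rep(1, length(t)))
  as.numeric(t < traj$t0 | (t >= traj$t2 & t < traj$t3) | t >= traj$t3)
}

#' Dense sampling of a trajectory
#'
#' @inheritParams depth_at
#' @param n Number of sample points.
#' @return A tibble with columns `t`, `depth`, `feeding`, `active`.
#' @export
trajectory_profile <- function(traj, n = 241) {
  t <- seq(0, 1, length.out = n)
  tibble::tibble(t = t, depth = depth_at(traj, t),
                 feeding = feeding_indicator(traj, t),
                 active = active_indicator(traj, t))
}

#' A full inherited strategy: one trajectory per developmental stage
#'
#' @param Y,J,A [dvm_trajectory()] objects for the young juveniles (CI-III),
#'   older juveniles (CIV-V) and adults (CVI).
#' @return An object of class `dvm_strategy`.
#' @examples
#' s <- dvm_strategy(
#'   Y = dvm_trajectory(35),
#'   J = dvm_trajectory(35, 120, t0 = 0.2),
#'   A = dvm_trajectory(35, 120, t0 = 0.2)
#' )
#' @export
dvm_strategy <- function(Y, J, A) {
  stopifnot(inherits(Y, "dvm_trajectory"), inherits(J, "dvm_trajectory"),
            inherits(A, "dvm_trajectory"))
  structure(list(Y = Y, J = J, A = A), class = "dvm_strategy")
}

#' @export
print.dvm_strategy <- function(x, ...) {
  cat("<dvm_strategy>\n")
  for (s in c("Y", "J", "A")) { cat(sprintf("  %s: ", s)); print(x[[s]]) }
  invisible(x)
}

#' Tabulate a strategy
#'
#' @param x A `dvm_strategy`.
#' @param ... Unused.
#' @return A tibble with one row per stage: depths, phase times, speeds and
#'   migration amplitude.
#' @export
as_tibble.dvm_strategy <- function(x, ...) {
  rows <- lapply(c("Y", "J", "A"), function(s) {
    tr <- x[[s]]
    tibble::tibble(stage = s, H0 = tr$H0, H1 = tr$H1,
                   t0 = tr$t0, t1 = tr$t1, t2 = tr$t2, t3 = tr$t3,
                   c_down = tr$c_down_day / 24, c_up = tr$c_up_day / 24,
                   amplitude = tr$H1 - tr$H0)
  })
  dplyr::bind_rows(rows)
}

#' Rebuild a strategy from its tabular form
#'
#' Inverse of [as_tibble.dvm_strategy()]: accepts a data frame with columns
#' `stage`, `H0`, `H1`, `t0` and optionally `t2`, `c_down`, `c_up` (m/h).
#'
#' @param df A data frame with one row per stage `Y`, `J`, `A`.
#' @return A `dvm_strategy`.
#' @export
as_dvm_strategy <- function(df) {
  stopifnot(is.data.frame(df), all(c("stage", "H0", "H1", "t0") %in% names(df)))
  get_tr <- function(s) {
    r <- df[df$stage == s, , drop = FALSE]
    if (nrow(r) != 1) stop("need exactly one row per stage; missing ", s,
                           call. = FALSE)
    dvm_trajectory(H0 = r$H0, H1 = r$H1, t0 = r$t0,
                   c_down = if ("c_down" %in% names(r)) r$c_down else 45,
                   c_up = if ("c_up" %in% names(r)) r$c_up else 45,
                   t2 = if ("t2" %in% names(r) && is.finite(r$t2)) r$t2 else NULL)
  }
  dvm_strategy(Y = get_tr("Y"), J = get_tr("J"), A = get_tr("A"))
}

check_day_fraction <- function(t) {
  if (any(!is.finite(t)) || any(t < 0 | t > 1))
    stop("`t` must lie in [0, 1]", call. = FALSE)
  invisible(t)
}
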