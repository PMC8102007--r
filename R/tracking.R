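# Registration of daily cell point-sets and frame-to-frame linking of
# melanophores into tracks.

# Least-squares rigid fit (Kabsch, 2-D, rotation only) mapping A -> B
# for matched point pairs. Returns list(theta, t, R).
kabsch2d <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  Hm <- crossprod(Ac, Bc)
  sv <- svd(Hm)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t <- cb - as.vector(R %*% ca)
  list(theta = atan2(R[2, 1], R[1, 1]), t = t, R = R)
}

applyRigid <- function(P, R, t) sweep(P %*% t(R), 2, -t)

#' Robust rigid registration of two point sets
#'
#' Estimates the rigid transform (rotation + translation) mapping
#' `pointsA` onto `pointsB` by robust sampling of correspondence
#' hypotheses (pairs of points with compatible inter-point distances),
#' scoring each by how many points of A land within `tol` px of some
#' point of B, followed by a least-squares (Kabsch) refit on the inlier
#' correspondences. Registration fails -- flagged, not an error -- when
#' no hypothesis reaches the required inlier fraction.
#'
#' @param pointsA,pointsB two-column matrices of (x, y); >= 3 points each.
#' @param inlierRatio minimum inlier fraction for success.
#' @param tol inlier residual tolerance, px.
#' @param maxIter number of sampling iterations.
#' @param seed RNG seed for the sampling (deterministic by default).
#' @return list: `theta` (radians), `translation`, `R` (2 x 2 rotation),
#'   `inliers` (indices into A), `matches` (indices into B, NA for
#'   non-inliers), `rmse`, `failed`.
#' @export
rigidRegister <- function(pointsA, pointsB, inlierRatio = 0.20, tol = 3,
                          maxIter = 1000L, seed = 1L) {
  A <- as.matrix(pointsA); B <- as.matrix(pointsB)
  if (nrow(A) < 3L || nrow(B) < 3L) stop("need >= 3 points in each set")
  nA <- nrow(A); nB <- nrow(B)
  score <- function(R, t) {
    TA <- applyRigid(A, R, t)
    D2 <- outer(TA[, 1], B[, 1], "-")^2 + outer(TA[, 2], B[, 2], "-")^2
    j <- max.col(-D2, ties.method = "first")
    d <- sqrt(D2[cbind(seq_len(nA), j)])
    inl <- which(d < tol)
    list(inl = inl, match = j, d = d, ssr = sum(d[inl]^2))
  }
  withSeed(seed, {
    # Hypotheses: a random ordered pair of A points against every
    # distance-compatible ordered pair of B points; candidates are
    # prefiltered by projecting a third probe point, and only survivors
    # are fully scored. This finds a true correspondence with high
    # probability in few samples even under heavy clutter.
    DB <- as.matrix(dist(B))
    tolD <- max(2, tol)
    nSamples <- max(10L, ceiling(maxIter / 25))
    best <- NULL; bestN <- -1L; bestSSR <- Inf
    consider <- function(R, t) {
      sc <- score(R, t)
      if (length(sc$inl) > bestN ||
          (length(sc$inl) == bestN && sc$ssr < bestSSR)) {
        bestN <<- length(sc$inl); bestSSR <<- sc$ssr
        best <<- list(fit = list(R = R, t = t), sc = sc)
      }
    }
    for (s in seq_len(nSamples)) {
      ia <- sample.int(nA, 2L)
      a1 <- A[ia[1], ]; a2 <- A[ia[2], ]
      da <- sqrt(sum((a2 - a1)^2))
      if (da < 1e-9) next                       # degenerate sample
      comp <- which(abs(DB - da) <= tolD, arr.ind = TRUE)
      comp <- comp[comp[, 1] != comp[, 2], , drop = FALSE]
      if (!nrow(comp)) next
      if (nrow(comp) > 600L)
        comp <- comp[sample.int(nrow(comp), 600L), , drop = FALSE]
      angA <- atan2(a2[2] - a1[2], a2[1] - a1[1])
      b1 <- B[comp[, 1], , drop = FALSE]; b2 <- B[comp[, 2], , drop = FALSE]
      theta <- atan2(b2[, 2] - b1[, 2], b2[, 1] - b1[, 1]) - angA
      ct <- cos(theta); st <- sin(theta)
      tx <- b1[, 1] - (ct * a1[1] - st * a1[2])
      ty <- b1[, 2] - (st * a1[1] + ct * a1[2])
      i3 <- sample(setdiff(seq_len(nA), ia), 1L)
      a3 <- A[i3, ]
      px <- ct * a3[1] - st * a3[2] + tx
      py <- st * a3[1] + ct * a3[2] + ty
      d2 <- outer(px, B[, 1], "-")^2 + outer(py, B[, 2], "-")^2
      dmin <- sqrt(apply(d2, 1, min))
      keep <- order(dmin)[seq_len(min(10L, nrow(comp)))]
      keep <- keep[dmin[keep] < tol]
      for (ci in keep) {
        R <- matrix(c(ct[ci], st[ci], -st[ci], ct[ci]), 2, 2)
        consider(R, c(tx[ci], ty[ci]))
      }
    }
    if (is.null(best) || bestN < max(2L, ceiling(inlierRatio * nA)))
      return(list(theta = NA_real_, translation = c(NA_real_, NA_real_),
                  R = diag(2), inliers = integer(), matches = integer(),
                  rmse = NA_real_, failed = TRUE))
    # refit on inlier correspondences until the matching stabilizes
    sc <- best$sc; fit <- best$fit
    for (round in 1:10) {
      inl <- sc$inl
      fit <- kabsch2d(A[inl, , drop = FALSE],
                      B[sc$match[inl], , drop = FALSE])
      newSc <- score(fit$R, fit$t)
      stable <- identical(newSc$inl, sc$inl) &&
        identical(newSc$match[newSc$inl], sc$match[sc$inl])
      sc <- newSc
      if (stable) break
    }
    match <- rep(NA_integer_, nA)
    match[sc$inl] <- sc$match[sc$inl]
    list(theta = fit$theta, translation = fit$t, R = fit$R,
         inliers = sc$inl, matches = match,
         rmse = sqrt(mean(sc$d[sc$inl]^2)), failed = FALSE)
  })
}

# Compact O(n^3) Hungarian assignment (Jonker-style shortest augmenting
# paths with potentials). cost: n x m matrix, n <= m; returns for each
# row the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1); p <- integer(m + 1)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Link registered cell detections across days into tracks
#'
#' Frame-to-frame assignment of detections to open tracks, subject to a
#' per-day displacement cap; links across a single missing day are
#' allowed with cap `2 * maxDisp`. Unmatched detections start new tracks.
#' The default greedy nearest-pair linking is deterministic and
#' approximates the optimal assignment; `method = "optimal"` solves the
#' exact minimum-cost bipartite assignment within the cap.
#'
#' @param frames list of [CellSet-class] objects or data.frames with
#'   `x`, `y`, in day order (registered to one reference frame).
#' @param days day index per frame (default `seq_along(frames)`).
#' @param maxDisp per-day displacement cap, px.
#' @param maxGap maximum missing days bridged by a link.
#' @param method `"greedy"` or `"optimal"`.
#' @return data.frame (`track`, `day`, `x`, `y`), one row per detection.
#' @export
linkTracks <- function(frames, days = seq_along(frames), maxDisp = 100,
                       maxGap = 1L, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  getXY <- function(f) {
    df <- if (is(f, "CellSet")) f@cells else as.data.frame(f)
    cbind(x = df$x, y = df$y)
  }
  lastDay <- numeric(0); lastX <- numeric(0); lastY <- numeric(0)
  rows <- list()
  nTracks <- 0L
  for (fi in seq_along(frames)) {
    d <- days[fi]
    P <- getXY(frames[[fi]])
    nDet <- nrow(P)
    assigned <- rep(NA_integer_, nDet)   # track index per detection
    active <- which(length(lastDay) > 0 & (d - lastDay) <= (maxGap + 1))
    if (length(active) && nDet) {
      gap <- d - lastDay[active]
      cap <- maxDisp * gap               # 2*maxDisp across one missing day
      D <- sqrt(outer(lastX[active], P[, 1], "-")^2 +
                  outer(lastY[active], P[, 2], "-")^2)
      D[D > cap] <- Inf
      if (method == "greedy") {
        repeat {
          mi <- which.min(D)
          if (!length(mi) || !is.finite(D[mi])) break
          ti <- (mi - 1L) %% nrow(D) + 1L
          di <- (mi - 1L) %/% nrow(D) + 1L
          assigned[di] <- active[ti]
          D[ti, ] <- Inf; D[, di] <- Inf
        }
      } else {
        BIG <- 1e9
        C <- D; C[!is.finite(C)] <- BIG
        if (nrow(C) <= ncol(C)) {
          sol <- hungarian(C)
          for (ti in seq_along(sol))
            if (is.finite(D[ti, sol[ti]])) assigned[sol[ti]] <- active[ti]
        } else {
          sol <- hungarian(t(C))
          for (di in seq_along(sol))
            if (is.finite(D[sol[di], di])) assigned[di] <- active[sol[di]]
        }
      }
    }
    for (di in seq_len(nDet)) {
      ti <- assigned[di]
      if (is.na(ti)) {
        nTracks <- nTracks + 1L
        ti <- nTracks
        lastDay[ti] <- d; lastX[ti] <- P[di, 1]; lastY[ti] <- P[di, 2]
      } else {
        lastDay[ti] <- d; lastX[ti] <- P[di, 1]; lastY[ti] <- P[di, 2]
      }
      rows[[length(rows) + 1L]] <- c(ti, d, P[di, 1], P[di, 2])
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (!nrow(out)) return(data.frame(track = integer(), day = numeric(),
                                    x = numeric(), y = numeric()))
  names(out) <- c("track", "day", "x", "y")
  out[order(out$track, out$day), , drop = FALSE]
}

#' Per-track motion statistics
#'
#' Filters tracks to those spanning at least `minSpan` days with at most
#' `maxMissing` missing days, then reports each track's net total
#' displacement (start to end, Euclidean) and median per-day speed
#' (interval distance / interval days).
#'
#' @param tracks data.frame from [linkTracks()].
#' @param minSpan minimum span (last day - first day + 1) for inclusion.
#' @param maxMissing maximum missing days within the span.
#' @return data.frame (`track`, `firstDay`, `lastDay`, `span`, `nObs`,
#'   `totalDisplacement`, `medianSpeed`); empty with attribute
#'   `"flag" = "no_qualifying_tracks"` when nothing qualifies.
#' @export
motionStats <- function(tracks, minSpan = 7L, maxMissing = 1L) {
  empty <- data.frame(track = integer(), firstDay = numeric(),
                      lastDay = numeric(), span = numeric(),
                      nObs = integer(), totalDisplacement = numeric(),
                      medianSpeed = numeric())
  if (!nrow(tracks)) { attr(empty, "flag") <- "no_qualifying_tracks"; return(empty) }
  res <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$day), , drop = FALSE]
    span <- tr$day[nrow(tr)] - tr$day[1] + 1
    missing <- span - nrow(tr)
    if (span < minSpan || missing > maxMissing) return(NULL)
    dd <- diff(tr$day)
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    data.frame(track = tr$track[1], firstDay = tr$day[1],
               lastDay = tr$day[nrow(tr)], span = span, nObs = nrow(tr),
               totalDisplacement = sqrt((tr$x[nrow(tr)] - tr$x[1])^2 +
                                          (tr$y[nrow(tr)] - tr$y[1])^2),
               medianSpeed = median(step / dd))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) { attr(empty, "flag") <- "no_qualifying_tracks"; return(empty) }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Register a list of daily cell sets to the first frame
#'
#' Composes pairwise rigid transforms cumulatively so all frames share
#' the first frame's coordinate system.
#'
#' @param frames list of [CellSet-class] or data.frames with `x`, `y`.
#' @param ... passed to [rigidRegister()].
#' @return list of data.frames with registered `x`, `y`.
#' @export
registerSeries <- function(frames, ...) {
  getXY <- function(f) {
    df <- if (is(f, "CellSet")) f@cells else as.data.frame(f)
    cbind(x = df$x, y = df$y)
  }
  out <- vector("list", length(frames))
  out[[1]] <- as.data.frame(getXY(frames[[1]]))
  R <- diag(2); t <- c(0, 0)        # cumulative frame-k -> frame-1
  for (k in 2:length(frames)) {
    fit <- rigidRegister(getXY(frames[[k]]), getXY(frames[[k - 1]]), ...)
    if (fit$failed) {
      warning(sprintf("registration of frame %d failed; using previous transform", k))
    } else {
      t <- as.vector(R %*% fit$translation) + t
      R <- R %*% fit$R
    }
    P <- applyRigid(getXY(frames[[k]]), R, t)
    out[[k]] <- data.frame(x = P[, 1], y = P[, 2])
  }
  out
}
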