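#' Minimum-image displacement for an orthorhombic box
#'
#' @param d displacement vector(s): numeric vector of length 3 or an n x 3
#'   matrix.
#' @param box length-3 vector of box edge lengths.
#' @return displacement(s) wrapped into the primary image.
#' @export
min_image <- function(d, box) {
  if (is.null(dim(d))) return(d - box * round(d / box))
  sweep(d, 2, box, function(x, b) x - b * round(x / b))
}

#' Relative-angular-distance (RAD) coordination shell of one centre
#'
#' Candidates within \code{cutoff} of the centre are sorted by distance and
#' a candidate j is retained iff no closer candidate k blocks it, i.e. iff
#' for all closer k: \code{1/r_ij^2 >= (1/r_ik^2) * cos(theta_jik)}, where
#' theta_jik is the angle at the centre between j and k. The construction is
#' parameter-free apart from the candidate cutoff and is deterministic for
#' fixed input. Note the relation is not symmetric: j in shell(i) does not
#' imply i in shell(j).
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param box length-3 box edge lengths for minimum-image distances, or NULL
#'   for no periodicity.
#' @param center row index of the centre.
#' @param candidates row indices of candidate neighbours (default: all other
#'   rows).
#' @param cutoff candidate cutoff in Angstrom (default 8).
#' @return integer vector of retained neighbour row indices, sorted by
#'   distance from the centre; attribute \code{"dist"} carries the distances.
#' @export
rad_shell <- function(positions, box = NULL, center, candidates = NULL,
                      cutoff = 8) {
  if (is.null(candidates))
    candidates <- setdiff(seq_len(nrow(positions)), center)
  candidates <- setdiff(candidates, center)
  if (!length(candidates)) return(structure(integer(0), dist = numeric(0)))
  d <- sweep(positions[candidates, , drop = FALSE], 2,
             positions[center, ], "-")
  if (!is.null(box)) d <- min_image(d, box)
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-8))
    stop("coincident atom positions at centre row ", center,
         ": RAD angle undefined")
  keep <- r <= cutoff
  candidates <- candidates[keep]; d <- d[keep, , drop = FALSE]; r <- r[keep]
  if (!length(candidates)) return(structure(integer(0), dist = numeric(0)))
  o <- order(r)
  candidates <- candidates[o]; d <- d[o, , drop = FALSE]; r <- r[o]
  u <- d / r
  m <- length(r)
  # cosang[j, k] = cos of angle at the centre between candidates j and k
  cosang <- tcrossprod(u)
  inv_r2 <- 1 / r^2
  blocked <- rep(FALSE, m)
  if (m > 1) {
    for (j in 2:m) {
      ks <- 1:(j - 1)
      blocked[j] <- any(inv_r2[j] < inv_r2[ks] * cosang[j, ks])
    }
  }
  structure(candidates[!blocked], dist = r[!blocked])
}

#' RAD coordination shells for every united atom of every frame
#'
#' Centres are the heavy atoms of the topology's united atoms. The result is
#' the solvent-structure layer the water classification, hydrogen-bond and
#' contact analyses consume.
#'
#' @param frames an \code{eemcc_frames}.
#' @param topology an \code{eemcc_topology}.
#' @param cutoff candidate cutoff, Angstrom (default 8, the usual non-bonded
#'   truncation).
#' @return an \code{eemcc_shells}: list with \code{ua} (the
#'   \code{\link{ua_table}}), \code{cutoff}, and \code{shells}, a list over
#'   frames of lists over united atoms of integer neighbour indices (rows of
#'   \code{ua}).
#' @export
build_shells <- function(frames, topology, cutoff = 8) {
  ua <- ua_table(topology)
  n_ua <- nrow(ua)
  shells <- vector("list", frames$n_frames)
  for (f in seq_len(frames$n_frames)) {
    pos <- frames$positions[ua$heavy_index, , f, drop = FALSE]
    dim(pos) <- c(n_ua, 3)
    box <- frames$box[f, ]
    # frame-wide candidate prefilter via a full min-image distance matrix
    fr <- vector("list", n_ua)
    dmat <- matrix(0, n_ua, n_ua)
    for (k in 1:3) {
      dd <- outer(pos[, k], pos[, k], "-")
      dd <- dd - box[k] * round(dd / box[k])
      dmat <- dmat + dd * dd
    }
    dmat <- sqrt(dmat)
    for (i in seq_len(n_ua)) {
      cand <- which(dmat[i, ] <= cutoff)
      cand <- cand[cand != i]
      fr[[i]] <- rad_shell(pos, box, i, cand, cutoff)
    }
    shells[[f]] <- fr
  }
  structure(list(ua = ua, cutoff = cutoff, shells = shells,
                 n_frames = frames$n_frames),
            class = "eemcc_shells")
}

#' @export
print.eemcc_shells <- function(x, ...) {
  ns <- mean(vapply(x$shells, function(fr)
    mean(lengths(fr)), numeric(1)))
  cat("eemcc coordination shells:", x$n_frames, "frames,", nrow(x$ua),
      "united atoms, mean shell size", round(ns, 2), "\n")
  invisible(x)
}
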