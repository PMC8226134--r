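#' Topological hydrogen-bond assignment
#'
#' A donor hydrogen is any H bonded to N or O. Among acceptor candidates
#' (heavy atoms of the united atoms in the donor's coordination shell,
#' excluding the donor's own united atom) the acceptor is the one with the
#' most negative qD*qA/r^2, where qD is the hydrogen's partial charge, qA
#' the acceptor heavy atom's partial charge and r their minimum-image
#' distance. If no candidate yields a negative product the hydrogen donates
#' no bond that frame. Each donor hydrogen maps to at most one acceptor.
#'
#' @param frames an \code{eemcc_frames}.
#' @param shells an \code{eemcc_shells} from \code{\link{build_shells}}.
#' @param topology an \code{eemcc_topology}.
#' @return an \code{eemcc_hbonds}: list over frames of data.frames with
#'   columns h_index (atom index of the donor hydrogen), donor_ua and
#'   acceptor_ua (row indices into \code{shells$ua}; acceptor_ua is NA when
#'   unassigned).
#' @export
assign_hbonds <- function(frames, shells, topology) {
  at <- topology$atoms
  ua <- shells$ua
  # donor hydrogens: H bonded to N or O
  b <- topology$bonds
  elem <- at$element[match(as.vector(b), at$index)]
  dim(elem) <- dim(b)
  don <- integer(0)
  if (nrow(b)) {
    h1 <- b[elem[, 1] == "H" & elem[, 2] %in% c("N", "O"), 1]
    h2 <- b[elem[, 2] == "H" & elem[, 1] %in% c("N", "O"), 2]
    don <- unique(c(h1, h2))
  }
  ua_of_atom <- at$ua_id[match(don, at$index)]
  donor_ua_row <- match(ua_of_atom, ua$ua_id)
  qd <- at$charge[match(don, at$index)]
  qa_all <- at$charge[match(ua$heavy_index, at$index)]

  out <- vector("list", frames$n_frames)
  for (f in seq_len(frames$n_frames)) {
    pos <- frames$positions[, , f, drop = FALSE]
    dim(pos) <- dim(frames$positions)[1:2]
    box <- frames$box[f, ]
    acc <- rep(NA_integer_, length(don))
    for (k in seq_along(don)) {
      sh <- shells$shells[[f]][[donor_ua_row[k]]]
      sh <- sh[sh != donor_ua_row[k]]
      if (!length(sh)) next
      d <- sweep(pos[ua$heavy_index[sh], , drop = FALSE], 2, pos[don[k], ], "-")
      d <- min_image(d, box)
      r2 <- rowSums(d * d)
      score <- qd[k] * qa_all[sh] / r2
      j <- which.min(score)
      if (score[j] < 0) acc[k] <- sh[j]
    }
    out[[f]] <- data.frame(h_index = don, donor_ua = donor_ua_row,
                           acceptor_ua = acc)
  }
  structure(list(frames = out, n_frames = frames$n_frames),
            class = "eemcc_hbonds")
}
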