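#' Orientational statistics of water from donor/acceptor events
#'
#' For each water molecule and frame, the observation is its coordination
#' shell (neighbour counts per species label), the species it donated
#' hydrogen bonds to and the species it accepted from. Observations are
#' pooled by shell type (the sorted multiset of neighbour species labels)
#' and reduced to, per type c and neighbour species i: p(Di) and p(Ai), the
#' weighted fractions of donation/acceptance events involving species i;
#' the hydrogen-bond bias p(HBi) = pD*pA/(pD+pA)^2 (0.25 when unbiased, and
#' invariant under swapping donor and acceptor roles); the mean neighbour
#' counts Ni and Nc; the shell-average bias p(HBav) = sum p(HBi) Ni / Nc;
#' and the effective neighbour count Neff = sum p(HBi) Ni / 0.25. Waters
#' with an empty shell are excluded and tallied.
#'
#' @param shell list of named numeric vectors (neighbour counts per species
#'   label), one per observation.
#' @param donations list of character vectors of donation-target species.
#' @param acceptances list of character vectors of acceptance-source species.
#' @param weights optional per-observation weights.
#' @return an \code{eemcc_orient_stats}: list with \code{shell_types}
#'   (data.frame: key, p_c, Nc, p_HBav, Neff), \code{by_species}
#'   (data.frame: key, species, Ni, pD, pA, pHB) and \code{diagnostics}.
#' @export
orientational_stats_from_events <- function(shell, donations, acceptances,
                                            weights = NULL) {
  n <- length(shell)
  stopifnot(length(donations) == n, length(acceptances) == n)
  if (is.null(weights)) weights <- rep(1, n)
  empty <- vapply(shell, function(s) length(s) == 0 || sum(s) == 0,
                  logical(1))
  n_empty <- sum(empty)
  shell <- shell[!empty]; donations <- donations[!empty]
  acceptances <- acceptances[!empty]; weights <- weights[!empty]
  if (!length(shell)) stop("no non-empty shell observations")

  keys <- vapply(shell, function(s) {
    s <- s[s > 0]
    o <- order(names(s))
    paste(sprintf("%s:%g", names(s)[o], s[o]), collapse = "|")
  }, character(1))
  uk <- sort(unique(keys))
  wtot <- sum(weights)

  st <- list(); bs <- list()
  for (kk in uk) {
    sel <- which(keys == kk)
    w <- weights[sel]
    species <- sort(unique(unlist(lapply(shell[sel], names))))
    Ni <- vapply(species, function(sp)
      sum(w * vapply(shell[sel], function(s)
        if (sp %in% names(s)) s[[sp]] else 0, numeric(1))) / sum(w),
      numeric(1))
    cnt <- function(evlist) vapply(species, function(sp)
      sum(w * vapply(evlist, function(e) sum(e == sp), numeric(1))),
      numeric(1))
    D <- cnt(donations[sel]); A <- cnt(acceptances[sel])
    pD <- if (sum(D) > 0) D / sum(D) else D * 0
    pA <- if (sum(A) > 0) A / sum(A) else A * 0
    pHB <- ifelse(pD + pA > 0, pD * pA / (pD + pA)^2, 0)
    Nc <- sum(Ni)
    p_HBav <- sum(pHB * Ni) / Nc
    Neff <- sum(pHB * Ni) / 0.25
    st[[kk]] <- data.frame(key = kk, p_c = sum(w) / wtot, Nc = Nc,
                           p_HBav = p_HBav, Neff = Neff,
                           stringsAsFactors = FALSE)
    bs[[kk]] <- data.frame(key = kk, species = species, Ni = Ni, pD = pD,
                           pA = pA, pHB = pHB, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  structure(
    list(shell_types = do.call(rbind, c(st, list(make.row.names = FALSE))),
         by_species = do.call(rbind, c(bs, list(make.row.names = FALSE))),
         diagnostics = list(n_empty_shells = n_empty,
                            n_observations = n - n_empty)),
    class = "eemcc_orient_stats"
  )
}

#' Donor/acceptor probabilities of shell waters from geometry
#'
#' Builds the orientational-statistics observations from coordination
#' shells and topological hydrogen bonds. Neighbour waters are labelled by
#' the solute they are closest to when they sit in a solute's coordination
#' shell, and \code{"bulk"} otherwise; neighbouring solutes are labelled by
#' their species role.
#'
#' @param frames an \code{eemcc_frames}.
#' @param shells an \code{eemcc_shells}.
#' @param hbonds an \code{eemcc_hbonds} from \code{\link{assign_hbonds}}.
#' @param topology an \code{eemcc_topology}.
#' @param weights optional per-frame weights.
#' @return an \code{eemcc_orient_stats} (see
#'   \code{\link{orientational_stats_from_events}}).
#' @export
donor_acceptor_probabilities <- function(frames, shells, hbonds, topology,
                                         weights = NULL) {
  ua <- shells$ua
  n_ua <- nrow(ua)
  is_water <- ua$species_role == "water"
  wrow <- which(is_water)
  nf <- shells$n_frames
  if (is.null(weights)) weights <- rep(1, nf)

  sh_l <- list(); don_l <- list(); acc_l <- list(); w_l <- numeric(0)
  for (f in seq_len(nf)) {
    fr <- shells$shells[[f]]
    # proximity label of each water united atom
    lab <- ifelse(is_water, "bulk", ua$species_role)
    best <- rep(Inf, n_ua)
    for (u in which(!is_water)) {
      sh <- fr[[u]]
      d <- attr(sh, "dist")
      for (j in seq_along(sh)) {
        v <- sh[j]
        if (is_water[v] && d[j] < best[v]) {
          best[v] <- d[j]
          lab[v] <- ua$species_role[u]
        }
      }
    }
    hb <- hbonds$frames[[f]]
    for (v in wrow) {
      sh <- fr[[v]]
      counts <- if (length(sh)) table(lab[sh]) else table(character(0))
      don <- hb$acceptor_ua[hb$donor_ua == v & !is.na(hb$acceptor_ua)]
      acc <- hb$donor_ua[!is.na(hb$acceptor_ua) & hb$acceptor_ua == v &
                           hb$donor_ua != v]
      sh_l[[length(sh_l) + 1]] <- stats::setNames(as.numeric(counts),
                                                  names(counts))
      don_l[[length(don_l) + 1]] <- lab[don]
      acc_l[[length(acc_l) + 1]] <- lab[acc]
      w_l <- c(w_l, weights[f])
    }
  }
  orientational_stats_from_events(sh_l, don_l, acc_l, weights = w_l)
}

#' Orientational entropy of water from pooled shell statistics
#'
#' S = kB * sum over shell types c of
#' p(c) log((Neff * pi)^(3/2) * p(HBav) / sigma) with sigma the water
#' symmetry number (2). In the bulk limit (four unbiased water neighbours)
#' this gives S/kB = log((4 pi)^(3/2) / 8) ~ 1.717. Shell types with
#' Neff * p(HBav) = 0 carry no orientational freedom for the logarithm; by
#' default they are dropped and p(c) renormalised over the remaining types
#' (the count is reported in the result's diagnostics).
#'
#' @param stats an \code{eemcc_orient_stats}.
#' @param constants \code{\link{eemcc_constants}}.
#' @param exponent \code{"neff_pi_3_2"} for (Neff*pi)^(3/2) (default) or
#'   \code{"neff_3_2_pi_1_2"} for Neff^(3/2)*pi^(1/2); the two differ by a
#'   constant offset per shell type and must be pinned before comparing
#'   absolute entropies.
#' @return entropy in J/K/mol, with attributes \code{"per_type"} (data.frame
#'   of per-shell-type contributions) and \code{"n_dropped"}.
#' @export
orientational_entropy <- function(stats, constants = eemcc_constants(),
                                  exponent = c("neff_pi_3_2",
                                               "neff_3_2_pi_1_2")) {
  exponent <- match.arg(exponent)
  st <- stats$shell_types
  ok <- st$Neff * st$p_HBav > 0
  n_dropped <- sum(!ok)
  st <- st[ok, , drop = FALSE]
  if (!nrow(st)) return(structure(0, per_type = st, n_dropped = n_dropped))
  pc <- st$p_c / sum(st$p_c)
  arg <- switch(exponent,
                neff_pi_3_2 = (st$Neff * pi)^1.5,
                neff_3_2_pi_1_2 = st$Neff^1.5 * sqrt(pi))
  term <- log(arg * st$p_HBav / constants$sigma_water)
  S <- constants$kB_entropy * sum(pc * term)
  structure(S,
            per_type = data.frame(key = st$key, p_c = pc,
                                  term_kB = term),
            n_dropped = n_dropped)
}
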