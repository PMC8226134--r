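#' Residue ionisation bookkeeping at a given pH
#'
#' Integer titration model: a basic group (Arg, Lys, His, N-terminus)
#' carries +1 iff pH < pKa; an acidic group (Asp, Glu, C-terminus, Tyr,
#' free Cys) carries -1 iff pH > pKa. Cysteines engaged in disulfide bonds
#' do not titrate. Default side-chain pKa values are the standard
#' free-amino-acid set (Asp 3.65, Glu 4.25, His 6.0, Cys 8.3, Tyr 10.07,
#' Lys 10.53, Arg 12.48; N-terminus 9.6, C-terminus 3.6).
#'
#' @name titration
NULL

DEFAULT_PKA <- c(D = 3.65, E = 4.25, H = 6.0, C = 8.3, Y = 10.07,
                 K = 10.53, R = 12.48, nterm = 9.6, cterm = 3.6)

#' Read a one-letter protein sequence from a FASTA file
#'
#' @param path FASTA file.
#' @return character vector of one-letter residue codes.
#' @export
read_protein_sequence <- function(path) {
  fa <- bio3d::read.fasta(path)
  toupper(as.vector(fa$ali[1, ]))
}

#' Count basic residues protonated at a given pH
#'
#' Basic side chains (Arg, Lys, His) whose pKa exceeds the pH; at pH 9 with
#' the default pKa set this counts Arg and Lys but not His.
#'
#' @param seq character vector of one-letter residue codes.
#' @param pH the pH.
#' @param pka named pKa vector (see \code{\link{titration}}).
#' @return integer count.
#' @export
count_basic_residues <- function(seq, pH = 7, pka = DEFAULT_PKA) {
  basics <- c("R", "K", "H")
  sum(vapply(basics, function(r) if (pka[[r]] > pH) sum(seq == r) else 0L,
             numeric(1)))
}

#' Net formal charge of a protein chain at a given pH
#'
#' Applies the integer titration rule of \code{\link{titration}} over side
#' chains and termini. Disulfide-bonded cysteines are excluded from
#' titration via \code{n_disulfides} (each bond retires two Cys).
#'
#' @param seq character vector of one-letter residue codes.
#' @param pH the pH.
#' @param n_disulfides number of disulfide bonds in the chain.
#' @param pka named pKa vector.
#' @param termini include N- and C-terminal charges (default TRUE).
#' @return the integer net charge.
#' @export
net_charge <- function(seq, pH = 7, n_disulfides = 0, pka = DEFAULT_PKA,
                       termini = TRUE) {
  pos <- sum(vapply(c("R", "K", "H"), function(r)
    if (pH < pka[[r]]) sum(seq == r) else 0L, numeric(1)))
  n_cys_free <- max(0L, sum(seq == "C") - 2L * n_disulfides)
  neg <- sum(vapply(c("D", "E"), function(r)
    if (pH > pka[[r]]) sum(seq == r) else 0L, numeric(1))) +
    (if (pH > pka[["C"]]) n_cys_free else 0L) +
    (if (pH > pka[["Y"]]) sum(seq == "Y") else 0L)
  if (termini) {
    pos <- pos + (pH < pka[["nterm"]])
    neg <- neg + (pH > pka[["cterm"]])
  }
  as.integer(pos - neg)
}
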