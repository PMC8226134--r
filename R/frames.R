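#' Trajectory frame ensemble
#'
#' An \code{eemcc_frames} object holds the per-frame quantities the analysis
#' consumes: positions (Angstrom), forces (kJ/mol/Angstrom), per-atom
#' potential and kinetic energies (kJ/mol), orthorhombic box edge lengths
#' (Angstrom), frame times, and optionally a per-frame bias potential
#' (kJ/mol). Atom count is constant across frames and rows are ordered by
#' atom id so they align with the topology's atom table.
#'
#' @name eemcc_frames
NULL

#' Construct a frame ensemble from arrays
#'
#' @param time numeric vector of frame times (must be non-decreasing).
#' @param box n_frames x 3 matrix of box edge lengths (Angstrom), or a
#'   length-3 vector recycled to all frames. Orthorhombic only.
#' @param positions n_atoms x 3 x n_frames array, Angstrom.
#' @param forces n_atoms x 3 x n_frames array, kJ/mol/Angstrom.
#' @param pe n_atoms x n_frames matrix of per-atom potential energy, kJ/mol.
#' @param ke n_atoms x n_frames matrix of per-atom kinetic energy, kJ/mol.
#' @param bias optional per-frame bias potential, kJ/mol.
#' @return an \code{eemcc_frames}.
#' @export
as_frames <- function(time, box, positions, forces = NULL, pe = NULL,
                      ke = NULL, bias = NULL) {
  nf <- length(time)
  if (nf < 1) stop("ensemble must contain at least one frame")
  if (is.null(dim(positions)) || length(dim(positions)) != 3 ||
      dim(positions)[2] != 3)
    stop("positions must be an n_atoms x 3 x n_frames array")
  na <- dim(positions)[1]
  if (dim(positions)[3] != nf)
    stop("atom-count/frame mismatch: positions have ", dim(positions)[3],
         " frames but ", nf, " times were given")
  if (is.unsorted(time)) stop("frames must be time-ordered")
  if (is.vector(box) && length(box) == 3)
    box <- matrix(box, nf, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (!all(dim(box) == c(nf, 3))) stop("box must be n_frames x 3")
  if (any(box <= 0)) stop("box edge lengths must be positive")
  chk3 <- function(a, nm) {
    if (is.null(a)) return(array(0, dim = c(na, 3, nf)))
    if (!all(dim(a) == c(na, 3, nf))) stop(nm, " has wrong dimensions")
    a
  }
  chk2 <- function(a, nm) {
    if (is.null(a)) return(matrix(0, na, nf))
    a <- as.matrix(a)
    if (!all(dim(a) == c(na, nf))) stop(nm, " has wrong dimensions")
    a
  }
  if (!is.null(bias)) {
    if (length(bias) != nf) stop("bias must have one value per frame")
    if (any(!is.finite(bias))) stop("non-finite bias value")
  }
  structure(
    list(time = as.numeric(time), box = box, positions = positions,
         forces = chk3(forces, "forces"), pe = chk2(pe, "pe"),
         ke = chk2(ke, "ke"), bias = bias,
         n_atoms = na, n_frames = nf),
    class = "eemcc_frames"
  )
}

#' @export
print.eemcc_frames <- function(x, ...) {
  cat("eemcc frame ensemble:", x$n_frames, "frames,", x$n_atoms, "atoms,",
      if (is.null(x$bias)) "no bias" else "with bias", "\n")
  invisible(x)
}

DUMP_FIELDS <- c("id", "x", "y", "z", "fx", "fy", "fz", "pe", "ke")

#' Read trajectory frames from a columnar dump file
#'
#' Parses the LAMMPS-dump-style text dialect: blocks of
#' \code{ITEM: TIMESTEP}, \code{ITEM: NUMBER OF ATOMS},
#' \code{ITEM: BOX BOUNDS} (three lo/hi lines, orthorhombic only) and
#' \code{ITEM: ATOMS <columns>}. Comment lines beginning '#' are ignored.
#' Frames are sorted by atom id.
#'
#' @param path dump file.
#' @param columns named character vector mapping the package fields
#'   \code{id,x,y,z,fx,fy,fz,pe,ke} to column labels in the file's
#'   \code{ITEM: ATOMS} header. Defaults to the common LAMMPS labels with
#'   per-atom energies as \code{c_pe}/\code{c_ke}.
#' @param scales optional named numeric vector of multiplicative unit
#'   conversions applied to fields on read (e.g.
#'   \code{c(x = 10, y = 10, z = 10)} for a dump written in nm).
#' @return an \code{eemcc_frames}.
#' @export
read_frames <- function(path,
                        columns = c(id = "id", x = "x", y = "y", z = "z",
                                    fx = "fx", fy = "fy", fz = "fz",
                                    pe = "c_pe", ke = "c_ke"),
                        scales = NULL) {
  miss <- setdiff(DUMP_FIELDS, names(columns))
  if (length(miss))
    stop("column map is missing fields: ", paste(miss, collapse = ", "))
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (!length(starts)) stop("no frames found in ", path)
  nf <- length(starts)
  ends <- c(starts[-1] - 1L, length(lines))

  frames <- vector("list", nf)
  times <- numeric(nf)
  boxes <- matrix(0, nf, 3)
  na_ref <- NA_integer_
  for (f in seq_len(nf)) {
    blk <- lines[starts[f]:ends[f]]
    times[f] <- as.numeric(blk[2])
    nat_line <- grep("^ITEM: NUMBER OF ATOMS", blk)
    nat <- as.integer(blk[nat_line + 1])
    if (is.na(na_ref)) na_ref <- nat
    if (nat != na_ref)
      stop("atom-count mismatch: frame ", f, " has ", nat,
           " atoms, expected ", na_ref)
    box_line <- grep("^ITEM: BOX BOUNDS", blk)
    if (grepl("xy|xz|yz", blk[box_line]))
      stop("triclinic boxes are not supported")
    for (d in 1:3) {
      lohi <- as.numeric(strsplit(trimws(blk[box_line + d]), "\\s+")[[1]])
      boxes[f, d] <- lohi[2] - lohi[1]
    }
    at_line <- grep("^ITEM: ATOMS", blk)
    hdr <- strsplit(trimws(sub("^ITEM: ATOMS", "", blk[at_line])), "\\s+")[[1]]
    col_idx <- match(columns, hdr)
    if (anyNA(col_idx))
      stop("dump is missing declared column(s): ",
           paste(columns[is.na(col_idx)], collapse = ", "))
    dat <- utils::read.table(text = blk[(at_line + 1):(at_line + nat)])
    if (ncol(dat) != length(hdr)) stop("malformed atom block in frame ", f)
    dat <- dat[, col_idx]
    names(dat) <- DUMP_FIELDS
    if (!is.null(scales))
      for (nm in names(scales)) dat[[nm]] <- dat[[nm]] * scales[[nm]]
    frames[[f]] <- dat[order(dat$id), ]
  }
  na <- na_ref
  pos <- array(0, c(na, 3, nf)); frc <- array(0, c(na, 3, nf))
  pe <- matrix(0, na, nf); ke <- matrix(0, na, nf)
  for (f in seq_len(nf)) {
    d <- frames[[f]]
    pos[, , f] <- as.matrix(d[, c("x", "y", "z")])
    frc[, , f] <- as.matrix(d[, c("fx", "fy", "fz")])
    pe[, f] <- d$pe; ke[, f] <- d$ke
  }
  as_frames(times, boxes, pos, frc, pe, ke)
}

#' Write trajectory frames in the columnar dump dialect
#'
#' Inverse of \code{\link{read_frames}} with the default column labels;
#' values are printed with enough digits for a lossless round trip at
#' printed precision.
#'
#' @param frames an \code{eemcc_frames}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(frames$n_frames)) {
    writeLines(c("ITEM: TIMESTEP", format(frames$time[f], digits = 15),
                 "ITEM: NUMBER OF ATOMS", as.character(frames$n_atoms),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", frames$box[f, 1]),
                 sprintf("0 %.10g", frames$box[f, 2]),
                 sprintf("0 %.10g", frames$box[f, 3]),
                 "ITEM: ATOMS id x y z fx fy fz c_pe c_ke"), con)
    d <- cbind(seq_len(frames$n_atoms), frames$positions[, , f],
               frames$forces[, , f], frames$pe[, f], frames$ke[, f])
    writeLines(apply(d, 1, function(r)
      paste(c(sprintf("%d", as.integer(r[1])),
              sprintf("%.10g", r[-1])), collapse = " ")), con)
  }
  invisible(path)
}

#' Read per-frame bias values from a COLVAR-style file
#'
#' Two whitespace-separated columns (time, bias in kJ/mol); '#' lines are
#' comments. Each frame of \code{frames} is matched to the bias row nearest
#' in time; an uncovered frame (no bias time within \code{tol}) is an error,
#' as is a non-monotonic time column.
#'
#' @param path bias file.
#' @param frames an \code{eemcc_frames} whose times must be covered.
#' @param tol matching tolerance in time units (default 1e-6 * time span,
#'   floored at 1e-9).
#' @return numeric vector of bias values, one per frame.
#' @export
read_bias <- function(path, frames, tol = NULL) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("bias file must have (time, bias) columns")
  bt <- tab[[1]]; bv <- tab[[2]]
  if (is.unsorted(bt, strictly = TRUE))
    stop("bias file times must be strictly increasing")
  if (is.null(tol)) tol <- max(1e-9, 1e-6 * diff(range(c(bt, frames$time))))
  idx <- vapply(frames$time, function(t) which.min(abs(bt - t)), integer(1))
  off <- abs(bt[idx] - frames$time)
  if (any(off > tol))
    stop("frame at time ", frames$time[which(off > tol)[1]],
         " is not covered by the bias file (nearest bias time off by ",
         signif(max(off), 3), ")")
  bv[idx]
}

#' Attach bias values to an ensemble
#'
#' @param frames an \code{eemcc_frames}.
#' @param bias numeric per-frame bias, kJ/mol.
#' @return the ensemble with \code{bias} set.
#' @export
set_bias <- function(frames, bias) {
  as_frames(frames$time, frames$box, frames$positions, frames$forces,
            frames$pe, frames$ke, bias = bias)
}
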