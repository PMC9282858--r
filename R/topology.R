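#' @title System model: Topology, Frame, Trajectory
#' @description Lightweight S3 containers for a molecular system. A
#'   `Topology` is a static atom table with derived residue bookkeeping and
#'   role tags; a `Frame` is one set of coordinates (with optional
#'   orthorhombic box); a `Trajectory` is an ordered list of frames bound to
#'   a topology.
#' @name memdyn-model
NULL

.default_water_names <- c("HOH", "WAT", "TIP3", "SOL")

#' Construct a topology from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (author residue number, 1-based), `resname` (3-letter code),
#'   `chain` (single character), and optionally `role`. Atom order is
#'   meaningful and preserved; atoms of one residue must be contiguous.
#' @param water_names residue names treated as water when assigning roles.
#' @param substrate_chains chains tagged with role `substrate` rather than
#'   `protein` (the enzyme/substrate split is by chain).
#' @param lipid_names residue names tagged as `lipid`.
#' @return object of class `Topology`: the atom table plus a derived
#'   residue table (`chain`, `resid`, `resname`, `first`, `last` atom rows).
#' @export
topology <- function(atoms, water_names = .default_water_names,
                     substrate_chains = character(),
                     lipid_names = c("POPC", "DDM", "LIP", "PC")) {
  req <- c("serial", "name", "element", "resid", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial)) {
    warning("duplicate atom serials; renumbering sequentially")
    atoms$serial <- seq_len(nrow(atoms))
  }
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  if (is.null(atoms$role)) {
    atoms$role <- ifelse(atoms$resname %in% water_names, "water",
                  ifelse(atoms$resname %in% lipid_names, "lipid",
                  ifelse(atoms$resname %in% .amino3,
                         ifelse(atoms$chain %in% substrate_chains, "substrate", "protein"),
                         "other")))
  }
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  brk <- c(TRUE, key[-1] != key[-length(key)])
  if (anyDuplicated(unique(key)) || any(duplicated(key[brk]))) {
    stop("atoms of one residue are not contiguous")
  }
  first <- which(brk)
  last <- c(first[-1] - 1L, nrow(atoms))
  residues <- data.frame(chain = atoms$chain[first], resid = atoms$resid[first],
                         resname = atoms$resname[first],
                         first = first, last = last, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues), class = "Topology")
}

.amino3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
             "HSD","HSE","HSP","HID","HIE","HIP","MSE")

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, chains [%s]\n",
              nrow(x$atoms), nrow(x$residues),
              paste(unique(x$atoms$chain), collapse = " ")))
  tab <- table(x$atoms$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `Topology`.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a single coordinate frame
#'
#' @param xyz N x 3 numeric matrix of coordinates in Angstrom.
#' @param box optional length-3 vector of orthorhombic box edges (Angstrom).
#' @param time optional time stamp in ns.
#' @return object of class `Frame`.
#' @export
frame <- function(xyz, box = NULL, time = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("frame coordinates must be N x 3")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive orthorhombic edge lengths")
    }
  }
  structure(list(xyz = xyz, box = box, time = time), class = "Frame")
}

#' Construct a trajectory
#'
#' The unit of replication for all downstream metrics: one simulation run,
#' analyzed per replicate and aggregated with [aggregate_replicates()].
#'
#' @param top `Topology` the frames refer to.
#' @param frames list of `Frame` objects, all with `n_atoms(top)` rows.
#' @param label free-form label (replicate id, environment).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(top, frames, label = "") {
  if (!inherits(top, "Topology")) stop("top must be a Topology")
  if (!length(frames)) stop("trajectory needs at least one frame")
  na <- n_atoms(top)
  for (k in seq_along(frames)) {
    if (!inherits(frames[[k]], "Frame")) stop("frames must be Frame objects")
    if (nrow(frames[[k]]$xyz) != na) {
      stop(sprintf("frame %d has %d atoms, topology has %d",
                   k, nrow(frames[[k]]$xyz), na))
    }
  }
  times <- vapply(frames, function(f) if (is.null(f$time)) NA_real_ else f$time, 0)
  if (!anyNA(times) && length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = top, frames = frames, label = label),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames x %d atoms%s\n", x$label,
              length(x$frames), n_atoms(x$topology),
              if (is.null(x$frames[[1]]$box)) "" else " (periodic)"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Residue label strings ("A/162/ASP") for a topology
#' @param top a `Topology`.
#' @keywords internal
residue_labels <- function(top) {
  with(top$residues, paste(chain, resid, resname, sep = "/"))
}
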