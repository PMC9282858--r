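#' @title Structure and trajectory I/O
#' @description Fixed-column PDB reading/writing (ATOM/HETATM/MODEL/ENDMDL/
#'   CRYST1) and a plain-text `xyz-table` trajectory dialect. Only
#'   orthorhombic boxes are supported; triclinic CRYST1 records raise an
#'   explicit error.
#' @name memdyn-io
NULL

#' Read a PDB file into a topology and first-frame coordinates
#'
#' Parses ATOM/HETATM records by fixed columns. Roles are assigned from
#' residue names (waters from `water_names`, standard amino acids to
#' protein/substrate by chain, known amphiphiles to lipid). A CRYST1
#' record, if present and orthorhombic (90/90/90 angles), populates the
#' frame box.
#'
#' @inheritParams topology
#' @param path PDB file path.
#' @return list with elements `topology` (a `Topology`) and `frame`
#'   (a `Frame` holding the first MODEL's coordinates).
#' @export
read_pdb <- function(path, water_names = .default_water_names,
                     substrate_chains = character(),
                     lipid_names = c("POPC", "DDM", "LIP", "PC")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  box <- .parse_cryst1(lines)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  end1 <- which(rec == "ENDMDL")[1]
  if (!is.na(end1)) keep <- keep & seq_along(lines) < end1
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  parsed <- .parse_atom_lines(lines[idx], idx)
  top <- topology(parsed$atoms, water_names = water_names,
                  substrate_chains = substrate_chains,
                  lipid_names = lipid_names)
  list(topology = top, frame = frame(parsed$xyz, box = box))
}

.parse_cryst1 <- function(lines) {
  ci <- which(substr(lines, 1, 6) == "CRYST1")[1]
  if (is.na(ci)) return(NULL)
  ln <- lines[ci]
  vals <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                        substr(ln, 25, 33), substr(ln, 34, 40),
                                        substr(ln, 41, 47), substr(ln, 48, 54))))
  if (anyNA(vals[1:3])) stop("unparseable CRYST1 record at line ", ci)
  ang <- vals[4:6]
  if (any(abs(ang - 90) > 1e-3, na.rm = TRUE)) {
    stop("triclinic box in CRYST1 is unsupported (orthorhombic only)")
  }
  vals[1:3]
}

.parse_atom_lines <- function(ln, lineno) {
  n <- length(ln)
  too_short <- nchar(ln) < 54
  if (any(too_short)) {
    stop(sprintf("malformed ATOM/HETATM record (line %d): fewer than 54 columns",
                 lineno[which(too_short)[1]]))
  }
  num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
  serial <- num(7, 11)
  name <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resid <- num(23, 26)
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  elem <- trimws(substr(ln, 77, 78))
  bad <- which(is.na(serial) | is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                 lineno[bad[1]], ln[bad[1]]))
  }
  # fall back to the first letter of the atom name when the element
  # column is absent (common in minimal hand-written files)
  noel <- !nzchar(elem)
  elem[noel] <- substr(gsub("[^A-Za-z].*", "", sub("^[0-9]+", "", name[noel])), 1, 1)
  atoms <- data.frame(serial = as.integer(serial), name = name, element = elem,
                      resid = as.integer(resid), resname = resname,
                      chain = chain, stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = cbind(x, y, z))
}

.format_atom_line <- function(serial, name, resname, chain, resid, xyz, element) {
  # PDB convention: 1-3 character names start in column 14
  nm <- ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial %% 100000L, nm, resname, chain, resid %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], element)
}

#' Write a topology + frame (or whole trajectory) as (multi-model) PDB
#'
#' @param top `Topology`.
#' @param frames a `Frame`, or list of `Frame`s (written as MODEL blocks).
#' @param path output path.
#' @export
write_pdb <- function(top, frames, path) {
  if (inherits(frames, "Frame")) frames <- list(frames)
  out <- character(0)
  box <- frames[[1]]$box
  if (!is.null(box)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          box[1], box[2], box[3], 90, 90, 90))
  }
  a <- top$atoms
  multi <- length(frames) > 1
  for (k in seq_along(frames)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    out <- c(out, .format_atom_line(a$serial, a$name, a$resname, a$chain,
                                    a$resid, frames[[k]]$xyz, a$element))
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Two dialects: `multi-model-pdb` (MODEL/ENDMDL blocks) and `xyz-table`,
#' a plain CSV defined by this package: a header line `# natoms <N>`,
#' optional per-frame `#BOX fx,bx,by,bz` comment lines, optional per-frame
#' `#TIME f,t` lines, then one row `frame,serial,x,y,z` per atom per frame.
#'
#' @param path file path.
#' @param top `Topology` the frames must match.
#' @param dialect `"multi-model-pdb"` or `"xyz-table"`.
#' @param label trajectory label.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, top, dialect = c("multi-model-pdb", "xyz-table"),
                            label = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "multi-model-pdb") .read_traj_pdb(path, top, label)
  else .read_traj_xyz(path, top, label)
}

.read_traj_pdb <- function(path, top, label) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: ", path)
  box <- .parse_cryst1(lines)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (!length(starts)) starts <- 1L
  ends <- c(starts[-1], length(lines) + 1L)
  na <- n_atoms(top)
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:(ends[k] - 1L)]
    sel <- substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")
    if (sum(sel) != na) {
      stop(sprintf("frame %d has %d atoms, topology has %d", k, sum(sel), na))
    }
    parsed <- .parse_atom_lines(blk[sel], which(sel) + starts[k] - 1L)
    frames[[k]] <- frame(parsed$xyz, box = box)
  }
  trajectory(top, frames, label = label)
}

.read_traj_xyz <- function(path, top, label) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: ", path)
  hdr <- grep("^# *natoms", lines, value = TRUE)
  na_hdr <- if (length(hdr)) as.integer(sub(".*natoms *", "", hdr[1])) else NA
  boxln <- grep("^#BOX ", lines, value = TRUE)
  timeln <- grep("^#TIME ", lines, value = TRUE)
  boxes <- NULL
  if (length(boxln)) {
    bm <- do.call(rbind, lapply(strsplit(sub("^#BOX ", "", boxln), ","),
                                as.numeric))
    boxes <- bm  # columns: frame, bx, by, bz
  }
  times <- NULL
  if (length(timeln)) {
    times <- do.call(rbind, lapply(strsplit(sub("^#TIME ", "", timeln), ","),
                                   as.numeric))
  }
  dat <- lines[!startsWith(lines, "#")]
  dat <- dat[nzchar(dat)]
  if (!length(dat)) stop("xyz-table has no data rows: ", path)
  m <- matrix(as.numeric(unlist(strsplit(dat, ","), use.names = FALSE)),
              ncol = 5, byrow = TRUE)
  na <- n_atoms(top)
  if (!is.na(na_hdr) && na_hdr != na) {
    stop(sprintf("xyz-table declares %d atoms, topology has %d", na_hdr, na))
  }
  fids <- unique(m[, 1])
  rows_by_frame <- split(seq_len(nrow(m)), m[, 1])
  frames <- vector("list", length(fids))
  for (k in seq_along(fids)) {
    rows <- m[rows_by_frame[[as.character(fids[k])]], , drop = FALSE]
    if (nrow(rows) != na) {
      stop(sprintf("frame %d has %d atoms, topology has %d", k, nrow(rows), na))
    }
    rows <- rows[order(rows[, 2]), , drop = FALSE]
    bx <- if (!is.null(boxes)) {
      hit <- which(boxes[, 1] == fids[k])
      if (length(hit)) boxes[hit[1], 2:4] else NULL
    } else NULL
    tk <- if (!is.null(times)) {
      hit <- which(times[, 1] == fids[k])
      if (length(hit)) times[hit[1], 2] else NULL
    } else NULL
    frames[[k]] <- frame(rows[, 3:5, drop = FALSE], box = bx, time = tk)
  }
  trajectory(top, frames, label = label)
}

#' Write a trajectory
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @param dialect `"multi-model-pdb"` or `"xyz-table"`.
#' @export
write_trajectory <- function(traj, path,
                             dialect = c("multi-model-pdb", "xyz-table")) {
  dialect <- match.arg(dialect)
  if (dialect == "multi-model-pdb") {
    return(write_pdb(traj$topology, traj$frames, path))
  }
  na <- n_atoms(traj$topology)
  serial <- traj$topology$atoms$serial
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# natoms %d", na), con)
  writeLines("# frame,serial,x,y,z", con)
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    if (!is.null(f$box)) {
      writeLines(sprintf("#BOX %d,%.6f,%.6f,%.6f", k, f$box[1], f$box[2], f$box[3]), con)
    }
    if (!is.null(f$time)) writeLines(sprintf("#TIME %d,%.6f", k, f$time), con)
    writeLines(sprintf("%d,%d,%.6f,%.6f,%.6f", k, serial,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}
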