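#' Trajectory container
#'
#' A minimal in-memory trajectory: an atom table, a coordinate array and an
#' orthorhombic periodic box. Coordinates are in nanometres throughout.
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{residue_name}, \code{residue_number}, \code{chain_id},
#'   \code{element}, \code{role}. Missing columns are filled with defaults;
#'   roles are assigned from residue/atom names via \code{\link{atom_role}}
#'   when absent.
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (a single
#'   \code{n_atoms x 3} matrix is promoted to one frame).
#' @param box NULL (non-periodic) or numeric: either a length-3 vector of
#'   orthorhombic edge lengths (nm), constant across frames, or an
#'   \code{n_frames x 3} matrix.
#' @param times_ps frame times in picoseconds (default \code{0:(n-1)}).
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(atoms, coords, box = NULL, times_ps = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]; n_frames <- dim(coords)[3]
  if (!all(is.finite(coords))) stop_data("non-finite coordinates")
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) != n_atoms)
    stop_usage("atom table (", nrow(atoms), ") and coords (", n_atoms,
               ") disagree")
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(n_atoms)
  if (anyDuplicated(atoms$atom_id)) stop_data("atom_ids must be unique")
  if (is.null(atoms$atom_name)) atoms$atom_name <- "X"
  if (is.null(atoms$residue_name)) atoms$residue_name <- "UNK"
  if (is.null(atoms$residue_number)) atoms$residue_number <- 1L
  if (is.null(atoms$chain_id)) atoms$chain_id <- "A"
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$atom_name, atoms$residue_name)
  if (is.null(atoms$role)) atoms$role <- assign_roles(atoms)
  if (!is.null(box)) {
    if (is.matrix(box)) {
      stopifnot(ncol(box) == 3L, nrow(box) == n_frames)
    } else {
      stopifnot(length(box) == 3L)
      box <- matrix(box, n_frames, 3L, byrow = TRUE)
    }
    if (any(box <= 0)) stop_data("box edges must be positive")
  }
  if (is.null(times_ps)) times_ps <- as.double(seq_len(n_frames) - 1L)
  structure(list(atoms = atoms, coords = coords, box = box,
                 times_ps = times_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " atoms, ", dim(x$coords)[3],
      " frames, ", if (is.null(x$box)) "no box" else
        paste0("box ", paste(signif(x$box[1, ], 4), collapse = " x "), " nm"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms of a trajectory
#' @param traj a \code{\link{trajectory}}.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Classify an atom into its interaction role
#'
#' Pure function of residue name, atom name and the C-terminal flag,
#' following the conventions of cation coordination analysis:
#' carboxylate carbons (Asp CG, Glu CD, C-terminal C), backbone carbonyl
#' oxygens (O), Gln side-chain carbonyl oxygen (OE1), hydroxyl oxygens
#' (Ser OG, Thr OG1), side-chain amino/amine nitrogens (Gln NE2,
#' Arg NE/NH1/NH2, Lys NZ) and the monatomic ions calcium, sodium and
#' chloride.
#'
#' @param residue_name 3-letter residue or ion residue name (e.g. "ASP",
#'   "CA", "NA", "CL"; common force-field ion aliases accepted).
#' @param atom_name atom name (e.g. "CG", "OE1").
#' @param is_cterm logical: atom belongs to a C-terminal residue.
#' @return role string; "other" when no rule matches.
#' @export
atom_role <- function(residue_name, atom_name, is_cterm = FALSE) {
  rn <- toupper(residue_name); an <- toupper(atom_name)
  ion_res <- rn %in% c("CA", "CAL", "CA2", "CA2+", "NA", "SOD", "NA+",
                       "CL", "CLA", "CL-")
  out <- rep("other", length(rn))
  out[ion_res & rn %in% c("CA", "CAL", "CA2", "CA2+")] <- "calcium"
  out[ion_res & rn %in% c("NA", "SOD", "NA+")] <- "sodium"
  out[ion_res & rn %in% c("CL", "CLA", "CL-")] <- "chloride"
  prot <- !ion_res
  out[prot & ((rn == "ASP" & an == "CG") | (rn == "GLU" & an == "CD") |
                (is_cterm & an == "C"))] <- "carboxylate_carbon"
  out[prot & an == "O" & out == "other"] <- "backbone_oxygen"
  out[prot & rn == "GLN" & an == "OE1"] <- "gln_carbonyl_oxygen"
  out[prot & ((rn == "SER" & an == "OG") | (rn == "THR" & an == "OG1"))] <-
    "hydroxyl_oxygen"
  out[prot & ((rn == "GLN" & an == "NE2") |
                (rn == "ARG" & an %in% c("NE", "NH1", "NH2")) |
                (rn == "LYS" & an == "NZ"))] <- "amino_nitrogen"
  out
}

assign_roles <- function(atoms) {
  # last residue of each chain is flagged C-terminal
  last_res <- tapply(atoms$residue_number, atoms$chain_id, max)
  is_ct <- atoms$residue_number == last_res[as.character(atoms$chain_id)] &
    atoms$residue_name %in% amino3()
  atom_role(atoms$residue_name, atoms$atom_name, is_ct)
}

amino3 <- function() c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

guess_element <- function(atom_name, residue_name = NULL) {
  an <- toupper(gsub("[0-9'+-]", "", atom_name))
  el <- substr(an, 1L, 1L)
  if (!is.null(residue_name)) {
    rn <- toupper(residue_name)
    ion <- c(CA = "Ca", CAL = "Ca", "NA" = "Na", SOD = "Na", CL = "Cl",
             CLA = "Cl", MG = "Mg", SR = "Sr", BA = "Ba", K = "K")
    hit <- !is.na(ion[rn])
    el[hit] <- ion[rn[hit]]
  }
  el
}

#' Read a trajectory from GRO, XYZ or the internal CSV dialect
#'
#' @param path input file.
#' @param format "gro", "xyz" or "csv"; guessed from the extension when
#'   missing.
#' @return a \code{\link{trajectory}}.
#'
#' @details GRO follows the fixed-column layout (positions in nm, three
#' decimals); multiple concatenated models become frames. XYZ files carry
#' coordinates in nm here, with an optional \code{box_nm= x y z} token in
#' the comment line. The internal CSV dialect has a \code{# box_nm: x y z}
#' header comment and columns \code{frame, atom_id, role, x, y, z}.
#' A trajectory without a box is accepted, but periodic analyses will
#' refuse it.
#' @export
read_frames <- function(path, format = c("auto", "gro", "xyz", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gro = "gro", xyz = "xyz", csv = "csv",
                     stop_usage("cannot guess format of ", path))
  }
  if (!file.exists(path)) stop_data("no such file: ", path)
  switch(format,
         gro = read_gro(path),
         xyz = read_xyz(path),
         csv = read_traj_csv(path))
}

read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- c(); i <- 1L
  atoms <- NULL
  while (i <= length(lines)) {
    title <- lines[i]
    t_ps <- if (grepl("t=", title))
      suppressWarnings(as.numeric(sub(".*t=\\s*([0-9eE.+-]+).*", "\\1", title)))
    else NA_real_
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop_data("GRO: bad atom count at line ", i + 1L)
    if (i + 1L + n + 1L > length(lines))
      stop_data("GRO: truncated frame (missing box line) starting at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    resnum <- suppressWarnings(as.integer(substr(body, 1L, 5L)))
    resname <- trimws(substr(body, 6L, 10L))
    atname <- trimws(substr(body, 11L, 15L))
    atid <- suppressWarnings(as.integer(substr(body, 16L, 20L)))
    x <- suppressWarnings(as.numeric(substr(body, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(body, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(body, 37L, 44L)))
    bad <- which(is.na(resnum) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop_data("GRO: malformed atom line ", i + 1L + bad[1L], " in ", path)
    boxline <- suppressWarnings(as.numeric(strsplit(trimws(
      lines[i + 2L + n]), "\\s+")[[1]]))
    if (length(boxline) < 3L || anyNA(boxline[1:3]))
      stop_data("GRO: malformed box line ", i + 2L + n, " in ", path)
    if (length(boxline) > 3L && any(abs(boxline[4:length(boxline)]) > 1e-9))
      stop_data("GRO: triclinic box not supported (line ", i + 2L + n, ")")
    if (is.null(atoms))
      atoms <- data.frame(atom_id = atid, atom_name = atname,
                          residue_name = resname, residue_number = resnum,
                          chain_id = "A", stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- boxline[1:3]
    times <- c(times, t_ps)
    i <- i + n + 3L
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  if (all(is.na(times))) times <- NULL else times[is.na(times)] <- 0
  trajectory(atoms, coords, box = do.call(rbind, boxes), times_ps = times)
}

#' Write a trajectory in GRO format
#'
#' @param traj a \code{\link{trajectory}} with a box (GRO requires one).
#' @param path output path.
#' @param frames frame indices to write (default all).
#' @return invisibly, \code{path}.
#' @export
write_gro <- function(traj, path, frames = seq_len(n_frames(traj))) {
  if (is.null(traj$box)) stop_data("GRO output requires a periodic box")
  a <- traj$atoms
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    xyz <- traj$coords[, , f, drop = FALSE]
    writeLines(sprintf("ionbridge frame t= %.3f", traj$times_ps[f]), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_number %% 100000L,
                       substr(a$residue_name, 1L, 5L),
                       substr(a$atom_name, 1L, 5L),
                       a$atom_id %% 100000L,
                       xyz[, 1L, 1L], xyz[, 2L, 1L], xyz[, 3L, 1L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1L], traj$box[f, 2L],
                       traj$box[f, 3L]), con)
  }
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); els <- NULL; box <- NULL; i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_data("XYZ: bad atom count at line ", i)
    comment <- lines[i + 1L]
    if (grepl("box_nm=", comment)) {
      box <- as.numeric(strsplit(trimws(sub(".*box_nm=", "", comment)),
                                 "\\s+")[[1]])[1:3]
    }
    body <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    ok <- lengths(body) >= 4L
    if (!all(ok)) stop_data("XYZ: malformed line ", i + 1L + which(!ok)[1L])
    if (is.null(els)) els <- vapply(body, `[[`, "", 1L)
    xyz <- t(vapply(body, function(b) as.numeric(b[2:4]), numeric(3)))
    if (anyNA(xyz)) stop_data("XYZ: non-numeric coordinates near line ", i + 2L)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + n + 2L
  }
  coords <- array(unlist(frames), c(length(els), 3L, length(frames)))
  atoms <- data.frame(atom_id = seq_along(els), atom_name = els,
                      residue_name = toupper(els), residue_number = 1L,
                      chain_id = "A", element = els,
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, box = box)
}

#' Write / read the internal CSV trajectory dialect
#'
#' Long-format CSV with a \code{# box_nm: x y z} comment header and columns
#' \code{frame, atom_id, role, x, y, z} (nm). This is the interchange
#' format used by the synthetic generators.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path file path.
#' @return \code{write_traj_csv}: invisibly \code{path};
#'   \code{read_traj_csv}: a \code{\link{trajectory}}.
#' @export
write_traj_csv <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(traj$box))
    writeLines(sprintf("# box_nm: %.6f %.6f %.6f", traj$box[1, 1],
                       traj$box[1, 2], traj$box[1, 3]), con)
  writeLines("frame,atom_id,role,x,y,z", con)
  nf <- n_frames(traj); na_ <- n_atoms(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("%d,%d,%s,%.6f,%.6f,%.6f", f, traj$atoms$atom_id,
                       traj$atoms$role, traj$coords[, 1L, f],
                       traj$coords[, 2L, f], traj$coords[, 3L, f]), con)
  }
  invisible(path)
}

#' @rdname write_traj_csv
#' @export
read_traj_csv <- function(path) {
  first <- readLines(path, n = 1L)
  box <- NULL; skip <- 0L
  if (startsWith(first, "# box_nm:")) {
    box <- as.numeric(strsplit(trimws(sub("# box_nm:", "", first)),
                               "\\s+")[[1]])
    skip <- 1L
  }
  d <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  need <- c("frame", "atom_id", "role", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop_data("CSV trajectory missing columns: ",
              paste(setdiff(need, names(d)), collapse = ", "))
  frames <- sort(unique(d$frame))
  ids <- d$atom_id[d$frame == frames[1L]]
  coords <- array(NA_real_, c(length(ids), 3L, length(frames)))
  for (k in seq_along(frames)) {
    dk <- d[d$frame == frames[k], ]
    dk <- dk[match(ids, dk$atom_id), ]
    if (anyNA(dk$atom_id)) stop_data("CSV trajectory: atom set varies by frame")
    coords[, , k] <- as.matrix(dk[, c("x", "y", "z")])
  }
  d1 <- d[d$frame == frames[1L], ]
  d1 <- d1[match(ids, d1$atom_id), ]
  atoms <- data.frame(atom_id = ids, atom_name = d1$role,
                      residue_name = "UNK", residue_number = 1L,
                      chain_id = "A", element = "X", role = d1$role,
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, box = box)
}
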