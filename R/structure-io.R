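#' @title Molecular structures and conformational ensembles
#' @description S3 containers and PDB-dialect readers/writers used by every
#'   other module. A `StructureModel` is a flat, ordered atom table (one row
#'   per atom) carrying the chain/residue hierarchy in its columns, in the
#'   spirit of a PDB file; a `Trajectory` is one topology plus a list of
#'   per-frame coordinate matrices.
#' @name structure-io
NULL

NUCLEOTIDE_RESNAMES <- c("DA", "DT", "DG", "DC", "DU", "DRP",
                         "A", "T", "G", "C", "U",
                         "ADE", "THY", "GUA", "CYT", "URA")

AMINO_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                    "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

SOLVENT_RESNAMES <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "NA", "CL", "K",
                      "MG", "ZN2", "CA2", "NA+", "CL-")

#' Classify a residue name
#' @param resname character vector of residue names.
#' @return one of "nucleotide", "amino-acid", "other" per element.
#' @export
residue_kind <- function(resname) {
  rn <- toupper(resname)
  out <- rep("other", length(rn))
  out[rn %in% NUCLEOTIDE_RESNAMES] <- "nucleotide"
  out[rn %in% AMINO_RESNAMES] <- "amino-acid"
  out
}

#' Canonicalize an atom name
#'
#' PDB dialects write sugar/backbone primes as \code{'}, \code{*} or the
#' Unicode prime; all are normalized to the ASCII apostrophe so that
#' \code{C3'}, \code{C3*} and \code{C3′} select the same atom.
#'
#' @param name character vector of atom names.
#' @return normalized names.
#' @export
normalize_atom_name <- function(name) {
  name <- gsub("′", "'", name)
  name <- gsub("\\*", "'", name)
  trimws(name)
}

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  two <- substr(nm, 1L, 2L)
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "FE", "NA", "MN") &
           nchar(nm) == 2L, two, substr(nm, 1L, 1L))
}

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `name`, `resname`, `chain`, `resid`,
#'   `x`, `y`, `z`; optional `serial`, `insert`, `occ`, `bfac`, `element`,
#'   `altloc`.
#' @param title free-text title.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, title = "") {
  need <- c("name", "resname", "chain", "resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("structure has zero atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$bfac)) atoms$bfac <- 0
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms$name <- normalize_atom_name(atoms$name)
  atoms$resid <- as.integer(atoms$resid)
  atoms$serial <- as.integer(atoms$serial)
  atoms$chain <- as.character(atoms$chain)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<StructureModel> %d atoms, %d residues, %d chains%s\n",
              nrow(x$atoms), nrow(rt), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a StructureModel.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#' @param model a StructureModel.
#' @return n x 3 matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value n x 3 matrix of replacement coordinates.
#' @export
`coords<-` <- function(model, value) {
  stopifnot(nrow(value) == n_atoms(model), ncol(value) == 3L)
  model$atoms$x <- value[, 1L]
  model$atoms$y <- value[, 2L]
  model$atoms$z <- value[, 3L]
  model
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resid, atoms$insert, sep = "|")

#' Table of residues in model order
#' @param model a StructureModel.
#' @return data.frame with chain, resid, insert, resname, kind, first/last
#'   atom row indices.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  idx <- which(first)
  ends <- c(idx[-1L] - 1L, nrow(a))
  data.frame(chain = a$chain[idx], resid = a$resid[idx], insert = a$insert[idx],
             resname = a$resname[idx], kind = residue_kind(a$resname[idx]),
             from = idx, to = ends, stringsAsFactors = FALSE)
}

#' Select atoms of a model
#'
#' Conjunction of clauses; each clause accepts a vector of admissible values.
#' Either pass clauses as arguments or a compact string query of the form
#' \code{"chain=I resid=34 name=C3'"} (values comma-separated for
#' alternatives). Matching atoms are returned as row indices in model order;
#' an empty result is not an error.
#'
#' @param model a StructureModel.
#' @param chain,resid,resname,name optional filter values.
#' @param element optional element filter.
#' @param query optional string query; clauses are space-separated
#'   `key=value[,value...]` pairs with keys chain/resid/resname/name/element.
#' @return integer vector of atom row indices (possibly empty).
#' @export
select_atoms <- function(model, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, element = NULL, query = NULL) {
  if (!is.null(query)) {
    cl <- parse_query(query)
    chain <- cl$chain %||% chain
    resid <- cl$resid %||% resid
    resname <- cl$resname %||% resname
    name <- cl$name %||% name
    element <- cl$element %||% element
  }
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% as.character(chain)
  if (!is.null(resid)) keep <- keep & a$resid %in% as.integer(resid)
  if (!is.null(resname)) keep <- keep & toupper(a$resname) %in% toupper(resname)
  if (!is.null(name)) keep <- keep & a$name %in% normalize_atom_name(name)
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  which(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_query <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  toks <- strsplit(trimws(query), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  out <- list()
  for (tk in toks) {
    kv <- strsplit(tk, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L || !nzchar(kv[2L]))
      stop("malformed selection clause: '", tk, "'")
    key <- tolower(kv[1L])
    if (!key %in% c("chain", "resid", "resname", "name", "element"))
      stop("unknown selection key: '", key, "'")
    vals <- strsplit(kv[2L], ",", fixed = TRUE)[[1L]]
    out[[key]] <- if (key == "resid") as.integer(vals) else vals
  }
  out
}

# Single-atom index lookup; errors with a residue-naming message when absent.
anchor_atom <- function(model, chain, resid, name) {
  i <- select_atoms(model, chain = chain, resid = resid, name = name)
  if (length(i) == 0L)
    stop(sprintf("anchor atom %s not found in residue %s:%s", name, chain, resid))
  i[1L]
}

## ---------------------------------------------------------------- PDB input

parse_pdb_lines <- function(lines, keep_solvent = FALSE) {
  rec <- substr(lines, 1L, 6L)
  at <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(at) == 0L) return(NULL)
  df <- data.frame(
    serial = suppressWarnings(as.integer(substr(at, 7L, 11L))),
    name = trimws(substr(at, 13L, 16L)),
    altloc = trimws(substr(at, 17L, 17L)),
    resname = trimws(substr(at, 18L, 20L)),
    chain = substr(at, 22L, 22L),
    resid = suppressWarnings(as.integer(substr(at, 23L, 26L))),
    insert = trimws(substr(at, 27L, 27L)),
    x = as.numeric(substr(at, 31L, 38L)),
    y = as.numeric(substr(at, 39L, 46L)),
    z = as.numeric(substr(at, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(at, 55L, 60L))),
    bfac = suppressWarnings(as.numeric(substr(at, 61L, 66L))),
    element = trimws(substr(at, 77L, 78L)),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  df$bfac[is.na(df$bfac)] <- 0
  df$serial[is.na(df$serial)] <- seq_len(nrow(df))[is.na(df$serial)]
  noel <- !nzchar(df$element)
  df$element[noel] <- guess_element(df$name[noel])
  if (!keep_solvent) df <- df[!toupper(df$resname) %in% SOLVENT_RESNAMES, , drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  # altloc: keep highest occupancy per (residue, atom name); ties -> first seen
  if (any(nzchar(df$altloc))) {
    key <- paste(df$chain, df$resid, df$insert, normalize_atom_name(df$name))
    ord <- order(factor(key, levels = unique(key)), -df$occ,
                 seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain, df$resid, df$insert,
                               normalize_atom_name(df$name))), , drop = FALSE]
    df <- df[order(match(paste(df$chain, df$resid, df$insert),
                         unique(paste(df$chain, df$resid, df$insert))),
                   df$serial), , drop = FALSE]
  }
  df$altloc <- ""
  df
}

#' Read a molecular structure from a PDB-dialect file
#'
#' All ATOM/HETATM records are retained in file order; alternate locations
#' resolve to the highest-occupancy copy (ties to the first encountered);
#' solvent and monoatomic ions are dropped unless `keep_solvent = TRUE`.
#' For multi-model files only the first MODEL is read (use
#' [read_trajectory()] for ensembles).
#'
#' @param path file path.
#' @param dialect only "pdb" is supported.
#' @param keep_solvent keep water/ion records?
#' @return a [structure_model()].
#' @export
read_structure <- function(path, dialect = "pdb", keep_solvent = FALSE) {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  # truncate at first ENDMDL so a multi-model file yields its first frame
  endm <- which(substr(lines, 1L, 6L) == "ENDMDL")
  if (length(endm)) lines <- lines[seq_len(endm[1L])]
  df <- parse_pdb_lines(lines, keep_solvent = keep_solvent)
  if (is.null(df)) stop("no ATOM/HETATM records parsed from ", path)
  ttl <- lines[substr(lines, 1L, 6L) == "TITLE "]
  title <- if (length(ttl)) trimws(substr(ttl[1L], 11L, 80L)) else ""
  structure_model(df, title = title)
}

format_pdb_atoms <- function(atoms) {
  # hybrid serial convention: serials above 99999 wrap back to 1
  ser <- ((atoms$serial - 1L) %% 99999L) + 1L
  nm <- atoms$name
  # PDB name justification: 1-char elements start in column 14
  pad <- ifelse(nchar(nm) <= 3L & nchar(guess_element(nm)) == 1L,
                paste0(" ", nm), nm)
  pad <- formatC(pad, width = -4L)
  rec <- ifelse(residue_kind(atoms$resname) == "other" &
                  !toupper(atoms$resname) %in% NUCLEOTIDE_RESNAMES,
                "HETATM", "ATOM  ")
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, ser, pad, "", substr(atoms$resname, 1L, 3L), atoms$chain,
          atoms$resid %% 10000L, substr(atoms$insert, 1L, 1L),
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$bfac,
          toupper(substr(atoms$element, 1L, 2L)))
}

#' Write a StructureModel as a PDB file
#'
#' Standard ATOM/HETATM records, coordinates at 3 decimals, a TER record
#' between chains and END at the end. Atom serials above 99999 wrap back to 1
#' (documented hybrid convention; residue numbering is preserved).
#'
#' @param model a StructureModel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (!inherits(model, "StructureModel") || n_atoms(model) == 0L)
    stop("empty or invalid model")
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(model$title)) writeLines(sprintf("TITLE     %s", model$title), con)
  writeLines(pdb_body_lines(model), con)
  writeLines("END", con)
  invisible(path)
}

pdb_body_lines <- function(model) {
  a <- model$atoms
  lines <- format_pdb_atoms(a)
  ch <- a$chain
  brk <- which(ch[-1L] != ch[-length(ch)])
  out <- character(0L)
  prev <- 1L
  for (b in c(brk, length(lines))) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1L
  }
  out
}

## --------------------------------------------------------------- trajectory

#' Construct a Trajectory
#'
#' @param topology a StructureModel giving names/residues for every frame.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param times frame times in ps; defaults to 0-based frame index. Must be
#'   strictly increasing.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "StructureModel"), is.list(frames),
            length(frames) >= 1L)
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != na)
      stop(sprintf("frame %d has %d atoms; topology has %d", i,
                   nrow(frames[[i]]), na))
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) stop("times length != frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, t = [%g, %g] ps\n",
              length(x$frames), n_atoms(x$topology),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a Trajectory.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a StructureModel
#' @param traj a Trajectory.
#' @param i frame index (1-based).
#' @export
frame_model <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- traj$topology
  coords(m) <- traj$frames[[i]]
  m
}

#' Read a conformational ensemble
#'
#' Multi-model PDB: one frame per MODEL record (or a single frame if no MODEL
#' records are present). Frame times are taken from `REMARK   6 TIME_PS`
#' lines when present, else the 0-based frame index. Binary formats (XTC,
#' TRR, DCD) are supported through the adapter contract: pass a function for
#' `path` that returns `list(frames = <list of n x 3 matrices>,
#' times = <numeric or NULL>)`.
#'
#' @param topology a StructureModel whose atom count every frame must match.
#' @param path file path, or an adapter function (see Details).
#' @param format "multi-model-pdb" or "adapter" (inferred when `path` is a
#'   function).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(topology, path, format = c("multi-model-pdb", "adapter")) {
  if (is.function(path)) format <- "adapter" else format <- match.arg(format)
  na <- n_atoms(topology)
  if (format == "adapter") {
    got <- path()
    frames <- got$frames
    times <- got$times
  } else {
    if (!file.exists(path)) stop("cannot read file: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1L, 6L)
    starts <- which(rec == "MODEL ")
    if (length(starts) == 0L) {
      m <- read_structure(path)
      return(trajectory(topology, list(coords(m)), times = NULL))
    }
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
    frames <- vector("list", length(starts))
    times <- rep(NA_real_, length(starts))
    for (k in seq_along(starts)) {
      blk <- lines[starts[k]:ends[k]]
      trem <- blk[startsWith(blk, "REMARK   6 TIME_PS")]
      if (length(trem)) times[k] <- as.numeric(sub(".*TIME_PS", "", trem[1L]))
      df <- parse_pdb_lines(blk, keep_solvent = TRUE)
      if (is.null(df)) stop("frame ", k, ": no atoms parsed")
      frames[[k]] <- as.matrix(df[, c("x", "y", "z")])
    }
    if (any(is.na(times))) times <- NULL
  }
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != na)
      stop(sprintf("topology mismatch at frame %d: %d atoms vs %d expected",
                   k, nrow(frames[[k]]), na))
  }
  trajectory(topology, frames, times = times)
}

#' Write a Trajectory as a multi-model PDB file
#' @param traj a Trajectory.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- traj$topology
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK   6 TIME_PS %g", traj$times[k]), con)
    coords(m) <- traj$frames[[k]]
    writeLines(pdb_body_lines(m), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
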