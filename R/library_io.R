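## Rotamer-library bundles: a weights text file (one intrinsic Boltzmann
## weight per line), a conformer topology (PDB), conformer coordinates
## (DCD or multi-model PDB), and a YAML manifest registering the pieces
## together with the atom names identifying the backbone triad and the
## nitroxide N-O pair.

#' Construct a rotamer library object
#'
#' A rotamer library represents the conformational ensemble of a covalently
#' attached paramagnetic probe as a finite set of conformers, each with an
#' intrinsic Boltzmann probability derived from dihedral clustering of label
#' simulations. Conformers are stored in a canonical backbone frame and are
#' superposed onto a labelled site via their (N, CA, C) triad.
#'
#' @param name Library identifier.
#' @param atoms Data frame with columns \code{name} (PDB atom name) and
#'   \code{element}; a logical \code{heavy} column is derived if absent.
#' @param coords Numeric array \code{R x A x 3} of conformer coordinates in nm.
#' @param p_int Length-R vector of intrinsic Boltzmann weights; normalized to
#'   sum to one.
#' @param triad Integer indices (into \code{atoms}) of the backbone N, CA, C.
#' @param nitroxide Integer indices of the nitroxide N and O atoms.
#' @return An object of class \code{rotamer_library}.
#' @seealso [load_library()], [validate_library()], [make_toy_library()]
#' @export
rotamer_library <- function(name, atoms, coords, p_int, triad, nitroxide) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  R <- dim(coords)[1]
  A <- dim(coords)[2]
  if (nrow(atoms) != A) stop("atom table rows do not match coordinate atoms")
  if (length(p_int) != R) {
    stop("weight count (", length(p_int), ") does not match conformer count (",
         R, ")")
  }
  if (any(p_int < 0)) stop("intrinsic weights must be non-negative")
  s <- sum(p_int)
  if (s <= 0) stop("intrinsic weights must not all be zero")
  if (is.null(atoms$heavy)) atoms$heavy <- atoms$element != "H"
  lib <- structure(
    list(name = name, n_rotamers = R, atoms = atoms, coords = coords,
         p_int = p_int / s, triad = as.integer(triad),
         nitroxide = as.integer(nitroxide)),
    class = "rotamer_library")
  bad <- validate_library(lib)
  if (length(bad)) stop("invalid rotamer library: ", paste(bad, collapse = "; "))
  lib
}

#' Validate a rotamer library
#'
#' Checks the structural invariants of a library and reports violations
#' without raising: non-negative weights summing to one, non-collinear
#' backbone triads (triangle area > 1e-6 nm^2) and a chemically sane
#' nitroxide N-O bond length (0.1-0.2 nm) in every conformer.
#'
#' @param lib A \code{rotamer_library}.
#' @return Character vector of violated invariants; empty if all hold.
#' @export
validate_library <- function(lib) {
  report <- character()
  if (any(lib$p_int < 0)) report <- c(report, "negative weight")
  if (abs(sum(lib$p_int) - 1) > 1e-9) {
    report <- c(report, "weights do not sum to 1")
  }
  R <- dim(lib$coords)[1]
  for (i in seq_len(R)) {
    tri <- lib$coords[i, lib$triad, , drop = TRUE]
    if (.triangle_area(tri) <= 1e-6) {
      report <- c(report, sprintf("collinear backbone triad in conformer %d", i))
      break
    }
  }
  d_no <- sqrt(rowSums((lib$coords[, lib$nitroxide[1], , drop = FALSE] -
                        lib$coords[, lib$nitroxide[2], , drop = FALSE])^2,
                       dims = 1))
  if (any(d_no < 0.1 | d_no > 0.2)) {
    report <- c(report, "nitroxide bond length outside [0.1, 0.2] nm")
  }
  report
}

.triangle_area <- function(tri) {
  v1 <- tri[2, ] - tri[1, ]
  v2 <- tri[3, ] - tri[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  0.5 * sqrt(sum(cr^2))
}

#' Load a rotamer library from a bundle manifest
#'
#' Reads a library registered in a YAML manifest. Each manifest entry maps a
#' library name to the bundle files (\code{weights}, \code{topology},
#' \code{trajectory}) and to the atom names of the backbone triad and the
#' nitroxide pair. File paths are resolved relative to the manifest. Conformer
#' coordinates may be a DCD trajectory or a multi-model PDB; file coordinates
#' are in Angstrom and are converted to nm on load. Intrinsic weights are
#' renormalized to sum to one.
#'
#' @param name Library name (a manifest key).
#' @param manifest Path to the YAML manifest file.
#' @return A validated \code{rotamer_library}.
#' @export
load_library <- function(name, manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  entries <- yaml::read_yaml(manifest)
  if (is.null(entries[[name]])) {
    stop("library '", name, "' not registered in ", manifest)
  }
  entry <- entries[[name]]
  dir <- dirname(manifest)
  path_of <- function(p) if (file.exists(p)) p else file.path(dir, p)
  wfile <- path_of(entry$weights)
  tfile <- path_of(entry$topology)
  cfile <- path_of(entry$trajectory)
  for (f in c(wfile, tfile, cfile)) {
    if (!file.exists(f)) stop("bundle file not found: ", f)
  }

  w <- .read_weights(wfile)
  top <- bio3d::read.pdb(tfile, verbose = FALSE)
  atoms <- data.frame(name = top$atom$elety,
                      element = .element_of(top$atom$elety, top$atom$elesy),
                      stringsAsFactors = FALSE)
  atoms$heavy <- atoms$element != "H"

  xyz <- .read_conformer_xyz(cfile)
  A <- nrow(atoms)
  if (ncol(xyz) != 3 * A) {
    stop("conformer coordinates have ", ncol(xyz) / 3,
         " atoms but topology has ", A)
  }
  if (nrow(xyz) != length(w)) {
    stop("weights file has ", length(w), " rows but trajectory has ",
         nrow(xyz), " frames")
  }
  coords <- aperm(array(t(xyz), dim = c(3, A, nrow(xyz))), c(3, 2, 1)) / 10

  triad_names <- unlist(entry$triad %||% list("N", "CA", "C"))
  no_names <- unlist(entry$nitroxide %||% list("N1", "O1"))
  triad <- match(triad_names, atoms$name)
  nitro <- match(no_names, atoms$name)
  if (anyNA(triad)) stop("triad atom(s) not found in topology: ",
                         paste(triad_names[is.na(triad)], collapse = ", "))
  if (anyNA(nitro)) stop("nitroxide atom(s) not found in topology: ",
                         paste(no_names[is.na(nitro)], collapse = ", "))
  rotamer_library(name, atoms, coords, w, triad, nitro)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_weights <- function(file) {
  lines <- readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  w <- suppressWarnings(as.numeric(lines))
  if (anyNA(w)) stop("non-numeric entry in weights file ", file)
  if (any(w < 0)) stop("negative weight in ", file)
  w
}

.read_conformer_xyz <- function(file) {
  if (grepl("\\.dcd$", file, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(file, verbose = FALSE)
  } else {
    xyz <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)$xyz
  }
  matrix(xyz, nrow = nrow(xyz), ncol = ncol(xyz))
}

# Derive an element symbol, preferring the PDB element column and falling
# back to the first alphabetic character of the atom name.
.element_of <- function(elety, elesy = NULL) {
  el <- if (is.null(elesy)) rep(NA_character_, length(elety)) else toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  el[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  sub("^[0-9]+", "", elety[miss])), 1, 1))
  el
}

#' Write a rotamer library as a bundle and register it in a manifest
#'
#' Writes the weights text file, the conformer topology (PDB), the conformer
#' coordinates (multi-model PDB or DCD; coordinates written in Angstrom) and
#' adds/updates the library's entry in a YAML manifest, creating the manifest
#' if needed.
#'
#' @param lib A \code{rotamer_library}.
#' @param dir Output directory (created if absent).
#' @param format \code{"pdb"} (multi-model, default) or \code{"dcd"} for the
#'   conformer coordinates.
#' @param manifest Manifest path; defaults to \code{libraries.yml} in
#'   \code{dir}.
#' @return The manifest path, invisibly.
#' @export
save_library <- function(lib, dir, format = c("pdb", "dcd"),
                         manifest = file.path(dir, "libraries.yml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wfile <- paste0(lib$name, "_weights.txt")
  tfile <- paste0(lib$name, "_top.pdb")
  cfile <- paste0(lib$name, "_conformers.", if (format == "dcd") "dcd" else "pdb")

  writeLines(c("# intrinsic Boltzmann weights, one rotamer per line",
               format(lib$p_int, digits = 15)),
             file.path(dir, wfile))

  A <- nrow(lib$atoms)
  xyz_ang <- matrix(aperm(lib$coords, c(3, 2, 1)),
                    nrow = lib$n_rotamers, byrow = TRUE) * 10
  .write_pdb_atoms(file.path(dir, tfile), lib$atoms, xyz_ang[1, , drop = FALSE],
                   resno = rep(1L, A), chain = rep("A", A),
                   resid = rep("ROT", A))
  if (format == "dcd") {
    write_dcd(file.path(dir, cfile), xyz_ang)
  } else {
    .write_pdb_atoms(file.path(dir, cfile), lib$atoms, xyz_ang,
                     resno = rep(1L, A), chain = rep("A", A),
                     resid = rep("ROT", A))
  }

  entries <- if (file.exists(manifest)) yaml::read_yaml(manifest) else list()
  entries[[lib$name]] <- list(
    weights = wfile, topology = tfile, trajectory = cfile,
    triad = as.list(lib$atoms$name[lib$triad]),
    nitroxide = as.list(lib$atoms$name[lib$nitroxide]))
  yaml::write_yaml(entries, manifest)
  invisible(manifest)
}

# Thin wrapper around bio3d::write.pdb for one or more models.
.write_pdb_atoms <- function(file, atoms, xyz_ang, resno, chain, resid) {
  bio3d::write.pdb(file = file, xyz = xyz_ang,
                   type = rep("ATOM", nrow(atoms)),
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$name, resid = resid, chain = chain,
                   resno = resno, elesy = atoms$element)
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat("Rotamer library '", x$name, "': ", x$n_rotamers, " conformers, ",
      nrow(x$atoms), " atoms (", sum(x$atoms$heavy), " heavy)\n", sep = "")
  cat("  triad atoms:", paste(x$atoms$name[x$triad], collapse = ", "),
      " nitroxide:", paste(x$atoms$name[x$nitroxide], collapse = "-"), "\n")
  invisible(x)
}
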