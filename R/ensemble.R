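## Ensemble engine: topology/trajectory reading, per-frame coordinate and
## selection access, and the high-level run_deer()/run_pre() drivers that
## compose placement with the DEER and PRE pipelines and write output files.

#' Read a structure or ensemble
#'
#' Loads a PDB topology and, optionally, a trajectory (multi-model PDB or
#' DCD). Coordinates are converted from Angstrom to nm. Without a trajectory,
#' the models of the topology file itself are the frames (one frame for a
#' plain structure).
#'
#' @param topology Path to a PDB file.
#' @param trajectory Optional path to a DCD or multi-model PDB trajectory.
#' @param stride Keep every \code{stride}-th frame (default 1).
#' @return An object of class \code{ensemble} with the atom table
#'   (\code{resno}, \code{chain}, \code{elety}, \code{element},
#'   \code{heavy}), the frame coordinates and counts.
#' @export
read_ensemble <- function(topology, trajectory = NULL, stride = 1L) {
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    elety = pdb$atom$elety,
    resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
    resno = pdb$atom$resno,
    element = .element_of(pdb$atom$elety, pdb$atom$elesy),
    stringsAsFactors = FALSE)
  atoms$heavy <- atoms$element != "H"
  xyz <- matrix(pdb$xyz, nrow = nrow(pdb$xyz))
  if (!is.null(trajectory)) {
    if (grepl("\\.xtc$", trajectory, ignore.case = TRUE)) {
      stop("XTC trajectories are not supported; convert to DCD or ",
           "multi-model PDB")
    }
    xyz <- .read_conformer_xyz(trajectory)
    if (ncol(xyz) != 3 * nrow(atoms)) {
      stop("trajectory has ", ncol(xyz) / 3, " atoms but topology has ",
           nrow(atoms))
    }
  }
  if (stride > 1) xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  structure(list(atoms = atoms, xyz = xyz / 10,
                 n_frames = nrow(xyz), n_atoms = nrow(atoms)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Ensemble: ", x$n_frames, " frame(s), ", x$n_atoms, " atoms, chains: ",
      paste(unique(x$atoms$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Frame indices of an ensemble
#'
#' @param ensemble An \code{ensemble}.
#' @param stride Keep every \code{stride}-th frame.
#' @return Integer vector of frame indices.
#' @export
iterate_frames <- function(ensemble, stride = 1L) {
  seq(1L, ensemble$n_frames, by = as.integer(stride))
}

#' Coordinates of one frame
#'
#' @param ensemble An \code{ensemble}.
#' @param frame Frame index.
#' @return \code{A x 3} matrix in nm.
#' @export
frame_coords <- function(ensemble, frame) {
  matrix(ensemble$xyz[frame, ], ncol = 3, byrow = TRUE)
}

# Resolve a possibly-missing chain ID: single-chain files allow omission;
# ambiguity is an error, never a silent first match.
.resolve_chain <- function(ensemble, chain) {
  chains <- unique(ensemble$atoms$chain)
  if (is.null(chain) || is.na(chain) || chain == "") {
    if (length(chains) > 1) {
      stop("structure has chains ", paste(chains, collapse = ", "),
           "; a chain ID is required")
    }
    return(chains)
  }
  if (!chain %in% chains) stop("chain '", chain, "' not present")
  chain
}

.residue_rows <- function(ensemble, resno, chain) {
  chain <- .resolve_chain(ensemble, chain)
  rows <- which(ensemble$atoms$resno == resno & ensemble$atoms$chain == chain)
  if (length(rows) == 0) {
    stop("residue ", resno, " (chain ", chain, ") not found in topology")
  }
  rows
}

.atom_coord <- function(ensemble, resno, chain, name, frame) {
  rows <- .residue_rows(ensemble, resno, chain)
  hit <- rows[ensemble$atoms$elety[rows] == name]
  if (length(hit) == 0) return(NULL)
  frame_coords(ensemble, frame)[hit[1], ]
}

#' Backbone triad of a residue in one frame
#'
#' @param ensemble An \code{ensemble}.
#' @param resno Residue number.
#' @param chain Chain identifier or \code{NA}.
#' @param frame Frame index.
#' @return A \code{labeled_site} holding the N, CA, C coordinates.
#' @export
site_from_frame <- function(ensemble, resno, chain = NA, frame = 1L) {
  tri <- rbind(.atom_coord(ensemble, resno, chain, "N", frame),
               .atom_coord(ensemble, resno, chain, "CA", frame),
               .atom_coord(ensemble, resno, chain, "C", frame))
  if (is.null(tri) || nrow(tri) != 3) {
    stop("backbone N/CA/C atoms incomplete for residue ", resno)
  }
  labeled_site(resno, chain, tri)
}

#' Steric environment of a labelled site in one frame
#'
#' All protein heavy atoms except the labelled residue's own side chain
#' (the native side chain is conceptually replaced by the probe); the
#' residue's backbone N, CA, C, O remain part of the environment.
#'
#' @inheritParams site_from_frame
#' @return List with \code{coords} (nm) and \code{elements}.
#' @export
environment_atoms <- function(ensemble, resno, chain = NA, frame = 1L) {
  chain <- .resolve_chain(ensemble, chain)
  a <- ensemble$atoms
  side <- a$resno == resno & a$chain == chain &
    !(a$elety %in% c("N", "CA", "C", "O"))
  keep <- a$heavy & !side
  list(coords = frame_coords(ensemble, frame)[keep, , drop = FALSE],
       elements = a$element[keep])
}

#' Amide-proton targets for PRE prediction
#'
#' Backbone amide protons (atom name \code{H}; \code{HN} accepted) of all
#' residues except the labelled one. Residues lacking an amide proton
#' (N-terminus, prolines) are skipped and listed in the \code{skipped}
#' attribute.
#'
#' @inheritParams site_from_frame
#' @param resno Labelled residue (excluded from the targets).
#' @return Data frame with \code{resno}, \code{chain} and proton coordinates
#'   \code{x, y, z} (nm).
#' @export
amide_protons <- function(ensemble, resno, chain = NA, frame = 1L) {
  chain <- .resolve_chain(ensemble, chain)
  a <- ensemble$atoms
  sel <- a$elety %in% c("H", "HN") &
    !(a$resno == resno & a$chain == chain)
  xyz <- frame_coords(ensemble, frame)[sel, , drop = FALSE]
  out <- data.frame(resno = a$resno[sel], chain = a$chain[sel],
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  all_res <- unique(a[a$resno != resno | a$chain != chain,
                      c("resno", "chain")])
  have <- paste(out$resno, out$chain)
  skipped <- all_res[!paste(all_res$resno, all_res$chain) %in% have, ]
  attr(out, "skipped") <- skipped
  out
}

.read_weight_file <- function(weights, n_frames) {
  if (is.character(weights) && length(weights) == 1) {
    weights <- .read_weights(weights)
  }
  if (!is.null(weights)) {
    if (length(weights) != n_frames) {
      stop("frame weight list length (", length(weights),
           ") does not match frame count (", n_frames, ")")
    }
    if (any(weights < 0) || !any(weights > 0)) {
      stop("frame weights must be non-negative with at least one positive")
    }
  }
  weights
}

#' Predict a DEER distance distribution and time trace for a label pair
#'
#' Runs the full pipeline for two spin-labelled positions over every frame of
#' an ensemble: rotamer placement and Boltzmann weighting at both sites,
#' pairwise electron-electron distance histograms weighted by
#' \eqn{p_i p_j}, Z-cutoff frame filtering, (weighted) frame averaging,
#' Gaussian low-pass filtering and back-calculation of S(t) and V(t).
#'
#' @param ensemble An \code{ensemble} from [read_ensemble()], or \code{NULL}
#'   to read from \code{topology}/\code{trajectory}.
#' @param residues Integer vector of the two labelled residue numbers.
#' @param lib A \code{rotamer_library}.
#' @param chains Character vector of the two chain IDs (or \code{NULL} for
#'   single-chain structures).
#' @param topology,trajectory Input files, used when \code{ensemble} is
#'   \code{NULL}.
#' @param temperature Temperature in K (default 298).
#' @param z_cutoff Frame-exclusion threshold on min(Z_A, Z_B) (default 0.05).
#' @param sigma_scaling Lennard-Jones sigma scaling (default 0.5).
#' @param lj_cutoff Lennard-Jones pair cutoff in nm (default 1.0).
#' @param lj Lennard-Jones parameter table.
#' @param r_max,dr Distance grid in nm (defaults 12, 0.05).
#' @param filter_stdev Low-pass filter standard deviation in nm
#'   (default 0.05).
#' @param t_min,t_max,dt Time grid in microseconds (defaults 0.01, 5.5,
#'   0.01).
#' @param lam Modulation depth (default 0.5); ignored when \code{fit_file}
#'   is given.
#' @param fit_file Optional two-column text file (time in microseconds, form
#'   factor) used to fit the modulation depth.
#' @param weights Optional frame weights (vector or one-per-line text file).
#' @param stride Frame stride (default 1).
#' @param output Optional output directory; when given, writes
#'   \code{res-<i>-<j>.dat} (r, raw and filtered P),
#'   \code{res-<i>-<j>-trace.dat} (t, S, V), \code{res-Z-<i>-<j>.dat}
#'   (per-frame Z), a per-frame \code{res-<i>-<j>-frames.rds} container and a
#'   run manifest.
#' @return Object of class \code{deer_result}: raw and filtered
#'   distributions, the \code{deer_trace}, the per-frame Z matrix and
#'   per-frame histograms.
#' @export
run_deer <- function(ensemble = NULL, residues, lib, chains = NULL,
                     topology = NULL, trajectory = NULL, temperature = 298,
                     z_cutoff = 0.05, sigma_scaling = 0.5, lj_cutoff = 1.0,
                     lj = lj_default_table(), r_max = 12, dr = 0.05,
                     filter_stdev = 0.05, t_min = 0.01, t_max = 5.5,
                     dt = 0.01, lam = 0.5, fit_file = NULL, weights = NULL,
                     stride = 1L, output = NULL) {
  if (is.null(ensemble)) ensemble <- read_ensemble(topology, trajectory)
  stopifnot(length(residues) == 2)
  if (is.null(chains)) chains <- c(NA, NA)
  ch <- vapply(chains, function(x) .resolve_chain(ensemble, x), character(1))
  if (residues[1] == residues[2] && ch[1] == ch[2]) {
    stop("the two labelled sites coincide (residue ", residues[1],
         ", chain ", ch[1], ")")
  }
  frames <- iterate_frames(ensemble, stride)
  weights <- .read_weight_file(weights, length(frames))

  zero_dist <- distance_distribution(numeric(round(r_max / dr)), r_max, dr)
  per_frame <- vector("list", length(frames))
  z_pairs <- matrix(0, length(frames), 2,
                    dimnames = list(NULL, c("Z_A", "Z_B")))
  for (k in seq_along(frames)) {
    f <- frames[k]
    pl <- lapply(1:2, function(s) {
      site <- site_from_frame(ensemble, residues[s], ch[s], f)
      env <- environment_atoms(ensemble, residues[s], ch[s], f)
      .place_rotamers(lib, site, env, lj, lj_cutoff, sigma_scaling,
                      temperature, f)
    })
    z_pairs[k, ] <- c(pl[[1]]$Z, pl[[2]]$Z)
    per_frame[[k]] <- if (min(z_pairs[k, ]) >= z_cutoff) {
      frame_distribution(pl[[1]], pl[[2]], r_max, dr)
    } else zero_dist
  }

  raw <- ensemble_distribution(per_frame, weights, z_pairs, z_cutoff)
  filtered <- lowpass_filter(raw, filter_stdev)

  if (!is.null(fit_file)) {
    exp_dat <- utils::read.table(fit_file)
    pred_t <- seq(t_min, t_max, by = dt)
    lam <- fit_modulation_depth(exp_dat[, 1], exp_dat[, 2], pred_t,
                                dipolar_signal(filtered, pred_t))
  }
  trace <- deer_trace(filtered, lam, t_min, t_max, dt)

  res <- structure(list(
    raw = raw, filtered = filtered, trace = trace, z = z_pairs,
    per_frame = per_frame, frames = frames, weights = weights,
    residues = residues, chains = ch,
    params = list(temperature = temperature, z_cutoff = z_cutoff,
                  sigma_scaling = sigma_scaling, lj_cutoff = lj_cutoff,
                  r_max = r_max, dr = dr, filter_stdev = filter_stdev,
                  t_min = t_min, t_max = t_max, dt = dt, lam = lam,
                  library = lib$name)),
    class = "deer_result")
  if (!is.null(output)) .write_deer_output(res, output)
  res
}

#' @export
print.deer_result <- function(x, ...) {
  kept <- sum(apply(x$z, 1, min) >= x$params$z_cutoff)
  cat("DEER prediction ", x$residues[1], "/", x$residues[2], ": ",
      length(x$frames), " frames (", kept, " kept), mode at ",
      x$filtered$r[which.max(x$filtered$density)], " nm, lambda = ",
      x$params$lam, "\n", sep = "")
  invisible(x)
}

.write_deer_output <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf("res-%d-%d", res$residues[1], res$residues[2])
  f1 <- file.path(dir, paste0(tag, ".dat"))
  writeLines("# r_nm P_raw P_filtered", f1)
  utils::write.table(
    cbind(res$raw$r, res$raw$density, res$filtered$density), f1,
    append = TRUE, col.names = FALSE, row.names = FALSE)
  f2 <- file.path(dir, paste0(tag, "-trace.dat"))
  writeLines("# t_us S V", f2)
  utils::write.table(cbind(res$trace$t, res$trace$S, res$trace$V), f2,
                     append = TRUE, col.names = FALSE, row.names = FALSE)
  fz <- file.path(dir, paste0("res-Z-", res$residues[1], "-",
                              res$residues[2], ".dat"))
  writeLines("# frame Z_A Z_B", fz)
  utils::write.table(cbind(res$frames, res$z), fz, append = TRUE,
                     col.names = FALSE, row.names = FALSE)
  saveRDS(list(frames = res$frames,
               density = do.call(rbind, lapply(res$per_frame, `[[`,
                                               "density")),
               z = res$z, r = res$raw$r, dr = res$raw$dr),
          file.path(dir, paste0(tag, "-frames.rds")), compress = "gzip")
  .write_run_manifest(file.path(dir, paste0(tag, "-run.yml")),
                      c(list(kind = "deer", residues = as.list(res$residues),
                             chains = as.list(unname(res$chains))),
                        res$params))
  invisible(dir)
}

.write_run_manifest <- function(path, params) {
  yaml::write_yaml(params, path)
}

#' Predict PRE rates and HSQC intensity ratios for one labelled site
#'
#' Runs the PRE pipeline over every frame: rotamer placement at the labelled
#' site, electron-proton distances to all backbone amide protons, model-free
#' order parameters, Solomon-Bloembergen rates, Z-cutoff filtering and
#' (weighted) ensemble averaging, then intensity ratios from the averaged
#' rates. \code{mode = "cbeta"} instead places the electron at the labelled
#' residue's C-beta atom (single state, order parameter 1) for comparison.
#'
#' @inheritParams run_deer
#' @param residue Labelled residue number.
#' @param chain Chain identifier (or \code{NULL} for single-chain
#'   structures).
#' @param params A \code{pre_parameters} object.
#' @param mode \code{"rotamer"} (default) or \code{"cbeta"}.
#' @param output Optional output directory; when given, writes
#'   \code{res-<site>.dat} (residue, rate, ratio), \code{res-Z-<site>.dat},
#'   a per-frame \code{res-<site>-frames.rds} container and a run manifest.
#' @return Object of class \code{pre_result} with the per-residue table
#'   (\code{resno}, \code{gamma2}, \code{ratio}), the per-frame rate matrix
#'   and the per-frame Z values.
#' @export
run_pre <- function(ensemble = NULL, residue, lib, chain = NULL,
                    params = pre_parameters(2e-9, 2e-10), topology = NULL,
                    trajectory = NULL, temperature = 298, z_cutoff = 0.05,
                    sigma_scaling = 0.5, lj_cutoff = 1.0,
                    lj = lj_default_table(), weights = NULL, stride = 1L,
                    output = NULL, mode = c("rotamer", "cbeta")) {
  mode <- match.arg(mode)
  if (is.null(ensemble)) ensemble <- read_ensemble(topology, trajectory)
  ch <- .resolve_chain(ensemble, if (is.null(chain)) NA else chain)
  frames <- iterate_frames(ensemble, stride)
  weights <- .read_weight_file(weights, length(frames))

  if (mode == "cbeta") {
    res <- cbeta_gamma2(ensemble, residue, params, ch, weights, stride)
    res$z_cutoff <- z_cutoff
    if (!is.null(output)) .write_pre_output(res, output)
    return(res)
  }

  protons0 <- amide_protons(ensemble, residue, ch, frames[1])
  nres <- nrow(protons0)
  g2 <- matrix(NA_real_, length(frames), nres)
  z <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    site <- site_from_frame(ensemble, residue, ch, f)
    env <- environment_atoms(ensemble, residue, ch, f)
    pl <- .place_rotamers(lib, site, env, lj, lj_cutoff, sigma_scaling,
                          temperature, f)
    z[k] <- pl$Z
    if (pl$Z <= 0) next
    protons <- amide_protons(ensemble, residue, ch, f)
    epd <- electron_proton_distances(pl, protons)
    for (j in seq_len(nres)) {
      op <- order_parameters(epd$r[j, ], epd$u[j, , ], pl$p)
      g2[k, j] <- gamma2(op$mean_r6inv, op$s2_radial * op$s2_angular, params)
    }
  }
  g2_mean <- ensemble_gamma2(g2, weights, z, z_cutoff)
  res <- .pre_result(protons0$resno, g2_mean,
                     intensity_ratio(g2_mean, params), g2, z, params,
                     residue, ch, mode = "rotamer")
  res$frames <- frames
  res$skipped <- attr(protons0, "skipped")
  res$z_cutoff <- z_cutoff
  if (!is.null(output)) .write_pre_output(res, output)
  res
}

.write_pre_output <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0("res-", res$site$resno)
  f1 <- file.path(dir, paste0(tag, ".dat"))
  writeLines("# resno gamma2_s-1 I_para/I_dia", f1)
  utils::write.table(res$residues, f1, append = TRUE, col.names = FALSE,
                     row.names = FALSE)
  fz <- file.path(dir, paste0("res-Z-", res$site$resno, ".dat"))
  writeLines("# frame Z", fz)
  frames <- res$frames %||% seq_along(res$Z)
  utils::write.table(cbind(frames, res$Z), fz, append = TRUE,
                     col.names = FALSE, row.names = FALSE)
  saveRDS(list(frames = frames, gamma2 = res$per_frame, z = res$Z,
               resno = res$residues$resno),
          file.path(dir, paste0(tag, "-frames.rds")), compress = "gzip")
  .write_run_manifest(
    file.path(dir, paste0(tag, "-run.yml")),
    list(kind = "pre", residue = res$site$resno, chain = res$site$chain,
         mode = res$mode, tau_c = res$params$tau_c, tau_t = res$params$tau_t,
         delay = res$params$delay, r2_dia = res$params$r2_dia,
         larmor_MHz = res$params$larmor_MHz,
         z_cutoff = res$z_cutoff %||% 0.05))
  invisible(dir)
}
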