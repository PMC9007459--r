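#' Read a PDB file into a Structure or Trajectory
#'
#' Thin wrapper around [bio3d::read.pdb] with the filtering conventions used
#' throughout the package: HETATM records (waters, ligands, bound partners)
#' are dropped by default, alternate locations keep the highest-occupancy
#' conformer (ties resolve to altLoc `A`), and multi-model files become a
#' [Trajectory-class] unless a single `modelIndex` is requested.
#'
#' @param path PDB file.
#' @param modelIndex integer: return only this MODEL as a
#'   [Structure-class]; `NULL` (default) returns all models (a Trajectory
#'   when more than one is present).
#' @param chainFilter character vector of chain identifiers to keep, or
#'   `NULL` for all chains.
#' @param caOnly keep only C-alpha atoms.
#' @param het keep HETATM records (default `FALSE`).
#' @return a [Structure-class], or a [Trajectory-class] for multi-model
#'   input with `modelIndex = NULL`.
#' @export
readPDB <- function(path, modelIndex = NULL, chainFilter = NULL,
                    caOnly = FALSE, het = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB file: ", conditionMessage(e)))
  a <- pdb$atom
  keep <- rep(TRUE, nrow(a))
  if (!het) keep <- keep & a$type == "ATOM"
  if (!is.null(chainFilter)) keep <- keep & a$chain %in% chainFilter
  if (caOnly) keep <- keep & a$elety == "CA"
  # altLoc: highest occupancy wins, ties go to 'A' (then alphabetical)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  grp <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(grp, -occ, alt)
  dup <- duplicated(grp[ord])
  keepAlt <- rep(TRUE, nrow(a))
  keepAlt[ord[dup]] <- FALSE
  keep <- keep & (alt == "" | keepAlt)
  if (!any(keep)) stop("zero atoms after filters")

  if (!all(is.finite(a$x[keep])) || !all(is.finite(a$y[keep])) ||
      !all(is.finite(a$z[keep])))
    stop("malformed coordinate field (non-finite coordinates)")

  elem <- a$elesy[keep]
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9]", "", a$elety[keep][bad]), 1, 1)
  atoms <- data.frame(
    eleno = a$eleno[keep], elety = a$elety[keep], elem = toupper(elem),
    resid = a$resid[keep], resno = a$resno[keep],
    insert = ifelse(is.na(a$insert[keep]), "", a$insert[keep]),
    chain = ifelse(is.na(a$chain[keep]), "A", a$chain[keep]),
    x = a$x[keep], y = a$y[keep], z = a$z[keep],
    stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  nModels <- if (is.matrix(xyz)) nrow(xyz) else 1
  sel <- bio3d::atom2xyz(which(keep))
  if (!is.null(modelIndex)) {
    if (modelIndex < 1 || modelIndex > nModels)
      stop("modelIndex out of range (file has ", nModels, " models)")
    m <- if (is.matrix(xyz)) xyz[modelIndex, sel] else xyz[sel]
    atoms$x <- m[seq(1, length(m), 3)]
    atoms$y <- m[seq(2, length(m), 3)]
    atoms$z <- m[seq(3, length(m), 3)]
    return(new("Structure", atoms = atoms))
  }
  if (nModels == 1) return(new("Structure", atoms = atoms))
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nModels))
  for (i in seq_len(nModels)) {
    m <- xyz[i, sel]
    arr[, 1, i] <- m[seq(1, length(m), 3)]
    arr[, 2, i] <- m[seq(2, length(m), 3)]
    arr[, 3, i] <- m[seq(3, length(m), 3)]
  }
  new("Trajectory", atoms = atoms, coords = arr, temperature = NA_real_,
      timestep = NA_real_, saveInterval = 1, seed = NA_integer_,
      energies = data.frame(pe = numeric(0), ke = numeric(0)))
}

#' Write a Structure (or Trajectory) to PDB
#'
#' Coordinates are written as ATOM records through [bio3d::write.pdb];
#' trajectories become multi-model files (one MODEL per frame).
#'
#' @param x a [Structure-class] or [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x)
  xyz <- if (is(x, "Trajectory")) {
    cc <- coords(x)
    t(apply(cc, 3, function(fr) as.numeric(t(fr))))
  } else as.numeric(t(coords(x)))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$eleno, elety = a$elety, resid = a$resid,
                   chain = a$chain, resno = a$resno,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$elem)
  invisible(path)
}
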