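#' Restrict a structure to a residue range and/or chain
#'
#' @param structure a [Structure-class].
#' @param resnoRange integer pair `c(first, last)` of residue numbers to
#'   keep, or `NULL`.
#' @param chain chain identifier(s) to keep, or `NULL`.
#' @return a [Structure-class].
#' @export
trimStructure <- function(structure, resnoRange = NULL, chain = NULL) {
  a <- atoms(structure)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resnoRange))
    keep <- keep & a$resno >= resnoRange[1] & a$resno <= resnoRange[2]
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!any(keep)) stop("zero atoms after trimming")
  new("Structure", atoms = a[keep, , drop = FALSE])
}

#' Group kinase structures by DFG class and average their PA CCS
#'
#' For each input PDB file: read the structure (first chain by default),
#' restrict it to the kinase-domain residue range, measure the DFG geometry
#' ([dfgGeometry()]) and compute the raw projection-approximation CCS
#' ([paCCS()]). Structures are then grouped by DFG label (with an optional
#' override for structures known to adopt an open activation loop) and the
#' per-group mean CCS is reported.
#'
#' @param files character vector of PDB paths; names are used as structure
#'   labels (default: file base names).
#' @param resnoRange kinase-domain residue range (default `c(122, 403)`,
#'   the Aurora A construct).
#' @param chainFilter chain(s) to read per file, or `NULL` for the first
#'   chain of each file.
#' @param groupOverride named character vector mapping a structure label to
#'   a group (e.g. `c("4C3P" = "open")`).
#' @param seed RNG seed for the Monte-Carlo CCS.
#' @param ... Monte-Carlo settings passed to [paCCS()] and residue numbers
#'   passed to [dfgGeometry()].
#' @return list with `perStructure` (data.frame `label`, `d1`, `d2`,
#'   `group`, `ccs_nm2`) and `groupMeans` (data.frame `group`,
#'   `mean_ccs_nm2`, `n`).
#' @export
groupCCSByDFG <- function(files, resnoRange = c(122, 403),
                          chainFilter = NULL, groupOverride = character(0),
                          seed = 1L, ...) {
  labels <- names(files)
  if (is.null(labels))
    labels <- sub("\\.(pdb|ent)$", "", basename(files), ignore.case = TRUE)
  dots <- list(...)
  dfgArgs <- dots[names(dots) %in% c("pheResidue", "chelixAnchorResidue",
                                     "beta3LysResidue", "thresholds")]
  paArgs <- dots[names(dots) %in% c("nOrientations", "nSamplePoints",
                                    "probeRadius", "radiusTable")]
  rows <- lapply(seq_along(files), function(i) {
    s <- readPDB(files[i])
    if (is(s, "Trajectory")) s <- getFrame(s, 1)
    ch <- if (is.null(chainFilter)) atoms(s)$chain[1] else chainFilter
    s <- trimStructure(s, resnoRange, ch)
    g <- do.call(dfgGeometry, c(list(structure = s), dfgArgs))
    pa <- do.call(paCCS, c(list(structure = s, seed = seed + i), paArgs))
    group <- if (labels[i] %in% names(groupOverride))
      unname(groupOverride[labels[i]]) else g$label
    data.frame(label = labels[i], d1 = g$d1, d2 = g$d2, group = group,
               ccs_nm2 = pa@ccs, stringsAsFactors = FALSE)
  })
  perStructure <- do.call(rbind, rows)
  groupMeans <- do.call(rbind, lapply(split(perStructure,
                                            perStructure$group),
                                      function(d)
    data.frame(group = d$group[1], mean_ccs_nm2 = mean(d$ccs_nm2),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(groupMeans) <- NULL
  list(perStructure = perStructure, groupMeans = groupMeans)
}
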