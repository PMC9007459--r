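#' Measure DFG-motif geometry of a kinase structure
#'
#' Two distances characterise the DFG-Phe side-chain position: D1 from the
#' DFG-Phe zeta carbon (CZ) to the C-alpha of a conserved C-helix anchor,
#' and D2 from the same CZ to the C-alpha of the beta3-strand salt-bridge
#' lysine. For Aurora A the residue triple is Phe275 / Gln185 / Lys162,
#' which is the default. The correlation of D1 and D2 assigns a DFG-in,
#' DFG-out or DFG-up/inter label via [classifyDFG()].
#'
#' C-alpha-only structures are rejected: D1/D2 are defined from the Phe CZ
#' atom.
#'
#' @param structure a [Structure-class].
#' @param pheResidue DFG-Phe residue number (default 275).
#' @param chelixAnchorResidue C-helix anchor residue number (default 185).
#' @param beta3LysResidue beta3 lysine residue number (default 162).
#' @param chain chain identifier, or `NULL` to use the first chain carrying
#'   the Phe residue.
#' @param thresholds passed to [classifyDFG()].
#' @return list with `d1`, `d2` (A) and `label`.
#' @export
dfgGeometry <- function(structure, pheResidue = 275L,
                        chelixAnchorResidue = 185L, beta3LysResidue = 162L,
                        chain = NULL, thresholds = NULL) {
  a <- atoms(structure)
  if (is.null(chain)) {
    ch <- unique(a$chain[a$resno == pheResidue])
    if (!length(ch)) stop("residue ", pheResidue, " not found in structure")
    chain <- ch[1]
  }
  a <- a[a$chain == chain, , drop = FALSE]
  pick <- function(resno, elety, what) {
    row <- a[a$resno == resno & a$elety == elety, , drop = FALSE]
    if (nrow(row) == 0) {
      if (!any(a$resno == resno))
        stop("residue ", resno, " (", what, ") missing from chain ", chain)
      stop("atom ", elety, " missing from residue ", resno, " (", what,
           "); C-alpha-only structures cannot be classified")
    }
    as.numeric(row[1, c("x", "y", "z")])
  }
  cz <- pick(pheResidue, "CZ", "DFG-Phe")
  q  <- pick(chelixAnchorResidue, "CA", "C-helix anchor")
  k  <- pick(beta3LysResidue, "CA", "beta3 Lys")
  d1 <- sqrt(sum((cz - q)^2))
  d2 <- sqrt(sum((cz - k)^2))
  label <- if (is.null(thresholds)) classifyDFG(d1, d2)
  else classifyDFG(d1, d2, thresholds)
  list(d1 = d1, d2 = d2, label = label)
}

#' Classify a DFG conformation from the D1/D2 distances
#'
#' Rule-based two-distance classification: `DFG_in` when the Phe sits close
#' to the C-helix anchor and away from the beta3 lysine
#' (`d1 <= t1 & d2 >= t2`); `DFG_out` for the reverse arrangement
#' (`d2 <= t2p & d1 >= t1p`); everything else is the intermediate
#' `DFG_inter` (DFG-up) family. The in-rule is evaluated first, so a point
#' exactly on all thresholds classifies as `DFG_in` (closed-side tie rule).
#'
#' The default 11 A cutoffs follow the published two-distance kinase
#' classification scheme; the structures studied here print no thresholds
#' of their own, so the defaults are overridable.
#'
#' @param d1,d2 distances in A (> 0); vectorized.
#' @param thresholds named vector `c(t1, t1p, t2, t2p)` in A; `t1 <= t1p`
#'   required.
#' @return character vector of labels: `DFG_in`, `DFG_out`, `DFG_inter`.
#' @export
#' @examples
#' classifyDFG(8, 15)   # DFG_in
#' classifyDFG(15, 8)   # DFG_out
classifyDFG <- function(d1, d2,
                        thresholds = c(t1 = 11, t1p = 11, t2 = 11,
                                       t2p = 11)) {
  if (any(d1 <= 0) || any(d2 <= 0)) stop("distances must be positive")
  t <- thresholds
  if (t["t1"] > t["t1p"])
    stop("inconsistent thresholds: t1 must not exceed t1p")
  unname(ifelse(d1 <= t[["t1"]] & d2 >= t[["t2"]], "DFG_in",
                ifelse(d2 <= t[["t2p"]] & d1 >= t[["t1p"]], "DFG_out",
                       "DFG_inter")))
}

#' DFG geometry along a trajectory
#'
#' Applies [dfgGeometry()] to every frame, returning the per-frame D1/D2
#' distances and labels — used, for example, to check that the DFG position
#' of the starting structure is maintained during a simulation.
#'
#' @param traj a [Trajectory-class].
#' @param ... passed to [dfgGeometry()].
#' @return data.frame with columns `frame`, `d1`, `d2`, `label`.
#' @export
trajectoryDFG <- function(traj, ...) {
  stopifnot(is(traj, "Trajectory"))
  rows <- lapply(seq_len(nFrames(traj)), function(f) {
    g <- dfgGeometry(getFrame(traj, f), ...)
    data.frame(frame = f, d1 = g$d1, d2 = g$d2, label = g$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
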