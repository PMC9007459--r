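#' Write / read a CCS profile as TSV
#'
#' Two tab-separated columns (`ccs`, `intensity`) preceded by `#`-prefixed
#' metadata header lines (`# key: value`), e.g. charge, trap collision
#' voltage and units.
#'
#' @param profile a [CCSProfile-class].
#' @param path file path.
#' @return `writeCCSProfile` returns `path` invisibly; `readCCSProfile`
#'   returns a [CCSProfile-class].
#' @export
writeCCSProfile <- function(profile, path) {
  md <- profile@metadata
  md$charge <- profile@charge
  hdr <- vapply(names(md), function(k)
    sprintf("# %s: %s", k, paste(format(md[[k]]), collapse = " ")),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("ccs\tintensity", con)
  utils::write.table(data.frame(ccs = ccsAxis(profile),
                                intensity = intensity(profile)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCCSProfile
#' @export
readCCSProfile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  md <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    vNum <- suppressWarnings(as.numeric(v))
    md[[trimws(k)]] <- if (is.na(vNum)) v else vNum
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#")
  charge <- if (!is.null(md$charge)) as.integer(md$charge) else NA_integer_
  md$charge <- NULL
  new("CCSProfile", axis = tab$ccs, intensity = tab$intensity,
      charge = charge, replicateSD = numeric(0), metadata = md)
}

#' Write a CIU series to disk, one TSV profile per voltage
#'
#' Files are named `ce_<voltage>.tsv` in `dir`; each carries its voltage in
#' the metadata header.
#'
#' @param series list of `list(voltage =, profile =)` pairs.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCIUSeries <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (e in series) {
    p <- e$profile
    p@metadata$voltage <- e$voltage
    writeCCSProfile(p, file.path(dir, sprintf("ce_%g.tsv", e$voltage)))
  }
  invisible(dir)
}

#' Read a CIU series from a directory of TSV profiles or a long CSV
#'
#' Accepts either a directory of `ce_<voltage>.tsv` profiles (as written by
#' [writeCIUSeries()]) or a single long-format CSV with columns
#' `voltage,ccs,intensity`.
#'
#' @param path directory or CSV file.
#' @return list of `list(voltage =, profile =)` pairs, sorted by voltage.
#' @export
readCIUSeries <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "^ce_.*\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no ce_<voltage>.tsv profiles in ", path)
    series <- lapply(files, function(f) {
      p <- readCCSProfile(f)
      v <- p@metadata$voltage
      if (is.null(v))
        v <- as.numeric(sub("^ce_(.*)\\.tsv$", "\\1", basename(f)))
      list(voltage = v, profile = p)
    })
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    tab <- utils::read.csv(path, comment.char = "#")
    stopifnot(all(c("voltage", "ccs", "intensity") %in% names(tab)))
    series <- lapply(sort(unique(tab$voltage)), function(v) {
      sub <- tab[tab$voltage == v, ]
      sub <- sub[order(sub$ccs), ]
      list(voltage = v,
           profile = new("CCSProfile", axis = sub$ccs,
                         intensity = sub$intensity, charge = NA_integer_,
                         replicateSD = numeric(0),
                         metadata = list(voltage = v)))
    })
  }
  series[order(vapply(series, function(e) e$voltage, numeric(1)))]
}

#' Export a CIU fingerprint as a CSV matrix
#'
#' Rows are voltages (first column `voltage`), remaining columns the CCS
#' grid values.
#'
#' @param fp a [CIUFingerprint-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeFingerprintCSV <- function(fp, path) {
  m <- as.data.frame(fingerprintMatrix(fp))
  names(m) <- format(ccsAxis(fp))
  utils::write.csv(cbind(voltage = voltages(fp), m), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a conformer fit as JSON or flat CSV
#'
#' @param fit a [ConformerFit-class].
#' @param path output path (`.json` or `.csv`, chosen by extension).
#' @return `path`, invisibly.
#' @export
writeConformerFit <- function(fit, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(components = components(fit),
                              r_squared = rSquared(fit),
                              crowded = fit@crowded),
                         path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.csv(cbind(components(fit), r_squared = rSquared(fit)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize / restore a Go model as JSON
#'
#' @param model a [GoModel-class].
#' @param path JSON path.
#' @return `writeGoModel` returns `path` invisibly; `readGoModel` a
#'   [GoModel-class].
#' @export
writeGoModel <- function(model, path) {
  jsonlite::write_json(
    list(beads = model@beads, bonds = model@bonds, angles = model@angles,
         dihedrals = model@dihedrals, contacts = model@contacts,
         rep_sigma = model@repSigma, rep_eps = model@repEps,
         params = model@params),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeGoModel
#' @export
readGoModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GoModel", beads = as.data.frame(j$beads),
      bonds = as.data.frame(j$bonds), angles = as.data.frame(j$angles),
      dihedrals = if (length(j$dihedrals)) as.data.frame(j$dihedrals)
                  else data.frame(),
      contacts = as.data.frame(j$contacts), repSigma = j$rep_sigma,
      repEps = j$rep_eps, params = j$params)
}
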