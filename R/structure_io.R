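# Structure input: reduce a PDB/mmCIF file to one effective atom per
# standard amino-acid residue, carrying author numbering and intrinsic
# hydrophobicity.  The per-residue table (class "fod_residues") is the
# package's working container; every downstream field is evaluated at the
# effective-atom positions.

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.res_key <- function(chain, resno, icode) paste(chain, resno, icode, sep = "|")

.as_fod_residues <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("fod_residues", "data.frame")
  df
}

#' Effective atom of a residue
#'
#' The unweighted arithmetic mean of the heavy-atom (non-hydrogen)
#' coordinates of one residue.  All fields of the model are evaluated at
#' this point.
#'
#' @param xyz numeric matrix with one row per heavy atom and columns x, y, z.
#' @return numeric length-3 vector.
#' @examples
#' effective_atom(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
effective_atom <- function(xyz) {
  xyz <- rbind(xyz)
  if (nrow(xyz) < 1L || ncol(xyz) != 3L)
    stop("degenerate residue: need at least one heavy atom with x, y, z")
  colMeans(xyz)
}

#' Read a protein structure into residue records
#'
#' Parses a PDB (or mmCIF) file with \pkg{bio3d} and reduces every standard
#' amino-acid residue to a single record holding its effective-atom
#' coordinate.  HETATM groups, waters, ions and cofactors are excluded;
#' hydrogens are ignored; for alternate locations the highest-occupancy
#' conformer is kept (ties by label order); only one model of a multi-model
#' file is used.  Modified residues with a known parent (e.g. MSE) are
#' renamed when `aliases = TRUE` so they receive the parent's
#' hydrophobicity.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model model number for multi-model (e.g. NMR) files; default 1.
#' @param chains optional character vector restricting to these chain IDs.
#' @param scale `hydro_scale` used to set intrinsic hydrophobicity, or
#'   `NULL` to leave the `h` column unset.
#' @param aliases map known modified-residue codes to their parent residue.
#' @return a `fod_residues` data frame with columns `chain`, `resno`
#'   (author numbering), `icode` (insertion code, `""` if none), `aa3`,
#'   `x`, `y`, `z` (effective atom, Angstrom) and `h` (intrinsic
#'   hydrophobicity).
#' @export
read_structure <- function(path, model = 1L, chains = NULL,
                           scale = hydro_scale(), aliases = TRUE) {
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, multi = (model > 1L), verbose = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom
  if (model > 1L) {
    nmod <- nrow(pdb$xyz)
    if (model > nmod) stop("model ", model, " not present (file has ",
                           nmod, ")")
    co <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- co[, 1L]; atoms$y <- co[, 2L]; atoms$z <- co[, 3L]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  aa <- toupper(atoms$resid)
  if (aliases) {
    hit <- aa %in% names(.AA_ALIAS)
    aa[hit] <- .AA_ALIAS[aa[hit]]
    atoms$resid <- aa
  }
  keep <- atoms$type == "ATOM" & aa %in% .STANDARD_AA
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  heavy <- is.na(atoms$elesy) | !(toupper(atoms$elesy) %in% c("H", "D"))
  heavy <- heavy & !grepl("^[0-9]*[HD]", atoms$elety)
  dropped <- unique(.res_key(atoms$chain, atoms$resno, atoms$insert)[keep & !heavy])
  keep <- keep & heavy
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no standard amino-acid residues found in '", path, "'")

  key <- .res_key(atoms$chain, atoms$resno, atoms$insert)
  # alternate locations: keep, per residue and atom name, the
  # highest-occupancy conformer (first on ties)
  if (any(atoms$alt != "")) {
    akey <- paste(key, atoms$elety)
    occ <- atoms$o
    occ[is.na(occ)] <- 1
    ord <- order(akey, -occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE][!duplicated(akey[ord]), , drop = FALSE]
    atoms <- atoms[order(match(.res_key(atoms$chain, atoms$resno, atoms$insert),
                               unique(key))), , drop = FALSE]
    key <- .res_key(atoms$chain, atoms$resno, atoms$insert)
  }
  lost <- setdiff(dropped, key)
  if (length(lost))
    warning("skipped ", length(lost),
            " residue(s) with no heavy atoms: ",
            paste(utils::head(lost, 5L), collapse = ", "))

  first <- !duplicated(key)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in '", path, "'")
  grp <- match(key, key[first])
  out <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$insert[first],
    aa3   = atoms$resid[first],
    x = as.numeric(tapply(xyz[, 1L], grp, mean)),
    y = as.numeric(tapply(xyz[, 2L], grp, mean)),
    z = as.numeric(tapply(xyz[, 3L], grp, mean)),
    h = NA_real_,
    stringsAsFactors = FALSE)
  out <- .as_fod_residues(out)
  if (!is.null(scale)) out <- assign_hydrophobicity(out, scale, aliases = aliases)
  out
}

#' @export
print.fod_residues <- function(x, ...) {
  cat("Residue records:", nrow(x), "residues,",
      length(unique(x$chain)), "chain(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write / read a residue selection report
#'
#' The selection report is a TSV with columns `chain`, `auth_seq_id`,
#' `icode`, `aa3`, `x`, `y`, `z`, `intrinsic_h`; re-reading it restores the
#' identical residue table, so reports double as portable fixtures.
#'
#' @param records a `fod_residues` data frame.
#' @param path output (input) file path.
#' @return `write_residue_tsv` returns `path` invisibly; `read_residue_tsv`
#'   returns a `fod_residues` data frame.
#' @export
write_residue_tsv <- function(records, path) {
  out <- data.frame(chain = records$chain, auth_seq_id = records$resno,
                    icode = records$icode, aa3 = records$aa3,
                    x = records$x, y = records$y, z = records$z,
                    intrinsic_h = records$h)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_residue_tsv
#' @export
read_residue_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(chain = "character",
                                          icode = "character",
                                          aa3 = "character"))
  tab$icode[is.na(tab$icode)] <- ""
  .as_fod_residues(data.frame(
    chain = tab$chain, resno = tab$auth_seq_id, icode = tab$icode,
    aa3 = tab$aa3, x = tab$x, y = tab$y, z = tab$z, h = tab$intrinsic_h,
    stringsAsFactors = FALSE))
}

# ---- structural-unit selections ------------------------------------------

#' Declare a structural unit
#'
#' A `unit_selection` names the part of a structure an analysis applies to:
#' whole chains, author-numbered residue ranges, and residues to exclude.
#' `mode` controls whether a fragment inherits the parent unit's Gaussian
#' field (`"part_of_parent"`) or gets its own fitted field
#' (`"individual"`).
#'
#' Ranges are written `"A:496-579"` (chain, inclusive author numbers),
#' optionally labelled `"A:496-579=Dom3"`.  Residue identifiers are written
#' `"A:48"` or, with an insertion code, `"A:48B"`.
#'
#' @param chains character vector of chain IDs, or `NULL`.
#' @param ranges character vector of range strings, or `NULL`.
#' @param excluded character vector of residue identifiers to drop.
#' @param mode `"individual"` or `"part_of_parent"`.
#' @param label optional display label.
#' @return an object of class `unit_selection`.
#' @export
unit_selection <- function(chains = NULL, ranges = NULL, excluded = NULL,
                           mode = c("individual", "part_of_parent"),
                           label = NULL) {
  mode <- match.arg(mode)
  rng <- if (length(ranges)) .parse_ranges(ranges) else NULL
  exc <- if (length(excluded)) parse_residue_ids(excluded) else NULL
  structure(list(chains = chains, ranges = rng, excluded = exc,
                 mode = mode, label = label),
            class = "unit_selection")
}

.parse_ranges <- function(ranges) {
  m <- regmatches(ranges,
                  regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)(=(.*))?$", ranges))
  bad <- vapply(m, length, 1L) == 0L | lengths(m) == 0L
  if (any(bad)) stop("cannot parse range(s): ",
                     paste(ranges[bad], collapse = ", "),
                     " (expected 'chain:start-end[=label]')")
  data.frame(chain = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end   = as.integer(vapply(m, `[`, "", 4L)),
             label = vapply(m, `[`, "", 6L),
             stringsAsFactors = FALSE)
}

#' Parse residue identifiers
#'
#' Accepts a character vector (or one comma-separated string) of residue
#' identifiers in author numbering, `"A:48"` or `"A:48B"` with an insertion
#' code.
#'
#' @param ids character vector or single comma-separated string.
#' @return data frame with columns `chain`, `resno`, `icode`.
#' @export
parse_residue_ids <- function(ids) {
  ids <- trimws(unlist(strsplit(ids, ",", fixed = TRUE)))
  ids <- ids[nzchar(ids)]
  m <- regmatches(ids, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", ids))
  bad <- lengths(m) == 0L
  if (any(bad)) stop("cannot parse residue id(s): ",
                     paste(ids[bad], collapse = ", "),
                     " (expected 'chain:resno[icode]')")
  data.frame(chain = vapply(m, `[`, "", 2L),
             resno = as.integer(vapply(m, `[`, "", 3L)),
             icode = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Resolve a unit selection against residue records
#'
#' Returns the positions (in record order, duplicate-free) of the residues
#' named by `selection`.  Ranges are inclusive in author numbering and
#' insertion-code aware: all inserted residues whose author number falls in
#' the range are included.
#'
#' @param records a `fod_residues` data frame.
#' @param selection a `unit_selection`.
#' @return integer vector of row indices into `records`.
#' @export
resolve_selection <- function(records, selection) {
  stopifnot(inherits(selection, "unit_selection"))
  n <- nrow(records)
  keep <- if (is.null(selection$chains) && is.null(selection$ranges))
    rep(TRUE, n) else rep(FALSE, n)
  if (!is.null(selection$chains))
    keep <- keep | records$chain %in% selection$chains
  if (!is.null(selection$ranges))
    for (i in seq_len(nrow(selection$ranges))) {
      r <- selection$ranges[i, ]
      keep <- keep | (records$chain == r$chain &
                      records$resno >= r$start & records$resno <= r$end)
    }
  if (!is.null(selection$excluded)) {
    exc <- .res_key(selection$excluded$chain, selection$excluded$resno,
                    selection$excluded$icode)
    key <- .res_key(records$chain, records$resno, records$icode)
    missing <- setdiff(exc, key[keep])
    if (length(missing))
      stop("excluded residue(s) not in selection: ",
           paste(missing, collapse = ", "))
    keep <- keep & !(key %in% exc)
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection resolves to an empty residue set")
  idx
}

#' Download PDB entries
#'
#' Thin wrapper over [bio3d::get.pdb()] fetching entries into `dir`.
#' Requires network access; files already present are reused.
#'
#' @param ids character vector of 4-character PDB identifiers.
#' @param dir download directory.
#' @return named character vector of file paths.
#' @export
fetch_pdb <- function(ids, dir = tempdir()) {
  paths <- suppressWarnings(bio3d::get.pdb(ids, path = dir, verbose = FALSE))
  ok <- file.exists(paths) & file.size(paths) > 0
  if (!all(ok))
    stop("could not retrieve PDB entr", if (sum(!ok) > 1) "ies: " else "y: ",
         paste(ids[!ok], collapse = ", "))
  stats::setNames(paths, ids)
}
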