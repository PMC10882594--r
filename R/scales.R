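# Intrinsic hydrophobicity scales (Hr).  All scales are rescaled to [0, 1]
# (min-max over the 20 standard residues) so that the observed-field sums are
# non-negative regardless of the published scale's original units.

.oildrop_env <- new.env(parent = emptyenv())

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# common non-standard residue codes mapped to their parent residue
.AA_ALIAS <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS",
               HSD = "HIS", HSE = "HIS", HSP = "HIS", MLY = "LYS",
               SEP = "SER", TPO = "THR", PTR = "TYR")

.aaindex_entry <- function(accession) {
  if (is.null(.oildrop_env$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    .oildrop_env$aaindex <- e$aaindex
  }
  idx <- grep(accession, names(.oildrop_env$aaindex), fixed = TRUE)
  if (length(idx) != 1L)
    stop("AAindex accession not found: ", accession)
  v <- .oildrop_env$aaindex[[idx]]$I
  names(v) <- toupper(names(v))
  v[.AA3]
}

.minmax <- function(v) (v - min(v)) / (max(v) - min(v))

#' Intrinsic hydrophobicity scales
#'
#' Returns a named, min-max normalized (0..1) intrinsic hydrophobicity scale
#' covering the 20 standard amino acids.  The default `"aggregate"` scale is
#' the mean of three classic hydropathy scales drawn from the AAindex
#' database (Kyte-Doolittle `KYTJ820101`, Fauchere-Pliska `FAUJ830101` and
#' the Eisenberg consensus `EISD840101`), each min-max normalized before
#' averaging, the average normalized again.  Individual scales are available
#' under `"kd"`, `"fauchere"` and `"eisenberg"`.
#'
#' Because published applications of the fuzzy oil drop model do not always
#' state their scale, reproduced RD and K values carry a tolerance
#' attributable to scale choice; any scale can be swapped in via
#' [read_hydro_scale()].
#'
#' @param name scale name: `"aggregate"` (default), `"kd"`, `"fauchere"` or
#'   `"eisenberg"`.
#' @return an object of class `hydro_scale`: a list with elements `name` and
#'   `values` (named numeric vector, three-letter codes, all in `[0, 1]`).
#' @examples
#' sc <- hydro_scale()
#' sc$values["PHE"]
#' @export
hydro_scale <- function(name = c("aggregate", "kd", "fauchere", "eisenberg")) {
  name <- match.arg(name)
  key <- paste0("scale_", name)
  if (!is.null(.oildrop_env[[key]])) return(.oildrop_env[[key]])
  values <- switch(name,
    aggregate = {
      comps <- vapply(c("KYTJ820101", "FAUJ830101", "EISD840101"),
                      function(a) .minmax(.aaindex_entry(a)),
                      numeric(20L))
      .minmax(rowMeans(comps))
    },
    kd        = .minmax(.aaindex_entry("KYTJ820101")),
    fauchere  = .minmax(.aaindex_entry("FAUJ830101")),
    eisenberg = .minmax(.aaindex_entry("EISD840101")))
  out <- structure(list(name = name, values = values), class = "hydro_scale")
  .oildrop_env[[key]] <- out
  out
}

#' Read a user hydrophobicity scale from a TSV file
#'
#' The file must have two tab-separated columns, three-letter residue code
#' and value, with or without a header.  Values must be non-negative and all
#' 20 standard residues must be present.
#'
#' @param path path to the TSV file.
#' @param name label stored with the scale (defaults to the file name).
#' @return a `hydro_scale` object.
#' @export
read_hydro_scale <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("aa3", "value"))
  if (!is.numeric(tab$value)) {          # header row present
    tab <- tab[-1L, , drop = FALSE]
    tab$value <- as.numeric(tab$value)
  }
  values <- stats::setNames(tab$value, toupper(tab$aa3))
  missing <- setdiff(.AA3, names(values))
  if (length(missing))
    stop("scale is missing standard residues: ", paste(missing, collapse = ", "))
  if (any(values < 0))
    stop("scale values must be non-negative")
  structure(list(name = name, values = values[.AA3]), class = "hydro_scale")
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Intrinsic hydrophobicity scale:", x$name, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Attach intrinsic hydrophobicity to residue records
#'
#' Looks each residue's three-letter code up in `scale` and fills the `h`
#' column.  Common modified residues (e.g. MSE for selenomethionine) are
#' mapped to their parent residue when `aliases = TRUE`.
#'
#' @param records a residue-record data frame (see [read_structure()]).
#' @param scale a `hydro_scale` object.
#' @param aliases map known modified-residue codes to their parent residue.
#' @return `records` with the `h` column set; row order preserved.
#' @export
assign_hydrophobicity <- function(records, scale = hydro_scale(),
                                  aliases = TRUE) {
  stopifnot(inherits(scale, "hydro_scale"))
  aa <- toupper(records$aa3)
  if (aliases) {
    hit <- aa %in% names(.AA_ALIAS)
    aa[hit] <- .AA_ALIAS[aa[hit]]
  }
  unknown <- !(aa %in% names(scale$values))
  if (any(unknown)) {
    pos <- which(unknown)
    stop("unknown residue code(s): ",
         paste0(records$aa3[pos], " (", records$chain[pos], ":",
                records$resno[pos], ")", collapse = ", "))
  }
  records$h <- unname(scale$values[aa])
  records
}
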