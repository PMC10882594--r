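# Core of the fuzzy oil drop model: the oriented 3D Gaussian body frame,
# the theoretical (T), observed (O) and uniform (R) per-residue
# hydrophobicity distributions, and the RD divergence-ratio statistic.

#' Fit the oriented Gaussian frame of a molecular body
#'
#' The frame of the theoretical hydrophobicity field: its center is the mean
#' of the effective-atom positions, its axes are the principal axes of the
#' point cloud (largest variance first, right-handed), and each sigma is set
#' by the three-sigma rule so the whole body lies within three standard
#' deviations: `sigma_k = (max |projection on axis k| + margin) / 3`.
#'
#' @param xyz numeric matrix of effective-atom coordinates (rows = residues),
#'   or a `fod_residues` data frame.
#' @param margin additive extent margin in Angstrom (default 0).
#' @return an object of class `gaussian_frame`: list with `center`
#'   (length 3), `axes` (3x3 rotation, axes in columns, det +1) and `sigma`
#'   (length 3, Angstrom).
#' @export
fit_gaussian_frame <- function(xyz, margin = 0) {
  if (inherits(xyz, "fod_residues") || is.data.frame(xyz))
    xyz <- cbind(xyz$x, xyz$y, xyz$z)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L)
    stop("frame error: need at least 3 points")
  center <- colMeans(xyz)
  cc <- sweep(xyz, 2L, center)
  eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axes <- eg$vectors                      # columns, decreasing variance
  # deterministic signs: make the dominant component of axes 1-2 positive,
  # then complete a right-handed (det +1) triad
  for (k in 1:2) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3L] <- c(axes[2L, 1L] * axes[3L, 2L] - axes[3L, 1L] * axes[2L, 2L],
                  axes[3L, 1L] * axes[1L, 2L] - axes[1L, 1L] * axes[3L, 2L],
                  axes[1L, 1L] * axes[2L, 2L] - axes[2L, 1L] * axes[1L, 2L])
  proj <- cc %*% axes
  ext <- apply(abs(proj), 2L, max)
  if (any(ext < 1e-8))
    stop("frame error: degenerate (collinear or planar) point cloud")
  structure(list(center = center, axes = axes, sigma = (ext + margin) / 3),
            class = "gaussian_frame")
}

#' @export
print.gaussian_frame <- function(x, ...) {
  cat("Gaussian frame: center (", paste(sprintf("%.2f", x$center),
                                        collapse = ", "),
      ") A, sigma (", paste(sprintf("%.2f", x$sigma), collapse = ", "),
      ") A\n", sep = "")
  invisible(x)
}

#' Theoretical hydrophobicity profile
#'
#' Evaluates the 3D Gaussian of `frame` at each effective-atom position and
#' normalizes to unit sum.  This is the hydrophobicity distribution an ideal
#' micelle-like fold would show: maximal at the body center, vanishing at
#' the surface.
#'
#' @param records `fod_residues` data frame (or coordinate matrix).
#' @param frame a `gaussian_frame`.
#' @return list with `raw` (unnormalized Gaussian values, peak value 1 at
#'   the center) and `p` (normalized, sums to 1).
#' @export
theoretical_profile <- function(records, frame) {
  stopifnot(inherits(frame, "gaussian_frame"))
  xyz <- if (is.data.frame(records)) cbind(records$x, records$y, records$z)
         else as.matrix(records)
  local <- sweep(xyz, 2L, frame$center) %*% frame$axes
  raw <- exp(-rowSums(sweep(local, 2L, frame$sigma, "/")^2) / 2)
  list(raw = raw, p = raw / sum(raw))
}

#' Levitt distance weight
#'
#' The polynomial hydrophobic-interaction weight of Levitt's pairwise
#' function: `1 - 1/2 (7 t^2 - 9 t^4 + 5 t^6 - t^8)` with `t = r / c`,
#' equal to 1 at contact and 0 at and beyond the cutoff `c`.
#'
#' @param r pairwise distance(s), Angstrom.
#' @param cutoff cutoff distance `c`, default 9 Angstrom.
#' @return numeric weight(s) in `[0, 1]`.
#' @export
levitt_weight <- function(r, cutoff = 9) {
  t2 <- (r / cutoff)^2
  w <- 1 - 0.5 * (7 * t2 - 9 * t2^2 + 5 * t2^3 - t2^4)
  w[r >= cutoff] <- 0
  w
}

#' Observed hydrophobicity profile
#'
#' Each residue collects the intrinsic hydrophobicity of its spatial
#' neighbours, weighted by Levitt's function of the effective-atom distance:
#' `raw_O_i = sum_j H_j levitt_weight(r_ij)` over pairs within the cutoff.
#' The self term (`j = i`, contributing `H_i`) is included by default.
#' The profile is normalized to unit sum.
#'
#' @param records `fod_residues` data frame with the `h` column set.
#' @param cutoff Levitt cutoff distance, default 9 Angstrom.
#' @param include_self include the `j = i` term (default `TRUE`).
#' @return list with `raw` and `p` (normalized) vectors.
#' @export
observed_profile <- function(records, cutoff = 9, include_self = TRUE) {
  if (any(is.na(records$h)))
    stop("intrinsic hydrophobicity not assigned; see assign_hydrophobicity()")
  xyz <- cbind(records$x, records$y, records$z)
  d <- as.matrix(stats::dist(xyz))
  w <- levitt_weight(d, cutoff)
  if (!include_self) diag(w) <- 0
  raw <- as.numeric(w %*% records$h)
  s <- sum(raw)
  if (s <= 0) stop("observed profile sums to zero (all-zero hydrophobicity?)")
  list(raw = raw, p = raw / s)
}

#' Kullback-Leibler divergence in bits
#'
#' `sum_i P_i log2(P_i / Q_i)` with the convention `0 log 0 = 0`.
#'
#' @param p,q normalized distributions of equal length.
#' @return non-negative divergence, bits.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(q <= 0 & p > 0))
    stop("divergence undefined: q has zero mass where p is positive")
  i <- p > 0
  sum(p[i] * log2(p[i] / q[i]))
}

# ---- profile container ---------------------------------------------------

.new_profile <- function(residues, raw_T, raw_O, frame, label = NULL) {
  n <- nrow(residues)
  structure(list(
    residues = residues,
    T = raw_T / sum(raw_T),
    O = raw_O / sum(raw_O),
    R = rep(1 / n, n),
    raw_T = raw_T, raw_O = raw_O,
    frame = frame, label = label, n = n), class = "hydro_profile")
}

#' Per-residue hydrophobicity profile of a structural unit
#'
#' Builds the aligned theoretical (T), observed (O) and uniform (R)
#' distributions for a set of residue records.  If no frame is supplied the
#' Gaussian frame is fitted on these records (the unit is treated as an
#' individual structural unit).
#'
#' @param records `fod_residues` data frame with hydrophobicity assigned.
#' @param frame optional pre-fitted `gaussian_frame`.
#' @param cutoff Levitt cutoff distance, Angstrom.
#' @param include_self include the self term of the observed sum.
#' @param margin sigma margin passed to [fit_gaussian_frame()].
#' @param label optional unit label.
#' @return an object of class `hydro_profile` with elements `residues`,
#'   `T`, `O`, `R` (each summing to 1), `raw_T`, `raw_O`, `frame`, `n`.
#' @export
hydro_profile <- function(records, frame = NULL, cutoff = 9,
                          include_self = TRUE, margin = 0, label = NULL) {
  if (nrow(records) < 2L) stop("a profile needs at least 2 residues")
  if (is.null(frame)) frame <- fit_gaussian_frame(records, margin = margin)
  tt <- theoretical_profile(records, frame)
  oo <- observed_profile(records, cutoff = cutoff, include_self = include_self)
  .new_profile(records, tt$raw, oo$raw, frame, label = label)
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat("Hydrophobicity profile", if (!is.null(x$label)) paste0("'", x$label, "'"),
      ":", x$n, "residues\n")
  invisible(x)
}

#' RD: relative distance of the observed distribution
#'
#' The micelle-likeness statistic
#' `RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))`.  `RD < 0.5` indicates the
#' observed distribution lies closer to the idealized Gaussian (a hydrophobic
#' core is present); values approaching 1 indicate its absence.
#'
#' @param profile a `hydro_profile`.
#' @return object of class `fod_result`: list with `rd`, `dkl_OT`,
#'   `dkl_OR` (bits) and `n_residues`.
#' @export
rd <- function(profile) {
  stopifnot(inherits(profile, "hydro_profile"))
  d_ot <- kl_divergence(profile$O, profile$T)
  d_or <- kl_divergence(profile$O, profile$R)
  if (d_ot + d_or == 0)
    stop("RD undefined: O is identical to both T and R")
  structure(list(rd = d_ot / (d_ot + d_or), dkl_OT = d_ot, dkl_OR = d_or,
                 n_residues = profile$n), class = "fod_result")
}

#' @export
print.fod_result <- function(x, ...) {
  cat(sprintf("RD = %.3f  (D_KL(O|T) = %.4f, D_KL(O|R) = %.4f bits, n = %d)\n",
              x$rd, x$dkl_OT, x$dkl_OR, x$n_residues))
  invisible(x)
}

.restrict_profile <- function(parent, idx, label = NULL) {
  if (!length(idx)) stop("selection resolves to an empty fragment")
  if (length(idx) < 2L) stop("a fragment profile needs at least 2 residues")
  .new_profile(parent$residues[idx, , drop = FALSE],
               parent$raw_T[idx], parent$raw_O[idx], parent$frame,
               label = label)
}

#' Fragment profile within a parent field
#'
#' Restricts a parent unit's T and O distributions to a fragment and
#' renormalizes them over the fragment (R becomes `1/n_frag`).  The parent's
#' Gaussian frame is kept: this is the "part of parent" view, measuring the
#' fragment's status within the whole unit's field.
#'
#' @param parent a `hydro_profile`.
#' @param selection a `unit_selection` with `mode = "part_of_parent"`, or an
#'   integer vector of positions in the parent profile.
#' @param label optional label for the fragment.
#' @return a `hydro_profile` over the fragment.
#' @export
fragment_profile <- function(parent, selection, label = NULL) {
  stopifnot(inherits(parent, "hydro_profile"))
  idx <- if (is.numeric(selection)) as.integer(selection)
         else {
           if (selection$mode != "part_of_parent")
             stop("fragment_profile() requires mode = 'part_of_parent'")
           resolve_selection(parent$residues, selection)
         }
  if (is.null(label) && !is.numeric(selection)) label <- selection$label
  .restrict_profile(parent, idx, label = label)
}

#' Eliminate residues from a profile
#'
#' Drops the listed residues and renormalizes T and O over the remainder,
#' keeping the parent's Gaussian frame and raw fields (the field of the
#' complete unit).  This is the operation behind "No-CAT" analyses, where
#' catalytic residues are eliminated before the profile comparison.
#'
#' @param parent a `hydro_profile`.
#' @param excluded residue identifiers (`"A:48"` style character vector or
#'   comma-separated string, or a data frame with `chain`, `resno`,
#'   `icode`).
#' @param label optional label.
#' @return a `hydro_profile` over the remaining residues.
#' @export
eliminate_residues <- function(parent, excluded, label = NULL) {
  stopifnot(inherits(parent, "hydro_profile"))
  if (is.character(excluded)) excluded <- parse_residue_ids(excluded)
  if (is.null(excluded) || nrow(excluded) == 0L) {
    out <- parent
    out$label <- label %||% parent$label
    return(out)
  }
  if (!("icode" %in% names(excluded))) excluded$icode <- ""
  key <- .res_key(parent$residues$chain, parent$residues$resno,
                  parent$residues$icode)
  exc <- .res_key(excluded$chain, excluded$resno, excluded$icode)
  missing <- setdiff(exc, key)
  if (length(missing))
    stop("residue(s) to eliminate not found: ", paste(missing, collapse = ", "))
  idx <- which(!(key %in% exc))
  if (!length(idx)) stop("elimination empties the unit")
  .restrict_profile(parent, idx, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-residue profile table
#'
#' Emits a TSV with one row per residue and columns `chain`, `auth_seq_id`,
#' `icode`, `aa3`, `T`, `O`, `R` and, when supplied, `M` plus flag columns
#' marking excluded and catalytic residues.  This is the tabular twin of the
#' usual T/O/M profile plots.
#'
#' @param profile a `hydro_profile`.
#' @param path output path.
#' @param M optional environment-modified distribution aligned with the
#'   profile (e.g. `scan_k(profile)$M_opt`).
#' @param excluded,catalytic optional residue identifier vectors used to set
#'   the flag columns.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, M = NULL, excluded = NULL,
                              catalytic = NULL) {
  res <- profile$residues
  out <- data.frame(chain = res$chain, auth_seq_id = res$resno,
                    icode = res$icode, aa3 = res$aa3,
                    T = profile$T, O = profile$O, R = profile$R)
  if (!is.null(M)) {
    stopifnot(length(M) == profile$n)
    out$M <- M
  }
  key <- .res_key(res$chain, res$resno, res$icode)
  flag <- function(ids) {
    if (is.null(ids)) return(rep(0L, nrow(res)))
    df <- if (is.character(ids)) parse_residue_ids(ids) else ids
    as.integer(key %in% .res_key(df$chain, df$resno, df$icode))
  }
  out$excluded <- flag(excluded)
  out$catalytic <- flag(catalytic)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
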