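# Deterministic synthetic structures with known hydrophobicity
# organization.  These encode the geometry of hydrophobicity only (an
# effective atom per residue, identities chosen to carry the desired
# intrinsic hydrophobicity under the active scale); they are not folded
# chains.  They give every stage of the pipeline a ground truth without any
# structure download.

#' Specify a synthetic structure
#'
#' Geometries: `ellipsoid_cloud` (residues uniform in an ellipsoidal body,
#' the generic globular case), `shell` (hollow surface cloud), `helix`
#' (elongated helical arrangement) and `two_domain` (two offset ellipsoid
#' clouds).  Organizations mirror the canonical folding regimes:
#' `micelle` (hydrophobic residues buried near the centroid, polar outside
#' — aqueous folding), `inverse_micelle` (the swap — hydrophobic/nonpolar
#' environment), `random` (no spatial order) and `polarized` (hydrophobic
#' residues on one side of a plane).
#'
#' The body volume is scaled to ~118 cubic Angstrom per residue (typical
#' globular packing at effective-atom resolution) with semi-axes in ratio
#' 1.25 : 1 : 0.8.
#'
#' @param n_residues number of residues (>= 10); default 120, a typical
#'   single-domain chain length.
#' @param geometry one of `"ellipsoid_cloud"`, `"shell"`, `"helix"`,
#'   `"two_domain"`.
#' @param organization one of `"micelle"`, `"inverse_micelle"`,
#'   `"random"`, `"polarized"`.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param noise_sigma coordinate jitter (sd, Angstrom) added to positions.
#' @param contrast organization strength in `[0, 1]`: probability margin by
#'   which the intended residue class is assigned (1 = deterministic).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 120L,
                           geometry = c("ellipsoid_cloud", "shell", "helix",
                                        "two_domain"),
                           organization = c("micelle", "inverse_micelle",
                                            "random", "polarized"),
                           seed = 1L, noise_sigma = 0, contrast = 1) {
  geometry <- match.arg(geometry)
  organization <- match.arg(organization)
  if (n_residues < 10L) stop("invalid spec: n_residues must be >= 10")
  if (noise_sigma < 0) stop("invalid spec: noise_sigma must be >= 0")
  if (contrast < 0 || contrast > 1) stop("invalid spec: contrast in [0, 1]")
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 organization = organization, seed = as.integer(seed),
                 noise_sigma = noise_sigma, contrast = contrast),
            class = "synthetic_spec")
}

.sample_geometry <- function(spec) {
  n <- spec$n_residues
  r0 <- (3 * 118 * n / (4 * pi))^(1 / 3)   # equivalent-sphere radius
  semi <- r0 * c(1.25, 1, 0.8) / (1.25 * 1 * 0.8)^(1 / 3)
  unit_ball <- function(m) {
    u <- matrix(stats::rnorm(3 * m), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    u * stats::runif(m)^(1 / 3)
  }
  xyz <- switch(spec$geometry,
    ellipsoid_cloud = sweep(unit_ball(n), 2L, semi, "*"),
    shell = {
      u <- matrix(stats::rnorm(3 * n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      sweep(u * stats::runif(n, 0.85, 1), 2L, semi, "*")
    },
    helix = {
      i <- seq_len(n)
      ang <- i * 100 * pi / 180
      cbind(4.6 * cos(ang), 4.6 * sin(ang), 1.5 * (i - (n + 1) / 2))
    },
    two_domain = {
      half <- n %/% 2L
      s <- semi * (0.5)^(1 / 3) * 1.12
      rbind(sweep(unit_ball(half), 2L, s, "*") -
              matrix(c(s[1L] * 1.1, 0, 0), half, 3L, byrow = TRUE),
            sweep(unit_ball(n - half), 2L, s, "*") +
              matrix(c(s[1L] * 1.1, 0, 0), n - half, 3L, byrow = TRUE))
    })
  if (spec$noise_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = spec$noise_sigma), ncol = 3L)
  xyz
}

#' Generate a synthetic structure with known organization
#'
#' Samples effective-atom coordinates per [synthetic_spec()] and assigns
#' residue identities that realize the requested hydrophobicity
#' organization under `scale`.  The target intrinsic hydrophobicity of each
#' position follows the Gaussian burial field of the body (its complement
#' for `inverse_micelle`, a spatial shuffle for `random`, a plane split for
#' `polarized`), and each position receives the standard residue whose
#' scale value is nearest the target, so the organization is encoded with
#' ordinary amino acids.  Optionally writes a standard PDB file (one pseudo-CA
#' per residue at the effective position) and a sidecar truth table.
#'
#' @param spec a `synthetic_spec`.
#' @param scale the active `hydro_scale`.
#' @param pdb_path optional path to write a PDB file.
#' @param truth_path optional path to write the truth TSV (`chain`,
#'   `auth_seq_id`, `intended`, `depth`).
#' @return a `fod_residues` data frame with hydrophobicity assigned and a
#'   `"truth"` attribute (data frame of intended classes and normalized
#'   centroid depth).
#' @export
generate_structure <- function(spec, scale = hydro_scale(),
                               pdb_path = NULL, truth_path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  xyz <- .sample_geometry(spec)
  n <- spec$n_residues
  # standardized ellipsoidal radius, scaled so the body surface sits near 3
  # (mirroring the downstream three-sigma frame rule)
  cc <- sweep(xyz, 2L, colMeans(xyz))
  sd3 <- apply(cc, 2L, stats::sd)
  rho <- sqrt(rowSums(sweep(cc, 2L, sd3, "/")^2))
  rho <- 3 * rho / max(rho)
  core <- exp(-rho^2 / 2)                 # Gaussian burial field, in (0, 1]
  target <- switch(spec$organization,
    micelle = core,
    inverse_micelle = 1 - core,
    random = sample(core),
    polarized = ifelse(cc[, 1L] > 0, 1, 0))
  # contrast < 1 flattens the organization toward an unstructured 0.5
  target <- 0.5 + spec$contrast * (target - 0.5)
  # realize the target hydrophobicity with the standard residue whose scale
  # value is nearest (ties to the first in scale order)
  aa3 <- names(scale$values)[
    apply(abs(outer(target, scale$values, "-")), 1L, which.min)]
  intended <- ifelse(target >= 0.5, "hydrophobic", "polar")
  depth <- rank(rho, ties.method = "first") / n   # 0 = center, 1 = surface
  rec <- .as_fod_residues(data.frame(
    chain = "A", resno = seq_len(n), icode = "", aa3 = aa3,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], h = NA_real_,
    stringsAsFactors = FALSE))
  rec <- assign_hydrophobicity(rec, scale)
  truth <- data.frame(chain = "A", auth_seq_id = seq_len(n),
                      intended = intended, depth = depth)
  attr(rec, "truth") <- truth
  if (!is.null(pdb_path)) write_structure_pdb(rec, pdb_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rec
}

#' Write residue records as a PDB file
#'
#' Emits one pseudo-CA atom per residue at the effective-atom position, so
#' the file round-trips through [read_structure()] (the effective atom of a
#' one-atom residue is that atom).
#'
#' @param records a `fod_residues` data frame.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(records, path) {
  n <- nrow(records)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(records$x, records$y, records$z))),
                   type = rep("ATOM", n), resno = records$resno,
                   resid = records$aa3, chain = records$chain,
                   insert = ifelse(nzchar(records$icode), records$icode, ""),
                   eleno = seq_len(n), elety = rep("CA", n),
                   o = rep(1, n), b = rep(0, n), elesy = rep("C", n))
  invisible(path)
}

#' Generate a profile with a known environment parameter
#'
#' Builds a random valid theoretical distribution T (from a random
#' ellipsoidal cloud and its fitted frame) and sets the observed
#' distribution to `O := M(T, k_true)`, optionally perturbed by
#' multiplicative gamma noise (Dirichlet-style: each component scaled by an
#' independent mean-1 gamma variate with coefficient of variation `noise`)
#' and renormalized.  Used to validate K recovery by [scan_k()].
#'
#' @param n number of residues (default 60).
#' @param k_true true environment parameter.
#' @param seed RNG seed.
#' @param noise relative noise level (0 = exact).
#' @return a `hydro_profile` whose true K is `k_true`.
#' @export
generate_profile_with_known_k <- function(n = 60L, k_true, seed = 1L,
                                          noise = 0) {
  set.seed(seed)
  spec <- synthetic_spec(n_residues = n, geometry = "ellipsoid_cloud",
                         organization = "random", seed = seed)
  xyz <- .sample_geometry(spec)
  frame <- fit_gaussian_frame(xyz)
  T <- theoretical_profile(xyz, frame)$p
  O <- m_profile(T, k_true)
  if (noise > 0) {
    g <- stats::rgamma(n, shape = 1 / noise^2, scale = noise^2)
    O <- O * g
    O <- O / sum(O)
  }
  res <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                    aa3 = "ALA",
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    h = NA_real_, stringsAsFactors = FALSE)
  .new_profile(.as_fod_residues(res), raw_T = T, raw_O = O, frame = frame,
               label = sprintf("synthetic K=%.1f", k_true))
}
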