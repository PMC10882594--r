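# Comparative protocols: complete structure vs catalytic-residue-eliminated
# ("No-CAT"), domains and fragments as part-of-parent vs individual units,
# greedy discordance elimination, and the RD/K three-group classification.

.unit_entry <- function(profile, k_grid = seq(0, 2, by = 0.1),
                        mode = "individual", label = NULL, ...) {
  res <- rd(profile)
  km <- scan_k(profile, k_grid = k_grid)
  structure(list(label = label %||% profile$label %||% "unit",
                 mode = mode, n = profile$n,
                 rd = res$rd, dkl_OT = res$dkl_OT, dkl_OR = res$dkl_OR,
                 k_opt = km$k_opt, dkl_OM = min(km$dkl_OM),
                 classification = classify_fod(res$rd, km$k_opt),
                 profile = profile, fodm = km, ...),
            class = "fod_entry")
}

#' @export
print.fod_entry <- function(x, ...) {
  cat(sprintf("%-24s %-14s n=%4d  RD = %.3f  K = %.1f  [%s]\n",
              x$label, paste0("(", x$mode, ")"), x$n, x$rd, x$k_opt,
              x$classification))
  invisible(x)
}

#' Analyze a complete structural unit
#'
#' Fits the Gaussian frame on the full selection (all records, or the given
#' chains), computes the T/O/R profiles, RD, and the environment parameter
#' K, and classifies the unit.
#'
#' @param records `fod_residues` data frame.
#' @param chains optional chain IDs restricting the unit.
#' @param k_grid K grid passed to [scan_k()].
#' @param cutoff,include_self,margin profile parameters, see
#'   [hydro_profile()].
#' @param label display label.
#' @return a `fod_entry`: label, mode, `n`, `rd`, divergences, `k_opt`,
#'   `classification`, plus the underlying `profile` and `fodm` objects.
#' @export
analyze_complete <- function(records, chains = NULL,
                             k_grid = seq(0, 2, by = 0.1), cutoff = 9,
                             include_self = TRUE, margin = 0,
                             label = "complete") {
  if (!is.null(chains)) {
    sel <- unit_selection(chains = chains)
    records <- records[resolve_selection(records, sel), , drop = FALSE]
  }
  prof <- hydro_profile(records, cutoff = cutoff, include_self = include_self,
                        margin = margin, label = label)
  .unit_entry(prof, k_grid = k_grid, mode = "individual", label = label)
}

#' Analyze a unit with catalytic residues eliminated ("No-CAT")
#'
#' Computes the complete-unit profile, eliminates the catalytic residues
#' (renormalizing T and O under the complete unit's Gaussian field), and
#' recomputes RD and K.  The entry additionally reports `delta_rd`, the RD
#' change relative to the complete unit.
#'
#' @param records `fod_residues` data frame.
#' @param chains optional chain IDs.
#' @param catalytic residue identifiers in author numbering
#'   (`"A:48,A:52,A:82"` style string or character vector).
#' @inheritParams analyze_complete
#' @return a `fod_entry` with extra fields `delta_rd` and `complete`.
#' @export
analyze_no_cat <- function(records, chains = NULL, catalytic = NULL,
                           k_grid = seq(0, 2, by = 0.1), cutoff = 9,
                           include_self = TRUE, margin = 0,
                           label = "no-cat") {
  compl <- analyze_complete(records, chains = chains, k_grid = k_grid,
                            cutoff = cutoff, include_self = include_self,
                            margin = margin, label = "complete")
  if (is.null(catalytic) || !length(catalytic)) {
    out <- compl
    out$label <- label
    out$delta_rd <- 0
    out$complete <- compl
    return(out)
  }
  prof <- eliminate_residues(compl$profile, catalytic, label = label)
  out <- .unit_entry(prof, k_grid = k_grid, mode = "individual",
                     label = label)
  out$delta_rd <- out$rd - compl$rd
  out$complete <- compl
  out
}

#' Analyze fragments as parts of the parent and/or as individual units
#'
#' For each author-numbered fragment the "part" view restricts and
#' renormalizes the parent unit's T and O distributions (parent frame kept),
#' while the "individual" view refits the Gaussian frame on the fragment
#' alone and recomputes both T and O within it.  Overlapping fragments (as
#' arise from disulfide-delimited segments) require `allow_overlap = TRUE`.
#'
#' @param records `fod_residues` data frame.
#' @param fragments character vector of range strings
#'   (`"A:496-579=Dom3"`), see [unit_selection()].
#' @param mode `"both"`, `"part"` or `"individual"`.
#' @param chains optional chain IDs defining the parent unit.
#' @param allow_overlap permit overlapping fragment ranges.
#' @inheritParams analyze_complete
#' @return list of `fod_entry` objects (one per fragment and mode).
#' @export
analyze_fragments <- function(records, fragments,
                              mode = c("both", "part", "individual"),
                              chains = NULL, allow_overlap = FALSE,
                              k_grid = seq(0, 2, by = 0.1), cutoff = 9,
                              include_self = TRUE, margin = 0) {
  mode <- match.arg(mode)
  if (!is.null(chains)) {
    records <- records[resolve_selection(records,
                                         unit_selection(chains = chains)), ,
                       drop = FALSE]
  }
  rng <- .parse_ranges(fragments)
  if (any(rng$start > rng$end))
    stop("invalid range(s): start exceeds end")
  if (!allow_overlap && nrow(rng) > 1L) {
    for (i in seq_len(nrow(rng) - 1L)) for (j in seq(i + 1L, nrow(rng))) {
      if (rng$chain[i] == rng$chain[j] &&
          rng$start[i] <= rng$end[j] && rng$start[j] <= rng$end[i])
        stop("overlapping fragments '", fragments[i], "' and '",
             fragments[j], "'; pass allow_overlap = TRUE if intended")
    }
  }
  parent <- if (mode != "individual")
    hydro_profile(records, cutoff = cutoff, include_self = include_self,
                  margin = margin, label = "parent") else NULL
  out <- list()
  for (i in seq_len(nrow(rng))) {
    lab <- if (nzchar(rng$label[i])) rng$label[i]
           else sprintf("%s:%d-%d", rng$chain[i], rng$start[i], rng$end[i])
    sel_str <- sprintf("%s:%d-%d", rng$chain[i], rng$start[i], rng$end[i])
    if (mode %in% c("both", "part")) {
      sel <- unit_selection(ranges = sel_str, mode = "part_of_parent")
      prof <- fragment_profile(parent, sel, label = lab)
      out[[paste0(lab, "|part")]] <-
        .unit_entry(prof, k_grid = k_grid, mode = "part_of_parent",
                    label = lab)
    }
    if (mode %in% c("both", "individual")) {
      sel <- unit_selection(ranges = sel_str)
      sub <- records[resolve_selection(records, sel), , drop = FALSE]
      prof <- hydro_profile(sub, cutoff = cutoff,
                            include_self = include_self, margin = margin,
                            label = lab)
      out[[paste0(lab, "|individual")]] <-
        .unit_entry(prof, k_grid = k_grid, mode = "individual", label = lab)
    }
  }
  out
}

#' Three-group RD/K classification
#'
#' Classifies a unit by its RD and K values: `micelle_like` when
#' `RD < 0.5` and `K < 0.5` (a hydrophobic core shaped by the aqueous
#' environment), `field_modified` when `RD > 0.7` and `K >= 1.0` (the whole
#' body records a strongly modified external field), and `threshold`
#' otherwise (RD near the 0.5 boundary, local disorder only).  The
#' boundaries are exposed as arguments.
#'
#' @param rd RD value in `[0, 1]`.
#' @param k environment parameter `K >= 0`.
#' @param rd_low,k_low bounds of the micelle-like group.
#' @param rd_high,k_high bounds of the field-modified group.
#' @return one of `"micelle_like"`, `"threshold"`, `"field_modified"`.
#' @export
classify_fod <- function(rd, k, rd_low = 0.5, k_low = 0.5,
                         rd_high = 0.7, k_high = 1.0) {
  stopifnot(is.finite(rd), is.finite(k))
  if (rd < rd_low && k < k_low) "micelle_like"
  else if (rd > rd_high && k >= k_high) "field_modified"
  else "threshold"
}

#' Greedy discordance elimination
#'
#' Iteratively removes, one residue at a time, the residue with the largest
#' absolute discordance `|O_i - T_i|` (on the current renormalized
#' profile), recomputing RD after each removal.  This operationalizes the
#' gradual elimination of residues carrying the largest local
#' excess/deficit of hydrophobicity; it stops once RD drops below
#' `rd_target` or `max_eliminations` residues have been removed.
#'
#' @param profile a `hydro_profile` of the complete unit.
#' @param max_eliminations maximum number of residues to remove.
#' @param rd_target stop once RD falls below this value.
#' @return list with `eliminated` (data frame: chain, resno, icode, aa3,
#'   discordance at removal), `trajectory` (RD after 0, 1, 2, ...
#'   removals) and `profile` (the final reduced profile).
#' @export
scan_eliminate <- function(profile, max_eliminations = 10L,
                           rd_target = 0.5) {
  stopifnot(inherits(profile, "hydro_profile"))
  cur <- profile
  traj <- rd(cur)$rd
  elim <- list()
  while (length(elim) < max_eliminations && traj[length(traj)] >= rd_target &&
         cur$n > 2L) {
    i <- which.max(abs(cur$O - cur$T))
    res <- cur$residues[i, c("chain", "resno", "icode", "aa3")]
    res$discordance <- cur$O[i] - cur$T[i]
    elim[[length(elim) + 1L]] <- res
    cur <- .restrict_profile(cur, setdiff(seq_len(cur$n), i),
                             label = profile$label)
    traj <- c(traj, rd(cur)$rd)
  }
  list(eliminated = if (length(elim)) do.call(rbind, elim)
                    else profile$residues[0, c("chain", "resno", "icode", "aa3")],
       trajectory = traj, profile = cur)
}

# ---- reports -------------------------------------------------------------

#' Assemble an analysis report
#'
#' Bundles unit entries with provenance (structure ID, scale, sigma rule,
#' K grid) for printing and JSON export.
#'
#' @param structure_id identifier of the analyzed structure.
#' @param entries a `fod_entry` or list of entries.
#' @param scale the `hydro_scale` used.
#' @param margin sigma margin used.
#' @param k_grid K grid used.
#' @return an object of class `fod_report`.
#' @export
fod_report <- function(structure_id, entries, scale = hydro_scale(),
                       margin = 0, k_grid = seq(0, 2, by = 0.1)) {
  if (inherits(entries, "fod_entry")) entries <- list(entries)
  structure(list(
    schema = "oildrop-report/1",
    structure_id = structure_id,
    scale = scale$name,
    sigma_rule = sprintf("principal-axes, (max extent + %g)/3", margin),
    k_grid = range(k_grid),
    entries = entries), class = "fod_report")
}

#' @export
print.fod_report <- function(x, ...) {
  cat("FOD analysis report -", x$structure_id,
      sprintf("(scale: %s)\n", x$scale))
  for (e in x$entries) print(e)
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report a `fod_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fod_report <- function(report, path) {
  entries <- lapply(report$entries, function(e) {
    out <- list(label = e$label, mode = e$mode, n = e$n, rd = e$rd,
                dkl_OT = e$dkl_OT, dkl_OR = e$dkl_OR, k_opt = e$k_opt,
                dkl_OM = e$dkl_OM, classification = e$classification)
    if (!is.null(e$delta_rd)) out$delta_rd <- e$delta_rd
    out
  })
  jsonlite::write_json(
    list(schema = report$schema, structure_id = report$structure_id,
         scale = report$scale, sigma_rule = report$sigma_rule,
         k_grid = report$k_grid, units = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
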